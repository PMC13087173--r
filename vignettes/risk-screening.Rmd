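---
title: "Element bioaccumulation and dietary risk screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element bioaccumulation and dietary risk screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotoxfish)
```

## Scope and model

`ecotoxfish` implements the desk-scale screening layer that sits on top of
an ICP-OES element survey of fish tissue: given per-group summary
concentrations (mean, sd, min, max per species × site × tissue × element),
it computes body-condition, bioaccumulation, regulatory-exceedance and
dietary-intake indices, converts kinetic enzyme-assay readings into
activities, and contrasts sites nonparametrically. All indices are simple
deterministic ratios; the scientific content is in the conventions — which
limit applies to which element, what happens at band boundaries, how
non-detects propagate — and those conventions are what this vignette
records.

Assumptions inherited from the screening tradition: concentrations are on
a single wet/dry basis (no conversion is attempted); the muscle mean
concentration represents what a consumer eats (no cooking losses, no
speciation — total As is screened against limits written for total As);
exposure is chronic and summarized by a constant daily ration, with no
exposure-duration weighting (the simpler EDI scheme, not the USEPA
THQ/EF·ED/AT machinery).

## The indices and their parameters

**Fulton condition factor.** `fulton_q()` computes Q = 100·W/L³ (W in g, L
in cm). The formula is defined for total length; the packaged survey
recorded standard length, which inflates Q. The function takes whatever
length is supplied — reproducing the survey's published values (1.40
urban, 2.20 rural) requires the standard-length means it printed.
Bands (`classify_condition()`): the literature gives anchor points (≤ 1
poor, = 1.2 moderate, ≥ 1.4 good), not intervals; we use the exhaustive
partition poor = [0, 1], moderate = (1, 1.4), good = [1.4, ∞), which
contains each anchor in the intended band.

**Bioconcentration factor.** `bcf()` is mean tissue concentration (mg/kg)
over water concentration (mg/L). Zero water concentration is a validation
error (an undefined ratio), never `Inf`. US-EPA classes
(`classify_bcf()`): < 1000, 1000–5000, > 5000, with both boundaries
belonging to the middle "bioaccumulative" class ("between 1000 and 5000"
read inclusively). No kinetic (uptake/depuration) modelling, no lipid
normalization.

**Risk quotient and cumulative index.** `rq()` is C/ML; `ri()` sums RQs
over the detected elements of a tissue × site group. Non-detects
contribute nothing (they are absent values, not zeros). RI bands: < 150
low, 150–300 moderate (boundaries in "moderate"), > 300 above moderate.
Liver rows are computed but flagged `non_edible` — liver is not typically
consumed, so its RQ/RI are an organ-burden diagnostic, not a consumer
risk.

**Which limit applies.** Regulatory limits are jurisdiction-dependent, so
they ship as an override-able JSON config rather than constants
(`ref_tables()`). The packaged table covers As, Cd, Cu, Se, Pb, Zn across
Brazil, MERCOSUL, Chile, FAO and WHO/FAO (Codex). The default RQ policy is
a per-element authority map — As and Pb against the Brazilian limits
(1.0, 2.0 mg/kg), Cu and Se against the Chilean ones (10, 0.3 mg/kg) —
which mirrors the practice of the survey this package is calibrated to.
That survey's risk table carried only these four elements even though Zn
was detected and has a limit; we found no computable rule behind that
choice, so the default map reproduces it explicitly, and
`assess(..., authority = "strictest")` or a single authority name brings
Zn/Cd in on a stated rule instead. Note the Se limit's authority
attribution is ambiguous in the source literature (called both a Brazilian
and an international limit); it is stored once, under Chile, and reports
cite whatever the config says.

**Exceedance.** The canonical convention is excess over the limit,
100·(C − ML)/ML, which satisfies `exceedance = 100·(RQ − 1)` exactly and
matches statements like "1850 % above the FAO limit". Some summaries mix
in the plain ratio convention (100·C/ML); `exceedance_pct(..., as_ratio =
TRUE)` emits that, labelled, rather than silently switching.

**Estimated daily intake.** `edi()` computes C·(IR/1000)/BW in
mg/kg-bw/day. The source literature prints the formula as C/(IR/BW),
which is dimensionally inverted relative to every tabulated value; the
tables are the ground truth, so the product form is implemented. IR stays
in g/day at the interface (mirroring how scenarios are quoted: 63 g/day
general Brazilian population, 416.39 g/day Amazon region) and is
converted internally. Profiles: 70 kg adult, 15 kg child — standard risk
assessment reference weights. `screen_rfd()` adds hazard ratio EDI/RfD
and flags ratios strictly above 1 (the boundary is not flagged). The As
RfD (0.003 mg/kg-bw/day) is revoked but still in screening use; it is
kept with `status = "revoked"` and a warning, never silently dropped.

**Rounding.** Internal computation is full precision; only
`render_report()` rounds, using the conventional table precisions (RQ/RI
2 dp, adult EDI 4 dp, child EDI 3 dp). One consequence worth knowing: an
RI recomputed from rounded displayed components can differ in the last
digit from the full-precision RI (49.28 vs 49.27 for the packaged urban
liver group).

## Biomarkers

`enzyme_activity()` converts the mean absorbance change per minute to U/L
by the kit factor: AChE ×62000, AST and ALT ×1746, ALP ×2757. The kit
documentation quotes these in Brazilian thousands notation ("62.000",
"2,757"); only these magnitudes place the observed activities inside each
kit's stated linearity range, which fixes the reading. Each value gets
exactly one QC flag — `below_detection` (< kit detection limit: AChE 50,
AST 1.756, ALT 0.998, ALP 3.08 U/L), `in_range`, or `above_linearity`
(> 20000, 400, 400, 1500 U/L respectively). The kits' verification lines
(e.g. Y = 1.0028·X − 170.85, r = 0.9964 for AChE) are linearity QC, not
part of the conversion; `apply_calibration = TRUE` inverts them as a
sensitivity analysis. Activities are reported in U/L as assayed;
normalization to nmol/min/mg protein needs a protein measurement the
survey did not report, so `specific_activity()` exposes it as an explicit
user-supplied conversion rather than guessing.

## Statistics

`mann_whitney()` computes U with midranks. The p-value is exact — full
enumeration of all C(n, nx) labelings — when the smaller sample has ≤ 8
observations and there are no ties (the enumeration then costs at most a
few thousand subset sums); otherwise the tie-corrected normal
approximation with continuity correction is used. The two-sided exact p
doubles the smaller tail, capped at 1, matching `stats::wilcox.test`; the
test suite checks the exact path against an independent brute-force
oracle that counts extreme labelings by direct pair comparison, not by
ranks. `correlate()` is the product-moment r (delegated to `stats::cor`
after validating length ≥ 3 and non-zero variance — re-deriving Pearson
would only duplicate base R). Strength labels follow Akoglu's bands; as
published they leave (0.30, 0.40) and (0.60, 0.70) unassigned, so we
close each gap at the upper anchor, exclusive below: weak < 0.40 ≤
moderate < 0.70 ≤ strong. This follows the formula rather than the loose
prose usage that rounds 0.6985 up to "strong". The significance level
defaults to 0.05 in `compare_groups()` but is a parameter. No p-value
adjustment is applied across correlation matrices, and no
normality/homogeneity pre-tests gate the contrast: the pipeline always
runs the nonparametric test.

## The synthetic generator

`default_config()` + `generate_survey()` emulate the packaged survey's
statistical structure:

- **Concentrations** are lognormal per element × tissue × site — right
  skew and positive support are the two features the summary tables
  demand — with log-moments solved from the target mean and sd by moment
  matching. Draws below the element's analytical detection limit are
  censored to non-detects, and a per-cell detection probability (1 where
  the survey detected the element, 0 where it did not) thins the rest.
  Detected cells with tiny printed sds are floored at 5 % CV so the
  lognormal does not degenerate.
- **Biometrics**: lengths uniform over each species' observed range;
  weights follow the cube law a·L³·exp(ε) with a = Q/100 solved from the
  published condition factor (0.0140 urban, 0.0220 rural) and lognormal
  noise of sd 0.05 — a realistic residual spread for within-population
  length–weight fits. A zero-noise config makes every fish hit Q = 100·a
  exactly, which the tests use as a closed-form check.
- **Enzymes**: normal truncated at zero with the published group mean/sd.
- **Water**: the survey's water chemistry came from an unpublished
  companion dataset, so the packaged `water_synthetic.csv` is a labelled
  stand-in back-derived as muscle mean / published muscle BCF. The
  quotients land on conspicuously round values (0.69, 0.2, 0.17,
  0.05 mg/L…), supporting the reconstruction; liver BCF cells that are
  inconsistent with these waters are documented as such and excluded from
  forward-reproduction claims.

Site differences are encoded purely through per-site parameters — the
survey reports no effect sizes, so no explicit effect model is imposed.
The generator does **not** emulate inter-element correlations, spatial or
temporal autocorrelation, fish-level covariance between tissues, or
measurement error structure; a green parameter-recovery test therefore
establishes that the pipeline is numerically faithful to the configured
marginal distributions, not that it would behave identically on real,
correlated field data. Reproducibility is exact: the same seed yields
byte-identical tables.

## Degenerate inputs and tie-breaks

- Empty inputs flow through: empty concentration tables validate to empty
  reports, `ri(numeric())` is 0/low, empty assessments render headers-only
  CSVs.
- Non-detect rows must have mean/sd/min/max all absent; a non-detect with
  a stray sd is flagged by `validate_concentrations()`, which reports
  per-row issues and passes clean rows through unchanged (report-based,
  never silently dropping data without a record).
- A handful of printed summary cells in the packaged survey contradict
  themselves (a max below its own mean, a min above it); those cells are
  stored as missing so the tables satisfy the invariants they are checked
  against. Means and sds are kept as printed.
- All band classifications are total functions on their domain with
  explicitly assigned boundaries (documented above), so no input falls
  between bands.

## Known limitations

- Single-basis concentrations: no wet/dry conversion, no speciation.
- The risk layer screens means, not distributions; no Monte-Carlo
  exposure uncertainty.
- The default authority map reproduces the calibrating survey's element
  selection, including its unexplained omissions; users wanting a
  principled rule should pass `authority = "strictest"`.
- The exact Mann–Whitney path refuses ties (by definition); tied data go
  through the corrected normal approximation even at small n.
- Correlations are computed on whatever paired table the user supplies;
  with only two sites, cross-site correlation structure is not
  statistically meaningful, and the package does not pretend otherwise.
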