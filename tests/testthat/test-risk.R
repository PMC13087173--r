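test_that("rq reproduces the published Se quotients", {
  expect_equal(round(rq(9.30, 0.3), 2), 31.00)
  expect_equal(round(rq(13.91, 0.3), 2), 46.37)
  x <- runif(10, 0.1, 50)
  expect_equal(rq(x, x), rep(1, 10))
  expect_error(rq(1, 0), class = "ecotox_validation_error")
})

test_that("ri sums components, bands correctly, and handles empty input", {
  expect_equal(round(ri(c(1.83, 0.03, 31.00))$ri, 2), 32.86)
  expect_equal(round(ri(c(53.13, 0.08))$ri, 2), 53.21)
  r0 <- ri(numeric())
  expect_equal(r0$ri, 0)
  expect_equal(as.character(r0$band), "low")
  # band boundaries: 150 and 300 are moderate
  expect_equal(as.character(classify_ri(c(149.99, 150, 300, 300.01))),
               c("low", "moderate", "moderate", "above_moderate"))
})

test_that("ri is permutation-invariant, monotone, and >= max component", {
  set.seed(11)
  for (i in 1:20) {
    comp <- runif(sample(2:8, 1), 0, 60)
    r <- ri(comp)
    expect_equal(ri(sample(comp))$ri, r$ri)
    expect_gte(r$ri, max(comp))
    expect_gte(ri(c(comp, runif(1, 0, 5)))$ri, r$ri)
    expect_equal(ri(comp[1])$ri, comp[1])  # singleton == its rq
  }
})

test_that("exceedance_pct matches prose values and the RQ identity", {
  expect_equal(exceedance_pct(3.90, 0.2), 1850)
  expect_equal(exceedance_pct(2.85, 0.5), 470)
  expect_equal(exceedance_pct(0.3, 0.3), 0)
  set.seed(3)
  c <- runif(25, 0, 20); ml <- runif(25, 0.01, 5)
  expect_equal(exceedance_pct(c, ml), 100 * (rq(c, ml) - 1))
  # ratio convention on request
  expect_equal(exceedance_pct(9.30, 0.3, as_ratio = TRUE), 3100)
})

test_that("edi reproduces intake-table cells and scales as C*IR/BW", {
  expect_equal(round(edi(1.83, 416.39, 70), 4), 0.0109)
  expect_equal(round(edi(13.06, 416.39, 15), 3), 0.363)
  expect_equal(edi(0, 63, 70), 0)
  # linear in c and IR; inverse in BW; child/adult ratio = 70/15
  set.seed(5)
  c <- runif(10, 0, 20)
  expect_equal(edi(2 * c, 63, 70), 2 * edi(c, 63, 70))
  expect_equal(edi(c, 2 * 63, 70), 2 * edi(c, 63, 70))
  expect_equal(edi(c, 63, 15) / edi(c, 63, 70), rep(70 / 15, 10))
  expect_error(edi(1, 63, 0), class = "ecotox_validation_error")
})

test_that("screen_rfd computes hazard ratios; boundary not flagged", {
  rfds <- ref_tables()$rfds
  intake <- data.frame(element = c("As", "As", "Al", "Na"),
                       edi = c(0.0016, 0.079, 0.286, 0.1))
  expect_warning(screen_rfd(intake, rfds), "revoked")
  out <- suppressWarnings(screen_rfd(intake, rfds))
  expect_equal(out$hazard_ratio[1], 0.533, tolerance = 1e-3)
  expect_false(out$exceeds_rfd[1])
  expect_equal(out$hazard_ratio[2], 26.3, tolerance = 1e-2)
  expect_true(out$exceeds_rfd[2])
  expect_false(out$exceeds_rfd[3])       # edi == rfd boundary
  expect_true(is.na(out$exceeds_rfd[4])) # no RfD configured for Na
})

test_that("assess drives the whole risk layer over the survey tables", {
  a <- assess(survey_concentrations())
  expect_s3_class(a, "ecotox_assessment")

  ri_um <- a$ri[a$ri$tissue == "muscle" & a$ri$site == "urban", ]
  expect_equal(round(ri_um$ri, 2), 32.86)
  expect_equal(as.character(ri_um$band), "low")

  # liver rows computed but flagged non-edible
  expect_true(all(a$rq$non_edible[a$rq$tissue == "liver"]))
  expect_true(all(!a$rq$non_edible[a$rq$tissue == "muscle"]))

  # EDI grid covers detected muscle RfD elements x 2 scenarios x 2 profiles;
  # rural Zn is a non-detect, so 8 urban + 7 rural element cells
  expect_setequal(unique(a$edi$element),
                  c("Al", "As", "Cr", "Ni", "Fe", "Mn", "Cu", "Zn"))
  expect_false(any(a$edi$element == "Zn" & a$edi$site == "rural"))
  expect_equal(nrow(a$edi), (8 + 7) * 2 * 2)

  # published adult scenario-2 cells at the printed rounding
  g <- function(el, st, sc, pr)
    a$edi$edi[a$edi$element == el & a$edi$site == st &
              a$edi$scenario == sc & a$edi$profile == pr]
  expect_equal(round(g("As", "urban", "amazon", "adult"), 4), 0.0109)
  expect_equal(round(g("Fe", "rural", "amazon", "adult"), 4), 0.0720)
  expect_equal(round(g("Al", "urban", "general", "adult"), 4), 0.0065)
  expect_equal(round(g("Al", "rural", "amazon", "child"), 3), 0.363)

  # deterministic ordering contract
  expect_equal(a$rq, order_by(a$rq, c("element", "tissue", "site")))
  expect_equal(a$edi, order_by(a$edi, c("element", "site", "scenario", "profile")))
})

test_that("assess authority policies: strictest and single-authority", {
  tab <- survey_concentrations()
  strict <- assess(tab, authority = "strictest")
  # strictest ML for Pb is FAO 0.2 -> urban liver RQ 3.90/0.2 = 19.5
  pb <- strict$rq[strict$rq$element == "Pb" & strict$rq$tissue == "liver", ]
  expect_equal(pb$ml, 0.2)
  expect_equal(round(pb$rq, 2), 19.50)
  # Zn enters under strictest (Chile 100) but not under the default map
  expect_true("Zn" %in% strict$rq$element)
  expect_false("Zn" %in% assess(tab)$rq$element)

  codex <- assess(tab, authority = "WHO_FAO_Codex")
  expect_setequal(unique(codex$rq$authority), "WHO_FAO_Codex")
  as_um <- codex$rq[codex$rq$element == "As" & codex$rq$tissue == "muscle" &
                      codex$rq$site == "urban", ]
  expect_equal(round(as_um$rq, 2), 3.66)  # 1.83 / 0.5
  expect_error(assess(tab, authority = "EU"), class = "ecotox_validation_error")
})

test_that("assess on a table with zero detected elements returns an empty report", {
  rows <- make_conc_rows(list(element = "Se", mean = NA, sd = NA, min = NA, max = NA),
                         list(element = "As", mean = NA, sd = NA, min = NA, max = NA))
  a <- assess(rows)
  expect_equal(nrow(a$rq), 0L)
  expect_equal(nrow(a$edi), 0L)
  expect_true(all(a$ri$ri == 0) || nrow(a$ri) == 0L)
})

test_that("rq * ml recovers the input concentration (RiskResult invariant)", {
  a <- assess(survey_concentrations())
  expect_equal(a$rq$rq * a$rq$ml, a$rq$conc)
  # ri equals the sum of its components per tissue x site
  for (i in seq_len(nrow(a$ri))) {
    g <- a$ri[i, ]
    comp <- a$rq$rq[a$rq$tissue == g$tissue & a$rq$site == g$site]
    expect_equal(g$ri, sum(comp))
    expect_equal(g$n_components, length(comp))
  }
})
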