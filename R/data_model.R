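#' Load regulatory reference tables
#'
#' Reads the reference configuration used throughout the risk layer:
#' maximum permissible limits (ML, mg/kg) per element and authority,
#' oral reference doses (RfD, mg/kg-bw/day), fish-consumption scenarios
#' (ingestion rate, g/day) and consumer body-weight profiles (kg). With no
#' argument the packaged defaults are returned: MLs for As/Cd/Cu/Se/Pb/Zn
#' across the Brazilian, MERCOSUL, Chilean, FAO and WHO/FAO (Codex)
#' frameworks; RfDs for Al, As, Cr, Ni, Fe, Mn, Cu, Zn; a general-population
#' scenario (63 g/day) and an Amazon high-consumption scenario
#' (416.39 g/day); adult (70 kg) and child (15 kg) profiles.
#'
#' The As RfD (0.003 mg/kg-bw/day) has been revoked by its issuing body but
#' remains widely used for screening; it is kept with `status = "revoked"`
#' and downstream reports warn when it is applied.
#'
#' @param path Optional path to a JSON file with the same shape as
#'   `system.file("extdata", "reference_tables.json", package = "ecotoxfish")`.
#' @return An object of class `ecotox_ref`: a list with data frames
#'   `limits` (element, authority, ml), `rfds` (element, rfd, source,
#'   status), `scenarios` (name, ingestion_rate, population), `profiles`
#'   (label, body_weight), and `rq_authority` (the per-element authority
#'   used by default when computing risk quotients).
#' @examples
#' ref <- ref_tables()
#' subset(ref$limits, element == "Pb" & authority == "FAO")$ml  # 0.2
#' @export
ref_tables <- function(path = NULL) {
  path <- path %||% extdata_file("reference_tables.json")
  if (!file.exists(path)) stop_io("reference config not found: %s", path)
  cfg <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_config("cannot parse reference config %s: %s",
                                                  path, conditionMessage(e)))
  limits <- as.data.frame(cfg$limits)
  rfds <- as.data.frame(cfg$rfds)
  scenarios <- as.data.frame(cfg$scenarios)
  profiles <- as.data.frame(cfg$profiles)
  rq_authority <- as.data.frame(cfg$rq_authority %||%
                                  data.frame(element = character(), authority = character()))

  for (nm in c("limits", "rfds", "scenarios", "profiles"))
    if (!nrow(get(nm))) stop_config("reference config is missing table '%s'", nm)

  limits$element <- normalize_element(limits$element)
  rfds$element <- normalize_element(rfds$element)
  if (nrow(rq_authority)) rq_authority$element <- normalize_element(rq_authority$element)

  bad_auth <- setdiff(unique(c(limits$authority, rq_authority$authority)), .authorities)
  if (length(bad_auth))
    stop_config("unknown authority key(s): %s", paste(bad_auth, collapse = ", "))

  key <- paste(limits$element, limits$authority)
  if (anyDuplicated(key))
    stop_config("duplicate (element, authority) limit rows: %s",
                paste(unique(key[duplicated(key)]), collapse = ", "))
  if (anyDuplicated(rfds$element))
    stop_config("duplicate RfD rows for element(s): %s",
                paste(unique(rfds$element[duplicated(rfds$element)]), collapse = ", "))

  if (any(!is.finite(limits$ml) | limits$ml <= 0))
    stop_validation("all MLs must be positive")
  if (any(!is.finite(rfds$rfd) | rfds$rfd <= 0))
    stop_validation("all RfDs must be positive")
  if (any(!is.finite(scenarios$ingestion_rate) | scenarios$ingestion_rate <= 0))
    stop_validation("all ingestion rates must be positive")
  if (any(!is.finite(profiles$body_weight) | profiles$body_weight <= 0))
    stop_validation("all body weights must be positive")
  if (is.null(rfds$status)) rfds$status <- "active"

  structure(list(limits = limits, rfds = rfds, scenarios = scenarios,
                 profiles = profiles, rq_authority = rq_authority),
            class = "ecotox_ref")
}

#' Write reference tables back to JSON
#'
#' Inverse of [ref_tables()]; round-tripping is lossless.
#'
#' @param ref An `ecotox_ref` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ref_tables <- function(ref, path) {
  stopifnot(inherits(ref, "ecotox_ref"))
  jsonlite::write_json(unclass(ref), path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a tissue-concentration table
#'
#' Checks the per-row invariants of a concentration summary table: known
#' element symbol, tissue in \{muscle, liver\}, `detection_limit > 0`,
#' `sd >= 0`, and `min <= mean <= max` where present. A row whose `mean` is
#' missing is a non-detect and must have `min`, `max` and `sd` missing too
#' (non-detects are stored as absent values, never as zero). Validation is
#' report-based: offending rows are flagged, clean rows pass through
#' unchanged.
#'
#' @param rows Data frame with columns `species`, `site`, `tissue`,
#'   `element`, `mean`, `sd`, `min`, `max`, `detection_limit`.
#' @return A list with `records` (the input with a logical `detected`
#'   column, elements case-normalized) and `issues` (data frame `row`,
#'   `reason`; zero rows when clean).
#' @examples
#' tab <- survey_concentrations()
#' validate_concentrations(tab)$issues  # empty
#' @export
validate_concentrations <- function(rows) {
  required <- c("species", "site", "tissue", "element", "mean", "sd",
                "min", "max", "detection_limit")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols))
    stop_validation("missing column(s): %s", paste(missing_cols, collapse = ", "))

  issues <- data.frame(row = integer(), reason = character())
  flag <- function(i, why) rbind(issues, data.frame(row = i, reason = why))

  if (!nrow(rows)) {
    rows$detected <- logical()
    return(list(records = rows, issues = issues))
  }

  rows$element <- normalize_element(rows$element, strict = FALSE)
  rows$detected <- !is.na(rows$mean)

  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (!(r$element %in% .element_symbols))
      issues <- flag(i, sprintf("unknown element symbol '%s'", r$element))
    if (!(r$tissue %in% .tissues))
      issues <- flag(i, sprintf("tissue must be one of %s", paste(.tissues, collapse = "/")))
    if (is.na(r$detection_limit) || r$detection_limit <= 0)
      issues <- flag(i, "detection_limit must be > 0")
    if (r$detected) {
      if (!is.na(r$sd) && r$sd < 0) issues <- flag(i, "sd must be >= 0")
      if (!is.na(r$min) && r$min > r$mean) issues <- flag(i, "min > mean")
      if (!is.na(r$max) && r$max < r$mean) issues <- flag(i, "max < mean")
      if (!is.na(r$min) && !is.na(r$max) && r$min > r$max) issues <- flag(i, "min > max")
      if (r$mean < 0) issues <- flag(i, "mean must be >= 0")
    } else {
      if (any(!is.na(c(r$min, r$max, r$sd))))
        issues <- flag(i, "non-detect row must have sd/min/max absent")
    }
  }
  clean <- !(seq_len(nrow(rows)) %in% issues$row)
  list(records = rows[clean, , drop = FALSE], issues = issues)
}

#' Packaged two-site field survey tables
#'
#' Summary tables from a field survey of two native characiform species
#' from the middle Tocantins River (Brazil): element concentrations
#' (mg/kg) in muscle and liver, fish biometrics, and enzyme-biomarker
#' activities, each summarized per group as mean, sd, min, max. One species
#' was sampled at an urban site (*Psectrogaster amazonica*) and one at a
#' rural site (*Caenotropus labyrhinthicus*), 15 fish per site.
#' Non-detects are stored as missing values. A few printed min/max cells
#' that contradict their own mean are stored as missing.
#'
#' `survey_water()` is a *synthetic* stand-in for the unpublished companion
#' water-chemistry data: values (mg/L) are back-derived as muscle mean
#' concentration divided by the published muscle bioconcentration factor.
#'
#' @return A data frame.
#' @export
survey_concentrations <- function() {
  read_concentration_table(extdata_file("tissue_concentrations.csv"))
}

#' @rdname survey_concentrations
#' @export
survey_biometrics <- function() {
  utils::read.csv(extdata_file("biometrics.csv"), stringsAsFactors = FALSE)
}

#' @rdname survey_concentrations
#' @export
survey_water <- function() {
  w <- utils::read.csv(extdata_file("water_synthetic.csv"), stringsAsFactors = FALSE)
  w$element <- normalize_element(w$element)
  w
}

#' @rdname survey_concentrations
#' @export
survey_enzymes <- function() {
  utils::read.csv(extdata_file("enzyme_activities.csv"), stringsAsFactors = FALSE)
}
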