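#' Kinetic assay kit specifications
#'
#' Conversion factors and quality-control metadata for the four enzyme
#' kits: acetylcholinesterase (AChE, 405 nm), aspartate aminotransferase
#' (AST, 340 nm), alanine aminotransferase (ALT, 340 nm) and alkaline
#' phosphatase (ALP, 405 nm). `conversion_factor` turns the mean change in
#' absorbance per minute into U/L; `detection_limit` and `linearity_max`
#' bound the kit's valid range; the calibration columns hold each kit's
#' linearity-verification line (slope, intercept, r), which is QC metadata,
#' not part of the conversion.
#'
#' @param path Optional JSON file overriding the packaged specs.
#' @return Data frame with one row per enzyme.
#' @export
assay_specs <- function(path = NULL) {
  path <- path %||% extdata_file("assay_specs.json")
  cfg <- jsonlite::fromJSON(path)
  s <- as.data.frame(cfg$specs)
  cal <- s$calibration
  s$calibration <- NULL
  s$cal_slope <- cal$slope
  s$cal_intercept <- cal$intercept
  s$cal_r <- cal$r
  if (any(s$conversion_factor <= 0)) stop_validation("conversion factors must be > 0")
  if (any(s$detection_limit >= s$linearity_max))
    stop_validation("detection limit must be below linearity max")
  s
}

#' Convert kinetic readings to enzyme activities
#'
#' Activity (U/L) is the absolute mean absorbance change per minute times
#' the kit's conversion factor. Each value gets exactly one QC flag:
#' `below_detection`, `in_range`, or `above_linearity`.
#'
#' @param delta_A_per_min Mean absorbance change per minute. Vectorized.
#' @param enzyme One of "AChE", "AST", "ALT", "ALP" (scalar or vector of
#'   the same length).
#' @param specs Kit specification table, see [assay_specs()].
#' @param apply_calibration If `TRUE`, additionally invert the kit's
#'   verification line (activity - intercept)/slope as a sensitivity
#'   correction. Off by default: the line documents linearity, it is not
#'   the conversion.
#' @return Data frame `enzyme`, `delta_A_per_min`, `activity` (U/L), `qc`.
#' @examples
#' enzyme_activity(0.01, "AChE")$activity  # 620
#' @export
enzyme_activity <- function(delta_A_per_min, enzyme, specs = assay_specs(),
                            apply_calibration = FALSE) {
  if (any(!is.finite(delta_A_per_min))) stop_validation("delta_A_per_min must be finite")
  enzyme <- as.character(enzyme)
  if (length(enzyme) == 1L) enzyme <- rep(enzyme, length(delta_A_per_min))
  if (length(enzyme) != length(delta_A_per_min))
    stop_validation("enzyme and delta_A_per_min lengths differ")
  i <- match(enzyme, specs$enzyme)
  if (anyNA(i))
    stop_validation("unknown enzyme(s): %s",
                    paste(unique(enzyme[is.na(i)]), collapse = ", "))
  activity <- abs(delta_A_per_min) * specs$conversion_factor[i]
  if (apply_calibration)
    activity <- (activity - specs$cal_intercept[i]) / specs$cal_slope[i]
  qc <- ifelse(activity < specs$detection_limit[i], "below_detection",
               ifelse(activity > specs$linearity_max[i], "above_linearity",
                      "in_range"))
  data.frame(enzyme = enzyme, delta_A_per_min = delta_A_per_min,
             activity = activity, qc = qc)
}

#' Specific activity per mg protein
#'
#' Converts a volumetric activity (U/L, i.e. umol/min/L, i.e. nmol/min/mL)
#' into nmol/min/mg protein given the homogenate protein concentration.
#' The survey kits report U/L; protein content must be measured separately.
#'
#' @param activity Activity, U/L. Vectorized.
#' @param protein_mg_per_ml Protein concentration of the homogenate, mg/mL.
#' @return Specific activity, nmol/min/mg protein.
#' @export
specific_activity <- function(activity, protein_mg_per_ml) {
  if (any(!is.finite(protein_mg_per_ml) | protein_mg_per_ml <= 0))
    stop_validation("protein concentration must be > 0")
  activity / protein_mg_per_ml
}

#' Summarize enzyme activities per group
#'
#' Group statistics (mean, sample sd, min, max, n) of activities by
#' species, site, enzyme and tissue. Singleton groups get sd 0 and a
#' `single_replicate` flag; empty groups are dropped with a warning.
#'
#' @param rows Data frame with columns `species`, `site`, `enzyme`,
#'   `tissue`, `activity`.
#' @return Summary data frame, deterministically ordered.
#' @export
summarize_activities <- function(rows) {
  required <- c("species", "site", "enzyme", "tissue", "activity")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols))
    stop_validation("missing column(s): %s", paste(missing_cols, collapse = ", "))
  keys <- interaction(rows$species, rows$site, rows$enzyme, rows$tissue, drop = FALSE)
  sp <- split(rows, keys)
  empty <- vapply(sp, function(d) nrow(d) == 0L || all(is.na(d$activity)), logical(1))
  if (any(empty))
    warning(sprintf("%d empty group(s) omitted", sum(empty)), call. = FALSE)
  sp <- sp[!empty]
  out <- do.call(rbind, lapply(sp, function(d) {
    a <- d$activity[!is.na(d$activity)]
    data.frame(species = d$species[1], site = d$site[1], enzyme = d$enzyme[1],
               tissue = d$tissue[1], n = length(a), mean = mean(a),
               sd = if (length(a) > 1) stats::sd(a) else 0,
               min = min(a), max = max(a),
               single_replicate = length(a) == 1L)
  }))
  rownames(out) <- NULL
  order_by(out, c("species", "site", "enzyme", "tissue"))
}
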