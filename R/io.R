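#' Read a tissue-concentration table
#'
#' Reads a delimited concentration summary with header
#' `species,site,tissue,element,mean,sd,min,max,detection_limit`. Empty
#' cells and the en-dash/hyphen non-detect markers used in printed tables
#' become missing values. Numbers always use "." as the decimal separator,
#' regardless of locale.
#'
#' @param path CSV file path.
#' @return Typed data frame with a logical `detected` column.
#' @export
read_concentration_table <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  required <- c("species", "site", "tissue", "element", "mean", "sd",
                "min", "max", "detection_limit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop_io("missing column(s) in %s: %s", path, paste(missing_cols, collapse = ", "))
  num_cols <- c("mean", "sd", "min", "max", "detection_limit")
  for (col in num_cols) {
    v <- raw[[col]]
    v[v %in% c("", "-", "–", "—", "NA")] <- NA
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad))
      stop_io("unparseable number in %s, column '%s', data line %d: '%s'",
              path, col, bad[1], v[bad[1]])
    raw[[col]] <- parsed
  }
  raw$element <- normalize_element(raw$element)
  raw$detected <- !is.na(raw$mean)
  raw
}

#' Write a tissue-concentration table
#'
#' Inverse of [read_concentration_table()]; missing values are written as
#' empty fields so the round trip is the identity on validated records.
#'
#' @param df Concentration data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(df, path) {
  df <- df[setdiff(names(df), "detected")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Report rounding policy: RQ/RI to 2 dp, adult EDI to 4 dp, child EDI to
# 3 dp (internal computation keeps full precision).
.round_rq <- function(x) round(x, 2)

#' Render an assessment to files
#'
#' Writes `rq.csv`, `ri.csv`, `edi_adult.csv`, `edi_child.csv` and
#' `exceedance.csv` under `dir`, applying the report rounding policy
#' (RQ/RI 2 dp, adult intake 4 dp, child intake 3 dp). With
#' `style = "text"` an additional `summary.txt` mirrors the conventional
#' survey-table layout and spells out the classification legends. Output
#' is deterministic: the same assessment renders byte-identical files.
#'
#' @param a An `ecotox_assessment` from [assess()].
#' @param dir Output directory (created if needed).
#' @param style `"csv"` or `"text"` (text adds the summary on top of the
#'   CSVs).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(a, dir, style = c("csv", "text")) {
  stopifnot(inherits(a, "ecotox_assessment"))
  style <- match.arg(style)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }

  rq_out <- a$rq
  rq_out$rq <- .round_rq(rq_out$rq)
  rq_out$exceedance_pct <- round(rq_out$exceedance_pct, 1)
  w(rq_out, "rq.csv")

  ri_out <- a$ri
  ri_out$ri <- .round_rq(ri_out$ri)
  w(ri_out, "ri.csv")

  for (prof in c("adult", "child")) {
    e <- a$edi[a$edi$profile == prof, , drop = FALSE]
    dp <- if (prof == "adult") 4 else 3
    e$edi <- round(e$edi, dp)
    e$hazard_ratio <- round(e$hazard_ratio, 3)
    w(e, paste0("edi_", prof, ".csv"))
  }

  exc <- a$exceedance
  exc$exceedance_pct <- round(exc$exceedance_pct, 1)
  w(exc, "exceedance.csv")

  if (style == "text") {
    path <- file.path(dir, "summary.txt")
    con <- file(path, "w")
    on.exit(close(con))
    out <- function(...) cat(..., "\n", sep = "", file = con)
    out("Ecotoxicological risk assessment summary")
    out("Authority policy: ", a$authority)
    out("")
    out("Cumulative risk index (RI = sum of RQ over detected elements)")
    out("  legend: RI < 150 low risk; 150-300 moderate; > 300 above moderate")
    for (i in seq_len(nrow(a$ri)))
      out(sprintf("  %-6s %-6s RI = %8.2f  %s%s", a$ri$tissue[i], a$ri$site[i],
                  a$ri$ri[i], a$ri$band[i],
                  if (a$ri$non_edible[i]) "  [non-edible tissue]" else ""))
    out("")
    out("Risk quotients (RQ = C/ML; RQ >= 1 flags potential adverse effects)")
    for (i in seq_len(nrow(rq_out)))
      out(sprintf("  %-2s %-6s %-6s C = %9.2f mg/kg  ML = %6.2f (%s)  RQ = %8.2f",
                  rq_out$element[i], rq_out$tissue[i], rq_out$site[i],
                  rq_out$conc[i], rq_out$ml[i], rq_out$authority[i],
                  rq_out$rq[i]))
    out("")
    out("Estimated daily intake (EDI = C x IR/BW, mg/kg-bw/day) vs RfD")
    revoked <- unique(a$edi$element[!is.na(a$edi$exceeds_rfd) & a$edi$element == "As"])
    if (length(revoked))
      out("  note: the As RfD (0.003) is revoked; shown for screening only")
    for (i in seq_len(nrow(a$edi))) {
      e <- a$edi[i, ]
      out(sprintf("  %-2s %-6s %-8s %-5s EDI = %8.4f%s", e$element, e$site,
                  e$scenario, e$profile, e$edi,
                  if (!is.na(e$exceeds_rfd) && e$exceeds_rfd)
                    sprintf("  EXCEEDS RfD %.3f", e$rfd) else ""))
    }
    files <- c(files, path)
  }
  invisible(files)
}

#' Write a raw synthetic survey to a directory
#'
#' @param raw Output of [generate_survey()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_survey <- function(raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in c("tissue", "biometrics", "enzymes", "water")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(raw[[nm]], path, row.names = FALSE, na = "")
    files <- c(files, path)
  }
  summary_path <- file.path(dir, "tissue_summary.csv")
  write_concentration_table(summarize_survey(raw), summary_path)
  invisible(c(files, summary_path))
}
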