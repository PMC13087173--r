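#' Risk quotient
#'
#' RQ = C / ML: the concentration of an element in edible tissue over its
#' maximum permissible limit. RQ >= 1 flags potential adverse effects for
#' consumers.
#'
#' @param c Concentration, mg/kg, >= 0. Vectorized.
#' @param ml Maximum permissible limit, mg/kg, > 0.
#' @return RQ, dimensionless.
#' @examples
#' rq(9.30, 0.3)  # 31
#' @export
rq <- function(c, ml) {
  if (any(!is.finite(ml) | ml <= 0)) stop_validation("ML must be > 0")
  if (any(!is.finite(c) | c < 0)) stop_validation("concentration must be >= 0")
  c / ml
}

#' Cumulative risk index
#'
#' RI = sum of the individual risk quotients of the elements detected in a
#' tissue. Bands: `low` below 150, `moderate` for 150-300 (inclusive),
#' `above_moderate` beyond.
#'
#' @param rqs Numeric vector of RQ values (possibly empty).
#' @return A list with `ri` (the sum, 0 for empty input), `band`, and `n`
#'   (number of components).
#' @examples
#' ri(c(1.83, 0.031, 31))$ri  # 32.861
#' @export
ri <- function(rqs) {
  rqs <- rqs[!is.na(rqs)]
  if (any(rqs < 0)) stop_validation("RQ components must be >= 0")
  total <- sum(rqs)
  list(ri = total, band = classify_ri(total), n = length(rqs))
}

#' @rdname ri
#' @param x An RI value, >= 0. Vectorized.
#' @export
classify_ri <- function(x) {
  if (any(!is.finite(x) | x < 0)) stop_validation("RI must be >= 0")
  factor(ifelse(x < 150, "low", ifelse(x <= 300, "moderate", "above_moderate")),
         levels = c("low", "moderate", "above_moderate"))
}

#' Exceedance percentage over a regulatory limit
#'
#' Excess of a concentration over its limit, as a percentage of the limit:
#' 100 (C - ML) / ML. Negative when the concentration is below the limit.
#' Related to the risk quotient by `exceedance = 100 * (rq - 1)`. Some
#' reports instead quote the plain ratio as a percentage (100 C / ML);
#' `as_ratio = TRUE` gives that convention.
#'
#' @param c Concentration, mg/kg. Vectorized.
#' @param ml Maximum permissible limit, mg/kg, > 0.
#' @param as_ratio Use the ratio convention instead of excess-over-limit.
#' @return Percent.
#' @examples
#' exceedance_pct(3.90, 0.2)  # 1850
#' @export
exceedance_pct <- function(c, ml, as_ratio = FALSE) {
  if (any(!is.finite(ml) | ml <= 0)) stop_validation("ML must be > 0")
  if (as_ratio) 100 * c / ml else 100 * (c - ml) / ml
}

#' Estimated daily intake
#'
#' EDI = C x IR / BW in mg per kg body weight per day, where C is the
#' element concentration in muscle (mg/kg), IR the fish ingestion rate
#' (supplied in g/day and converted to kg/day internally), and BW the
#' consumer body weight (kg).
#'
#' @param c Concentration in muscle, mg/kg, >= 0. Vectorized.
#' @param ingestion_rate Ingestion rate, g/day, > 0.
#' @param body_weight Body weight, kg, > 0.
#' @return EDI, mg/kg-bw/day.
#' @examples
#' edi(1.83, 416.39, 70)  # 0.0109 for a high-consumption adult
#' @export
edi <- function(c, ingestion_rate, body_weight) {
  if (any(!is.finite(c) | c < 0)) stop_validation("concentration must be >= 0")
  if (any(!is.finite(ingestion_rate) | ingestion_rate <= 0))
    stop_validation("ingestion rate must be > 0")
  if (any(!is.finite(body_weight) | body_weight <= 0))
    stop_validation("body weight must be > 0")
  c * (ingestion_rate / 1000) / body_weight
}

#' Screen intakes against oral reference doses
#'
#' Completes an intake table with the hazard ratio EDI/RfD and an
#' exceedance flag (`hazard_ratio > 1`; the boundary is not flagged).
#' Elements with no configured RfD get `NA` in all three columns. Using a
#' revoked RfD raises a warning.
#'
#' @param intake Data frame with columns `element` and `edi`.
#' @param rfds Reference-dose table, e.g. `ref_tables()$rfds`.
#' @return `intake` with columns `rfd`, `hazard_ratio`, `exceeds_rfd` added.
#' @export
screen_rfd <- function(intake, rfds) {
  stopifnot(all(c("element", "edi") %in% names(intake)))
  i <- match(normalize_element(intake$element, strict = FALSE), rfds$element)
  intake$rfd <- rfds$rfd[i]
  intake$hazard_ratio <- intake$edi / intake$rfd
  intake$exceeds_rfd <- intake$hazard_ratio > 1
  revoked <- !is.na(i) & rfds$status[i] == "revoked"
  if (any(revoked))
    warning(sprintf("revoked RfD used for: %s",
                    paste(unique(intake$element[revoked]), collapse = ", ")),
            call. = FALSE)
  intake
}

# Resolve the ML used for each element under an authority policy.
select_ml <- function(ref, authority) {
  lim <- ref$limits
  if (identical(authority, "default")) {
    map <- ref$rq_authority
    m <- merge(map, lim, by = c("element", "authority"))
    if (nrow(m) < nrow(map))
      stop_config("rq_authority refers to (element, authority) pairs absent from limits")
    return(m[c("element", "authority", "ml")])
  }
  if (identical(authority, "strictest")) {
    sp <- split(lim, lim$element)
    out <- do.call(rbind, lapply(sp, function(d) d[which.min(d$ml), ]))
    rownames(out) <- NULL
    return(out[c("element", "authority", "ml")])
  }
  if (!authority %in% .authorities)
    stop_validation("unknown authority '%s'", authority)
  lim[lim$authority == authority, c("element", "authority", "ml")]
}

#' Full risk assessment of a tissue-concentration table
#'
#' Drives the whole human-health risk layer over a validated concentration
#' summary: per-element risk quotients and exceedance percentages against
#' the selected maximum permissible limits, cumulative risk indices per
#' tissue x site, and an estimated-daily-intake grid over every consumption
#' scenario x consumer profile for muscle concentrations of RfD-bearing
#' elements, screened against the reference doses. Liver rows are computed
#' for completeness but flagged `non_edible = TRUE` (liver is not typically
#' consumed). Non-detects never contribute. Row order is deterministic.
#'
#' @param tissue Concentration summary table (schema of
#'   [validate_concentrations()]).
#' @param ref Reference tables, see [ref_tables()].
#' @param authority `"default"` (the packaged per-element authority map,
#'   which mirrors common practice: As and Pb against the Brazilian limits,
#'   Cu and Se against the Chilean ones), `"strictest"` (lowest ML available
#'   per element), or a single authority name.
#' @return An object of class `ecotox_assessment`: list of data frames
#'   `rq`, `ri`, `edi`, `exceedance`, plus `issues` from validation.
#' @examples
#' a <- assess(survey_concentrations())
#' subset(a$ri, tissue == "muscle")
#' @export
assess <- function(tissue, ref = ref_tables(), authority = "default") {
  stopifnot(inherits(ref, "ecotox_ref"))
  v <- validate_concentrations(tissue)
  rows <- v$records[v$records$detected, , drop = FALSE]
  mls <- select_ml(ref, authority)

  m <- merge(rows[c("element", "tissue", "site", "mean")], mls, by = "element")
  rq_tab <- data.frame(element = m$element, tissue = m$tissue, site = m$site,
                       conc = m$mean, ml = m$ml, authority = m$authority,
                       rq = rq(m$mean, m$ml),
                       non_edible = m$tissue == "liver")
  rq_tab$exceedance_pct <- exceedance_pct(rq_tab$conc, rq_tab$ml)
  rq_tab <- order_by(rq_tab, c("element", "tissue", "site"))

  groups <- unique(rows[c("tissue", "site")])
  groups <- order_by(groups, c("tissue", "site"))
  ri_empty <- data.frame(tissue = character(), site = character(), ri = numeric(),
                         band = character(), n_components = integer(),
                         non_edible = logical())
  ri_tab <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    comp <- rq_tab$rq[rq_tab$tissue == g$tissue & rq_tab$site == g$site]
    r <- ri(comp)
    data.frame(tissue = g$tissue, site = g$site, ri = r$ri,
               band = as.character(r$band), n_components = r$n,
               non_edible = g$tissue == "liver")
  })) %||% ri_empty
  rownames(ri_tab) <- NULL

  muscle <- rows[rows$tissue == "muscle" & rows$element %in% ref$rfds$element, ,
                 drop = FALSE]
  grid <- expand.grid(i = seq_len(nrow(muscle)), s = seq_len(nrow(ref$scenarios)),
                      p = seq_len(nrow(ref$profiles)))
  edi_tab <- data.frame(element = muscle$element[grid$i],
                        site = muscle$site[grid$i],
                        scenario = ref$scenarios$name[grid$s],
                        profile = ref$profiles$label[grid$p],
                        conc = muscle$mean[grid$i],
                        ingestion_rate = ref$scenarios$ingestion_rate[grid$s],
                        body_weight = ref$profiles$body_weight[grid$p])
  edi_tab$edi <- if (nrow(edi_tab))
    edi(edi_tab$conc, edi_tab$ingestion_rate, edi_tab$body_weight) else numeric()
  edi_tab <- withCallingHandlers(
    screen_rfd(edi_tab, ref$rfds),
    warning = function(w) invokeRestart("muffleWarning"))  # revoked-RfD note goes in reports
  edi_tab <- order_by(edi_tab, c("element", "site", "scenario", "profile"))

  structure(list(rq = rq_tab, ri = ri_tab, edi = edi_tab,
                 exceedance = rq_tab[c("element", "tissue", "site", "authority",
                                       "ml", "conc", "exceedance_pct")],
                 issues = v$issues, authority = authority),
            class = "ecotox_assessment")
}

#' @export
print.ecotox_assessment <- function(x, ...) {
  cat("Ecotoxicological risk assessment (authority policy: ", x$authority, ")\n",
      sep = "")
  cat(sprintf("  %d RQ rows, %d tissue x site groups, %d intake rows\n",
              nrow(x$rq), nrow(x$ri), nrow(x$edi)))
  worst <- x$ri[order(-x$ri$ri), ]
  if (nrow(worst)) {
    cat("  cumulative risk index by group:\n")
    for (i in seq_len(nrow(worst)))
      cat(sprintf("    %-6s %-6s RI = %7.2f (%s)%s\n", worst$tissue[i],
                  worst$site[i], worst$ri[i], worst$band[i],
                  if (worst$non_edible[i]) "  [non-edible tissue]" else ""))
  }
  if (nrow(x$issues)) cat(sprintf("  %d validation issue(s) — see $issues\n",
                                  nrow(x$issues)))
  invisible(x)
}
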