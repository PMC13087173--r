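#' Element concentration from an acid digest
#'
#' Converts an ICP-OES instrument reading on a digested tissue sample to a
#' tissue concentration: reading (mg/L) times extract volume (L) divided by
#' the digested sample mass (kg), giving mg/kg.
#'
#' @param reading Instrument reading, mg/L. Vectorized.
#' @param volume Extract volume, L.
#' @param mass Digested sample mass, kg.
#' @return Concentration in mg/kg.
#' @examples
#' digest_concentration(2.5, 0.010, 0.0005)  # 50 mg/kg
#' @export
digest_concentration <- function(reading, volume, mass) {
  if (any(!is.finite(reading) | reading < 0)) stop_validation("reading must be >= 0")
  if (any(!is.finite(volume) | volume <= 0)) stop_validation("extract volume must be > 0")
  if (any(!is.finite(mass) | mass <= 0)) stop_validation("sample mass must be > 0")
  reading * volume / mass
}

#' Fulton condition factor
#'
#' Q = 100 W / L^3 with W in grams and L in centimetres. A dimensionless
#' body-condition index: fish at Q <= 1 are in poor condition, around 1.2
#' moderate, and at Q >= 1.4 in good condition. The formula is defined for
#' total length; surveys often apply it to standard length (as the packaged
#' survey does), which inflates Q — supply whichever length you mean, the
#' function does not convert.
#'
#' @param weight Body weight, g. Vectorized.
#' @param length Length, cm.
#' @return Q, dimensionless.
#' @examples
#' fulton_q(96, 19)  # 1.40
#' @export
fulton_q <- function(weight, length) {
  if (any(!is.finite(weight) | weight <= 0)) stop_validation("weight must be > 0")
  if (any(!is.finite(length) | length <= 0)) stop_validation("length must be > 0")
  100 * weight / length^3
}

#' Classify a Fulton condition factor
#'
#' Bands: `poor` for Q <= 1, `good` for Q >= 1.4, `moderate` in between
#' (the open interval, so the anchor points 1 and 1.4 fall in the outer
#' bands).
#'
#' @param q Condition factor, >= 0. Vectorized.
#' @return Factor with levels poor/moderate/good.
#' @export
classify_condition <- function(q) {
  if (any(!is.finite(q) | q < 0)) stop_validation("q must be >= 0")
  factor(ifelse(q <= 1, "poor", ifelse(q >= 1.4, "good", "moderate")),
         levels = c("poor", "moderate", "good"))
}

#' Bioconcentration factor
#'
#' Tissue concentration (mg/kg) divided by water concentration (mg/L); the
#' group mean tissue concentration is the conventional numerator. A zero
#' water concentration is an error (undefined ratio), never infinity.
#'
#' @param c_org Concentration in the organism, mg/kg, >= 0. Vectorized.
#' @param c_water Concentration in water, mg/L, > 0.
#' @return BCF, dimensionless.
#' @examples
#' bcf(298.79, 0.17)  # ~1757.6
#' @export
bcf <- function(c_org, c_water) {
  if (any(!is.finite(c_org) | c_org < 0)) stop_validation("c_org must be >= 0")
  if (any(!is.finite(c_water) | c_water <= 0))
    stop_validation("c_water must be > 0 (BCF undefined for zero water concentration)")
  c_org / c_water
}

#' Classify a bioconcentration factor (US-EPA bands)
#'
#' `non_bioaccumulative` below 1000, `bioaccumulative` for 1000-5000
#' (boundaries inclusive), `high` above 5000.
#'
#' @param v BCF value, >= 0. Vectorized.
#' @return Factor with levels non_bioaccumulative/bioaccumulative/high.
#' @export
classify_bcf <- function(v) {
  if (any(!is.finite(v) | v < 0)) stop_validation("BCF must be >= 0")
  factor(ifelse(v < 1000, "non_bioaccumulative",
                ifelse(v <= 5000, "bioaccumulative", "high")),
         levels = c("non_bioaccumulative", "bioaccumulative", "high"))
}

#' BCF table from tissue and water tables
#'
#' Joins a validated tissue-concentration summary with a water table on
#' (element, site) and computes the BCF of each detected element x tissue x
#' site cell from the mean tissue concentration, with US-EPA class.
#' Elements with no water value are dropped.
#'
#' @param tissue Concentration summary table (see
#'   [validate_concentrations()] for the schema).
#' @param water Data frame with columns `element`, `site`, `value` (mg/L).
#' @return Data frame `element`, `tissue`, `site`, `c_org`, `c_water`,
#'   `bcf`, `class`, ordered deterministically.
#' @export
bcf_table <- function(tissue, water) {
  v <- validate_concentrations(tissue)
  rows <- v$records[v$records$detected, , drop = FALSE]
  water$element <- normalize_element(water$element)
  m <- merge(rows[c("element", "tissue", "site", "mean")],
             water[c("element", "site", "value")],
             by = c("element", "site"))
  if (!nrow(m)) {
    return(data.frame(element = character(), tissue = character(), site = character(),
                      c_org = numeric(), c_water = numeric(), bcf = numeric(),
                      class = character()))
  }
  out <- data.frame(element = m$element, tissue = m$tissue, site = m$site,
                    c_org = m$mean, c_water = m$value,
                    bcf = bcf(m$mean, m$value))
  out$class <- as.character(classify_bcf(out$bcf))
  order_by(out, c("element", "tissue", "site"))
}
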