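#' Mann-Whitney U test
#'
#' Rank-sum location contrast between two independent samples. The U
#' statistic uses midranks for ties. The p-value is exact — by full
#' enumeration of the \eqn{\binom{n_x+n_y}{n_x}} labelings — when the
#' smaller sample has at most `exact_max` observations and there are no
#' ties; otherwise the tie-corrected normal approximation with continuity
#' correction is used. The two-sided exact p doubles the smaller tail
#' (capped at 1).
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative "two.sided" (default), "greater" (x shifted right),
#'   or "less".
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` auto-selects. Forcing `TRUE` with ties is an error.
#' @param exact_max Largest min(n_x, n_y) for the automatic exact path.
#' @return List with `statistic` (U of `x`), `p.value`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL, exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop_validation("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_validation("samples must not contain NA")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  do_exact <- if (is.null(exact)) {
    !ties && min(nx, ny) <= exact_max && choose(n, nx) <= 2e6
  } else exact
  if (do_exact && ties)
    stop_validation("exact p-value is not defined with ties")

  if (do_exact) {
    # Null distribution of U by enumerating which ranks go to x.
    us <- utils::combn(n, nx, FUN = sum) - nx * (nx + 1) / 2
    total <- length(us)
    p <- switch(alternative,
      greater = sum(us >= u) / total,
      less = sum(us <= u) / total,
      two.sided = min(1, 2 * min(sum(us <= u), sum(us >= u)) / total))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) stop_validation("all observations identical; U test undefined")
    cc <- function(d) d - sign(d) * 0.5  # continuity correction toward the mean
    p <- switch(alternative,
      greater = stats::pnorm(cc(u - mu) / sigma, lower.tail = FALSE),
      less = stats::pnorm(cc(u - mu) / sigma),
      two.sided = min(1, 2 * stats::pnorm(abs(cc(u - mu)) / sigma,
                                          lower.tail = FALSE)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = u, p.value = p, method = method, n = c(nx = nx, ny = ny))
}

#' Product-moment correlation
#'
#' Pearson r between two equal-length samples, with the validation the
#' screening pipeline needs: at least 3 paired observations and non-zero
#' variance on each side (a constant sample has no defined correlation).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return r in [-1, 1].
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 3) stop_validation("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop_validation("samples must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined for zero-variance sample")
  stats::cor(x, y)
}

#' Correlation strength label
#'
#' Interprets |r| on the Akoglu bands: `weak` below 0.40, `moderate` for
#' [0.40, 0.70), `strong` for 0.70 and above. The published anchor points
#' leave (0.30, 0.40) and (0.60, 0.70) unassigned; this partition closes
#' each gap at the upper anchor, exclusive below.
#'
#' @param r Correlation value(s), |r| <= 1.
#' @return Factor with levels weak/moderate/strong.
#' @examples
#' classify_strength(c(0.7112, 0.5749, -0.62))
#' @export
classify_strength <- function(r) {
  if (any(!is.finite(r) | abs(r) > 1)) stop_validation("|r| must be <= 1")
  a <- abs(r)
  factor(ifelse(a < 0.40, "weak", ifelse(a < 0.70, "moderate", "strong")),
         levels = c("weak", "moderate", "strong"))
}

#' Pairwise correlation matrix with strength labels
#'
#' All pairwise Pearson correlations between the numeric columns of a
#' table, in long format with [classify_strength()] labels. Zero-variance
#' columns are dropped with a warning.
#'
#' @param df Data frame; non-numeric columns are ignored.
#' @return Data frame `var1`, `var2`, `r`, `strength` (upper triangle).
#' @export
correlation_matrix <- function(df) {
  num <- df[vapply(df, is.numeric, logical(1))]
  keep <- vapply(num, function(v) stats::sd(v, na.rm = TRUE) > 0, logical(1))
  if (any(!keep))
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(names(num)[!keep], collapse = ", ")), call. = FALSE)
  num <- num[keep]
  if (ncol(num) < 2) stop_validation("need at least 2 usable numeric columns")
  cm <- stats::cor(num, use = "pairwise.complete.obs")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(var1 = rownames(cm)[idx[, 1]], var2 = colnames(cm)[idx[, 2]],
                    r = cm[idx])
  out$strength <- as.character(classify_strength(out$r))
  order_by(out, c("var1", "var2"))
}

#' Site contrast over grouped measurements
#'
#' Runs [mann_whitney()] between the two levels of `group_col` within each
#' combination of `by` columns — the standard urban-vs-rural contrast on
#' per-fish measurements. Cells where either site is missing are skipped.
#'
#' @param df Long data frame of raw measurements.
#' @param value_col Name of the numeric measurement column.
#' @param group_col Name of the two-level grouping column (e.g. site).
#' @param by Character vector of stratifying columns.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame with medians per group, U, p, and significance.
#' @export
compare_groups <- function(df, value_col, group_col, by = c("element", "tissue"),
                           alpha = 0.05) {
  for (col in c(value_col, group_col, by))
    if (!col %in% names(df)) stop_validation("missing column '%s'", col)
  levels_g <- sort(unique(df[[group_col]]))
  if (length(levels_g) != 2)
    stop_validation("'%s' must have exactly 2 levels, found %d",
                    group_col, length(levels_g))
  sp <- split(df, df[by], drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    x <- d[[value_col]][d[[group_col]] == levels_g[1]]
    y <- d[[value_col]][d[[group_col]] == levels_g[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) return(NULL)
    mw <- mann_whitney(x, y)
    cbind(d[1, by, drop = FALSE],
          data.frame(group1 = levels_g[1], group2 = levels_g[2],
                     n1 = length(x), n2 = length(y),
                     median1 = stats::median(x), median2 = stats::median(y),
                     U = mw$statistic, p = mw$p.value,
                     significant = mw$p.value < alpha))
  }))
  rownames(out) <- NULL
  order_by(out, by)
}
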