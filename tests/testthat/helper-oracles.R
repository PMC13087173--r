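# Independent oracles used across test files.

# Mann-Whitney U by direct pair counting (no ranks).
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact p by brute-force enumeration of all labelings of the pooled sample:
# every choice of which nx pooled values are called "x" is equally likely
# under the null. Independent of the implementation's rank-sum path.
oracle_exact_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  nx <- length(x)
  u_obs <- oracle_u(x, y)
  subsets <- utils::combn(length(pooled), nx)
  us <- apply(subsets, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  total <- length(us)
  switch(alternative,
    greater = sum(us >= u_obs) / total,
    less = sum(us <= u_obs) / total,
    two.sided = min(1, 2 * min(sum(us <= u_obs), sum(us >= u_obs)) / total))
}

# Minimal clean concentration rows for plumbing tests.
make_conc_rows <- function(...) {
  base <- data.frame(species = "sp", site = "urban", tissue = "muscle",
                     element = "Se", mean = 9.3, sd = 4.13, min = 5.24,
                     max = 15.62, detection_limit = 0.024,
                     stringsAsFactors = FALSE)
  mods <- list(...)
  if (!length(mods)) return(base)
  do.call(rbind, lapply(mods, function(m) {
    r <- base
    for (nm in names(m)) r[[nm]] <- m[[nm]]
    r
  }))
}
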