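test_that("separated samples give U = 0 and exact p = 0.1 at n = 3 + 3", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p.value, 0.1)   # 2/20 labelings as extreme
  expect_match(mw$method, "exact")
})

test_that("identical samples give p = 1; U identity holds", {
  x <- c(2, 5, 9, 1)
  expect_equal(mann_whitney(x, x, exact = FALSE)$p.value, 1)
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(2:9, 1)); b <- rnorm(sample(2:9, 1))
    ua <- mann_whitney(a, b)$statistic
    ub <- mann_whitney(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
  }
})

test_that("exact p agrees with the brute-force labeling oracle (n <= 10)", {
  set.seed(101)
  sizes <- expand.grid(nx = 2:5, ny = 2:5)
  sizes <- sizes[sizes$nx + sizes$ny <= 10, ]
  for (i in seq_len(nrow(sizes))) {
    for (rep in 1:3) {
      x <- round(rnorm(sizes$nx[i]), 6)   # continuous draws: no ties
      y <- round(rnorm(sizes$ny[i]), 6)
      for (alt in c("two.sided", "less", "greater")) {
        got <- mann_whitney(x, y, alternative = alt)
        expect_match(got$method, "exact")
        expect_equal(got$p.value, oracle_exact_p(x, y, alt),
                     info = sprintf("n=(%d,%d) alt=%s rep=%d",
                                    sizes$nx[i], sizes$ny[i], alt, rep))
        expect_equal(got$statistic, oracle_u(x, y))
      }
    }
  }
})

test_that("exact path also matches stats::wilcox.test where both are exact", {
  set.seed(77)
  for (rep in 1:10) {
    x <- rnorm(5); y <- rnorm(7)
    got <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value)
  }
})

test_that("approximate path handles ties like the tie-corrected normal test", {
  set.seed(31)
  for (rep in 1:10) {
    x <- sample(1:5, 15, replace = TRUE)  # heavy ties
    y <- sample(2:6, 18, replace = TRUE)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_match(got$method, "approximation")
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
    expect_gt(got$p.value, 0)
    expect_lte(got$p.value, 1)
  }
  expect_error(mann_whitney(c(1, 1), c(1, 1, 1), exact = TRUE),
               class = "ecotox_validation_error")
  expect_error(mann_whitney(numeric(), 1:3), class = "ecotox_validation_error")
})

test_that("correlate validates and matches hand-computed r", {
  expect_equal(correlate(1:10, 2 * (1:10) + 1), 1)
  expect_equal(correlate(1:10, -(1:10)), -1)
  expect_equal(correlate(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(correlate(1:3, 1:4), class = "ecotox_validation_error")
  expect_error(correlate(1:2, 1:2), class = "ecotox_validation_error")
  expect_error(correlate(c(1, 1, 1), 1:3), class = "ecotox_validation_error")
})

test_that("correlate is affine-invariant and antisymmetric under negation", {
  set.seed(13)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    r <- correlate(x, y)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(correlate(a * x + b, y), r)
    expect_equal(correlate(x, -y), -r)
  }
})

test_that("strength labels follow the closed-gap Akoglu partition", {
  expect_equal(as.character(classify_strength(c(0, 0.30, 0.399, 0.40, 0.5749,
                                                0.699, 0.70, 0.7112, 1))),
               c("weak", "weak", "weak", "moderate", "moderate", "moderate",
                 "strong", "strong", "strong"))
  # symmetric in sign
  r <- c(-0.9, -0.5, -0.1, 0.1, 0.5, 0.9)
  expect_equal(classify_strength(r), classify_strength(-r))
  expect_error(classify_strength(1.2), class = "ecotox_validation_error")
})

test_that("correlation_matrix returns labelled upper-triangle pairs", {
  set.seed(4)
  df <- data.frame(a = rnorm(20), b = rnorm(20), label = letters[1:20])
  df$c <- df$a * 2 + rnorm(20, sd = 0.01)
  out <- correlation_matrix(df)
  expect_equal(nrow(out), 3)  # 3 numeric columns -> 3 pairs
  ac <- out[out$var1 == "a" & out$var2 == "c", ]
  expect_equal(ac$strength, "strong")
  expect_warning(correlation_matrix(cbind(df, k = 1)), "zero-variance")
})

test_that("compare_groups contrasts two sites per stratum", {
  set.seed(55)
  df <- rbind(
    data.frame(element = "Se", tissue = "muscle", site = "urban",
               value = rlnorm(15, 2, 0.3)),
    data.frame(element = "Se", tissue = "muscle", site = "rural",
               value = rlnorm(15, 2.8, 0.3)),
    data.frame(element = "Cu", tissue = "muscle", site = "urban",
               value = rlnorm(15, 0, 0.3)),
    data.frame(element = "Cu", tissue = "muscle", site = "rural",
               value = rlnorm(15, 0, 0.3)))
  out <- compare_groups(df, "value", "site")
  expect_equal(nrow(out), 2)
  se <- out[out$element == "Se", ]
  expect_true(se$significant)
  expect_lt(se$p, 0.05)
  expect_error(compare_groups(df[df$site == "urban", ], "value", "site"),
               class = "ecotox_validation_error")
})
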