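# Mixed ANOVA, t-tests, Holm-Bonferroni, Pearson correlation, cohort
# battery.

test_that("mixed ANOVA decomposes sums of squares classically", {
  # zero-effect construction: period and cell means all balance out, so
  # F_period = F_interaction = 0 (with nonzero within-subject error)
  d0 <- data.frame(
    animal = rep(c("a1", "a2", "b1", "b2"), each = 2),
    group = rep(c("A", "B"), each = 4),
    period = rep(c("pre", "pos"), 4),
    value = c(1, 2, 2, 1, 3, 4, 4, 3))
  a0 <- mixedAnova2x2(d0)
  expect_equal(a0$F[a0$effect == "period"], 0)
  expect_equal(a0$F[a0$effect == "group:period"], 0)

  # random unequal-n datasets agree with the definitional oracle
  for (s in 1:20) {
    d <- randomMixedData(s)
    a <- mixedAnova2x2(d)
    o <- ssOracle(d)
    expect_equal(a$ss[a$effect == "group"], o$group, tolerance = 1e-10)
    expect_equal(a$ss[a$effect == "period"], o$period, tolerance = 1e-10)
    expect_equal(a$ss[a$effect == "group:period"], o$interaction,
      tolerance = 1e-10)
    expect_equal(attr(a, "ss_subjects"), o$subjects, tolerance = 1e-10)
    expect_equal(attr(a, "ss_within_error"), o$within, tolerance = 1e-10)
    # SS decomposition identity: the five components sum to SS_total
    expect_equal(sum(a$ss) + attr(a, "ss_subjects") +
      attr(a, "ss_within_error"), attr(a, "ss_total"), tolerance = 1e-12)
    expect_true(all(a$F >= 0))
    expect_true(all(a$p >= 0 & a$p <= 1))
  }

  # design df match the group sizes (2 groups, N animals)
  d <- randomMixedData(99, nRange = 5:6)
  a <- mixedAnova2x2(d)
  N <- length(unique(d$animal))
  expect_equal(a$df, c(1, 1, 1))
  expect_equal(a$df_error, rep(N - 2, 3))

  dMiss <- d[-1, ]
  expect_error(mixedAnova2x2(dMiss), "exactly one value per period")
})

test_that("t-tests expose pairing, tails and the Welch adjustment", {
  # identical paired samples: t = 0, two-tailed p = 1
  r0 <- tTest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # closed-form Welch example
  r <- tTest(c(1, 2, 3), c(2, 3, 4), paired = FALSE, welch = TRUE)
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$df, 4.0, tolerance = 1e-9)

  # one-tailed p is half of two-tailed p in the favored direction
  set.seed(4)
  x <- rnorm(8, 1)
  y <- rnorm(8, 0)
  two <- tTest(x, y, paired = TRUE, tail = "two")
  one <- tTest(x, y, paired = TRUE, tail = "greater")
  expect_equal(one$p, two$p / 2)

  # equal-variance equal-n data: Welch and pooled t agree
  xx <- c(1.1, 2.0, 2.9, 4.1)
  yy <- c(1.9, 3.1, 3.9, 5.2)
  tw <- tTest(xx, yy, welch = TRUE)
  tp <- tTest(xx, yy, welch = FALSE)
  expect_equal(tw$statistic, tp$statistic, tolerance = 1e-9)

  # Welch is the default exactly when the sample sizes differ
  expect_true(tTest(rnorm(5), rnorm(6))$welch)
  expect_false(tTest(rnorm(5), rnorm(5))$welch)

  expect_error(tTest(rep(1, 4), rep(1, 4), paired = FALSE),
    "undefined t statistic")
  expect_error(tTest(c(1, 1, 1), c(2, 2, 2), paired = TRUE),
    "undefined t statistic")
})

test_that("Holm-Bonferroni steps down and dominates Bonferroni", {
  h <- holmBonferroni(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_identical(h$reject, c(TRUE, FALSE, FALSE))
  expect_equal(h$p_adjusted, c(0.03, 0.06, 0.06))

  hAll1 <- holmBonferroni(rep(1, 5))
  expect_false(any(hAll1$reject))
  expect_true(all(hAll1$p_adjusted == 1))

  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    h <- holmBonferroni(p, alpha = 0.05)
    bonf <- p < 0.05 / length(p)
    uncorr <- p < 0.05
    expect_true(all(h$reject[bonf]))        # contains Bonferroni's set
    expect_true(all(uncorr[h$reject]))      # inside the uncorrected set
    expect_equal(h$p_adjusted, p.adjust(p, "holm"))
  }
})

test_that("Pearson correlation matches the definitional formula", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(c(-1, 0, 1), c(1, -2, 1))$r, 0)

  set.seed(10)
  a <- rnorm(10)
  b <- rnorm(10)
  r <- pearsonCorrelation(a, b)
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, want, tolerance = 1e-12)

  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "zero-variance")
  expect_error(pearsonCorrelation(1:2, 1:2), "n >= 3")
})

test_that("the cohort battery flags a planted rate effect correctly", {
  # statistics-level check on constructed tables (no simulation noise)
  set.seed(15)
  mkrates <- function(trDelta) {
    rbind(
      data.frame(animal = sprintf("N%02d", 1:6), group = "NAIVE",
        period = "pre", value = 0.06 + rnorm(6, 0, 0.01)),
      data.frame(animal = sprintf("N%02d", 1:6), group = "NAIVE",
        period = "pos", value = 0.06 + rnorm(6, 0, 0.01)),
      data.frame(animal = sprintf("T%02d", 1:5), group = "TR",
        period = "pre", value = 0.06 + rnorm(5, 0, 0.01)),
      data.frame(animal = sprintf("T%02d", 1:5), group = "TR",
        period = "pos", value = 0.06 + trDelta + rnorm(5, 0, 0.01)))
  }
  rep1 <- analyzeCohort(list(rates = mkrates(0.1), vds = NULL, mec = NULL))
  expect_lt(rep1$rates$anova$p[rep1$rates$anova$effect == "group:period"],
    0.05)
  ph <- rep1$rates$posthoc
  expect_true(ph$reject[ph$group == "TR"])
  expect_false(ph$reject[ph$group == "NAIVE"])
  expect_lt(rep1$rates$welch_diff$p, 0.05)

  expect_error(
    analyzeCohort(list(rates = mkrates(0)[1:4, ], vds = NULL, mec = NULL)),
    "fewer than 2 animals")
})
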