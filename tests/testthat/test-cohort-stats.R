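test_that("effect size and percent difference follow the pooled-SD definitions", {
  wt <- c(2, 2.2, 1.8); het <- c(4, 4.1, 3.9)
  es <- effectSize(wt, het)
  s2p <- (2 * var(wt) + 2 * var(het)) / 4
  expect_equal(es$d, (mean(het) - mean(wt)) / sqrt(s2p))
  expect_equal(es$percent_diff, 100 * (mean(het) - mean(wt)) / mean(wt))
  # exact doubling with zero spread: percent difference defined, d is not
  expect_warning(es0 <- effectSize(c(2, 2), c(4, 4)), "pooled SD")
  expect_equal(es0$percent_diff, 100)
  expect_true(is.na(es0$d))
  # large-sample recovery of a generative d = 2
  set.seed(12)
  esl <- effectSize(rnorm(10000, 10, 1), rnorm(10000, 12, 1))
  expect_equal(esl$d, 2, tolerance = 0.05)
  # shift/scale invariance of d
  es1 <- effectSize(wt, het)
  es2 <- effectSize(3 + 2 * wt, 3 + 2 * het)
  expect_equal(es1$d, es2$d, tolerance = 1e-12)
})

test_that("relative-difference conversion to d is linear", {
  expect_equal(dForRelativeDifference(10, 0.2, 2), 1.0)
  expect_equal(dForRelativeDifference(10, 0, 2), 0)
  expect_equal(dForRelativeDifference(10, 0.2, 4),
               dForRelativeDifference(10, 0.2, 2) / 2)
})

test_that("sample size satisfies the one-tailed noncentral-t minimality contract", {
  for (d in c(0.5, 1.0, 2.43, 7.48)) {
    n <- sampleSizeTwoSampleT(d)
    expect_gte(powerTwoSampleT(d, n), 0.80)
    if (n > 2) expect_lt(powerTwoSampleT(d, n - 1), 0.80)
  }
  # agreement with the closed-form iteration in stats::power.t.test
  for (d in c(0.8, 1.0, 1.58)) {
    nref <- ceiling(power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                 power = 0.80, type = "two.sample",
                                 alternative = "one.sided")$n)
    expect_equal(as.integer(sampleSizeTwoSampleT(d)), nref)
  }
  # headline planning values: a very large effect needs only 2-3 per group
  expect_lte(as.integer(sampleSizeTwoSampleT(7.48)), 3)
  expect_true(as.integer(sampleSizeTwoSampleT(1.0)) %in% c(13, 14))
})

test_that("sample size is monotone in effect size and target power", {
  ds <- c(0.3, 0.5, 1, 2, 5)
  ns <- vapply(ds, function(d) as.integer(sampleSizeTwoSampleT(d)), 0L)
  expect_true(all(diff(ns) <= 0))
  pows <- c(0.7, 0.8, 0.9, 0.95)
  np <- vapply(pows, function(p)
    as.integer(sampleSizeTwoSampleT(1, power = p)), 0L)
  expect_true(all(diff(np) >= 0))
  tab <- powerTable(c(1, 2.43))
  expect_equal(tab$n_per_group, c(14L, 4L))
  expect_true(all(tab$achieved_power >= 0.8))
})

test_that("correlations match closed forms and rank behaviour", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, 2 * x + 1)$r2, 1)
  # monotone nonlinear: spearman 1, pearson < 1
  y <- exp(x / 2)
  expect_equal(correlate(x, y, "spearman")$r, 1)
  expect_lt(correlate(x, y, "pearson")$r, 1)
  # fixed table vs the covariance formula
  set.seed(33)
  a <- rnorm(10); b <- 0.5 * a + rnorm(10, 0, 0.4)
  rHand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate(a, b)$r, rHand, tolerance = 1e-12)
  expect_error(correlate(a, rep(1, 10)), "zero variance")
  expect_error(correlate(a[1:2], b[1:2]), "at least 3")
})

test_that("4PL mass-dose curve is recovered and inverted", {
  lm10 <- seq(-2, 2, length.out = 9)
  truth <- list(a = 2, b = 2, c = 0, d = 6)
  vt <- truth$a + (truth$d - truth$a) /
    (1 + 10^(truth$b * (lm10 - truth$c)))
  fit <- fit4pl(lm10, vt)
  expect_equal(fit$a, 2, tolerance = 1e-4)
  expect_equal(fit$b, 2, tolerance = 1e-4)
  expect_equal(fit$c, 0, tolerance = 1e-4)
  expect_equal(fit$d, 6, tolerance = 1e-4)
  # half-drop mass at the inflection: 10^0 = 1
  expect_equal(massAtDrop(fit, 0.5), 1.0, tolerance = 1e-4)
  # drop fractions map monotonically to mass
  expect_lt(massAtDrop(fit, 0.2), massAtDrop(fit, 0.8))
  expect_error(fit4pl(lm10, rep(3, 9)), "flat")
  flat <- structure(list(a = 3, b = 1, c = 0, d = 3, rss = 0),
                    class = "FourPLModel")
  expect_warning(expect_true(is.na(massAtDrop(flat, 0.5))), "no solution")
})

test_that("Welch region comparison reports effects with Bonferroni scaling", {
  set.seed(44)
  df <- expand.grid(region = c("striatum", "thalamus"),
                    genotype = c("WT", "HET"), rep = 1:8)
  df$value <- ifelse(df$genotype == "HET", 6, 3) + rnorm(nrow(df), 0, 0.4)
  out <- welchByRegion(df)
  expect_equal(nrow(out), 2)
  expect_true(all(out$d > 0))
  expect_true(all(out$p_bonferroni >= out$p))
  expect_true(all(out$percent_diff > 50))
})
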