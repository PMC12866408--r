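test_that("rTRV and aTRV follow their defining arithmetic", {
  expect_equal(rtrv(1.0, 1.0), 0)
  expect_equal(rtrv(2.2, 1.8), 20)
  expect_equal(rtrv(1.8, 2.2), -20)
  expect_equal(atrv(2.2, 1.8), 20)
  expect_equal(atrv(1.8, 2.2), 20)
  expect_error(rtrv(1, -1), "zero")
  # antisymmetry, |rTRV| = aTRV, and scale invariance across random pairs
  set.seed(8)
  a <- runif(50, 0.5, 5); b <- runif(50, 0.5, 5)
  expect_equal(rtrv(a, b), -rtrv(b, a))
  expect_equal(atrv(a, b), abs(rtrv(a, b)))
  expect_equal(rtrv(3.1 * a, 3.1 * b), rtrv(a, b), tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits use the n-1 SD of rTRV differences", {
  mk <- function(te, re) {
    n <- length(te)
    data.frame(animal = rep(sprintf("a%02d", 1:n), 2),
               session = rep(c("test", "retest"), each = n),
               value = c(te, re))
  }
  # identical pairs
  ba0 <- blandAltman(mk(c(2, 3, 4), c(2, 3, 4)))
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$limits), c(0, 0))
  # rTRVs {+10, -10}: bias 0, sd = sqrt(200), limits +/- 27.7186
  ba <- blandAltman(mk(c(1.05, 0.95), c(0.95, 1.05)))
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$sd, sqrt(200), tolerance = 1e-12)
  expect_equal(unname(ba$limits), c(-1, 1) * 1.96 * sqrt(200),
               tolerance = 1e-12)
  expect_error(blandAltman(mk(2, 2)), "insufficient")
})

test_that("about 95% of normal differences fall inside the limits of agreement", {
  co <- simulateTrtCohort(trtCohortSpec(500, c(WT = 5), sdBetween = 0.8,
                                        sdWithin = 0.25, seed = 23))
  ba <- blandAltman(co)
  inside <- mean(ba$differences >= ba$limits[1] &
                 ba$differences <= ba$limits[2])
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
})

test_that("REML ICC matches ground truth across variance ratios", {
  # no within-animal variance: all variance is between animals
  co1 <- simulateTrtCohort(trtCohortSpec(8, c(WT = 3, HET = 6),
                                         sdBetween = 0.5, sdWithin = 0,
                                         seed = 2))
  expect_equal(suppressWarnings(iccReml(co1)$icc), 1.0, tolerance = 1e-3)
  # sigma2_b = 3, sigma2_w = 1 at n = 200: ICC within 0.05 of 0.75
  co2 <- simulateTrtCohort(trtCohortSpec(200, c(WT = 5, HET = 5),
                                         sdBetween = sqrt(3), sdWithin = 1,
                                         seed = 31))
  expect_equal(iccReml(co2)$icc, 0.75, tolerance = 0.05)
  # no animal variance: ICC near zero
  co3 <- simulateTrtCohort(trtCohortSpec(200, c(WT = 5, HET = 5),
                                         sdBetween = 0, sdWithin = 1,
                                         seed = 7))
  expect_lte(suppressWarnings(iccReml(co3)$icc), 0.05)
})

test_that("REML equals the one-way ANOVA estimator on balanced structure-free data", {
  co <- simulateTrtCohort(trtCohortSpec(30, c(WT = 5), sdBetween = 1,
                                        sdWithin = 0.5, seed = 13))
  reml <- iccReml(co, includeFixed = FALSE)
  mom <- iccAnova(co)
  expect_equal(unname(reml$components["animal"]), mom$sigma2_between,
               tolerance = 1e-8)
  expect_equal(unname(reml$components["residual"]), mom$sigma2_within,
               tolerance = 1e-8)
  expect_equal(reml$icc, mom$icc, tolerance = 1e-8)
})

test_that("ICC is invariant to shift and positive rescaling", {
  co <- simulateTrtCohort(trtCohortSpec(40, c(WT = 4, HET = 7),
                                        sdBetween = 0.8, sdWithin = 0.5,
                                        seed = 17))
  base <- iccReml(co)$icc
  sh <- co; sh$value <- sh$value + 11.3
  sc <- co; sc$value <- sc$value * 4.2
  expect_equal(iccReml(sh)$icc, base, tolerance = 1e-6)
  expect_equal(iccReml(sc)$icc, base, tolerance = 1e-6)
})

test_that("median ICC estimate tracks the generative ICC across variance ratios", {
  for (ratio in c(0.25, 1, 3, 9)) {
    gen <- ratio / (1 + ratio)
    est <- vapply(1:7, function(r) {
      co <- simulateTrtCohort(trtCohortSpec(100, c(WT = 5, HET = 5),
                                            sdBetween = sqrt(ratio),
                                            sdWithin = 1,
                                            seed = 1000 * ratio + r))
      suppressWarnings(iccReml(co)$icc)
    }, 0)
    expect_lt(abs(median(est) - gen), 0.05)
  }
})

test_that("test-retest report has the region x metric x genotype shape", {
  co <- rbind(
    simulateTrtCohort(trtCohortSpec(6, c(WT = 3, HET = 6), sdBetween = 0.5,
                                    sdWithin = 0.3, seed = 3),
                      region = "striatum", metric = "V_T"),
    simulateTrtCohort(trtCohortSpec(6, c(WT = 0.5, HET = 1.1),
                                    sdBetween = 0.1, sdWithin = 0.05,
                                    seed = 4),
                      region = "striatum", metric = "SUV"))
  rep <- suppressWarnings(trtReport(co))
  expect_equal(nrow(rep), 2)
  expect_true(all(c("rTRV_mean_WT", "aTRV_sd_HET", "ICC") %in% names(rep)))
  expect_true(all(rep$ICC >= 0 & rep$ICC <= 1))
})
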