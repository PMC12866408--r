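bloodTimes <- c(5, 15, 30, 60, 90)

test_that("biexponential parent-fraction fit recovers generating parameters", {
  truth <- parentFractionModel(0.6, 0.002, 0.4, 0.03)
  tab <- data.frame(time = bloodTimes, whole_blood = 100, plasma = 110,
                    parent_fraction = predict(truth, bloodTimes))
  fit <- fitParentFraction(tab, constrainT0 = TRUE)
  expect_equal(fit$a1, 0.6, tolerance = 1e-6)
  expect_equal(fit$mu1, 0.002, tolerance = 1e-6)
  expect_equal(fit$a2, 0.4, tolerance = 1e-6)
  expect_equal(fit$mu2, 0.03, tolerance = 1e-6)
  expect_lt(attr(fit, "rss"), 1e-12)
  # unconstrained route recovers the same model (a1 + a2 = 1 here)
  fit2 <- fitParentFraction(tab, constrainT0 = FALSE)
  expect_equal(predict(fit2, bloodTimes), predict(truth, bloodTimes),
               tolerance = 1e-5)
})

test_that("constant parent fraction fits as f identical to 1 with zero RSS", {
  tab <- data.frame(time = bloodTimes, whole_blood = 100, plasma = 110,
                    parent_fraction = 1.0)
  fit <- fitParentFraction(tab)
  expect_equal(predict(fit, seq(0, 120, 10)), rep(1, 13), tolerance = 1e-6)
  expect_lt(attr(fit, "rss"), 1e-10)
})

test_that("parent-fraction fit hits the calibrated 90-min plasma fraction", {
  pf <- defaultParentFraction()
  tab <- data.frame(time = bloodTimes, whole_blood = 100, plasma = 110,
                    parent_fraction = round(predict(pf, bloodTimes), 3))
  fit <- fitParentFraction(tab)
  expect_gt(predict(fit, 90), 0.79)
  expect_lt(predict(fit, 90), 0.81)
})

test_that("parent-fraction fit validates inputs", {
  bad <- data.frame(time = bloodTimes, whole_blood = 100, plasma = 110,
                    parent_fraction = c(0.9, 0.8, 1.2, 0.7, 0.6))
  expect_error(fitParentFraction(bad), "\\[0, 1\\]")
  few <- data.frame(time = c(5, 15), whole_blood = 100, plasma = 110,
                    parent_fraction = c(0.95, 0.9))
  expect_error(fitParentFraction(few), "under-determined")
  nofrac <- data.frame(time = bloodTimes, whole_blood = 100, plasma = 110)
  expect_error(fitParentFraction(nofrac), "parent_fraction")
  # optional extraction-efficiency pre-division
  tab <- data.frame(time = bloodTimes, whole_blood = 100, plasma = 110,
                    parent_fraction = 0.914 * exp(-0.001 * bloodTimes))
  fit <- fitParentFraction(tab, extractionEfficiency = 0.914)
  expect_equal(predict(fit, 0), 1, tolerance = 1e-6)
})

test_that("plasma-to-whole-blood line is recovered by OLS", {
  tab <- data.frame(time = bloodTimes, whole_blood = 100,
                    plasma = 100 * (1.2 + 0.001 * bloodTimes))
  fit <- fitPlasmaToBlood(tab)
  expect_equal(fit$r0, 1.2, tolerance = 1e-12)
  expect_equal(fit$r1, 0.001, tolerance = 1e-12)
  expect_equal(attr(fit, "r2"), 1)
  # constant ratio
  tabc <- data.frame(time = bloodTimes, whole_blood = 80, plasma = 80)
  fitc <- fitPlasmaToBlood(tabc)
  expect_equal(fitc$r0, 1.0, tolerance = 1e-12)
  expect_equal(fitc$r1, 0.0, tolerance = 1e-12)
})

test_that("noisy ratio fit matches the closed-form OLS oracle", {
  set.seed(101)
  ratio <- 1.1 + 0.002 * bloodTimes + rnorm(5, 0, 0.02)
  tab <- data.frame(time = bloodTimes, whole_blood = 100,
                    plasma = 100 * ratio)
  fit <- fitPlasmaToBlood(tab)
  slope <- sum((bloodTimes - mean(bloodTimes)) * (ratio - mean(ratio))) /
    sum((bloodTimes - mean(bloodTimes))^2)
  expect_equal(fit$r1, slope, tolerance = 1e-12)
  expect_equal(fit$r0, mean(ratio) - slope * mean(bloodTimes),
               tolerance = 1e-12)
  expect_error(fitPlasmaToBlood(tab[1, ]), "under-determined")
})

test_that("IDIF correction is pointwise multiplicative and order-independent", {
  t <- seq(0, 120, by = 0.5)
  wb <- predict(inputModelParams(), t)
  # identity and constant-scaling cases
  id <- correctIdif(t, wb, plasmaToBloodModel(1, 0), parentFractionModel(1, 0, 0, 0))
  expect_equal(plasmaParent(id), wholeBlood(id))
  half <- correctIdif(t, wb, plasmaToBloodModel(1, 0),
                      parentFractionModel(0.5, 0, 0, 0))
  expect_equal(plasmaParent(half), 0.5 * wholeBlood(half))
  # product structure: correcting with both models equals the pointwise
  # product of the two single-model corrections divided by the raw curve
  p2 <- defaultPlasmaToBlood(); pf <- defaultParentFraction()
  both <- correctIdif(t, wb, p2, pf)
  onlyRatio <- correctIdif(t, wb, p2, parentFractionModel(1, 0, 0, 0))
  g <- gridTimes(both)
  expect_equal(plasmaParent(both),
               plasmaParent(onlyRatio) * predict(pf, g), tolerance = 1e-12)
  # plasma-parent / plasma ratio at 90 min equals the calibrated fraction
  i90 <- which.min(abs(g - 90))
  plasma90 <- wholeBlood(both)[i90] * predict(p2, 90)
  expect_gt(plasmaParent(both)[i90] / plasma90, 0.79)
  expect_lt(plasmaParent(both)[i90] / plasma90, 0.81)
})

test_that("simulate-then-fit round trip reproduces the input models", {
  pfT <- defaultParentFraction(); p2T <- defaultPlasmaToBlood()
  prm <- inputModelParams()
  wb <- predict(prm, bloodTimes)
  tab <- data.frame(time = bloodTimes, whole_blood = wb,
                    plasma = wb * predict(p2T, bloodTimes),
                    parent_fraction = predict(pfT, bloodTimes))
  pfF <- fitParentFraction(tab)
  p2F <- fitPlasmaToBlood(tab)
  expect_equal(predict(pfF, bloodTimes), predict(pfT, bloodTimes),
               tolerance = 1e-6)
  expect_equal(predict(p2F, bloodTimes), predict(p2T, bloodTimes),
               tolerance = 1e-9)
})
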