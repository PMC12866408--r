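test_that("k3 = 0 reduces the 2TCM to the one-tissue closed form", {
  p <- twotcmParams(K1 = 0.4, k2 = 0.12, k3 = 0, k4 = 0, vB = 0)
  pred <- twotcmPredict(p, INPUT, FS)
  ct <- indepConv1tcm(0.4, 0.12, gridTimes(INPUT), plasmaParent(INPUT))
  oracle <- indepFrameAvg(gridTimes(INPUT), ct, frameStarts(FS), frameEnds(FS))
  scaleRef <- max(oracle)
  expect_true(all(abs(pred - oracle) <= 1e-3 * pmax(abs(oracle),
                                                    0.01 * scaleRef)))
})

test_that("K1 = 0 leaves only the fractional blood signal", {
  p <- twotcmParams(0, 0.1, 0, 0, vB = 0.05)
  pred <- twotcmPredict(p, INPUT, FS)
  wbAvg <- indepFrameAvg(gridTimes(INPUT), wholeBlood(INPUT),
                         frameStarts(FS), frameEnds(FS))
  expect_equal(pred, 0.05 * wbAvg, tolerance = 1e-10)
})

test_that("impulse-response integral equals (K1/k2)(1 + k3/k4)", {
  # steady-state quadrature: with a unit-constant input and no blood term,
  # the late model value converges to the integral of h, here 2 * (1 + 1) = 4
  p <- twotcmParams(0.5, 0.25, 0.05, 0.05, 0)
  t <- seq(0, 600, by = 0.05)
  inp <- inputFunction(t, rep(0, length(t)), rep(1, length(t)))
  fsLate <- frameSchedule(c(0, 590), c(590, 10))
  expect_equal(twotcmPredict(p, inp, fsLate)[2], vT(p), tolerance = 1e-6)
  expect_equal(vT(p), 4.0)
})

test_that("2TCM prediction is linear in the plasma input at vB = 0", {
  p <- twotcmParams(0.3, 0.15, 0.06, 0.03, 0)
  scaled <- inputFunction(gridTimes(INPUT), wholeBlood(INPUT),
                          3.7 * plasmaParent(INPUT))
  expect_equal(twotcmPredict(p, scaled, FS),
               3.7 * twotcmPredict(p, INPUT, FS), tolerance = 1e-12)
})

test_that("noise-free 2TCM fit recovers V_T and is seed-deterministic", {
  p <- twotcmParams(0.3, 0.15, 0.06, 0.03, 0.03)
  tac <- simulateTac(p, INPUT, FS)
  fit <- fit2tcm(tac, INPUT, restarts = 5, seed = 2)
  expect_equal(vT(fit), 6.0, tolerance = 0.01)
  expect_true(fit@converged)
  fit2 <- fit2tcm(tac, INPUT, restarts = 5, seed = 2)
  expect_identical(vT(fit), vT(fit2))
  # V_T recomputable from the fitted rate constants
  expect_equal(vT(fit), vT(fit@params))
})

test_that("degenerate TACs are rejected or flagged", {
  zero <- tacTable(FS, list(r = rep(0, nFrames(FS))))
  expect_error(fit2tcm(zero, INPUT), "all-zero")
  # pure blood-fraction TAC: delivery is unidentifiable
  bloodOnly <- simulateTac(twotcmParams(0, 0.1, 0, 0, 0.05), INPUT, FS)
  fit <- fit2tcm(bloodOnly, INPUT, restarts = 5, seed = 3)
  expect_lt(fit@params@K1, 0.01)
  expect_true(any(grepl("K1", fit@flags)))
})

test_that("Logan slope equals the proportionality constant for equilibrium curves", {
  cpAvg <- indepFrameAvg(gridTimes(INPUT), plasmaParent(INPUT),
                         frameStarts(FS), frameEnds(FS))
  tac <- tacTable(FS, list(r = 4 * cpAvg))
  lg <- loganVt(tac, INPUT, tStar = 10)
  expect_equal(vT(lg), 4.0, tolerance = 0.005)
  expect_gt(lg@r2, 0.9999)
})

test_that("Logan V_T agrees with the analytic value for a reversible tracer", {
  p <- twotcmParams(0.3, 0.15, 0.06, 0.03, 0)
  tac <- simulateTac(p, INPUT, FS)
  lg <- loganVt(tac, INPUT, tStar = 30)
  expect_equal(vT(lg), 6.0, tolerance = 0.03)
  expect_equal(lg@tStar, 30)
  expect_gte(lg@nPoints, 3)
})

test_that("Logan slope scaling follows the ratio structure of the plot", {
  p <- twotcmParams(0.25, 0.12, 0.05, 0.04, 0)
  tac <- simulateTac(p, INPUT, FS)
  base <- vT(loganVt(tac, INPUT, tStar = 30))
  # common rescaling of TAC and input leaves the slope unchanged
  c0 <- 2.9
  tacS <- tacTable(FS, list(r = c0 * tacValues(tac, 1)))
  inpS <- inputFunction(gridTimes(INPUT), c0 * wholeBlood(INPUT),
                        c0 * plasmaParent(INPUT))
  expect_equal(vT(loganVt(tacS, inpS, tStar = 30)), base, tolerance = 1e-9)
  # scaling only the input by c scales the slope by 1/c
  expect_equal(vT(loganVt(tac, inpS, tStar = 30)), base / c0,
               tolerance = 1e-9)
})

test_that("automatic t* lands on a frame boundary and meets the residual rule", {
  p <- twotcmParams(0.3, 0.15, 0.06, 0.03, 0)
  tac <- simulateTac(p, INPUT, FS)
  lg <- loganVt(tac, INPUT, tStar = "auto")
  expect_true(any(abs(frameStarts(FS) - lg@tStar) < 1e-9))
  # the late-frame requirement still holds
  expect_gte(sum(frameMidpoints(FS) >= lg@tStar), 3)
  expect_error(loganVt(tac, INPUT, tStar = 119), "insufficient")
})

test_that("added frame noise biases Logan V_T nonpositively in the median", {
  p <- twotcmParams(0.3, 0.15, 0.06, 0.03, 0)
  tacClean <- simulateTac(p, INPUT, FS)
  vtClean <- vT(loganVt(tacClean, INPUT, tStar = 30))
  vts <- vapply(1:1500, function(i)
    vT(loganVt(simulateTac(p, INPUT, FS, noiseSpec(0.1, i)), INPUT,
               tStar = 30)), 0)
  expect_lte(median(vts), vtClean)
})

test_that("time-stability percentages behave as kinetics dictate", {
  slow <- simulateTac(twotcmParams(0.3, 0.15, 0.06, 0.005, 0), INPUT, FS)
  ts <- timeStability(slow, INPUT, durations = c(60, 90, 120), tStar = 30)
  expect_equal(ts$percent_of_full[3], 100)
  expect_lt(ts$percent_of_full[1], 100)
  expect_true(all(diff(ts$percent_of_full) > 0))
  fast <- simulateTac(twotcmParams(0.3, 0.15, 0.06, 0.1, 0), INPUT, FS)
  tf <- timeStability(fast, INPUT, durations = c(60, 90, 120), tStar = 30)
  expect_true(all(abs(tf$percent_of_full - 100) < 5))
  expect_error(timeStability(slow, INPUT, durations = 20, tStar = 30),
               "exceed t")
})

test_that("SUV follows the dose-per-weight unit contract on the late window", {
  tac <- tacTable(FS, list(r = rep(200, nFrames(FS))))
  sv <- computeSuv(tac, dose = 4, weight = 20)
  expect_equal(sv$suv, 1.0)
  expect_equal(sv$n_frames, 4)  # frames starting 100, 105, 110, 115 min
  # halving weight at fixed dose halves SUV
  expect_equal(computeSuv(tac, dose = 4, weight = 10)$suv, 0.5)
  expect_error(computeSuv(tac, 4, 20, window = c(118, 119)), "no frame")
  expect_error(computeSuv(tac, 4, 20, window = c(110, 130)), "scan span")
})

test_that("V_T and SUV rank together across a simulated cohort", {
  set.seed(5)
  vts <- c(); suvs <- c()
  for (i in 1:16) {
    K1 <- runif(1, 0.2, 0.4)
    k3 <- runif(1, 0.01, 0.1)
    p <- twotcmParams(K1, 0.15, k3, 0.03, 0.03)
    tac <- simulateTac(p, INPUT, FS, noiseSpec(0.05, i))
    vts <- c(vts, vT(loganVt(tac, INPUT, tStar = 30)))
    suvs <- c(suvs, computeSuv(tac, dose = 4, weight = 30)$suv)
  }
  agree <- correlate(vts, suvs, "spearman")
  expect_gt(agree$r2, 0.9)
})
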