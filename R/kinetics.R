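## Two-tissue-compartment forward model, weighted nonlinear fitting, Logan
## graphical analysis, time-stability truncation and SUV.
##
## Forward model on the input's uniform fine grid:
##   C_model(t) = (1 - vB) (h (x) C_p)(t) + vB C_wb(t)
##   h(t) = K1/(a2 - a1) [ (k3 + k4 - a1) e^(-a1 t) + (a2 - k3 - k4) e^(-a2 t) ]
##   a1,2 = 0.5 [ (k2 + k3 + k4) -/+ sqrt((k2 + k3 + k4)^2 - 4 k2 k4) ]
## The exponential convolutions are exact for a piecewise-linear C_p
## (recursive update evaluated with stats::filter), then frame-averaged.

#' Two-tissue-compartment model parameters
#'
#' @param K1 delivery rate, mL cm^-3 min^-1.
#' @param k2,k3,k4 tissue rate constants, min^-1 (k4 > 0 whenever k3 > 0).
#' @param vB fractional blood volume, in [0, 0.2].
#' @return a \linkS4class{TwoTcmParams}.
#' @examples
#' p <- twotcmParams(K1 = 0.5, k2 = 0.25, k3 = 0.05, k4 = 0.05)
#' vT(p)  # (0.5/0.25) * (1 + 1) = 4
#' @export
twotcmParams <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  new("TwoTcmParams", K1 = as.numeric(K1), k2 = as.numeric(k2),
      k3 = as.numeric(k3), k4 = as.numeric(k4), vB = as.numeric(vB))
}

#' @rdname vT
#' @export
setMethod("vT", "TwoTcmParams", function(x) {
  bp <- if (x@k3 == 0) 0 else x@k3 / x@k4
  (x@K1 / x@k2) * (1 + bp)
})

#' @rdname vT
#' @export
setMethod("vT", "TwoTcmFit", function(x) x@vT)

#' @rdname vT
#' @export
setMethod("vT", "LoganResult", function(x) x@vT)

setMethod("show", "TwoTcmParams", function(object) {
  cat(sprintf(
    "TwoTcmParams: K1=%.4g k2=%.4g k3=%.4g k4=%.4g vB=%.3g  (V_T = %.4g)\n",
    object@K1, object@k2, object@k3, object@k4, object@vB, vT(object)))
})

setMethod("show", "TwoTcmFit", function(object) {
  p <- object@params
  cat(sprintf("TwoTcmFit: V_T = %.4g mL/cm^3 (%sconverged, %d starts)\n",
              object@vT, if (object@converged) "" else "NOT ",
              as.integer(object@nRestarts)))
  cat(sprintf("  K1=%.4g k2=%.4g k3=%.4g k4=%.4g vB=%.3g  wRSS=%.4g\n",
              p@K1, p@k2, p@k3, p@k4, p@vB, object@rss))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "LoganResult", function(object) {
  cat(sprintf(
    "LoganResult: V_T = %.4g mL/cm^3 (t* = %g min, %d points, r2 = %.4f)\n",
    object@vT, object@tStar, as.integer(object@nPoints), object@r2))
})

## Exact convolution of exp(-alpha t) with a piecewise-linear curve sampled
## on a uniform grid (step dt). Returns the convolution at the grid points.
expConvLin <- function(alpha, dt, cp) {
  n <- length(cp)
  if (n < 2) return(numeric(n))
  c0 <- cp[-n]; c1 <- cp[-1]
  if (alpha * dt < 1e-10) {
    seg <- dt * (c0 + c1) / 2
    return(c(0, cumsum(seg)))
  }
  E <- exp(-alpha * dt)
  seg <- c1 * (1 - E) / alpha +
    ((c0 - c1) / dt) * (1 - E * (1 + alpha * dt)) / alpha^2
  c(0, stats::filter(seg, E, method = "recursive"))
}

## Tissue impulse-response convolved with the plasma-parent input, on the
## input's fine grid.
twotcmTissueCurve <- function(params, input) {
  K1 <- params@K1; k2 <- params@k2; k3 <- params@k3; k4 <- params@k4
  t <- input@times; dt <- t[2] - t[1]
  cp <- input@plasmaParent
  if (K1 == 0) return(numeric(length(t)))
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 0) disc <- 0  # numeric guard; impossible for valid params
  rt <- sqrt(disc)
  if (rt < 1e-9 * max(s, 1)) {  # near-repeated roots: separate slightly
    k4 <- k4 * (1 + 1e-6) + 1e-9
    s <- k2 + k3 + k4
    rt <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  }
  a1 <- (s - rt) / 2
  a2 <- (s + rt) / 2
  (K1 / (a2 - a1)) * ((k3 + k4 - a1) * expConvLin(a1, dt, cp) +
                      (a2 - k3 - k4) * expConvLin(a2, dt, cp))
}

## Frame averages of a finely sampled curve via its cumulative trapezoid
## integral, linearly interpolated at frame boundaries.
frameAverage <- function(times, curve, fs) {
  ends <- frameEnds(fs)
  if (min(frameStarts(fs)) < times[1] - 1e-9 ||
      max(ends) > times[length(times)] + 1e-9)
    stop("input grid does not cover the frame schedule")
  dt <- diff(times)
  cum <- c(0, cumsum(dt * (curve[-length(curve)] + curve[-1]) / 2))
  Ia <- approx(times, cum, xout = frameStarts(fs))$y
  Ib <- approx(times, cum, xout = ends)$y
  (Ib - Ia) / frameDurations(fs)
}

#' Frame-averaged two-tissue-compartment model prediction
#'
#' Evaluates the model curve (1 - vB) (h (x) C_p) + vB C_wb on the input's
#' fine grid and averages it over each acquisition frame.
#'
#' @param params a \linkS4class{TwoTcmParams}.
#' @param input an \linkS4class{InputFunction} whose grid covers the
#'   schedule.
#' @param fs a \linkS4class{FrameSchedule}.
#' @return numeric vector of frame-averaged model concentrations (kBq/mL).
#' @export
twotcmPredict <- function(params, input, fs) {
  stopifnot(is(params, "TwoTcmParams"), is(input, "InputFunction"),
            is(fs, "FrameSchedule"))
  ct <- twotcmTissueCurve(params, input)
  cm <- (1 - params@vB) * ct + params@vB * input@wholeBlood
  frameAverage(input@times, cm, fs)
}

#' Fit the two-tissue-compartment model to one regional TAC
#'
#' Minimizes the weighted residual sum of squares
#' sum(w_i (C_obs,i - C_model,i)^2) by Levenberg-Marquardt within box bounds,
#' restarted from seeded log-uniform parameter draws. Deterministic for a
#' fixed seed.
#'
#' @param tac a \linkS4class{TacTable}; if it holds several regions, name one
#'   via \code{region}.
#' @param input an \linkS4class{InputFunction} covering the schedule.
#' @param region region column to fit (default: the single region present).
#' @param weights \code{"duration"} (default, w_i = frame duration),
#'   \code{"uniform"}, or a numeric vector of length nFrames.
#' @param lower,upper parameter bounds for (K1, k2, k3, k4, vB). Defaults:
#'   K1 in (0, 2], k2, k3, k4 in (0, 1] min^-1, vB in [0, 0.2].
#' @param vBFixed optional fixed blood-volume fraction (disables vB fitting).
#' @param restarts number of multi-start draws (default 10).
#' @param seed integer seed for the start draws.
#' @return a \linkS4class{TwoTcmFit}.
#' @export
fit2tcm <- function(tac, input, region = NULL, weights = "duration",
                    lower = c(1e-4, 1e-4, 1e-5, 1e-5, 0),
                    upper = c(2, 1, 1, 1, 0.2),
                    vBFixed = NULL, restarts = 10, seed = 1) {
  fs <- schedule(tac)
  if (nFrames(fs) < 10) stop("need at least 10 frames to fit the 2TCM")
  if (is.null(region)) {
    if (ncol(tac@values) != 1)
      stop("tac holds several regions; specify `region`")
    region <- colnames(tac@values)[1]
  }
  obs <- tacValues(tac, region)
  if (all(abs(obs) < 1e-12)) stop("degenerate input: all-zero TAC")
  w <- if (identical(weights, "duration")) frameDurations(fs)
       else if (identical(weights, "uniform")) rep(1, nFrames(fs))
       else as.numeric(weights)
  stopifnot(length(w) == nFrames(fs), all(w > 0))
  sw <- sqrt(w)

  fitVB <- is.null(vBFixed)
  makePar <- function(th) {
    vb <- if (fitVB) th[5] else vBFixed
    twotcmParams(th[1], th[2], th[3], th[4], vb)
  }
  ## rate constants are optimized on the log scale (vB stays linear):
  ## evens out parameter sensitivities and keeps the LM steps well scaled
  toTheta <- function(u) c(exp(u[1:4]), if (fitVB) u[5])
  residFun <- function(u) {
    sw * (twotcmPredict(makePar(toTheta(u)), input, fs) - obs)
  }
  npar <- if (fitVB) 5L else 4L
  lo <- c(log(lower[1:4]), if (fitVB) lower[5])
  hi <- c(log(upper[1:4]), if (fitVB) upper[5])

  ## seeded log-uniform starts within bounds (vB start uniform on its
  ## interval), preceded by deterministic starts covering slow, mid and
  ## fast kinetic regimes
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  drawLo <- log(pmax(lower[1:4], c(0.02, 0.002, 0.002, 0.002)))
  drawHi <- log(upper[1:4])
  starts <- list(c(log(c(0.2, 0.1, 0.02, 0.02)), if (fitVB) 0.05),
                 c(log(c(0.6, 0.3, 0.1, 0.05)), if (fitVB) 0.05),
                 c(log(c(0.08, 0.04, 0.005, 0.01)), if (fitVB) 0.05))
  for (i in seq_len(max(restarts - 3L, 0L))) {
    u <- runif(4, drawLo, drawHi)
    if (fitVB) u <- c(u, runif(1, lower[5], upper[5]))
    starts[[length(starts) + 1L]] <- u
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  best <- NULL
  for (u0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = u0, fn = residFun, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) { best <- fit }
  }
  if (is.null(best)) stop("2TCM fit failed on all restarts")
  th <- toTheta(best$par)
  params <- makePar(th)
  flags <- character(0)
  nm <- c("K1", "k2", "k3", "k4", if (fitVB) "vB")
  linLo <- lower[seq_len(npar)]; linHi <- upper[seq_len(npar)]
  atLo <- th <= linLo * (1 + 1e-4) + 1e-12
  atHi <- th >= linHi * (1 - 1e-4)
  if (any(atLo)) flags <- c(flags, paste0(nm[atLo], "-at-lower-bound"))
  if (any(atHi)) flags <- c(flags, paste0(nm[atHi], "-at-upper-bound"))
  if (th[1] <= linLo[1] * (1 + 1e-4))
    flags <- c(flags, "unidentifiable: K1 at lower bound")
  new("TwoTcmFit", params = params, vT = vT(params), rss = best$deviance,
      converged = best$info %in% 1:4, nRestarts = as.numeric(restarts),
      flags = flags)
}

#' Logan graphical analysis of the total volume of distribution
#'
#' Regresses y(T) = int_0^T C_obs dt / C_obs(T) on
#' x(T) = int_0^T C_p dt / C_p... using frames whose midpoint is at or after
#' t*; the slope of the late linear segment estimates V_T. Tissue integrals
#' use the trapezoid rule on frame midpoints (anchored at the origin); the
#' input is integrated on its fine grid.
#'
#' With \code{tStar = "auto"} the smallest frame-start time for which the
#' maximum relative residual of the linear fit is at most 10\% is chosen.
#'
#' @param tac a \linkS4class{TacTable} (single region or \code{region}
#'   given).
#' @param input an \linkS4class{InputFunction}.
#' @param tStar start of the linear segment in minutes, or \code{"auto"}.
#' @param region region column to analyse.
#' @param maxRelResid relative-residual threshold used by \code{"auto"}.
#' @return a \linkS4class{LoganResult}.
#' @export
loganVt <- function(tac, input, tStar = 30, region = NULL,
                    maxRelResid = 0.10) {
  fs <- schedule(tac)
  if (is.null(region)) {
    if (ncol(tac@values) != 1)
      stop("tac holds several regions; specify `region`")
    region <- colnames(tac@values)[1]
  }
  obs <- tacValues(tac, region)
  mid <- frameMidpoints(fs)

  ## cumulative tissue integral at midpoints (trapezoid, anchored at 0)
  tt <- c(0, mid); cc <- c(0, obs)
  cumT <- cumsum(c(0, diff(tt) * (cc[-length(cc)] + cc[-1]) / 2))[-1]
  ## cumulative input integral on the fine grid, read off at midpoints
  gt <- input@times; cp <- input@plasmaParent
  cumP <- c(0, cumsum(diff(gt) * (cp[-length(cp)] + cp[-1]) / 2))
  cumPmid <- approx(gt, cumP, xout = mid)$y

  fitAt <- function(ts) {
    use <- mid >= ts - 1e-9
    if (sum(use) < 3) return(NULL)
    if (any(obs[use] <= 0))
      stop("nonpositive late-frame TAC values; Logan undefined")
    x <- cumPmid[use] / obs[use]
    y <- cumT[use] / obs[use]
    fit <- lm(y ~ x)
    res <- list(slope = unname(coef(fit)[2]), icpt = unname(coef(fit)[1]),
                r2 = summary(fit)$r.squared, n = sum(use),
                maxRel = max(abs(fit$residuals) / pmax(abs(y), 1e-12)))
    res
  }

  if (identical(tStar, "auto")) {
    chosen <- NULL
    for (cand in frameStarts(fs)) {
      # candidates whose segment still contains nonpositive frames are skipped
      r <- tryCatch(fitAt(cand), error = function(e) NA)
      if (is.null(r)) break
      if (identical(r, NA)) next
      if (r$maxRel <= maxRelResid) { chosen <- list(ts = cand, r = r); break }
    }
    if (is.null(chosen))
      stop("no t* satisfies the maximum-relative-residual criterion")
    tStar <- chosen$ts; r <- chosen$r
  } else {
    r <- fitAt(tStar)
    if (is.null(r))
      stop("insufficient data: fewer than 3 frames at or after t*")
  }
  new("LoganResult", vT = r$slope, intercept = r$icpt, tStar = as.numeric(tStar),
      r2 = r$r2, nPoints = as.numeric(r$n))
}

#' Time-stability of Logan V_T under scan truncation
#'
#' Recomputes the Logan V_T after truncating the acquisition to each
#' requested duration (t* unchanged) and expresses it as a percentage of the
#' full-scan V_T.
#'
#' @param tac a \linkS4class{TacTable} covering the full scan.
#' @param input an \linkS4class{InputFunction}.
#' @param durations truncation durations in minutes, each > t* and <= full
#'   scan.
#' @param tStar Logan t* (min), kept fixed across truncations.
#' @param region region column to analyse.
#' @return data.frame with columns \code{duration_min}, \code{vt},
#'   \code{percent_of_full}.
#' @export
timeStability <- function(tac, input, durations, tStar = 30, region = NULL) {
  full <- scanDuration(schedule(tac))
  if (any(durations <= tStar))
    stop("every truncation duration must exceed t*")
  if (any(durations > full + 1e-9))
    stop("durations cannot exceed the full scan")
  vtFull <- vT(loganVt(tac, input, tStar = tStar, region = region))
  rows <- lapply(durations, function(d) {
    v <- vT(loganVt(truncateTac(tac, d), input, tStar = tStar,
                    region = region))
    data.frame(duration_min = d, vt = v, percent_of_full = 100 * v / vtFull)
  })
  out <- do.call(rbind, rows)
  attr(out, "vt_full") <- vtFull
  out
}

#' Standardized uptake value over a late static window
#'
#' Duration-weighted mean concentration over the frames lying fully inside
#' the window, divided by injected dose per body weight. Unit contract:
#' kBq/mL divided by (MBq x 1000 / g) = kBq/g gives SUV in g/mL.
#'
#' @param tac a \linkS4class{TacTable}.
#' @param dose injected dose in MBq.
#' @param weight body weight in g.
#' @param window static window in minutes, default c(100, 120).
#' @param region region column.
#' @return list of class \code{SuvResult}: \code{suv} (g/mL),
#'   \code{mean_conc} (kBq/mL), \code{window}, \code{n_frames}, \code{dose},
#'   \code{weight}.
#' @export
computeSuv <- function(tac, dose, weight, window = c(100, 120),
                       region = NULL) {
  stopifnot(dose > 0, weight > 0, length(window) == 2, window[2] > window[1])
  fs <- schedule(tac)
  if (window[1] < -1e-9 || window[2] > scanDuration(fs) + 1e-9)
    stop("window must lie within the scan span")
  if (is.null(region)) {
    if (ncol(tac@values) != 1)
      stop("tac holds several regions; specify `region`")
    region <- colnames(tac@values)[1]
  }
  inWin <- frameStarts(fs) >= window[1] - 1e-9 &
           frameEnds(fs) <= window[2] + 1e-9
  if (!any(inWin)) stop("no frame lies fully inside the SUV window")
  v <- tacValues(tac, region)[inWin]
  d <- frameDurations(fs)[inWin]
  meanConc <- sum(v * d) / sum(d)
  suv <- meanConc / (dose * 1000 / weight)
  structure(list(suv = suv, mean_conc = meanConc, window = window,
                 n_frames = sum(inWin), dose = dose, weight = weight,
                 region = region),
            class = "SuvResult")
}

#' @export
print.SuvResult <- function(x, ...) {
  cat(sprintf("SUV = %.4g g/mL (window %g-%g min, %d frames, %.3g kBq/mL mean)\n",
              x$suv, x$window[1], x$window[2], x$n_frames, x$mean_conc))
  invisible(x)
}

#' Physical decay of the injected dose (optional utility)
#'
#' Remaining activity of an F-18 dose after \code{elapsedMin} minutes.
#' Frame activities in this package are decay-corrected, so this is only
#' needed when relating doses measured at different times.
#'
#' @param dose activity at calibration (MBq).
#' @param elapsedMin minutes elapsed.
#' @param halflife physical half-life in minutes (default F-18, 109.8).
#' @return decayed activity in MBq.
#' @export
decayedDose <- function(dose, elapsedMin, halflife = F18_HALFLIFE_MIN) {
  dose * 2^(-elapsedMin / halflife)
}

#' Per-region kinetic quantification report
#'
#' Runs the 2TCM fit, Logan analysis and SUV for every region of a TAC
#' table, returning one row per region.
#'
#' @param tac a \linkS4class{TacTable}.
#' @param input an \linkS4class{InputFunction}.
#' @param dose,weight injected dose (MBq) and body weight (g) for SUV.
#' @param tStar Logan t* (min).
#' @param suvWindow SUV window (min).
#' @param ... further arguments passed to [fit2tcm()].
#' @return data.frame: region, K1, k2, k3, k4, vB, V_T_2tcm, V_T_logan,
#'   logan_r2, suv, flags.
#' @export
quantifyRegions <- function(tac, input, dose, weight, tStar = 30,
                            suvWindow = c(100, 120), ...) {
  rows <- lapply(regionNames(tac), function(rg) {
    fit <- fit2tcm(tac, input, region = rg, ...)
    lg <- loganVt(tac, input, tStar = tStar, region = rg)
    sv <- computeSuv(tac, dose, weight, window = suvWindow, region = rg)
    p <- fit@params
    data.frame(region = rg, K1 = p@K1, k2 = p@k2, k3 = p@k3, k4 = p@k4,
               vB = p@vB, V_T_2tcm = fit@vT, V_T_logan = lg@vT,
               logan_r2 = lg@r2, suv = sv$suv,
               flags = paste(fit@flags, collapse = ";"))
  })
  do.call(rbind, rows)
}
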