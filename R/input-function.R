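## Metabolite-corrected input-function construction.
##
## The plasma-parent input is built multiplicatively from the whole-blood
## curve: C_p(t) = C_wb(t) * (r0 + r1 t) * f(t), with a linear
## plasma-to-whole-blood ratio and a biexponential intact-parent fraction
## f(t) = a1 exp(-mu1 t) + a2 exp(-mu2 t).

#' Biexponential intact-parent fraction model
#'
#' f(t) = a1 exp(-mu1 t) + a2 exp(-mu2 t), the fraction of plasma activity
#' attributable to intact (unmetabolized) radioligand. Must stay within
#' [0, 1] over the scan window.
#'
#' @param a1,a2 unitless weights.
#' @param mu1,mu2 decay rates, per minute, nonnegative.
#' @param window time span (min) over which validity is enforced.
#' @return an object of class \code{ParentFractionModel}.
#' @seealso [defaultParentFraction()], [fitParentFraction()]
#' @export
parentFractionModel <- function(a1, mu1, a2, mu2, window = c(0, 120)) {
  if (mu1 < 0 || mu2 < 0) stop("decay rates must be nonnegative")
  m <- structure(list(a1 = a1, mu1 = mu1, a2 = a2, mu2 = mu2),
                 class = "ParentFractionModel")
  tt <- seq(window[1], window[2], length.out = 241)
  f <- predict(m, tt)
  if (any(f < -1e-9) || any(f > 1 + 1e-9))
    stop("parent fraction model leaves [0, 1] on the scan window")
  m
}

#' @export
predict.ParentFractionModel <- function(object, t, ...) {
  object$a1 * exp(-object$mu1 * t) + object$a2 * exp(-object$mu2 * t)
}

#' @export
print.ParentFractionModel <- function(x, ...) {
  cat(sprintf("ParentFractionModel: f(t) = %.4g exp(-%.4g t) + %.4g exp(-%.4g t)\n",
              x$a1, x$mu1, x$a2, x$mu2))
  if (!is.null(attr(x, "rss")))
    cat(sprintf("  fit RSS: %.4g\n", attr(x, "rss")))
  invisible(x)
}

#' Default calibrated parent-fraction model
#'
#' Constructed so that f(0) = 1 (the injectate is pure parent compound) and
#' f(90 min) = 0.799, the intact-parent plasma fraction observed 90 min after
#' injection for this radioligand class. The slow component (a2 = 0.75,
#' mu2 = 5e-4 / min) is fixed and the fast rate mu1 is solved in closed form.
#'
#' @return a \code{ParentFractionModel} with f(0) = 1, f(90) = 0.799.
#' @examples
#' pf <- defaultParentFraction()
#' predict(pf, c(0, 90))
#' @export
defaultParentFraction <- function() {
  a2 <- 0.75; mu2 <- 5e-4; a1 <- 1 - a2
  target90 <- 0.799
  mu1 <- -log((target90 - a2 * exp(-mu2 * 90)) / a1) / 90
  parentFractionModel(a1 = a1, mu1 = mu1, a2 = a2, mu2 = mu2)
}

#' Linear plasma-to-whole-blood ratio model
#'
#' ratio(t) = r0 + r1 t; must stay positive over the scan window.
#'
#' @param r0 unitless intercept.
#' @param r1 slope, per minute.
#' @param window time span (min) over which positivity is enforced.
#' @return an object of class \code{PlasmaToBloodModel}.
#' @export
plasmaToBloodModel <- function(r0, r1, window = c(0, 120)) {
  if (min(r0 + r1 * window) <= 0)
    stop("plasma-to-whole-blood ratio must be positive on the scan window")
  structure(list(r0 = r0, r1 = r1), class = "PlasmaToBloodModel")
}

#' @export
predict.PlasmaToBloodModel <- function(object, t, ...) object$r0 + object$r1 * t

#' @export
print.PlasmaToBloodModel <- function(x, ...) {
  cat(sprintf("PlasmaToBloodModel: ratio(t) = %.4g + %.4g t", x$r0, x$r1))
  if (!is.null(attr(x, "r2"))) cat(sprintf("  (r2 = %.4f)", attr(x, "r2")))
  cat("\n"); invisible(x)
}

#' Default plasma-to-whole-blood ratio model
#'
#' A mildly increasing ratio typical of small radioligands partitioning
#' slightly into plasma: ratio(t) = 1.1 + 0.001 t.
#' @return a \code{PlasmaToBloodModel}.
#' @export
defaultPlasmaToBlood <- function() plasmaToBloodModel(r0 = 1.1, r1 = 0.001)

#' Validate a blood-sampling table
#'
#' Columns: \code{time} (min, strictly increasing), \code{whole_blood} and
#' \code{plasma} (kBq/mL, nonnegative), optional \code{parent_fraction} in
#' [0, 1].
#'
#' @param samples a data.frame.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validateBloodTable <- function(samples) {
  need <- c("time", "whole_blood", "plasma")
  if (!all(need %in% names(samples)))
    stop("blood table must contain columns: ", paste(need, collapse = ", "))
  if (is.unsorted(samples$time, strictly = TRUE))
    stop("sample times must be strictly increasing")
  if (any(samples$whole_blood < 0, na.rm = TRUE) ||
      any(samples$plasma < 0, na.rm = TRUE))
    stop("activities must be nonnegative")
  if ("parent_fraction" %in% names(samples)) {
    pf <- samples$parent_fraction
    if (any(pf < 0 | pf > 1, na.rm = TRUE))
      stop("parent fractions must lie in [0, 1]")
  }
  samples
}

#' Fit a biexponential intact-parent fraction to blood samples
#'
#' Weighted least squares fit of f(t) = a1 exp(-mu1 t) + a2 exp(-mu2 t) to
#' measured parent fractions, by Levenberg-Marquardt from several
#' deterministic starts. With \code{constrainT0 = TRUE} (default) a1 + a2 = 1
#' is enforced, reflecting a radiochemically pure injectate. Components of
#' the returned model are ordered by increasing decay rate.
#'
#' @param samples blood table (see [validateBloodTable()]) with a
#'   \code{parent_fraction} column.
#' @param constrainT0 logical; force f(0) = 1.
#' @param weights optional per-sample weights (default uniform); supply
#'   1/SD^2 for inverse-variance weighting when replicate SDs are available.
#' @param extractionEfficiency optional scalar in (0, 1]; measured fractions
#'   are divided by it before fitting (off by default).
#' @return a \code{ParentFractionModel} with attribute \code{rss}, the
#'   weighted residual sum of squares.
#' @export
fitParentFraction <- function(samples, constrainT0 = TRUE, weights = NULL,
                              extractionEfficiency = NULL) {
  samples <- validateBloodTable(samples)
  if (!"parent_fraction" %in% names(samples))
    stop("samples carry no parent_fraction column")
  ok <- !is.na(samples$parent_fraction)
  t <- samples$time[ok]
  f <- samples$parent_fraction[ok]
  if (!is.null(extractionEfficiency)) {
    stopifnot(extractionEfficiency > 0, extractionEfficiency <= 1)
    f <- pmin(f / extractionEfficiency, 1)
  }
  needed <- if (constrainT0) 3L else 4L
  if (length(t) < needed)
    stop("under-determined: need at least ", needed, " parent-fraction samples")
  w <- if (is.null(weights)) rep(1, length(t)) else weights[ok]
  sw <- sqrt(w)

  resid_fun <- if (constrainT0) {
    function(p) sw * (p[1] * exp(-p[2] * t) + (1 - p[1]) * exp(-p[3] * t) - f)
  } else {
    function(p) sw * (p[1] * exp(-p[2] * t) + p[4] * exp(-p[3] * t) - f)
  }
  lower <- if (constrainT0) c(0, 0, 0) else c(0, 0, 0, 0)
  upper <- if (constrainT0) c(1, 2, 2) else c(1.5, 2, 2, 1.5)
  starts <- list(c(0.5, 0.05, 0.001), c(0.3, 0.01, 1e-4),
                 c(0.7, 0.1, 0.005), c(0.9, 0.02, 0), c(0.2, 0.5, 0.01))
  best <- NULL
  for (s in starts) {
    p0 <- if (constrainT0) s else c(s[1], s[2], s[3], max(0, 1 - s[1]))
    fit <- try(minpack.lm::nls.lm(
      par = p0, fn = resid_fun, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("parent-fraction fit failed to converge")
  p <- best$par
  a1 <- p[1]; mu1 <- p[2]; mu2 <- p[3]
  a2 <- if (constrainT0) 1 - p[1] else p[4]
  comp <- if (mu1 <= mu2) c(a1, mu1, a2, mu2) else c(a2, mu2, a1, mu1)
  m <- parentFractionModel(comp[1], comp[2], comp[3], comp[4])
  attr(m, "rss") <- best$deviance
  m
}

#' Fit a linear plasma-to-whole-blood ratio
#'
#' Ordinary least squares of the per-sample plasma/whole-blood ratio against
#' time.
#'
#' @param samples blood table with positive \code{whole_blood} and
#'   \code{plasma} values.
#' @return a \code{PlasmaToBloodModel} with attribute \code{r2}.
#' @export
fitPlasmaToBlood <- function(samples) {
  samples <- validateBloodTable(samples)
  ok <- !is.na(samples$plasma) & !is.na(samples$whole_blood)
  if (any(samples$whole_blood[ok] == 0))
    stop("whole-blood activity of zero in a used sample")
  t <- samples$time[ok]
  ratio <- samples$plasma[ok] / samples$whole_blood[ok]
  if (length(t) < 2) stop("under-determined: need at least 2 valid samples")
  fit <- lm(ratio ~ t)
  m <- plasmaToBloodModel(r0 = unname(coef(fit)[1]), r1 = unname(coef(fit)[2]))
  # noise-free tables fit exactly; the usual summary.lm caveat is moot
  attr(m, "r2") <- suppressWarnings(summary(fit)$r.squared)
  m
}

#' Metabolite-correct a whole-blood curve into a plasma-parent input
#'
#' Applies the pointwise multiplicative correction
#' C_p(t) = C_wb(t) (r0 + r1 t) f(t). The whole-blood samples are
#' piecewise-linearly interpolated onto a uniform grid; the whole-blood curve
#' itself is passed through unchanged.
#'
#' @param times sample times of the whole-blood curve (min, from 0).
#' @param wholeBlood whole-blood activity at those times (kBq/mL).
#' @param p2wb a \code{PlasmaToBloodModel}.
#' @param pf a \code{ParentFractionModel}.
#' @param gridStep uniform output grid step (min), default 0.05.
#' @param tEnd end of the output grid (min); defaults to the last sample
#'   time, but should be set to the scan end when the samples are frame
#'   midpoints (the tail is extended by last-value carry-forward).
#' @return an \linkS4class{InputFunction}.
#' @export
correctIdif <- function(times, wholeBlood, p2wb, pf, gridStep = 0.05,
                        tEnd = max(times)) {
  stopifnot(length(times) == length(wholeBlood), gridStep > 0)
  if (any(wholeBlood < 0)) stop("whole-blood curve must be nonnegative")
  grid <- seq(0, tEnd, by = gridStep)
  wb <- approx(times, wholeBlood, xout = grid, rule = 2)$y
  ratio <- predict(p2wb, grid)
  frac <- predict(pf, grid)
  if (any(ratio <= 0)) stop("invalid model: plasma-to-blood ratio <= 0 on span")
  if (any(frac < -1e-9 | frac > 1 + 1e-9))
    stop("invalid model: parent fraction outside [0, 1] on span")
  inputFunction(grid, wb, wb * ratio * pmin(pmax(frac, 0), 1))
}

#' Construct and interrogate input functions
#'
#' An \linkS4class{InputFunction} holds the whole-blood and
#' metabolite-corrected plasma-parent activity curves on a shared uniform
#' grid.
#'
#' @param times uniform grid (min) starting at 0.
#' @param wholeBlood,plasmaParent activity curves (kBq/mL).
#' @param x an \linkS4class{InputFunction}.
#' @return \code{inputFunction} returns an \linkS4class{InputFunction};
#'   accessors return the corresponding numeric vector.
#' @name inputFunction
#' @aliases InputFunction-class
#' @export
inputFunction <- function(times, wholeBlood, plasmaParent) {
  new("InputFunction", times = as.numeric(times),
      wholeBlood = pmax(as.numeric(wholeBlood), 0),
      plasmaParent = pmax(as.numeric(plasmaParent), 0))
}

#' @rdname inputFunction
#' @export
setMethod("gridTimes", "InputFunction", function(x) x@times)

#' @rdname inputFunction
#' @export
setMethod("wholeBlood", "InputFunction", function(x) x@wholeBlood)

#' @rdname inputFunction
#' @export
setMethod("plasmaParent", "InputFunction", function(x) x@plasmaParent)

setMethod("show", "InputFunction", function(object) {
  t <- object@times
  cat(sprintf("InputFunction: %d points, 0-%g min (step %.4g min)\n",
              length(t), t[length(t)], t[2] - t[1]))
  cat(sprintf("  whole blood peak %.3g kBq/mL at %.2f min; plasma parent peak %.3g kBq/mL\n",
              max(object@wholeBlood), t[which.max(object@wholeBlood)],
              max(object@plasmaParent)))
})
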