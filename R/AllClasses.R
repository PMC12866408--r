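## Core S4 containers. All times are minutes, activities kBq/mL.

#' FrameSchedule: ordered, contiguous PET acquisition frames
#'
#' Defines the frame grid over which model curves are averaged. Frames are
#' half-open intervals [start, end) in minutes; the schedule must begin at 0,
#' be contiguous, and have strictly positive durations.
#'
#' @slot starts numeric vector of frame start times (min), first element 0.
#' @slot durations numeric vector of frame durations (min), all > 0.
#' @export
setClass("FrameSchedule",
  representation(starts = "numeric", durations = "numeric"),
  validity = function(object) {
    s <- object@starts; d <- object@durations
    if (length(s) != length(d)) return("starts and durations differ in length")
    if (length(s) == 0) return("schedule is empty")
    if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite frame times")
    if (abs(s[1]) > 1e-12) return("first frame must start at 0")
    if (any(d <= 0)) return("all frame durations must be > 0")
    if (length(s) > 1 &&
        any(abs(s[-1] - (s[-length(s)] + d[-length(d)])) > 1e-9))
      return("frames are not contiguous")
    TRUE
  })

#' InputFunction: whole-blood and metabolite-corrected plasma-parent curves
#'
#' Both curves are sampled on a shared uniform time grid starting at 0 and
#' covering at least the scan span.
#'
#' @slot times numeric uniform grid (min) from 0.
#' @slot wholeBlood numeric whole-blood activity (kBq/mL), nonnegative.
#' @slot plasmaParent numeric metabolite-corrected plasma-parent activity
#'   (kBq/mL), nonnegative.
#' @export
setClass("InputFunction",
  representation(times = "numeric", wholeBlood = "numeric",
                 plasmaParent = "numeric"),
  validity = function(object) {
    t <- object@times
    if (length(t) < 2) return("grid needs at least 2 points")
    if (abs(t[1]) > 1e-12) return("grid must start at 0")
    dt <- diff(t)
    if (any(dt <= 0)) return("grid times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(dt)) return("grid must be uniform")
    if (length(object@wholeBlood) != length(t) ||
        length(object@plasmaParent) != length(t))
      return("curve lengths must match the grid")
    if (any(!is.finite(object@wholeBlood)) ||
        any(!is.finite(object@plasmaParent)))
      return("non-finite curve values")
    if (any(object@wholeBlood < -1e-9) || any(object@plasmaParent < -1e-9))
      return("curves must be nonnegative")
    TRUE
  })

#' TwoTcmParams: rate constants of the reversible two-tissue model
#'
#' K1 (mL cm^-3 min^-1) and k2 (min^-1) must be positive; k3, k4 (min^-1)
#' nonnegative, with k4 > 0 whenever k3 > 0 so the model stays reversible and
#' V_T = (K1/k2) (1 + k3/k4) is finite. vB is the fractional blood volume.
#'
#' @slot K1,k2,k3,k4 numeric rate constants.
#' @slot vB numeric blood volume fraction in [0, 0.2].
#' @export
setClass("TwoTcmParams",
  representation(K1 = "numeric", k2 = "numeric", k3 = "numeric",
                 k4 = "numeric", vB = "numeric"),
  validity = function(object) {
    p <- c(object@K1, object@k2, object@k3, object@k4, object@vB)
    if (length(p) != 5 || any(!is.finite(p))) return("all five parameters must be finite scalars")
    if (object@K1 < 0) return("K1 must be >= 0")
    if (object@k2 <= 0) return("k2 must be > 0")
    if (object@k3 < 0 || object@k4 < 0) return("k3 and k4 must be >= 0")
    if (object@k3 > 0 && object@k4 <= 0)
      return("reversible model requires k4 > 0 when k3 > 0")
    if (object@vB < 0 || object@vB > 0.2) return("vB must lie in [0, 0.2]")
    TRUE
  })

#' TacTable: frame-averaged regional activity concentrations for one scan
#'
#' Values are kBq/mL, one column per region, one row per frame. Negative
#' values are permitted (reconstruction noise) but are flagged by
#' \code{hasNegativeFrames}.
#'
#' @slot schedule a \linkS4class{FrameSchedule}.
#' @slot values numeric matrix, frames x regions, with region column names.
#' @export
setClass("TacTable",
  representation(schedule = "FrameSchedule", values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (nrow(v) != length(object@schedule@starts))
      return("one row per frame required")
    if (is.null(colnames(v)) || any(!nzchar(colnames(v))) ||
        anyDuplicated(colnames(v)))
      return("region columns must have unique nonempty names")
    if (any(!is.finite(v))) return("all values must be finite")
    TRUE
  })

#' TwoTcmFit: result of fitting the two-tissue model to one regional TAC
#'
#' @slot params fitted \linkS4class{TwoTcmParams}.
#' @slot vT total volume of distribution (mL/cm^3), (K1/k2)(1 + k3/k4).
#' @slot rss weighted residual sum of squares of the best start.
#' @slot converged logical convergence flag.
#' @slot nRestarts number of multi-start draws used.
#' @slot flags character vector of diagnostic flags (may be empty).
#' @export
setClass("TwoTcmFit",
  representation(params = "TwoTcmParams", vT = "numeric", rss = "numeric",
                 converged = "logical", nRestarts = "numeric",
                 flags = "character"),
  validity = function(object) {
    if (object@rss < -1e-12) return("rss must be >= 0")
    TRUE
  })

#' LoganResult: Logan graphical analysis of one regional TAC
#'
#' @slot vT slope of the late linear segment = total volume of distribution.
#' @slot intercept intercept of the linear segment (min).
#' @slot tStar earliest midpoint time included (min).
#' @slot r2 coefficient of determination of the linear segment.
#' @slot nPoints number of frames used (>= 3).
#' @export
setClass("LoganResult",
  representation(vT = "numeric", intercept = "numeric", tStar = "numeric",
                 r2 = "numeric", nPoints = "numeric"),
  validity = function(object) {
    if (object@nPoints < 3) return("Logan fit needs at least 3 points")
    if (is.finite(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
      return("r2 must lie in [0, 1]")
    TRUE
  })
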