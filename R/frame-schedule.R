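#' Construct and interrogate acquisition frame schedules
#'
#' \code{frameSchedule} builds a schedule from frame start times and
#' durations (minutes) and validates contiguity. Accessors return the start,
#' end, duration and midpoint of every frame, the frame count, and the total
#' scan duration.
#'
#' @param starts numeric frame start times in minutes, beginning at 0.
#' @param durations numeric frame durations in minutes, all positive.
#' @param x a \linkS4class{FrameSchedule} (or object carrying one).
#' @return \code{frameSchedule} returns a \linkS4class{FrameSchedule}.
#' @examples
#' fs <- frameSchedule(starts = c(0, 1, 2), durations = c(1, 1, 2))
#' frameMidpoints(fs)
#' scanDuration(fs)
#' @name frameSchedule
#' @aliases FrameSchedule-class
#' @export
frameSchedule <- function(starts, durations) {
  new("FrameSchedule", starts = as.numeric(starts),
      durations = as.numeric(durations))
}

#' Build a schedule from groups of equal-duration frames
#'
#' @param counts integer vector, number of frames in each group.
#' @param durations_sec numeric vector, frame duration of each group in
#'   seconds.
#' @return a \linkS4class{FrameSchedule} in minutes.
#' @examples
#' framesFromGroups(c(2, 1), c(30, 60))
#' @export
framesFromGroups <- function(counts, durations_sec) {
  stopifnot(length(counts) == length(durations_sec))
  d <- rep(durations_sec / 60, times = counts)
  frameSchedule(starts = cumsum(c(0, d[-length(d)])), durations = d)
}

#' The 45-frame, 120-minute dynamic mouse acquisition schedule
#'
#' Frames of increasing duration: 12 x 10 s, 3 x 20 s, 3 x 30 s, 3 x 60 s,
#' 3 x 150 s, then 21 x 300 s, totalling exactly 120 min. This is the default
#' schedule used by the synthetic-data generator and the worked examples.
#'
#' @return a \linkS4class{FrameSchedule} with 45 contiguous frames.
#' @examples
#' fs <- defaultFrameSchedule()
#' nFrames(fs)        # 45
#' scanDuration(fs)   # 120
#' @export
defaultFrameSchedule <- function() {
  framesFromGroups(counts = c(12, 3, 3, 3, 3, 21),
                   durations_sec = c(10, 20, 30, 60, 150, 300))
}

#' @rdname frameSchedule
#' @export
setMethod("frameStarts", "FrameSchedule", function(x) x@starts)

#' @rdname frameSchedule
#' @export
setMethod("frameEnds", "FrameSchedule", function(x) x@starts + x@durations)

#' @rdname frameSchedule
#' @export
setMethod("frameDurations", "FrameSchedule", function(x) x@durations)

#' @rdname frameSchedule
#' @export
setMethod("frameMidpoints", "FrameSchedule",
          function(x) x@starts + x@durations / 2)

#' @rdname frameSchedule
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@starts))

#' @rdname frameSchedule
#' @export
setMethod("scanDuration", "FrameSchedule",
          function(x) x@starts[length(x@starts)] +
                      x@durations[length(x@durations)])

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, 0-%g min\n",
              nFrames(object), scanDuration(object)))
  d <- rle(object@durations)
  cat("  groups:", paste(sprintf("%d x %g s", d$lengths, d$values * 60),
                         collapse = ", "), "\n")
})

#' Truncate a schedule to an acquisition duration
#'
#' Keeps frames whose end does not exceed \code{duration} minutes.
#'
#' @param x a \linkS4class{FrameSchedule}.
#' @param duration truncation time in minutes (> first frame end).
#' @return a shorter \linkS4class{FrameSchedule}.
#' @export
truncateSchedule <- function(x, duration) {
  keep <- frameEnds(x) <= duration + 1e-9
  if (!any(keep)) stop("duration shorter than the first frame")
  frameSchedule(x@starts[keep], x@durations[keep])
}
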