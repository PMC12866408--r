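#' Construct and interrogate regional time-activity tables
#'
#' A \linkS4class{TacTable} couples a \linkS4class{FrameSchedule} with a
#' frames x regions matrix of frame-averaged activity concentrations
#' (kBq/mL). Negative frame values are allowed (reconstruction noise) but
#' flagged.
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param values numeric matrix (frames x regions) with region column names,
#'   or a named list / data.frame of per-region numeric vectors.
#' @param x a \linkS4class{TacTable}.
#' @param region region name or index.
#' @return \code{tacTable} returns a \linkS4class{TacTable}.
#' @name tacTable
#' @aliases TacTable-class
#' @export
tacTable <- function(schedule, values) {
  if (is.data.frame(values) || is.list(values))
    values <- do.call(cbind, lapply(values, as.numeric))
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, "region1"))
  new("TacTable", schedule = schedule, values = as.matrix(values))
}

#' @rdname tacTable
#' @export
setMethod("schedule", "TacTable", function(x) x@schedule)

#' @rdname tacTable
#' @export
setMethod("regionNames", "TacTable", function(x) colnames(x@values))

#' @rdname tacTable
#' @export
setMethod("tacValues", "TacTable", function(x, region) {
  if (missing(region)) return(x@values)
  x@values[, region]
})

#' @rdname tacTable
#' @export
setMethod("hasNegativeFrames", "TacTable", function(x) any(x@values < 0))

setMethod("show", "TacTable", function(object) {
  cat(sprintf("TacTable: %d frames x %d region(s) [%s], 0-%g min\n",
              nFrames(object@schedule), ncol(object@values),
              paste(colnames(object@values), collapse = ", "),
              scanDuration(object@schedule)))
  if (hasNegativeFrames(object))
    cat("  note: contains negative frame values (noise)\n")
})

#' Truncate a TAC table to a shorter acquisition
#'
#' @param x a \linkS4class{TacTable}.
#' @param duration truncation time (min).
#' @return a \linkS4class{TacTable} limited to frames ending by
#'   \code{duration}.
#' @export
truncateTac <- function(x, duration) {
  fs <- truncateSchedule(schedule(x), duration)
  tacTable(fs, x@values[seq_len(nFrames(fs)), , drop = FALSE])
}
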