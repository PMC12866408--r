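#' @rdname frameSchedule
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))

#' @rdname frameSchedule
#' @export
setGeneric("frameEnds", function(x) standardGeneric("frameEnds"))

#' @rdname frameSchedule
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))

#' @rdname frameSchedule
#' @export
setGeneric("frameMidpoints", function(x) standardGeneric("frameMidpoints"))

#' @rdname frameSchedule
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname frameSchedule
#' @export
setGeneric("scanDuration", function(x) standardGeneric("scanDuration"))

#' Total volume of distribution implied by a parameter set or fit
#'
#' For two-tissue-compartment parameters, V_T = (K1/k2) (1 + k3/k4); the
#' k3 = 0 special case reduces to K1/k2. For fit and Logan objects the stored
#' estimate is returned.
#'
#' @param x a \linkS4class{TwoTcmParams}, \linkS4class{TwoTcmFit} or
#'   \linkS4class{LoganResult}.
#' @return numeric V_T in mL/cm^3.
#' @export
setGeneric("vT", function(x) standardGeneric("vT"))

#' @rdname inputFunction
#' @export
setGeneric("gridTimes", function(x) standardGeneric("gridTimes"))

#' @rdname inputFunction
#' @export
setGeneric("wholeBlood", function(x) standardGeneric("wholeBlood"))

#' @rdname inputFunction
#' @export
setGeneric("plasmaParent", function(x) standardGeneric("plasmaParent"))

#' @rdname tacTable
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname tacTable
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname tacTable
#' @export
setGeneric("tacValues", function(x, region) standardGeneric("tacValues"))

#' @rdname tacTable
#' @export
setGeneric("hasNegativeFrames", function(x) standardGeneric("hasNegativeFrames"))
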