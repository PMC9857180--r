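#' @rdname chainVolume
#' @export
setGeneric("chainVolume", function(object) standardGeneric("chainVolume"))

#' @rdname deltaChi
#' @export
setGeneric("deltaChi", function(object) standardGeneric("deltaChi"))

#' @rdname doublingTime
#' @export
setGeneric("doublingTime", function(object) standardGeneric("doublingTime"))

#' @rdname predictSpeedup
#' @export
setGeneric("predictSpeedup", function(object, ...) standardGeneric("predictSpeedup"))

#' Accessors for growth objects
#'
#' `growthRate` returns the fitted (or generating) exponential rate in 1/min;
#' `condition` returns the culture-condition label.
#'
#' @param object a [GrowthFit-class] or [GrowthCurve-class].
#' @return numeric(1) or character(1).
#' @export
setGeneric("growthRate", function(object) standardGeneric("growthRate"))

#' @rdname growthRate
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
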