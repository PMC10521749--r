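#' @rdname Tomogram-class
#' @param object,x a [Tomogram] or [SegmentationMask].
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname Tomogram-class
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))

#' @rdname Tomogram-class
#' @export
setGeneric("mediumRI", function(x) standardGeneric("mediumRI"))

#' @rdname Tomogram-class
#' @export
setGeneric("wavelengthUm", function(x) standardGeneric("wavelengthUm"))

#' @rdname Tomogram-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname SegmentationMask-class
#' @param x a [SegmentationMask].
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname SegmentationMask-class
#' @export
setGeneric("thresholdRI", function(x) standardGeneric("thresholdRI"))

#' @rdname EvaluationReport-class
#' @param x an [EvaluationReport].
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
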