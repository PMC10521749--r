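#' @rdname Tomogram-class
#' @export
setMethod("voxels", "Tomogram", function(x) x@voxels)

#' @rdname Tomogram-class
#' @export
setMethod("pitch", "Tomogram", function(x) x@pitch)

#' @rdname Tomogram-class
#' @export
setMethod("mediumRI", "Tomogram", function(x) x@mediumRI)

#' @rdname Tomogram-class
#' @export
setMethod("wavelengthUm", "Tomogram", function(x) x@wavelengthUm)

#' @rdname Tomogram-class
#' @export
setMethod("cellId", "Tomogram", function(x) x@cellId)

#' @rdname SegmentationMask-class
#' @export
setMethod("maskArray", "SegmentationMask", function(x) x@mask)

#' @rdname SegmentationMask-class
#' @export
setMethod("thresholdRI", "SegmentationMask", function(x) x@thresholdRI)

#' @rdname SegmentationMask-class
#' @export
setMethod("cellId", "SegmentationMask", function(x) x@cellId)

#' @rdname EvaluationReport-class
#' @export
setMethod("accuracy", "EvaluationReport", function(x) x@accuracy)

#' @rdname EvaluationReport-class
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(x) x@confusion)

setMethod("show", "Tomogram", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Tomogram '%s': %d x %d x %d voxels (z,y,x)\n",
              object@cellId, d[1], d[2], d[3]))
  cat(sprintf("  pitch (um): %s | medium RI: %.4f | RI range: [%.4f, %.4f]\n",
              paste(format(object@pitch, digits = 3), collapse = " x "),
              object@mediumRI, min(object@voxels), max(object@voxels)))
})

setMethod("show", "SegmentationMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("SegmentationMask '%s': %d/%d voxels at RI > %.3f\n",
              object@cellId, sum(object@mask), prod(d), object@thresholdRI))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': V ~ N(%.1f, %.1f^2) fL, sphericity ~ N(%.3f, %.3f^2), PD ~ N(%.2f, %.2f^2) g/dL\n",
              object@className, object@volumeMeanFl, object@volumeSdFl,
              object@sphericityMean, object@sphericitySd,
              object@pdMeanGdl, object@pdSdGdl))
  cat(sprintf("  grid %s @ %.3g um, medium RI %.3f, nucleus f=%.2f (+%.3g RI), noise sd %.3g\n",
              paste(object@gridShape, collapse = "x"), object@pitchUm[1],
              object@mediumRI, object@nucleusVolumeFraction,
              object@nucleusRiOffset, object@noiseSdRi))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s]: accuracy %.3f on %d cells\n",
              object@modelName, object@accuracy, sum(object@confusion)))
  print(object@confusion)
})
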