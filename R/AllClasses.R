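#' Tomogram: a single-cell refractive index volume
#'
#' Container for a reconstructed 3D refractive index (RI) tomogram together
#' with the acquisition metadata that every downstream computation needs.
#' Arrays are indexed `(z, y, x)`; voxel centres sit at `(i + 0.5) * pitch`
#' with 0-based indices, so geometry is unambiguous for analytic oracles.
#'
#' @slot voxels 3D numeric array of refractive index values, dim `(nz, ny, nx)`.
#'   Biological RI values are typically in 1.33--1.42.
#' @slot pitch numeric(3), voxel edge lengths in micrometres, `(z, y, x)` order.
#' @slot mediumRI refractive index of the surrounding medium (dimensionless).
#' @slot wavelengthUm illumination wavelength in micrometres (`NA` if unknown).
#' @slot cellId opaque identifier string.
#'
#' @section Validity:
#' All voxels finite with minimum at least 1.0 (values below 1 cannot be a
#' biological RI map); strictly positive pitch; medium RI within
#' \[1.30, 1.40\].
#'
#' @seealso [readTomogram()], [writeTomogram()], [segmentCell()]
#' @export
setClass("Tomogram",
  representation(voxels = "array", pitch = "numeric", mediumRI = "numeric",
                 wavelengthUm = "numeric", cellId = "character"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3D array")
    if (length(v) == 0L) return("voxels must be non-empty")
    if (!all(is.finite(v))) return("voxels must be finite")
    if (min(v) < 1.0) return("voxel values below 1.0 are not RI-like")
    if (length(object@pitch) != 3L || any(!is.finite(object@pitch)) ||
        any(object@pitch <= 0)) return("pitch must be 3 strictly positive values")
    if (length(object@mediumRI) != 1L || object@mediumRI < 1.30 ||
        object@mediumRI > 1.40) return("mediumRI must lie in [1.30, 1.40]")
    if (length(object@wavelengthUm) != 1L)
      return("wavelengthUm must be a single value (NA allowed)")
    if (length(object@cellId) != 1L) return("cellId must be a single string")
    TRUE
  })

#' SegmentationMask: the analysis region of a tomogram
#'
#' Boolean 3D raster aligned voxel-for-voxel with its source [Tomogram],
#' produced by [segmentCell()]: RI thresholding followed by selection of the
#' largest 26-connected component.
#'
#' @slot mask 3D logical array, same dim as the source voxels.
#' @slot thresholdRI the RI threshold that produced the mask.
#' @slot cellId identifier of the source tomogram.
#' @export
setClass("SegmentationMask",
  representation(mask = "array", thresholdRI = "numeric", cellId = "character"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@thresholdRI) != 1L || !is.finite(object@thresholdRI))
      return("thresholdRI must be a single finite value")
    TRUE
  })

#' PhantomSpec: generation parameters for one synthetic cell class
#'
#' Per-class parameters of the spheroid phantom generator. The defaults
#' returned by [defaultClassSpecs()] carry the published per-class mean/SD of
#' cellular volume, sphericity and protein density for bone marrow B
#' lymphocytes, monocytes, myelocytes and T lymphocytes.
#'
#' @slot className class label, e.g. "B", "Mono", "My", "T".
#' @slot volumeMeanFl,volumeSdFl cell volume distribution, femtolitres.
#' @slot sphericityMean,sphericitySd sphericity distribution, dimensionless
#'   in (0, 1\].
#' @slot pdMeanGdl,pdSdGdl protein density distribution, g/dL.
#' @slot nucleusVolumeFraction fraction of cell volume occupied by the
#'   concentric nuclear spheroid, in \[0, 1).
#' @slot nucleusRiOffset RI contrast of the nucleus over the cytoplasm.
#' @slot noiseSdRi additive Gaussian voxel noise, RI units.
#' @slot mediumRI medium refractive index.
#' @slot pitchUm numeric(3) voxel pitch in micrometres `(z, y, x)`.
#' @slot gridShape integer(3) output grid `(nz, ny, nx)`.
#' @export
setClass("PhantomSpec",
  representation(className = "character",
                 volumeMeanFl = "numeric", volumeSdFl = "numeric",
                 sphericityMean = "numeric", sphericitySd = "numeric",
                 pdMeanGdl = "numeric", pdSdGdl = "numeric",
                 nucleusVolumeFraction = "numeric", nucleusRiOffset = "numeric",
                 noiseSdRi = "numeric", mediumRI = "numeric",
                 pitchUm = "numeric", gridShape = "integer"),
  validity = function(object) {
    if (object@volumeMeanFl <= 0 || object@volumeSdFl < 0)
      return("volume mean must be positive, SD non-negative")
    if (object@sphericityMean <= 0 || object@sphericityMean > 1)
      return("sphericityMean must lie in (0, 1]")
    if (object@nucleusVolumeFraction < 0 || object@nucleusVolumeFraction >= 1)
      return("nucleusVolumeFraction must lie in [0, 1)")
    if (length(object@pitchUm) != 3L || any(object@pitchUm <= 0))
      return("pitchUm must be 3 positive values")
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
      return("gridShape must be 3 integers >= 8")
    if (object@mediumRI < 1.30 || object@mediumRI > 1.40)
      return("mediumRI must lie in [1.30, 1.40]")
    TRUE
  })

#' EvaluationReport: held-out classification metrics
#'
#' @slot modelName classifier identifier.
#' @slot accuracy fraction correct on the evaluated split, in \[0, 1\].
#' @slot confusion count matrix, rows = true class, columns = predicted.
#' @slot perClass data.frame with per-class precision and recall.
#' @slot classNames ordered class labels.
#' @slot seed the RNG seed the run used.
#' @export
setClass("EvaluationReport",
  representation(modelName = "character", accuracy = "numeric",
                 confusion = "matrix", perClass = "data.frame",
                 classNames = "character", seed = "numeric"),
  validity = function(object) {
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
    tot <- sum(cm)
    if (tot > 0 && abs(object@accuracy - sum(diag(cm)) / tot) > 1e-12)
      return("accuracy must equal trace(confusion)/total")
    if (object@accuracy < 0 || object@accuracy > 1)
      return("accuracy must lie in [0, 1]")
    TRUE
  })
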