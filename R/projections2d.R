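#' Projection2D: a 2D image derived from a tomogram
#'
#' Three kinds are supported: `mip` (per-pixel maximum RI along one axis),
#' `phase` (projection-approximation phase in radians) and `amplitude` (an
#' exponential-attenuation proxy, dimensionless). Phase and amplitude are
#' synthetic stand-ins computed from the volume: real interferometric
#' acquisitions are not modelled, so absolute 2D accuracies on real data
#' are out of scope here.
#'
#' @slot pixels 2D numeric matrix `(ny, nx)`.
#' @slot kind `"mip"`, `"phase"` or `"amplitude"`.
#' @slot pitchXY pixel pitch in um `(y, x)`.
#' @slot cellId source cell identifier.
#' @slot units `"RI"`, `"radians"` or `"dimensionless"`.
#' @export
setClass("Projection2D",
  representation(pixels = "matrix", kind = "character", pitchXY = "numeric",
                 cellId = "character", units = "character"),
  validity = function(object) {
    if (!object@kind %in% c("mip", "phase", "amplitude"))
      return("kind must be mip, phase or amplitude")
    if (!all(is.finite(object@pixels))) return("pixels must be finite")
    TRUE
  })

setMethod("show", "Projection2D", function(object) {
  cat(sprintf("Projection2D [%s] '%s': %d x %d px (%s), range [%.4g, %.4g]\n",
              object@kind, object@cellId, nrow(object@pixels),
              ncol(object@pixels), object@units, min(object@pixels),
              max(object@pixels)))
})

#' Maximum intensity projection of a tomogram
#'
#' Per-(y, x) maximum over z (or the chosen axis), obtained directly from
#' the 3D tomogram.
#'
#' @param t a [Tomogram].
#' @param axis projection axis (`"z"`, `"y"` or `"x"`).
#' @return a [Projection2D] of kind `"mip"` (units: RI).
#' @export
mip <- function(t, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  ax <- match(axis, c("z", "y", "x"))
  px <- apply(voxels(t), setdiff(1:3, ax), max)
  new("Projection2D", pixels = px, kind = "mip",
      pitchXY = pitch(t)[setdiff(1:3, ax)], cellId = cellId(t),
      units = "RI")
}

#' Projection-approximation phase image
#'
#' `phi(y, x) = (2 pi / lambda) * sum_z (n - n0) * pitch_z`: the optical
#' path delay accumulated along z, in radians. No diffraction or unwrapping
#' is modelled.
#'
#' @param t a [Tomogram].
#' @param wavelengthUm illumination wavelength in um; defaults to the
#'   tomogram's metadata and errors when neither is present.
#' @return a [Projection2D] of kind `"phase"` (radians).
#' @export
syntheticPhase <- function(t, wavelengthUm = NULL) {
  wl <- if (is.null(wavelengthUm)) wavelengthUm(t) else wavelengthUm
  if (is.na(wl) || is.null(wl))
    stop("wavelength missing: give wavelengthUm or set it in the tomogram")
  opd <- apply(voxels(t) - mediumRI(t), c(2, 3), sum) * pitch(t)[1]
  new("Projection2D", pixels = 2 * pi / wl * opd, kind = "phase",
      pitchXY = pitch(t)[2:3], cellId = cellId(t), units = "radians")
}

#' Exponential-attenuation amplitude proxy
#'
#' `A(y, x) = exp(-absorptionCoeff * OPD(y, x))` with the optical path
#' delay in um. A proxy for an amplitude image, labelled as such: cells are
#' nearly transparent, so the coefficient merely controls the synthetic
#' contrast.
#'
#' @param t a [Tomogram].
#' @param absorptionCoeff attenuation per um of optical path delay.
#' @return a [Projection2D] of kind `"amplitude"` (dimensionless).
#' @export
amplitudeProxy <- function(t, absorptionCoeff = 1) {
  opd <- apply(voxels(t) - mediumRI(t), c(2, 3), sum) * pitch(t)[1]
  new("Projection2D", pixels = exp(-absorptionCoeff * opd),
      kind = "amplitude", pitchXY = pitch(t)[2:3], cellId = cellId(t),
      units = "dimensionless")
}

# 2D image as a (1, ny, nx) volume for the conv-net machinery
projectionVolume <- function(p) {
  px <- p@pixels
  array(px, c(1L, nrow(px), ncol(px)))
}

#' Project a cohort into 2D images
#'
#' @param cohort in-memory cohort from [generateCohort()] or a manifest
#'   data.frame of tomogram files.
#' @param kind projection kind; one kind per cohort (mixing kinds in one
#'   training input is an error downstream).
#' @param wavelengthUm wavelength for `kind = "phase"` (default 0.532 um,
#'   a typical tomographic illumination).
#' @param absorptionCoeff see [amplitudeProxy()].
#' @return list with `manifest` and `projections` (named list of
#'   [Projection2D]), consumable by [trainNetwork()].
#' @export
projectCohort <- function(cohort, kind = c("mip", "phase", "amplitude"),
                          wavelengthUm = 0.532, absorptionCoeff = 1) {
  kind <- match.arg(kind)
  src <- if (is.data.frame(cohort)) {
    list(manifest = cohort, get = function(p) readTomogram(p))
  } else {
    list(manifest = cohort$manifest, get = function(p) cohort$tomograms[[p]])
  }
  projections <- lapply(src$manifest$path, function(p) {
    t <- src$get(p)
    switch(kind, mip = mip(t),
           phase = syntheticPhase(t, wavelengthUm),
           amplitude = amplitudeProxy(t, absorptionCoeff))
  })
  names(projections) <- src$manifest$path
  list(manifest = src$manifest, projections = projections, kind = kind)
}

#' Train the 2D baseline classifier
#'
#' Reuses the DS--US--DS training loop with 2D operator analogues (the
#' singleton z axis turns every kernel, pool and upsampling into its 2D
#' counterpart). One projection kind per training run.
#'
#' @param projCohort output of [projectCohort()].
#' @param tcfg a [trainConfig()].
#' @param netCfg optional [networkConfig()].
#' @param verbose per-epoch progress.
#' @return a `tomoCheckpoint`.
#' @export
train2d <- function(projCohort, tcfg = trainConfig(), netCfg = NULL,
                    verbose = FALSE) {
  kinds <- unique(vapply(projCohort$projections, function(p) p@kind, ""))
  if (length(kinds) != 1L)
    stop("mixed projection kinds in one training input: ",
         paste(kinds, collapse = ", "))
  trainNetwork(projCohort, tcfg = tcfg, netCfg = netCfg, verbose = verbose)
}
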