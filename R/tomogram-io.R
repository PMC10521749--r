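#' Construct a Tomogram
#'
#' @param voxels 3D numeric array of RI values, dim `(nz, ny, nx)`.
#' @param pitchUm voxel pitch in micrometres: either a single value
#'   (isotropic) or 3 values in `(z, y, x)` order.
#' @param mediumRI refractive index of the surrounding medium.
#' @param wavelengthUm optional illumination wavelength (um).
#' @param cellId identifier string.
#' @return a validated [Tomogram].
#' @examples
#' t <- Tomogram(array(1.337, c(8, 8, 8)), pitchUm = 0.2, mediumRI = 1.337)
#' pitch(t)
#' @export
Tomogram <- function(voxels, pitchUm, mediumRI, wavelengthUm = NA_real_,
                     cellId = "cell") {
  if (length(pitchUm) == 1L) pitchUm <- rep(pitchUm, 3L)
  obj <- new("Tomogram", voxels = voxels, pitch = as.numeric(pitchUm),
             mediumRI = as.numeric(mediumRI),
             wavelengthUm = as.numeric(wavelengthUm), cellId = cellId)
  validObject(obj)
  obj
}

sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta.json")

#' Write a tomogram to disk
#'
#' Volumes are stored as multi-page 32-bit float TIFF (one page per z slice,
#' page 0 = lowest z) with a JSON metadata sidecar `<name>.meta.json`. RI
#' values are shifted by a recorded offset into \[0, 1\] for storage; the
#' float32 representation keeps the round-trip error below 1e-6 RI.
#'
#' @param t a [Tomogram].
#' @param path output file path (`.tiff`/`.tif`).
#' @param format on-disk format; only `"tiff"` is available in this build
#'   (no HDF5 binding is linked).
#' @return the path, invisibly.
#' @seealso [readTomogram()]
#' @export
writeTomogram <- function(t, path, format = c("tiff", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 output is not available: no HDF5 binding is linked in this ",
         "build; use format = 'tiff'")
  stopifnot(is(t, "Tomogram"))
  validObject(t)
  v <- voxels(t)
  offset <- 1.0  # RI >= 1 by validity; stored values land in [0, 1)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] - offset)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF to '", path, "': ", attr(ok, "condition")$message)
  meta <- list(pitch_xyz = rev(pitch(t)), medium_ri = mediumRI(t),
               wavelength_um = wavelengthUm(t), cell_id = cellId(t),
               ri_offset = offset)
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a tomogram from disk
#'
#' Reads the multi-page TIFF + JSON sidecar layout written by
#' [writeTomogram()]. Pitch is mandatory metadata and is never defaulted:
#' a missing or incomplete sidecar is an error, as silently guessing the
#' voxel size would corrupt every downstream volume and area.
#'
#' @param path TIFF file path.
#' @param format on-disk format; only `"tiff"` is available in this build.
#' @return a validated [Tomogram].
#' @export
readTomogram <- function(path, format = c("tiff", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 input is not available: no HDF5 binding is linked in this ",
         "build; use format = 'tiff'")
  if (!file.exists(path)) stop("no such file: ", path)
  mp <- sidecarPath(path)
  if (!file.exists(mp))
    stop("metadata sidecar missing: ", mp,
         " (pitch is mandatory and is never defaulted)")
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (key in c("pitch_xyz", "medium_ri"))
    if (is.null(meta[[key]]) || any(is.na(meta[[key]])))
      stop("metadata key '", key, "' missing in ", mp)
  if (length(meta$pitch_xyz) != 3L)
    stop("pitch_xyz must hold 3 values in ", mp)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  v <- array(0, c(length(pages), d[1], d[2]))
  offset <- if (!is.null(meta$ri_offset)) meta$ri_offset else 0
  for (z in seq_along(pages)) v[z, , ] <- pages[[z]] + offset
  wl <- if (is.null(meta$wavelength_um)) NA_real_ else as.numeric(meta$wavelength_um)
  id <- if (is.null(meta$cell_id)) basename(path) else meta$cell_id
  tryCatch(
    Tomogram(v, pitchUm = rev(as.numeric(meta$pitch_xyz)),
             mediumRI = as.numeric(meta$medium_ri), wavelengthUm = wl,
             cellId = id),
    error = function(e) stop("'", path, "' is not RI-like: ", conditionMessage(e)))
}
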