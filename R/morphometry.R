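#' Segment a cell from its RI tomogram
#'
#' Voxels with RI above `thresholdRI` are selected (default 1.35, chosen
#' above the ~1.33 medium RI plus experimental noise), optionally closed
#' morphologically (radius 1 voxel), and reduced to the largest 26-connected
#' component so that debris and noise specks cannot inflate the features.
#'
#' @param t a [Tomogram].
#' @param thresholdRI segmentation RI threshold.
#' @param closing apply a radius-1 morphological closing before component
#'   selection (useful for noisy data; off by default).
#' @param largestComponent keep only the largest 26-connected component
#'   (default). `FALSE` returns the raw (optionally closed) threshold mask,
#'   which is monotone in the threshold.
#' @return a [SegmentationMask].
#' @export
segmentCell <- function(t, thresholdRI = 1.35, closing = FALSE,
                        largestComponent = TRUE) {
  stopifnot(is(t, "Tomogram"))
  m <- voxels(t) > thresholdRI
  if (closing) m <- morphClose3d(m)
  if (!any(m))
    stop("empty segmentation: no voxel above RI ", thresholdRI,
         " in tomogram '", cellId(t), "'")
  if (largestComponent)
    m <- .cc_largest(m, dim(m))
  new("SegmentationMask", mask = m, thresholdRI = thresholdRI,
      cellId = cellId(t))
}

# radius-1 (6-neighbourhood) binary closing via array shifts
morphClose3d <- function(m) {
  shift1 <- function(a, axis, by, fill) {
    d <- dim(a); idx <- lapply(d, seq_len)
    src <- idx; src[[axis]] <- idx[[axis]] - by
    out <- array(fill, d)
    keep <- src[[axis]] >= 1 & src[[axis]] <= d[axis]
    dst <- idx; dst[[axis]] <- idx[[axis]][keep]; src[[axis]] <- src[[axis]][keep]
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  nb <- function(a, op, fill) {
    r <- a
    for (ax in 1:3) for (by in c(-1L, 1L))
      r <- op(r, shift1(a, ax, by, fill))
    r
  }
  dil <- nb(m, `|`, FALSE)
  nb(dil, `&`, TRUE)
}

#' Cellular volume from a segmentation mask
#'
#' Voxel count times voxel volume; 1 um^3 = 1 fL.
#'
#' @param m a [SegmentationMask].
#' @param pitchUm voxel pitch (um), scalar or `(z, y, x)`.
#' @return volume in fL.
#' @export
cellVolume <- function(m, pitchUm) {
  stopifnot(is(m, "SegmentationMask"))
  if (length(pitchUm) == 1L) pitchUm <- rep(pitchUm, 3L)
  if (any(!is.finite(pitchUm)) || any(pitchUm <= 0))
    stop("pitch must be strictly positive")
  n <- sum(m@mask)
  if (n == 0L) stop("empty mask")
  n * prod(pitchUm)
}

#' Surface area of the segmented cell
#'
#' Area of the triangulated isosurface of the selected component. The
#' component indicator is Gaussian-smoothed and the surface is extracted
#' at the 0.5 level by marching tetrahedra with
#' linear interpolation, then triangle areas are summed in um^2. Extracting
#' the symmetric 0.5 level of the smoothed indicator places the surface at
#' the binarization boundary without the level-fraction offset a raw-RI
#' extraction at the threshold would have; voxel-face counting is avoided
#' entirely because it overestimates curved surfaces by tens of percent and
#' would corrupt sphericity.
#'
#' @param t the source [Tomogram] (for pitch; a mask alone carries no
#'   geometry).
#' @param m a [SegmentationMask].
#' @param smoothSigma Gaussian sigma in voxels applied to the component
#'   indicator before extraction; 0 disables smoothing. The default
#'   (`NULL`) uses `0.8 * (0.2 / pitch)^(1/3)` voxels, i.e. 0.8 voxel at
#'   the reference 0.2 um pitch: shrinking the physical width while
#'   growing the voxel width as pitch decreases makes the area estimate
#'   converge to the analytic value.
#' @return surface area in um^2.
#' @export
surfaceArea <- function(t, m, smoothSigma = NULL) {
  stopifnot(is(t, "Tomogram"), is(m, "SegmentationMask"))
  if (is.null(smoothSigma))
    smoothSigma <- 0.8 * (0.2 / min(pitch(t)))^(1 / 3)
  mk <- m@mask
  d <- dim(mk)
  if (!any(mk)) stop("empty mask")
  w <- which(mk, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  if (any(lo == 1L) || any(hi == d))
    warning("mask touches the volume boundary; extracting on a padded field")
  pad <- as.integer(ceiling(3 * max(smoothSigma, 1)) + 1)
  lo <- pmax(1L, lo - pad); hi <- pmin(d, hi + pad)
  sub <- mk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  sd2 <- dim(sub) + 2L
  ind <- array(0, sd2)                      # one-voxel zero pad all around
  ind[2:(sd2[1] - 1), 2:(sd2[2] - 1), 2:(sd2[3] - 1)] <- as.numeric(sub)
  f <- .gaussian_smooth3d(ind, dim(ind), smoothSigma)
  .isosurface_area(f, dim(f), 0.5, pitch(t))
}

#' Sphericity from volume and surface area
#'
#' `pi^(1/3) * (6 V)^(2/3) / S`: 1 for a sphere, below 1 otherwise
#' (isoperimetric inequality; mesh discretization may exceed 1 by up to
#' ~0.02).
#'
#' @param V volume in fL.
#' @param S surface area in um^2.
#' @return dimensionless sphericity.
#' @export
sphericity <- function(V, S) {
  if (any(V <= 0) || any(S <= 0)) stop("V and S must be positive")
  pi^(1 / 3) * (6 * V)^(2 / 3) / S
}

#' Per-voxel protein concentration field
#'
#' `C = (n - n0) / alpha` in g/mL under the linear RI model `n = n0 + alpha
#' C`. Negative values (noise below the medium RI) are kept, not clipped,
#' so the algebraic identities between protein density, dry mass and mean
#' RI stay exact.
#'
#' @param t a [Tomogram].
#' @param alpha refractive index increment, mL/g (default 0.2).
#' @param mediumRI override of the tomogram's medium RI.
#' @return 3D array of concentrations, g/mL.
#' @export
concentrationField <- function(t, alpha = 0.2, mediumRI = NULL) {
  if (alpha <= 0) stop("alpha must be positive")
  n0 <- if (is.null(mediumRI)) mediumRI(t) else mediumRI
  (voxels(t) - n0) / alpha
}

#' Protein density over the segmented cell
#'
#' Mean concentration over the mask, reported in g/dL (g/mL x 100).
#'
#' @inheritParams concentrationField
#' @param m a [SegmentationMask].
#' @return protein density in g/dL.
#' @export
proteinDensity <- function(t, m, alpha = 0.2, mediumRI = NULL) {
  stopifnot(is(m, "SegmentationMask"))
  if (!any(m@mask)) stop("empty mask")
  C <- concentrationField(t, alpha, mediumRI)
  mean(C[m@mask]) * 100
}

#' Dry mass of the segmented cell
#'
#' Integral of the concentration over the cell volume: `sum(C) * voxel
#' volume`, with C in g/mL = pg/fL, so the result is in pg and equals
#' `proteinDensity / 100 * volume` by construction.
#'
#' @inheritParams proteinDensity
#' @param pitchUm voxel pitch (um); defaults to the tomogram's.
#' @return dry mass in pg.
#' @export
dryMass <- function(t, m, alpha = 0.2, mediumRI = NULL, pitchUm = NULL) {
  stopifnot(is(m, "SegmentationMask"))
  if (!any(m@mask)) stop("empty mask")
  if (is.null(pitchUm)) pitchUm <- pitch(t)
  if (length(pitchUm) == 1L) pitchUm <- rep(pitchUm, 3L)
  C <- concentrationField(t, alpha, mediumRI)
  sum(C[m@mask]) * prod(pitchUm)
}

#' Mean refractive index over the segmented cell
#'
#' @param t a [Tomogram].
#' @param m a [SegmentationMask].
#' @return mean voxel RI over the mask.
#' @export
meanRI <- function(t, m) {
  stopifnot(is(m, "SegmentationMask"))
  if (!any(m@mask)) stop("empty mask")
  mean(voxels(t)[m@mask])
}

#' Profile one cell: all six parameters
#'
#' Runs [segmentCell()] then computes cellular volume, surface area,
#' sphericity, dry mass, protein density and mean RI, plus the fraction of
#' negative-concentration voxels as a QC flag.
#'
#' @inheritParams segmentCell
#' @param alpha refractive index increment, mL/g.
#' @param smoothSigma see [surfaceArea()].
#' @return one-row data.frame with columns `cell_id, volume_fl,
#'   surface_area_um2, sphericity, dry_mass_pg, pd_gdl, mean_ri,
#'   neg_c_fraction`.
#' @export
profileCell <- function(t, thresholdRI = 1.35, alpha = 0.2, closing = FALSE,
                        smoothSigma = NULL) {
  m <- segmentCell(t, thresholdRI, closing = closing)
  V <- cellVolume(m, pitch(t))
  S <- surfaceArea(t, m, smoothSigma = smoothSigma)
  C <- concentrationField(t, alpha)
  cm <- C[m@mask]
  pd <- mean(cm) * 100
  data.frame(cell_id = cellId(t), volume_fl = V, surface_area_um2 = S,
             sphericity = sphericity(V, S), dry_mass_pg = sum(cm) * prod(pitch(t)),
             pd_gdl = pd, mean_ri = meanRI(t, m),
             neg_c_fraction = mean(cm < 0), stringsAsFactors = FALSE)
}

#' Profile a whole cohort into a feature table
#'
#' @param x either a manifest data.frame (`path`, `label`, optional
#'   `split`) of tomogram files, or the in-memory result of
#'   [generateCohort()].
#' @inheritParams profileCell
#' @param verbose print progress every 100 cells.
#' @return data.frame: `cell_id, label[, split]` plus the six parameters
#'   and the negative-concentration QC fraction.
#' @export
profileCohort <- function(x, thresholdRI = 1.35, alpha = 0.2,
                          closing = FALSE, smoothSigma = NULL,
                          verbose = FALSE) {
  if (is.data.frame(x)) {
    manifest <- x
    getTom <- function(i) readTomogram(manifest$path[i])
  } else {
    manifest <- x$manifest
    getTom <- function(i) x$tomograms[[manifest$path[i]]]
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- profileCell(getTom(i), thresholdRI, alpha, closing, smoothSigma)
    rec$label <- manifest$label[i]
    if (!is.null(manifest$split)) rec$split <- manifest$split[i]
    rows[[i]] <- rec
    if (verbose && i %% 100 == 0) message(i, " cells profiled")
  }
  out <- do.call(rbind, rows)
  front <- intersect(c("cell_id", "label", "split"), names(out))
  out[, c(front, setdiff(names(out), front))]
}
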