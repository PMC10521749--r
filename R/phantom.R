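#' Closed-form spheroid surface area
#'
#' Surface area of a spheroid with semi-axes `(a, a, c)`: oblate (`c < a`),
#' prolate (`c > a`) or sphere (`c == a`), in the units of the inputs.
#'
#' @param a equatorial semi-axis.
#' @param c polar semi-axis.
#' @return surface area.
#' @export
spheroidSurfaceArea <- function(a, c) {
  if (a <= 0 || c <= 0) stop("semi-axes must be positive")
  if (abs(a - c) < 1e-12 * a) return(4 * pi * a^2)
  if (c < a) {                       # oblate
    e <- sqrt(1 - (c / a)^2)
    2 * pi * a^2 * (1 + ((1 - e^2) / e) * atanh(e))
  } else {                           # prolate
    e <- sqrt(1 - (a / c)^2)
    2 * pi * a^2 * (1 + (c / (a * e)) * asin(e))
  }
}

# sphericity of an oblate spheroid with flattening k = a/c >= 1 (volume-free)
oblateSphericity <- function(k) {
  a <- k^(1 / 3); c <- a / k         # unit-volume normalization a^2 c = 1
  S <- spheroidSurfaceArea(a, c)
  V <- 4 / 3 * pi * a^2 * c
  pi^(1 / 3) * (6 * V)^(2 / 3) / S
}

# solve the oblate flattening whose sphericity equals s
flatteningForSphericity <- function(s) {
  if (s >= 1) return(1)
  uniroot(function(k) oblateSphericity(k) - s, c(1 + 1e-9, 1e3),
          tol = 1e-12)$root
}

#' Construct a PhantomSpec
#'
#' @param className class label.
#' @param volumeMeanFl,volumeSdFl cell volume Normal parameters (fL); draws
#'   are truncated at 3 SD and at zero.
#' @param sphericityMean,sphericitySd sphericity Normal parameters; draws are
#'   truncated at 3 SD and clipped into (0, 1\].
#' @param pdMeanGdl,pdSdGdl protein density Normal parameters (g/dL).
#' @param nucleusVolumeFraction,nucleusRiOffset concentric nuclear spheroid:
#'   volume fraction and RI contrast over the cytoplasm. The cytoplasm RI is
#'   lowered by `fraction * offset` so the volume-weighted interior mean RI
#'   stays exactly `mediumRI + alpha * C`.
#' @param noiseSdRi additive Gaussian voxel noise (RI units).
#' @param mediumRI medium refractive index.
#' @param pitchUm voxel pitch (um), scalar or `(z, y, x)`.
#' @param gridShape output grid `(nz, ny, nx)`.
#' @return a validated [PhantomSpec].
#' @export
PhantomSpec <- function(className, volumeMeanFl, volumeSdFl,
                        sphericityMean, sphericitySd,
                        pdMeanGdl, pdSdGdl,
                        nucleusVolumeFraction = 0.4, nucleusRiOffset = 0.004,
                        noiseSdRi = 0.002, mediumRI = 1.337,
                        pitchUm = 0.2, gridShape = c(64L, 64L, 64L)) {
  if (length(pitchUm) == 1L) pitchUm <- rep(pitchUm, 3L)
  obj <- new("PhantomSpec", className = className,
             volumeMeanFl = volumeMeanFl, volumeSdFl = volumeSdFl,
             sphericityMean = sphericityMean, sphericitySd = sphericitySd,
             pdMeanGdl = pdMeanGdl, pdSdGdl = pdSdGdl,
             nucleusVolumeFraction = nucleusVolumeFraction,
             nucleusRiOffset = nucleusRiOffset, noiseSdRi = noiseSdRi,
             mediumRI = mediumRI, pitchUm = as.numeric(pitchUm),
             gridShape = as.integer(gridShape))
  validObject(obj)
  obj
}

#' Published per-class phantom parameterization
#'
#' One [PhantomSpec] per bone marrow WBC class (B lymphocyte, monocyte,
#' myelocyte, T lymphocyte), carrying the published mean/SD of cellular
#' volume (fL), sphericity and protein density (g/dL) for each class. Dry
#' mass, surface area and mean RI are not free parameters: they follow from
#' these three plus the RI model `n = n0 + alpha * C`.
#'
#' The common grid (112^3 at 0.2 um pitch, 22.4 um extent) accommodates the
#' worst-case truncated draw (a monocyte at volume mean + 3 SD flattened to
#' sphericity mean - 3 SD) with margin under arbitrary rotation.
#'
#' @param noiseSdRi additive voxel noise; 0 gives noise-free phantoms.
#' @param gridShape common grid for all classes, or `"fit"` for the smallest
#'   per-class grid (multiple of 8) holding that class's worst-case draw.
#'   Fitted grids differ across classes, so they suit single-class cohorts
#'   (morphometry studies); classifier cohorts need the common grid.
#' @param pitchUm voxel pitch in um.
#' @param mediumRI medium RI; 1.337 (RPMI-like) makes the published
#'   protein-density and mean-RI columns mutually consistent.
#' @return named list of [PhantomSpec] (`B`, `Mono`, `My`, `T`).
#' @export
defaultClassSpecs <- function(noiseSdRi = 0.002,
                              gridShape = c(112L, 112L, 112L),
                              pitchUm = 0.2, mediumRI = 1.337) {
  fit <- identical(gridShape, "fit")
  par <- list(
    B    = c(185.05, 34.86, 0.794, 0.026, 15.58, 1.05),
    Mono = c(422.79, 61.31, 0.725, 0.076, 15.15, 1.55),
    My   = c(404.19, 53.10, 0.792, 0.057, 17.09, 1.26),
    T    = c(232.31, 30.35, 0.854, 0.022, 15.67, 0.83))
  lapply(setNames(names(par), names(par)), function(nm) {
    p <- par[[nm]]
    gs <- if (fit) fittedGridShape(p[1], p[2], p[3], p[4], pitchUm) else gridShape
    PhantomSpec(nm, p[1], p[2], p[3], p[4], p[5], p[6],
                noiseSdRi = noiseSdRi, mediumRI = mediumRI,
                pitchUm = pitchUm, gridShape = gs)
  })
}

# smallest multiple-of-8 cubic grid that holds the worst-case truncated draw
# (volume at +3 SD flattened to sphericity at -3 SD) with margin and jitter
fittedGridShape <- function(vMean, vSd, sMean, sSd, pitchUm, marginVox = 6) {
  vMax <- vMean + 3 * vSd
  sMin <- max(sMean - 3 * sSd, 0.05)
  k <- flatteningForSphericity(min(sMin, 1))
  extent <- 2 * (3 * vMax / (4 * pi))^(1 / 3) * k^(1 / 3)
  n <- ceiling(extent / min(pitchUm)) + marginVox
  rep(as.integer(ceiling(n / 8) * 8), 3L)
}

# truncated normal draw: within mean +/- 3 sd and > lower (rejection)
rtruncn <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(mean)
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (abs(x - mean) <= 3 * sd && x > lower && x < upper) return(x)
  }
  stop("truncated normal rejection failed (degenerate parameters)")
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# L'Ecuyer-CMRG substream for cell `index` under master `seed`
cellStream <- function(seed, index) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed %% 2147483647L), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", .GlobalEnv)
  for (i in seq_len(index)) s <- parallel::nextRNGStream(s)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  s
}

#' Generate one synthetic cell tomogram with analytic ground truth
#'
#' Draws a cell volume, sphericity and protein concentration from the spec's
#' truncated Normal distributions, solves the oblate spheroid flattening
#' whose closed-form sphericity equals the drawn value, applies a uniform
#' random 3D rotation and sub-voxel centre jitter, and voxelizes (a voxel is
#' interior iff its centre lies inside the analytic surface). Interior RI is
#' `mediumRI + alpha * C` (alpha = 0.2 mL/g) with a mean-preserving
#' concentric nuclear spheroid, plus optional Gaussian voxel noise.
#'
#' The returned truth holds the analytic (pre-voxelization, pre-noise)
#' values, so `dry_mass_pg == pd_gdl / 100 * volume_fl` and
#' `mean_ri == mediumRI + alpha * pd_gdl / 100` hold identically.
#'
#' @param spec a [PhantomSpec].
#' @param seed master seed; together with `index` it fully determines the
#'   cell (one splittable RNG substream per cell, so a cell's content does
#'   not depend on cohort size).
#' @param index substream index (cell number within a cohort).
#' @param cellId identifier; default derived from class and index.
#' @return list with `tomogram` ([Tomogram]) and `truth` (one-row
#'   data.frame: `cell_id,label,volume_fl,surface_area_um2,sphericity,
#'   pd_gdl,dry_mass_pg,mean_ri`).
#' @export
generateCell <- function(spec, seed, index = 1L,
                         cellId = sprintf("%s_%04d", spec@className, index)) {
  stopifnot(is(spec, "PhantomSpec"))
  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  oldKind <- RNGkind()
  on.exit({
    RNGkind(oldKind[1], oldKind[2], oldKind[3])
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv)
  })
  assign(".Random.seed", cellStream(seed, index), .GlobalEnv)

  V <- rtruncn(spec@volumeMeanFl, spec@volumeSdFl, lower = 0)
  s <- min(rtruncn(spec@sphericityMean, spec@sphericitySd, lower = 0), 1)
  pd <- rtruncn(spec@pdMeanGdl, spec@pdSdGdl, lower = 0)

  k <- flatteningForSphericity(s)
  req <- (3 * V / (4 * pi))^(1 / 3)          # volume-equivalent radius, um
  a <- req * k^(1 / 3); cax <- a / k          # semi-axes (a, a, c)
  pitchZ <- spec@pitchUm
  if (cax < 2 * min(pitchZ))
    stop(sprintf("generation error for '%s': sphericity draw %.3f needs polar semi-axis %.2f um, below the 2-voxel resolution limit at pitch %.3g um",
                 cellId, s, cax, min(pitchZ)))
  extent <- 2 * a
  gridUm <- spec@gridShape * pitchZ
  if (any(extent + 4 * pitchZ + 1 * pitchZ > gridUm))
    stop(sprintf("generation error for '%s': volume draw %.1f fL at sphericity %.3f spans %.1f um and does not fit grid %s (pitch %.3g um) with a 2-voxel margin",
                 cellId, V, s, extent, paste(spec@gridShape, collapse = "x"),
                 min(pitchZ)))

  R <- randomRotation()
  d <- spec@gridShape
  centre <- d / 2 * pitchZ + runif(3, -0.5, 0.5) * pitchZ   # (z, y, x) um

  # voxelize inside the bounding box of the rotated spheroid
  half <- extent / 2 + 2 * max(pitchZ)
  lo <- pmax(1L, floor((centre - half) / pitchZ))
  hi <- pmin(d, ceiling((centre + half) / pitchZ))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  zc <- (zi - 0.5) * pitchZ[1] - centre[1]
  yc <- (yi - 0.5) * pitchZ[2] - centre[2]
  xc <- (xi - 0.5) * pitchZ[3] - centre[3]
  g <- expand.grid(z = zc, y = yc, x = xc)
  # body frame: rows of R are the body axes in (z,y,x) lab coordinates
  b <- as.matrix(g) %*% t(R)
  q <- (b[, 1] / a)^2 + (b[, 2] / a)^2 + (b[, 3] / cax)^2
  fNuc <- spec@nucleusVolumeFraction
  sc <- fNuc^(2 / 3)
  alpha <- 0.2
  C <- pd / 100                               # g/mL
  riCyt <- spec@mediumRI + alpha * C - fNuc * spec@nucleusRiOffset
  sub <- array(spec@mediumRI, dim = c(length(zi), length(yi), length(xi)))
  inside <- q <= 1
  sub[inside] <- riCyt
  if (fNuc > 0) sub[q <= sc] <- riCyt + spec@nucleusRiOffset

  vox <- array(spec@mediumRI, dim = d)
  vox[zi, yi, xi] <- sub
  if (spec@noiseSdRi > 0) {
    vox <- vox + array(rnorm(prod(d), 0, spec@noiseSdRi), dim = d)
    vox[vox < 1] <- 1   # physical floor; affects essentially no voxels
  }

  truth <- data.frame(
    cell_id = cellId, label = spec@className, volume_fl = V,
    surface_area_um2 = spheroidSurfaceArea(a, cax), sphericity = s,
    pd_gdl = pd, dry_mass_pg = pd / 100 * V,
    mean_ri = spec@mediumRI + alpha * pd / 100,
    stringsAsFactors = FALSE)
  list(tomogram = Tomogram(vox, pitchUm = pitchZ, mediumRI = spec@mediumRI,
                           cellId = cellId),
       truth = truth)
}

#' Generate a labelled synthetic cohort
#'
#' Generates `nPerClass` cells per spec, writes (or keeps in memory) the
#' tomograms, a `truth.csv` ground-truth table, and a stratified-split
#' manifest. Fully reproducible from `seed`: each cell uses its own RNG
#' substream indexed by its position in the cohort.
#'
#' @param specs list of [PhantomSpec] (one per class). All specs must share
#'   one grid shape, since downstream classifiers consume fixed-shape input.
#' @param nPerClass cells per class.
#' @param seed master seed.
#' @param outDir output directory for TIFF volumes, `truth.csv` and
#'   `manifest.csv`; `NULL` keeps the cohort in memory.
#' @param fractions train/val/test fractions (default 7:1:2).
#' @return list with `manifest`, `truth`, and (in-memory mode) `tomograms`
#'   (named list of [Tomogram]).
#' @export
generateCohort <- function(specs, nPerClass, seed, outDir = NULL,
                           fractions = c(0.7, 0.1, 0.2)) {
  if (nPerClass < 1) stop("nPerClass must be >= 1")
  shapes <- unique(lapply(specs, function(s) s@gridShape))
  if (length(shapes) != 1L)
    stop("inconsistent grid shapes across specs: ",
         paste(vapply(shapes, paste, "", collapse = "x"), collapse = " vs "))
  write <- !is.null(outDir)
  if (write) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  truth <- vector("list", length(specs) * nPerClass)
  toms <- if (!write) vector("list", length(truth)) else NULL
  paths <- character(length(truth)); labels <- character(length(truth))
  i <- 0L
  for (spec in specs) {
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      cell <- generateCell(spec, seed, index = i)
      truth[[i]] <- cell$truth
      labels[i] <- spec@className
      if (write) {
        p <- file.path(outDir, paste0(cell$truth$cell_id, ".tiff"))
        writeTomogram(cell$tomogram, p)
        paths[i] <- p
      } else {
        paths[i] <- cell$truth$cell_id
        toms[[i]] <- cell$tomogram
      }
    }
  }
  truth <- do.call(rbind, truth)
  manifest <- splitManifest(
    data.frame(path = paths, label = labels, stringsAsFactors = FALSE),
    fractions = fractions, seed = seed)
  attr(manifest, "classNames") <- vapply(specs, function(s) s@className, "")
  if (write) {
    write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE,
              quote = FALSE)
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
  }
  out <- list(manifest = manifest, truth = truth)
  if (!write) out$tomograms <- setNames(toms, paths)
  out
}
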