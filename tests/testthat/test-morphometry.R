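sphereT <- function() memo("sphereT", mkEllipsoid())  # r = 2 um, 64^3, 0.2 um

test_that("segmentation matches brute-force center-in-sphere counting", {
  t <- sphereT()
  m <- segmentCell(t)
  # independent oracle: count voxel centres inside the analytic sphere
  cc <- (seq_len(64) - 0.5) * 0.2 - 6.4
  q <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  expect_identical(sum(maskArray(m)), sum(q <= 4))
  expect_s4_class(m, "SegmentationMask")
  expect_identical(thresholdRI(m), 1.35)
})

test_that("background-only tomograms give an explicit empty-segmentation error", {
  flat <- Tomogram(array(1.337, c(16, 16, 16)), 0.2, 1.337)
  expect_error(segmentCell(flat), "empty segmentation")
  expect_error(profileCell(flat), "empty segmentation")
})

test_that("raw threshold masks are nested as the threshold rises", {
  set.seed(4)
  v <- array(runif(16^3, 1.33, 1.42), c(16, 16, 16))
  t <- Tomogram(v, 0.2, 1.337)
  lo <- maskArray(segmentCell(t, 1.35, largestComponent = FALSE))
  hi <- maskArray(segmentCell(t, 1.36, largestComponent = FALSE))
  expect_true(all(lo[hi]))          # mask(1.36) subset of mask(1.35)
  expect_lt(sum(hi), sum(lo))
})

test_that("largest 26-connected component suppresses debris", {
  v <- array(1.337, c(24, 24, 24))
  v[6:18, 6:18, 6:18] <- 1.38      # the cell
  v[2, 2, 2] <- 1.41               # a bright speck
  t <- Tomogram(v, 0.2, 1.337)
  m <- segmentCell(t)
  expect_identical(sum(maskArray(m)), 2197L)
  expect_false(maskArray(m)[2, 2, 2])
})

test_that("volume, area and sphericity match closed forms on the sphere", {
  t <- sphereT()
  m <- segmentCell(t)
  V <- cellVolume(m, pitch(t))
  S <- surfaceArea(t, m)
  expect_lt(abs(V / (4 / 3 * pi * 8) - 1), 0.03)
  expect_lt(abs(S / (4 * pi * 4) - 1), 0.03)
  expect_lt(abs(sphericity(V, S) - 1), 0.02)
  expect_error(cellVolume(m, c(-1, 1, 1)))
  expect_error(sphericity(-1, 10), "positive")
})

test_that("prolate spheroid area and sphericity match the closed form", {
  a <- (8 / 2)^(1 / 3)             # 2:1 prolate with the sphere's volume
  t <- mkEllipsoid(semiAxes = c(a, a, 2 * a))
  m <- segmentCell(t)
  V <- cellVolume(m, pitch(t))
  S <- surfaceArea(t, m)
  e <- sqrt(1 - 1 / 4)
  Sref <- 2 * pi * a^2 * (1 + (2 / e) * asin(e))
  expect_lt(abs(S / Sref - 1), 0.03)
  sphRef <- pi^(1 / 3) * (6 * 4 / 3 * pi * 8)^(2 / 3) / Sref
  expect_lt(abs(sphericity(V, S) / sphRef - 1), 0.02)
  expect_identical(Sref, spheroidSurfaceArea(a, 2 * a))
})

test_that("degenerate masks still yield positive finite areas", {
  v <- array(1.337, c(8, 8, 8)); v[4, 4, 4] <- 1.40
  t <- Tomogram(v, 0.2, 1.337)
  m <- segmentCell(t)
  S <- surfaceArea(t, m, smoothSigma = 0)
  expect_true(is.finite(S) && S > 0)
})

test_that("masks touching the boundary are padded with a warning", {
  v <- array(1.337, c(12, 12, 12)); v[1:6, 5:8, 5:8] <- 1.40
  t <- Tomogram(v, 0.2, 1.337)
  m <- segmentCell(t)
  expect_warning(S <- surfaceArea(t, m), "boundary")
  expect_true(is.finite(S) && S > 0)
})

test_that("sphere sphericity error shrinks monotonically with pitch", {
  # generic (jittered) centre, as in real acquisitions: a perfectly
  # lattice-aligned sphere puts voxel centres exactly on the boundary
  errs <- vapply(c(0.4, 0.2, 0.1), function(p) {
    d <- as.integer(round(12.8 / p))
    t <- mkEllipsoid(pitchUm = p, dim = d,
                     centreUm = d / 2 * p + c(0.137, 0.211, 0.083))
    m <- segmentCell(t)
    abs(sphericity(cellVolume(m, p), surfaceArea(t, m)) - 1)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("biochemical identities are exact and scaling laws hold", {
  spec <- defaultClassSpecs(gridShape = c(64L, 64L, 64L), pitchUm = 0.35)$My
  for (i in 1:6) {
    cell <- generateCell(spec, seed = 17, index = i)
    t <- cell$tomogram
    p <- profileCell(t)
    expect_equal(p$dry_mass_pg, p$pd_gdl / 100 * p$volume_fl,
                 tolerance = 1e-9)
    expect_equal(p$mean_ri, mediumRI(t) + 0.2 * p$pd_gdl / 100,
                 tolerance = 1e-9)
    expect_lte(p$sphericity, 1.02)
  }
  # alpha scaling: doubling alpha halves protein density
  t <- sphereT(); m <- segmentCell(t)
  expect_equal(proteinDensity(t, m, alpha = 0.4),
               proteinDensity(t, m, alpha = 0.2) / 2, tolerance = 1e-12)
  expect_equal(proteinDensity(mkEllipsoid(ri = 1.3501), segmentCell(mkEllipsoid(ri = 1.3501), 1.34)), 6.55,
               tolerance = 1e-6)
  # units audit: pitch scaling k moves V by k^3, S by k^2, mass by k^3,
  # and leaves sphericity / pd / mean RI unchanged
  tk <- Tomogram(voxels(t), pitchUm = 0.4, mediumRI = 1.337)
  mk <- segmentCell(tk)
  expect_equal(cellVolume(mk, pitch(tk)), cellVolume(m, pitch(t)) * 8,
               tolerance = 1e-12)
  expect_equal(surfaceArea(tk, mk, smoothSigma = 0.8),
               surfaceArea(t, m, smoothSigma = 0.8) * 4, tolerance = 1e-9)
  expect_equal(dryMass(tk, mk), dryMass(t, m) * 8, tolerance = 1e-12)
  expect_equal(meanRI(tk, mk), meanRI(t, m), tolerance = 1e-15)
  # single voxel at 0.2 um pitch is 0.008 fL
  v1 <- array(1.337, c(8, 8, 8)); v1[4, 4, 4] <- 1.4
  m1 <- segmentCell(Tomogram(v1, 0.2, 1.337))
  expect_equal(cellVolume(m1, 0.2), 0.008, tolerance = 1e-12)
})

test_that("dry mass integrates concentration over volume", {
  # uniform C = 0.15 g/mL over a known voxel volume
  v <- array(1.337, c(20, 20, 20))
  v[5:15, 5:15, 5:15] <- 1.337 + 0.2 * 0.15
  t <- Tomogram(v, 0.2, 1.337)
  m <- segmentCell(t)
  vol <- cellVolume(m, pitch(t))
  expect_equal(dryMass(t, m), 0.15 * vol, tolerance = 1e-9)
  # C = 0 everywhere in the mask gives zero mass
  t0 <- Tomogram(v, 0.2, 1.337)
  m0 <- segmentCell(t0, 1.35)
  expect_equal(dryMass(t0, m0, mediumRI = 1.337 + 0.2 * 0.15), 0,
               tolerance = 1e-12)
})

test_that("noise-free phantom round trip recovers truth within tolerance", {
  specs <- defaultClassSpecs(gridShape = "fit", noiseSdRi = 0)
  rows <- list()
  for (cls in c("B", "T")) {
    for (i in 1:100) {
      cell <- generateCell(specs[[cls]], seed = 77, index = i)
      p <- profileCell(cell$tomogram)
      rows[[paste(cls, i)]] <- c(
        v = abs(p$volume_fl / cell$truth$volume_fl - 1),
        s = abs(p$surface_area_um2 / cell$truth$surface_area_um2 - 1),
        sp = abs(p$sphericity / cell$truth$sphericity - 1),
        pd = abs(p$pd_gdl / cell$truth$pd_gdl - 1),
        dm = abs(p$dry_mass_pg / cell$truth$dry_mass_pg - 1))
    }
  }
  err <- apply(do.call(rbind, rows), 2, median)
  expect_lt(err[["v"]], 0.03)
  expect_lt(err[["s"]], 0.05)
  expect_lt(err[["sp"]], 0.05)
  expect_lt(err[["pd"]], 0.03)
  expect_lt(err[["dm"]], 0.03)
})

test_that("negative concentrations are kept and flagged, not clipped", {
  set.seed(8)
  v <- array(1.36, c(12, 12, 12)) + array(rnorm(12^3, 0, 0.01), c(12, 12, 12))
  t <- Tomogram(pmax(v, 1.30 + 0.05), 0.2, 1.36)
  m <- segmentCell(t, 1.35, largestComponent = TRUE)
  p <- suppressWarnings(profileCell(t))   # mask reaches the volume edge
  expect_gt(p$neg_c_fraction, 0)
  expect_equal(p$mean_ri, 1.36 + 0.2 * p$pd_gdl / 100, tolerance = 1e-9)
})
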