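test_that("sphere limit: zero sphericity spread at 1 gives an exact sphere", {
  spec <- PhantomSpec("S", 120, 0, 1, 0, 16, 0, nucleusVolumeFraction = 0,
                      noiseSdRi = 0, pitchUm = 0.2,
                      gridShape = c(48L, 48L, 48L))
  cell <- generateCell(spec, seed = 3)
  expect_identical(cell$truth$sphericity, 1)
  r <- (3 * 120 / (4 * pi))^(1 / 3)
  expect_equal(cell$truth$surface_area_um2, 4 * pi * r^2, tolerance = 1e-12)
  # voxelized volume matches the analytic draw closely
  m <- segmentCell(cell$tomogram)
  expect_lt(abs(cellVolume(m, 0.2) / 120 - 1), 0.03)
})

test_that("generation is bitwise deterministic and substream-independent", {
  spec <- defaultClassSpecs(gridShape = c(48L, 48L, 48L), pitchUm = 0.3)$B
  a <- generateCell(spec, seed = 9, index = 4L)
  b <- generateCell(spec, seed = 9, index = 4L)
  expect_identical(voxels(a$tomogram), voxels(b$tomogram))
  expect_identical(a$truth, b$truth)
  # a cell's content depends on its own substream, not on cohort size
  expect_false(identical(voxels(a$tomogram),
                         voxels(generateCell(spec, seed = 9, index = 5L)$tomogram)))
})

test_that("truth identities hold exactly for every generated cell", {
  specs <- defaultClassSpecs(gridShape = c(64L, 64L, 64L), pitchUm = 0.35)
  for (spec in specs) {
    for (i in 1:5) {
      tr <- generateCell(spec, seed = 31, index = i)$truth
      expect_equal(tr$dry_mass_pg, tr$pd_gdl / 100 * tr$volume_fl,
                   tolerance = 1e-12)
      expect_equal(tr$mean_ri, spec@mediumRI + 0.2 * tr$pd_gdl / 100,
                   tolerance = 1e-12)
      expect_true(tr$sphericity > 0 && tr$sphericity <= 1)
    }
  }
})

test_that("uniform-RI sphere implies the closed-form protein density", {
  # RI 1.371 in medium 1.337 at alpha 0.2 mL/g is 17.0 g/dL
  t <- mkEllipsoid(ri = 1.371, mediumRI = 1.337)
  m <- segmentCell(t)
  expect_equal(proteinDensity(t, m), 17.0, tolerance = 1e-9)
})

test_that("unattainable draws raise generation errors naming the draw", {
  big <- PhantomSpec("big", 5000, 0, 0.9, 0, 16, 0, noiseSdRi = 0,
                     pitchUm = 0.2, gridShape = c(32L, 32L, 32L))
  expect_error(generateCell(big, seed = 1), "does not fit grid")
  flat <- PhantomSpec("flat", 30, 0, 0.25, 0, 16, 0, noiseSdRi = 0,
                      pitchUm = 0.4, gridShape = c(64L, 64L, 64L))
  expect_error(generateCell(flat, seed = 1), "resolution limit")
})

test_that("cohort generation is reproducible with stratified 7:1:2 split", {
  specs <- overlapSpecs32()
  co <- generateCohort(specs, nPerClass = 10, seed = 5)
  expect_identical(nrow(co$manifest), 40L)
  expect_identical(as.integer(table(co$manifest$split)[c("train", "val", "test")]),
                   c(28L, 4L, 8L))
  co2 <- generateCohort(specs, nPerClass = 10, seed = 5)
  expect_identical(co$truth, co2$truth)
  # truth means drift toward the spec means (SD/sqrt(n) convergence)
  vB <- co$truth$volume_fl[co$truth$label == "L1"]
  expect_lt(abs(mean(vB) - 90), 5 * 12 / sqrt(length(vB)))
  # written cohorts carry truth.csv and manifest.csv
  dir <- file.path(tempdir(), "cohortW")
  cow <- generateCohort(specs["L1"], nPerClass = 3, seed = 5, outDir = dir)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rt <- readTomogram(cow$manifest$path[1])
  expect_identical(dim(voxels(rt)), c(32L, 32L, 32L))
})

test_that("inconsistent grid shapes across cohort specs are rejected", {
  sp <- overlapSpecs32()
  sp$L2@gridShape <- c(40L, 40L, 40L)
  expect_error(generateCohort(sp, 2, seed = 1), "inconsistent grid shapes")
})

test_that("fitted per-class grids accommodate the worst-case truncated draw", {
  specs <- defaultClassSpecs(gridShape = "fit", noiseSdRi = 0)
  gs <- vapply(specs, function(s) s@gridShape[1], 0L)
  expect_true(all(gs %% 8L == 0L))
  # low-sphericity, high-volume classes need bigger grids
  expect_gt(gs[["Mono"]], gs[["T"]])
  # many draws from the widest class all fit (no generation error)
  for (i in 1:20)
    expect_silent(generateCell(specs$Mono, seed = 13, index = i))
})
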