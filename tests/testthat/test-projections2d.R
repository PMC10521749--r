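test_that("MIP of a constant volume is constant and idempotent", {
  t <- Tomogram(array(1.337, c(8, 10, 12)), 0.2, 1.337)
  p <- mip(t)
  expect_identical(dim(p@pixels), c(10L, 12L))
  expect_true(all(p@pixels == 1.337))
  # a 1-slice restack of a MIP projects to itself
  t1 <- Tomogram(array(p@pixels, c(1, 10, 12)), 0.2, 1.337)
  expect_identical(mip(t1)@pixels, p@pixels)
})

test_that("sphere MIP preserves peak RI and lateral silhouette", {
  t <- mkEllipsoid(ri = 1.38)           # r = 2 um at 0.2 um pitch
  p <- mip(t)
  expect_identical(max(p@pixels), max(voxels(t)))
  # silhouette radius within one voxel of the analytic radius
  disk <- p@pixels > 1.35
  areaPx <- sum(disk)
  rPx <- sqrt(areaPx / pi)
  expect_lt(abs(rPx - 2 / 0.2), 1)
  # convex silhouette equals the union of slice masks
  sil <- apply(voxels(t) > 1.35, c(2, 3), any)
  expect_identical(disk, sil)
})

test_that("projection-approximation phase matches the chord-length oracle", {
  t <- mkEllipsoid(ri = 1.38)           # delta n = 0.043
  ph <- syntheticPhase(t, wavelengthUm = 0.532)
  centre <- ph@pixels[32, 32]
  expect_lt(abs(centre - 2 * pi * 0.043 * 4 / 0.532), 0.15)
  # zero object gives exactly zero phase
  flat <- Tomogram(array(1.337, c(8, 8, 8)), 0.2, 1.337)
  expect_true(all(syntheticPhase(flat, 0.532)@pixels == 0))
  # doubling the wavelength halves the phase
  ph2 <- syntheticPhase(t, wavelengthUm = 1.064)
  expect_equal(ph@pixels, 2 * ph2@pixels, tolerance = 1e-12)
  expect_error(syntheticPhase(t), "wavelength")
})

test_that("phase is additive over disjoint objects", {
  t1 <- mkEllipsoid(semiAxes = c(1, 1, 1), dim = 48L,
                    centreUm = c(2.4, 2.4, 2.4))
  t2 <- mkEllipsoid(semiAxes = c(1, 1, 1), dim = 48L,
                    centreUm = c(7.2, 7.2, 7.2))
  both <- Tomogram(pmax(voxels(t1), voxels(t2)), 0.2, 1.337)
  pb <- syntheticPhase(both, 0.532)@pixels
  ps <- syntheticPhase(t1, 0.532)@pixels + syntheticPhase(t2, 0.532)@pixels
  expect_equal(pb, ps, tolerance = 1e-12)
})

test_that("amplitude proxy attenuates with optical path length", {
  t <- mkEllipsoid(ri = 1.38)
  a0 <- amplitudeProxy(t, absorptionCoeff = 0)
  expect_true(all(a0@pixels == 1))
  a1 <- amplitudeProxy(t, absorptionCoeff = 1)
  expect_true(all(a1@pixels <= 1))
  expect_lt(a1@pixels[32, 32], min(a1@pixels[1, ]))
})

test_that("2D training rejects mixed kinds and learns a separable cohort", {
  cohort <- tinyCohort16()
  proj <- projectCohort(cohort, "mip")
  expect_identical(length(proj$projections), nrow(cohort$manifest))
  bad <- proj
  bad$projections[[1]] <- syntheticPhase(cohort$tomograms[[1]], 0.532)
  expect_error(train2d(bad), "mixed")
  # a slightly larger cohort of the same two classes for a meaningful
  # validation and test split
  mk <- function(nm, vol, pd) PhantomSpec(nm, vol, vol * 0.05, 0.95, 0.01,
                                          pd, 0.3, pitchUm = 0.5,
                                          gridShape = c(16L, 16L, 16L))
  co <- generateCohort(list(a = mk("a", 18, 13), b = mk("b", 38, 18)),
                       nPerClass = 24, seed = 31,
                       fractions = c(0.6, 0.2, 0.2))
  pr <- projectCohort(co, "mip")
  ck <- train2d(pr, trainConfig(lr = 0.002, maxEpochs = 25, seed = 2,
                                batchSize = 4L, selection = "mse"),
                smallNetConfig(c(1L, 16L, 16L), 2L))
  rep <- evaluateCheckpoint(ck, pr)
  expect_gte(accuracy(rep), 0.9)
})
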