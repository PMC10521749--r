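# Analytic fixtures and shared (memoized) expensive objects.

.cache <- new.env(parent = emptyenv())
memo <- function(name, expr) {
  if (!exists(name, .cache)) assign(name, force(expr), .cache)
  get(name, .cache)
}

# Tomogram of an axis-aligned ellipsoid evaluated at voxel centres
# ((i - 0.5) * pitch), independent of the package's phantom generator.
mkEllipsoid <- function(semiAxes = c(2, 2, 2), ri = 1.38, mediumRI = 1.337,
                        pitchUm = 0.2, dim = 64L, cellId = "fixture",
                        centreUm = NULL) {
  if (length(dim) == 1L) dim <- rep(dim, 3L)
  if (is.null(centreUm)) centreUm <- dim / 2 * pitchUm
  cz <- (seq_len(dim[1]) - 0.5) * pitchUm - centreUm[1]
  cy <- (seq_len(dim[2]) - 0.5) * pitchUm - centreUm[2]
  cx <- (seq_len(dim[3]) - 0.5) * pitchUm - centreUm[3]
  # semiAxes given as (x, y, z) half-lengths
  q <- outer(outer((cz / semiAxes[3])^2, (cy / semiAxes[2])^2, "+"),
             (cx / semiAxes[1])^2, "+")
  v <- array(mediumRI, dim)
  v[q <= 1] <- ri
  Tomogram(v, pitchUm, mediumRI, cellId = cellId)
}

# four widely separated classes (every feature >= 10 pooled SDs apart)
# on the desk-scale 64^3 grid at 0.2 um pitch
separableSpecs64 <- function(noiseSdRi = 0.002) {
  mk <- function(nm, vol, volSd, pd, sph = 0.95, sphSd = 0.01) {
    PhantomSpec(nm, vol, volSd, sph, sphSd, pd, 0.3,
                noiseSdRi = noiseSdRi, pitchUm = 0.2,
                gridShape = c(64L, 64L, 64L))
  }
  list(c1 = mk("c1", 60, 5, 13.0), c2 = mk("c2", 150, 8, 15.5),
       c3 = mk("c3", 300, 12, 18.0),
       c4 = mk("c4", 420, 12, 20.5, sph = 0.96, sphSd = 0.008))
}

# four classes with deliberate partial overlap, 32^3 at 0.4 um pitch,
# built so each input modality has a different ceiling.
# L1/L2 are feature-identical and differ only in nuclear volume fraction
# (mean-RI preserved): invisible to the six-feature table, visible as
# bright nuclear disks of different radius in any image. M1/M2 share the
# volume distribution; M2 carries a *dark* nucleus whose cytoplasm RI is
# equalized to M1's at the class mean, so a maximum projection along z
# occludes the nucleus entirely (every column through it ends on brighter
# cytoplasm) while the 3D volume shows the dark core outright; the
# feature table sees the pair only through a ~2.6 SD protein-density gap.
overlapSpecs32 <- function() {
  mk <- function(nm, vol, volSd, pd, f, offset) {
    PhantomSpec(nm, vol, volSd, 0.90, 0.02, pd, 0.8,
                nucleusVolumeFraction = f, nucleusRiOffset = offset,
                noiseSdRi = 0.002, pitchUm = 0.4,
                gridShape = c(32L, 32L, 32L))
  }
  # M2 cytoplasm = n0 + alpha*C + f*|offset| matches M1's n0 + alpha*C1
  # when pd1 - pd2 = 100 * f * |offset| / alpha = 2.1 g/dL
  list(L1 = mk("L1", 90, 12, 15.5, 0.15, +0.012),
       L2 = mk("L2", 90, 12, 15.5, 0.55, +0.012),
       M1 = mk("M1", 150, 15, 15.9, 0.00, 0),
       M2 = mk("M2", 150, 15, 13.8, 0.35, -0.012))
}

smallNetConfig <- function(inShape, nClasses = 4L)
  networkConfig(inShape, nClasses, baseChannels = 2L, nResBlocks = 1L)

tinyCohort16 <- function() {
  memo("tinyCohort16", {
    mk <- function(nm, vol, pd) PhantomSpec(nm, vol, vol * 0.05, 0.95, 0.01,
                                            pd, 0.3, pitchUm = 0.5,
                                            gridShape = c(16L, 16L, 16L))
    generateCohort(list(a = mk("a", 18, 13), b = mk("b", 38, 18)),
                   nPerClass = 12, seed = 31)
  })
}

# feature table for ML tests: modest overlapping 4-class cohort
mlFeatureTable <- function() {
  memo("mlFeatureTable", {
    cohort <- generateCohort(overlapSpecs32(), nPerClass = 50, seed = 11)
    ft <- profileCohort(cohort)
    attr(ft, "classNames") <- names(overlapSpecs32())
    ft
  })
}

# eight-cell memorization run (augmentation off, train == val)
overfitRun <- function() {
  memo("overfitRun", {
    mk <- function(nm, vol, pd) PhantomSpec(nm, vol, vol * 0.1, 0.92, 0.02,
                                            pd, 0.6, pitchUm = 0.4,
                                            gridShape = c(32L, 32L, 32L))
    co <- generateCohort(list(a = mk("a", 80, 14), b = mk("b", 200, 18)),
                         nPerClass = 4, seed = 8)
    co$manifest$split <- "train"
    val <- co$manifest; val$split <- "val"
    co$manifest <- rbind(co$manifest, val)
    ck <- trainNetwork(co, trainConfig(maxEpochs = 200, seed = 3,
                                       targetValAcc = 1.0,
                                       augment = list(translate = 0,
                                                      noiseSd = 0)),
                       smallNetConfig(c(32L, 32L, 32L), 2L))
    list(cohort = co, ckpt = ck)
  })
}

# the separable-cohort classifier shared between classifier-sanity and
# embedding tests (training it once keeps the suite fast)
separableRun <- function() {
  memo("separableRun", {
    cohort <- generateCohort(separableSpecs64(), nPerClass = 100, seed = 21)
    # desk-scale protocol: halved learning rate and MSE-based selection
    # keep small-batch training stable on a 280-cell train split
    tcfg <- trainConfig(lr = 0.002, maxEpochs = 8, seed = 21,
                        selection = "mse", targetValAcc = 1.0)
    ckpt <- trainNetwork(cohort, tcfg, smallNetConfig(c(64L, 64L, 64L)))
    list(cohort = cohort, ckpt = ckpt,
         report = evaluateCheckpoint(ckpt, cohort))
  })
}
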