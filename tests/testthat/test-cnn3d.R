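test_that("forward pass honours the shape and finiteness contract", {
  cfg <- smallNetConfig(c(32L, 32L, 32L), nClasses = 4L)
  net <- tomocyte:::buildNetwork(cfg, seed = 1)
  x <- array(0, c(32, 32, 32, 1, 1))
  out <- tomocyte:::networkForward(net, x, tap = TRUE)
  expect_identical(dim(out$logits), c(4L, 1L))
  expect_true(all(is.finite(out$logits)))
  # tap dimension equals the second DS block's channel count (4 x base)
  expect_identical(nrow(out$features), 8L)
})

test_that("configuration errors state the minimum input size", {
  expect_error(networkConfig(c(12, 12, 12), 4), "divisible by 8")
  expect_error(networkConfig(c(4, 4, 4), 4), ">= 8")
  expect_error(networkConfig(c(32, 32, 32), 1), "nClasses")
})

test_that("He initialization is deterministic given (cfg, seed)", {
  cfg <- smallNetConfig(c(16L, 16L, 16L))
  a <- tomocyte:::paramChecksum(tomocyte:::buildNetwork(cfg, seed = 5))
  b <- tomocyte:::paramChecksum(tomocyte:::buildNetwork(cfg, seed = 5))
  d <- tomocyte:::paramChecksum(tomocyte:::buildNetwork(cfg, seed = 6))
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("gradient steps decrease single-batch cross-entropy", {
  cfg <- smallNetConfig(c(16L, 16L, 16L))
  net <- tomocyte:::buildNetwork(cfg, seed = 2)
  set.seed(2)
  x <- array(rnorm(16^3 * 4, 1.35, 0.01), c(16, 16, 16, 1, 4))
  y <- c(1L, 2L, 3L, 4L)
  tcfg <- trainConfig(lr = 0.002)
  st <- tomocyte:::adamInit(net)
  losses <- numeric(6)
  for (i in 1:6) {
    out <- tomocyte:::networkForward(net, x, training = TRUE)
    lg <- tomocyte:::ceLossGrad(out$logits, y)
    losses[i] <- lg$loss
    tomocyte:::zeroGrads(net)
    tomocyte:::networkBackward(net, lg$grad)
    st <- tomocyte:::adamStep(net, st, tcfg)
  }
  expect_lt(losses[6], losses[1])
})

test_that("conv/pool/upsample backward passes match finite differences", {
  # tiny shapes so central differences are cheap and tight
  set.seed(7)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2, 1))
  W <- array(rnorm(27 * 2 * 3, 0, 0.5), c(3, 3, 3, 2, 3))
  b <- rnorm(3)
  g <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3, 1))
  loss <- function(xx) sum(tomocyte:::.conv_fwd(xx, dim(x), W, dim(W), b) * g)
  bwd <- tomocyte:::.conv_bwd(x, dim(x), W, dim(W), g)
  eps <- 1e-6
  for (idx in c(1L, 37L, 100L)) {
    xp <- x; xp[idx] <- xp[idx] + eps
    xm <- x; xm[idx] <- xm[idx] - eps
    expect_equal(bwd$gradIn[idx], (loss(xp) - loss(xm)) / (2 * eps),
                 tolerance = 1e-5)
  }
  lossW <- function(WW) sum(tomocyte:::.conv_fwd(x, dim(x), WW, dim(W), b) * g)
  for (idx in c(2L, 50L)) {
    Wp <- W; Wp[idx] <- Wp[idx] + eps
    Wm <- W; Wm[idx] <- Wm[idx] - eps
    expect_equal(bwd$gradW[idx], (lossW(Wp) - lossW(Wm)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("training is deterministic and the lr schedule is multiplicative", {
  cohort <- tinyCohort16()
  tcfg <- trainConfig(maxEpochs = 2, seed = 4, batchSize = 4L)
  c1 <- trainNetwork(cohort, tcfg, smallNetConfig(c(16L, 16L, 16L), 2L))
  c2 <- trainNetwork(cohort, tcfg, smallNetConfig(c(16L, 16L, 16L), 2L))
  expect_identical(c1$curve, c2$curve)
  expect_identical(c1$snapshot, c2$snapshot)
  # lr after k steps is lr0 * decay^k
  stepsPerEpoch <- ceiling(sum(cohort$manifest$split == "train") / 4)
  expect_equal(c1$curve$lr,
               0.004 * 0.9999^(stepsPerEpoch * (1:2) - 1),
               tolerance = 1e-12)
})

test_that("a small network memorizes a handful of cells", {
  ck <- overfitRun()$ckpt
  expect_identical(ck$provenance$valAccuracy, 1)
  expect_lte(ck$provenance$epoch, 200)
})

test_that("inference is normalized, batch-invariant and reproducible", {
  run <- separableRun()
  pr <- predictTomograms(run$ckpt, run$cohort)
  expect_true(all(abs(rowSums(pr$probabilities) - 1) < 1e-6))
  expect_true(all(pr$probabilities >= 0))
  one <- predictTomograms(run$ckpt, run$cohort$tomograms[[5]])
  expect_lt(max(abs(one$probabilities -
                      pr$probabilities[5, , drop = FALSE])), 1e-5)
  # argmax equals the reported label
  expect_identical(pr$labels,
                   run$ckpt$classNames[max.col(pr$probabilities)])
})

test_that("checkpoints round-trip through disk and reproduce val accuracy", {
  run <- separableRun()
  dir <- file.path(tempdir(), "ckpt")
  saveCheckpoint(run$ckpt, dir)
  ck2 <- loadCheckpoint(dir)
  expect_true(file.exists(file.path(dir, "meta.json")))
  expect_true(file.exists(file.path(dir, "curve.csv")))
  rep <- evaluateCheckpoint(ck2, run$cohort, split = "val")
  expect_equal(accuracy(rep), run$ckpt$provenance$valAccuracy,
               tolerance = 1e-12)
  # shape mismatch is a clear error
  expect_error(predictTomograms(ck2, array(1.35, c(16, 16, 16))),
               "does not match")
})

test_that("divergence and imbalance are reported", {
  cohort <- tinyCohort16()
  # an overflowing learning rate drives the loss non-finite
  tcfg <- trainConfig(lr = 1e120, maxEpochs = 2, batchSize = 4L, seed = 1)
  expect_error(
    suppressWarnings(trainNetwork(cohort, tcfg,
                                  smallNetConfig(c(16L, 16L, 16L), 2L))),
    "diverged")
  # a class under 10% of the train split triggers the imbalance warning
  skew <- cohort
  aRow <- which(skew$manifest$label == "a")[1]
  bRow <- which(skew$manifest$label == "b")[1]
  man <- skew$manifest[c(rep(aRow, 19), bRow, aRow, bRow), ]
  man$split <- c(rep("train", 20), "val", "val")
  skew$manifest <- man
  expect_warning(
    trainNetwork(skew, trainConfig(maxEpochs = 1, batchSize = 4L),
                 smallNetConfig(c(16L, 16L, 16L), 2L)),
    "imbalance")
})

test_that("augmentations preserve shape and fill with background", {
  set.seed(5)
  v <- array(rnorm(16^3, 1.35, 0.01), c(16, 16, 16))
  v[1, 1, 1] <- 1.337
  set.seed(6)
  tr <- tomocyte:::augTranslate(v, 0.2, fill = 1.337)
  expect_identical(dim(tr), dim(v))
  cp <- tomocyte:::augCropPad(v, 0.2, fill = 1.337)
  expect_identical(dim(cp), dim(v))
  el <- tomocyte:::augElastic(v, 2, 4)
  expect_identical(dim(el), dim(v))
  expect_true(all(el %in% v))      # warping resamples existing voxels
})
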