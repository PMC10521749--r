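#' Training configuration
#'
#' Optimization follows the ADAM recipe with a multiplicative per-step
#' learning-rate decay (`lr * decay^step`) and cross-entropy loss.
#' "Momentum 0.9" is read as ADAM's beta1 (ADAM has no classical momentum
#' term); the decay is applied per optimizer step, since a per-epoch 0.9999
#' decay would be indistinguishable from no decay at realistic epoch
#' counts.
#'
#' @param lr initial learning rate.
#' @param beta1,beta2 ADAM moment coefficients.
#' @param lrDecayPerStep multiplicative decay applied each optimizer step.
#' @param batchSize minibatch size.
#' @param maxEpochs training epochs.
#' @param seed seed for shuffling, augmentation and weight init.
#' @param augment list of switches/magnitudes: `translate` and `crop` as
#'   fractions of the extent, `noiseSd` in RI units, `elastic` logical with
#'   `elasticAlpha` (displacement SD, voxels) and `elasticSigma` (smoothing
#'   SD, voxels).
#' @param selection model-selection metric over the validation split:
#'   `"accuracy"` (maximized, default) or `"mse"` (mean squared error of the
#'   softmax probabilities against one-hot labels, minimized).
#' @param targetValAcc optional early stop once validation accuracy reaches
#'   this value.
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(lr = 0.004, beta1 = 0.9, beta2 = 0.999,
                        lrDecayPerStep = 0.9999, batchSize = 8L,
                        maxEpochs = 10L, seed = 1L,
                        augment = list(translate = 0.1, crop = 0,
                                       noiseSd = 0.002, elastic = FALSE,
                                       elasticAlpha = 2, elasticSigma = 4),
                        selection = c("accuracy", "mse"),
                        targetValAcc = NULL) {
  if (lr <= 0) stop("lr must be positive")
  if (lrDecayPerStep <= 0 || lrDecayPerStep > 1)
    stop("lrDecayPerStep must lie in (0, 1]")
  aug <- modifyList(list(translate = 0, crop = 0, noiseSd = 0,
                         elastic = FALSE, elasticAlpha = 2,
                         elasticSigma = 4), augment)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 lrDecayPerStep = lrDecayPerStep,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 augment = aug, selection = match.arg(selection),
                 targetValAcc = targetValAcc),
            class = "trainConfig")
}

# ---- label-preserving augmentations on a (nz, ny, nx) array ----

augTranslate <- function(v, maxFrac, fill) {
  d <- dim(v)
  sh <- vapply(d, function(n) {
    if (n <= 1) return(0L)
    r <- as.integer(floor(maxFrac * n))
    sample.int(2L * r + 1L, 1L) - r - 1L
  }, 0L)
  if (all(sh == 0L)) return(v)
  out <- array(fill, d)
  src <- dst <- list()
  for (ax in 1:3) {
    i <- seq_len(d[ax])
    keep <- i + sh[ax] >= 1 & i + sh[ax] <= d[ax]
    src[[ax]] <- i[keep]; dst[[ax]] <- i[keep] + sh[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
  out
}

augCropPad <- function(v, maxFrac, fill) {
  d <- dim(v)
  out <- v
  for (ax in 1:3) {
    if (d[ax] == 1) next
    cut <- sample.int(floor(maxFrac * d[ax]) + 1, 1) - 1L
    if (cut == 0) next
    lo <- sample.int(cut + 1, 1) - 1L; hi <- cut - lo
    idx <- lapply(dim(out), seq_len)
    idx[[ax]] <- (1L + lo):(d[ax] - hi)
    kept <- out[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out <- array(fill, d)
    idx[[ax]] <- seq_len(d[ax] - cut) + lo
    out[idx[[1]], idx[[2]], idx[[3]]] <- kept
  }
  out
}

augElastic <- function(v, alphaVox, sigmaVox) {
  d <- dim(v)
  idx <- arrayInd(seq_len(prod(d)), d)
  warped <- idx
  for (ax in 1:3) {
    if (d[ax] == 1) next
    disp <- .gaussian_smooth3d(array(rnorm(prod(d)), d), d, sigmaVox)
    disp <- disp / max(sd(disp), 1e-12) * alphaVox
    warped[, ax] <- pmin(pmax(round(idx[, ax] + as.numeric(disp)), 1L), d[ax])
  }
  array(v[warped], d)
}

augmentVolume <- function(v, aug, fill) {
  if (aug$translate > 0) v <- augTranslate(v, aug$translate, fill)
  if (aug$crop > 0) v <- augCropPad(v, aug$crop, fill)
  if (isTRUE(aug$elastic)) v <- augElastic(v, aug$elasticAlpha, aug$elasticSigma)
  if (aug$noiseSd > 0) v <- v + array(rnorm(length(v), 0, aug$noiseSd), dim(v))
  v
}

# ---- data plumbing: uniform access to cohorts, manifests, lists ----

volumeSource <- function(x) {
  if (is.data.frame(x))
    return(list(manifest = x,
                fetch = function(p) voxels(readTomogram(p))))
  if (is.list(x) && !is.null(x$manifest)) {
    if (!is.null(x$tomograms))
      return(list(manifest = x$manifest,
                  fetch = function(p) voxels(x$tomograms[[p]])))
    if (!is.null(x$projections))
      return(list(manifest = x$manifest,
                  fetch = function(p) projectionVolume(x$projections[[p]])))
  }
  stop("unsupported training input; give a manifest data.frame or a cohort")
}

assembleBatch <- function(vols, idx, aug = NULL) {
  d <- dim(vols[[idx[1]]])
  x <- array(0, c(d, 1L, length(idx)))
  for (j in seq_along(idx)) {
    v <- vols[[idx[j]]]
    if (!is.null(aug)) v <- augmentVolume(v, aug, fill = v[1, 1, 1])
    x[, , , 1L, j] <- v
  }
  x
}

adamInit <- function(net) {
  st <- list(t = 0L)
  st$m <- lapply(net$layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- st$m
  st
}

adamStep <- function(net, st, tcfg) {
  st$t <- st$t + 1L
  lr <- tcfg$lr * tcfg$lrDecayPerStep^(st$t - 1L)
  b1 <- tcfg$beta1; b2 <- tcfg$beta2
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    for (pn in names(l$params)) {
      g <- l$grads[[pn]]
      st$m[[nm]][[pn]] <- b1 * st$m[[nm]][[pn]] + (1 - b1) * g
      st$v[[nm]][[pn]] <- b2 * st$v[[nm]][[pn]] + (1 - b2) * g * g
      l$params[[pn]] <- l$params[[pn]] -
        lr * (st$m[[nm]][[pn]] / c1) / (sqrt(st$v[[nm]][[pn]] / c2) + 1e-8)
    }
  }
  st
}

evalOnSet <- function(net, vols, idx, yIdx, nClasses, batchSize) {
  correct <- 0; se <- 0; n <- 0
  for (start in seq(1, length(idx), by = batchSize)) {
    sel <- idx[start:min(start + batchSize - 1, length(idx))]
    out <- networkForward(net, assembleBatch(vols, sel), training = FALSE)
    p <- softmaxCols(out$logits)
    pred <- apply(p, 2, which.max)
    truthIdx <- yIdx[sel]
    correct <- correct + sum(pred == truthIdx)
    oneHot <- matrix(0, nClasses, length(sel))
    oneHot[cbind(truthIdx, seq_along(sel))] <- 1
    se <- se + sum((p - oneHot)^2)
    n <- n + length(sel)
  }
  list(acc = correct / n, mse = se / (n * nClasses))
}

#' Train the classifier
#'
#' ADAM with cross-entropy loss, per-step learning-rate decay, seeded
#' shuffling and label-preserving augmentation. The best model over epochs
#' is selected on the validation split (accuracy by default, softmax MSE
#' optionally) and returned as a checkpoint together with the training
#' curve. Fully deterministic given `(data, tcfg)`.
#'
#' @param x training data: a manifest data.frame (`path,label,split` with
#'   train and val rows) of tomogram files, or an in-memory cohort from
#'   [generateCohort()] / [projectCohort()].
#' @param tcfg a [trainConfig()].
#' @param netCfg a [networkConfig()]; `inShape` defaults to the volume
#'   shape.
#' @param verbose print one line per epoch.
#' @return a checkpoint (class `tomoCheckpoint`): best weights, network
#'   config, class names, provenance (seed, best epoch, validation
#'   accuracy) and the per-epoch curve (`epoch,loss,val_acc,val_mse,lr`).
#' @export
trainNetwork <- function(x, tcfg = trainConfig(), netCfg = NULL,
                         verbose = FALSE) {
  src <- volumeSource(x)
  manifest <- src$manifest
  if (!all(c("train", "val") %in% manifest$split))
    stop("manifest must contain train and val splits")
  classNames <- attr(manifest, "classNames")
  if (is.null(classNames)) classNames <- sort(unique(manifest$label))
  nC <- length(classNames)
  use <- manifest$split %in% c("train", "val")
  vols <- lapply(manifest$path[use], src$fetch)
  names(vols) <- manifest$path[use]
  sub <- manifest[use, ]
  yIdx <- match(sub$label, classNames)
  trainIdx <- which(sub$split == "train")
  valIdx <- which(sub$split == "val")
  shares <- table(factor(sub$label[trainIdx], levels = classNames)) /
    length(trainIdx)
  if (any(shares < 0.1))
    warning("class imbalance: ",
            paste(names(shares)[shares < 0.1], collapse = ", "),
            " below 10% of the train split")
  d <- dim(vols[[1]])
  if (is.null(netCfg)) netCfg <- networkConfig(d, nC)
  if (!all(netCfg$inShape == d))
    stop("volume shape ", paste(d, collapse = "x"),
         " does not match network inShape")
  net <- buildNetwork(netCfg, seed = tcfg$seed)
  st <- adamInit(net)
  set.seed(tcfg$seed)
  best <- NULL; bestScore <- -Inf; bestEpoch <- NA; bestAcc <- NA
  curve <- vector("list", tcfg$maxEpochs)
  for (epoch in seq_len(tcfg$maxEpochs)) {
    ord <- trainIdx[sample.int(length(trainIdx))]
    losses <- c()
    for (start in seq(1, length(ord), by = tcfg$batchSize)) {
      sel <- ord[start:min(start + tcfg$batchSize - 1, length(ord))]
      xb <- assembleBatch(vols, sel, aug = tcfg$augment)
      out <- networkForward(net, xb, training = TRUE)
      lg <- ceLossGrad(out$logits, yIdx[sel])
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; reduce the learning rate")
      losses <- c(losses, lg$loss)
      zeroGrads(net)
      networkBackward(net, lg$grad)
      st <- adamStep(net, st, tcfg)
    }
    ev <- evalOnSet(net, vols, valIdx, yIdx, nC, tcfg$batchSize)
    lrNow <- tcfg$lr * tcfg$lrDecayPerStep^(st$t - 1L)
    curve[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                 val_acc = ev$acc, val_mse = ev$mse,
                                 lr = lrNow)
    score <- if (tcfg$selection == "accuracy") ev$acc else -ev$mse
    if (score > bestScore) {
      bestScore <- score; best <- paramSnapshot(net)
      bestEpoch <- epoch; bestAcc <- ev$acc
    }
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val acc %.3f val mse %.4f",
                      epoch, mean(losses), ev$acc, ev$mse))
    if (!is.null(tcfg$targetValAcc) && ev$acc >= tcfg$targetValAcc) break
  }
  structure(list(snapshot = best, cfg = netCfg, classNames = classNames,
                 provenance = list(seed = tcfg$seed, epoch = bestEpoch,
                                   valAccuracy = bestAcc),
                 curve = do.call(rbind, curve[!vapply(curve, is.null, TRUE)]),
                 selection = tcfg$selection),
            class = "tomoCheckpoint")
}

restoreNetwork <- function(ckpt) {
  net <- buildNetwork(ckpt$cfg, seed = 1)
  applySnapshot(net, ckpt$snapshot)
  net
}

#' Classify tomograms with a trained checkpoint
#'
#' @param ckpt a `tomoCheckpoint` from [trainNetwork()].
#' @param x a [Tomogram], list of tomograms/arrays, manifest data.frame or
#'   in-memory cohort.
#' @param batchSize inference batch size (inference is batch-invariant:
#'   normalization uses stored running statistics).
#' @return list with `probabilities` (cells x classes, rows sum to 1) and
#'   `labels` (argmax class names).
#' @export
predictTomograms <- function(ckpt, x, batchSize = 8L) {
  vols <- inputVolumes(ckpt, x)
  net <- restoreNetwork(ckpt)
  nC <- length(ckpt$classNames)
  probs <- matrix(0, length(vols), nC,
                  dimnames = list(names(vols), ckpt$classNames))
  for (start in seq(1, length(vols), by = batchSize)) {
    sel <- start:min(start + batchSize - 1, length(vols))
    out <- networkForward(net, assembleBatch(vols, sel), training = FALSE)
    probs[sel, ] <- t(softmaxCols(out$logits))
  }
  list(probabilities = probs,
       labels = ckpt$classNames[max.col(probs, ties.method = "first")])
}

inputVolumes <- function(ckpt, x) {
  toVol <- function(v) {
    if (is(v, "Tomogram")) v <- voxels(v)
    if (is(v, "Projection2D")) v <- projectionVolume(v)
    if (!all(dim(v) == ckpt$cfg$inShape))
      stop("input shape ", paste(dim(v), collapse = "x"),
           " does not match network inShape ",
           paste(ckpt$cfg$inShape, collapse = "x"),
           " and no resize policy is set")
    v
  }
  if (is(x, "Tomogram") || is(x, "Projection2D") ||
      (is.array(x) && length(dim(x)) == 3))
    return(list(cell = toVol(x)))
  if (is.data.frame(x))
    return(setNames(lapply(x$path, function(p) toVol(readTomogram(p))), x$path))
  if (is.list(x) && !is.null(x$manifest)) {
    src <- volumeSource(x)
    return(setNames(lapply(x$manifest$path, function(p) toVol(src$fetch(p))),
                    x$manifest$path))
  }
  if (is.list(x)) return(lapply(x, toVol))
  stop("unsupported input type")
}

#' Evaluate a checkpoint on one split
#'
#' @param ckpt a `tomoCheckpoint`.
#' @param x manifest data.frame or in-memory cohort with labels.
#' @param split which split to evaluate (`"test"` default).
#' @return an [EvaluationReport].
#' @export
evaluateCheckpoint <- function(ckpt, x, split = "test") {
  src <- volumeSource(x)
  manifest <- src$manifest
  if (!is.null(split)) manifest <- manifest[manifest$split == split, ]
  if (!nrow(manifest)) stop("no records in split '", split, "'")
  mfClasses <- attr(src$manifest, "classNames")
  if (!is.null(mfClasses) && !all(mfClasses == ckpt$classNames))
    stop("checkpoint class names are inconsistent with the manifest")
  sub <- list(manifest = manifest,
              tomograms = setNames(lapply(manifest$path, src$fetch),
                                   manifest$path))
  # fetch returns raw arrays; wrap for inputVolumes
  vols <- lapply(sub$tomograms, identity)
  pred <- predictTomograms(ckpt, vols)
  buildReport(paste0("cnn_", if (ckpt$cfg$inShape[1] == 1) "2d" else "3d"),
              manifest$label, pred$labels, ckpt$classNames,
              ckpt$provenance$seed)
}

#' Save / load a checkpoint directory
#'
#' Weights go to `weights.rds`; the network config, class names and
#' provenance are mirrored in a human-readable `meta.json`.
#'
#' @param ckpt a `tomoCheckpoint`.
#' @param dir checkpoint directory.
#' @return `dir` (save) or the checkpoint (load).
#' @export
saveCheckpoint <- function(ckpt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ckpt, file.path(dir, "weights.rds"))
  meta <- list(networkConfig = unclass(ckpt$cfg),
               class_names = ckpt$classNames,
               provenance = ckpt$provenance, selection = ckpt$selection)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(ckpt$curve, file.path(dir, "curve.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
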