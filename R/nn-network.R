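#' Network configuration for the volumetric classifier
#'
#' The classifier follows a downsample--upsample--downsample (DS--US--DS)
#' topology: two DS stages (batch norm, leaky rectifier, convolution, max
#' pooling) extract features at decreasing resolution; a US block upsamples
#' by nearest-neighbour interpolation and refines via residual blocks fed by
#' a skip from the first DS stage; a second DS block consumes the refined
#' features plus a skip from the first block at matching resolution; the
#' head applies batch norm, leaky rectifier, a 1x1x1 convolution to class
#' logits and global adaptive average pooling. Channel widths and kernel
#' sizes are configuration, sized so a 64^3 model trains on one CPU.
#'
#' 2D inputs are expressed as `inShape = c(1, ny, nx)`: all kernels, pools
#' and upsampling then act on the two trailing axes only.
#'
#' @param inShape integer(3) input shape `(nz, ny, nx)`; axes of extent > 1
#'   must be divisible by 8 (three 2x poolings).
#' @param nClasses number of classes (>= 2).
#' @param baseChannels channel width of the first stage (doubles twice).
#' @param nResBlocks residual refinement blocks in the US stage.
#' @param negativeSlope leaky rectifier slope.
#' @return a `networkConfig` list.
#' @export
networkConfig <- function(inShape, nClasses, baseChannels = 16L,
                          nResBlocks = 2L, negativeSlope = 0.01) {
  inShape <- as.integer(inShape)
  if (length(inShape) != 3L) stop("inShape must be (nz, ny, nx)")
  for (ax in 1:3)
    if (inShape[ax] > 1L && (inShape[ax] < 8L || inShape[ax] %% 8L != 0L))
      stop("input axis ", ax, " has extent ", inShape[ax],
           "; non-singleton axes must be >= 8 and divisible by 8 ",
           "(three 2x poolings)")
  if (nClasses < 2L) stop("nClasses must be >= 2")
  structure(list(inShape = inShape, nClasses = as.integer(nClasses),
                 baseChannels = as.integer(baseChannels),
                 nResBlocks = as.integer(nResBlocks),
                 negativeSlope = negativeSlope),
            class = "networkConfig")
}

#' Build the DS--US--DS classifier
#'
#' Weights are He-initialized from the current RNG state under `seed`, so
#' the same `(cfg, seed)` always yields bit-identical parameters.
#'
#' @param cfg a [networkConfig()].
#' @param seed initialization seed.
#' @return network handle (environment) consumed by [trainNetwork()],
#'   [predictTomograms()] and [extractFeatures()].
#' @export
buildNetwork <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "networkConfig"))
  set.seed(as.integer(seed %% 2147483647L))
  C <- cfg$baseChannels
  sing <- cfg$inShape == 1L
  kern <- ifelse(sing, 1L, 3L)
  fact <- ifelse(sing, 1L, 2L)
  mk <- function(cin, cout, k = kern)
    layerConv(cin, cout, rep(as.integer(k), length.out = 3L))
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$kern <- kern; net$fact <- fact
  sl <- cfg$negativeSlope
  L <- list(
    bn0 = layerBatchNorm(1L), act0 = layerLeakyReLU(sl),
    conv1 = mk(1L, C), pool1 = layerMaxPool(as.integer(fact)),
    bn1 = layerBatchNorm(C), act1 = layerLeakyReLU(sl),
    conv2 = mk(C, 2L * C), pool2 = layerMaxPool(as.integer(fact)),
    up = layerUpsample(as.integer(fact)),
    bnU = layerBatchNorm(3L * C), actU = layerLeakyReLU(sl),
    convU = mk(3L * C, 2L * C),
    bnD1 = layerBatchNorm(2L * C), actD1 = layerLeakyReLU(sl),
    convD1 = mk(2L * C, 2L * C), poolD1 = layerMaxPool(as.integer(fact)),
    bnD2 = layerBatchNorm(2L * C), actD2 = layerLeakyReLU(sl),
    convD2 = mk(2L * C, 4L * C), poolD2 = layerMaxPool(as.integer(fact)),
    bnH = layerBatchNorm(4L * C), actH = layerLeakyReLU(sl),
    convH = mk(4L * C, cfg$nClasses, k = 1L))
  for (r in seq_len(cfg$nResBlocks)) {
    L[[sprintf("bnR%da", r)]] <- layerBatchNorm(2L * C)
    L[[sprintf("actR%da", r)]] <- layerLeakyReLU(sl)
    L[[sprintf("convR%da", r)]] <- mk(2L * C, 2L * C)
    L[[sprintf("bnR%db", r)]] <- layerBatchNorm(2L * C)
    L[[sprintf("actR%db", r)]] <- layerLeakyReLU(sl)
    L[[sprintf("convR%db", r)]] <- mk(2L * C, 2L * C)
  }
  net$layers <- L
  net
}

runSeq <- function(layers, x, training) {
  for (l in layers) x <- l$fwd(x, training)
  x
}

bwdSeq <- function(layers, g) {
  for (l in rev(layers)) g <- l$bwd(g)
  g
}

# forward pass; returns logits (nClasses x N) and, when tap = TRUE, the
# globally average-pooled output of the second DS block
networkForward <- function(net, x, training = FALSE, tap = FALSE) {
  L <- net$layers
  A <- runSeq(L[c("bn0", "act0", "conv1", "pool1")], x, training)
  B <- runSeq(L[c("bn1", "act1", "conv2", "pool2")], A, training)
  u <- catChannels(L$up$fwd(B, training), A)
  if (training) net$catDims <- dim(u)
  u <- runSeq(L[c("bnU", "actU", "convU")], u, training)
  for (r in seq_len(net$cfg$nResBlocks)) {
    nm <- sprintf(c("bnR%da", "actR%da", "convR%da",
                    "bnR%db", "actR%db", "convR%db"), r)
    u <- u + runSeq(L[nm], u, training)
  }
  d1 <- runSeq(L[c("bnD1", "actD1", "convD1", "poolD1")], u, training) + B
  d2 <- runSeq(L[c("bnD2", "actD2", "convD2", "poolD2")], d1, training)
  if (training) net$d2Dims <- dim(d2)
  h <- runSeq(L[c("bnH", "actH", "convH")], d2, training)
  if (training) net$hDims <- dim(h)
  logits <- globalAvgPool(h)
  out <- list(logits = logits)
  if (tap) out$features <- globalAvgPool(d2)
  out
}

# backward pass from d(loss)/d(logits); accumulates parameter grads
networkBackward <- function(net, gLogits) {
  L <- net$layers
  g <- globalAvgPoolBwd(gLogits, net$hDims)
  g <- bwdSeq(L[c("bnH", "actH", "convH")], g)
  g <- bwdSeq(L[c("bnD2", "actD2", "convD2", "poolD2")], g)
  gB <- g                                   # skip add: gradient into B
  g <- bwdSeq(L[c("bnD1", "actD1", "convD1", "poolD1")], g)
  for (r in rev(seq_len(net$cfg$nResBlocks))) {
    nm <- sprintf(c("bnR%da", "actR%da", "convR%da",
                    "bnR%db", "actR%db", "convR%db"), r)
    g <- g + bwdSeq(L[nm], g)               # residual add
  }
  g <- bwdSeq(L[c("bnU", "actU", "convU")], g)
  C <- net$cfg$baseChannels
  gUp <- g[, , , seq_len(2L * C), , drop = FALSE]
  gA <- g[, , , 2L * C + seq_len(C), , drop = FALSE]
  dim(gUp) <- c(dim(g)[1:3], 2L * C, dim(g)[5])
  dim(gA) <- c(dim(g)[1:3], C, dim(g)[5])
  gB <- gB + L$up$bwd(gUp)
  gA2 <- bwdSeq(L[c("bn1", "act1", "conv2", "pool2")], gB)
  gA <- gA + gA2
  invisible(bwdSeq(L[c("bn0", "act0", "conv1", "pool1")], gA))
}

zeroGrads <- function(net) {
  for (l in net$layers)
    for (nm in names(l$grads))
      l$grads[[nm]] <- l$grads[[nm]] * 0
}

# snapshot / restore of all learnable state (params + BN running moments)
paramSnapshot <- function(net) {
  lapply(net$layers, function(l) {
    s <- list(params = l$params)
    if (l$type == "batchnorm") {
      s$runMean <- l$runMean; s$runVar <- l$runVar; s$count <- l$count
    }
    s
  })
}

applySnapshot <- function(net, snap) {
  for (nm in names(snap)) {
    l <- net$layers[[nm]]
    l$params <- snap[[nm]]$params
    if (l$type == "batchnorm") {
      l$runMean <- snap[[nm]]$runMean
      l$runVar <- snap[[nm]]$runVar
      l$count <- snap[[nm]]$count
    }
  }
  invisible(net)
}

# checksum over all parameters (init-determinism contract)
paramChecksum <- function(net) {
  v <- unlist(lapply(net$layers, function(l) unlist(l$params)))
  sum(v * seq_along(v) %% 97)
}

softmaxCols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# mean cross-entropy and d(loss)/d(logits) for one-hot targets
ceLossGrad <- function(logits, yIdx) {
  p <- softmaxCols(logits)
  N <- ncol(p)
  picked <- p[cbind(yIdx, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  g <- p
  g[cbind(yIdx, seq_len(N))] <- g[cbind(yIdx, seq_len(N))] - 1
  list(loss = loss, grad = g / N)
}
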