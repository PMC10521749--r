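# Layer objects for the volumetric conv net. Each layer is an environment
# holding params / grads / state with fwd(x, training) and bwd(gy) closures;
# activations are arrays dim (nz, ny, nx, C, N). Written against the C++
# kernels in src/convnet.cpp; everything is deterministic given the R RNG.

layerBatchNorm <- function(C, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "batchnorm"
  l$params <- list(gamma = rep(1, C), beta = rep(0, C))
  l$grads <- list(gamma = rep(0, C), beta = rep(0, C))
  # running moments kept as debiased exponential averages so that short
  # training runs already evaluate with sensible statistics
  l$runMean <- rep(0, C); l$runVar <- rep(0, C); l$count <- 0L
  l$fwd <- function(x, training) {
    d <- dim(x); nvox <- prod(d[1:3]); C <- d[4]; N <- d[5]
    if (training) {
      mo <- .chan_moments(x, nvox)
      mu <- rowMeans(matrix(mo$mean, C, N))
      v <- pmax(rowMeans(matrix(mo$meansq, C, N)) - mu^2, 0)
      l$runMean <- (1 - momentum) * l$runMean + momentum * mu
      l$runVar <- (1 - momentum) * l$runVar + momentum * v
      l$count <- l$count + 1L
    } else if (l$count > 0L) {
      corr <- 1 - (1 - momentum)^l$count
      mu <- l$runMean / corr; v <- l$runVar / corr
    } else {
      mu <- rep(0, C); v <- rep(1, C)
    }
    inv <- 1 / sqrt(v + eps)
    xhat <- .chan_affine(x, nvox, rep(inv, N), rep(-mu * inv, N))
    if (training) { l$xhat <- xhat; l$inv <- inv }
    .chan_affine(xhat, nvox, rep(l$params$gamma, N), rep(l$params$beta, N))
  }
  l$bwd <- function(gy) {
    d <- dim(gy); nvox <- prod(d[1:3]); C <- d[4]; N <- d[5]
    s <- .chan_sums(gy, l$xhat, nvox)
    sum_gy <- rowSums(matrix(s$sum, C, N))
    sum_gyx <- rowSums(matrix(s$sumx, C, N))
    l$grads$gamma <- l$grads$gamma + sum_gyx
    l$grads$beta <- l$grads$beta + sum_gy
    M <- nvox * N
    coef <- l$params$gamma * l$inv
    gx <- .bn_bwd_fuse(gy, l$xhat, nvox, rep(coef, N),
                       rep(-coef * sum_gyx / M, N),
                       rep(-coef * sum_gy / M, N))
    l$xhat <- NULL
    gx
  }
  l
}

layerLeakyReLU <- function(slope = 0.01) {
  l <- new.env(parent = emptyenv())
  l$type <- "leakyrelu"
  l$params <- list(); l$grads <- list()
  l$fwd <- function(x, training) {
    y <- .lrelu_fwd(x, slope)
    if (training) l$y <- y
    y
  }
  l$bwd <- function(gy) {
    g <- .lrelu_bwd(gy, l$y, slope)
    l$y <- NULL
    g
  }
  l
}

layerConv <- function(cin, cout, kernel = c(3L, 3L, 3L)) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  fanIn <- prod(kernel) * cin
  W <- array(rnorm(fanIn * cout, 0, sqrt(2 / fanIn)),  # He initialization
             dim = c(kernel, cin, cout))
  l$params <- list(W = W, b = rep(0, cout))
  l$grads <- list(W = array(0, dim(W)), b = rep(0, cout))
  l$fwd <- function(x, training) {
    if (training) l$x <- x
    .conv_fwd(x, dim(x), l$params$W, dim(l$params$W), l$params$b)
  }
  l$bwd <- function(gy) {
    g <- .conv_bwd(l$x, dim(l$x), l$params$W, dim(l$params$W), gy)
    l$grads$W <- l$grads$W + g$gradW
    l$grads$b <- l$grads$b + g$gradB
    gi <- g$gradIn
    dim(gi) <- dim(l$x)
    l$x <- NULL
    gi
  }
  l
}

layerMaxPool <- function(factor = c(2L, 2L, 2L)) {
  l <- new.env(parent = emptyenv())
  l$type <- "maxpool"
  l$params <- list(); l$grads <- list()
  l$fwd <- function(x, training) {
    r <- .maxpool_fwd(x, dim(x), factor)
    if (training) { l$argmax <- r$argmax; l$inDims <- dim(x); l$outDims <- dim(r$out) }
    r$out
  }
  l$bwd <- function(gy) {
    g <- .maxpool_bwd(gy, l$argmax, l$inDims, l$outDims)
    l$argmax <- NULL
    g
  }
  l
}

layerUpsample <- function(factor = c(2L, 2L, 2L)) {
  l <- new.env(parent = emptyenv())
  l$type <- "upsample"
  l$params <- list(); l$grads <- list()
  l$fwd <- function(x, training) {
    if (training) l$inDims <- dim(x)
    .upsample_fwd(x, dim(x), factor)
  }
  l$bwd <- function(gy) .upsample_bwd(gy, l$inDims, factor)
  l
}

# channel concatenation of two activations with matching spatial dims
catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

globalAvgPool <- function(x) {
  d <- dim(x); nvox <- prod(d[1:3])
  matrix(colMeans(matrix(x, nvox, d[4] * d[5])), d[4], d[5])
}

globalAvgPoolBwd <- function(gy, dims) {
  nvox <- prod(dims[1:3])
  array(rep(as.numeric(gy), each = nvox) / nvox, dims)
}
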