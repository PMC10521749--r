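# Compact UMAP: fuzzy simplicial set on exact k-nearest neighbours, PCA
# initialization, and batch gradient descent on the cross-entropy layout
# objective with negative sampling. Written for cohort-scale inputs
# (hundreds to a few thousand points) where exact neighbour search is
# cheap and full-batch updates keep the layout deterministic given a seed.

umapGraph <- function(X, nNeighbors) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(nNeighbors)]))
  nnd <- t(vapply(seq_len(n), function(i) D[i, nn[i, ]],
                  numeric(nNeighbors)))
  rho <- nnd[, 1]
  target <- log2(nNeighbors)
  sigma <- vapply(seq_len(n), function(i) {
    d <- pmax(nnd[i, ] - rho[i], 0)
    if (all(d == 0)) return(1)
    lo <- 1e-6; hi <- 1e3
    for (iter in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-d / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, 0)
  w <- matrix(0, n, n)
  for (i in seq_len(n))
    w[i, nn[i, ]] <- exp(-pmax(nnd[i, ] - rho[i], 0) / sigma[i])
  w <- w + t(w) - w * t(w)        # fuzzy set union
  w
}

# a, b of the low-dimensional kernel 1/(1 + a d^(2b)) fitted so the kernel
# approximates the min_dist offset-exponential, as in the reference method
umapCurveParams <- function(minDist, spread = 1) {
  xs <- seq(0, spread * 3, length.out = 300)
  ys <- ifelse(xs < minDist, 1, exp(-(xs - minDist) / spread))
  fit <- optim(c(a = 1.5, b = 1), function(p) {
    yhat <- 1 / (1 + p[1] * xs^(2 * p[2]))
    sum((yhat - ys)^2)
  }, method = "L-BFGS-B", lower = c(1e-3, 1e-3))
  fit$par
}

runUMAP <- function(X, nNeighbors = 15, minDist = 0.1, nEpochs = 150,
                    seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < nNeighbors + 1)
    stop("need at least nNeighbors + 1 = ", nNeighbors + 1,
         " points, got ", n)
  w <- umapGraph(X, nNeighbors)
  ab <- umapCurveParams(minDist)
  pc <- prcomp(X, rank. = 2)$x
  init <- scale(pc)
  init[is.na(init)] <- 0
  edges <- which(w > 0 & upper.tri(w), arr.ind = TRUE)
  .umap_layout(init, edges[, 1], edges[, 2], w[edges],
               as.integer(nEpochs), ab[1], ab[2], 1.0, 5L,
               as.integer(seed %% 2147483647))
}
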