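#' Extract learned features at the classifier's tap point
#'
#' Features are the globally average-pooled activations of the last layer
#' of the second downsampling block, immediately before the classifier
#' head; the feature dimension equals that block's channel count (4 x
#' `baseChannels`). Deterministic: inference uses stored normalization
#' statistics.
#'
#' @param ckpt a `tomoCheckpoint`.
#' @param x tomograms (any form accepted by [predictTomograms()]).
#' @param batchSize inference batch size.
#' @return matrix, one row per cell.
#' @export
extractFeatures <- function(ckpt, x, batchSize = 8L) {
  vols <- inputVolumes(ckpt, x)
  net <- restoreNetwork(ckpt)
  feats <- NULL
  for (start in seq(1, length(vols), by = batchSize)) {
    sel <- start:min(start + batchSize - 1, length(vols))
    out <- networkForward(net, assembleBatch(vols, sel), training = FALSE,
                          tap = TRUE)
    feats <- rbind(feats, t(out$features))
  }
  rownames(feats) <- names(vols)
  feats
}

#' Embed learned features in 2D with UMAP
#'
#' Builds the fuzzy topological representation of the feature vectors on
#' exact k-nearest neighbours and optimizes a 2D layout of it (see the
#' methods vignette for the implementation notes). Re-running with the
#' same seed gives identical coordinates.
#'
#' @param features numeric matrix, one row per cell.
#' @param labels class labels (stored alongside the coordinates).
#' @param nNeighbors,minDist,nEpochs UMAP hyperparameters (Euclidean
#'   metric).
#' @param seed layout seed.
#' @return data.frame `cell_id,label,x,y` with attribute `params`.
#' @export
embedUMAP <- function(features, labels = NULL, nNeighbors = 15,
                      minDist = 0.1, nEpochs = 150, seed = 1) {
  Y <- runUMAP(features, nNeighbors = nNeighbors, minDist = minDist,
               nEpochs = nEpochs, seed = seed)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  out <- data.frame(cell_id = ids,
                    label = if (is.null(labels)) NA_character_ else labels,
                    x = Y[, 1], y = Y[, 2], stringsAsFactors = FALSE)
  attr(out, "params") <- list(n_neighbors = nNeighbors, min_dist = minDist,
                              metric = "euclidean", n_epochs = nEpochs,
                              seed = seed)
  out
}

#' Plot a 2D embedding coloured by class
#'
#' @param embedding output of [embedUMAP()].
#' @param path optional output file (PNG/SVG via ggsave); `NULL` returns
#'   the ggplot object.
#' @return the ggplot object, invisibly when written to file.
#' @export
plotEmbedding <- function(embedding, path = NULL) {
  g <- ggplot2::ggplot(embedding,
                       ggplot2::aes(x = x, y = y,
                                    colour = label)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
  if (is.null(path)) return(g)
  ggplot2::ggsave(path, g, width = 5, height = 4, dpi = 120)
  invisible(g)
}

#' Mean silhouette score of a labelled 2D embedding
#'
#' Euclidean silhouette over the embedding coordinates against the true
#' labels: the quantitative stand-in for "clearly clustered".
#'
#' @param embedding output of [embedUMAP()] (needs `label`).
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouetteScore <- function(embedding) {
  Y <- as.matrix(embedding[, c("x", "y")])
  lab <- embedding$label
  D <- as.matrix(dist(Y))
  n <- nrow(Y)
  s <- vapply(seq_len(n), function(i) {
    own <- lab == lab[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(D[i, lab == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}
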