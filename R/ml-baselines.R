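featureColumns <- c("volume_fl", "surface_area_um2", "sphericity",
                    "dry_mass_pg", "pd_gdl", "mean_ri")

checkFeatureTable <- function(table) {
  miss <- setdiff(c("label", "split", featureColumns), names(table))
  if (length(miss)) stop("feature table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(table[, featureColumns])) stop("feature table has missing values")
  invisible(table)
}

# z-score standardization with statistics from the train split only
standardizeFeatures <- function(table) {
  checkFeatureTable(table)
  tr <- table[table$split == "train", featureColumns, drop = FALSE]
  centre <- colMeans(tr)
  scale_ <- vapply(tr, sd, 0)
  scale_[scale_ == 0] <- 1
  for (f in featureColumns) table[[f]] <- (table[[f]] - centre[f]) / scale_[f]
  attr(table, "center") <- centre
  attr(table, "scale") <- scale_
  table
}

#' Map the four WBC subtypes onto the two lineages
#'
#' Relabels `B`/`T` as `lymphoid` and `Mono`/`My` as `myeloid`, turning any
#' four-class table or manifest into the binary lineage task.
#'
#' @param x data.frame with a `label` column.
#' @return `x` with remapped labels.
#' @export
relabelLineage <- function(x) {
  map <- c(B = "lymphoid", T = "lymphoid", Mono = "myeloid", My = "myeloid")
  bad <- setdiff(unique(x$label), names(map))
  if (length(bad)) stop("no lineage mapping for label(s): ",
                        paste(bad, collapse = ", "))
  x$label <- unname(map[x$label])
  attr(x, "classNames") <- c("lymphoid", "myeloid")
  x
}

# deterministic k-nearest-neighbour classifier; ties in the vote are broken
# by smallest mean distance to the tied class, then by class order
knnPredict <- function(trainX, trainY, testX, k, classNames) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  n <- nrow(testX)
  out <- character(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(trainX) - testX[i, ])^2))
    nb <- order(d)[seq_len(k)]
    votes <- table(factor(trainY[nb], levels = classNames))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      meanD <- vapply(top, function(cl) mean(d[nb][trainY[nb] == cl]), 0)
      top <- top[meanD == min(meanD)]
    }
    out[i] <- top[1L]
  }
  out
}

# one-vs-one SVM committee with error-correcting-output-code decoding:
# C(K,2) binary linear SVMs; the predicted class minimizes the Hamming
# distance between its code word and the binary decisions (= pairwise vote)
svmEcoc <- function(trainX, trainY, testX, classNames, kernel = "linear") {
  pairs <- utils::combn(classNames, 2, simplify = FALSE)
  votes <- matrix(0L, nrow(testX), length(classNames),
                  dimnames = list(NULL, classNames))
  for (pr in pairs) {
    sel <- trainY %in% pr
    fit <- e1071::svm(x = as.matrix(trainX[sel, , drop = FALSE]),
                      y = factor(trainY[sel], levels = pr),
                      kernel = kernel, scale = FALSE)
    pred <- as.character(predict(fit, as.matrix(testX)))
    for (cl in pr) votes[, cl] <- votes[, cl] + (pred == cl)
  }
  # ties broken by class order
  classNames[apply(votes, 1, which.max)]
}

buildReport <- function(modelName, truth, pred, classNames, seed) {
  cm <- table(factor(truth, levels = classNames),
              factor(pred, levels = classNames))
  cm <- matrix(as.integer(cm), nrow = length(classNames),
               dimnames = list(true = classNames, predicted = classNames))
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  new("EvaluationReport", modelName = modelName,
      accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
      perClass = data.frame(class = classNames, precision = prec,
                            recall = rec, row.names = NULL),
      classNames = classNames, seed = as.numeric(seed))
}

#' Train and evaluate one classical classifier on the six features
#'
#' Fits on the train split only (standardization statistics included) and
#' reports held-out metrics on the test split. Models: `svm_ecoc` (six
#' pairwise linear SVMs combined by error-correcting-output-code voting),
#' `knn` (k = 5, Euclidean on standardized features, deterministic
#' tie-breaks), `ldc` (linear discriminant), `nb` (Gaussian naive Bayes),
#' `dt` (decision tree, Gini impurity).
#'
#' @param table feature table: `label`, `split` and the six feature columns
#'   `volume_fl, surface_area_um2, sphericity, dry_mass_pg, pd_gdl, mean_ri`.
#' @param model model name.
#' @param seed RNG seed recorded in the report (fitting is deterministic).
#' @param k neighbours for `knn`.
#' @param kernel SVM kernel (`"linear"` default, `"radial"` optional).
#' @param evalSplit split to evaluate on (default `"test"`).
#' @return an [EvaluationReport].
#' @export
trainEval <- function(table, model = c("svm_ecoc", "knn", "ldc", "nb", "dt"),
                      seed = 1, k = 5, kernel = "linear",
                      evalSplit = "test") {
  model <- match.arg(model)
  checkFeatureTable(table)
  classNames <- attr(table, "classNames")
  if (is.null(classNames)) classNames <- sort(unique(table$label))
  if (length(classNames) < 2L) stop("need at least 2 classes")
  if (!all(c("train", "val", "test") %in% table$split))
    stop("table must contain train, val and test splits")
  missing_ <- setdiff(classNames, table$label[table$split == "train"])
  if (length(missing_)) stop("class absent from train split: ",
                             paste(missing_, collapse = ", "))
  std <- standardizeFeatures(table)
  tr <- std[std$split == "train", ]
  te <- std[std$split == evalSplit, ]
  trX <- tr[, featureColumns]; teX <- te[, featureColumns]
  trY <- factor(tr$label, levels = classNames)
  set.seed(as.integer(seed %% 2147483647L))
  pred <- switch(model,
    svm_ecoc = svmEcoc(trX, tr$label, teX, classNames, kernel),
    knn = knnPredict(trX, tr$label, teX, k, classNames),
    ldc = {
      fit <- MASS::lda(trX, grouping = trY)
      as.character(predict(fit, teX)$class)
    },
    nb = {
      fit <- e1071::naiveBayes(trX, trY)
      as.character(predict(fit, teX))
    },
    dt = {
      d <- cbind(label = trY, trX)
      fit <- rpart::rpart(label ~ ., data = d, method = "class",
                          parms = list(split = "gini"))
      as.character(predict(fit, teX, type = "class"))
    })
  buildReport(model, te$label, pred, classNames, seed)
}

#' Run all five classical baselines over several seeds
#'
#' @param table feature table (see [trainEval()]).
#' @param seeds integer vector of seeds.
#' @param csvPath optional path for the comparison CSV.
#' @param figPath optional path for a bar-chart figure (PNG).
#' @return data.frame `(model, mean_accuracy, sd_accuracy)` with the
#'   per-seed reports in attribute `reports`.
#' @export
benchmarkAll <- function(table, seeds = 1:3, csvPath = NULL, figPath = NULL) {
  models <- c("svm_ecoc", "knn", "ldc", "nb", "dt")
  reports <- list()
  rows <- lapply(models, function(mo) {
    acc <- vapply(seeds, function(s) {
      rep_ <- trainEval(table, mo, seed = s)
      reports[[paste(mo, s, sep = "_")]] <<- rep_
      accuracy(rep_)
    }, 0)
    data.frame(model = mo, mean_accuracy = mean(acc),
               sd_accuracy = if (length(acc) > 1) sd(acc) else 0)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csvPath))
    write.csv(format(out, digits = 15, scientific = FALSE, trim = TRUE),
              csvPath, row.names = FALSE, quote = FALSE)
  if (!is.null(figPath)) {
    g <- ggplot2::ggplot(out, ggplot2::aes(x = model, y = mean_accuracy)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_accuracy - sd_accuracy,
                                          ymax = mean_accuracy + sd_accuracy),
                             width = 0.2) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(y = "test accuracy", x = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(figPath, g, width = 5, height = 3.5, dpi = 120)
  }
  attr(out, "reports") <- reports
  out
}
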