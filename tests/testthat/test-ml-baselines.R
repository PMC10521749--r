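sepTable <- function() {
  memo("sepTable", {
    # widely separated classes: every model should be perfect
    set.seed(2)
    n <- 40
    rows <- lapply(1:4, function(k) {
      data.frame(cell_id = sprintf("c%d_%02d", k, 1:n),
                 label = paste0("k", k),
                 volume_fl = rnorm(n, 100 * k, 3),
                 surface_area_um2 = rnorm(n, 120 * k, 3),
                 sphericity = rnorm(n, 0.70 + 0.05 * k, 0.002),
                 dry_mass_pg = rnorm(n, 20 * k, 0.5),
                 pd_gdl = rnorm(n, 12 + 2 * k, 0.05),
                 mean_ri = rnorm(n, 1.34 + 0.008 * k, 1e-4))
    })
    tb <- do.call(rbind, rows)
    splitManifest(within(tb, path <- cell_id), seed = 3)
  })
}

test_that("all five models are perfect on a widely separated cohort", {
  tb <- sepTable()
  for (mo in c("svm_ecoc", "knn", "ldc", "nb", "dt")) {
    r <- trainEval(tb, mo, seed = 1)
    expect_identical(accuracy(r), 1, info = mo)
    cm <- confusionMatrix(r)
    expect_identical(unname(rowSums(cm)),
                     as.numeric(table(tb$label[tb$split == "test"])))
    expect_equal(accuracy(r), sum(diag(cm)) / sum(cm))
  }
})

test_that("KNN with k = 5 equals brute-force neighbour enumeration", {
  trainX <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5, 6, 5, 5, 6,
                     10, 0, 11, 0, 10, 1, 0, 10, 1, 10, 0, 11),
                   ncol = 2, byrow = TRUE)
  trainY <- rep(c("a", "b", "c", "d"), each = 3)
  testX <- matrix(c(0.2, 0.3, 5.1, 5.2, 10.2, 0.1, 0.5, 10.5,
                    3, 3, 7, 3), ncol = 2, byrow = TRUE)
  got <- tomocyte:::knnPredict(trainX, trainY, testX, k = 5,
                               classNames = c("a", "b", "c", "d"))
  # independent oracle: exhaustive distances, majority vote, mean-distance
  # then class-order tie-breaks
  want <- apply(testX, 1, function(p) {
    d <- sqrt(rowSums(sweep(trainX, 2, p)^2))
    nb <- order(d)[1:5]
    v <- table(factor(trainY[nb], levels = c("a", "b", "c", "d")))
    top <- names(v)[v == max(v)]
    if (length(top) > 1) {
      md <- sapply(top, function(cl) mean(d[nb][trainY[nb] == cl]))
      top <- top[md == min(md)]
    }
    top[1]
  })
  expect_identical(got, unname(want))
})

test_that("label permutation drops accuracy to chance", {
  tb <- mlFeatureTable()
  set.seed(99)
  tb$label <- sample(tb$label)
  attr(tb, "classNames") <- sort(unique(tb$label))
  r <- trainEval(tb, "knn", seed = 1)
  nTest <- sum(tb$split == "test")
  ci <- 2.576 * sqrt(0.25 * 0.75 / nTest)
  expect_gt(accuracy(r), 0.25 - ci)
  expect_lt(accuracy(r), 0.25 + ci)
})

test_that("fits are functions of the train split only (no leakage)", {
  tb <- sepTable()
  poisoned <- tb
  sel <- poisoned$split == "test"
  poisoned[sel, tomocyte:::featureColumns] <-
    poisoned[sel, tomocyte:::featureColumns] * 10 + 3
  for (mo in c("svm_ecoc", "knn", "ldc", "nb", "dt")) {
    a <- trainEval(tb, mo, seed = 1, evalSplit = "val")
    b <- trainEval(poisoned, mo, seed = 1, evalSplit = "val")
    expect_identical(confusionMatrix(a), confusionMatrix(b), info = mo)
  }
})

test_that("missing splits, classes or values are rejected", {
  tb <- sepTable()
  noTrain <- tb[tb$split != "train", ]
  expect_error(trainEval(noTrain, "knn"), "train")
  oneOut <- tb[!(tb$label == "k1" & tb$split == "train"), ]
  expect_error(trainEval(oneOut, "knn"), "absent from train")
  bad <- tb; bad$pd_gdl[1] <- NA
  expect_error(trainEval(bad, "knn"), "missing")
})

test_that("benchmarkAll writes a deterministic comparison table", {
  tb <- sepTable()
  f1 <- file.path(tempdir(), "cmp1.csv"); f2 <- file.path(tempdir(), "cmp2.csv")
  out <- benchmarkAll(tb, seeds = 1:2, csvPath = f1)
  benchmarkAll(tb, seeds = 1:2, csvPath = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(nrow(out), 5L)
  expect_true(all(out$mean_accuracy == 1))
})

test_that("lineage relabelling collapses the four classes to two", {
  tb <- mlFeatureTable()
  tb$label <- c(L1 = "B", L2 = "T", M1 = "Mono", M2 = "My")[tb$label]
  attr(tb, "classNames") <- NULL
  bin <- relabelLineage(tb)
  expect_identical(sort(unique(bin$label)), c("lymphoid", "myeloid"))
  r <- trainEval(bin, "ldc", seed = 1)
  expect_identical(dim(confusionMatrix(r)), c(2L, 2L))
  # volume separates the lineages well in this cohort
  expect_gt(accuracy(r), 0.8)
  expect_error(relabelLineage(data.frame(label = "X")), "mapping")
})
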