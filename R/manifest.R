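#' Dataset manifests
#'
#' A manifest is a plain data.frame with columns `path`, `label` and
#' (optionally) `split`, stored on disk as UTF-8 CSV with that header. It
#' binds tomogram files to class labels and train/val/test assignment.
#'
#' @param path CSV file.
#' @param classNames optional ordered class vector; defaults to the sorted
#'   unique labels. Any label outside `classNames` is an error.
#' @return data.frame with attribute `classNames`.
#' @export
loadManifest <- function(path, classNames = NULL) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have columns path,label[,split]")
  if (is.null(classNames)) classNames <- sort(unique(m$label))
  bad <- setdiff(unique(m$label), classNames)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (!is.null(m$split)) {
    badSplit <- setdiff(unique(m$split), c("train", "val", "test"))
    if (length(badSplit)) stop("unknown split value(s): ",
                               paste(badSplit, collapse = ", "))
  }
  attr(m, "classNames") <- classNames
  m
}

#' @rdname loadManifest
#' @param m manifest data.frame.
#' @export
writeManifest <- function(m, path) {
  keep <- intersect(c("path", "label", "split"), names(m))
  write.csv(m[, keep, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# largest-remainder apportionment of n into parts proportional to fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign train/val/test splits
#'
#' Deterministic, seeded assignment. By default the split is stratified per
#' class (largest-remainder apportionment of each class to the three splits,
#' so per-class counts are within 1 of `fraction * class size`); a global
#' shuffle over the pooled records is available with `stratified = FALSE`.
#'
#' @param m manifest data.frame (`path`, `label`).
#' @param fractions numeric(3) `(train, val, test)` summing to 1; the
#'   default is the 7:1:2 protocol.
#' @param seed integer RNG seed; the assignment is a pure function of the
#'   record order and this seed.
#' @param stratified per-class (default) or global shuffling.
#' @return the manifest with a `split` column.
#' @export
splitManifest <- function(m, fractions = c(0.7, 0.1, 0.2), seed = 1,
                          stratified = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (length(fractions) != 3L) stop("fractions must be (train, val, test)")
  splitNames <- c("train", "val", "test")
  m$split <- NA_character_
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (stratified) {
    for (lab in unique(m$label)) {
      rows <- which(m$label == lab)
      counts <- apportion(length(rows), fractions)
      assign <- rep(splitNames, counts)
      m$split[rows] <- assign[sample.int(length(rows))]
    }
  } else {
    counts <- apportion(nrow(m), fractions)
    assign <- rep(splitNames, counts)
    m$split <- assign[sample.int(nrow(m))]
  }
  m
}
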