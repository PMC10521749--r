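test_that("write/read round trip preserves voxels and metadata", {
  v <- array(1.337, c(16, 16, 16))
  v[8, 8, 8] <- 1.39
  t <- Tomogram(v, pitchUm = 0.2, mediumRI = 1.337, wavelengthUm = 0.532,
                cellId = "rt1")
  path <- file.path(tempdir(), "rt1.tiff")
  writeTomogram(t, path)
  r <- readTomogram(path)
  expect_equal(voxels(r), voxels(t), tolerance = 1e-6)
  expect_identical(pitch(r), pitch(t))
  expect_identical(mediumRI(r), mediumRI(t))
  expect_identical(wavelengthUm(r), wavelengthUm(t))
  expect_identical(cellId(r), "rt1")
  # float32 storage keeps 64-bit inputs to < 1e-6 absolute
  set.seed(3)
  t2 <- Tomogram(array(runif(16^3, 1.33, 1.42), c(16, 16, 16)), 0.2, 1.337)
  p2 <- file.path(tempdir(), "rt2.tiff")
  writeTomogram(t2, p2)
  expect_lt(max(abs(voxels(readTomogram(p2)) - voxels(t2))), 1e-6)
  # z-slice order is preserved (page 0 = lowest z)
  vz <- array(1.337, c(4, 6, 6)); vz[2, , ] <- 1.40
  pz <- file.path(tempdir(), "rt3.tiff")
  writeTomogram(Tomogram(vz, 0.2, 1.337), pz)
  expect_equal(which.max(apply(voxels(readTomogram(pz)), 1, max)), 2L)
})

test_that("metadata contracts are enforced, never defaulted", {
  t <- Tomogram(array(1.35, c(8, 8, 8)), 0.2, 1.337)
  path <- file.path(tempdir(), "meta1.tiff")
  writeTomogram(t, path)
  # missing sidecar
  file.remove(sub("\\.tiff$", ".meta.json", path))
  expect_error(readTomogram(path), "sidecar")
  # missing pitch key
  writeTomogram(t, path)
  mp <- sub("\\.tiff$", ".meta.json", path)
  m <- jsonlite::read_json(mp)
  m$pitch_xyz <- NULL
  jsonlite::write_json(m, mp, auto_unbox = TRUE)
  expect_error(readTomogram(path), "pitch")
  expect_error(readTomogram(file.path(tempdir(), "absent.tiff")), "no such")
  expect_error(writeTomogram(t, path, format = "hdf5"), "HDF5")
})

test_that("non-RI-like and degenerate volumes are rejected", {
  expect_error(Tomogram(array(0.8, c(4, 4, 4)), 0.2, 1.337), "RI")
  expect_error(Tomogram(array(numeric(0), c(0, 4, 4)), 0.2, 1.337),
               "non-empty")
  expect_error(Tomogram(array(1.35, c(4, 4, 4)), -0.2, 1.337), "pitch")
  expect_error(Tomogram(array(1.35, c(4, 4, 4)), 0.2, 1.5), "mediumRI")
})

test_that("manifest split conserves records and stratifies per class", {
  # the study's cohort arithmetic: 403 + 379 + 399 + 689 = 1870 records
  m <- data.frame(
    path = sprintf("c%04d.tiff", 1:1870),
    label = rep(c("My", "Mono", "B", "T"), c(403, 379, 399, 689)))
  s <- splitManifest(m, c(0.7, 0.1, 0.2), seed = 42)
  expect_identical(nrow(s), 1870L)
  expect_identical(sort(unique(s$split)), c("test", "train", "val"))
  expect_identical(as.integer(sum(table(s$split))), 1870L)
  # stratified: per-class counts within 1 of fraction * class size
  for (lab in unique(m$label)) {
    cls <- s[s$label == lab, ]
    for (i in 1:3) {
      frac <- c(train = 0.7, val = 0.1, test = 0.2)[i]
      expect_lte(abs(sum(cls$split == names(frac)) - frac * nrow(cls)), 1)
    }
  }
  # determinism and seed sensitivity
  expect_identical(splitManifest(m, seed = 7)$split,
                   splitManifest(m, seed = 7)$split)
  expect_false(identical(splitManifest(m, seed = 7)$split,
                         splitManifest(m, seed = 8)$split))
  # exact enumeration for 10 records of one class at 7:1:2
  m10 <- data.frame(path = letters[1:10], label = rep("B", 10))
  s10 <- splitManifest(m10, c(0.7, 0.1, 0.2), seed = 1)
  expect_identical(as.integer(table(s10$split)[c("train", "val", "test")]),
                   c(7L, 1L, 2L))
})

test_that("manifest loading validates labels and splits", {
  f <- file.path(tempdir(), "man.csv")
  write.csv(data.frame(path = c("a", "b"), label = c("B", "T"),
                       split = c("train", "test")), f, row.names = FALSE)
  m <- loadManifest(f)
  expect_identical(attr(m, "classNames"), c("B", "T"))
  expect_error(loadManifest(f, classNames = c("B")), "unknown label")
  write.csv(data.frame(path = "a", label = "B", split = "holdout"), f,
            row.names = FALSE)
  expect_error(loadManifest(f), "split")
  expect_error(splitManifest(data.frame(path = "a", label = "B"),
                             c(0.5, 0.3, 0.1)), "sum to 1")
})
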