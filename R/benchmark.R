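#' Experiment configuration for the end-to-end benchmark
#'
#' A single source of truth for one benchmark run: phantom specs, cohort
#' size, split protocol, task, classical models, network/training settings
#' and the output directory. The fully resolved configuration is written
#' beside the outputs of every run.
#'
#' @param specs named list of [PhantomSpec] (all on one grid).
#' @param nPerClass cells per class.
#' @param fractions train/val/test fractions.
#' @param seed master seed for generation, splitting and training.
#' @param task `"four_class"` or `"binary_lineage"` (`{B,T} -> lymphoid`,
#'   `{Mono,My} -> myeloid`).
#' @param models classical baselines to run.
#' @param baseChannels,nResBlocks network size knobs.
#' @param epochs3d,epochs2d training epochs for the 3D and 2D classifiers.
#' @param projectionKind 2D input kind for the 2D baseline.
#' @param makeFigures write PNG figures (off for byte-level reproducibility
#'   checks, which compare the text outputs).
#' @param outDir output directory.
#' @return an `experimentConfig` list.
#' @export
experimentConfig <- function(specs, nPerClass = 12, fractions = c(0.7, 0.1, 0.2),
                             seed = 1, task = c("four_class", "binary_lineage"),
                             models = c("svm_ecoc", "knn", "ldc", "nb", "dt"),
                             baseChannels = 2L, nResBlocks = 1L,
                             epochs3d = 4L, epochs2d = 6L,
                             projectionKind = "mip", makeFigures = FALSE,
                             outDir = tempfile("benchmark")) {
  cfg <- list(specs = specs, nPerClass = nPerClass, fractions = fractions,
              seed = seed, task = match.arg(task), models = models,
              baseChannels = as.integer(baseChannels),
              nResBlocks = as.integer(nResBlocks),
              epochs3d = as.integer(epochs3d), epochs2d = as.integer(epochs2d),
              projectionKind = projectionKind, makeFigures = makeFigures,
              outDir = outDir)
  class(cfg) <- "experimentConfig"
  validateExperimentConfig(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' Structural checks (field presence, types, ranges) applied before any
#' stage runs, so a malformed configuration fails fast with a named field.
#'
#' @param cfg an `experimentConfig` (or plain list).
#' @return the config, invisibly; errors name the offending field.
#' @export
validateExperimentConfig <- function(cfg) {
  fail <- function(f, why) stop("config field '", f, "': ", why)
  if (!length(cfg$specs)) fail("specs", "at least one PhantomSpec required")
  for (s in cfg$specs) if (!is(s, "PhantomSpec"))
    fail("specs", "entries must be PhantomSpec objects")
  if (length(unique(lapply(cfg$specs, function(s) s@gridShape))) != 1)
    fail("specs", "all specs must share one grid shape")
  if (!is.numeric(cfg$nPerClass) || cfg$nPerClass < 1)
    fail("nPerClass", "must be >= 1")
  if (abs(sum(cfg$fractions) - 1) > 1e-9)
    fail("fractions", "must sum to 1")
  if (!cfg$task %in% c("four_class", "binary_lineage"))
    fail("task", "must be four_class or binary_lineage")
  bad <- setdiff(cfg$models, c("svm_ecoc", "knn", "ldc", "nb", "dt"))
  if (length(bad)) fail("models", paste("unknown:", paste(bad, collapse = ",")))
  if (!cfg$projectionKind %in% c("mip", "phase", "amplitude"))
    fail("projectionKind", "must be mip, phase or amplitude")
  invisible(cfg)
}

serializeConfig <- function(cfg) {
  specList <- lapply(cfg$specs, function(s)
    list(class_name = s@className, volume_mean_fl = s@volumeMeanFl,
         volume_sd_fl = s@volumeSdFl, sphericity_mean = s@sphericityMean,
         sphericity_sd = s@sphericitySd, pd_mean_gdl = s@pdMeanGdl,
         pd_sd_gdl = s@pdSdGdl,
         nucleus_volume_fraction = s@nucleusVolumeFraction,
         nucleus_ri_offset = s@nucleusRiOffset, noise_sd_ri = s@noiseSdRi,
         medium_ri = s@mediumRI, pitch_um = s@pitchUm,
         grid_shape = s@gridShape))
  c(list(specs = specList), cfg[setdiff(names(cfg), c("specs", "outDir"))])
}

numfmt <- function(d) {
  for (nm in names(d)) if (is.numeric(d[[nm]]))
    d[[nm]] <- format(d[[nm]], digits = 15, scientific = FALSE, trim = TRUE)
  d
}

#' Run the full benchmark: phantoms to comparison table
#'
#' Generates a cohort, profiles it, runs the classical baselines, trains
#' the 2D-projection and 3D classifiers, embeds the 3D model's learned
#' features, and writes a model-comparison CSV, per-stage reports, the
#' resolved configuration (YAML), a hash manifest of every output and a
#' `run.log` with per-stage wall times. Reproducible: the same config and
#' seed give byte-identical text outputs.
#'
#' @param cfg an [experimentConfig()].
#' @return list with `comparison` (data.frame), `reports`, `embedding`,
#'   `outDir`.
#' @export
runBenchmark <- function(cfg) {
  validateExperimentConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(cfg$outDir, "run.log")
  cat("", file = logFile)
  logLine <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  stageNum <- 0
  stage <- function(name, expr) {
    stageNum <<- stageNum + 1
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("benchmark stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs kept in ", cfg$outDir, ")", call. = FALSE))
    logLine("stage %d [%s]: %.2f s", stageNum, name, proc.time()[3] - t0)
    out
  }
  yaml::write_yaml(serializeConfig(cfg),
                   file.path(cfg$outDir, "config_resolved.yaml"))

  cohort <- stage("simulate", {
    co <- generateCohort(cfg$specs, cfg$nPerClass, cfg$seed,
                         fractions = cfg$fractions)
    if (cfg$task == "binary_lineage") {
      co$manifest <- relabelLineage(co$manifest)
      co$truth$label <- co$manifest$label
    }
    co
  })
  features <- stage("features", {
    ft <- profileCohort(cohort)
    attr(ft, "classNames") <- attr(cohort$manifest, "classNames")
    write.csv(numfmt(ft), file.path(cfg$outDir, "features.csv"),
              row.names = FALSE, quote = FALSE)
    ft
  })
  mlResults <- stage("ml_baselines", {
    rows <- lapply(cfg$models, function(mo) {
      r <- trainEval(features, mo, seed = cfg$seed)
      data.frame(model = mo, accuracy = accuracy(r))
    })
    do.call(rbind, rows)
  })
  gs <- cfg$specs[[1]]@gridShape
  ckpt2d <- stage("cnn2d", {
    proj <- projectCohort(cohort, cfg$projectionKind)
    train2d(proj, trainConfig(maxEpochs = cfg$epochs2d, seed = cfg$seed),
            networkConfig(c(1L, gs[2], gs[3]),
                          length(attr(cohort$manifest, "classNames")),
                          baseChannels = cfg$baseChannels,
                          nResBlocks = cfg$nResBlocks))
  })
  ckpt3d <- stage("cnn3d", {
    trainNetwork(cohort, trainConfig(maxEpochs = cfg$epochs3d, seed = cfg$seed),
                 networkConfig(gs, length(attr(cohort$manifest, "classNames")),
                               baseChannels = cfg$baseChannels,
                               nResBlocks = cfg$nResBlocks))
  })
  reports <- stage("evaluate", {
    r2 <- evaluateCheckpoint(ckpt2d,
                             projectCohort(cohort, cfg$projectionKind))
    r3 <- evaluateCheckpoint(ckpt3d, cohort)
    list(cnn2d = r2, cnn3d = r3)
  })
  embedding <- stage("embedding", {
    test <- cohort$manifest[cohort$manifest$split == "test", ]
    sub <- list(manifest = test,
                tomograms = cohort$tomograms[test$path])
    feats <- extractFeatures(ckpt3d, sub)
    nb <- min(15, nrow(feats) - 1)
    emb <- embedUMAP(feats, labels = test$label, nNeighbors = nb,
                     seed = cfg$seed)
    write.csv(numfmt(emb), file.path(cfg$outDir, "embedding.csv"),
              row.names = FALSE, quote = FALSE)
    if (cfg$makeFigures)
      plotEmbedding(emb, file.path(cfg$outDir, "embedding.png"))
    emb
  })
  comparison <- stage("report", {
    cmp <- rbind(mlResults,
                 data.frame(model = paste0("cnn2d_", cfg$projectionKind),
                            accuracy = accuracy(reports$cnn2d)),
                 data.frame(model = "cnn3d", accuracy = accuracy(reports$cnn3d)))
    write.csv(numfmt(cmp), file.path(cfg$outDir, "comparison.csv"),
              row.names = FALSE, quote = FALSE)
    if (cfg$makeFigures) {
      g <- ggplot2::ggplot(cmp, ggplot2::aes(x = model,
                                             y = accuracy)) +
        ggplot2::geom_col() + ggplot2::ylim(0, 1) +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      ggplot2::ggsave(file.path(cfg$outDir, "comparison.png"), g,
                      width = 5, height = 3.5, dpi = 120)
    }
    cmp
  })
  stage("provenance", {
    outs <- setdiff(list.files(cfg$outDir),
                    c("hashes.json", "run.log"))
    hashes <- as.list(tools::md5sum(file.path(cfg$outDir, outs)))
    names(hashes) <- outs
    cfgHash <- unname(tools::md5sum(file.path(cfg$outDir,
                                              "config_resolved.yaml")))
    jsonlite::write_json(list(config_md5 = cfgHash, outputs = hashes),
                         file.path(cfg$outDir, "hashes.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  list(comparison = comparison, reports = reports, embedding = embedding,
       ml = mlResults, checkpoints = list(cnn2d = ckpt2d, cnn3d = ckpt3d),
       outDir = cfg$outDir)
}

#' Verify a benchmark output directory against its hash manifest
#'
#' @param outDir benchmark output directory containing `hashes.json`.
#' @return logical vector per file (TRUE = intact), invisibly; tampered
#'   files are reported in a warning.
#' @export
verifyHashes <- function(outDir) {
  h <- jsonlite::read_json(file.path(outDir, "hashes.json"),
                           simplifyVector = TRUE)
  now <- tools::md5sum(file.path(outDir, names(h$outputs)))
  ok <- unname(now) == unlist(h$outputs)
  names(ok) <- names(h$outputs)
  if (any(!ok)) warning("hash mismatch: ",
                        paste(names(ok)[!ok], collapse = ", "))
  invisible(ok)
}
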