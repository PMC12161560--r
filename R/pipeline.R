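#' @include training.R
NULL

#' Default experiment configuration
#'
#' Returns a fully populated configuration list for an end-to-end synthetic
#' experiment: simulate a cohort with known slow/fast structure, train the
#' four model variants across seeds, embed every window, and run the
#' evaluation suite (window classification, cross-seed reliability, wFNC
#' manifold comparison, patient clustering with dwell statistics).  Any
#' entry can be overridden before passing the list to
#' \code{\link{runExperiment}}; the same schema can be written as YAML and
#' passed by path.
#'
#' @param outputDir run directory for all artifacts
#' @param seeds training seeds
#' @param maxEpochs epoch budget per run
#' @return nested configuration list
#' @export
defaultExperimentConfig <- function(outputDir,
                                    seeds = c(42L, 1337L, 1212L, 9999L),
                                    maxEpochs = 20L) {
  list(
    output_dir = outputDir,
    synthetic = list(n_subjects_per_group = 50L, n_components = 10L,
                     n_timesteps = 160L, context_dim = 2L, local_dim = 4L,
                     context_drift_timescale = 32, ar_coefficient = 0.3,
                     mixing = "tanh", noise_std = 0.1, seed = 1L),
    data = NULL,        # list(data_path=, metadata_path=) for external data
    normalization = "none",
    window = list(width = 32L, stride = 4L),
    split = list(fractions = c(0.6, 0.2, 0.2), seed = 11L),
    models = list(
      dsvae = list(variant = "dsvae", localSize = 4L, contextSize = 2L,
                   beta = 0.1, gamma = 0.001, maxEpochs = maxEpochs),
      idsvae = list(variant = "idsvae", localSize = 4L, contextSize = 2L,
                    beta = 0.1, gamma = 0.001, maxEpochs = maxEpochs),
      lvae = list(variant = "lvae", localSize = 4L, beta = 0.1,
                  maxEpochs = maxEpochs),
      cvae = list(variant = "cvae", contextSize = 2L, gamma = 0.001,
                  maxEpochs = maxEpochs)),
    seeds = as.integer(seeds),
    training = list(batch_size = 64L, patience = 10L),
    grid = NULL,        # optional list of model-config lists for `grid`
    evaluation = list(svm_cost = 1, k = 3L, max_pairs = 1e6,
                      wfnc_pca_dim = 2L, cluster_model = "dsvae"))
}

.validateExperimentConfig <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list")
  for (f in c("output_dir", "window", "split", "models", "seeds",
              "evaluation"))
    if (is.null(cfg[[f]])) stop(sprintf("config field '%s' is required", f))
  if (is.null(cfg$synthetic) && is.null(cfg$data))
    stop("config needs either a 'synthetic' spec or external 'data' paths")
  if (!is.numeric(cfg$split$fractions) || length(cfg$split$fractions) != 3L)
    stop("split$fractions must be three numbers")
  if (abs(sum(cfg$split$fractions) - 1) > 1e-9)
    stop("split$fractions must sum to 1")
  for (m in cfg$models)
    if (is.null(m$variant) || !m$variant %in% .VARIANTS)
      stop("every model entry needs a valid 'variant'")
  if (!is.null(cfg$evaluation$cluster_model) &&
      !cfg$evaluation$cluster_model %in% names(cfg$models))
    stop("evaluation$cluster_model must name a configured model")
  invisible(TRUE)
}

.cfgHash <- function(cfg) {
  # stable content hash of the resolved config (drop output_dir so a moved
  # run directory still counts as up to date)
  cfg$output_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, digits = NA, auto_unbox = TRUE)
  unname(tools::md5sum(f))
}

.syntheticSpecFromCfg <- function(sc) {
  syntheticSpec(
    nSubjectsPerGroup = sc$n_subjects_per_group %||% 50L,
    nComponents = sc$n_components %||% 10L,
    nTimesteps = sc$n_timesteps %||% 160L,
    contextDim = sc$context_dim %||% 2L,
    localDim = sc$local_dim %||% 4L,
    contextGroupOffset = sc$context_group_offset,
    contextDriftTimescale = sc$context_drift_timescale %||% 32,
    arCoefficient = sc$ar_coefficient %||% 0.3,
    mixing = sc$mixing %||% "tanh",
    noiseStd = sc$noise_std %||% 0.1,
    seed = sc$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.modelConfigFromCfg <- function(mc, seed) {
  args <- mc[intersect(names(mc),
                       c("variant", "localSize", "contextSize", "beta",
                         "gamma", "contextEncoderArch", "hiddenSize",
                         "convKernel", "learningRate", "maxEpochs",
                         "inputNoiseStd"))]
  args$seed <- seed
  do.call(modelConfig, args)
}

.stageDone <- function(dir, stage, hash) {
  marker <- file.path(dir, paste0(".done.", stage))
  file.exists(marker) && identical(readLines(marker, n = 1L), hash)
}

.markDone <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, paste0(".done.", stage)))
}

.updateManifest <- function(dir, stage, hash, files) {
  mf <- file.path(dir, "manifest.json")
  man <- if (file.exists(mf)) jsonlite::read_json(mf) else
    list(package_version = as.character(utils::packageVersion("dsvae")),
         config_hash = hash, stages = list())
  man$config_hash <- hash
  files <- files[file.exists(files)]
  man$stages[[stage]] <- list(
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(man, mf, digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

.loadExperimentData <- function(cfg, out) {
  if (!is.null(cfg$synthetic)) {
    records <- loadTimecourses(file.path(out, "data"),
                               file.path(out, "data", "metadata.csv"))
  } else {
    records <- loadTimecourses(cfg$data$data_path, cfg$data$metadata_path)
  }
  normalizeComponents(records, method = cfg$normalization %||% "zscore")
}

#' Run an experiment stage (or all of them)
#'
#' Stages: \code{simulate} writes the synthetic cohort (timecourse TSVs,
#' metadata CSV, ground-truth TSV) under the run directory; \code{train}
#' fits every configured model for every seed and checkpoints them;
#' \code{grid} runs a hyperparameter grid search when \code{config$grid} is
#' set; \code{embed} writes one embedding TSV per (model, seed);
#' \code{evaluate} produces the JSON evaluation report; \code{all} runs
#' simulate through evaluate.  Completed stages are skipped when re-run
#' with an identical resolved config unless \code{force = TRUE}; every run
#' directory receives a frozen copy of the resolved config and a manifest
#' of artifact checksums.
#'
#' @param config configuration list (see
#'   \code{\link{defaultExperimentConfig}}) or the path of a YAML file
#' @param stage one of simulate, train, grid, embed, evaluate, all
#' @param force rerun stages even if up to date
#' @param quiet suppress progress messages
#' @return for \code{evaluate}/\code{all}, the evaluation report list
#'   (invisibly otherwise)
#' @export
runExperiment <- function(config, stage = c("all", "simulate", "train",
                                            "grid", "embed", "evaluate"),
                          force = FALSE, quiet = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  .validateExperimentConfig(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- .cfgHash(config)
  jsonlite::write_json(config, file.path(out, "config.resolved.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- if (stage == "all")
    c("simulate", "train", "grid", "embed", "evaluate") else stage
  report <- NULL

  for (st in stages) {
    if (!force && .stageDone(out, st, hash)) {
      say("stage '%s' is up to date", st)
      if (st == "evaluate")
        report <- jsonlite::read_json(file.path(out, "report.json"))
      next
    }
    say("running stage '%s'", st)
    if (st == "simulate") {
      if (is.null(config$synthetic)) { say("no synthetic spec; skipping") }
      else {
        spec <- .syntheticSpecFromCfg(config$synthetic)
        ds <- generateDataset(spec)
        writeTimecourses(ds$records, file.path(out, "data"),
                         file.path(out, "data", "metadata.csv"))
        writeGroundTruth(ds$truth, file.path(out, "ground_truth.tsv"))
        .updateManifest(out, st, hash,
                        c(file.path(out, "data", "metadata.csv"),
                          file.path(out, "ground_truth.tsv")))
      }
    } else if (st == "train") {
      env <- .prepareWindows(config, out)
      dir.create(file.path(out, "models"), showWarnings = FALSE)
      for (mn in names(config$models)) for (sd in config$seeds) {
        cfg <- .modelConfigFromCfg(config$models[[mn]], sd)
        fit <- trainModel(env$trainW, env$valW, cfg,
                          batchSize = config$training$batch_size %||% 64L,
                          patience = config$training$patience %||% 10L)
        base <- file.path(out, "models", sprintf("%s_seed%d", mn, sd))
        saveModel(fit, paste0(base, ".json"))
        utils::write.table(fit@history, paste0(base, "_history.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        say("  trained %s seed %d", mn, sd)
      }
      .updateManifest(out, st, hash,
                      list.files(file.path(out, "models"), full.names = TRUE))
    } else if (st == "grid") {
      if (is.null(config$grid)) { say("no grid configured; skipping") }
      else {
        env <- .prepareWindows(config, out)
        configs <- lapply(config$grid, .modelConfigFromCfg, seed = 42L)
        gr <- gridSearch(env$trainW, env$valW, configs,
                         seeds = config$seeds,
                         batchSize = config$training$batch_size %||% 64L,
                         patience = config$training$patience %||% 10L)
        jsonlite::write_json(
          list(selected = gr@selected, runs = gr@runs,
               config_means = gr@configMeans),
          file.path(out, "grid_result.json"), digits = NA,
          auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
        .updateManifest(out, st, hash, file.path(out, "grid_result.json"))
      }
    } else if (st == "embed") {
      env <- .prepareWindows(config, out)
      dir.create(file.path(out, "embeddings"), showWarnings = FALSE)
      for (mn in names(config$models)) for (sd in config$seeds) {
        model <- loadModel(file.path(out, "models",
                                     sprintf("%s_seed%d.json", mn, sd)))
        tb <- embedDataset(model, env$allW, env$split, env$diagnoses)
        writeEmbeddings(tb, file.path(out, "embeddings",
                                      sprintf("%s_seed%d.tsv", mn, sd)))
      }
      .updateManifest(out, st, hash,
                      list.files(file.path(out, "embeddings"),
                                 full.names = TRUE))
    } else if (st == "evaluate") {
      report <- .evaluateExperiment(config, out)
      jsonlite::write_json(report, file.path(out, "report.json"),
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
      .updateManifest(out, st, hash, file.path(out, "report.json"))
    }
    .markDone(out, st, hash)
  }
  if (!is.null(report)) return(invisible(report))
  invisible(NULL)
}

.prepareWindows <- function(config, out) {
  records <- .loadExperimentData(config, out)
  split <- splitSubjects(records, config$split$fractions,
                         config$split$seed %||% 1L)
  spec <- windowSpec(config$window$width %||% 32L,
                     config$window$stride %||% 4L)
  allW <- makeWindows(records, spec)
  spl <- splitOf(split, allW@subjectId)
  diagnoses <- stats::setNames(
    vapply(records@records, function(r) r@diagnosis, character(1)),
    subjectIds(records))
  list(records = records, split = split, allW = allW,
       trainW = subsetWindows(allW, names(split@assignment)[
         split@assignment == "train"]),
       valW = subsetWindows(allW, names(split@assignment)[
         split@assignment == "val"]),
       diagnoses = diagnoses)
}

.readTruth <- function(path, spec) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ids <- unique(df$subject_id)
  cd <- sum(grepl("^c[0-9]+$", names(df)))
  ld <- sum(grepl("^l[0-9]+$", names(df)))
  ctx <- list(); loc <- list(); grp <- character(0)
  for (i in seq_along(ids)) {
    sub <- df[df$subject_id == ids[i], ]
    sub <- sub[order(sub$t), ]
    ctx[[i]] <- t(as.matrix(sub[, paste0("c", seq_len(cd)), drop = FALSE]))
    loc[[i]] <- t(as.matrix(sub[, paste0("l", seq_len(ld)), drop = FALSE]))
    grp[i] <- sub$group[1L]
  }
  new("SyntheticTruth", subjectId = ids, group = grp, context = ctx,
      local = loc, spec = spec)
}

.evaluateExperiment <- function(config, out) {
  env <- .prepareWindows(config, out)
  ev <- config$evaluation
  seeds <- config$seeds
  readTb <- function(mn, sd)
    readEmbeddings(file.path(out, "embeddings",
                             sprintf("%s_seed%d.tsv", mn, sd)))

  models <- list()
  for (mn in names(config$models)) {
    tbs <- lapply(seeds, function(sd) readTb(mn, sd))
    names(tbs) <- as.character(seeds)
    accs <- vapply(tbs, function(tb)
      as.numeric(classifyContext(tb, cost = ev$svm_cost %||% 1)), numeric(1))
    rel <- if (length(tbs) >= 2L) seedReliability(tbs)@meanR2 else NA_real_
    models[[mn]] <- list(
      test_accuracy_per_seed = as.list(accs),
      mean_test_accuracy = mean(accs),
      reliability_mean_r2 = rel)
  }

  wfncTb <- wfncPcaEmbeddings(env$allW, env$split, env$diagnoses,
                              dim = ev$wfnc_pca_dim %||% 2L)
  wfncAcc <- as.numeric(classifyContext(wfncTb, cost = ev$svm_cost %||% 1))

  cm <- ev$cluster_model %||% names(config$models)[1L]
  refTb <- readTb(cm, seeds[1L])
  refTb@width <- env$allW@width
  manifold <- manifoldSimilarity(refTb@embedding, wfncVectors(env$allW),
                                 maxPairs = ev$max_pairs %||% 1e6,
                                 seed = seeds[1L])

  patientTb <- refTb[refTb@info$diagnosis == "patient"]
  k <- ev$k %||% 3L
  clus <- kmeansFit(patientTb, k = k, seed = seeds[1L])
  dwell <- list(
    age = dwellStatistics(clus, env$records, "age"),
    cognitive_score = dwellStatistics(clus, env$records, "cognitive_score"))
  maps <- clusterWfncMaps(clus, env$allW)

  recovery <- NULL
  truthPath <- file.path(out, "ground_truth.tsv")
  if (!is.null(config$synthetic) && file.exists(truthPath)) {
    truth <- .readTruth(truthPath, .syntheticSpecFromCfg(config$synthetic))
    recovery <- lapply(stats::setNames(names(config$models),
                                       names(config$models)), function(mn) {
      tb <- readTb(mn, seeds[1L])
      tb@width <- env$allW@width
      contextRecoveryScore(tb, truth)
    })
  }

  list(
    settings = list(svm_cost = ev$svm_cost %||% 1, k = k,
                    cluster_model = cm, seeds = as.list(seeds)),
    models = models,
    wfnc_pca = list(dim = ev$wfnc_pca_dim %||% 2L,
                    test_accuracy = wfncAcc),
    manifold_r2 = manifold,
    clusters = list(
      sizes = as.list(as.integer(table(factor(clus@assignment,
                                              levels = seq_len(k))))),
      dwell = lapply(dwell, function(d) {
        attr(d, "excluded") <- NULL
        d
      }),
      map_norms = lapply(maps, function(m) sqrt(sum(m^2)))),
    context_recovery_r2 = recovery)
}
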