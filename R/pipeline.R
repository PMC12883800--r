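# Pipeline orchestration: a YAML run configuration drives seven stages
# (simulate, features, select, train, classify, change, evaluate), each
# idempotent given the same config + seed. Every stage writes a manifest with
# the config hash so stale upstream artifacts are refused. The thin
# command-line wrapper in inst/cli/fscchange.R maps these functions to
# subcommands with distinct exit codes.

.fscError <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Default run configuration
#'
#' @param outDir output directory for all stage artifacts.
#' @param seed master seed; stage seeds are derived from it.
#' @return Nested list of class `RunConfig` with sections `simulate`,
#'   `features`, `select`, `train` and `paths`.
#' @export
defaultRunConfig <- function(outDir = "fsc_run", seed = 1L) {
  structure(list(
    out_dir = outDir,
    seed = as.integer(seed),
    simulate = list(grid = c(220L, 220L), pixel_size = 10, n_fsc = 650L,
                    class_proportions = c(0.4387, 0.4002, 0.1397, 0.0073, 0.0141),
                    change_fraction = 0.1, noise_sd = 0.04, nodata_frac = 0),
    features = list(patch_size = 5L, texture_bands = "B8", glcm_levels = 32L,
                    vi_per_pixel = FALSE, min_area_m2 = 3000),
    select = list(threshold_spectral = 0.85, threshold_texture = 0.85,
                  nrounds = 100L, max_depth = 4L, eta = 0.1),
    train = list(model = "PSO-BPNN", train_fraction = 0.8,
                 hidden = c(50L, 50L), learning_rate = 0.01, epochs = 300L,
                 pso = list(swarm = 12L, iterations = 10L),
                 proxy_epochs = 25L, stage2 = TRUE)
  ), class = "RunConfig")
}

#' Load a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. Validates the structure and returns a `RunConfig`.
#'
#' @param path YAML file path.
#' @return A `RunConfig` list.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) .fscError("fsc_config_error",
                                    paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  merge <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  cfg <- merge(unclass(cfg), user)
  if (abs(sum(cfg$simulate$class_proportions) - 1) > 1e-9)
    .fscError("fsc_config_error", "simulate$class_proportions must sum to 1")
  if (!cfg$train$model %in% c("RF", "SVM", "BPNN", "PSO-BPNN"))
    .fscError("fsc_config_error",
              paste("unknown model kind:", cfg$train$model))
  structure(cfg, class = "RunConfig")
}

# config sections a stage's outputs depend on (cumulative along the pipeline)
.STAGE_SECTIONS <- list(
  simulate = c("seed", "simulate"),
  features = c("seed", "simulate", "features"),
  select   = c("seed", "simulate", "features", "select"),
  train    = c("seed", "simulate", "features", "select", "train"),
  classify = c("seed", "simulate", "features", "select", "train"),
  change   = c("seed", "simulate", "features", "select", "train"),
  evaluate = c("seed", "simulate", "features", "select", "train")
)

.configHash <- function(config, stage) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  sub <- unclass(config)[.STAGE_SECTIONS[[stage]]]
  jsonlite::write_json(sub, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.writeManifest <- function(config, stage, outputs) {
  man <- list(stage = stage, config_hash = .configHash(config, stage),
              seed = config$seed, timestamp = format(Sys.time(), tz = "UTC"),
              outputs = as.list(outputs),
              checksums = as.list(tools::md5sum(unlist(outputs))))
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.checkUpstream <- function(config, stage) {
  path <- file.path(config$out_dir, paste0("manifest_", stage, ".json"))
  if (!file.exists(path))
    .fscError("fsc_data_error",
              paste0("upstream stage '", stage, "' has not been run (missing ",
                     path, ")"))
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(man$config_hash, .configHash(config, stage)))
    .fscError("fsc_stale_error",
              paste0("stale upstream artifact: stage '", stage,
                     "' was produced under a different configuration; re-run it"))
  invisible(man)
}

#' Stage 1: generate the synthetic scene pair
#'
#' @param config a `RunConfig`.
#' @return Paths of the written scene files, invisibly.
#' @export
runStageSimulate <- function(config) {
  sc <- config$simulate
  cfg <- sceneConfig(gridShape = sc$grid, pixelSize = sc$pixel_size,
                     nFsc = sc$n_fsc, classProportions = sc$class_proportions,
                     changeFraction = sc$change_fraction, noiseSd = sc$noise_sd,
                     nodataFrac = sc$nodata_frac, seed = config$seed)
  pair <- generateScenePair(cfg)
  paths <- writeSceneFiles(pair, file.path(config$out_dir, "scene"))
  .writeManifest(config, "simulate", paths)
  invisible(paths)
}

#' Stage 2: feature tables per epoch
#' @param config a `RunConfig`.
#' @return Paths of the feature CSVs, invisibly.
#' @export
runStageFeatures <- function(config) {
  .checkUpstream(config, "simulate")
  sceneDir <- file.path(config$out_dir, "scene")
  fsc <- readFscLayer(file.path(sceneDir, "fsc.geojson"))
  fe <- config$features
  paths <- character()
  for (ep in c("e1", "e2")) {
    scene <- readScene(file.path(sceneDir, paste0("raster_", ep, ".tif")))
    tab <- featureTable(scene, fsc, size = fe$patch_size,
                        textureBands = fe$texture_bands,
                        glcmLevels = fe$glcm_levels,
                        viPerPixel = fe$vi_per_pixel,
                        minAreaM2 = fe$min_area_m2)
    p <- file.path(config$out_dir, paste0("features_", ep, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths[ep] <- p
  }
  .writeManifest(config, "features", paths)
  invisible(paths)
}

.readFeatureCsv <- function(path) {
  if (!file.exists(path))
    .fscError("fsc_data_error", paste("feature table not found:", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fsc_id", "epoch", "area_m2", "in_distribution", "valid", "label")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    .fscError("fsc_data_error",
              paste0("feature table ", path, " lacks column(s): ",
                     paste(miss, collapse = ", ")))
  tab
}

.featureGroups <- function(featNames) {
  stats::setNames(ifelse(grepl("^GLCM_", featNames), "texture", "spectral"),
                  featNames)
}

#' Stage 3: grouped gain ranking and cumulative selection
#' @param config a `RunConfig`.
#' @return The selected feature names, invisibly.
#' @export
runStageSelect <- function(config) {
  .checkUpstream(config, "features")
  tab <- .readFeatureCsv(file.path(config$out_dir, "features_e1.csv"))
  use <- tab$valid & tab$in_distribution & !is.na(tab$label)
  feats <- featureColumns(tab)
  se <- config$select
  ranking <- rankByGain(tab[use, feats], tab$label[use],
                        groups = .featureGroups(feats),
                        nrounds = se$nrounds, maxDepth = se$max_depth,
                        eta = se$eta, seed = config$seed)
  selected <- c(
    selectByCumulative(ranking$spectral, se$threshold_spectral),
    selectByCumulative(ranking$texture, se$threshold_texture))
  rkAll <- do.call(rbind, lapply(names(ranking), function(g)
    cbind(group = g, rank = seq_len(nrow(ranking[[g]])), ranking[[g]])))
  pr <- file.path(config$out_dir, "ranking.csv")
  ps <- file.path(config$out_dir, "selection.json")
  utils::write.csv(rkAll, pr, row.names = FALSE)
  jsonlite::write_json(list(selected = selected), ps, auto_unbox = FALSE)
  .writeManifest(config, "select", c(ranking = pr, selection = ps))
  invisible(selected)
}

#' Stage 4: train the configured classifier
#' @param config a `RunConfig`.
#' @return The fitted model, invisibly (also saved under the output dir).
#' @export
runStageTrain <- function(config) {
  .checkUpstream(config, "select")
  tab <- .readFeatureCsv(file.path(config$out_dir, "features_e1.csv"))
  selected <- unlist(jsonlite::read_json(
    file.path(config$out_dir, "selection.json"), simplifyVector = TRUE))
  use <- which(tab$valid & !is.na(tab$label))
  tab <- tab[use, , drop = FALSE]
  sp <- trainTestSplit(tab$label, tab$in_distribution,
                       trainFraction = config$train$train_fraction,
                       seed = config$seed)
  X <- tab[sp$train, selected, drop = FALSE]
  y <- tab$label[sp$train]
  tr <- config$train
  model <- switch(tr$model,
    "RF" = trainBaseline("RF", X, y, seed = config$seed),
    "SVM" = trainBaseline("SVM", X, y, seed = config$seed),
    "BPNN" = trainBpnn(X, y, hidden = tr$hidden,
                       learningRate = tr$learning_rate, epochs = tr$epochs,
                       seed = config$seed),
    "PSO-BPNN" = trainPsoBpnn(
      X, y,
      psoStage1 = psoConfig(swarmSize = tr$pso$swarm,
                            iterations = tr$pso$iterations,
                            seed = config$seed),
      psoStage2 = psoConfig(swarmSize = tr$pso$swarm,
                            iterations = tr$pso$iterations,
                            seed = config$seed + 1L),
      proxyEpochs = tr$proxy_epochs, finalEpochs = tr$epochs,
      stage2 = tr$stage2, seed = config$seed))
  pm <- file.path(config$out_dir, "model.rds")
  saveRDS(model, pm)
  paths <- c(model = pm)
  if (is(model, "BPNNClassifier")) {
    pl <- file.path(config$out_dir, "loss_curve.csv")
    utils::write.csv(data.frame(epoch = seq_along(model@lossTrace),
                                loss = model@lossTrace), pl, row.names = FALSE)
    paths["loss_curve"] <- pl
  }
  ph <- file.path(config$out_dir, "holdout.json")
  jsonlite::write_json(list(train_ids = tab$fsc_id[sp$train],
                            test_ids = tab$fsc_id[sp$test]), ph)
  paths["holdout"] <- ph
  .writeManifest(config, "train", paths)
  invisible(model)
}

#' Stage 5: classify every sub-compartment in both epochs
#' @param config a `RunConfig`.
#' @return Paths of the per-epoch label tables, invisibly.
#' @export
runStageClassify <- function(config) {
  .checkUpstream(config, "train")
  model <- readRDS(file.path(config$out_dir, "model.rds"))
  paths <- character()
  for (ep in c("e1", "e2")) {
    tab <- .readFeatureCsv(file.path(config$out_dir,
                                     paste0("features_", ep, ".csv")))
    out <- data.frame(fsc_id = tab$fsc_id, epoch = ep,
                      in_distribution = tab$in_distribution,
                      label = NA_character_, max_prob = NA_real_,
                      stringsAsFactors = FALSE)
    ok <- which(tab$valid)
    if (length(ok)) {
      pred <- predictClasses(model, tab[ok, model@featureNames, drop = FALSE])
      out$label[ok] <- pred$labels
      out$max_prob[ok] <- apply(pred$probabilities, 1, max)
    }
    p <- file.path(config$out_dir, paste0("labels_", ep, ".csv"))
    utils::write.csv(out, p, row.names = FALSE)
    paths[ep] <- p
  }
  .writeManifest(config, "classify", paths)
  invisible(paths)
}

#' Stage 6: change detection, transition matrix and rates
#' @param config a `RunConfig`.
#' @return The [TransitionMatrix-class], invisibly.
#' @export
runStageChange <- function(config) {
  .checkUpstream(config, "classify")
  l1 <- utils::read.csv(file.path(config$out_dir, "labels_e1.csv"),
                        stringsAsFactors = FALSE)
  l2 <- utils::read.csv(file.path(config$out_dir, "labels_e2.csv"),
                        stringsAsFactors = FALSE)
  rec <- compareEpochs(l1, l2)
  tm <- transitionMatrix(rec)
  fsc <- readFscLayer(file.path(config$out_dir, "scene", "fsc.geojson"))
  rec$changed[is.na(rec$changed)] <- FALSE
  pc <- file.path(config$out_dir, "changes.csv")
  pt <- file.path(config$out_dir, "transitions.csv")
  pg <- file.path(config$out_dir, "change_layer.geojson")
  prt <- file.path(config$out_dir, "rates.csv")
  utils::write.csv(rec, pc, row.names = FALSE)
  utils::write.csv(as.data.frame(transitionCounts(tm)), pt)
  exportChangeLayer(rec, fsc, pg)
  cls <- tm@classOrder
  rates <- do.call(rbind, lapply(cls, function(a) {
    rs <- sum(transitionCounts(tm)[a, ])
    if (rs == 0) return(NULL)
    data.frame(from_class = a, to_class = cls,
               rate_pct = vapply(cls, function(b) conversionRate(tm, a, b), 0))
  }))
  utils::write.csv(rates, prt, row.names = FALSE)
  .writeManifest(config, "change",
                 c(changes = pc, transitions = pt, layer = pg, rates = prt))
  invisible(tm)
}

#' Stage 7: accuracy metrics, detection rate and spatial clustering
#'
#' Evaluates classification accuracy on the holdout samples, the change
#' detection rate against the generator's injected changes, and the
#' nearest-neighbor index of the changed-unit centroids.
#'
#' @param config a `RunConfig`.
#' @return The metric report list, invisibly (also written as JSON).
#' @export
runStageEvaluate <- function(config) {
  .checkUpstream(config, "change")
  truth <- utils::read.csv(file.path(config$out_dir, "scene", "labels.csv"),
                           stringsAsFactors = FALSE)
  holdout <- jsonlite::read_json(file.path(config$out_dir, "holdout.json"),
                                 simplifyVector = TRUE)
  report <- list()
  for (ep in c("e1", "e2")) {
    tabf <- .readFeatureCsv(file.path(config$out_dir,
                                      paste0("features_", ep, ".csv")))
    pred <- utils::read.csv(file.path(config$out_dir,
                                      paste0("labels_", ep, ".csv")),
                            stringsAsFactors = FALSE)
    idx <- if (ep == "e1")
      which(tabf$valid & tabf$fsc_id %in% holdout$test_ids)
    else which(tabf$valid)
    ref <- truth[[paste0("class_", ep)]][match(pred$fsc_id[idx], truth$fsc_id)]
    got <- pred$label[idx]
    ok <- !is.na(got)
    cm <- confusionCounts(ref[ok], got[ok])
    m <- classificationMetrics(cm)
    report[[paste0("classification_", ep)]] <-
      list(OA = m$OA, precision = m$precision, recall = m$recall,
           F1 = m$F1, kappa = m$kappa, n = sum(ok))
  }
  rec <- utils::read.csv(file.path(config$out_dir, "changes.csv"),
                         stringsAsFactors = FALSE)
  refChanged <- truth$fsc_id[truth$class_e1 != truth$class_e2]
  detected <- rec$fsc_id[rec$changed]
  if (length(refChanged)) {
    dr <- detectionRate(refChanged, detected)
    report$change_detection <- dr
  }
  fsc <- readFscLayer(file.path(config$out_dir, "scene", "fsc.geojson"))
  chIdx <- match(detected, fscIds(fsc))
  chIdx <- chIdx[!is.na(chIdx)]
  if (length(chIdx) >= 2L) {
    pts <- t(vapply(fscGeometry(fsc)[chIdx], polygonCentroid, c(0, 0)))
    gs <- config$simulate$grid
    report$nni <- nearestNeighborIndex(
      pts, gs[1] * gs[2] * config$simulate$pixel_size^2)
  }
  pj <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(report, pj, auto_unbox = TRUE, digits = NA)
  .writeManifest(config, "evaluate", c(metrics = pj))
  invisible(report)
}

#' Run the full pipeline
#'
#' Executes all seven stages in order under one configuration.
#'
#' @param config a `RunConfig` (or path to a YAML file).
#' @return The evaluation report, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- loadRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  runStageSimulate(config)
  runStageFeatures(config)
  runStageSelect(config)
  runStageTrain(config)
  runStageClassify(config)
  runStageChange(config)
  invisible(runStageEvaluate(config))
}
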