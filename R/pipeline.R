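.defaultRunConfig <- function() {
  list(
    seed = 1L,
    outDir = "phosfusion_run",
    logLevel = "info",
    synth = list(nKinases = 12L, sitesPerKinase = 5L,
                 nSubstrateSites = 100L, nSamples = 40L, sparsity = 0.3,
                 criticalFrac = 0.3, beta = 2, noiseSD = 0.1,
                 seqDim = 256L, delta = 4),
    preprocess = list(minDetectFrac = 0.1, eps = 1e-4),
    embedder = list(dModel = 32L, nHeads = 4L, encLayers = 1L,
                    decLayers = 1L, dropout = 0, anchors = 20L,
                    gatingHidden = 8L, maskFraction = 0.15,
                    batchSize = 16L, lr = 1e-3, maxEpochs = 8L,
                    patience = 5L),
    classifier = list(rounds = 2L, ratio = 3L, wOut = 4, lr = 1e-2,
                      maxEpochs = 60L, patience = 5L, folds = 3L,
                      topFrac = 0.05),
    inputs = list(matrix = NULL, seqEmbeddings = NULL, labels = NULL)
  )
}

.mergeConfig <- function(defaults, user, path = character(0)) {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown config key: ", paste(c(path, k), collapse = "."))
    if (is.list(defaults[[k]]) && !is.null(user[[k]])) {
      if (!is.list(user[[k]]))
        stop("config key ", paste(c(path, k), collapse = "."),
             " must be a block")
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration, fills defaults, and rejects unknown keys by
#' name. All randomness in a run flows from the single `seed` via derived
#' per-stage substreams.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list of class `runConfig`.
#' @seealso [writeRunConfig()] for the serialize half of the round trip.
#' @export
loadRunConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- .mergeConfig(.defaultRunConfig(), user)
  structure(cfg, class = "runConfig")
}

#' @rdname loadRunConfig
#' @param cfg a `runConfig`.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 7919L + stage * 131L
}

.cacheValid <- function(file, sidecar, cfgJSON) {
  file.exists(file) && file.exists(sidecar) &&
    identical(readLines(sidecar, warn = FALSE),
              strsplit(cfgJSON, "\n")[[1]])
}

.writeSidecar <- function(sidecar, cfgJSON) {
  writeLines(cfgJSON, sidecar)
}

#' Run the end-to-end synthetic pipeline
#'
#' Chains the stages: synthetic data generation, preprocessing, embedder
#' pretraining, site-embedding extraction, bimodal classifier training,
#' and prediction. Each stage writes versioned outputs into `outDir`
#' together with a sidecar recording the configuration it ran under; a
#' rerun with an unchanged configuration reuses the cached outputs.
#'
#' @param cfg a [loadRunConfig()] object, a YAML path, or `NULL` for
#'   defaults.
#' @param outDir output directory (overrides `cfg$outDir`).
#' @param overwrite force recomputation of every stage.
#' @param verbose log stage progress.
#' @return (invisibly) list with the run artifacts: the normalized matrix,
#'   embedder, embeddings, fusion model, predictions, high-confidence
#'   sites, and the paths written.
#' @export
runPipeline <- function(cfg = NULL, outDir = NULL, overwrite = FALSE,
                        verbose = FALSE) {
  if (is.null(cfg) || is.character(cfg)) cfg <- loadRunConfig(cfg)
  if (!is.null(outDir)) cfg$outDir <- outDir
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[phosfusion] ", ...)
  writeRunConfig(cfg, file.path(cfg$outDir, "config_resolved.yaml"))
  js <- function(x) jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)

  # -- stage 1: data ----------------------------------------------------
  synthJSON <- paste0(js(cfg$synth), js(cfg$seed))
  synthRDS <- file.path(cfg$outDir, "synth.rds")
  synthSide <- file.path(cfg$outDir, "synth.config.json")
  if (!overwrite && .cacheValid(synthRDS, synthSide, synthJSON)) {
    say("stage synth: cached")
    synth <- readRDS(synthRDS)
  } else {
    say("stage synth: generating")
    synth <- do.call(simPhosMatrix, c(cfg$synth[c(
      "nKinases", "sitesPerKinase", "nSubstrateSites", "nSamples",
      "sparsity", "criticalFrac", "beta", "noiseSD")],
      list(seed = .stageSeed(cfg$seed, 1L))))
    saveRDS(synth, synthRDS)
    .writeSidecar(synthSide, synthJSON)
  }
  nm <- synth$matrix
  kinaseSites <- unlist(synth$kinaseSiteMap, use.names = FALSE)
  normPath <- file.path(cfg$outDir, "normalized_matrix.tsv")
  writeNormalizedPhosMatrix(nm, normPath)

  # -- stage 2: embedder pretraining -----------------------------------
  embJSON <- paste0(js(cfg$embedder), synthJSON)
  embRDS <- file.path(cfg$outDir, "embedder.rds")
  embSide <- file.path(cfg$outDir, "embedder.config.json")
  if (!overwrite && .cacheValid(embRDS, embSide, embJSON)) {
    say("stage pretrain: cached")
    embedder <- readRDS(embRDS)
  } else {
    say("stage pretrain: training embedder")
    mc <- msEmbedderConfig(dModel = cfg$embedder$dModel,
                           nHeads = cfg$embedder$nHeads,
                           encLayers = cfg$embedder$encLayers,
                           decLayers = cfg$embedder$decLayers,
                           dropout = cfg$embedder$dropout,
                           anchors = cfg$embedder$anchors,
                           gatingHidden = cfg$embedder$gatingHidden)
    pc <- msPretrainConfig(maskFraction = cfg$embedder$maskFraction,
                           batchSize = cfg$embedder$batchSize,
                           lr = cfg$embedder$lr,
                           maxEpochs = cfg$embedder$maxEpochs,
                           patience = cfg$embedder$patience,
                           seed = .stageSeed(cfg$seed, 2L))
    embedder <- pretrainEmbedder(nm, mc, pc)
    saveRDS(embedder, embRDS)
    .writeSidecar(embSide, embJSON)
  }

  # -- stage 3: site embeddings ----------------------------------------
  say("stage embed: extracting site embeddings")
  msEmb <- extractSiteEmbeddings(embedder, nm, kinaseSites)
  embPath <- file.path(cfg$outDir, "site_embeddings.tsv")
  utils::write.table(
    data.frame(site = rownames(msEmb), msEmb, check.names = FALSE),
    embPath, sep = "\t", quote = FALSE, row.names = FALSE)

  # -- stage 4: surrogate sequence embeddings + labels -----------------
  labels <- setNames(as.integer(kinaseSites %in% synth$criticalSites),
                     kinaseSites)
  seqEmb <- simSiteEmbeddings(kinaseSites, labels,
                              dim = cfg$synth$seqDim,
                              delta = cfg$synth$delta,
                              seed = .stageSeed(cfg$seed, 3L))

  # -- stage 5: fusion classifier --------------------------------------
  clsJSON <- paste0(js(cfg$classifier), embJSON, js(cfg$synth$seqDim),
                    js(cfg$synth$delta))
  clsRDS <- file.path(cfg$outDir, "fusion_model.rds")
  clsSide <- file.path(cfg$outDir, "classifier.config.json")
  if (!overwrite && .cacheValid(clsRDS, clsSide, clsJSON)) {
    say("stage train: cached")
    model <- readRDS(clsRDS)
  } else {
    say("stage train: fitting fusion classifier")
    proto <- fusionProtocol(rounds = cfg$classifier$rounds,
                            ratio = cfg$classifier$ratio,
                            wOut = cfg$classifier$wOut,
                            lr = cfg$classifier$lr,
                            maxEpochs = cfg$classifier$maxEpochs,
                            patience = cfg$classifier$patience,
                            folds = cfg$classifier$folds,
                            seed = .stageSeed(cfg$seed, 4L))
    model <- trainFusionClassifier(seqEmb, msEmb, labels, protocol = proto)
    saveRDS(model, clsRDS)
    .writeSidecar(clsSide, clsJSON)
  }

  # -- stage 6: prediction ---------------------------------------------
  say("stage predict: scoring sites")
  scores <- predictFusion(model, seqEmb, msEmb)
  hc <- selectHighConfidence(scores, cfg$classifier$topFrac)
  pred <- data.frame(site = names(scores), score = as.numeric(scores),
                     rank = rank(-scores, ties.method = "first"),
                     highConfidence = names(scores) %in% hc,
                     critical = labels[names(scores)] == 1L,
                     row.names = NULL)
  pred <- pred[order(pred$rank), ]
  predPath <- file.path(cfg$outDir, "predictions.tsv")
  utils::write.table(pred, predPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  metrics <- c(as.list(model$metricMean),
               list(nSites = length(scores), nHighConfidence = length(hc)))
  jsonlite::write_json(metrics, file.path(cfg$outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(config = cfg, matrix = nm, embedder = embedder,
                 msEmbeddings = msEmb, seqEmbeddings = seqEmb,
                 model = model, predictions = pred,
                 highConfidence = hc, labels = labels,
                 paths = list(norm = normPath, embeddings = embPath,
                              predictions = predPath)))
}
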