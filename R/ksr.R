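#' Pool site embeddings into a kinase embedding
#'
#' Componentwise maximum over the embeddings of the phosphosites on a
#' kinase; permutation-invariant and idempotent under duplication.
#'
#' @param siteEmbeddings numeric matrix (sites x d) or list of equal-length
#'   vectors.
#' @return numeric vector of length d.
#' @export
poolKinaseEmbedding <- function(siteEmbeddings) {
  if (is.list(siteEmbeddings))
    siteEmbeddings <- do.call(rbind, siteEmbeddings)
  siteEmbeddings <- as.matrix(siteEmbeddings)
  if (!nrow(siteEmbeddings)) stop("kinase unobserved: no site embeddings")
  apply(siteEmbeddings, 2, max)
}

#' Construct curated negative kinase-substrate pairs
#'
#' Draws uniform random (kinase, substrate-site) pairs excluding known
#' positives, pairs whose external prediction score exceeds 0.7 (strict
#' inequality: a score of exactly 0.7 stays eligible), and self-pairs
#' (substrate on the kinase itself). Duplicate (kinase, site) draws are
#' forbidden.
#'
#' @param kinases character vector of kinase accessions.
#' @param substrateSites character vector of substrate site IDs.
#' @param knownPairs data.frame with columns `kinase`, `site` (positives).
#' @param predictedScores optional data.frame with columns `kinase`,
#'   `site`, `score` (external predictor output).
#' @param ratio negatives per positive (1 or 10; any positive integer
#'   accepted).
#' @param seed RNG seed.
#' @return data.frame with columns `kinase`, `site`, `label`
#'   (`"negative"`).
#' @export
buildNegativePairs <- function(kinases, substrateSites, knownPairs,
                               predictedScores = NULL, ratio = 1L,
                               seed = 1L) {
  key <- function(k, s) paste(k, s, sep = "\r")
  grid <- expand.grid(kinase = kinases, site = substrateSites,
                      stringsAsFactors = FALSE)
  siteAcc <- parseSiteID(grid$site)$accession
  bad <- key(knownPairs$kinase, knownPairs$site)
  if (!is.null(predictedScores)) {
    hi <- predictedScores$score > 0.7
    bad <- c(bad, key(predictedScores$kinase[hi], predictedScores$site[hi]))
  }
  eligible <- grid[!(key(grid$kinase, grid$site) %in% bad) &
                     grid$kinase != siteAcc, , drop = FALSE]
  nNeed <- ratio * nrow(knownPairs)
  if (nrow(eligible) < nNeed)
    stop("insufficient eligible pairs: need ", nNeed, ", have ",
         nrow(eligible))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- eligible[sample(nrow(eligible), nNeed), , drop = FALSE]
  data.frame(kinase = pick$kinase, site = pick$site, label = "negative",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Train and evaluate the kinase-substrate relation classifier
#'
#' Concatenates the max-pooled kinase embedding with the substrate-site
#' embedding and feeds the pair into a two-linear-layer MLP (LayerNorm,
#' ReLU and dropout between the layers). Pairs are split 7:2:1 into
#' train/validation/test; optimization early-stops when validation AUROC no
#' longer improves and the best weights are restored; AUROC/AUPRC/F1/MCC
#' are reported on the test portion.
#'
#' @param pairs data.frame with columns `kinase`, `site`, `label`
#'   (`"positive"`/`"negative"` or 1/0).
#' @param siteEmbeddings matrix (sites x d), rownames = site IDs; must cover
#'   all substrate sites and the kinases' sites.
#' @param kinaseSiteMap named list: kinase accession -> site IDs on that
#'   kinase present in `siteEmbeddings`.
#' @param hidden hidden layer width (default 64).
#' @param lr,maxEpochs,patience,dropout optimizer settings.
#' @param seed RNG seed (split + init).
#' @return list of class `ksrModel` with `params`, `metrics` (test set),
#'   `predict` inputs and the splits.
#' @export
trainKSRClassifier <- function(pairs, siteEmbeddings, kinaseSiteMap,
                               hidden = 64L, lr = 1e-3, maxEpochs = 200L,
                               patience = 10L, dropout = 0, seed = 1L) {
  lab <- pairs$label
  y <- if (is.character(lab) || is.factor(lab))
    as.integer(as.character(lab) == "positive") else as.integer(lab)
  if (length(unique(y)) < 2L) stop("both labels required")
  kinEmb <- t(vapply(unique(pairs$kinase), function(k) {
    ss <- intersect(kinaseSiteMap[[k]], rownames(siteEmbeddings))
    if (!length(ss)) stop("kinase unobserved: ", k)
    poolKinaseEmbedding(siteEmbeddings[ss, , drop = FALSE])
  }, numeric(ncol(siteEmbeddings))))
  miss <- setdiff(pairs$site, rownames(siteEmbeddings))
  if (length(miss))
    stop("substrate site(s) without embedding: ",
         paste(utils::head(miss, 3), collapse = ", "))
  X <- cbind(kinEmb[pairs$kinase, , drop = FALSE],
             siteEmbeddings[pairs$site, , drop = FALSE])
  n <- nrow(X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  testIdx <- .stratSplit(y, 0.1, seed + 1L)
  rest <- setdiff(seq_len(n), testIdx)
  valIdx <- rest[.stratSplit(y[rest], 2 / 9, seed + 2L)]
  trIdx <- setdiff(rest, valIdx)
  params <- list(mlp = .mlpInit(c(ncol(X), hidden, 1L)))
  state <- .adamInit(params)
  best <- list(params = params, auroc = -Inf)
  wait <- 0L
  for (epoch in seq_len(maxEpochs)) {
    fw <- .mlpFwd(params$mlp, X[trIdx, , drop = FALSE], dropout,
                  training = TRUE)
    logits <- as.numeric(fw$out)
    dlogit <- matrix((.sigmoid(logits) - y[trIdx]) / length(trIdx),
                     ncol = 1L)
    bw <- .mlpBwd(params$mlp, fw$caches, dlogit)
    st <- .adamStep(params, list(mlp = bw$grads), state, lr = lr)
    params <- st$params; state <- st$state
    vout <- as.numeric(.mlpFwd(params$mlp, X[valIdx, , drop = FALSE])$out)
    auroc <- computeMetrics(y[valIdx], vout)[["AUROC"]]
    if (auroc > best$auroc + 1e-9) {
      best <- list(params = params, auroc = auroc)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  params <- best$params
  testProb <- .sigmoid(as.numeric(
    .mlpFwd(params$mlp, X[testIdx, , drop = FALSE])$out))
  structure(list(params = params,
                 metrics = computeMetrics(y[testIdx], testProb),
                 valAUROC = best$auroc,
                 split = list(train = trIdx, val = valIdx, test = testIdx),
                 dim = ncol(X)),
            class = "ksrModel")
}

#' @export
print.ksrModel <- function(x, ...) {
  cat("ksrModel: input dim", x$dim, "\n")
  print(round(x$metrics, 3))
  invisible(x)
}
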