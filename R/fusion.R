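#' Fuse a sequence embedding with an MS embedding
#'
#' Sites carrying both modalities get the plain concatenation
#' (dimension `D = seqDim + msDim`); sites with only a sequence embedding are
#' expanded to the same dimension by a learned linear alignment layer, so
#' every site enters the classifier with an equal-length vector.
#'
#' @param seqEmb numeric vector (sequence-model embedding, 1024-dim by
#'   convention).
#' @param msEmb numeric vector (MS-embedder embedding, `d`-dim) or `NULL`.
#' @param alignLayer list with `W` (seqDim x D) and `b` (length D), e.g. the
#'   trained alignment layer of a fusion classifier; required when `msEmb`
#'   is `NULL`.
#' @param msDim MS embedding dimension (needed to size the output when
#'   `msEmb` is `NULL` and no `alignLayer` is given -- then a zero-filled
#'   alignment is an error).
#' @return numeric vector of length `seqDim + msDim` with attribute
#'   `"provenance"` equal to `"both"` or `"sequence-only"`.
#' @export
fuseEmbeddings <- function(seqEmb, msEmb = NULL, alignLayer = NULL,
                           msDim = NULL) {
  seqEmb <- as.numeric(seqEmb)
  if (!is.null(msEmb)) {
    out <- c(seqEmb, as.numeric(msEmb))
    return(structure(out, provenance = "both"))
  }
  if (is.null(alignLayer)) stop("sequence-only fusion needs an alignLayer")
  if (nrow(alignLayer$W) != length(seqEmb))
    stop("alignLayer expects ", nrow(alignLayer$W), "-dim input, got ",
         length(seqEmb))
  out <- as.numeric(seqEmb %*% alignLayer$W + alignLayer$b)
  structure(out, provenance = "sequence-only")
}

#' Loss weights by activation-loop membership
#'
#' Out-of-A-loop sites get weight `wOut` (>= 1); in-loop sites keep weight
#' 1. Up-weighting out-of-loop sites counteracts the classifier's bias
#' toward the conserved A-loop.
#'
#' @param inALoop logical vector.
#' @param wOut out-of-loop weight, typically a power of two in 1..16
#'   (default 4).
#' @return numeric weight vector.
#' @export
assignLossWeights <- function(inALoop, wOut = 4) {
  stopifnot(wOut >= 1)
  ifelse(inALoop, 1, wOut)
}

#' Weighted binary cross-entropy on logits
#'
#' `-(1/N) * sum_i w_i * (y_i log sigma(x_i) + (1-y_i) log(1-sigma(x_i)))`,
#' computed in a numerically stable form.
#'
#' @param logits,labels,weights equal-length numeric vectors; labels in
#'   \{0,1\}; weights >= 0 (default all 1).
#' @return scalar loss (natural log).
#' @export
weightedBCE <- function(logits, labels, weights = rep(1, length(labels))) {
  stopifnot(length(logits) == length(labels),
            length(weights) == length(labels), all(weights >= 0))
  if (any(!is.finite(logits))) stop("non-finite logits")
  # stable: max(x,0) - x*y + log(1 + exp(-|x|))
  per <- pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
  mean(weights * per)
}

#' Classifier evaluation metrics
#'
#' AUROC as the tie-corrected concordance probability (Mann-Whitney), AUPRC
#' by step-wise integration of the precision-recall curve over distinct
#' score thresholds, F1 and Matthews correlation at a fixed probability
#' threshold.
#'
#' @param labels binary vector; both classes must be present.
#' @param scores numeric scores (higher = more positive).
#' @param threshold classification threshold for F1/MCC (default 0.5).
#' @return named numeric vector `c(AUROC, AUPRC, F1, MCC)`.
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC/AUPRC need both classes")
  r <- rank(scores)
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  ys <- labels[ord]; ss <- scores[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)   # end of each tie block
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp); rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1); TN <- sum(pred == 0 & labels == 0)
  f1 <- if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  c(AUROC = auroc, AUPRC = auprc, F1 = f1, MCC = mcc)
}

#' Disjoint negative under-sampling across training rounds
#'
#' Positives are reused every round; negatives are drawn without
#' replacement from a shuffled pool so the rounds' negative sets are
#' pairwise disjoint. When the pool is too small, later rounds take the
#' remainder (possibly empty) with a warning.
#'
#' @param positives,negativePool identifier vectors.
#' @param ratio negatives per positive (default 10).
#' @param rounds number of rounds (default 3).
#' @param seed RNG seed for the shuffle.
#' @return list of length `rounds`; each element a list with `positives`
#'   and `negatives`.
#' @export
undersampleRounds <- function(positives, negativePool, ratio = 10L,
                              rounds = 3L, seed = 1L) {
  if (!length(positives)) stop("no positives")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(negativePool)
  need <- ratio * length(positives)
  out <- vector("list", rounds)
  used <- 0L
  for (r in seq_len(rounds)) {
    take <- perm[seq_len(min(need, max(0L, length(perm) - used))) + used]
    take <- take[!is.na(take)]
    if (length(take) < need)
      warning("round ", r, ": only ", length(take), " of ", need,
              " negatives available")
    out[[r]] <- list(positives = positives, negatives = take)
    used <- used + length(take)
  }
  out
}

#' Top-fraction high-confidence site selection
#'
#' Returns the `ceil(frac * n)` highest-scoring sites; score ties at the
#' selection boundary are broken by site-ID (lexicographic) order for
#' determinism.
#'
#' @param scores named numeric vector (names = site IDs).
#' @param frac fraction to select, in (0, 1\] (default 0.05).
#' @return character vector of selected site IDs, highest score first.
#' @export
selectHighConfidence <- function(scores, frac = 0.05) {
  stopifnot(frac > 0, frac <= 1)
  if (!length(scores)) return(character(0))
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  k <- ceiling(frac * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(k)]
}

# ---- fusion classifier ------------------------------------------------

.fusionWidths <- function(D) c(D, D %/% 2L, D %/% 4L, D %/% 8L, 1L)

.fusionInit <- function(seqDim, msDim, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- seqDim + msDim
  p <- list(mlp = .mlpInit(.fusionWidths(D)))
  if (msDim > 0L) p$align <- .linearInit(seqDim, D)
  p
}

# Build the classifier input matrix; seq-only rows go through align.
.fusionInput <- function(params, seqEmb, msEmb, hasMS) {
  n <- nrow(seqEmb)
  if (is.null(msEmb)) return(list(I = seqEmb, hasMS = rep(TRUE, n)))
  D <- ncol(seqEmb) + ncol(msEmb)
  I <- matrix(0, n, D)
  if (any(hasMS))
    I[hasMS, ] <- cbind(seqEmb[hasMS, , drop = FALSE],
                        msEmb[hasMS, , drop = FALSE])
  if (any(!hasMS))
    I[!hasMS, ] <- .linearFwd(params$align, seqEmb[!hasMS, , drop = FALSE])
  list(I = I, hasMS = hasMS)
}

.fusionTrainOne <- function(params, seqEmb, msEmb, hasMS, labels, weights,
                            valIdx, lr, maxEpochs, patience, dropout,
                            seedEpoch) {
  n <- nrow(seqEmb)
  trIdx <- setdiff(seq_len(n), valIdx)
  state <- .adamInit(params)
  best <- list(params = params, auroc = -Inf)
  wait <- 0L
  for (epoch in seq_len(maxEpochs)) {
    fi <- .fusionInput(params, seqEmb[trIdx, , drop = FALSE],
                       if (is.null(msEmb)) NULL else
                         msEmb[trIdx, , drop = FALSE], hasMS[trIdx])
    fw <- .mlpFwd(params$mlp, fi$I, dropout, training = TRUE)
    logits <- as.numeric(fw$out)
    y <- labels[trIdx]; w <- weights[trIdx]
    dlogit <- matrix(w * (.sigmoid(logits) - y) / length(y), ncol = 1L)
    bw <- .mlpBwd(params$mlp, fw$caches, dlogit)
    grads <- list(mlp = bw$grads)
    if (!is.null(params$align)) {
      grads$align <- list(W = params$align$W * 0, b = params$align$b * 0)
      seqOnly <- which(!hasMS[trIdx])
      if (length(seqOnly)) {
        ba <- .linearBwd(params$align,
                         seqEmb[trIdx[seqOnly], , drop = FALSE],
                         bw$dX[seqOnly, , drop = FALSE])
        grads$align <- ba$grads
      }
    }
    st <- .adamStep(params, grads, state, lr = lr)
    params <- st$params; state <- st$state
    # validation AUROC
    vi <- .fusionInput(params, seqEmb[valIdx, , drop = FALSE],
                       if (is.null(msEmb)) NULL else
                         msEmb[valIdx, , drop = FALSE], hasMS[valIdx])
    vout <- as.numeric(.mlpFwd(params$mlp, vi$I)$out)
    auroc <- if (length(unique(labels[valIdx])) < 2L) NA_real_ else
      computeMetrics(labels[valIdx], vout)[["AUROC"]]
    if (!is.na(auroc) && auroc > best$auroc + 1e-9) {
      best <- list(params = params, auroc = auroc)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best$params
}

.fusionPredict <- function(params, seqEmb, msEmb, hasMS) {
  fi <- .fusionInput(params, seqEmb, msEmb, hasMS)
  .sigmoid(as.numeric(.mlpFwd(params$mlp, fi$I)$out))
}

.stratSplit <- function(labels, frac, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  test <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(frac * length(idx))))
  }))
  sort(test)
}

.stratFolds <- function(labels, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Training protocol for the fusion classifier
#'
#' @param rounds under-sampling rounds (default 3).
#' @param ratio negatives per positive per round (default 10).
#' @param testFrac held-out test fraction per round (default 0.2, an 8:2
#'   split).
#' @param folds cross-validation folds on the training portion (default 5).
#' @param wOut loss weight for out-of-A-loop sites (default 4, i.e. 2^2).
#' @param lr,maxEpochs,patience,dropout optimizer settings (early stopping
#'   monitors fold-validation AUROC).
#' @param threshold probability threshold for F1/MCC.
#' @param seed master seed; per-round seeds are derived from it.
#' @return list of class `fusionProtocol`.
#' @export
fusionProtocol <- function(rounds = 3L, ratio = 10L, testFrac = 0.2,
                           folds = 5L, wOut = 4, lr = 1e-2,
                           maxEpochs = 150L, patience = 10L, dropout = 0,
                           threshold = 0.5, seed = 1L) {
  structure(list(rounds = as.integer(rounds), ratio = as.integer(ratio),
                 testFrac = testFrac, folds = as.integer(folds),
                 wOut = wOut, lr = lr, maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), dropout = dropout,
                 threshold = threshold, seed = as.integer(seed)),
            class = "fusionProtocol")
}

#' Train the bimodal fusion classifier
#'
#' Implements the full protocol: per round, all positives are paired with a
#' fresh disjoint negative under-sample (`ratio`:1), the round data are
#' split stratified into train and test (8:2), `folds`-fold cross-validation
#' models are trained on the training portion with early stopping on
#' fold-validation AUROC, and the fold ensemble (mean probability) is
#' evaluated on the round's test portion. The alignment layer for
#' sequence-only sites is trained jointly with the classifier.
#'
#' @param seqEmb numeric matrix (sites x seqDim), rownames = site IDs.
#' @param msEmb numeric matrix (sites x msDim) or `NULL` for single-modality
#'   training; rows of sites lacking an MS embedding may be `NA` (they take
#'   the alignment path).
#' @param labels named binary vector over the union of sites.
#' @param inALoop named logical vector (default: none in loop, all weights
#'   `wOut`... i.e. effectively unweighted when `wOut = 1`).
#' @param protocol a [fusionProtocol()].
#' @return object of class `fusionModel`: per-round fold models and test
#'   metrics, aggregate mean/sd metrics, the best round, dimensions.
#' @export
trainFusionClassifier <- function(seqEmb, msEmb = NULL, labels,
                                  inALoop = NULL,
                                  protocol = fusionProtocol()) {
  seqEmb <- as.matrix(seqEmb)
  sitesAll <- rownames(seqEmb)
  if (is.null(sitesAll)) stop("seqEmb needs rownames (site IDs)")
  labels <- labels[sitesAll]
  if (any(is.na(labels))) stop("labels missing for some sites")
  labels <- as.integer(as.logical(labels))
  names(labels) <- sitesAll
  if (is.null(inALoop)) inALoop <- setNames(rep(FALSE, length(sitesAll)),
                                            sitesAll)
  hasMS <- rep(FALSE, length(sitesAll))
  msDim <- 0L
  if (!is.null(msEmb)) {
    msEmb <- as.matrix(msEmb)
    msDim <- ncol(msEmb)
    full <- matrix(NA_real_, length(sitesAll), msDim,
                   dimnames = list(sitesAll, NULL))
    common <- intersect(rownames(msEmb), sitesAll)
    full[common, ] <- msEmb[common, , drop = FALSE]
    hasMS <- rowSums(is.na(full)) == 0L
    full[!hasMS, ] <- 0
    msEmb <- full
  }
  pos <- sitesAll[labels == 1L]
  neg <- sitesAll[labels == 0L]
  if (!length(pos) || !length(neg)) stop("both classes required")
  roundsData <- undersampleRounds(pos, neg, protocol$ratio,
                                  protocol$rounds, seed = protocol$seed)
  weightsAll <- assignLossWeights(inALoop[sitesAll], protocol$wOut)
  names(weightsAll) <- sitesAll
  roundOut <- vector("list", protocol$rounds)
  for (r in seq_len(protocol$rounds)) {
    rd <- roundsData[[r]]
    ids <- c(rd$positives, rd$negatives)
    if (length(rd$negatives) == 0L) {
      roundOut[[r]] <- NULL
      next
    }
    idx <- match(ids, sitesAll)
    y <- labels[idx]
    rseed <- protocol$seed + 1000L * r
    testLoc <- .stratSplit(y, protocol$testFrac, rseed)
    trainLoc <- setdiff(seq_along(ids), testLoc)
    foldId <- .stratFolds(y[trainLoc], protocol$folds, rseed + 1L)
    foldModels <- vector("list", protocol$folds)
    for (f in seq_len(protocol$folds)) {
      params <- .fusionInit(ncol(seqEmb), msDim, seed = rseed + 10L + f)
      valLoc <- trainLoc[foldId == f]
      fitLocal <- c(trainLoc[foldId != f], valLoc)   # order: fit then val
      sub <- fitLocal
      foldModels[[f]] <- .fusionTrainOne(
        params,
        seqEmb[idx[sub], , drop = FALSE],
        if (is.null(msEmb)) NULL else msEmb[idx[sub], , drop = FALSE],
        hasMS[idx[sub]], labels[idx[sub]], weightsAll[idx[sub]],
        valIdx = which(sub %in% valLoc),
        lr = protocol$lr, maxEpochs = protocol$maxEpochs,
        patience = protocol$patience, dropout = protocol$dropout)
    }
    testIdx <- idx[testLoc]
    probs <- rowMeans(vapply(foldModels, function(p)
      .fusionPredict(p, seqEmb[testIdx, , drop = FALSE],
                     if (is.null(msEmb)) NULL else
                       msEmb[testIdx, , drop = FALSE], hasMS[testIdx]),
      numeric(length(testIdx))))
    metrics <- computeMetrics(labels[testIdx], probs, protocol$threshold)
    roundOut[[r]] <- list(foldModels = foldModels, metrics = metrics,
                          testSites = sitesAll[testIdx])
  }
  roundOut <- Filter(Negate(is.null), roundOut)
  mm <- do.call(rbind, lapply(roundOut, `[[`, "metrics"))
  bestRound <- which.max(mm[, "AUROC"])
  structure(list(rounds = roundOut, metricMean = colMeans(mm),
                 metricSD = apply(mm, 2, stats::sd), bestRound = bestRound,
                 seqDim = ncol(seqEmb), msDim = msDim,
                 protocol = protocol),
            class = "fusionModel")
}

#' @export
print.fusionModel <- function(x, ...) {
  cat(sprintf("fusionModel: D = %d + %d, %d round(s)\n",
              x$seqDim, x$msDim, length(x$rounds)))
  cat("test metrics (mean +/- sd over rounds):\n")
  for (m in names(x$metricMean))
    cat(sprintf("  %s: %.3f +/- %.3f\n", m, x$metricMean[[m]],
                x$metricSD[[m]]))
  invisible(x)
}

#' Score sites with a trained fusion classifier
#'
#' Uses the fold-model ensemble of the best round (highest test AUROC).
#'
#' @param model a [trainFusionClassifier()] result.
#' @param seqEmb matrix (sites x seqDim), rownames = site IDs.
#' @param msEmb matrix of MS embeddings or `NULL`; sites absent from it take
#'   the alignment path.
#' @return named numeric probability vector.
#' @export
predictFusion <- function(model, seqEmb, msEmb = NULL) {
  seqEmb <- as.matrix(seqEmb)
  sites <- rownames(seqEmb)
  hasMS <- rep(FALSE, nrow(seqEmb))
  full <- NULL
  if (model$msDim > 0L) {
    full <- matrix(0, nrow(seqEmb), model$msDim,
                   dimnames = list(sites, NULL))
    if (!is.null(msEmb)) {
      common <- intersect(rownames(msEmb), sites)
      ok <- common[rowSums(is.na(msEmb[common, , drop = FALSE])) == 0L]
      full[ok, ] <- msEmb[ok, , drop = FALSE]
      hasMS <- sites %in% ok
    }
  }
  fm <- model$rounds[[model$bestRound]]$foldModels
  probs <- rowMeans(vapply(fm, function(p)
    .fusionPredict(p, seqEmb, full, hasMS), numeric(nrow(seqEmb))))
  setNames(probs, sites)
}
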