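#' Configuration for the phospho-MS masked-autoencoding embedder
#'
#' The embedder treats each phosphosite as one token sequence whose tokens
#' are the site's values across samples; sample identity plays the role
#' positions play in language models. An attention encoder sees only the
#' observed (nonzero, unmasked) tokens; a decoder over all sample positions
#' reconstructs the full row, with learned mask/zero embeddings standing in
#' for hidden and missing cells.
#'
#' @param dModel embedding width (default 128).
#' @param nHeads attention heads (must divide `dModel`).
#' @param encLayers,decLayers number of encoder/decoder transformer blocks.
#' @param backend decoder attention backend: `"exact"` softmax attention or
#'   `"linear"` (positive-random-feature approximation for long sample
#'   axes; inference only).
#' @param nRandomFeatures random-feature count for the linear backend.
#' @param dropout dropout rate applied inside blocks during training.
#' @param norm block normalization placement: `"pre"` (LayerNorm before
#'   each sublayer; residual stream unnormalized, the easier-to-train
#'   modern layout) or `"post"` (classic placement).
#' @param anchors number of autodiscretization anchor embeddings.
#' @param gatingHidden hidden width of the autodiscretization gating net.
#' @return list of class `msEmbedderConfig`.
#' @export
msEmbedderConfig <- function(dModel = 128L, nHeads = 4L, encLayers = 2L,
                             decLayers = 2L, backend = c("exact", "linear"),
                             nRandomFeatures = 256L, dropout = 0,
                             anchors = 100L, gatingHidden = 16L,
                             norm = c("pre", "post")) {
  backend <- match.arg(backend)
  norm <- match.arg(norm)
  if (dModel %% nHeads != 0L) stop("dModel must be divisible by nHeads")
  structure(list(dModel = as.integer(dModel), nHeads = as.integer(nHeads),
                 encLayers = as.integer(encLayers),
                 decLayers = as.integer(decLayers), backend = backend,
                 nRandomFeatures = as.integer(nRandomFeatures),
                 dropout = dropout, anchors = as.integer(anchors),
                 gatingHidden = as.integer(gatingHidden), norm = norm),
            class = "msEmbedderConfig")
}

#' Pretraining configuration
#'
#' @param maskFraction fraction of a site's nonzero tokens to mask each
#'   epoch (default 0.15); the same *count* of zero tokens is masked.
#' @param batchSize sites per optimizer step.
#' @param lr Adam learning rate.
#' @param maxEpochs training epoch cap.
#' @param valFraction fraction of sites held out for validation (default
#'   0.25, i.e. a 75:25 split).
#' @param patience epochs without validation-MSE improvement before early
#'   stop.
#' @param accuracyTau reconstruction counts as accurate when
#'   `|pred - true| < accuracyTau` (default 0.1).
#' @param seed RNG seed governing splits, masks, init and batch order.
#' @return list of class `msPretrainConfig`.
#' @export
msPretrainConfig <- function(maskFraction = 0.15, batchSize = 16L,
                             lr = 1e-3, maxEpochs = 20L, valFraction = 0.25,
                             patience = 5L, accuracyTau = 0.1, seed = 1L) {
  stopifnot(maskFraction >= 0, maskFraction <= 1,
            valFraction > 0, valFraction < 1)
  structure(list(maskFraction = maskFraction,
                 batchSize = as.integer(batchSize), lr = lr,
                 maxEpochs = as.integer(maxEpochs),
                 valFraction = valFraction, patience = as.integer(patience),
                 accuracyTau = accuracyTau, seed = as.integer(seed)),
            class = "msPretrainConfig")
}

#' Balanced-count mask plan for one site row
#'
#' Masks `n = round(maskFraction * #nonzero)` nonzero tokens and *the same
#' number* of zero tokens (capped at availability of either kind), chosen
#' uniformly without replacement. Equal counts -- not equal proportions --
#' prevent the model from scoring well by predicting zero everywhere.
#'
#' @param values numeric row in \[0,1\]; 0 marks originally-missing cells.
#' @param maskFraction fraction of nonzero tokens to mask.
#' @param seed optional seed for a local, reproducible draw.
#' @return list of class `maskPlan` with integer index vectors
#'   `maskedNonzero`, `maskedZero`.
#' @export
makeMaskPlan <- function(values, maskFraction = 0.15, seed = NULL) {
  nz <- which(values > 0)
  z <- which(values == 0)
  if (!length(nz)) stop("all-zero site row (should have been filtered)")
  n <- round(maskFraction * length(nz))
  n <- min(n, length(nz), length(z))
  draw <- function() {
    list(maskedNonzero = if (n > 0) sort(sample(nz, n)) else integer(0),
         maskedZero = if (n > 0) sort(sample(z, n)) else integer(0))
  }
  plan <- if (is.null(seed)) draw() else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed); draw()
  }
  structure(plan, class = "maskPlan")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Initialize an untrained embedder
#'
#' @param config an [msEmbedderConfig()].
#' @param sampleIDs character vector of sample identifiers the model will
#'   embed (the sample look-up table covers exactly these).
#' @param seed seed for weight initialization.
#' @return object of class `msEmbedder` (parameters + config).
#' @export
initEmbedder <- function(config, sampleIDs, seed = 1L) {
  stopifnot(inherits(config, "msEmbedderConfig"), length(sampleIDs) >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d <- config$dModel
  params <- list(
    autodis = list(W1 = .rmat(1L, config$gatingHidden, 0.5),
                   b1 = numeric(config$gatingHidden),
                   W2 = .rmat(config$gatingHidden, config$anchors, 0.5),
                   b2 = numeric(config$anchors),
                   anchors = .rmat(config$anchors, d, 0.1)),
    sampleEmb = {
      m <- .rmat(length(sampleIDs), d, 0.1)
      rownames(m) <- sampleIDs
      m
    },
    maskEmb = matrix(stats::rnorm(d, sd = 0.1), 1L, d),
    zeroEmb = matrix(stats::rnorm(d, sd = 0.1), 1L, d),
    enc = lapply(seq_len(config$encLayers), function(i) .blockInit(d)),
    decIn = .linearInit(d, d),
    dec = lapply(seq_len(config$decLayers), function(i) .blockInit(d)),
    outProj = .linearInit(d, 1L)
  )
  omega <- .rmat(config$nRandomFeatures, d %/% config$nHeads, 1)
  structure(list(params = params, config = config,
                 sampleIDs = sampleIDs, omega = omega, seed = seed),
            class = "msEmbedder")
}

#' @export
print.msEmbedder <- function(x, ...) {
  cfg <- x$config
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(
    "msEmbedder: d=%d, %d enc / %d dec blocks, %d heads, %d samples, %s params\n",
    cfg$dModel, cfg$encLayers, cfg$decLayers, cfg$nHeads,
    length(x$sampleIDs), format(np, big.mark = ",")))
  invisible(x)
}

.autodisFwd <- function(p, values) {
  v <- matrix(values, ncol = 1L)
  H <- tanh(sweep(v %*% p$W1, 2, p$b1, "+"))
  L <- sweep(H %*% p$W2, 2, p$b2, "+")
  P <- .softmaxRows(L)
  list(E = P %*% p$anchors, P = P, H = H, v = v)
}

.autodisBwd <- function(p, cache, dE) {
  dAnchors <- crossprod(cache$P, dE)
  dP <- dE %*% t(p$anchors)
  dL <- cache$P * (dP - rowSums(dP * cache$P))
  dH <- dL %*% t(p$W2)
  dpre <- dH * (1 - cache$H^2)
  list(W1 = crossprod(cache$v, dpre), b1 = colSums(dpre),
       W2 = crossprod(cache$H, dL), b2 = colSums(dL),
       anchors = dAnchors)
}

#' Autodiscretization embedding of continuous values
#'
#' Embeds each scalar in \[0,1\] as a softmax-gated convex combination of
#' learned anchor embeddings: a two-layer gating network maps the scalar to
#' a probability vector over anchors, and the embedding is the weighted
#' anchor sum.
#'
#' @param values numeric vector in \[0,1\].
#' @param embedder an [initEmbedder()]/[pretrainEmbedder()] model.
#' @return matrix (length(values) x dModel); attribute `"weights"` carries
#'   the gating probability matrix.
#' @export
autoDisEmbed <- function(values, embedder) {
  if (any(!is.finite(values))) stop("non-finite value")
  fw <- .autodisFwd(embedder$params$autodis, values)
  structure(fw$E, weights = fw$P)
}

# Encoder over a set of (value, sampleID) tokens; rows of the result
# correspond to tokens in input order. keyMask marks real (TRUE) vs padding.
.encodeCore <- function(params, config, values, sampleNames,
                        keyMask = NULL, training = FALSE,
                        collectCache = FALSE) {
  ad <- .autodisFwd(params$autodis, values)
  X <- ad$E + params$sampleEmb[sampleNames, , drop = FALSE]
  caches <- vector("list", length(params$enc))
  H <- X
  for (i in seq_along(params$enc)) {
    bf <- .blockFwd(params$enc[[i]], H, config$nHeads, config$dropout,
                    training, keyMask = keyMask,
                    norm = config$norm %||% "pre")
    caches[[i]] <- bf$cache
    H <- bf$Y
  }
  list(H = H, ad = ad, caches = if (collectCache) caches else NULL,
       X = X)
}

#' Contextual encoder embeddings of a site's observed tokens
#'
#' Runs the encoder over the unmasked nonzero tokens of one site row (the
#' tokens an autoencoding step is allowed to see). There is no positional
#' order: sample-identity embeddings are added to the value embeddings, so
#' permuting tokens permutes the outputs identically.
#'
#' @param embedder an `msEmbedder`.
#' @param values named numeric row (names = sample IDs; defaults to the
#'   embedder's sample order when unnamed).
#' @param maskPlan optional [makeMaskPlan()]; masked nonzero tokens are
#'   withheld from the encoder.
#' @param padTo optionally right-pad the token sequence to this length with
#'   padding tokens excluded from attention (outputs for real tokens are
#'   unaffected).
#' @return matrix (tokens x dModel), rownames = sample IDs of the consumed
#'   tokens; zero-row matrix when no token is visible.
#' @export
encodeTokens <- function(embedder, values, maskPlan = NULL, padTo = NULL) {
  nms <- names(values)
  if (is.null(nms)) {
    if (length(values) != length(embedder$sampleIDs))
      stop("unnamed values must cover every sample")
    nms <- embedder$sampleIDs
  }
  if (any(!nms %in% rownames(embedder$params$sampleEmb)))
    stop("sample ID(s) absent from embedding table: ",
         paste(setdiff(nms, rownames(embedder$params$sampleEmb)),
               collapse = ", "))
  keep <- values > 0
  if (!is.null(maskPlan)) keep[maskPlan$maskedNonzero] <- FALSE
  idx <- which(keep)
  d <- embedder$config$dModel
  if (!length(idx))
    return(matrix(numeric(0), 0L, d))
  v <- values[idx]; sn <- nms[idx]
  keyMask <- NULL
  if (!is.null(padTo) && padTo > length(idx)) {
    nPad <- padTo - length(idx)
    v <- c(v, rep(0, nPad))
    sn <- c(sn, rep(sn[1L], nPad))      # pad identity is irrelevant: masked out
    keyMask <- c(rep(TRUE, length(idx)), rep(FALSE, nPad))
  }
  out <- .encodeCore(embedder$params, embedder$config, v, sn,
                     keyMask = keyMask)$H
  out <- out[seq_along(idx), , drop = FALSE]
  rownames(out) <- nms[idx]
  out
}

# Full forward pass for one site row. Returns predictions for all samples
# plus (optionally) every cache needed for the backward pass.
.forwardSite <- function(params, config, v, plan, omega = NULL,
                         training = FALSE, collectCache = FALSE) {
  S <- length(v)
  d <- config$dModel
  nzIdx <- which(v > 0)
  obsIdx <- setdiff(nzIdx, plan$maskedNonzero)
  maskedIdx <- sort(c(plan$maskedNonzero, plan$maskedZero))
  zeroUnmasked <- setdiff(which(v == 0), plan$maskedZero)
  enc <- NULL
  if (length(obsIdx)) {
    enc <- .encodeCore(params, config, v[obsIdx],
                       rownames(params$sampleEmb)[obsIdx],
                       training = training, collectCache = collectCache)
  }
  A <- matrix(0, S, d)
  if (length(obsIdx)) A[obsIdx, ] <- enc$H
  if (length(maskedIdx))
    A[maskedIdx, ] <- matrix(params$maskEmb, length(maskedIdx), d,
                             byrow = TRUE)
  if (length(zeroUnmasked))
    A[zeroUnmasked, ] <- matrix(params$zeroEmb, length(zeroUnmasked), d,
                                byrow = TRUE)
  Ain <- A + params$sampleEmb
  D0 <- .linearFwd(params$decIn, Ain)
  decCaches <- vector("list", length(params$dec))
  H <- D0
  for (i in seq_along(params$dec)) {
    bf <- .blockFwd(params$dec[[i]], H, config$nHeads, config$dropout,
                    training, backend = config$backend, omega = omega,
                    norm = config$norm %||% "pre")
    decCaches[[i]] <- bf$cache
    H <- bf$Y
  }
  pred <- as.numeric(.linearFwd(params$outProj, H))
  if (!collectCache)
    return(list(pred = pred, decoderOut = H))
  list(pred = pred, decoderOut = H, enc = enc, Ain = Ain, D0in = Ain,
       decCaches = decCaches, decH = H, obsIdx = obsIdx,
       maskedIdx = maskedIdx, zeroUnmasked = zeroUnmasked)
}

.backwardSite <- function(params, config, v, cache, dpred) {
  S <- length(v)
  grads <- list()
  bo <- .linearBwd(params$outProj, cache$decH, matrix(dpred, S, 1L))
  grads$outProj <- bo$grads
  dH <- bo$dX
  decG <- vector("list", length(params$dec))
  for (i in rev(seq_along(params$dec))) {
    bb <- .blockBwd(params$dec[[i]], cache$decCaches[[i]], dH)
    decG[[i]] <- bb$grads
    dH <- bb$dX
  }
  grads$dec <- decG
  bi <- .linearBwd(params$decIn, cache$D0in, dH)
  grads$decIn <- bi$grads
  dA <- bi$dX
  grads$sampleEmb <- dA                       # every row gets its identity
  if (length(cache$maskedIdx))
    grads$maskEmb <- matrix(colSums(dA[cache$maskedIdx, , drop = FALSE]),
                            1L, config$dModel)
  else grads$maskEmb <- params$maskEmb * 0
  if (length(cache$zeroUnmasked))
    grads$zeroEmb <- matrix(colSums(dA[cache$zeroUnmasked, , drop = FALSE]),
                            1L, config$dModel)
  else grads$zeroEmb <- params$zeroEmb * 0
  if (length(cache$obsIdx)) {
    dHenc <- dA[cache$obsIdx, , drop = FALSE]
    encG <- vector("list", length(params$enc))
    for (i in rev(seq_along(params$enc))) {
      bb <- .blockBwd(params$enc[[i]], cache$enc$caches[[i]], dHenc)
      encG[[i]] <- bb$grads
      dHenc <- bb$dX
    }
    grads$enc <- encG
    grads$sampleEmb[cache$obsIdx, ] <-
      grads$sampleEmb[cache$obsIdx, , drop = FALSE] + dHenc
    grads$autodis <- .autodisBwd(params$autodis, cache$enc$ad, dHenc)
  } else {
    grads$enc <- .zeroLike(params$enc)
    grads$autodis <- .zeroLike(params$autodis)
  }
  grads
}

#' Decode and reconstruct a full site row
#'
#' Assembles a full-length token sequence at the original sample positions
#' (encoder outputs where observed, the mask embedding at masked positions,
#' the zero embedding at unmasked-zero positions, each plus the sample
#' identity embedding), passes it through a position-wise linear map, the
#' decoder and a final projection to one predicted value per sample. The
#' true values at masked cells never enter the forward pass.
#'
#' @param embedder an `msEmbedder`.
#' @param values full numeric row over the embedder's samples.
#' @param maskPlan a [makeMaskPlan()].
#' @return numeric vector of reconstructed values, one per sample.
#' @export
decodeReconstruct <- function(embedder, values, maskPlan) {
  if (length(values) != length(embedder$sampleIDs))
    stop("values must cover every sample")
  .forwardSite(embedder$params, embedder$config, values, maskPlan,
               omega = embedder$omega)$pred
}

#' Mean squared error at masked positions
#'
#' @param pred,true numeric vectors of equal length.
#' @param maskPlan a [makeMaskPlan()] (its masked nonzero + zero indices).
#' @return mean squared error over the masked positions only.
#' @export
maskedMSE <- function(pred, true, maskPlan) {
  stopifnot(length(pred) == length(true))
  idx <- c(maskPlan$maskedNonzero, maskPlan$maskedZero)
  if (!length(idx)) stop("empty mask")
  mean((pred[idx] - true[idx])^2)
}

.evalEmbedder <- function(params, config, V, plans, omega, tau) {
  preds <- numeric(0); trues <- numeric(0)
  for (i in seq_len(nrow(V))) {
    plan <- plans[[i]]
    idx <- c(plan$maskedNonzero, plan$maskedZero)
    if (!length(idx)) next
    fw <- .forwardSite(params, config, V[i, ], plan, omega = omega)
    preds <- c(preds, fw$pred[idx])
    trues <- c(trues, V[i, idx])
  }
  c(mse = mean((preds - trues)^2),
    accuracy = mean(abs(preds - trues) < tau),
    correlation = if (stats::sd(preds) > 0 && stats::sd(trues) > 0)
      stats::cor(preds, trues) else NA_real_)
}

#' Pretrain the embedder by masked-value reconstruction
#'
#' Sites are split 75:25 into training and validation; each epoch draws
#' fresh balanced mask plans for the training sites, minimizes the masked
#' MSE with Adam, and evaluates masked MSE / accuracy / Pearson correlation
#' on fixed validation masks. Early-stops when validation MSE stops
#' improving; the best parameters are restored.
#'
#' @param x a [NormalizedPhosMatrix] or a numeric matrix in \[0,1\]
#'   (rows = sites, 0 = missing).
#' @param config an [msEmbedderConfig()].
#' @param pretrain an [msPretrainConfig()].
#' @param verbose print per-epoch metrics.
#' @return trained `msEmbedder`; element `report` holds the per-epoch
#'   metrics (epoch 0 = initial weights), `valSites`/`trainSites` the split.
#' @export
pretrainEmbedder <- function(x, config = msEmbedderConfig(),
                             pretrain = msPretrainConfig(),
                             verbose = FALSE) {
  V <- if (is(x, "NormalizedPhosMatrix")) normValues(x) else as.matrix(x)
  if (pretrain$maskFraction <= 0)
    stop("maskFraction must be > 0: no training signal")
  allZero <- rowSums(V > 0) == 0
  if (any(allZero)) {
    warning(sum(allZero), " all-zero site row(s) dropped")
    V <- V[!allZero, , drop = FALSE]
  }
  if (nrow(V) < 2L) stop("need >= 2 sites with observations")
  if (config$backend == "linear")
    stop("training requires the exact attention backend")
  model <- initEmbedder(config, colnames(V) %||%
                          paste0("sample", seq_len(ncol(V))),
                        seed = pretrain$seed)
  colnames(V) <- model$sampleIDs
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(pretrain$seed)
  n <- nrow(V)
  valIdx <- sort(sample(n, max(1L, round(pretrain$valFraction * n))))
  trainIdx <- setdiff(seq_len(n), valIdx)
  valPlans <- lapply(valIdx, function(i)
    makeMaskPlan(V[i, ], pretrain$maskFraction))
  params <- model$params
  state <- .adamInit(params)
  report <- list()
  ev0 <- .evalEmbedder(params, config, V[valIdx, , drop = FALSE], valPlans,
                       model$omega, pretrain$accuracyTau)
  report[[1L]] <- c(epoch = 0, train_mse = NA_real_, ev0)
  best <- list(params = params, mse = ev0[["mse"]], epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(pretrain$maxEpochs)) {
    ord <- sample(trainIdx)
    plans <- setNames(lapply(ord, function(i)
      makeMaskPlan(V[i, ], pretrain$maskFraction)), as.character(ord))
    batchStarts <- seq(1L, length(ord), by = pretrain$batchSize)
    epochLoss <- 0; nLoss <- 0L
    for (bs in batchStarts) {
      batch <- ord[bs:min(bs + pretrain$batchSize - 1L, length(ord))]
      gAcc <- NULL
      used <- 0L
      for (i in batch) {
        plan <- plans[[as.character(i)]]
        idx <- c(plan$maskedNonzero, plan$maskedZero)
        if (!length(idx)) next
        fw <- .forwardSite(params, config, V[i, ], plan,
                           training = TRUE, collectCache = TRUE)
        err <- fw$pred - V[i, ]
        loss <- mean(err[idx]^2)
        if (!is.finite(loss)) stop("non-finite loss: training diverged")
        epochLoss <- epochLoss + loss; nLoss <- nLoss + 1L
        dpred <- numeric(length(err))
        dpred[idx] <- 2 * err[idx] / length(idx)
        g <- .backwardSite(params, config, V[i, ], fw, dpred)
        gAcc <- .gradAdd(gAcc, g)
        used <- used + 1L
      }
      if (used == 0L) next
      gAcc <- .gradScale(gAcc, 1 / used)
      st <- .adamStep(params, gAcc, state, lr = pretrain$lr)
      params <- st$params; state <- st$state
    }
    ev <- .evalEmbedder(params, config, V[valIdx, , drop = FALSE], valPlans,
                        model$omega, pretrain$accuracyTau)
    report[[epoch + 1L]] <- c(epoch = epoch,
                              train_mse = epochLoss / max(nLoss, 1L), ev)
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f", epoch,
                      epochLoss / max(nLoss, 1L), ev[["mse"]]))
    if (ev[["mse"]] < best$mse - 1e-12) {
      best <- list(params = params, mse = ev[["mse"]], epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= pretrain$patience) break
    }
  }
  model$params <- best$params
  model$report <- as.data.frame(do.call(rbind, report))
  model$trainSites <- rownames(V)[trainIdx]
  model$valSites <- rownames(V)[valIdx]
  model$valPlans <- valPlans
  model$bestEpoch <- best$epoch
  model
}

#' Extract per-site embeddings from a trained embedder
#'
#' Feeds each site's nonzero tokens through the (frozen) encoder and
#' max-pools the contextual sample embeddings componentwise into one
#' fixed-length vector per site.
#'
#' @param embedder a (pre)trained `msEmbedder`.
#' @param x [NormalizedPhosMatrix] or numeric matrix over the embedder's
#'   samples.
#' @param sites optional subset of site IDs (default: all rows).
#' @return matrix (sites x dModel); sites with no nonzero value are omitted
#'   and listed in attribute `"noEmbedding"`.
#' @export
extractSiteEmbeddings <- function(embedder, x, sites = NULL) {
  V <- if (is(x, "NormalizedPhosMatrix")) normValues(x) else as.matrix(x)
  if (is.null(sites)) sites <- rownames(V)
  if (is.null(sites)) stop("matrix has no rownames; supply `sites`")
  missing_ <- setdiff(sites, rownames(V))
  if (length(missing_))
    stop("site(s) absent from matrix: ", paste(missing_, collapse = ", "))
  out <- matrix(NA_real_, length(sites), embedder$config$dModel,
                dimnames = list(sites, NULL))
  none <- character(0)
  for (s in sites) {
    v <- V[s, ]
    names(v) <- colnames(V)
    H <- encodeTokens(embedder, v)
    if (!nrow(H)) { none <- c(none, s); next }
    out[s, ] <- apply(H, 2, max)
  }
  keep <- !(sites %in% none)
  structure(out[keep, , drop = FALSE], noEmbedding = none)
}
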