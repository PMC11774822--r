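#' Split samples by detection of a kinase phosphosite
#'
#' Partitions samples into a phos-group (site value > 0) and a non-phos
#' group (value 0, i.e. originally missing).
#'
#' @param x a [NormalizedPhosMatrix] (or numeric matrix with 0 = missing).
#' @param site site ID (row name).
#' @return list with character vectors `phos` and `nonPhos`.
#' @export
splitBySiteDetection <- function(x, site) {
  V <- if (is(x, "NormalizedPhosMatrix")) normValues(x) else as.matrix(x)
  if (!site %in% rownames(V)) stop("site absent from matrix: ", site)
  v <- V[site, ]
  list(phos = colnames(V)[v > 0], nonPhos = colnames(V)[v == 0])
}

#' Rank all sites by between-group fold change
#'
#' For every site, computes `log2((mean(phos-group) + eps) /
#' (mean(non-phos group) + eps))` and returns the sites sorted by
#' decreasing score (ties broken by site ID for determinism).
#'
#' @param x [NormalizedPhosMatrix] or numeric matrix.
#' @param groups list with `phos`, `nonPhos` sample-ID vectors
#'   (from [splitBySiteDetection()]); both must be nonempty.
#' @param eps pseudo-count guarding zero means (default 1e-6).
#' @return data.frame with columns `site`, `score`, sorted descending.
#' @export
rankByFoldChange <- function(x, groups, eps = 1e-6) {
  V <- if (is(x, "NormalizedPhosMatrix")) normValues(x) else as.matrix(x)
  stopifnot(length(groups$phos) > 0, length(groups$nonPhos) > 0)
  m1 <- rowMeans(V[, groups$phos, drop = FALSE])
  m0 <- rowMeans(V[, groups$nonPhos, drop = FALSE])
  score <- log2((m1 + eps) / (m0 + eps))
  ord <- order(-score, rownames(V))
  data.frame(site = rownames(V)[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: at a gene-set hit the running sum rises by
#' `|score|^p` normalized by the total over hits; at a miss it falls by
#' `1/(N - Nhits)`. The enrichment score is the extremum (largest
#' |deviation|) of the walk.
#'
#' @param ranked data.frame from [rankByFoldChange()] (columns `site`,
#'   `score`), or a named score vector sorted in ranking order.
#' @param geneSet character vector of site IDs (e.g. a kinase's substrate
#'   set).
#' @param p weighting exponent (default 1; `p = 0` gives the classic
#'   unweighted KS statistic).
#' @return list with `ES` and the `runningSum` profile.
#' @export
enrichmentScore <- function(ranked, geneSet, p = 1) {
  if (is.data.frame(ranked)) {
    sites <- ranked$site; scores <- ranked$score
  } else {
    sites <- names(ranked); scores <- as.numeric(ranked)
  }
  hit <- sites %in% geneSet
  N <- length(sites); Nh <- sum(hit)
  if (Nh == 0L) stop("gene set does not intersect the ranking")
  if (Nh == N) stop("gene set covers the whole ranking (no misses)")
  wHit <- abs(scores)^p
  denomHit <- sum(wHit[hit])
  if (denomHit == 0) {
    wHit <- rep(1, N); denomHit <- Nh     # all-zero scores: fall back to p=0
  }
  step <- ifelse(hit, wHit / denomHit, -1 / (N - Nh))
  rs <- cumsum(step)
  ES <- rs[which.max(abs(rs))]
  list(ES = ES, runningSum = rs)
}

#' Normalized enrichment score by set-membership permutation
#'
#' Recomputes the enrichment score for `nPerm` random gene sets of the same
#' size drawn from the ranked sites; NES is the observed ES divided by the
#' mean |ES| of the same-sign permutation scores.
#'
#' @param ranked as in [enrichmentScore()].
#' @param geneSet character vector of site IDs.
#' @param nPerm permutation count (>= 100; default 1000).
#' @param p weighting exponent.
#' @param seed RNG seed.
#' @return list of class `enrichmentResult`: `ES`, `NES`, `nPerm`,
#'   `pValue` (fraction of same-sign permutations at least as extreme).
#'   `NES` is `NA` (flagged) when no permutation shares the sign of ES.
#' @export
normalizedEnrichment <- function(ranked, geneSet, nPerm = 1000L, p = 1,
                                 seed = 1L) {
  stopifnot(nPerm >= 100L)
  es <- enrichmentScore(ranked, geneSet, p)$ES
  sites <- if (is.data.frame(ranked)) ranked$site else names(ranked)
  size <- sum(sites %in% geneSet)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- vapply(seq_len(nPerm), function(i)
    enrichmentScore(ranked, sample(sites, size), p)$ES, numeric(1))
  same <- perm[sign(perm) == sign(es)]
  nes <- if (!length(same) || es == 0) NA_real_ else es / mean(abs(same))
  pval <- if (!length(same)) NA_real_ else mean(abs(same) >= abs(es))
  structure(list(ES = es, NES = nes, nPerm = nPerm, pValue = pval,
                 setSize = size),
            class = "enrichmentResult")
}

#' @export
print.enrichmentResult <- function(x, ...) {
  cat(sprintf("ES = %.3f, NES = %.3f (n = %d sites, %d permutations, p = %.3g)\n",
              x$ES, x$NES, x$setSize, x$nPerm, x$pValue))
  invisible(x)
}

#' Downshifted-Gaussian imputation of missing intensities
#'
#' Replaces missing values by i.i.d. draws from
#' `Normal(mu0 + delta * sigma0, (lambda * sigma0)^2)` where `mu0`,
#' `sigma0` are the mean and SD of the observed values -- the conventional
#' left-shifted imputation for missing-not-at-random phospho-MS data ahead
#' of survival modeling. Sites with too many missing values are rejected.
#'
#' @param values numeric vector with `NA` marking missing entries.
#' @param delta shift in observed-SD units (default -0.5).
#' @param lambda scale in observed-SD units (default 0.5, > 0).
#' @param maxMissingFrac reject when the missing fraction reaches this
#'   bound (default 0.5: "fewer than 50% missing" is required).
#' @param seed RNG seed.
#' @return completed numeric vector; attribute `"imputed"` marks filled
#'   positions.
#' @export
downshiftImpute <- function(values, delta = -0.5, lambda = 0.5,
                            maxMissingFrac = 0.5, seed = 1L) {
  stopifnot(lambda > 0)
  miss <- is.na(values)
  frac <- mean(miss)
  if (frac >= maxMissingFrac)
    stop(sprintf("site rejected: %.0f%% missing (limit < %.0f%%)",
                 100 * frac, 100 * maxMissingFrac))
  obs <- values[!miss]
  if (length(obs) < 2L) stop("need >= 2 observed values")
  mu0 <- mean(obs); s0 <- stats::sd(obs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  values[miss] <- stats::rnorm(sum(miss), mu0 + delta * s0, lambda * s0)
  structure(values, imputed = which(miss))
}
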