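smallCfg <- function(...) msEmbedderConfig(dModel = 8L, nHeads = 2L,
                                           encLayers = 1L, decLayers = 1L,
                                           anchors = 6L, gatingHidden = 4L,
                                           ...)

test_that("mask plans balance nonzero and zero counts with the cap rule", {
  v <- c(runif(6, 0.1, 1), rep(0, 10))
  pl <- makeMaskPlan(v, 0.5, seed = 1)
  expect_length(pl$maskedNonzero, 3L)
  expect_length(pl$maskedZero, 3L)
  expect_true(all(v[pl$maskedNonzero] > 0))
  expect_true(all(v[pl$maskedZero] == 0))

  # zero-side cap: 4 nonzero, 1 zero, fraction 0.5 -> 1 + 1
  v2 <- c(runif(4, 0.1, 1), 0)
  pl2 <- makeMaskPlan(v2, 0.5, seed = 2)
  expect_length(pl2$maskedNonzero, 1L)
  expect_length(pl2$maskedZero, 1L)

  expect_length(makeMaskPlan(v, 0, seed = 3)$maskedNonzero, 0L)
  expect_error(makeMaskPlan(rep(0, 5)), "all-zero")
})

test_that("equal-count masking holds for random rows at every fraction", {
  set.seed(17)
  for (i in 1:50) {
    v <- runif(30); v[runif(30) < runif(1, 0.2, 0.8)] <- 0
    if (!any(v > 0)) v[1] <- 0.5
    fr <- runif(1, 0.05, 0.9)
    pl <- makeMaskPlan(v, fr)
    expect_identical(length(pl$maskedNonzero), length(pl$maskedZero))
    expect_length(intersect(pl$maskedNonzero, pl$maskedZero), 0L)
  }
})

test_that("autodiscretization embeds scalars as convex anchor mixtures", {
  emb <- initEmbedder(smallCfg(), paste0("s", 1:5), seed = 4)
  E <- autoDisEmbed(c(0.2, 0.8, 0.2), emb)
  W <- attr(E, "weights")
  expect_true(all(W >= 0))
  expect_equal(rowSums(W), rep(1, 3))
  expect_equal(E[1, ], E[3, ])                    # determinism for equal values
  # convex combination: bounded by the largest anchor magnitude per dim
  A <- emb$params$autodis$anchors
  expect_true(all(abs(E) <= max(abs(A)) + 1e-12))
  expect_error(autoDisEmbed(NaN, emb), "non-finite")

  # single-anchor degenerate case: output equals that anchor for any value
  emb1 <- initEmbedder(msEmbedderConfig(dModel = 8L, nHeads = 2L,
                                        anchors = 1L, gatingHidden = 4L),
                       paste0("s", 1:3), seed = 5)
  E1 <- autoDisEmbed(c(0.1, 0.9), emb1)
  expect_equal(unname(E1[1, ]), unname(as.numeric(emb1$params$autodis$anchors)))
  expect_equal(E1[1, ], E1[2, ])
})

test_that("the encoder is permutation-equivariant over sample tokens", {
  emb <- initEmbedder(smallCfg(), paste0("s", 1:12), seed = 6)
  v <- setNames(c(0.3, 0, 0.8, 0.5, 0, 0.1, 0.9, 0, 0.2, 0.6, 0, 0.4),
                paste0("s", 1:12))
  H <- encodeTokens(emb, v)
  set.seed(8)
  perm <- sample(length(v))
  H2 <- encodeTokens(emb, v[perm])
  expect_lt(max(abs(H[rownames(H2), ] - H2)), 1e-10)
})

test_that("padding tokens are excluded from attention", {
  emb <- initEmbedder(smallCfg(), paste0("s", 1:10), seed = 7)
  v <- setNames(c(0.3, 0, 0.8, 0.5, 0, 0, 0.9, 0.2, 0, 0.6), paste0("s", 1:10))
  H <- encodeTokens(emb, v)
  Hpad <- encodeTokens(emb, v, padTo = 16L)
  expect_lt(max(abs(H - Hpad)), 1e-10)
  expect_error(encodeTokens(emb, setNames(0.5, "zz")), "absent")
})

test_that("a site with every token masked or zero still decodes", {
  emb <- initEmbedder(smallCfg(), paste0("s", 1:6), seed = 9)
  v <- c(0.5, 0, 0, 0.7, 0, 0)
  pl <- structure(list(maskedNonzero = c(1L, 4L), maskedZero = c(2L, 5L)),
                  class = "maskPlan")
  expect_equal(nrow(encodeTokens(emb, setNames(v, emb$sampleIDs), pl)), 0L)
  pred <- decodeReconstruct(emb, v, pl)
  expect_length(pred, 6L)
  expect_true(all(is.finite(pred)))
})

test_that("reconstruction never sees the true values at masked cells", {
  emb <- initEmbedder(smallCfg(), paste0("s", 1:10), seed = 10)
  v <- c(0.3, 0, 0.8, 0.5, 0, 0, 0.9, 0.2, 0, 0.6)
  pl <- makeMaskPlan(v, 0.5, seed = 11)
  base <- decodeReconstruct(emb, v, pl)
  expect_length(base, 10L)
  for (j in pl$maskedNonzero) {
    v2 <- v
    v2[j] <- runif(1, 0.01, 1)       # perturb a hidden truth
    expect_identical(decodeReconstruct(emb, v2, pl), base)
  }
})

test_that("linear-attention decoding converges to exact attention", {
  set.seed(12)
  mkEmb <- function(m, seed) {
    cfg <- msEmbedderConfig(dModel = 16L, nHeads = 2L, encLayers = 1L,
                            decLayers = 1L, anchors = 8L, gatingHidden = 4L,
                            backend = "linear", nRandomFeatures = m)
    initEmbedder(cfg, paste0("s", 1:16), seed = seed)
  }
  embL64 <- mkEmb(64L, 13)
  embL1024 <- mkEmb(1024L, 13)      # same weights, more random features
  embE <- embL64
  embE$config$backend <- "exact"
  v <- runif(16, 0.05, 1); v[c(3, 9, 14)] <- 0
  pl <- makeMaskPlan(v, 0.3, seed = 14)
  pe <- decodeReconstruct(embE, v, pl)
  e64 <- max(abs(decodeReconstruct(embL64, v, pl) - pe))
  e1024 <- max(abs(decodeReconstruct(embL1024, v, pl) - pe))
  expect_lt(e1024, e64)             # error shrinks with feature count
  expect_lt(e1024, 0.3)
})

test_that("masked MSE ignores unmasked positions", {
  pl <- structure(list(maskedNonzero = 2L, maskedZero = 4L),
                  class = "maskPlan")
  expect_equal(maskedMSE(c(1, 1, 1, 1), c(1, 1, 1, 1), pl), 0)
  expect_equal(maskedMSE(c(0, 0.5, 0, 0), c(9, 0, 9, 0), pl),
               (0.5^2 + 0) / 2)
  # garbage at unmasked positions leaves the value unchanged
  expect_equal(maskedMSE(c(99, 0.5, -99, 0), c(-5, 0, 77, 0), pl),
               (0.5^2 + 0) / 2)
  empty <- structure(list(maskedNonzero = integer(0),
                          maskedZero = integer(0)), class = "maskPlan")
  expect_error(maskedMSE(1, 1, empty), "empty mask")
})

test_that("pretraining is deterministic and rejects degenerate inputs", {
  set.seed(20)
  V <- matrix(runif(20 * 12, 0.05, 1), 20, 12,
              dimnames = list(paste0("P", 1:20, ":S", 1:20),
                              paste0("s", 1:12)))
  V[runif(240) < 0.3] <- 0
  V[1, ] <- c(0.5, rep(0.4, 11))     # guarantee nonzero rows exist
  cfg <- smallCfg()
  pc <- msPretrainConfig(maxEpochs = 2L, seed = 77, batchSize = 8L)
  m1 <- pretrainEmbedder(V, cfg, pc)
  m2 <- pretrainEmbedder(V, cfg, pc)
  expect_identical(m1$report, m2$report)          # bit-identical loss curves
  expect_identical(m1$params$outProj, m2$params$outProj)

  expect_error(pretrainEmbedder(V, cfg, msPretrainConfig(maskFraction = 0)),
               "no training signal")
  Vz <- V; Vz[3, ] <- 0
  expect_warning(pretrainEmbedder(Vz, cfg, pc), "all-zero")
  expect_error(pretrainEmbedder(V[1, , drop = FALSE], cfg, pc), ">= 2 sites")
})

test_that("site embeddings max-pool encoder outputs deterministically", {
  emb <- initEmbedder(smallCfg(), paste0("s", 1:8), seed = 30)
  V <- rbind(a = c(0.2, 0, 0.7, 0.4, 0, 0.9, 0, 0.3),
             b = c(0.2, 0, 0.7, 0.4, 0, 0.9, 0, 0.3),    # duplicate row
             c = c(0, 0.5, 0, 0, 0.8, 0, 0.1, 0),
             d = rep(0, 8))
  rownames(V) <- c("P1:S1", "P2:S2", "P3:S3", "P4:S4")
  colnames(V) <- paste0("s", 1:8)
  E <- extractSiteEmbeddings(emb, V)
  # identical rows embed identically; all-zero row is flagged, not NaN
  expect_equal(E["P1:S1", ], E["P2:S2", ])
  expect_equal(attr(E, "noEmbedding"), "P4:S4")
  expect_equal(nrow(E), 3L)
  # pooled vector is the componentwise max of the contextual vectors
  H <- encodeTokens(emb, setNames(V["P1:S1", ], colnames(V)))
  expect_equal(unname(E["P1:S1", ]), unname(apply(H, 2, max)))
  # single-token site: embedding equals that token's contextual vector
  v1 <- setNames(c(0.6, rep(0, 7)), paste0("s", 1:8))
  H1 <- encodeTokens(emb, v1)
  E1 <- extractSiteEmbeddings(emb, matrix(v1, 1,
                                          dimnames = list("P9:S9",
                                                          names(v1))))
  expect_equal(unname(E1[1, ]), unname(H1[1, ]))
})
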