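test_that("fusing both modalities concatenates to seqDim + msDim", {
  out <- fuseEmbeddings(rnorm(1024), rnorm(128))
  expect_length(out, 1152L)
  expect_equal(attr(out, "provenance"), "both")
})

test_that("sequence-only sites are aligned to the fused dimension", {
  align <- list(W = matrix(0, 1024, 1152), b = numeric(1152))
  out <- fuseEmbeddings(rnorm(1024), NULL, alignLayer = align)
  expect_length(out, 1152L)
  expect_equal(attr(out, "provenance"), "sequence-only")
  expect_equal(as.numeric(out), rep(0, 1152))     # zero map -> zero vector
  expect_error(fuseEmbeddings(rnorm(10), NULL, alignLayer = align), "10")
  expect_error(fuseEmbeddings(rnorm(1024), NULL), "alignLayer")
})

test_that("loss weights follow A-loop membership", {
  expect_equal(assignLossWeights(c(TRUE, FALSE, FALSE), 4), c(1, 4, 4))
  expect_equal(assignLossWeights(c(TRUE, FALSE), 1), c(1, 1))
  expect_equal(assignLossWeights(TRUE, 16), 1)
  expect_error(assignLossWeights(FALSE, 0.5), "wOut")
})

test_that("weighted BCE matches the closed form and scales linearly", {
  expect_equal(weightedBCE(0, 1, 1), log(2), tolerance = 1e-12)
  l1 <- weightedBCE(c(0.3, -1.2), c(1, 0), c(2, 3))
  expect_equal(weightedBCE(c(0.3, -1.2), c(1, 0), 2 * c(2, 3)), 2 * l1,
               tolerance = 1e-12)
  expect_lt(weightedBCE(20, 1, 1), 1e-8)
  # unweighted equivalence to the explicit formula
  set.seed(2)
  x <- rnorm(50); y <- rbinom(50, 1, 0.4)
  manual <- -mean(y * log(plogis(x)) + (1 - y) * log(1 - plogis(x)))
  expect_equal(weightedBCE(x, y), manual, tolerance = 1e-12)
  expect_error(weightedBCE(Inf, 1, 1), "non-finite")
})

test_that("larger out-of-loop weights increase the loss on out-of-loop errors", {
  logits <- c(2, -2, 0.5)
  labels <- c(0, 1, 0)               # all wrong-ish
  inLoop <- c(FALSE, TRUE, FALSE)
  losses <- vapply(c(1, 2, 4, 8, 16), function(w)
    weightedBCE(logits, labels, assignLossWeights(inLoop, w)), numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("computeMetrics matches the worked AUROC example and edge cases", {
  m <- computeMetrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(m[["AUROC"]], 0.75)
  expect_equal(aurocPairwise(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)

  perfect <- computeMetrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect[["AUROC"]], 1)
  expect_equal(perfect[["MCC"]], 1)

  # TP=1, FP=1, FN=1 at threshold: F1 = 0.5
  m2 <- computeMetrics(c(1, 1, 0, 0), c(0.9, 0.1, 0.8, 0.2))
  expect_equal(m2[["F1"]], 0.5)

  expect_error(computeMetrics(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUROC equals the pairwise-concordance oracle on random instances", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(computeMetrics(labels, scores)[["AUROC"]],
                 aurocPairwise(labels, scores))
  }
})

test_that("under-sampling rounds draw disjoint negatives and exhaust the pool", {
  pos <- paste0("p", 1:3)
  pool <- paste0("n", 1:90)
  rds <- undersampleRounds(pos, pool, ratio = 10L, rounds = 3L, seed = 5)
  negs <- lapply(rds, `[[`, "negatives")
  expect_equal(lengths(negs), rep(30L, 3))
  expect_length(Reduce(intersect, negs), 0L)
  expect_setequal(unlist(negs), pool)

  one <- undersampleRounds(pos, pool, ratio = 10L, rounds = 1L, seed = 5)
  expect_length(one[[1]]$negatives, 30L)

  expect_warning(expect_warning(
    short <- undersampleRounds(pos, paste0("n", 1:50), 10L, 3L, seed = 5),
    "round 2"), "round 3")          # rounds 2 and 3 both under-filled
  expect_equal(lengths(lapply(short, `[[`, "negatives")), c(30L, 20L, 0L))
  expect_error(undersampleRounds(character(0), pool), "no positives")
})

test_that("high-confidence selection takes the ceiling of the top fraction", {
  set.seed(8)
  sc <- setNames(runif(100), sprintf("P%03d:S1", 1:100))
  expect_length(selectHighConfidence(sc, 0.05), 5L)
  expect_length(selectHighConfidence(setNames(runif(10), letters[1:10]),
                                     0.05), 1L)
  top <- selectHighConfidence(sc, 0.05)
  expect_equal(top, names(sort(sc, decreasing = TRUE))[1:5])
  # boundary ties break lexicographically
  tied <- setNames(c(1, 1, 1, 0.5), c("d", "b", "a", "c"))
  expect_equal(selectHighConfidence(tied, 0.5), c("a", "b"))
  expect_length(selectHighConfidence(numeric(0)), 0L)
})

test_that("fusion training is deterministic and handles missing MS rows", {
  set.seed(44)
  n <- 60
  sites <- sprintf("K%02d:S%d", 1:n, 1:n)
  labels <- setNames(rep(c(1, 0), c(10, 50)), sites)
  seqE <- simSiteEmbeddings(sites, labels, dim = 24, delta = 4, seed = 1)
  msE <- simSiteEmbeddings(sites, labels, dim = 8, delta = 4, seed = 2)
  msE <- msE[1:40, , drop = FALSE]          # 20 sites are sequence-only
  proto <- fusionProtocol(rounds = 2L, ratio = 3L, folds = 2L,
                          maxEpochs = 30L, seed = 9)
  f1 <- suppressWarnings(trainFusionClassifier(seqE, msE, labels,
                                               protocol = proto))
  f2 <- suppressWarnings(trainFusionClassifier(seqE, msE, labels,
                                               protocol = proto))
  expect_identical(f1$metricMean, f2$metricMean)
  expect_identical(predictFusion(f1, seqE, msE), predictFusion(f2, seqE, msE))
  expect_equal(f1$msDim, 8L)
  expect_length(predictFusion(f1, seqE, msE), n)
  # negative sets disjoint across rounds
  n1 <- f1$rounds[[1]]$testSites
  expect_true(all(n1 %in% sites))
})

test_that("the classifier input is D-dimensional for both provenances", {
  params <- phosfusion:::.fusionInit(24, 8, seed = 3)
  seqE <- matrix(rnorm(5 * 24), 5)
  msE <- matrix(rnorm(5 * 8), 5)
  hasMS <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  fi <- phosfusion:::.fusionInput(params, seqE, msE, hasMS)
  expect_equal(dim(fi$I), c(5L, 32L))
  expect_true(all(is.finite(fi$I)))
  # widths halve down to a single logit
  widths <- phosfusion:::.fusionWidths(1152L)
  expect_equal(widths, c(1152L, 576L, 288L, 144L, 1L))
})
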