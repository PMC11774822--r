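test_that("extractFlank truncates at termini and tracks the center", {
  fw <- extractFlank("MKSTP", 3, 2)
  expect_equal(fw$window, "MKSTP")
  expect_equal(fw$centerOffset, 3L)
  expect_equal(fw$residue, "S")

  fw2 <- extractFlank("MKSTP", 1, 2)
  expect_equal(fw2$window, "MKS")
  expect_equal(fw2$centerOffset, 1L)

  expect_equal(extractFlank("MKSTP", 3, 7)$window, "MKSTP")
  expect_equal(extractFlank("MKSTP", 3, 7)$effectiveLength, 5L)
  expect_error(extractFlank("MKSTP", 6, 2), "out of range")
  expect_error(extractFlank("MKSTP", 0, 2), "out of range")
})

test_that("group composition counts overlapping residue classes", {
  sch <- aaGroupScheme()
  expect_equal(unname(groupComposition("GGY", sch)["Small"]), 2 / 3)
  expect_equal(unname(groupComposition("DDD", sch)["NegativelyCharged"]), 1)
  g <- groupComposition("KRH", sch)
  expect_equal(unname(g["PositivelyCharged"]), 1)
  expect_equal(unname(g["Aromatic"]), 1 / 3)    # H belongs to both groups
  expect_true(all(g >= 0 & g <= 1))
  expect_warning(groupComposition("AXB", sch), "non-standard")
  expect_error(groupComposition(""), "empty")
})

test_that("the seventeen residue groups carry the standard memberships", {
  sch <- aaGroupScheme()
  expect_length(sch, 17L)
  expect_setequal(sch$Asx, c("D", "N"))
  expect_setequal(sch$Uncharged, c("N", "C", "Q", "S", "T", "Y"))
  expect_setequal(sch$Hydrophilic, c("S", "T", "H", "N", "Q", "E", "D", "K", "R"))
  expect_setequal(sch$BSR, c("I", "F", "T", "W", "Y", "V"))
  expect_setequal(sch$UFR, c("G", "P"))
  expect_true(all(lengths(sch) > 0))
})

test_that("k-mer rates use overlap counting and sum to one", {
  expect_equal(kmerRates("AAB", 2), c(AA = 0.5, AB = 0.5))
  expect_equal(kmerRates("AAAA", 2), c(AA = 1.0))
  expect_length(kmerRates("AB", 3), 0L)
  set.seed(5)
  for (i in 1:20) {
    w <- paste(sample(LETTERS[1:6], sample(3:12, 1), replace = TRUE),
               collapse = "")
    k <- sample(1:3, 1)
    if (nchar(w) >= k) expect_equal(sum(kmerRates(w, k)), 1)
  }
})

test_that("feature selection screens by rank-sum p, k-mer rules and correlation", {
  set.seed(21)
  n <- 10
  lab <- rep(c(1, 0), each = 5)
  # complete 5v5 separation: exact two-sided rank-sum p = 2/choose(10,5)
  sep <- c(6:10, 1:5) + runif(n, 0, 0.01)
  noise <- rnorm(n)
  tab <- data.frame(sep = sep, sepCopy = sep, noise = noise)
  pExact <- stats::wilcox.test(sep[lab == 1], sep[lab == 0],
                               exact = TRUE)$p.value
  expect_equal(pExact, 2 / choose(10, 5), tolerance = 1e-12)
  sel <- selectFeatures(tab, lab)
  expect_true("sep" %in% sel)
  expect_false("noise" %in% sel)
  expect_false("sepCopy" %in% sel)        # r = 1 with sep -> dropped

  # 2-mer rules: presence frequency > 0.2 AND log2FC > 1.5 required
  mk <- function(fPos, fNeg) c(ifelse(seq_len(5) <= round(fPos * 5), 0.3, 0),
                               ifelse(seq_len(5) <= round(fNeg * 5), 0.3, 0))
  tab2 <- data.frame(kmer_GY = mk(0.4, 0),     # freq .4, FC inf -> kept
                     kmer_AA = mk(0.2, 0),     # freq .2 not > .2 -> dropped
                     kmer_CC = mk(0.8, 0.4))   # log2FC = 1 < 1.5 -> dropped
  sel2 <- selectFeatures(tab2, lab)
  expect_equal(sel2, "kmer_GY")

  expect_warning(selectFeatures(data.frame(sep = sep, const = rep(1, n)), lab),
                 "constant")
  expect_error(selectFeatures(tab, rep(1, n)), "each class")
})

test_that("dropping an insignificant feature never changes the selection", {
  set.seed(33)
  lab <- rep(c(1, 0), each = 8)
  tab <- data.frame(strong = lab * 3 + rnorm(16, sd = 0.3),
                    weak = rnorm(16),
                    mid = lab * 2 + rnorm(16, sd = 0.8))
  full <- selectFeatures(tab, lab)
  reduced <- selectFeatures(tab[, c("strong", "mid")], lab)
  expect_equal(full, reduced)
})

test_that("pcaSelect picks the smallest k exceeding the variance fraction", {
  set.seed(2)
  # known spectrum: singular values 3, 1, 0.5 -> ratios 9 : 1 : 0.25
  U <- qr.Q(qr(matrix(rnorm(80 * 3), 80)))
  Vm <- qr.Q(qr(matrix(rnorm(9), 3)))
  X <- U %*% diag(c(3, 1, 0.5)) %*% t(Vm)
  X <- scale(X, scale = FALSE)           # already centered up to fp noise
  ratios <- c(9, 1, 0.25) / 10.25
  out85 <- pcaSelect(X, varFrac = 0.85, center = FALSE)
  expect_equal(out85$k, which(cumsum(ratios) > 0.85)[1])
  out95 <- pcaSelect(X, varFrac = 0.95, center = FALSE)
  expect_equal(out95$k, which(cumsum(ratios) > 0.95)[1])
  expect_equal(ncol(out95$projection), out95$k)

  # rank-1 matrix: one component for any threshold below 1
  r1 <- outer(rnorm(20), rnorm(5))
  expect_equal(pcaSelect(r1, 0.99)$k, 1L)

  # k is non-decreasing in the variance fraction
  ks <- vapply(c(0.5, 0.8, 0.9, 0.99),
               function(v) pcaSelect(X, v, center = FALSE)$k, integer(1))
  expect_true(all(diff(ks) >= 0))

  expect_error(pcaSelect(matrix(0, 4, 3), 0.95), "zero-variance")
})

test_that("siteFeatureTable assembles flank features from FASTA sequences", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">KIN001 test kinase", "MKSTPGGYAADDKRH",
               ">KIN002", "MMSSTTYYAACCGG"), f)
  seqs <- readKinaseFasta(f)
  expect_equal(names(seqs), c("KIN001", "KIN002"))
  sites <- data.frame(accession = c("KIN001", "KIN002"),
                      residue = c("S", "Y"), position = c(3L, 7L),
                      label = c(1, 0))
  tab <- siteFeatureTable(seqs, sites, w = 7)
  expect_equal(rownames(tab), c("KIN001:S3", "KIN002:Y7"))
  expect_true(all(c("Small", "Aromatic") %in% colnames(tab)))
  expect_true(any(grepl("^kmer_", colnames(tab))))
  expect_false(anyNA(tab))
  expect_error(siteFeatureTable(seqs, data.frame(accession = "NOPE",
                                                 residue = "S",
                                                 position = 1L)),
               "no sequence")
})
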