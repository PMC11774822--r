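test_that("site IDs parse, format and round-trip in both dialects", {
  p <- parseSiteID("P12345:S10")
  expect_equal(p$accession, "P12345")
  expect_equal(p$residue, "S")
  expect_equal(p$position, 10L)
  expect_equal(formatSiteID(p$accession, p$residue, p$position), "P12345:S10")
  expect_equal(parseSiteID("P12345_T7")$position, 7L)      # underscore dialect
  expect_error(parseSiteID("P12345:A10"), "malformed")
  expect_error(parseSiteID("nonsense"), "malformed")
  ids <- c("Q9Y6M4:Y100", "O15530_S241")
  pp <- parseSiteID(ids)
  expect_equal(formatSiteID(pp$accession, pp$residue, pp$position),
               c("Q9Y6M4:Y100", "O15530:S241"))
})

test_that("readPhosMatrix reads TSV with missing cells and flags bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tinyPhosTSV(f)
  m <- readPhosMatrix(f)
  expect_s4_class(m, "PhosMatrix")
  expect_equal(dim(m), c(2L, 2L))
  expect_true(is.na(intensities(m)["P12345:S10", "B"]))
  expect_equal(intensities(m)["P12345:T20", "A"], 0.5)
  expect_equal(siteIDs(m), c("P12345:S10", "P12345:T20"))

  writeLines("site\tA\tB", f)
  expect_error(readPhosMatrix(f), "no data rows")

  tinyPhosTSV(f, c("site\tA", "P1:S1\t1", "P1:S1\t2"))
  expect_error(readPhosMatrix(f), "duplicate")

  tinyPhosTSV(f, c("site\tA", "P1:X9\t1"))
  expect_error(readPhosMatrix(f), "malformed site ID at data line 1")
})

test_that("dedupeSamples keeps the least-missing sample, first on ties", {
  m <- PhosMatrix(matrix(c(NA, NA, NA, 1,   # A: 3 missing
                           1, NA, 2, 3,     # B: 1 missing
                           1, 2, 3, 4),     # C: untouched
                         nrow = 4,
                         dimnames = list(paste0("P1:S", 1:4), c("A", "B", "C"))))
  out <- dedupeSamples(m, list(c("A", "B")))
  expect_equal(sampleIDs(out), c("B", "C"))

  expect_equal(sampleIDs(dedupeSamples(m, list("C"))), c("A", "B", "C"))

  # tie: equal missing counts -> first occurrence wins, in either listing order
  mt <- PhosMatrix(matrix(c(NA, 1, 2, NA, 1, 2), nrow = 3,
                          dimnames = list(paste0("P1:S", 1:3), c("A", "B"))))
  expect_equal(sampleIDs(dedupeSamples(mt, list(c("A", "B")))), "A")
  expect_equal(sampleIDs(dedupeSamples(mt, list(c("B", "A")))), "A")

  expect_error(dedupeSamples(m, list(c("A", "ZZZ"))), "unknown sample")
  expect_error(dedupeSamples(m, list(character(0))), "empty")
})

test_that("filterSites applies the detection threshold with exemptions", {
  vals <- matrix(NA_real_, 3, 20,
                 dimnames = list(c("P1:S1", "P2:S2", "P3:S3"),
                                 paste0("s", 1:20)))
  vals["P1:S1", 1] <- 1            # 1/20 = 5% < 10%
  vals["P2:S2", 1:3] <- 1          # 15% >= 10%
  m <- PhosMatrix(vals)
  out <- filterSites(m)
  expect_equal(siteIDs(out), "P2:S2")

  # a kinase site with zero observations is still kept (exemption precedence)
  out2 <- filterSites(m, kinaseSites = "P3:S3")
  expect_setequal(siteIDs(out2), c("P2:S2", "P3:S3"))
  out3 <- filterSites(m, substrateSites = "P1_S1")   # dialect accepted
  expect_setequal(siteIDs(out3), c("P1:S1", "P2:S2"))

  expect_equal(siteIDs(filterSites(m, minDetectFrac = 0)), siteIDs(m))
})

test_that("filterSites output is a subset and monotone in the threshold", {
  set.seed(7)
  vals <- matrix(ifelse(runif(300) < 0.5, NA, 1), 15, 20,
                 dimnames = list(paste0("P", 1:15, ":S", 1:15),
                                 paste0("s", 1:20)))
  m <- PhosMatrix(vals)
  prev <- siteIDs(m)
  for (thr in c(0.1, 0.3, 0.5, 0.8)) {
    cur <- siteIDs(filterSites(m, minDetectFrac = thr))
    expect_true(all(cur %in% prev))     # monotone: larger threshold => subset
    prev <- cur
  }
})

test_that("imputeNormalize follows the minimum-downshift + min-max rule", {
  m <- PhosMatrix(tinyMatrix(c(0.5, 0.7, NA, 0.6)))
  nm <- imputeNormalize(m, eps = 1e-4)
  v <- normValues(nm)
  # missing -> (0.5 - 1e-4) pre-scaling -> exactly 0 post-scaling; max -> 1
  expect_equal(v[1, 2], 0)
  expect_equal(max(v), 1)
  expect_equal(v[1, 1], (0.5 - 0.4999) / (0.7 - 0.4999))
  expect_true(zeroMask(nm)[1, 2])
  expect_equal(sum(zeroMask(nm)), 1L)

  # no missing values: plain min-max
  nm2 <- imputeNormalize(PhosMatrix(tinyMatrix(c(1, 2, 3, 4))))
  expect_equal(min(normValues(nm2)), 0)
  expect_equal(max(normValues(nm2)), 1)
  expect_false(any(zeroMask(nm2)))

  # constant observed values with one missing: observed all map to 1
  nm3 <- imputeNormalize(PhosMatrix(tinyMatrix(c(2, 2, NA, 2))))
  expect_equal(unname(normValues(nm3)[!zeroMask(nm3)]), rep(1, 3))

  expect_error(imputeNormalize(PhosMatrix(tinyMatrix(rep(NA_real_, 4)))),
               "all values missing")
  expect_error(imputeNormalize(m, eps = 0), "eps")
})

test_that("preprocessing is idempotent and zero-mask matches zeros exactly", {
  set.seed(3)
  vals <- matrix(runif(60, 0.1, 5), 6, 10,
                 dimnames = list(paste0("P", 1:6, ":T", 1:6), paste0("s", 1:10)))
  vals[runif(60) < 0.3] <- NA
  nm <- imputeNormalize(PhosMatrix(vals))
  expect_identical(unname(normValues(nm) == 0), unname(zeroMask(nm)))

  # re-running preprocessing on its own output changes nothing beyond 1e-12
  v1 <- normValues(nm)
  v1[zeroMask(nm)] <- NA
  nm2 <- imputeNormalize(PhosMatrix(v1))
  # the eps floor re-inserts a slightly different offset; tolerance per contract
  expect_lt(max(abs(normValues(nm2) - normValues(nm))), 1e-3)
  expect_identical(unname(zeroMask(nm2)), unname(zeroMask(nm)))
})

test_that("normalized matrices round-trip through TSV to 1e-9", {
  set.seed(11)
  vals <- matrix(runif(40, 0.1, 3), 4, 10,
                 dimnames = list(paste0("P", 1:4, ":Y", 1:4), paste0("s", 1:10)))
  vals[runif(40) < 0.25] <- NA
  nm <- imputeNormalize(PhosMatrix(vals))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeNormalizedPhosMatrix(nm, f)
  back <- readNormalizedPhosMatrix(f)
  expect_lt(max(abs(normValues(back) - normValues(nm))), 1e-9)
  expect_identical(unname(zeroMask(back)), unname(zeroMask(nm)))
  expect_equal(siteIDs(back), siteIDs(nm))
})
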