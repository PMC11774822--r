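#' Read a phospho-MS intensity matrix from TSV
#'
#' Expects a tab-separated file whose first column holds site IDs
#' (`"ACC:R<pos>"`, underscore dialect accepted) and whose remaining columns
#' are samples, with missing intensities encoded as an empty field or one of
#' `na` tokens.
#'
#' @param path file path.
#' @param na character vector of missing-value tokens (besides the empty
#'   field).
#' @return a [PhosMatrix]; row and column order follow the file.
#' @export
readPhosMatrix <- function(path, na = c("NA", "NaN", "")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = na, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("no data rows in ", path)
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(!is.na(as.matrix(df[, -1L, drop = FALSE])) & is.na(vals),
               arr.ind = TRUE)
  if (length(bad))
    stop("non-numeric value at data line ", bad[1L, 1L], " of ", path)
  pm <- try(PhosMatrix(vals, siteIDs = ids, sampleIDs = colnames(vals)),
            silent = TRUE)
  if (inherits(pm, "try-error")) {
    # re-raise parse failures naming the offending line
    parsed <- vapply(ids, function(id)
      !inherits(try(parseSiteID(id), silent = TRUE), "try-error"),
      logical(1))
    if (any(!parsed))
      stop("malformed site ID at data line ", which(!parsed)[1L], ": ",
           ids[which(!parsed)[1L]])
    stop(attr(pm, "condition")$message)
  }
  pm
}

#' Write / read normalized matrices (TSV round trip)
#'
#' `writeNormalizedPhosMatrix` writes the `values` assay as TSV with full
#' precision; because `0 == originally missing` is a class invariant, the
#' zero mask is implied and restored on read.
#'
#' @param x a [NormalizedPhosMatrix].
#' @param path file path.
#' @return `readNormalizedPhosMatrix` returns a [NormalizedPhosMatrix].
#' @export
writeNormalizedPhosMatrix <- function(x, path) {
  stopifnot(is(x, "NormalizedPhosMatrix"))
  v <- normValues(x)
  df <- data.frame(site = rownames(v), format(v, digits = 17, trim = TRUE,
                                              scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("site", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNormalizedPhosMatrix
#' @export
readNormalizedPhosMatrix <- function(path) {
  pm <- readPhosMatrix(path, na = character(0))
  v <- intensities(pm)
  NormalizedPhosMatrix(v, zeroMask = v == 0,
                       siteIDs = rownames(v), sampleIDs = colnames(v))
}

#' Collapse duplicate samples
#'
#' Within each group of replicate sample IDs, the sample with the fewest
#' missing cells is retained; ties keep the earliest group member in matrix
#' column order. Ungrouped samples pass through unchanged.
#'
#' @param m a [PhosMatrix].
#' @param duplicateGroups list of character vectors, each a group of sample
#'   IDs considered duplicates of one another.
#' @return a [PhosMatrix] with one column per group.
#' @export
dedupeSamples <- function(m, duplicateGroups) {
  stopifnot(is(m, "PhosMatrix"))
  samp <- sampleIDs(m)
  miss <- missingCount(m)
  drop <- character(0)
  for (g in duplicateGroups) {
    if (length(g) == 0L) stop("empty duplicate group")
    unknown <- setdiff(g, samp)
    if (length(unknown))
      stop("duplicate group references unknown sample(s): ",
           paste(unknown, collapse = ", "))
    g <- samp[samp %in% g]                 # matrix order => first-occurrence tie-break
    keep <- g[which.min(miss[g])]
    drop <- c(drop, setdiff(g, keep))
  }
  m[, setdiff(samp, drop)]
}

#' Detection filtering of phosphosites
#'
#' Keeps a site if it lies on a kinase, is a (known or predicted) substrate
#' site, or is detected in at least `minDetectFrac` of the samples.
#'
#' @param m a [PhosMatrix].
#' @param kinaseSites,substrateSites character vectors of site IDs exempt
#'   from the detection threshold.
#' @param minDetectFrac minimum fraction of samples with an observed value
#'   (default 0.10).
#' @return a [PhosMatrix] with the retained sites, input order preserved.
#' @export
filterSites <- function(m, kinaseSites = character(0),
                        substrateSites = character(0),
                        minDetectFrac = 0.10) {
  stopifnot(is(m, "PhosMatrix"),
            minDetectFrac >= 0, minDetectFrac <= 1)
  canon <- function(ids) if (length(ids)) {
    p <- parseSiteID(ids); formatSiteID(p$accession, p$residue, p$position)
  } else character(0)
  exempt <- union(canon(kinaseSites), canon(substrateSites))
  detFrac <- rowMeans(!is.na(intensities(m)))
  keep <- siteIDs(m) %in% exempt | detFrac >= minDetectFrac
  m[keep, ]
}

#' Impute missing values and min-max normalize to \[0, 1\]
#'
#' Missing cells are set to (global observed minimum − `eps`), then the whole
#' matrix is min-max scaled so originally-missing cells map to exactly 0 and
#' the global maximum to 1.
#'
#' @param m a [PhosMatrix].
#' @param eps positive offset below the observed minimum (default `1e-4`).
#' @return a [NormalizedPhosMatrix]; its `zeroMask` records original
#'   missingness.
#' @export
imputeNormalize <- function(m, eps = 1e-4) {
  stopifnot(is(m, "PhosMatrix"))
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  v <- intensities(m)
  miss <- is.na(v)
  if (all(miss)) stop("all values missing; nothing to normalize")
  lo <- min(v, na.rm = TRUE) - if (any(miss)) eps else 0
  v[miss] <- lo
  hi <- max(v)
  rng <- hi - lo
  v <- if (rng > 0) (v - lo) / rng else v * 0 + as.numeric(!miss)
  v[miss] <- 0                        # exact zero regardless of rounding
  NormalizedPhosMatrix(v, zeroMask = miss,
                       siteIDs = siteIDs(m), sampleIDs = sampleIDs(m))
}
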