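#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Phosphosite identifiers
#'
#' A phosphosite is identified by a protein accession, a phosphorylatable
#' residue (S, T or Y) and a 1-based position within the protein sequence.
#' The canonical string form is \code{"ACC:R<pos>"} (e.g. \code{"P12345:S10"});
#' the underscore dialect \code{"ACC_R<pos>"} is accepted on parsing.
#'
#' @param x character vector of site-ID strings.
#' @return \code{parseSiteID} returns a data.frame with columns
#'   \code{accession}, \code{residue}, \code{position};
#'   \code{formatSiteID} returns the canonical character form.
#' @examples
#' parseSiteID("P12345:S10")
#' formatSiteID("P12345", "S", 10)
#' @export
parseSiteID <- function(x) {
  x <- as.character(x)
  norm <- sub("_(?=[STY][0-9]+$)", ":", x, perl = TRUE)
  m <- regmatches(norm, regexec("^([A-Za-z0-9.-]+):([STY])([0-9]+)$", norm))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed site ID(s): ", paste(x[bad], collapse = ", "),
         " (expected 'ACC:R<pos>' with R in S/T/Y)")
  }
  acc <- vapply(m, `[`, character(1), 2L)
  res <- vapply(m, `[`, character(1), 3L)
  pos <- as.integer(vapply(m, `[`, character(1), 4L))
  if (any(pos < 1L)) stop("site position must be >= 1")
  data.frame(accession = acc, residue = res, position = pos,
             stringsAsFactors = FALSE)
}

#' @rdname parseSiteID
#' @param accession,residue,position site-ID components (vectorized).
#' @export
formatSiteID <- function(accession, residue, position) {
  stopifnot(all(residue %in% c("S", "T", "Y")), all(position >= 1))
  paste0(accession, ":", residue, position)
}

#' Container for raw phospho-MS intensity matrices
#'
#' `PhosMatrix` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"intensity"` assay holding non-negative site-by-sample intensities,
#' `NA` marking missing (undetected) cells. Row names are canonical site IDs
#' and `rowData` carries the parsed accession/residue/position.
#'
#' `NormalizedPhosMatrix` holds the preprocessed matrix: a `"values"` assay in
#' \[0, 1\] where 0 corresponds to originally-missing cells, and a logical
#' `"zeroMask"` assay recording that original missingness. When at least one
#' cell was missing, `value == 0` and the mask coincide exactly (the imputed
#' floor lies below every observed value); a fully observed matrix scales
#' its observed minimum to 0 with an all-`FALSE` mask.
#'
#' @param values numeric site-by-sample matrix (`NA` = missing for
#'   `PhosMatrix`; in \[0,1\] for `NormalizedPhosMatrix`).
#' @param siteIDs character vector of site IDs (default: rownames of
#'   `values`).
#' @param sampleIDs character vector of sample IDs (default: colnames).
#' @param zeroMask logical matrix, `TRUE` where the original value was
#'   missing.
#' @return A `PhosMatrix` or `NormalizedPhosMatrix` object.
#' @examples
#' m <- matrix(c(1, NA, 3, 4), 2, 2,
#'             dimnames = list(c("P1:S5", "P1:T9"), c("a", "b")))
#' pm <- PhosMatrix(m)
#' siteIDs(pm)
#' @aliases PhosMatrix-class NormalizedPhosMatrix-class
#' @exportClass PhosMatrix
setClass("PhosMatrix", contains = "SummarizedExperiment")

#' @rdname PhosMatrix
#' @exportClass NormalizedPhosMatrix
setClass("NormalizedPhosMatrix", contains = "SummarizedExperiment")

.makePhosSE <- function(values, siteIDs, sampleIDs, extra = list()) {
  values <- as.matrix(values)
  if (is.null(siteIDs)) siteIDs <- rownames(values)
  if (is.null(sampleIDs)) sampleIDs <- colnames(values)
  if (is.null(siteIDs)) stop("site IDs required (argument or rownames)")
  if (is.null(sampleIDs)) sampleIDs <- paste0("sample", seq_len(ncol(values)))
  parsed <- parseSiteID(siteIDs)
  canon <- formatSiteID(parsed$accession, parsed$residue, parsed$position)
  if (anyDuplicated(canon))
    stop("duplicate site ID(s): ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "))
  dimnames(values) <- list(canon, sampleIDs)
  assays <- c(list(values), extra)
  for (i in seq_along(assays)) dimnames(assays[[i]]) <- dimnames(values)
  SummarizedExperiment(assays = assays,
                       rowData = DataFrame(parsed, row.names = canon))
}

#' @rdname PhosMatrix
#' @export
PhosMatrix <- function(values, siteIDs = NULL, sampleIDs = NULL) {
  se <- .makePhosSE(values, siteIDs, sampleIDs)
  names(SummarizedExperiment::assays(se)) <- "intensity"
  new("PhosMatrix", se)
}

#' @rdname PhosMatrix
#' @export
NormalizedPhosMatrix <- function(values, zeroMask = NULL, siteIDs = NULL,
                                 sampleIDs = NULL) {
  if (is.null(zeroMask)) zeroMask <- as.matrix(values) == 0
  zeroMask <- as.matrix(zeroMask)
  storage.mode(zeroMask) <- "logical"
  se <- .makePhosSE(values, siteIDs, sampleIDs, extra = list(zeroMask))
  names(SummarizedExperiment::assays(se)) <- c("values", "zeroMask")
  new("NormalizedPhosMatrix", se)
}

setValidity("PhosMatrix", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!"intensity" %in% names(a)) return("missing 'intensity' assay")
  v <- a[["intensity"]]
  if (!is.numeric(v)) return("intensities must be numeric")
  obs <- v[!is.na(v)]
  if (any(!is.finite(obs))) return("observed intensities must be finite")
  if (any(obs < 0)) return("intensities must be non-negative")
  if (anyDuplicated(rownames(object))) return("duplicate site IDs")
  TRUE
})

setValidity("NormalizedPhosMatrix", function(object) {
  a <- SummarizedExperiment::assays(object)
  if (!all(c("values", "zeroMask") %in% names(a)))
    return("need 'values' and 'zeroMask' assays")
  v <- a[["values"]]; z <- a[["zeroMask"]]
  if (any(!is.finite(v))) return("values must be finite")
  if (any(v < 0 | v > 1)) return("values must lie in [0, 1]")
  if (!is.logical(z)) return("zeroMask must be logical")
  # Masked (originally missing) cells must be exactly 0. The converse
  # (0 => masked) holds whenever the matrix had any missing cell -- the
  # imputed floor sits below every observed value -- but a fully observed
  # matrix legitimately min-max-scales its observed minimum to 0.
  if (any(v[z] != 0))
    return("zeroMask cells must hold the value 0")
  if (any(z) && !identical(unname(v == 0), unname(z)))
    return("with missing cells present, value 0 must mean originally missing")
  TRUE
})

#' Accessors for phospho-MS containers
#'
#' @param x a [PhosMatrix] or [NormalizedPhosMatrix].
#' @return `siteIDs`/`sampleIDs`: character vectors; `intensities`: the raw
#'   numeric matrix with `NA` for missing; `normValues`: the \[0,1\] matrix;
#'   `zeroMask`: logical matrix of original missingness; `missingCount`:
#'   integer per-sample count of missing cells.
#' @examples
#' m <- matrix(c(1, NA, 3, 4), 2, 2,
#'             dimnames = list(c("P1:S5", "P1:T9"), c("a", "b")))
#' missingCount(PhosMatrix(m))
#' @name phos-accessors
NULL

#' @rdname phos-accessors
#' @export
siteIDs <- function(x) rownames(x)

#' @rdname phos-accessors
#' @export
sampleIDs <- function(x) colnames(x)

#' @rdname phos-accessors
#' @export
intensities <- function(x) assay(x, "intensity")

#' @rdname phos-accessors
#' @export
normValues <- function(x) assay(x, "values")

#' @rdname phos-accessors
#' @export
zeroMask <- function(x) assay(x, "zeroMask")

#' @rdname phos-accessors
#' @export
missingCount <- function(x) {
  if (is(x, "NormalizedPhosMatrix")) colSums(zeroMask(x))
  else colSums(is.na(intensities(x)))
}

setMethod("show", "PhosMatrix", function(object) {
  v <- intensities(object)
  cat(sprintf("PhosMatrix: %d sites x %d samples (%.1f%% missing)\n",
              nrow(v), ncol(v), 100 * mean(is.na(v))))
  callNextMethod()
})

setMethod("show", "NormalizedPhosMatrix", function(object) {
  v <- normValues(object)
  cat(sprintf(
    "NormalizedPhosMatrix: %d sites x %d samples (%.1f%% originally missing)\n",
    nrow(v), ncol(v), 100 * mean(zeroMask(object))))
  callNextMethod()
})
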