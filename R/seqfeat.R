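#' Amino-acid grouping schemes for flank composition features
#'
#' Seventeen physicochemical/structural residue groups used to summarize the
#' composition of sequence windows flanking phosphosites: ambiguous pairs
#' (Asx, Glx, Xle), charge classes, aromatic/aliphatic, size, hydropathy,
#' polarity, and secondary-structure propensity classes (alpha-helix,
#' beta-sheet, reverse-turn and unfolding-prone residues).
#'
#' @return named list of character vectors of one-letter residue codes.
#' @examples
#' aaGroupScheme()$Aromatic
#' @export
aaGroupScheme <- function() {
  list(
    Asx = c("D", "N"),
    Glx = c("E", "Q"),
    Xle = c("I", "L"),
    PositivelyCharged = c("K", "R", "H"),
    NegativelyCharged = c("D", "E"),
    Uncharged = c("N", "C", "Q", "S", "T", "Y"),
    Aromatic = c("F", "W", "Y", "H"),
    Aliphatic = c("V", "I", "L", "M"),
    Small = c("P", "G", "A", "S"),
    Hydrophilic = c("S", "T", "H", "N", "Q", "E", "D", "K", "R"),
    Hydrophobic = c("V", "I", "L", "F", "W", "Y", "M"),
    Polar = c("R", "N", "D", "C", "Q", "E", "H", "K", "S", "T", "Y"),
    Nonpolar = c("A", "G", "I", "L", "M", "F", "P", "W", "V"),
    AHR = c("A", "C", "Q", "E", "H", "L", "K", "M"),
    BSR = c("I", "F", "T", "W", "Y", "V"),
    RTR = c("N", "D", "G", "P", "S"),
    UFR = c("G", "P")
  )
}

#' Extract the sequence window flanking a site
#'
#' Returns the `+/- w` residue window around `position`, truncated at the
#' protein termini (no padding). `centerOffset` is the 1-based index of the
#' site residue within the window; `effectiveLength` the realized window
#' length.
#'
#' @param sequence protein sequence (single string).
#' @param position 1-based site position.
#' @param w half-window width in residues (7 for composition/k-mer features,
#'   30 for language-model input windows).
#' @return list with `window`, `effectiveLength`, `centerOffset`, `residue`.
#' @examples
#' extractFlank("MKSTP", 3, 2)
#' @export
extractFlank <- function(sequence, position, w = 7L) {
  sequence <- as.character(sequence)
  L <- nchar(sequence)
  if (position < 1L || position > L)
    stop("position ", position, " out of range 1..", L)
  from <- max(1L, position - w)
  to <- min(L, position + w)
  win <- substr(sequence, from, to)
  list(window = win,
       effectiveLength = nchar(win),
       centerOffset = position - from + 1L,
       residue = substr(sequence, position, position))
}

#' Residue-group composition of a window
#'
#' Fraction of window residues (center included) belonging to each group.
#' Groups overlap, so fractions need not sum to 1. Residue letters outside
#' the 20 standard codes count toward no group (with a warning).
#'
#' @param window a window string or the list from [extractFlank()].
#' @param scheme named list of groups; default [aaGroupScheme()].
#' @return named numeric vector of fractions in \[0, 1\].
#' @export
groupComposition <- function(window, scheme = aaGroupScheme()) {
  win <- if (is.list(window)) window$window else as.character(window)
  if (!nzchar(win)) stop("empty window")
  letters_ <- strsplit(win, "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (any(!letters_ %in% std))
    warning("non-standard residue letter(s) ignored: ",
            paste(unique(letters_[!letters_ %in% std]), collapse = ""))
  vapply(scheme, function(g) mean(letters_ %in% g), numeric(1))
}

#' Sliding-window k-mer occurrence rates
#'
#' Scans the window with a stride-1 sliding window of size `k`; each k-mer's
#' rate is its count divided by the number of window placements
#' (`effectiveLength - k + 1`), so rates sum to 1.
#'
#' @param window window string or [extractFlank()] result.
#' @param k k-mer size (>= 1).
#' @return named numeric vector of rates (empty when the window is shorter
#'   than `k`).
#' @examples
#' kmerRates("AAAB", 2)
#' @export
kmerRates <- function(window, k = 2L) {
  win <- if (is.list(window)) window$window else as.character(window)
  stopifnot(k >= 1L)
  n <- nchar(win)
  if (n < k) return(setNames(numeric(0), character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(win, starts, starts + k - 1L)
  tab <- table(kmers)
  setNames(as.numeric(tab) / length(starts), names(tab))
}

#' Build a per-site feature table from sequences
#'
#' Convenience wrapper: for each site, extracts the `+/- w` flank from its
#' protein sequence and assembles group-composition fractions plus 2-mer
#' presence/rate columns (named `kmer_<XY>`).
#'
#' @param sequences named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences keyed by accession.
#' @param sites data.frame with columns `accession`, `position` (and
#'   optionally `label`), or a character vector of site IDs.
#' @param w half-window width (default 7).
#' @param k k-mer size (default 2).
#' @return data.frame of features, rownames = site IDs, plus a `label` column
#'   when provided.
#' @export
siteFeatureTable <- function(sequences, sites, w = 7L, k = 2L) {
  if (methods::is(sequences, "AAStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  if (is.character(sites)) sites <- parseSiteID(sites)
  scheme <- aaGroupScheme()
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    acc <- sites$accession[i]
    if (!acc %in% names(sequences))
      stop("no sequence for accession ", acc)
    fw <- extractFlank(sequences[[acc]], sites$position[i], w)
    c(groupComposition(fw, scheme), kmerRates(fw, k))
  })
  kmerNames <- sort(unique(unlist(lapply(rows, function(r)
    setdiff(names(r), names(scheme))))))
  cols <- c(names(scheme), kmerNames)
  tab <- t(vapply(rows, function(r) {
    out <- setNames(numeric(length(cols)), cols)
    out[names(r)] <- r
    out
  }, numeric(length(cols))))
  colnames(tab) <- c(names(scheme), paste0("kmer_", kmerNames))
  ids <- if (!is.null(sites$residue))
    formatSiteID(sites$accession, sites$residue, sites$position)
  else paste0(sites$accession, ":", sites$position)
  df <- as.data.frame(tab, row.names = make.unique(ids))
  if (!is.null(sites$label)) df$label <- sites$label
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-stage feature selection with correlation de-duplication
#'
#' Implements the screening used for the classical-ML feature sets:
#' \enumerate{
#'   \item non-k-mer features are kept when a two-sided rank-sum
#'     (Mann-Whitney) test between classes gives p < `pThreshold`;
#'   \item k-mer features (columns named `kmer_*`) are kept when the
#'     positive-class presence frequency exceeds `kmerMinFreq` and the
#'     log2 fold change of positive vs negative presence frequency exceeds
#'     `kmerMinLog2FC` (a zero negative frequency counts as infinite fold
#'     change);
#'   \item surviving features are ordered by increasing p-value
#'     (significance) and later features with |Pearson r| > `corrThreshold`
#'     to any already-kept feature are dropped greedily.
#' }
#' Constant features are excluded with a warning.
#'
#' @param table data.frame/matrix of features with a binary `labels` vector.
#' @param labels binary (0/1 or logical) class labels, >= 2 per class.
#' @param pThreshold,kmerMinFreq,kmerMinLog2FC,corrThreshold screening
#'   thresholds (defaults 0.05, 0.2, 1.5, 0.7).
#' @return character vector of selected feature names, in significance order.
#' @export
selectFeatures <- function(table, labels, pThreshold = 0.05,
                           kmerMinFreq = 0.2, kmerMinLog2FC = 1.5,
                           corrThreshold = 0.7) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L || min(tabulate(labels + 1L, 2L)) < 2L)
    stop("need >= 2 samples in each class")
  X <- as.matrix(table[, setdiff(colnames(table), "label"), drop = FALSE])
  pos <- labels == 1L
  isKmer <- grepl("^kmer_", colnames(X))
  keep <- character(0); pvals <- numeric(0)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (stats::sd(x) == 0) {
      warning("constant feature excluded: ", colnames(X)[j])
      next
    }
    if (isKmer[j]) {
      fPos <- mean(x[pos] > 0)
      fNeg <- mean(x[!pos] > 0)
      l2fc <- if (fNeg == 0) Inf else log2(fPos / fNeg)
      if (fPos > kmerMinFreq && l2fc > kmerMinLog2FC) {
        keep <- c(keep, colnames(X)[j])
        # order k-mers after rank-sum features by (1 - fPos) as pseudo-p
        pvals <- c(pvals, 1 + (1 - fPos))
      }
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(x[pos], x[!pos], exact = sum(pos) <= 8 &&
                             sum(!pos) <= 8)$p.value)
      if (is.finite(p) && p < pThreshold) {
        keep <- c(keep, colnames(X)[j])
        pvals <- c(pvals, p)
      }
    }
  }
  if (!length(keep)) return(character(0))
  ord <- order(pvals, match(keep, colnames(X)))
  keep <- keep[ord]
  selected <- character(0)
  for (f in keep) {
    if (!length(selected)) { selected <- f; next }
    r <- abs(stats::cor(X[, f], X[, selected, drop = FALSE]))
    if (all(r <= corrThreshold, na.rm = TRUE)) selected <- c(selected, f)
  }
  selected
}

#' PCA with a cumulative explained-variance cutoff
#'
#' Returns the smallest number of principal components whose cumulative
#' explained-variance ratio exceeds `varFrac`, together with the projection
#' of the rows onto those components.
#'
#' @param matrix numeric matrix (rows = observations).
#' @param varFrac required cumulative variance fraction in (0, 1); default
#'   0.95.
#' @param center,scale. passed to [stats::prcomp()].
#' @return list with `k` (component count), `projection` (rows x k), and
#'   `explained` (variance ratios).
#' @export
pcaSelect <- function(matrix, varFrac = 0.95, center = TRUE, scale. = FALSE) {
  stopifnot(nrow(matrix) >= 2L, ncol(matrix) >= 1L,
            varFrac > 0, varFrac < 1)
  pc <- stats::prcomp(matrix, center = center, scale. = scale.)
  ev <- pc$sdev^2
  if (sum(ev) == 0) stop("zero-variance matrix")
  ratio <- ev / sum(ev)
  k <- which(cumsum(ratio) > varFrac)[1L]
  if (is.na(k)) k <- length(ratio)
  list(k = k, projection = pc$x[, seq_len(k), drop = FALSE],
       explained = ratio)
}

#' Read kinase sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of protein sequences; names are the first
#'   whitespace-delimited token of each header (typically the accession).
#' @export
readKinaseFasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
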