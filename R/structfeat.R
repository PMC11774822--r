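#' Parse a PROSITE pattern
#'
#' Supports the standard PROSITE pattern syntax: dash-separated elements that
#' are literal residues (`K`), alternative sets (`[ST]`), exclusion sets
#' (`{P}`), the wildcard `x`, repeated elements (`x(2)`, `x(2,4)`,
#' `[DE](2)`), and the `<`/`>` N-/C-terminal anchors. A trailing period is
#' tolerated.
#'
#' @param patternText pattern string, e.g. `"[LIV]-G-{P}-G-x(2)-[SG]"`.
#' @return object of class `prositePattern`: a list of elements, each with
#'   `allowed` (character vector of permitted letters), `min`, `max` repeat
#'   counts, plus `nAnchor`/`cAnchor` flags.
#' @export
parseProsite <- function(patternText) {
  txt <- gsub("[[:space:]]", "", patternText)
  txt <- sub("\\.$", "", txt)
  nAnchor <- grepl("^<", txt)
  cAnchor <- grepl(">$", txt)
  txt <- sub("^<", "", txt); txt <- sub(">$", "", txt)
  if (!nzchar(txt)) stop("empty pattern")
  parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  elems <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    m <- regexec("^(\\[[A-Z]+\\]|\\{[A-Z]+\\}|[A-Zx])(\\((\\d+)(,(\\d+))?\\))?$",
                 p)[[1]]
    if (m[1] == -1)
      stop("PROSITE syntax error in element ", i, ": '", p, "'")
    g <- regmatches(p, regexec(
      "^(\\[[A-Z]+\\]|\\{[A-Z]+\\}|[A-Zx])(\\((\\d+)(,(\\d+))?\\))?$", p))[[1]]
    core <- g[2]
    lo <- if (nzchar(g[4])) as.integer(g[4]) else 1L
    hi <- if (nzchar(g[6])) as.integer(g[6]) else lo
    if (lo > hi) stop("invalid repeat range in element ", i, ": '", p, "'")
    allowed <- if (core == "x") aa
      else if (startsWith(core, "[")) strsplit(gsub("[][]", "", core), "")[[1]]
      else if (startsWith(core, "{"))
        setdiff(aa, strsplit(gsub("[{}]", "", core), "")[[1]])
      else core
    list(allowed = allowed, min = lo, max = hi, text = p)
  })
  structure(list(elements = elems, nAnchor = nAnchor, cAnchor = cAnchor,
                 text = patternText),
            class = "prositePattern")
}

#' @export
print.prositePattern <- function(x, ...) {
  cat("PROSITE pattern:", x$text, "-", length(x$elements), "elements\n")
  invisible(x)
}

# All matches of elements[k..] beginning at sequence position pos.
# Each match is list(ep = per-element first-residue position (NA for
# zero-length repeats), after = first position past the match).
.matchFrom <- function(chars, elems, k, pos) {
  if (k > length(elems))
    return(list(list(ep = integer(0), after = pos)))
  e <- elems[[k]]
  out <- list()
  for (rep_ in e$min:e$max) {
    if (rep_ > 0L) {
      if (pos + rep_ - 1L > length(chars)) next
      seg <- chars[pos:(pos + rep_ - 1L)]
      if (any(!seg %in% e$allowed)) next
    }
    rest <- .matchFrom(chars, elems, k + 1L, pos + rep_)
    for (r in rest)
      out[[length(out) + 1L]] <-
        list(ep = c(if (rep_ > 0L) pos else NA_integer_, r$ep),
             after = r$after)
  }
  out
}

#' Scan a sequence with a PROSITE pattern
#'
#' Reports every distinct match span (1-based, inclusive); variable-length
#' wildcards are expanded over all lengths, and matches differing only in
#' internal wildcard lengths but sharing a span are collapsed to one span
#' (the expansion with the shortest elements is kept for element positions).
#'
#' @param pattern a pattern string or [parseProsite()] result.
#' @param sequence protein sequence string.
#' @return data.frame with columns `start`, `end`, and an `elementPos` list
#'   column (integer vector per match: first-residue position of each
#'   pattern element; `NA` for zero-length repeats). Zero rows when there is
#'   no match.
#' @examples
#' scanProsite("K-x(2)-D", "AKGGD")
#' @export
scanProsite <- function(pattern, sequence) {
  if (is.character(pattern)) pattern <- parseProsite(pattern)
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  if (!length(chars)) stop("empty sequence")
  starts <- if (pattern$nAnchor) 1L else seq_along(chars)
  hits <- list()
  for (s in starts) {
    ms <- .matchFrom(chars, pattern$elements, 1L, s)
    for (m in ms) {
      endpos <- m$after - 1L
      if (endpos < s) next                       # all-zero-length match
      if (pattern$cAnchor && endpos != length(chars)) next
      hits[[length(hits) + 1L]] <- list(start = s, end = endpos, ep = m$ep)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      elementPos = I(list())))
  key <- vapply(hits, function(h) paste(h$start, h$end), character(1))
  hits <- hits[!duplicated(key)]
  ord <- order(vapply(hits, `[[`, integer(1), "start"),
               vapply(hits, `[[`, integer(1), "end"))
  hits <- hits[ord]
  data.frame(start = vapply(hits, `[[`, integer(1), "start"),
             end = vapply(hits, `[[`, integer(1), "end"),
             elementPos = I(lapply(hits, `[[`, "ep")))
}

#' Locate a conserved residue via a signature match
#'
#' Finds the first match of `pattern` in `sequence` and returns the sequence
#' position of the requested pattern element (1-based element index; e.g. the
#' terminal conserved K of the ATP-binding signature, or the catalytic D of
#' the active-site signatures).
#'
#' @param sequence protein sequence string.
#' @param pattern PROSITE pattern string or [parseProsite()] object.
#' @param elementIndex 1-based index of the pattern element whose position is
#'   wanted; negative values count from the end (-1 = last element).
#' @return integer position, or `NA_integer_` with attribute
#'   `reason = "signature absent"` when the pattern does not match.
#' @export
locateConserved <- function(sequence, pattern, elementIndex = -1L) {
  if (is.character(pattern)) pattern <- parseProsite(pattern)
  hits <- scanProsite(pattern, sequence)
  if (!nrow(hits))
    return(structure(NA_integer_, reason = "signature absent"))
  ep <- hits$elementPos[[1L]]
  n <- length(pattern$elements)
  idx <- if (elementIndex < 0L) n + 1L + elementIndex else elementIndex
  if (idx < 1L || idx > n) stop("elementIndex out of range")
  ep[idx]
}

#' Read C-alpha coordinates from a PDB file
#'
#' Keeps one C-alpha per residue (first altloc wins); other atoms are
#' ignored. Suited to AlphaFold-style single-chain models where PDB residue
#' numbers equal sequence positions; `offset` shifts residue numbering when
#' they do not.
#'
#' @param path PDB file path.
#' @param offset integer added to PDB residue numbers (default 0).
#' @return object of class `structureModel`: list with `coords` (n x 3
#'   matrix, rownames `"<chain>:<resno>"`), `chain`, `resno`, `source`.
#' @export
readStructure <- function(path, offset = 0L) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sel <- pdb$atom$elety == "CA" & pdb$atom$type == "ATOM"
  at <- pdb$atom[sel, , drop = FALSE]
  if (!nrow(at)) stop("no CA ATOM records in ", path)
  key <- paste0(at$chain, ":", at$resno)
  at <- at[!duplicated(key), , drop = FALSE]     # first altloc kept
  coords <- as.matrix(at[, c("x", "y", "z")])
  resno <- at$resno + offset
  rownames(coords) <- paste0(at$chain, ":", resno)
  structure(list(coords = coords, chain = at$chain, resno = resno,
                 source = path),
            class = "structureModel")
}

#' @export
print.structureModel <- function(x, ...) {
  cat("structureModel:", nrow(x$coords), "CA atoms from", x$source, "\n")
  invisible(x)
}

#' Sequence or spatial distance from a site to a target residue
#'
#' @param sitePos 1-based site position.
#' @param targetPos 1-based target residue position (e.g. a conserved K/D).
#' @param mode `"sequence"` (|difference| in residues) or `"spatial"`
#'   (Euclidean C-alpha distance in Angstrom).
#' @param structure a [readStructure()] model (required for spatial mode).
#' @param chain chain ID used to look up coordinates (default `"A"`).
#' @return numeric distance.
#' @export
residueDistance <- function(sitePos, targetPos,
                            mode = c("sequence", "spatial"),
                            structure = NULL, chain = "A") {
  mode <- match.arg(mode)
  if (mode == "sequence") return(abs(sitePos - targetPos))
  if (is.null(structure)) stop("spatial mode requires a structure")
  k1 <- paste0(chain, ":", sitePos)
  k2 <- paste0(chain, ":", targetPos)
  for (k in c(k1, k2)) if (!k %in% rownames(structure$coords))
    stop("residue ", k, " absent from structure")
  sqrt(sum((structure$coords[k1, ] - structure$coords[k2, ])^2))
}

#' Load an externally computed structural-feature table
#'
#' Ingests per-site surface/burial descriptors computed by an external
#' structural-analysis program: backbone accessible-surface-area sum
#' (`ASA_backbone_sum`), mean protrusion index (`CX_total_mean`) and mean
#' depth index (`DPX_total_mean`).
#'
#' @param path TSV with columns `site`, `ASA_backbone_sum`, `CX_total_mean`,
#'   `DPX_total_mean`; extra columns are ignored with a warning.
#' @return data.frame keyed by canonical site ID (rownames).
#' @export
loadStructuralTable <- function(path) {
  need <- c("site", "ASA_backbone_sum", "CX_total_mean", "DPX_total_mean")
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!all(need %in% colnames(df)))
    stop("structural table must have columns: ", paste(need, collapse = ", "))
  extra <- setdiff(colnames(df), need)
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  p <- parseSiteID(df$site)
  ids <- formatSiteID(p$accession, p$residue, p$position)
  if (anyDuplicated(ids))
    stop("duplicate site row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (cc in need[-1]) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(is.na(v)))
      stop("malformed numeric value in column ", cc, " at data line ",
           which(is.na(v))[1L])
    df[[cc]] <- v
  }
  out <- df[, need[-1]]
  rownames(out) <- ids
  out
}

#' Activation-loop membership
#'
#' @param position 1-based site position.
#' @param intervals matrix or data.frame of 1-based inclusive
#'   `[start, end]` activation-loop intervals (columns `start`, `end`).
#' @return logical: `TRUE` iff the position lies inside any interval
#'   (boundaries included).
#' @export
inALoop <- function(position, intervals) {
  if (is.null(intervals) || NROW(intervals) == 0L) return(FALSE)
  iv <- as.data.frame(intervals)
  stopifnot(all(iv$start <= iv$end))
  any(position >= iv$start & position <= iv$end)
}
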