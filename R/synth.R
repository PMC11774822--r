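# Seeded generators for desk-scale fixtures emulating the real inputs:
# sparse phospho-MS matrices with planted kinase->substrate coupling,
# kinase sequences carrying signature motifs with conserved K/D residues,
# class-separated surrogate sequence embeddings, and helical toy
# structures. Every generator is bit-reproducible under a fixed seed.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Synthetic signature patterns used by the sequence generator
#'
#' Two PROSITE-style patterns planted into every generated kinase: an
#' ATP-binding-like signature whose *last* element is a conserved lysine,
#' and an active-site-like signature whose second element is a conserved
#' aspartate.
#'
#' @return named list of pattern strings (`atp`, `active`).
#' @export
synthSignatures <- function() {
  list(atp = "[LIV]-G-x-G-x(2)-[SG]-K",
       active = "[RH]-D-[LI]-x(2)-N")
}

.instantiate <- function(patternText, seed = NULL) {
  pat <- parseProsite(patternText)
  paste(vapply(pat$elements, function(e) {
    n <- e$min
    paste(sample(e$allowed, n, replace = TRUE), collapse = "")
  }, character(1)), collapse = "")
}

#' Generate a sparse phospho-MS matrix with planted structure
#'
#' Each kinase carries `sitesPerKinase` phosphosites; a fraction of kinases
#' receives a planted "critical" site whose value tracks a per-sample
#' latent kinase activity `a ~ Uniform(0,1)`. The kinase's substrate sites
#' take values `clip01(beta * a + noise)` -- downstream phosphorylation
#' follows kinase activity -- while all other sites are independent noise.
#' Missingness (encoded 0) is applied completely at random at rate
#' `sparsity`; critical sites are additionally left-censored below the
#' detection limit so that their detection status reflects their level.
#'
#' @param nKinases,sitesPerKinase,nSubstrateSites,nSamples problem sizes.
#' @param sparsity missing-cell fraction in (0, 1).
#' @param criticalFrac fraction of kinases given a planted critical site.
#' @param beta coupling strength between kinase activity and substrate
#'   values (default 2, a strong planted effect; 0 = null).
#' @param noiseSD Gaussian noise SD on substrate values (default 0.1).
#' @param siteScaleRange range of the per-site multiplicative abundance
#'   factor (default `c(0.3, 1)`), emulating site-specific abundance and
#'   ionization differences; together with the per-sample activities this
#'   plants low-rank structure. `c(1, 1)` disables it.
#' @param detectionLimit critical-site cells whose value falls below
#'   `detectionLimit * siteScale` are censored to missing (left-censoring at
#'   the detection limit), so detection of a critical site tracks its
#'   phosphorylation level; 0 disables. Other sites stay missing completely
#'   at random.
#' @param seed RNG seed.
#' @return list with `matrix` (a [NormalizedPhosMatrix]), `criticalSites`,
#'   `kinaseSubstrateMap` (kinase accession -> substrate site IDs),
#'   `kinaseSiteMap` (kinase accession -> its own site IDs),
#'   `activities` (kinase x sample latent activities), `siteInfo`.
#' @export
simPhosMatrix <- function(nKinases = 10L, sitesPerKinase = 5L,
                          nSubstrateSites = 100L, nSamples = 40L,
                          sparsity = 0.3, criticalFrac = 0.3, beta = 2,
                          noiseSD = 0.1, siteScaleRange = c(0.3, 1),
                          detectionLimit = 0.15, seed = 1L) {
  if (nSubstrateSites < nKinases)
    stop("need at least one substrate site per kinase")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  clip01 <- function(x) pmin(1, pmax(1e-3, x))
  kin <- sprintf("KIN%03d", seq_len(nKinases))
  samples <- sprintf("S%03d", seq_len(nSamples))
  nCrit <- round(criticalFrac * nKinases)
  critKin <- if (nCrit > 0) kin[seq_len(nCrit)] else character(0)
  activities <- matrix(stats::runif(nKinases * nSamples), nKinases,
                       nSamples, dimnames = list(kin, samples))
  # kinase sites: positions spread along a nominal 300-residue protein
  siteInfo <- do.call(rbind, lapply(seq_len(nKinases), function(i) {
    pos <- sort(sample(15:285, sitesPerKinase))
    data.frame(accession = kin[i],
               residue = sample(c("S", "T", "Y"), sitesPerKinase,
                                replace = TRUE),
               position = pos,
               critical = c(kin[i] %in% critKin,
                            rep(FALSE, sitesPerKinase - 1L)),
               stringsAsFactors = FALSE)
  }))
  siteInfo$site <- formatSiteID(siteInfo$accession, siteInfo$residue,
                                siteInfo$position)
  # substrates: each assigned to one kinase, round-robin
  subAcc <- sprintf("SUB%04d", seq_len(nSubstrateSites))
  subKin <- rep_len(kin, nSubstrateSites)
  subInfo <- data.frame(accession = subAcc,
                        residue = sample(c("S", "T", "Y"),
                                         nSubstrateSites, replace = TRUE),
                        position = sample(5:400, nSubstrateSites,
                                          replace = TRUE),
                        kinase = subKin, stringsAsFactors = FALSE)
  subInfo$site <- formatSiteID(subInfo$accession, subInfo$residue,
                               subInfo$position)
  V <- matrix(0, nrow(siteInfo) + nSubstrateSites, nSamples,
              dimnames = list(c(siteInfo$site, subInfo$site), samples))
  scale_ <- stats::runif(nrow(V), siteScaleRange[1], siteScaleRange[2])
  for (i in seq_len(nrow(siteInfo))) {
    V[siteInfo$site[i], ] <- scale_[i] * (if (siteInfo$critical[i])
      clip01(activities[siteInfo$accession[i], ] +
               stats::rnorm(nSamples, 0, noiseSD / 2))
      else stats::runif(nSamples, 0.05, 1))
  }
  for (j in seq_len(nSubstrateSites)) {
    k <- subInfo$kinase[j]
    V[subInfo$site[j], ] <- scale_[nrow(siteInfo) + j] * (if (k %in% critKin)
      clip01(beta * activities[k, ] + stats::rnorm(nSamples, 0, noiseSD))
      else stats::runif(nSamples, 0.05, 1))
  }
  V <- pmax(V, 1e-3)
  miss <- matrix(stats::runif(length(V)) < sparsity, nrow(V), ncol(V))
  for (i in which(siteInfo$critical))   # kinase sites occupy rows 1..nKin*spk
    miss[i, ] <- miss[i, ] | (V[i, ] < detectionLimit * scale_[i])
  # keep at least one observed value per row so rows stay embeddable
  for (i in which(rowSums(!miss) == 0)) miss[i, sample(nSamples, 1L)] <- FALSE
  V[miss] <- 0
  nm <- NormalizedPhosMatrix(V, zeroMask = miss)
  ksMap <- split(subInfo$site, subInfo$kinase)[kin]
  names(ksMap) <- kin
  kinSiteMap <- split(siteInfo$site, siteInfo$accession)[kin]
  names(kinSiteMap) <- kin
  list(matrix = nm,
       criticalSites = siteInfo$site[siteInfo$critical],
       kinaseSubstrateMap = ksMap,
       kinaseSiteMap = kinSiteMap,
       activities = activities,
       siteInfo = siteInfo, substrateInfo = subInfo)
}

#' Generate kinase sequences with planted signatures and annotations
#'
#' Each sequence carries one instance of the ATP-binding-like signature
#' (conserved K, early in the sequence) and one of the active-site-like
#' signature (conserved D), an activation-loop interval downstream of the
#' active site, and a set of phosphosites. Critical sites are placed close
#' to the conserved residues with flanks enriched for a configured letter
#' set; non-critical sites are placed uniformly with uniform flanks.
#'
#' @param nKinases number of kinases.
#' @param seqLength nominal protein length (default 300).
#' @param sitesPerKinase phosphosites per kinase (first one critical when
#'   selected).
#' @param criticalFrac fraction of kinases with a critical site.
#' @param flankBias letters enriched around critical sites (default
#'   G/Y/C/W/T, the composition contrast the feature tests exploit).
#' @param seed RNG seed.
#' @return list with `sequences` (named character), `annotations`
#'   (data.frame: site, accession, residue, position, critical, aloopStart,
#'   aloopEnd, conservedK, conservedD), and `signatures`.
#' @export
simKinaseSequences <- function(nKinases = 20L, seqLength = 300L,
                               sitesPerKinase = 4L, criticalFrac = 0.5,
                               flankBias = c("G", "Y", "C", "W", "T"),
                               seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sig <- synthSignatures()
  seqs <- character(nKinases)
  ann <- list()
  acc <- sprintf("KIN%03d", seq_len(nKinases))
  nCrit <- round(criticalFrac * nKinases)
  for (i in seq_len(nKinases)) {
    L <- seqLength + sample(-20:20, 1L)
    chars <- sample(.AA, L, replace = TRUE)
    atpIns <- .instantiate(sig$atp)
    atpPos <- sample(25:40, 1L)
    substr_ <- function(chars, at, txt) {
      chars[at:(at + nchar(txt) - 1L)] <- strsplit(txt, "")[[1]]
      chars
    }
    chars <- substr_(chars, atpPos, atpIns)
    conservedK <- atpPos + nchar(atpIns) - 1L
    actIns <- .instantiate(sig$active)
    actPos <- sample(130:150, 1L)
    chars <- substr_(chars, actPos, actIns)
    conservedD <- actPos + 1L
    aloop <- c(actPos + 8L, actPos + 48L)
    isCrit <- i <= nCrit
    nSites <- sitesPerKinase
    pos <- integer(0)
    if (isCrit) {
      repeat {
        # near the conserved D, inside the A-loop; offset >= 12 keeps the
        # enriched +/-7 flank clear of the planted signature span
        p <- conservedD + sample(12:40, 1L)
        if (p <= L - 8L) break
      }
      pos <- p
    }
    while (length(pos) < nSites) {
      p <- sample(10:(L - 10L), 1L)
      if (!p %in% pos &&
          !(p %in% atpPos:(atpPos + nchar(atpIns) - 1L)) &&
          !(p %in% actPos:(actPos + nchar(actIns) - 1L)))
        pos <- c(pos, p)
    }
    res <- sample(c("S", "T", "Y"), nSites, replace = TRUE)
    for (s in seq_len(nSites)) {
      chars[pos[s]] <- res[s]
      flank <- setdiff((pos[s] - 7L):(pos[s] + 7L), pos[s])
      flank <- flank[flank >= 1L & flank <= L]
      if (isCrit && s == 1L) {
        enrich <- sample(flank, round(0.6 * length(flank)))
        chars[enrich] <- sample(flankBias, length(enrich), replace = TRUE)
      }
    }
    # planted residues may have clobbered signatures only outside their
    # spans (positions excluded above), so the instances survive intact
    seqs[i] <- paste(chars, collapse = "")
    ann[[i]] <- data.frame(
      accession = acc[i], residue = res, position = pos,
      critical = isCrit & seq_len(nSites) == 1L,
      aloopStart = aloop[1L], aloopEnd = aloop[2L],
      conservedK = conservedK, conservedD = conservedD,
      stringsAsFactors = FALSE)
  }
  names(seqs) <- acc
  ann <- do.call(rbind, ann)
  ann$site <- formatSiteID(ann$accession, ann$residue, ann$position)
  list(sequences = seqs, annotations = ann, signatures = sig)
}

#' Class-separated surrogate sequence embeddings
#'
#' Gaussian embeddings standing in for protein-language-model output:
#' unit-covariance noise plus a class-mean separation of `delta` along a
#' random unit direction for label-1 sites.
#'
#' @param siteIDs character vector.
#' @param labels binary vector aligned with `siteIDs`.
#' @param dim embedding dimension (default 1024).
#' @param delta mean separation between classes (0 = null).
#' @param seed RNG seed.
#' @return matrix (sites x dim) with rownames `siteIDs`.
#' @export
simSiteEmbeddings <- function(siteIDs, labels, dim = 1024L, delta = 4,
                              seed = 1L) {
  stopifnot(delta >= 0, length(labels) == length(siteIDs))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- stats::rnorm(dim); u <- u / sqrt(sum(u^2))
  E <- matrix(stats::rnorm(length(siteIDs) * dim), length(siteIDs), dim)
  E <- E + outer(as.numeric(as.logical(labels)) * delta, u)
  rownames(E) <- siteIDs
  E
}

#' Write helical C-alpha-only toy structures as PDB files
#'
#' Residue `i` sits on an ideal helix (rise 1.5 A, 100 degrees per turn,
#' radius chosen so consecutive C-alpha atoms are ~3.8 A apart), plus a
#' small seeded jitter, so spatial distances are computable and locally
#' sequence-monotone.
#'
#' @param sequences named character vector of protein sequences.
#' @param dir output directory (created if needed).
#' @param jitter coordinate jitter SD in Angstrom (default 0.01).
#' @param seed RNG seed.
#' @return named character vector of written file paths.
#' @export
simToyStructures <- function(sequences, dir, jitter = 0.01, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
  rise <- 1.5; turn <- 100 * pi / 180
  r <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
  out <- character(length(sequences))
  for (i in seq_along(sequences)) {
    chars <- strsplit(sequences[[i]], "")[[1]]
    n <- length(chars)
    t_ <- seq_len(n)
    xyz <- cbind(r * cos(turn * t_), r * sin(turn * t_), rise * t_) +
      matrix(stats::rnorm(3 * n, 0, jitter), n, 3)
    lines_ <- sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      t_, unname(three[chars]), t_, xyz[, 1], xyz[, 2], xyz[, 3])
    path <- file.path(dir, paste0(names(sequences)[i], ".pdb"))
    writeLines(c(lines_, "END"), path)
    out[i] <- path
  }
  names(out) <- names(sequences)
  out
}
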