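# Shared fixtures and independent oracles used across the suite.

tinyPhosTSV <- function(path, body = c(
  "site\tA\tB",
  "P12345:S10\t1.5\t",
  "P12345:T20\t0.5\t0.7")) {
  writeLines(body, path)
  path
}

tinyMatrix <- function(vals, sites = NULL, samples = NULL) {
  n <- length(vals) / 2
  m <- matrix(vals, ncol = 2)
  rownames(m) <- sites %||% paste0("P", seq_len(nrow(m)), ":S", 10 + seq_len(nrow(m)))
  colnames(m) <- samples %||% c("A", "B")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) pairwise-concordance AUROC oracle (0.5 credit for ties).
aurocPairwise <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force weighted-KS running-sum oracle.
esBrute <- function(scores, hit, p = 1) {
  N <- length(scores)
  Nh <- sum(hit)
  w <- abs(scores)^p
  denom <- sum(w[hit])
  if (denom == 0) { w <- rep(1, N); denom <- Nh }
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] / denom else -1 / (N - Nh)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# Independent regex-based PROSITE oracle: converts the pattern to an
# anchored ERE and tests every (start, end) substring.
prositeRegexOracle <- function(patternText, sequence) {
  txt <- gsub("[[:space:]]", "", sub("\\.$", "", patternText))
  nA <- grepl("^<", txt); cA <- grepl(">$", txt)
  txt <- sub("^<", "", sub(">$", "", txt))
  parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  rx <- paste(vapply(parts, function(p) {
    g <- regmatches(p, regexec(
      "^(\\[[A-Z]+\\]|\\{[A-Z]+\\}|[A-Zx])(\\((\\d+)(,(\\d+))?\\))?$", p))[[1]]
    core <- g[2]
    rep_ <- if (nzchar(g[4]) && nzchar(g[6])) sprintf("{%s,%s}", g[4], g[6])
      else if (nzchar(g[4])) sprintf("{%s}", g[4]) else ""
    base <- if (core == "x") sprintf("[%s]", aa)
      else if (startsWith(core, "[")) core
      else if (startsWith(core, "{"))
        sprintf("[%s]", paste(setdiff(strsplit(aa, "")[[1]],
                                      strsplit(gsub("[{}]", "", core),
                                               "")[[1]]), collapse = ""))
      else core
    paste0(base, rep_)
  }, character(1)), collapse = "")
  L <- nchar(sequence)
  out <- NULL
  starts <- if (nA) 1L else seq_len(L)
  for (s in starts) for (e in s:L) {
    if (cA && e != L) next
    if (grepl(paste0("^", rx, "$"), substr(sequence, s, e)))
      out <- rbind(out, c(s, e))
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0))
  else data.frame(start = out[, 1], end = out[, 2])
}

# Constrained random generator of (pattern, sequence) pairs.
randomPrositeCase <- function() {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  nel <- sample(2:5, 1)
  els <- vapply(seq_len(nel), function(i) {
    kind <- sample(c("lit", "set", "excl", "x", "xn", "xnm"), 1)
    switch(kind,
      lit = sample(aa, 1),
      set = paste0("[", paste(sample(aa, sample(2:4, 1)), collapse = ""), "]"),
      excl = paste0("{", paste(sample(aa, sample(1:3, 1)), collapse = ""), "}"),
      x = "x",
      xn = sprintf("x(%d)", sample(1:3, 1)),
      xnm = sprintf("x(%d,%d)", sample(0:2, 1), sample(2:4, 1)))
  }, character(1))
  list(pattern = paste(els, collapse = "-"),
       sequence = paste(sample(aa, sample(10:25, 1), replace = TRUE),
                        collapse = ""))
}
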