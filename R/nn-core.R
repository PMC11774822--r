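# Minimal dense neural-network core: forward/backward passes written in
# base R matrix algebra, parameters held in nested named lists, optimized
# with Adam. Shapes follow the (tokens x features) convention.

.rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.linearInit <- function(nin, nout) {
  list(W = .rmat(nin, nout, sd = sqrt(2 / (nin + nout))),
       b = numeric(nout))
}

.linearFwd <- function(p, X) {
  Y <- X %*% p$W
  sweep(Y, 2, p$b, "+")
}

.linearBwd <- function(p, X, dY) {
  list(dX = dY %*% t(p$W),
       grads = list(W = crossprod(X, dY), b = colSums(dY)))
}

.lnInit <- function(d) list(g = rep(1, d), b = numeric(d))

.lnFwd <- function(p, X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  list(Y = Y, cache = list(xhat = xhat, inv = inv))
}

.lnBwd <- function(p, cache, dY) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(dY, 2, p$g, "*")
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX,
       grads = list(g = colSums(dY * xhat), b = colSums(dY)))
}

.softmaxRows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Multi-head attention. keyMask: logical, FALSE = padding key (excluded).
.mhaInit <- function(d) {
  list(Wq = .linearInit(d, d), Wk = .linearInit(d, d),
       Wv = .linearInit(d, d), Wo = .linearInit(d, d))
}

.mhaFwd <- function(p, X, nHeads, keyMask = NULL) {
  n <- nrow(X); d <- ncol(X); dk <- d %/% nHeads
  Q <- .linearFwd(p$Wq, X); K <- .linearFwd(p$Wk, X); V <- .linearFwd(p$Wv, X)
  O <- matrix(0, n, d)
  heads <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    if (!is.null(keyMask) && any(!keyMask))
      S[, !keyMask] <- -1e30
    P <- .softmaxRows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    heads[[h]] <- P
  }
  Y <- .linearFwd(p$Wo, O)
  list(Y = Y, cache = list(X = X, Q = Q, K = K, V = V, O = O,
                           heads = heads, nHeads = nHeads, keyMask = keyMask))
}

.mhaBwd <- function(p, cache, dY) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V
  nHeads <- cache$nHeads
  d <- ncol(X); dk <- d %/% nHeads
  bo <- .linearBwd(p$Wo, cache$O, dY)
  dO <- bo$dX
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    P <- cache$heads[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dP <- tcrossprod(dOh, V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))          # softmax backward
    dS <- dS / sqrt(dk)
    dQ[, idx] <- dS %*% K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, Q[, idx, drop = FALSE])
  }
  bq <- .linearBwd(p$Wq, X, dQ)
  bk <- .linearBwd(p$Wk, X, dK)
  bv <- .linearBwd(p$Wv, X, dV)
  list(dX = bq$dX + bk$dX + bv$dX,
       grads = list(Wq = bq$grads, Wk = bk$grads, Wv = bv$grads,
                    Wo = bo$grads))
}

# Performer-style linear attention: positive random features approximating
# the softmax kernel. Forward-only backend (used for inference/embedding).
.linAttnFwd <- function(p, X, nHeads, omega) {
  n <- nrow(X); d <- ncol(X); dk <- d %/% nHeads
  Q <- .linearFwd(p$Wq, X); K <- .linearFwd(p$Wk, X); V <- .linearFwd(p$Wv, X)
  O <- matrix(0, n, d)
  m <- nrow(omega)
  phi <- function(U) {
    Us <- U / dk^0.25
    proj <- tcrossprod(Us, omega)             # n x m
    exp(proj - rowSums(Us^2) / 2) / sqrt(m)
  }
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    qf <- phi(Q[, idx, drop = FALSE])
    kf <- phi(K[, idx, drop = FALSE])
    num <- qf %*% crossprod(kf, V[, idx, drop = FALSE])
    den <- as.numeric(qf %*% colSums(kf))
    O[, idx] <- num / den
  }
  .linearFwd(p$Wo, O)
}

.ffnInit <- function(d, dff = 2L * d) {
  list(L1 = .linearInit(d, dff), L2 = .linearInit(dff, d))
}

.blockInit <- function(d) {
  list(attn = .mhaInit(d), ln1 = .lnInit(d),
       ffn = .ffnInit(d), ln2 = .lnInit(d))
}

.dropoutMask <- function(dim1, dim2, rate) {
  matrix(stats::rbinom(dim1 * dim2, 1, 1 - rate), dim1, dim2) / (1 - rate)
}

# Transformer block; norm = "pre" (LN before each sublayer, residual
# stream unnormalized) or "post" (classic LN after each residual add).
.blockFwd <- function(p, X, nHeads, dropout = 0, training = FALSE,
                      keyMask = NULL, backend = "exact", omega = NULL,
                      norm = "pre") {
  if (backend == "linear") {
    if (norm == "pre") {
      A <- .linAttnFwd(p$attn, .lnFwd(p$ln1, X)$Y, nHeads, omega)
      X1 <- X + A
      F_ <- .linearFwd(p$ffn$L2,
                       pmax(.linearFwd(p$ffn$L1, .lnFwd(p$ln2, X1)$Y), 0))
      return(list(Y = X1 + F_, cache = NULL))
    }
    A <- .linAttnFwd(p$attn, X, nHeads, omega)
    ln1 <- .lnFwd(p$ln1, X + A)
    Hff <- pmax(.linearFwd(p$ffn$L1, ln1$Y), 0)
    F_ <- .linearFwd(p$ffn$L2, Hff)
    ln2 <- .lnFwd(p$ln2, ln1$Y + F_)
    return(list(Y = ln2$Y, cache = NULL))
  }
  if (norm == "pre") {
    ln1 <- .lnFwd(p$ln1, X)
    att <- .mhaFwd(p$attn, ln1$Y, nHeads, keyMask)
    A <- att$Y
    m1 <- NULL
    if (training && dropout > 0) {
      m1 <- .dropoutMask(nrow(A), ncol(A), dropout)
      A <- A * m1
    }
    X1 <- X + A
    ln2 <- .lnFwd(p$ln2, X1)
    H1 <- .linearFwd(p$ffn$L1, ln2$Y)
    R <- pmax(H1, 0)
    F_ <- .linearFwd(p$ffn$L2, R)
    m2 <- NULL
    if (training && dropout > 0) {
      m2 <- .dropoutMask(nrow(F_), ncol(F_), dropout)
      F_ <- F_ * m2
    }
    return(list(Y = X1 + F_,
                cache = list(att = att$cache, ln1 = ln1$cache,
                             ln2 = ln2$cache, X = X, ln1Y = ln1$Y,
                             ln2Y = ln2$Y, H1 = H1, R = R,
                             m1 = m1, m2 = m2, norm = "pre")))
  }
  att <- .mhaFwd(p$attn, X, nHeads, keyMask)
  A <- att$Y
  m1 <- NULL
  if (training && dropout > 0) {
    m1 <- .dropoutMask(nrow(A), ncol(A), dropout)
    A <- A * m1
  }
  ln1 <- .lnFwd(p$ln1, X + A)
  H1 <- .linearFwd(p$ffn$L1, ln1$Y)
  R <- pmax(H1, 0)
  F_ <- .linearFwd(p$ffn$L2, R)
  m2 <- NULL
  if (training && dropout > 0) {
    m2 <- .dropoutMask(nrow(F_), ncol(F_), dropout)
    F_ <- F_ * m2
  }
  ln2 <- .lnFwd(p$ln2, ln1$Y + F_)
  list(Y = ln2$Y,
       cache = list(att = att$cache, ln1 = ln1$cache, ln2 = ln2$cache,
                    X = X, ln1Y = ln1$Y, H1 = H1, R = R,
                    m1 = m1, m2 = m2, norm = "post"))
}

.blockBwd <- function(p, cache, dY) {
  if (identical(cache$norm, "pre")) {
    # Y = X1 + F(LN2(X1)); X1 = X + A(LN1(X))
    dF <- dY
    if (!is.null(cache$m2)) dF <- dF * cache$m2
    bl2 <- .linearBwd(p$ffn$L2, cache$R, dF)
    dH1 <- bl2$dX * (cache$H1 > 0)
    bl1 <- .linearBwd(p$ffn$L1, cache$ln2Y, dH1)
    b2 <- .lnBwd(p$ln2, cache$ln2, bl1$dX)
    dX1 <- dY + b2$dX
    dA <- dX1
    if (!is.null(cache$m1)) dA <- dA * cache$m1
    ba <- .mhaBwd(p$attn, cache$att, dA)
    b1 <- .lnBwd(p$ln1, cache$ln1, ba$dX)
    return(list(dX = dX1 + b1$dX,
                grads = list(attn = ba$grads, ln1 = b1$grads,
                             ffn = list(L1 = bl1$grads, L2 = bl2$grads),
                             ln2 = b2$grads)))
  }
  b2 <- .lnBwd(p$ln2, cache$ln2, dY)
  dF <- b2$dX
  if (!is.null(cache$m2)) dF <- dF * cache$m2
  bl2 <- .linearBwd(p$ffn$L2, cache$R, dF)
  dH1 <- bl2$dX * (cache$H1 > 0)
  bl1 <- .linearBwd(p$ffn$L1, cache$ln1Y, dH1)
  dLn1Y <- b2$dX + bl1$dX
  b1 <- .lnBwd(p$ln1, cache$ln1, dLn1Y)
  dA <- b1$dX
  if (!is.null(cache$m1)) dA <- dA * cache$m1
  ba <- .mhaBwd(p$attn, cache$att, dA)
  list(dX = b1$dX + ba$dX,
       grads = list(attn = ba$grads, ln1 = b1$grads,
                    ffn = list(L1 = bl1$grads, L2 = bl2$grads),
                    ln2 = b2$grads))
}

# ---- nested-list parameter utilities ----------------------------------

.zeroLike <- function(p) {
  if (is.list(p)) lapply(p, .zeroLike) else p * 0
}

.gradAdd <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) mapply(.gradAdd, a, b, SIMPLIFY = FALSE) else a + b
}

.gradScale <- function(g, s) {
  if (is.list(g)) lapply(g, .gradScale, s = s) else g * s
}

.adamInit <- function(params) {
  list(m = .zeroLike(params), v = .zeroLike(params), t = 0L)
}

.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      if (!is.null(names(p))) g <- g[names(p)]   # grads may be built in
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)  # another order
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# ---- generic MLP: linear layers with LayerNorm + ReLU + dropout -------

.mlpInit <- function(widths) {
  nl <- length(widths) - 1L
  layers <- vector("list", nl)
  for (i in seq_len(nl)) {
    layers[[i]] <- list(lin = .linearInit(widths[i], widths[i + 1L]))
    if (i < nl) layers[[i]]$ln <- .lnInit(widths[i + 1L])
  }
  layers
}

.mlpFwd <- function(layers, X, dropout = 0, training = FALSE) {
  caches <- vector("list", length(layers))
  H <- X
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- .linearFwd(layers[[i]]$lin, H)
    if (i < nl) {
      ln <- .lnFwd(layers[[i]]$ln, Z)
      R <- pmax(ln$Y, 0)
      mk <- NULL
      if (training && dropout > 0) {
        mk <- .dropoutMask(nrow(R), ncol(R), dropout)
        R <- R * mk
      }
      caches[[i]] <- list(H = H, Z = Z, ln = ln$cache, lnY = ln$Y, mk = mk)
      H <- R
    } else {
      caches[[i]] <- list(H = H)
      H <- Z
    }
  }
  list(out = H, caches = caches)
}

.mlpBwd <- function(layers, caches, dOut) {
  nl <- length(layers)
  grads <- vector("list", nl)
  dH <- dOut
  for (i in rev(seq_len(nl))) {
    cc <- caches[[i]]
    if (i < nl) {
      dR <- dH
      if (!is.null(cc$mk)) dR <- dR * cc$mk
      dLnY <- dR * (cc$lnY > 0)
      bl <- .lnBwd(layers[[i]]$ln, cc$ln, dLnY)
      bb <- .linearBwd(layers[[i]]$lin, cc$H, bl$dX)
      grads[[i]] <- list(lin = bb$grads, ln = bl$grads)
      dH <- bb$dX
    } else {
      bb <- .linearBwd(layers[[i]]$lin, cc$H, dH)
      grads[[i]] <- list(lin = bb$grads)
      dH <- bb$dX
    }
  }
  list(grads = grads, dX = dH)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
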