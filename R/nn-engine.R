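# Minimal neural-network engine: parameters are nested lists of numeric
# matrices/vectors; every layer exposes a forward returning (value, cache)
# and a backward mapping upstream gradients to (input gradient, parameter
# gradients). All gradients are hand-derived and verified against central
# finite differences in the test suite.

add_bias <- function(M, b) M + rep(b, each = nrow(M))

init_lin <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = numeric(n_out))
}

lin_fwd <- function(p, X) add_bias(X %*% p$W, p$b)

lin_bwd <- function(p, X, dY) {
  list(dX = dY %*% t(p$W),
       g = list(W = crossprod(X, dY), b = colSums(dY)))
}

# Two-layer FFNN: linear -> ReLU -> (inverted dropout) -> linear.
init_ffnn2 <- function(n_in, n_hidden, n_out) {
  list(l1 = init_lin(n_in, n_hidden), l2 = init_lin(n_hidden, n_out))
}

ffnn2_fwd <- function(p, X, dropout = 0, training = FALSE) {
  H <- lin_fwd(p$l1, X)
  A <- pmax(H, 0)
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix(
      (runif(length(A)) >= dropout) / (1 - dropout), nrow(A), ncol(A))
    A <- A * mask
  }
  list(out = lin_fwd(p$l2, A),
       cache = list(X = X, H = H, A = A, mask = mask))
}

ffnn2_bwd <- function(p, cache, dY) {
  b2 <- lin_bwd(p$l2, cache$A, dY)
  dA <- b2$dX
  if (!is.null(cache$mask)) dA <- dA * cache$mask
  dH <- dA * (cache$H > 0)
  b1 <- lin_bwd(p$l1, cache$X, dH)
  list(dX = b1$dX, g = list(l1 = b1$g, l2 = b2$g))
}

# Layer normalization over the feature dimension (per row).
init_ln <- function(d) list(g = rep(1, d), b = numeric(d))

ln_fwd <- function(p, X, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(p$g, each = nrow(X)), p$b),
       cache = list(xhat = xhat, inv = inv))
}

ln_bwd <- function(p, cache, dY) {
  xhat <- cache$xhat
  dxhat <- dY * rep(p$g, each = nrow(dY))
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, g = list(g = colSums(dY * xhat), b = colSums(dY)))
}

# Multi-head self-attention over a short token sequence. Tokens are stacked
# row-wise: X is (T*B) x d, token t occupying rows ((t-1)*B+1):(t*B).
init_mha <- function(d, scale = sqrt(1 / d)) {
  list(Wq = matrix(rnorm(d * d, 0, scale), d, d), bq = numeric(d),
       Wk = matrix(rnorm(d * d, 0, scale), d, d), bk = numeric(d),
       Wv = matrix(rnorm(d * d, 0, scale), d, d), bv = numeric(d),
       Wo = matrix(rnorm(d * d, 0, scale), d, d), bo = numeric(d))
}

tok_rows <- function(t, B) ((t - 1L) * B + 1L):(t * B)

mha_fwd <- function(p, X, n_tok, n_head) {
  B <- nrow(X) %/% n_tok
  d <- ncol(X)
  dh <- d %/% n_head
  Q <- add_bias(X %*% p$Wq, p$bq)
  K <- add_bias(X %*% p$Wk, p$bk)
  V <- add_bias(X %*% p$Wv, p$bv)
  O <- matrix(0, nrow(X), d)
  A <- vector("list", n_tok)  # A[[t]][[h]]: B x n_tok attention rows
  for (t in seq_len(n_tok)) A[[t]] <- vector("list", n_head)
  for (h in seq_len(n_head)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    for (t in seq_len(n_tok)) {
      Qt <- Q[tok_rows(t, B), cols, drop = FALSE]
      S <- matrix(0, B, n_tok)
      for (s in seq_len(n_tok)) {
        S[, s] <- rowSums(Qt * K[tok_rows(s, B), cols, drop = FALSE]) / sqrt(dh)
      }
      S <- exp(S - apply(S, 1, max))
      At <- S / rowSums(S)
      A[[t]][[h]] <- At
      Ot <- matrix(0, B, dh)
      for (s in seq_len(n_tok)) {
        Ot <- Ot + V[tok_rows(s, B), cols, drop = FALSE] * At[, s]
      }
      O[tok_rows(t, B), cols] <- Ot
    }
  }
  list(out = add_bias(O %*% p$Wo, p$bo),
       cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A,
                    n_tok = n_tok, n_head = n_head, B = B, dh = dh))
}

mha_bwd <- function(p, cache, dY) {
  B <- cache$B; dh <- cache$dh
  n_tok <- cache$n_tok; n_head <- cache$n_head
  dO <- dY %*% t(p$Wo)
  dQ <- matrix(0, nrow(dY), ncol(dY))
  dK <- dQ; dV <- dQ
  for (h in seq_len(n_head)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    for (t in seq_len(n_tok)) {
      rt <- tok_rows(t, B)
      dOt <- dO[rt, cols, drop = FALSE]
      At <- cache$A[[t]][[h]]
      dA <- matrix(0, B, n_tok)
      for (s in seq_len(n_tok)) {
        rs <- tok_rows(s, B)
        dA[, s] <- rowSums(dOt * cache$V[rs, cols, drop = FALSE])
        dV[rs, cols] <- dV[rs, cols] + dOt * At[, s]
      }
      dS <- At * (dA - rowSums(At * dA))  # softmax backward, row-wise
      Qt <- cache$Q[rt, cols, drop = FALSE]
      for (s in seq_len(n_tok)) {
        rs <- tok_rows(s, B)
        dQ[rt, cols] <- dQ[rt, cols] +
          cache$K[rs, cols, drop = FALSE] * (dS[, s] / sqrt(dh))
        dK[rs, cols] <- dK[rs, cols] + Qt * (dS[, s] / sqrt(dh))
      }
    }
  }
  X <- cache$X
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       g = list(Wq = crossprod(X, dQ), bq = colSums(dQ),
                Wk = crossprod(X, dK), bk = colSums(dK),
                Wv = crossprod(X, dV), bv = colSums(dV),
                Wo = crossprod(cache$O, dY), bo = colSums(dY)))
}

# One transformer encoder block (post-layer-norm): X + MHA -> LN -> + FFN -> LN.
init_transformer <- function(d, n_head = 4, ff_mult = 4) {
  list(attn = init_mha(d), ln1 = init_ln(d),
       ffn = init_ffnn2(d, ff_mult * d, d), ln2 = init_ln(d))
}

transformer_fwd <- function(p, X, n_tok, n_head) {
  at <- mha_fwd(p$attn, X, n_tok, n_head)
  l1 <- ln_fwd(p$ln1, X + at$out)
  ff <- ffnn2_fwd(p$ffn, l1$out)
  l2 <- ln_fwd(p$ln2, l1$out + ff$out)
  list(out = l2$out, cache = list(at = at$cache, l1 = l1$cache,
                                  ff = ff$cache, l2 = l2$cache,
                                  n_tok = n_tok, n_head = n_head))
}

transformer_bwd <- function(p, cache, dY) {
  b2 <- ln_bwd(p$ln2, cache$l2, dY)
  bf <- ffnn2_bwd(p$ffn, cache$ff, b2$dX)
  dZ <- b2$dX + bf$dX
  b1 <- ln_bwd(p$ln1, cache$l1, dZ)
  ba <- mha_bwd(p$attn, cache$at, b1$dX)
  list(dX = b1$dX + ba$dX,
       g = list(attn = ba$g, ln1 = b1$g, ffn = bf$g, ln2 = b2$g))
}

# Single-head cross-attention between two embeddings viewed as sequences of
# feature chunks: queries come from Xq's chunks, keys/values from Xkv's.
init_xattn <- function(d, n_chunk = 4) {
  dc <- d %/% n_chunk
  sc <- sqrt(1 / dc)
  list(Wq = matrix(rnorm(dc * dc, 0, sc), dc, dc),
       Wk = matrix(rnorm(dc * dc, 0, sc), dc, dc),
       Wv = matrix(rnorm(dc * dc, 0, sc), dc, dc),
       Wo = matrix(rnorm(dc * dc, 0, sc), dc, dc))
}

chunk_cols <- function(t, dc) ((t - 1L) * dc + 1L):(t * dc)

xattn_fwd <- function(p, Xq, Xkv, n_chunk = 4) {
  dc <- ncol(Xq) %/% n_chunk
  B <- nrow(Xq)
  Qs <- Ks <- Vs <- vector("list", n_chunk)
  for (t in seq_len(n_chunk)) {
    Qs[[t]] <- Xq[, chunk_cols(t, dc), drop = FALSE] %*% p$Wq
    Ks[[t]] <- Xkv[, chunk_cols(t, dc), drop = FALSE] %*% p$Wk
    Vs[[t]] <- Xkv[, chunk_cols(t, dc), drop = FALSE] %*% p$Wv
  }
  out <- matrix(0, B, ncol(Xq))
  A <- Ot <- vector("list", n_chunk)
  for (t in seq_len(n_chunk)) {
    S <- matrix(0, B, n_chunk)
    for (s in seq_len(n_chunk)) S[, s] <- rowSums(Qs[[t]] * Ks[[s]]) / sqrt(dc)
    S <- exp(S - apply(S, 1, max))
    At <- S / rowSums(S)
    A[[t]] <- At
    O <- matrix(0, B, dc)
    for (s in seq_len(n_chunk)) O <- O + Vs[[s]] * At[, s]
    Ot[[t]] <- O
    out[, chunk_cols(t, dc)] <- O %*% p$Wo
  }
  list(out = out, cache = list(Xq = Xq, Xkv = Xkv, Qs = Qs, Ks = Ks, Vs = Vs,
                               A = A, Ot = Ot, n_chunk = n_chunk, dc = dc))
}

xattn_bwd <- function(p, cache, dY) {
  n_chunk <- cache$n_chunk; dc <- cache$dc
  B <- nrow(dY)
  dXq <- matrix(0, B, ncol(dY)); dXkv <- dXq
  dWq <- dWk <- dWv <- dWo <- matrix(0, dc, dc)
  dQs <- dKs <- dVs <- rep(list(matrix(0, B, dc)), n_chunk)
  for (t in seq_len(n_chunk)) {
    dYt <- dY[, chunk_cols(t, dc), drop = FALSE]
    dWo <- dWo + crossprod(cache$Ot[[t]], dYt)
    dO <- dYt %*% t(p$Wo)
    At <- cache$A[[t]]
    dA <- matrix(0, B, n_chunk)
    for (s in seq_len(n_chunk)) {
      dA[, s] <- rowSums(dO * cache$Vs[[s]])
      dVs[[s]] <- dVs[[s]] + dO * At[, s]
    }
    dS <- At * (dA - rowSums(At * dA))
    for (s in seq_len(n_chunk)) {
      dQs[[t]] <- dQs[[t]] + cache$Ks[[s]] * (dS[, s] / sqrt(dc))
      dKs[[s]] <- dKs[[s]] + cache$Qs[[t]] * (dS[, s] / sqrt(dc))
    }
  }
  for (t in seq_len(n_chunk)) {
    cc <- chunk_cols(t, dc)
    Xqt <- cache$Xq[, cc, drop = FALSE]
    Xkt <- cache$Xkv[, cc, drop = FALSE]
    dWq <- dWq + crossprod(Xqt, dQs[[t]])
    dWk <- dWk + crossprod(Xkt, dKs[[t]])
    dWv <- dWv + crossprod(Xkt, dVs[[t]])
    dXq[, cc] <- dQs[[t]] %*% t(p$Wq)
    dXkv[, cc] <- dKs[[t]] %*% t(p$Wk) + dVs[[t]] %*% t(p$Wv)
  }
  list(dXq = dXq, dXkv = dXkv,
       g = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo))
}

# --- parameter-tree utilities ---------------------------------------------

grad_like <- function(par) {
  if (is.list(par)) lapply(par, grad_like) else par * 0
}

tree_axpy <- function(a, x, y) {  # y + a*x over matching trees
  if (is.list(y)) {
    for (nm in names(y)) y[[nm]] <- tree_axpy(a, x[[nm]], y[[nm]])
    y
  } else y + a * x
}

par_flatten <- function(par) unlist(par, use.names = FALSE)

# Reorder a gradient tree to the reference (parameter) tree's structure,
# filling absent branches with zeros, so flattened trees align element-wise.
tree_align <- function(g, ref) {
  if (!is.list(ref)) {
    if (is.null(g)) return(ref * 0)
    return(g)
  }
  out <- ref
  for (nm in names(ref)) out[[nm]] <- tree_align(g[[nm]], ref[[nm]])
  out
}

par_unflatten <- function(par, v) {
  i <- 0L
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    k <- length(p)
    out <- v[(i + 1L):(i + k)]
    i <<- i + k
    if (is.matrix(p)) dim(out) <- dim(p) else names(out) <- names(p)
    out
  }
  fill(par)
}

# Nesterov-momentum SGD step. Weight decay is skipped for uncertainty
# parameters (s), the macro-micro blend (alpha) and anything else whose leaf
# name appears in `no_decay` -- decaying log-variances would bias all
# uncertainty weights toward 1/2.
sgd_step <- function(par, grad, mom, lr, momentum = 0.9, weight_decay = 0,
                     no_decay = c("s", "task_s", "alpha_logit")) {
  step <- function(p, g, m, nm) {
    if (is.list(p)) {
      out_p <- p; out_m <- m
      for (k in names(p)) {
        if (is.null(g[[k]])) next  # untouched branch (e.g. absent participant)
        r <- step(p[[k]], g[[k]], m[[k]], k)
        out_p[[k]] <- r$p; out_m[[k]] <- r$m
      }
      return(list(p = out_p, m = out_m))
    }
    wd <- if (nm %in% no_decay) 0 else weight_decay
    gg <- g + wd * p
    m <- momentum * m + gg
    list(p = p - lr * (gg + momentum * m), m = m)
  }
  step(par, grad, mom, "")
}
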