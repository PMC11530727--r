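# Modality fusion: the DRUW uncertainty-weighted block plus the comparison
# fusion operators. Exported functions accept a single embedding vector or a
# batch matrix (rows = records); internal *_fwd/*_bwd drive training.

as_batch <- function(x) if (is.matrix(x)) x else matrix(x, 1)
un_batch <- function(x, was_vec) if (was_vec) drop(x) else x

#' Uncertainty-weighted (DRUW) fusion of two modality embeddings
#'
#' Fuses the physical-activity and speech embeddings with weights derived
#' from learned log-variance parameters, `w_m = exp(-s_m)/2`:
#' `fused = w_phys * h_phys + w_speech * h_speech`. The accompanying penalty
#' `sum(s)/2 + lambda * (sum(w) - tau)^2` joins the training objective; at
#' the symmetric initialization `s = (0, 0)` with `tau = 1` it vanishes, and
#' the fusion reduces to plain averaging.
#'
#' @param h_phys,h_speech Embedding vectors (length d) or batch matrices
#'   (rows = records).
#' @param s Named log-variance parameters `c(phys = , speech = )`.
#' @param lambda Restraint coefficient (default 0.1).
#' @param tau Restraint target for the summed modality weights (default 1,
#'   i.e. M/2 for M = 2 modalities).
#' @return List with `fused`, `weights` and `penalty`.
#' @export
druw_fuse <- function(h_phys, h_speech, s = c(phys = 0, speech = 0),
                      lambda = 0.1, tau = 1) {
  if (!all(is.finite(s))) abort("fusion uncertainty parameters must be finite")
  w <- druw_weights(s)
  was_vec <- !is.matrix(h_phys)
  hp <- as_batch(h_phys); hs <- as_batch(h_speech)
  stopifnot(all(dim(hp) == dim(hs)))
  fused <- w[1] * hp + w[2] * hs
  penalty <- sum(s) / 2 + lambda * (sum(w) - tau)^2
  list(fused = un_batch(fused, was_vec), weights = w, penalty = penalty)
}

#' Concatenate and project two modality embeddings
#'
#' @param h_phys,h_speech Embedding vectors or batch matrices.
#' @param proj A linear map `list(W, b)` with `W` of shape 2d x d.
#' @return The fused embedding.
#' @export
basic_concat_fusion <- function(h_phys, h_speech, proj) {
  was_vec <- !is.matrix(h_phys)
  out <- lin_fwd(proj, cbind(as_batch(h_phys), as_batch(h_speech)))
  un_batch(out, was_vec)
}

#' Element-wise maximum fusion
#'
#' @param h_phys,h_speech Embedding vectors or batch matrices of equal shape.
#' @return The element-wise maximum.
#' @export
max_fusion <- function(h_phys, h_speech) {
  if (length(h_phys) != length(h_speech)) abort("embeddings must have equal shape")
  pmax(h_phys, h_speech)
}

#' Gated fusion
#'
#' A logistic gate computed from both embeddings blends them per dimension:
#' `g = logistic(G [h_phys; h_speech] + b)`,
#' `fused = g * h_phys + (1 - g) * h_speech`.
#'
#' @param h_phys,h_speech Embedding vectors or batch matrices.
#' @param gate A linear map `list(W, b)` with `W` of shape 2d x d.
#' @return The fused embedding.
#' @export
gated_fusion <- function(h_phys, h_speech, gate) {
  was_vec <- !is.matrix(h_phys)
  hp <- as_batch(h_phys); hs <- as_batch(h_speech)
  g <- plogis(lin_fwd(gate, cbind(hp, hs)))
  un_batch(g * hp + (1 - g) * hs, was_vec)
}

#' Attention-based fusion
#'
#' Three attention variants over the two modality embeddings:
#' `post_concat` runs multi-head self-attention over the two embeddings as a
#' 2-token sequence and mean-pools; `solo` re-weights each embedding's
#' dimensions with a learned logistic gate before concatenation and
#' projection; `cross_modal` views each embedding as a short sequence of
#' feature chunks, lets each modality's chunks attend to the other's, and
#' sums the two directions.
#'
#' @param h_phys,h_speech Embedding vectors or batch matrices.
#' @param params Parameters created by [mf_init_params()] for the matching
#'   fusion kind (fields depend on `mode`).
#' @param mode `"post_concat"`, `"solo"` or `"cross_modal"`.
#' @param n_head Heads for `post_concat` (default 4).
#' @return The fused embedding.
#' @export
attention_fusion <- function(h_phys, h_speech, params,
                             mode = c("post_concat", "solo", "cross_modal"),
                             n_head = 4) {
  mode <- match.arg(mode)
  was_vec <- !is.matrix(h_phys)
  hp <- as_batch(h_phys); hs <- as_batch(h_speech)
  out <- switch(mode,
    post_concat = {
      r <- mha_fwd(params$attn, rbind(hp, hs), n_tok = 2, n_head = n_head)
      B <- nrow(hp)
      (r$out[seq_len(B), , drop = FALSE] +
         r$out[B + seq_len(B), , drop = FALSE]) / 2
    },
    solo = {
      C <- cbind(hp * rep(plogis(params$a_phys), each = nrow(hp)),
                 hs * rep(plogis(params$a_speech), each = nrow(hs)))
      lin_fwd(params$proj, C)
    },
    cross_modal = {
      xattn_fwd(params$p2s, hp, hs)$out + xattn_fwd(params$s2p, hs, hp)$out
    }
  )
  un_batch(out, was_vec)
}

#' Fixed-weight fusion
#'
#' @param h_phys,h_speech Embedding vectors or batch matrices.
#' @param weights Two non-negative fixed weights.
#' @return `weights[1] * h_phys + weights[2] * h_speech`.
#' @export
pure_weighted_fusion <- function(h_phys, h_speech, weights = c(0.5, 0.5)) {
  if (length(weights) != 2 || any(weights < 0)) {
    abort("weights must be two non-negative numbers")
  }
  weights[1] * h_phys + weights[2] * h_speech
}

#' Merge the ZCM and PIM encoder outputs into one physiological stream
#'
#' The two actigraphy embeddings are concatenated and linearly projected back
#' to width d, giving the single physical-activity stream that enters fusion
#' (the fusion stage carries one uncertainty parameter per *modality*, not
#' per actigraphy channel).
#'
#' @param h_zcm,h_pim Embedding vectors or batch matrices.
#' @param proj A linear map `list(W, b)` with `W` of shape 2d x d.
#' @return The combined physiological embedding.
#' @export
combine_physiological <- function(h_zcm, h_pim, proj) {
  was_vec <- !is.matrix(h_zcm)
  out <- lin_fwd(proj, cbind(as_batch(h_zcm), as_batch(h_pim)))
  un_batch(out, was_vec)
}

# --- internal dispatch -----------------------------------------------------

fusion_fwd <- function(arch, fpar, hp, hs, n_head) {
  switch(arch$fusion,
    druw = {
      w <- druw_weights(fpar$s)
      fused <- w[1] * hp + w[2] * hs
      pen <- sum(fpar$s) / 2 +
        arch$fusion_lambda * (sum(w) - arch$fusion_tau)^2
      list(fused = fused, penalty = pen, cache = list(hp = hp, hs = hs, w = w))
    },
    basic_concat = {
      C <- cbind(hp, hs)
      list(fused = lin_fwd(fpar$proj, C), penalty = 0, cache = list(C = C))
    },
    max = {
      m <- hp >= hs
      list(fused = pmax(hp, hs), penalty = 0, cache = list(m = m))
    },
    gated = {
      C <- cbind(hp, hs)
      g <- plogis(lin_fwd(fpar$gate, C))
      list(fused = g * hp + (1 - g) * hs, penalty = 0,
           cache = list(C = C, g = g, hp = hp, hs = hs))
    },
    attention = {
      r <- mha_fwd(fpar$attn, rbind(hp, hs), n_tok = 2, n_head = n_head)
      B <- nrow(hp)
      fused <- (r$out[seq_len(B), , drop = FALSE] +
                  r$out[B + seq_len(B), , drop = FALSE]) / 2
      list(fused = fused, penalty = 0, cache = list(at = r$cache, B = B))
    },
    solo_attention = {
      gp <- plogis(fpar$a_phys); gs <- plogis(fpar$a_speech)
      C <- cbind(hp * rep(gp, each = nrow(hp)), hs * rep(gs, each = nrow(hs)))
      list(fused = lin_fwd(fpar$proj, C), penalty = 0,
           cache = list(C = C, gp = gp, gs = gs, hp = hp, hs = hs))
    },
    cross_modal = {
      r1 <- xattn_fwd(fpar$p2s, hp, hs)
      r2 <- xattn_fwd(fpar$s2p, hs, hp)
      list(fused = r1$out + r2$out, penalty = 0,
           cache = list(c1 = r1$cache, c2 = r2$cache))
    },
    pure_weighted = {
      w <- arch$fusion_weights
      list(fused = w[1] * hp + w[2] * hs, penalty = 0, cache = list(w = w))
    },
    abort(sprintf("unknown fusion kind '%s'", arch$fusion))
  )
}

fusion_bwd <- function(arch, fpar, cache, dF, n_head) {
  switch(arch$fusion,
    druw = {
      w <- cache$w
      dw_data <- c(sum(dF * cache$hp), sum(dF * cache$hs))
      dw_pen <- 2 * arch$fusion_lambda * (sum(w) - arch$fusion_tau)
      ds <- -w * (dw_data + dw_pen) + 0.5
      names(ds) <- names(fpar$s)
      list(dhp = w[1] * dF, dhs = w[2] * dF, g = list(s = ds))
    },
    basic_concat = {
      b <- lin_bwd(fpar$proj, cache$C, dF)
      d <- ncol(dF)
      list(dhp = b$dX[, seq_len(d), drop = FALSE],
           dhs = b$dX[, d + seq_len(d), drop = FALSE],
           g = list(proj = b$g))
    },
    max = list(dhp = dF * cache$m, dhs = dF * (!cache$m), g = list()),
    gated = {
      g <- cache$g
      dg <- dF * (cache$hp - cache$hs)
      dpre <- dg * g * (1 - g)
      b <- lin_bwd(fpar$gate, cache$C, dpre)
      d <- ncol(dF)
      list(dhp = dF * g + b$dX[, seq_len(d), drop = FALSE],
           dhs = dF * (1 - g) + b$dX[, d + seq_len(d), drop = FALSE],
           g = list(gate = b$g))
    },
    attention = {
      B <- cache$B
      b <- mha_bwd(fpar$attn, cache$at, rbind(dF, dF) / 2)
      list(dhp = b$dX[seq_len(B), , drop = FALSE],
           dhs = b$dX[B + seq_len(B), , drop = FALSE],
           g = list(attn = b$g))
    },
    solo_attention = {
      b <- lin_bwd(fpar$proj, cache$C, dF)
      d <- ncol(dF)
      dC1 <- b$dX[, seq_len(d), drop = FALSE]
      dC2 <- b$dX[, d + seq_len(d), drop = FALSE]
      gp <- cache$gp; gs <- cache$gs
      list(dhp = dC1 * rep(gp, each = nrow(dC1)),
           dhs = dC2 * rep(gs, each = nrow(dC2)),
           g = list(a_phys = colSums(dC1 * cache$hp) * gp * (1 - gp),
                    a_speech = colSums(dC2 * cache$hs) * gs * (1 - gs),
                    proj = b$g))
    },
    cross_modal = {
      b1 <- xattn_bwd(fpar$p2s, cache$c1, dF)
      b2 <- xattn_bwd(fpar$s2p, cache$c2, dF)
      list(dhp = b1$dXq + b2$dXkv, dhs = b1$dXkv + b2$dXq,
           g = list(p2s = b1$g, s2p = b2$g))
    },
    pure_weighted = {
      w <- cache$w
      list(dhp = w[1] * dF, dhs = w[2] * dF, g = list())
    }
  )
}
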