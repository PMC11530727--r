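mf_fusions <- c("basic_concat", "max", "gated", "attention",
                "solo_attention", "cross_modal", "pure_weighted", "druw")
mf_personalizations <- c("basic_ffnn", "transformer_only", "adapter",
                         "macromicro", "none")
mf_mtls <- c("equal", "fixed_weighted", "multioutput", "druw")
mf_masks <- c("zcm", "pim", "speech", "all")

#' Specify a macro-micro multimodal multitask model
#'
#' Defines the architecture without allocating parameters: three 2-layer
#' feed-forward encoders (ZCM, PIM, speech) of width `d`; the ZCM and PIM
#' embeddings merged into one physiological stream; a fusion block joining
#' the physiological and speech streams; a macro stage (emotional FFNN plus
#' one transformer encoder layer over the fused/physiological/speech tokens,
#' mean-pooled into the shared macro embedding); a personalization stage;
#' and nine logistic prediction heads, one per mood dimension. The proposed
#' configuration is `fusion = "druw"`, `personalization = "macromicro"`,
#' `mtl = "druw"`.
#'
#' @param speech_dim Width D of the speech feature vectors.
#' @param d Embedding width (default 128).
#' @param hidden Encoder hidden width (default `d`).
#' @param fusion One of `r paste0('"', mf_fusions, '"', collapse = ", ")`.
#' @param personalization One of
#'   `r paste0('"', mf_personalizations, '"', collapse = ", ")`;
#'   `"transformer_only"` also bypasses the emotional FFNN in the macro stage.
#' @param mtl Multitask weighting: one of
#'   `r paste0('"', mf_mtls, '"', collapse = ", ")`.
#' @param modality_mask Which modality's inputs to keep (`"all"` keeps
#'   everything; `"zcm"`, `"pim"` or `"speech"` zero the other encoders'
#'   inputs, reproducing single-modality models).
#' @param alpha Macro-micro blending factor in \[0, 1\] (default 0.5).
#' @param learn_alpha If `TRUE`, alpha becomes a per-participant learnable
#'   parameter through a logistic reparameterization.
#' @param dropout Encoder dropout rate (default 0.1; training only).
#' @param loss Per-task training loss, `"mse"` (default) or `"one_minus_ccc"`.
#' @param lambda Restraint coefficient of the DRUW multitask loss.
#' @param fusion_lambda Restraint coefficient of the DRUW fusion penalty.
#' @param fixed_task_weights Weights for `mtl = "fixed_weighted"`.
#' @param fusion_weights Weights for `fusion = "pure_weighted"`.
#' @param adapter_ratio Bottleneck ratio of the adapter personalization
#'   (hidden width `d / adapter_ratio`, default 8).
#' @param n_head Attention heads in the transformer stage (default 4).
#' @return An object of class `mf_model` describing the architecture.
#' @export
mf_model <- function(speech_dim, d = 128, hidden = d,
                     fusion = "druw", personalization = "macromicro",
                     mtl = "druw", modality_mask = "all",
                     alpha = 0.5, learn_alpha = FALSE, dropout = 0.1,
                     loss = c("mse", "one_minus_ccc"),
                     lambda = 0.1, fusion_lambda = 0.1,
                     fixed_task_weights = NULL,
                     fusion_weights = c(0.5, 0.5),
                     adapter_ratio = 8, n_head = 4) {
  fusion <- match.arg(fusion, mf_fusions)
  personalization <- match.arg(personalization, mf_personalizations)
  mtl <- match.arg(mtl, mf_mtls)
  modality_mask <- match.arg(modality_mask, mf_masks)
  loss <- match.arg(loss)
  if (d %% n_head != 0) abort("d must be divisible by n_head")
  if (d %% 4 != 0) abort("d must be divisible by 4 (cross-modal chunks)")
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  if (mtl == "fixed_weighted") {
    if (is.null(fixed_task_weights)) fixed_task_weights <- rep(1 / 9, 9)
    if (length(fixed_task_weights) != 9 || any(fixed_task_weights < 0)) {
      abort("fixed_task_weights must be 9 non-negative numbers")
    }
  }
  structure(list(
    speech_dim = as.integer(speech_dim), d = as.integer(d),
    hidden = as.integer(hidden), fusion = fusion,
    personalization = personalization, mtl = mtl,
    modality_mask = modality_mask, alpha = alpha, learn_alpha = learn_alpha,
    dropout = dropout, loss = loss,
    lambda = lambda, fusion_lambda = fusion_lambda,
    tau = 9 / 2, fusion_tau = 1,
    fixed_task_weights = fixed_task_weights,
    fusion_weights = fusion_weights,
    adapter_ratio = adapter_ratio, n_head = as.integer(n_head)
  ), class = "mf_model")
}

#' @exportS3Method base::print
print.mf_model <- function(x, ...) {
  cat(sprintf(
    "<mf_model> d = %d, speech_dim = %d | fusion: %s | personalization: %s | mtl: %s | mask: %s\n",
    x$d, x$speech_dim, x$fusion, x$personalization, x$mtl, x$modality_mask))
  invisible(x)
}

# Per-participant micro layer: a residual perturbation of the macro
# embedding, zero-initialized so personalization starts at the identity.
init_micro_layer <- function(d, learn_alpha = FALSE, alpha = 0.5) {
  out <- list(l1 = init_lin(d, d), W2 = matrix(0, d, d), b2 = numeric(d))
  if (learn_alpha) out$alpha_logit <- qlogis(min(max(alpha, 1e-6), 1 - 1e-6))
  out
}

init_adapter_layer <- function(d, ratio = 8) {
  k <- max(1L, d %/% ratio)
  list(down = init_lin(d, k),
       up = list(W = matrix(0, k, d), b = numeric(d)))
}

#' Allocate model parameters
#'
#' Draws all weights from the current RNG state (seed before calling for
#' reproducibility). Per-participant personalization layers are allocated
#' for `participants`; records from unknown participants fall back to the
#' macro embedding at prediction time.
#'
#' @param arch An `mf_model` architecture.
#' @param participants Character vector of participant ids to personalize.
#' @return A nested parameter list.
#' @export
mf_init_params <- function(arch, participants = character()) {
  d <- arch$d
  par <- list(
    enc_zcm = init_ffnn2(60, arch$hidden, d),
    enc_pim = init_ffnn2(60, arch$hidden, d),
    enc_sp = init_ffnn2(arch$speech_dim, arch$hidden, d),
    phys_proj = init_lin(2 * d, d),
    fus = switch(arch$fusion,
      druw = list(s = c(phys = 0, speech = 0)),
      basic_concat = list(proj = init_lin(2 * d, d)),
      max = list(),
      gated = list(gate = init_lin(2 * d, d)),
      attention = list(attn = init_mha(d)),
      solo_attention = list(a_phys = numeric(d), a_speech = numeric(d),
                            proj = init_lin(2 * d, d)),
      cross_modal = list(p2s = init_xattn(d), s2p = init_xattn(d)),
      pure_weighted = list()
    ),
    emo = init_ffnn2(d, d, d),
    tok = matrix(rnorm(3 * d, 0, 0.02), 3, d),
    trans = init_transformer(d, arch$n_head),
    heads = init_lin(d, 9, scale = sqrt(1 / d))
  )
  par$pers <- switch(arch$personalization,
    basic_ffnn = list(shared = init_ffnn2(d, d, d)),
    macromicro = stats::setNames(
      lapply(participants, function(p)
        init_micro_layer(d, arch$learn_alpha, arch$alpha)),
      participants),
    adapter = stats::setNames(
      lapply(participants, function(p) init_adapter_layer(d, arch$adapter_ratio)),
      participants),
    list()
  )
  if (arch$mtl == "druw") {
    par$task_s <- stats::setNames(numeric(9), dams_emotions)
  }
  par
}

# Personalization forward over a batch grouped by participant id.
pers_fwd <- function(par, arch, M, pids) {
  kind <- arch$personalization
  if (kind %in% c("none", "transformer_only")) {
    return(list(P = M, cache = NULL))
  }
  if (kind == "basic_ffnn") {
    r <- ffnn2_fwd(par$pers$shared, M)
    return(list(P = r$out, cache = r$cache))
  }
  P <- M
  groups <- split(seq_len(nrow(M)), pids)
  known <- names(groups) %in% names(par$pers)
  if (any(!known)) {
    inform(sprintf(
      "no personalization layer for participant(s) %s; using the macro embedding",
      paste(names(groups)[!known], collapse = ", ")))
    groups <- groups[known]
  }
  caches <- list()
  for (pid in names(groups)) {
    rows <- groups[[pid]]
    Mi <- M[rows, , drop = FALSE]
    lp <- par$pers[[pid]]
    if (kind == "macromicro") {
      a <- if (arch$learn_alpha) plogis(lp$alpha_logit) else arch$alpha
      H <- lin_fwd(lp$l1, Mi)
      R <- pmax(H, 0)
      Z <- add_bias(R %*% lp$W2, lp$b2)  # residual perturbation of FFNN_i
      P[rows, ] <- Mi + (1 - a) * Z
      caches[[pid]] <- list(rows = rows, Mi = Mi, H = H, R = R, Z = Z, a = a)
    } else {  # adapter
      H <- lin_fwd(lp$down, Mi)
      R <- pmax(H, 0)
      Z <- lin_fwd(lp$up, R)
      P[rows, ] <- Mi + Z
      caches[[pid]] <- list(rows = rows, Mi = Mi, H = H, R = R)
    }
  }
  list(P = P, cache = caches)
}

pers_bwd <- function(par, arch, cache, dP) {
  kind <- arch$personalization
  if (kind %in% c("none", "transformer_only")) {
    return(list(dM = dP, g = list()))
  }
  if (kind == "basic_ffnn") {
    b <- ffnn2_bwd(par$pers$shared, cache, dP)
    return(list(dM = b$dX, g = list(shared = b$g)))
  }
  dM <- dP
  g <- list()
  for (pid in names(cache)) {
    cc <- cache[[pid]]
    rows <- cc$rows
    lp <- par$pers[[pid]]
    dPi <- dP[rows, , drop = FALSE]
    if (kind == "macromicro") {
      dZ <- (1 - cc$a) * dPi
      dR <- dZ %*% t(lp$W2)
      dH <- dR * (cc$H > 0)
      b1 <- lin_bwd(lp$l1, cc$Mi, dH)
      dM[rows, ] <- dPi + b1$dX
      gi <- list(l1 = b1$g, W2 = crossprod(cc$R, dZ), b2 = colSums(dZ))
      if (arch$learn_alpha) {
        a <- cc$a
        gi$alpha_logit <- -sum(dPi * cc$Z) * a * (1 - a)
      }
      g[[pid]] <- gi
    } else {
      bu <- lin_bwd(lp$up, cc$R, dPi)
      dH <- bu$dX * (cc$H > 0)
      bd <- lin_bwd(lp$down, cc$Mi, dH)
      dM[rows, ] <- dPi + bd$dX
      g[[pid]] <- list(down = bd$g, up = bu$g)
    }
  }
  # participants absent from the batch are simply left out of the gradient
  # tree; the optimizer skips them (their gradient is exactly zero)
  list(dM = dM, g = g)
}

# Full forward pass over a batch. X is list(zcm, pim, sp) of standardized
# input matrices; the modality mask zeroes excluded inputs.
mf_forward <- function(par, arch, X, pids, training = FALSE) {
  mask <- arch$modality_mask
  Xz <- if (mask %in% c("all", "zcm")) X$zcm else X$zcm * 0
  Xp <- if (mask %in% c("all", "pim")) X$pim else X$pim * 0
  Xs <- if (mask %in% c("all", "speech")) X$sp else X$sp * 0

  ez <- ffnn2_fwd(par$enc_zcm, Xz, arch$dropout, training)
  ep <- ffnn2_fwd(par$enc_pim, Xp, arch$dropout, training)
  es <- ffnn2_fwd(par$enc_sp, Xs, arch$dropout, training)
  Cphys <- cbind(ez$out, ep$out)
  h_phys <- lin_fwd(par$phys_proj, Cphys)
  h_sp <- es$out

  fu <- fusion_fwd(arch, par$fus, h_phys, h_sp, arch$n_head)

  if (arch$personalization == "transformer_only") {
    e <- fu$fused
    emo_cache <- NULL
  } else {
    r <- ffnn2_fwd(par$emo, fu$fused)
    e <- r$out
    emo_cache <- r$cache
  }

  B <- nrow(e)
  d <- arch$d
  X3 <- rbind(e + rep(par$tok[1, ], each = B),
              h_phys + rep(par$tok[2, ], each = B),
              h_sp + rep(par$tok[3, ], each = B))
  tr <- transformer_fwd(par$trans, X3, n_tok = 3, n_head = arch$n_head)
  M <- (tr$out[seq_len(B), , drop = FALSE] +
          tr$out[B + seq_len(B), , drop = FALSE] +
          tr$out[2 * B + seq_len(B), , drop = FALSE]) / 3

  pe <- pers_fwd(par, arch, M, pids)
  yhat <- plogis(lin_fwd(par$heads, pe$P))

  list(yhat = yhat, M = M, P = pe$P, fused = fu$fused,
       h_phys = h_phys, h_zcm = ez$out, h_pim = ep$out, h_sp = h_sp,
       penalty = fu$penalty,
       cache = list(ez = ez$cache, ep = ep$cache, es = es$cache,
                    Cphys = Cphys, fu = fu$cache, emo = emo_cache,
                    tr = tr$cache, pers = pe$cache, B = B))
}

# Backward pass: dyhat is the gradient of the scalar objective w.r.t. the
# sigmoid outputs. Returns a gradient tree matching the parameter tree.
mf_backward <- function(par, arch, fw, dyhat) {
  cc <- fw$cache
  B <- cc$B
  g <- list()

  dZhead <- dyhat * fw$yhat * (1 - fw$yhat)
  bh <- lin_bwd(par$heads, fw$P, dZhead)
  g$heads <- bh$g

  pb <- pers_bwd(par, arch, cc$pers, bh$dX)
  g$pers <- pb$g
  dM <- pb$dM

  dY3 <- rbind(dM, dM, dM) / 3
  bt <- transformer_bwd(par$trans, cc$tr, dY3)
  g$trans <- bt$g
  dX3 <- bt$dX
  de <- dX3[seq_len(B), , drop = FALSE]
  dhp_tok <- dX3[B + seq_len(B), , drop = FALSE]
  dhs_tok <- dX3[2 * B + seq_len(B), , drop = FALSE]
  g$tok <- rbind(colSums(de), colSums(dhp_tok), colSums(dhs_tok))

  if (arch$personalization == "transformer_only") {
    dfused <- de
    g$emo <- grad_like(par$emo)
  } else {
    be <- ffnn2_bwd(par$emo, cc$emo, de)
    g$emo <- be$g
    dfused <- be$dX
  }

  fb <- fusion_bwd(arch, par$fus, cc$fu, dfused, arch$n_head)
  g$fus <- fb$g
  dh_phys <- fb$dhp + dhp_tok
  dh_sp <- fb$dhs + dhs_tok

  bp <- lin_bwd(par$phys_proj, cc$Cphys, dh_phys)
  g$phys_proj <- bp$g
  d <- arch$d
  dhz <- bp$dX[, seq_len(d), drop = FALSE]
  dhp <- bp$dX[, d + seq_len(d), drop = FALSE]

  g$enc_zcm <- ffnn2_bwd(par$enc_zcm, cc$ez, dhz)$g
  g$enc_pim <- ffnn2_bwd(par$enc_pim, cc$ep, dhp)$g
  g$enc_sp <- ffnn2_bwd(par$enc_sp, cc$es, dh_sp)$g
  g
}

# Combine per-task losses according to the multitask strategy. Returns the
# task total, the per-task gradient scales, and (for DRUW) the uncertainty
# gradient and loss breakdown.
mtl_combine <- function(arch, par, L) {
  switch(arch$mtl,
    equal = list(total = mean(L), scales = rep(1 / length(L), length(L))),
    multioutput = list(total = sum(L), scales = rep(1, length(L))),
    fixed_weighted = list(total = sum(arch$fixed_task_weights * L),
                          scales = arch$fixed_task_weights),
    druw = {
      br <- druw_multitask_loss(L, par$task_s, arch$lambda, arch$tau)
      list(total = br$total, scales = unname(br$weights),
           ds = druw_grad_s(L, par$task_s, arch$lambda, arch$tau),
           breakdown = br)
    }
  )
}

# One objective evaluation: forward, per-task losses, multitask combination,
# fusion penalty, and (optionally) the full gradient tree.
mf_objective <- function(par, arch, X, Y, pids, training = FALSE,
                         gradient = TRUE) {
  fw <- mf_forward(par, arch, X, pids, training = training)
  L <- task_loss(fw$yhat, Y, arch$loss)
  comb <- mtl_combine(arch, par, L)
  total <- comb$total + fw$penalty
  out <- list(total = total, task_losses = L, penalty = fw$penalty,
              breakdown = comb$breakdown, yhat = fw$yhat)
  if (gradient) {
    G <- task_loss_grad(fw$yhat, Y, arch$loss)
    dyhat <- G * rep(comb$scales, each = nrow(G))
    grads <- mf_backward(par, arch, fw, dyhat)
    if (arch$mtl == "druw") grads$task_s <- comb$ds
    out$grads <- grads
  }
  out
}

#' Encode the three modality inputs into d-dimensional embeddings
#'
#' Runs the three 2-layer feed-forward encoders (dropout disabled).
#'
#' @param zcm,pim Standardized 60-entry actigraphy windows (vectors) or
#'   batch matrices with 60 columns.
#' @param speech Standardized speech feature vector or batch matrix.
#' @param par Model parameters from [mf_init_params()].
#' @return List with `h_zcm`, `h_pim`, `h_speech`.
#' @export
encode_modalities <- function(zcm, pim, speech, par) {
  was_vec <- !is.matrix(zcm)
  Xz <- as_batch(zcm); Xp <- as_batch(pim); Xs <- as_batch(speech)
  if (ncol(Xz) != nrow(par$enc_zcm$l1$W) || ncol(Xp) != nrow(par$enc_pim$l1$W) ||
      ncol(Xs) != nrow(par$enc_sp$l1$W)) {
    abort("input width does not match the encoder's expected dimension")
  }
  list(h_zcm = un_batch(ffnn2_fwd(par$enc_zcm, Xz)$out, was_vec),
       h_pim = un_batch(ffnn2_fwd(par$enc_pim, Xp)$out, was_vec),
       h_speech = un_batch(ffnn2_fwd(par$enc_sp, Xs)$out, was_vec))
}

#' Macro emotional-space embedding
#'
#' Applies the emotional FFNN to the fused embedding, assembles the
#' three-token sequence (fused, physiological, speech) with learned
#' token-type embeddings, runs one transformer encoder layer and mean-pools
#' the tokens into the shared macro embedding M.
#'
#' @param fused,h_phys,h_speech Embedding vectors or batch matrices.
#' @param par Model parameters from [mf_init_params()].
#' @param n_head Attention heads (default 4).
#' @param use_emotional_ffnn If `FALSE` the fused embedding enters the
#'   transformer directly.
#' @return The macro embedding (same shape convention as the inputs).
#' @export
macro_forward <- function(fused, h_phys, h_speech, par, n_head = 4,
                          use_emotional_ffnn = TRUE) {
  was_vec <- !is.matrix(fused)
  f <- as_batch(fused); hp <- as_batch(h_phys); hs <- as_batch(h_speech)
  e <- if (use_emotional_ffnn) ffnn2_fwd(par$emo, f)$out else f
  B <- nrow(e)
  X3 <- rbind(e + rep(par$tok[1, ], each = B),
              hp + rep(par$tok[2, ], each = B),
              hs + rep(par$tok[3, ], each = B))
  out <- transformer_fwd(par$trans, X3, n_tok = 3, n_head = n_head)$out
  M <- (out[seq_len(B), , drop = FALSE] +
          out[B + seq_len(B), , drop = FALSE] +
          out[2 * B + seq_len(B), , drop = FALSE]) / 3
  un_batch(M, was_vec)
}

#' Blend the macro embedding with a participant's micro layer
#'
#' `P_i = alpha * M + (1 - alpha) * FFNN_i(M)` where `FFNN_i` is the
#' participant's micro layer (a residual one-hidden-layer perturbation).
#' For a participant without a micro layer the macro embedding is returned
#' unchanged, with a message (alpha effectively forced to 1).
#'
#' @param M Macro embedding vector or batch matrix.
#' @param participant_id Participant id to personalize for.
#' @param bank Named list of micro layers (see [mf_init_params()]).
#' @param alpha Blending factor in \[0, 1\].
#' @return The personalized embedding.
#' @export
micro_forward <- function(M, participant_id, bank, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  lp <- bank[[participant_id]]
  if (is.null(lp)) {
    inform(sprintf(
      "no micro layer for participant '%s'; returning the macro embedding",
      participant_id))
    return(M)
  }
  was_vec <- !is.matrix(M)
  Mi <- as_batch(M)
  Z <- add_bias(pmax(lin_fwd(lp$l1, Mi), 0) %*% lp$W2, lp$b2)
  un_batch(Mi + (1 - alpha) * Z, was_vec)
}

#' Nine-dimension mood predictions from a personalized embedding
#'
#' Applies the nine linear-logistic prediction heads; outputs lie strictly
#' in (0, 1), matching the normalized label scale.
#'
#' @param P Personalized embedding vector or batch matrix.
#' @param heads Head parameters `list(W, b)` with `W` of shape d x 9.
#' @return Numeric vector (or matrix) of predictions named by emotion.
#' @export
predict_heads <- function(P, heads) {
  was_vec <- !is.matrix(P)
  out <- plogis(lin_fwd(heads, as_batch(P)))
  colnames(out) <- dams_emotions[seq_len(ncol(out))]
  un_batch(out, was_vec)
}
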