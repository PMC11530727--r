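# White-box access to engine internals for oracle checks.
lin_fwd <- mf_ns$lin_fwd
ffnn2_fwd <- mf_ns$ffnn2_fwd

toy_params <- function(d = 8, D = 12, hidden = 6, seed = 1,
                       participants = c("A", "B"), ...) {
  arch <- mf_model(speech_dim = D, d = d, hidden = hidden, dropout = 0,
                   n_head = 2, ...)
  set.seed(seed)
  list(arch = arch, par = mf_init_params(arch, participants))
}

test_that("encoders produce d-vectors and obey the affine+ReLU composition", {
  tp <- toy_params()
  z <- rnorm(60); p <- rnorm(60); s <- rnorm(12)
  h <- encode_modalities(z, p, s, tp$par)
  expect_length(h$h_zcm, 8)
  expect_length(h$h_pim, 8)
  expect_length(h$h_speech, 8)

  # zero weights and biases give the zero embedding
  par0 <- tp$par
  for (enc in c("enc_zcm", "enc_pim", "enc_sp")) {
    par0[[enc]]$l1$W[] <- 0; par0[[enc]]$l1$b[] <- 0
    par0[[enc]]$l2$W[] <- 0; par0[[enc]]$l2$b[] <- 0
  }
  h0 <- encode_modalities(z, p, s, par0)
  expect_equal(h0$h_zcm, rep(0, 8))

  # single-unit pencil-and-paper oracle: x -> relu(w1 x + b1) * w2 + b2
  pp <- list(l1 = list(W = matrix(2, 1, 1), b = -1),
             l2 = list(W = matrix(3, 1, 1), b = 0.5))
  xs <- c(-2, 0, 0.25, 1.5)
  got <- vapply(xs, function(x) ffnn2_fwd(pp, matrix(x, 1, 1))$out[1, 1],
                numeric(1))
  expect_equal(got, vapply(xs, function(x) max(2 * x - 1, 0) * 3 + 0.5,
                           numeric(1)), tolerance = 1e-12)

  expect_error(encode_modalities(rnorm(59), p, s, tp$par), "dimension")
})

test_that("the physiological merge is a concatenation-projection", {
  d <- 4
  hz <- rnorm(d); hp <- rnorm(d)
  # identity block on the ZCM half recovers h_zcm
  proj <- list(W = rbind(diag(d), matrix(0, d, d)), b = rep(0, d))
  expect_equal(combine_physiological(hz, hp, proj), hz, tolerance = 1e-12)
  # zero inputs return the bias
  proj$b <- rnorm(d)
  expect_equal(combine_physiological(rep(0, d), rep(0, d), proj), proj$b)
  # random case against an explicit matrix product
  W <- matrix(rnorm(2 * d * d), 2 * d, d)
  b <- rnorm(d)
  expect_equal(combine_physiological(hz, hp, list(W = W, b = b)),
               as.vector(c(hz, hp) %*% W) + b, tolerance = 1e-12)
})

test_that("DRUW fusion averages at symmetric init with zero penalty", {
  hp <- rnorm(6); hs <- rnorm(6)
  r <- druw_fuse(hp, hs, s = c(phys = 0, speech = 0), lambda = 0.7, tau = 1)
  expect_equal(r$fused, (hp + hs) / 2, tolerance = 1e-12)
  expect_equal(unname(r$weights), c(0.5, 0.5))
  expect_equal(r$penalty, 0, tolerance = 1e-12)
  # weights strictly decreasing in s
  r2 <- druw_fuse(hp, hs, s = c(phys = log(2), speech = 0))
  expect_equal(unname(r2$weights[1]), 0.25)
  expect_lt(r2$weights[1], r$weights[1])
  expect_error(druw_fuse(hp, hs, s = c(phys = NaN, speech = 0)), "finite")
})

test_that("fusion penalty gradient matches finite differences on 50 draws", {
  set.seed(31)
  for (i in 1:50) {
    lambda <- runif(1, 0.01, 0.5)
    tau <- 1
    s <- rnorm(2, 0, 1)
    f <- function(v) {
      sum(v) / 2 + lambda * (sum(exp(-v) / 2) - tau)^2
    }
    w <- exp(-s) / 2
    g_an <- 0.5 - 2 * lambda * (sum(w) - tau) * w  # analytic form used in training
    g_num <- fd_grad(f, s)
    expect_equal(g_an, g_num, tolerance = 1e-4)
  }
})

test_that("macro embedding has width d and is symmetric in tied modality tokens", {
  tp <- toy_params(d = 8)
  fused <- rnorm(8); hp <- rnorm(8); hs <- rnorm(8)
  M <- macro_forward(fused, hp, hs, tp$par, n_head = 2)
  expect_length(M, 8)
  # tie the two modality token-type embeddings, then swapping the modality
  # tokens must leave the mean-pooled macro embedding unchanged
  par2 <- tp$par
  par2$tok[3, ] <- par2$tok[2, ]
  M1 <- macro_forward(fused, hp, hs, par2, n_head = 2)
  M2 <- macro_forward(fused, hs, hp, par2, n_head = 2)
  expect_equal(M1, M2, tolerance = 1e-10)
})

test_that("micro personalization blends macro and per-participant layers", {
  d <- 6
  set.seed(9)
  bank <- list(A = moodfuse:::init_micro_layer(d))
  M <- rnorm(d)
  # zero-initialized micro layer: FFNN_i is the identity, any alpha returns M
  expect_equal(micro_forward(M, "A", bank, alpha = 0.5), M)
  # randomize the perturbation
  bank$A$W2 <- matrix(rnorm(d * d, 0, 0.3), d, d)
  bank$A$b2 <- rnorm(d)
  pert <- as.vector(pmax(M %*% bank$A$l1$W + bank$A$l1$b, 0) %*% bank$A$W2) +
    bank$A$b2
  expect_equal(micro_forward(M, "A", bank, alpha = 1), M)            # macro only
  expect_equal(micro_forward(M, "A", bank, alpha = 0), M + pert,
               tolerance = 1e-12)                                    # micro only
  expect_equal(micro_forward(M, "A", bank, alpha = 0.5), M + pert / 2,
               tolerance = 1e-12)
  # unknown participant falls back to the macro embedding with a message
  expect_message(out <- micro_forward(M, "ZZ", bank), "ZZ")
  expect_equal(out, M)
  expect_error(micro_forward(M, "A", bank, alpha = 1.2), "\\[0, 1\\]")
})

test_that("prediction heads are logistic maps into (0, 1)", {
  d <- 5
  heads <- list(W = matrix(0, d, 9), b = rep(0, 9))
  y <- predict_heads(rnorm(d), heads)
  expect_equal(unname(y), rep(0.5, 9))
  expect_named(y, dams_emotions)
  set.seed(4)
  heads2 <- list(W = matrix(rnorm(d * 9, 0, 2), d, 9), b = rnorm(9, 0, 2))
  y2 <- predict_heads(rnorm(d), heads2)
  expect_true(all(y2 > 0 & y2 < 1))
  # 2-dim pencil-and-paper oracle
  h3 <- list(W = matrix(c(1, -1), 2, 1), b = 0.5)
  expect_equal(unname(predict_heads(c(2, 1), h3))[1], plogis(2 - 1 + 0.5),
               tolerance = 1e-12)
})

test_that("the forward pass is deterministic with dropout disabled", {
  tp <- toy_params()
  X <- list(zcm = matrix(rnorm(5 * 60), 5), pim = matrix(rnorm(5 * 60), 5),
            sp = matrix(rnorm(5 * 12), 5))
  pids <- c("A", "B", "A", "B", "A")
  f1 <- mf_ns$mf_forward(tp$par, tp$arch, X, pids, training = FALSE)
  f2 <- mf_ns$mf_forward(tp$par, tp$arch, X, pids, training = FALSE)
  expect_identical(f1$yhat, f2$yhat)
  expect_true(all(f1$yhat > 0 & f1$yhat < 1))
  expect_equal(dim(f1$yhat), c(5, 9))
})

test_that("full-model gradients match finite differences", {
  tp <- toy_params(d = 8, D = 10, hidden = 5, seed = 13)
  arch <- tp$arch
  set.seed(13)
  # randomize zero-initialized pieces so every path is active
  rand <- function(p) if (is.list(p)) lapply(p, rand) else
    p + rnorm(length(p), 0, 0.3)
  par <- rand(tp$par)
  par$fus$s <- c(phys = 0.2, speech = -0.3)
  B <- 6
  X <- list(zcm = matrix(rnorm(B * 60), B), pim = matrix(rnorm(B * 60), B),
            sp = matrix(rnorm(B * 10), B))
  Y <- matrix(runif(B * 9, 0.1, 0.9), B, 9)
  pids <- c("A", "B", "A", "B", "A", "B")
  obj <- mf_ns$mf_objective(par, arch, X, Y, pids, training = FALSE,
                            gradient = TRUE)
  g_an <- mf_ns$par_flatten(mf_ns$tree_align(obj$grads, par))
  v0 <- mf_ns$par_flatten(par)
  f <- function(v) {
    mf_ns$mf_objective(mf_ns$par_unflatten(par, v), arch, X, Y, pids,
                       training = FALSE, gradient = FALSE)$total
  }
  set.seed(14)
  idx <- sort(sample(length(v0), 150))
  g_num <- fd_grad(f, v0, idx)
  rel <- abs(g_an[idx] - g_num) / pmax(abs(g_num), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("no parameter group is silently detached from the objective", {
  tp <- toy_params(d = 8, D = 10, seed = 21, learn_alpha = TRUE)
  set.seed(21)
  rand <- function(p) if (is.list(p)) lapply(p, rand) else
    p + rnorm(length(p), 0, 0.3)
  par <- rand(tp$par)
  B <- 8
  X <- list(zcm = matrix(rnorm(B * 60), B), pim = matrix(rnorm(B * 60), B),
            sp = matrix(rnorm(B * 10), B))
  Y <- matrix(runif(B * 9, 0.1, 0.9), B, 9)
  pids <- rep(c("A", "B"), 4)
  obj <- mf_ns$mf_objective(par, tp$arch, X, Y, pids, training = FALSE,
                            gradient = TRUE)
  g <- obj$grads
  expect_true(all(abs(g$fus$s) > 0))
  expect_true(all(abs(g$task_s) > 0))
  for (pid in c("A", "B")) {
    gp <- g$pers[[pid]]
    expect_gt(sum(abs(gp$l1$W)), 0)
    expect_gt(sum(abs(gp$W2)), 0)
    expect_gt(abs(gp$alpha_logit), 0)
  }
  for (nm in c("enc_zcm", "enc_pim", "enc_sp")) {
    expect_gt(sum(abs(g[[nm]]$l1$W)), 0)
  }
  expect_gt(sum(abs(g$trans$attn$Wq)), 0)
  expect_gt(sum(abs(g$emo$l1$W)), 0)
})

test_that("fusion weights stay positive and bounded for reachable parameters", {
  s_vals <- seq(-4, 4, by = 0.5)
  for (s in s_vals) {
    w <- druw_weights(s)
    expect_gt(w, 0)
    expect_lt(w, exp(abs(s)))
  }
})
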