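#' Concordance correlation coefficient
#'
#' Agreement between predictions and observations, penalizing both loss of
#' correlation and shifts in scale or location:
#' `ccc = 2 * rho * sd_x * sd_y / (sd_x^2 + sd_y^2 + (mu_x - mu_y)^2)`.
#' All moments use the population convention (divisor n). If both inputs are
#' constant the coefficient is defined as 0 and flagged degenerate.
#'
#' @param pred,true Numeric vectors of equal length (at least 2).
#' @return An object of class `ccc_stats`: a list with elements `ccc`, `rho`,
#'   `mu_x`, `mu_y`, `sd_x`, `sd_y`, `n` and `degenerate`.
#' @export
ccc <- function(pred, true) {
  if (length(pred) != length(true)) {
    abort("pred and true must have equal length")
  }
  n <- length(pred)
  if (n < 2) abort("ccc() needs at least 2 observations")
  if (!all(is.finite(pred)) || !all(is.finite(true))) {
    abort("ccc() inputs must be finite")
  }
  mu_x <- mean(pred)
  mu_y <- mean(true)
  sd_x <- sqrt(mean((pred - mu_x)^2))
  sd_y <- sqrt(mean((true - mu_y)^2))
  cov_xy <- mean((pred - mu_x) * (true - mu_y))
  degenerate <- sd_x == 0 && sd_y == 0
  rho <- if (sd_x > 0 && sd_y > 0) cov_xy / (sd_x * sd_y) else 0
  denom <- sd_x^2 + sd_y^2 + (mu_x - mu_y)^2
  cc <- if (degenerate || denom == 0) 0 else 2 * cov_xy / denom
  structure(
    list(ccc = cc, rho = rho, mu_x = mu_x, mu_y = mu_y,
         sd_x = sd_x, sd_y = sd_y, n = n, degenerate = degenerate),
    class = "ccc_stats"
  )
}

#' @exportS3Method base::print
print.ccc_stats <- function(x, ...) {
  cat(sprintf("<ccc_stats> ccc = %.4f (rho = %.4f, n = %d%s)\n",
              x$ccc, x$rho, x$n, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Fast numeric-only CCC used in inner loops; same definition as ccc().
ccc_value <- function(pred, true) {
  mu_x <- mean(pred); mu_y <- mean(true)
  vx <- mean((pred - mu_x)^2); vy <- mean((true - mu_y)^2)
  cxy <- mean((pred - mu_x) * (true - mu_y))
  denom <- vx + vy + (mu_x - mu_y)^2
  if (denom == 0) 0 else 2 * cxy / denom
}

#' Per-task losses over a batch
#'
#' Computes one loss per mood dimension over a batch of predictions:
#' mean squared error (the default training loss) or `1 - ccc` per column.
#'
#' @param pred,true Numeric matrices, rows = records, columns = the 9 mood
#'   dimensions (any column count is accepted).
#' @param kind `"mse"` or `"one_minus_ccc"`.
#' @return Named numeric vector of per-task losses.
#' @export
task_loss <- function(pred, true, kind = c("mse", "one_minus_ccc")) {
  kind <- match.arg(kind)
  pred <- as.matrix(pred); true <- as.matrix(true)
  if (!all(dim(pred) == dim(true))) abort("pred and true must have equal shape")
  if (kind == "one_minus_ccc" && nrow(pred) < 2) {
    abort("one_minus_ccc needs a batch of at least 2 records")
  }
  out <- switch(kind,
    mse = colMeans((pred - true)^2),
    one_minus_ccc = vapply(seq_len(ncol(pred)), function(k) {
      1 - ccc_value(pred[, k], true[, k])
    }, numeric(1))
  )
  names(out) <- colnames(pred) %||% paste0("task_", seq_along(out))
  out
}

# Gradient of each per-task loss w.r.t. pred, as a matrix matching pred.
# Column k holds d L_k / d pred[, k].
task_loss_grad <- function(pred, true, kind = c("mse", "one_minus_ccc")) {
  kind <- match.arg(kind)
  n <- nrow(pred)
  if (kind == "mse") return(2 * (pred - true) / n)
  g <- matrix(0, n, ncol(pred))
  for (k in seq_len(ncol(pred))) {
    x <- pred[, k]; y <- true[, k]
    mu_x <- mean(x); mu_y <- mean(y)
    vx <- mean((x - mu_x)^2); vy <- mean((y - mu_y)^2)
    cxy <- mean((x - mu_x) * (y - mu_y))
    denom <- vx + vy + (mu_x - mu_y)^2
    if (denom == 0) next
    num <- 2 * cxy
    dnum <- 2 * (y - mu_y) / n
    ddenom <- 2 * (x - mu_x) / n + 2 * (mu_x - mu_y) / n
    # d(1 - ccc)/dx = -(dnum * denom - num * ddenom) / denom^2
    g[, k] <- -(dnum * denom - num * ddenom) / denom^2
  }
  g
}

#' Uncertainty weights from log-variance parameters
#'
#' `w = exp(-s) / 2`, the weight a task or modality receives when its
#' log-variance parameter is `s = log(sigma^2)`; equivalently `1 / (2 sigma^2)`.
#'
#' @param s Numeric vector of log-variance parameters.
#' @return Strictly positive weights.
#' @export
druw_weights <- function(s) {
  if (!all(is.finite(s))) abort("uncertainty parameters must be finite")
  exp(-s) / 2
}

#' Dynamic restrained uncertainty-weighted multitask loss
#'
#' Combines per-task losses with learned uncertainty weights plus a restraint
#' on the total weight mass:
#' `total = sum_k w_k L_k + sum_k s_k / 2 + lambda * (sum_k w_k - tau)^2`
#' with `w_k = exp(-s_k) / 2`. The log term (`s/2 = log sigma`) stops weights
#' from growing without bound; the squared restraint stops them from
#' collectively collapsing or exploding away from the target mass `tau`.
#' At the symmetric initialization `s = 0`, `tau = K/2` makes both penalty
#' terms vanish.
#'
#' @param L Non-negative finite per-task losses.
#' @param s Log-variance parameter per task (same length as `L`).
#' @param lambda Restraint coefficient (>= 0, default 0.1).
#' @param tau Restraint target for the summed weights (default `length(L)/2`,
#'   the weight mass at `s = 0`).
#' @return An object of class `druw_loss`: list with `per_task`, `weights`,
#'   `weighted_sum`, `log_term`, `restraint`, `total`.
#' @export
druw_multitask_loss <- function(L, s, lambda = 0.1, tau = length(L) / 2) {
  if (!all(is.finite(L)) || any(L < 0)) abort("task losses must be finite and >= 0")
  if (length(s) != length(L)) abort("one uncertainty parameter per task is required")
  if (lambda < 0) abort("lambda must be >= 0")
  w <- druw_weights(s)
  weighted_sum <- sum(w * L)
  log_term <- sum(s) / 2
  restraint <- lambda * (sum(w) - tau)^2
  structure(
    list(per_task = L, weights = w, weighted_sum = weighted_sum,
         log_term = log_term, restraint = restraint,
         total = weighted_sum + log_term + restraint,
         lambda = lambda, tau = tau),
    class = "druw_loss"
  )
}

#' @exportS3Method base::print
print.druw_loss <- function(x, ...) {
  cat(sprintf(
    "<druw_loss> total %.6g = weighted %.6g + log %.6g + restraint %.6g (K = %d)\n",
    x$total, x$weighted_sum, x$log_term, x$restraint, length(x$per_task)))
  invisible(x)
}

# Gradient of the DRUW total w.r.t. s (dw/ds = -w).
druw_grad_s <- function(L, s, lambda = 0.1, tau = length(L) / 2) {
  w <- druw_weights(s)
  -w * L + 0.5 - 2 * lambda * (sum(w) - tau) * w
}

#' Equal-weight multitask loss
#'
#' @param L Per-task losses.
#' @return Their arithmetic mean.
#' @export
equal_weight_loss <- function(L) {
  if (!all(is.finite(L))) abort("task losses must be finite")
  mean(L)
}

#' Fixed-weight multitask loss
#'
#' @param L Per-task losses.
#' @param weights Non-negative fixed weights, one per task.
#' @return The weighted sum.
#' @export
fixed_weight_loss <- function(L, weights) {
  if (length(weights) != length(L)) abort("one weight per task is required")
  if (any(weights < 0)) abort("fixed task weights must be >= 0")
  sum(weights * L)
}

#' Broom-style tidier for a DRUW loss breakdown
#'
#' @param x A `druw_loss` object.
#' @param ... Unused.
#' @return A tibble with one row per task: `task`, `loss`, `weight` and
#'   `weighted_loss`.
#' @export
tidy.druw_loss <- function(x, ...) {
  tibble(
    task = names(x$per_task) %||% paste0("task_", seq_along(x$per_task)),
    loss = unname(x$per_task),
    weight = unname(x$weights),
    weighted_loss = unname(x$weights * x$per_task)
  )
}

#' One-row summary of a DRUW loss breakdown
#'
#' @param x A `druw_loss` object.
#' @param ... Unused.
#' @return A one-row tibble with the loss components and total.
#' @export
glance.druw_loss <- function(x, ...) {
  tibble(
    weighted_sum = x$weighted_sum, log_term = x$log_term,
    restraint = x$restraint, total = x$total,
    lambda = x$lambda, tau = x$tau, n_tasks = length(x$per_task)
  )
}
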