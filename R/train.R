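#' Training schedule configuration
#'
#' The optimization schedule used throughout: stochastic gradient descent
#' with Nesterov momentum 0.9, initial learning rate 0.001, batch size 16,
#' weight decay 1e-4 (uncertainty parameters and alpha excluded), up to 100
#' epochs, and the learning rate multiplied by 0.9 whenever the development
#' mean CCC fails to improve for 5 consecutive epochs.
#'
#' @param epochs Maximum epochs (default 100).
#' @param lr Initial learning rate (default 0.001).
#' @param momentum Nesterov momentum (default 0.9).
#' @param lr_decay Plateau decay factor (default 0.9).
#' @param lr_patience Non-improving epochs before decay (default 5).
#' @param batch_size Records per batch (default 16).
#' @param weight_decay L2 weight decay on network weights (default 1e-4).
#' @param min_delta Smallest dev-CCC increase counted as improvement
#'   (default 1e-6).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100, lr = 0.001, momentum = 0.9,
                         lr_decay = 0.9, lr_patience = 5, batch_size = 16,
                         weight_decay = 1e-4, min_delta = 1e-6, seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, momentum >= 0, momentum < 1,
            lr_decay > 0, lr_decay <= 1, lr_patience >= 1,
            batch_size >= 1, weight_decay >= 0, min_delta >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 lr_decay = lr_decay, lr_patience = as.integer(lr_patience),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Plateau learning-rate schedule
#'
#' Given the development-metric history (higher is better), decays the
#' learning rate by `factor` when each of the last `patience` epochs failed
#' to exceed the best value seen before it; otherwise the rate is unchanged.
#'
#' @param history Numeric vector of per-epoch development metrics.
#' @param current_lr Current learning rate.
#' @param patience Consecutive non-improving epochs required (default 5).
#' @param factor Multiplicative decay (default 0.9).
#' @param min_delta Improvement threshold (default 1e-6).
#' @return List with `lr` (possibly decayed) and `plateaued` (logical).
#' @export
lr_schedule_step <- function(history, current_lr, patience = 5,
                             factor = 0.9, min_delta = 1e-6) {
  if (length(history) == 0) abort("metric history must be non-empty")
  best_before <- cummax(c(-Inf, head(history, -1)))
  non_improving <- history <= best_before + min_delta
  plateaued <- length(history) >= patience &&
    all(tail(non_improving, patience))
  list(lr = if (plateaued) factor * current_lr else current_lr,
       plateaued = plateaued)
}

# Extract the model input matrices and labels once; batches index rows.
ema_matrices <- function(data) {
  list(zcm = as.matrix(data[, zcm_cols()]),
       pim = as.matrix(data[, pim_cols()]),
       sp = as.matrix(data[, speech_cols(speech_dim(data))]),
       Y = as.matrix(data[, label_cols()]),
       pids = data$participant_id)
}

subset_X <- function(mats, rows) {
  list(zcm = mats$zcm[rows, , drop = FALSE],
       pim = mats$pim[rows, , drop = FALSE],
       sp = mats$sp[rows, , drop = FALSE])
}

# Predictions in evaluation mode (no dropout), chunked to bound memory.
predict_rows <- function(par, arch, mats, rows, chunk = 1024L) {
  out <- matrix(NA_real_, length(rows), 9)
  for (start in seq(1, length(rows), by = chunk)) {
    idx <- rows[start:min(start + chunk - 1L, length(rows))]
    fw <- mf_forward(par, arch, subset_X(mats, idx), mats$pids[idx],
                     training = FALSE)
    out[start:(start + length(idx) - 1L), ] <- fw$yhat
  }
  colnames(out) <- dams_emotions
  out
}

mean_ccc_of <- function(pred, truth) {
  mean(vapply(seq_len(ncol(pred)),
              function(k) ccc_value(pred[, k], truth[, k]), numeric(1)))
}

#' Train a macro-micro model
#'
#' Runs the full optimization schedule on the training split, evaluating the
#' development mean CCC after every epoch, decaying the learning rate on
#' plateaus, and returning the checkpoint with the best development mean CCC.
#' Expects records that have been cleaned, label-normalized and standardized
#' (see [clean_records()], [normalize_labels()], [apply_standardization()]).
#'
#' @param data A preprocessed EMA record tibble.
#' @param split A split tibble from [partition_by_time()].
#' @param model An `mf_model` architecture.
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `mf_fit`: the architecture, best parameters,
#'   per-epoch `history` tibble, configuration, participant registry and
#'   selection summary.
#' @export
mf_train <- function(data, split, model, config = train_config(),
                     verbose = FALSE) {
  stopifnot(inherits(model, "mf_model"), inherits(config, "train_config"))
  if (speech_dim(data) != model$speech_dim) {
    abort(sprintf("model expects speech_dim %d but data has %d",
                  model$speech_dim, speech_dim(data)))
  }
  if (max(as.matrix(data[, label_cols()])) > 1 + 1e-9) {
    abort("labels exceed 1; run normalize_labels() before training")
  }
  tr_rows <- split_rows(split, "train")
  de_rows <- split_rows(split, "dev")
  if (length(tr_rows) == 0 || length(de_rows) == 0) {
    abort("training and development splits must be non-empty")
  }
  mats <- ema_matrices(data)
  registry <- sort(unique(mats$pids[tr_rows]))

  set.seed(config$seed)
  par <- mf_init_params(model, registry)
  mom <- grad_like(par)
  lr <- config$lr
  best <- -Inf
  best_par <- par
  best_epoch <- 0L
  since_improve <- 0L
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample(tr_rows)
    starts <- seq(1, length(perm), by = config$batch_size)
    sums <- c(total = 0, weighted = 0, log_term = 0, restraint = 0,
              penalty = 0)
    n_batch <- 0L
    for (st in starts) {
      b <- perm[st:min(st + config$batch_size - 1L, length(perm))]
      if (model$loss == "one_minus_ccc" && length(b) < 2) next
      obj <- mf_objective(par, model, subset_X(mats, b),
                          mats$Y[b, , drop = FALSE], mats$pids[b],
                          training = TRUE, gradient = TRUE)
      if (!is.finite(obj$total)) {
        abort(sprintf(
          "non-finite loss at epoch %d (lr %.2g); task losses: %s",
          epoch, lr, paste(signif(obj$task_losses, 3), collapse = ", ")))
      }
      upd <- sgd_step(par, obj$grads, mom, lr, config$momentum,
                      config$weight_decay)
      par <- upd$p
      mom <- upd$m
      sums["total"] <- sums["total"] + obj$total
      sums["penalty"] <- sums["penalty"] + obj$penalty
      if (!is.null(obj$breakdown)) {
        sums["weighted"] <- sums["weighted"] + obj$breakdown$weighted_sum
        sums["log_term"] <- sums["log_term"] + obj$breakdown$log_term
        sums["restraint"] <- sums["restraint"] + obj$breakdown$restraint
      }
      n_batch <- n_batch + 1L
    }
    dev_pred <- predict_rows(par, model, mats, de_rows)
    dev_ccc <- mean_ccc_of(dev_pred, mats$Y[de_rows, , drop = FALSE])
    hist[[epoch]] <- tibble(
      epoch = epoch, lr = lr,
      train_loss = sums[["total"]] / n_batch,
      weighted_loss = sums[["weighted"]] / n_batch,
      log_term = sums[["log_term"]] / n_batch,
      restraint = sums[["restraint"]] / n_batch,
      fusion_penalty = sums[["penalty"]] / n_batch,
      dev_mean_ccc = dev_ccc
    )
    if (verbose) {
      message(sprintf("epoch %3d  loss %.5f  dev CCC %.4f  lr %.2g",
                      epoch, sums[["total"]] / n_batch, dev_ccc, lr))
    }
    if (dev_ccc > best + config$min_delta) {
      best <- dev_ccc
      best_par <- par
      best_epoch <- epoch
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$lr_patience) {
        lr <- lr * config$lr_decay
        since_improve <- 0L
      }
    }
  }
  structure(list(model = model, par = best_par, history = dplyr::bind_rows(hist),
                 config = config, registry = registry,
                 best_epoch = best_epoch, best_dev_ccc = best),
            class = "mf_fit")
}

#' @exportS3Method base::print
print.mf_fit <- function(x, ...) {
  cat(sprintf(
    "<mf_fit> %s/%s/%s | %d epochs, best dev mean CCC %.4f at epoch %d\n",
    x$model$fusion, x$model$personalization, x$model$mtl,
    nrow(x$history), x$best_dev_ccc, x$best_epoch))
  invisible(x)
}

#' Per-epoch training history of a fitted model
#'
#' @param x An `mf_fit` object.
#' @param ... Unused.
#' @return The history tibble (one row per epoch).
#' @export
tidy.mf_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `mf_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the selection summary.
#' @export
glance.mf_fit <- function(x, ...) {
  tibble(fusion = x$model$fusion, personalization = x$model$personalization,
         mtl = x$model$mtl, epochs = nrow(x$history),
         best_epoch = x$best_epoch, best_dev_ccc = x$best_dev_ccc,
         final_lr = tail(x$history$lr, 1),
         n_participants = length(x$registry))
}

#' Learning-curve plot for a fitted model
#'
#' @param object An `mf_fit` object.
#' @param ... Unused.
#' @return A ggplot of training loss and development mean CCC by epoch.
#' @export
autoplot.mf_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("epoch", "train_loss", "dev_mean_ccc")],
    -"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Predict mood dimensions for EMA records
#'
#' @param object An `mf_fit` object.
#' @param data A preprocessed EMA tibble (same schema as training data).
#' @param modality_mask Optional mask overriding the model's
#'   (`"zcm"`, `"pim"`, `"speech"`, `"all"`).
#' @param ... Unused.
#' @return A tibble with `participant_id`, `timestamp` and one
#'   `.pred_<emotion>` column per mood dimension, in (0, 1).
#' @export
predict.mf_fit <- function(object, data, modality_mask = NULL, ...) {
  arch <- object$model
  if (!is.null(modality_mask)) {
    arch$modality_mask <- match.arg(modality_mask, mf_masks)
  }
  mats <- ema_matrices(data)
  pred <- predict_rows(object$par, arch, mats, seq_len(nrow(data)))
  colnames(pred) <- paste0(".pred_", dams_emotions)
  dplyr::bind_cols(data[, c("participant_id", "timestamp")], as_tibble(pred))
}

#' Learned DRUW modality weights of a fitted model
#'
#' @param fit An `mf_fit` object with `fusion = "druw"`.
#' @return A tibble with `modality`, `s` (log-variance) and `weight`.
#' @export
fusion_weights <- function(fit) {
  if (fit$model$fusion != "druw") abort("fit does not use DRUW fusion")
  s <- fit$par$fus$s
  tibble(modality = names(s), s = unname(s), weight = unname(druw_weights(s)))
}

#' Learned DRUW task weights of a fitted model
#'
#' @param fit An `mf_fit` object with `mtl = "druw"`.
#' @return A tibble with `task`, `s` and `weight`.
#' @export
task_weights <- function(fit) {
  if (fit$model$mtl != "druw") abort("fit does not use the DRUW multitask loss")
  s <- fit$par$task_s
  tibble(task = names(s), s = unname(s), weight = unname(druw_weights(s)))
}

#' Per-emotion CCC evaluation table
#'
#' Computes the pooled concordance correlation coefficient per mood
#' dimension over one split part (predictions against normalized labels),
#' plus the mean and SD across the nine dimensions -- the layout used to
#' compare fusion/personalization/multitask variants.
#'
#' @param fit An `mf_fit` object.
#' @param data The preprocessed EMA tibble the split refers to.
#' @param split A split tibble from [partition_by_time()].
#' @param part `"test"` (default), `"dev"` or `"train"`.
#' @param modality_mask Optional mask overriding the model's: `"zcm"`,
#'   `"pim"`, `"speech"` or `"all"` (excluded encoders' inputs are zeroed,
#'   reproducing single-modality models).
#' @return An `eval_table`: a tibble with columns `emotion` and `ccc`, with
#'   the mean/SD and context attached as attributes (see [glance.eval_table()]).
#' @export
evaluate <- function(fit, data, split, part = c("test", "dev", "train"),
                     modality_mask = NULL) {
  part <- match.arg(part)
  arch <- fit$model
  if (!is.null(modality_mask)) {
    if (!modality_mask %in% mf_masks) {
      abort(sprintf("unknown modality mask '%s'", modality_mask))
    }
    arch$modality_mask <- modality_mask
  }
  rows <- split_rows(split, part)
  if (length(rows) < 2) abort(sprintf("split part '%s' has fewer than 2 records", part))
  mats <- ema_matrices(data)
  pred <- predict_rows(fit$par, arch, mats, rows)
  truth <- mats$Y[rows, , drop = FALSE]
  cc <- vapply(seq_len(9), function(k) ccc_value(pred[, k], truth[, k]),
               numeric(1))
  out <- tibble(emotion = dams_emotions, ccc = cc)
  attr(out, "mean_ccc") <- mean(cc)
  attr(out, "sd_ccc") <- sd(cc)
  attr(out, "n_records") <- length(rows)
  attr(out, "part") <- part
  attr(out, "modality_mask") <- arch$modality_mask
  class(out) <- c("eval_table", class(out))
  out
}

#' @exportS3Method base::print
print.eval_table <- function(x, ...) {
  cat(sprintf("<eval_table> %s records: %d, mask: %s, mean CCC %.3f (SD %.3f)\n",
              attr(x, "part"), attr(x, "n_records"),
              attr(x, "modality_mask"), attr(x, "mean_ccc"),
              attr(x, "sd_ccc")))
  NextMethod()
}

#' @rdname evaluate
#' @param x An `eval_table`.
#' @param ... Unused.
#' @export
tidy.eval_table <- function(x, ...) {
  tibble(emotion = x$emotion, ccc = x$ccc)
}

#' One-row summary of an evaluation table
#'
#' @param x An `eval_table`.
#' @param ... Unused.
#' @return A one-row tibble with `mean_ccc`, `sd_ccc`, `n_records`, `part`
#'   and `modality_mask`.
#' @export
glance.eval_table <- function(x, ...) {
  tibble(mean_ccc = attr(x, "mean_ccc"), sd_ccc = attr(x, "sd_ccc"),
         n_records = attr(x, "n_records"), part = attr(x, "part"),
         modality_mask = attr(x, "modality_mask"))
}

#' Bar chart of per-emotion CCC
#'
#' @param object An `eval_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eval_table <- function(object, ...) {
  df <- tibble(emotion = factor(object$emotion, levels = dams_emotions),
               ccc = object$ccc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emotion, y = .data$ccc)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_ccc"),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "CCC") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
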