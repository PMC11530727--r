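#' Fit per-channel standardization statistics on the training split
#'
#' Computes the mean and population standard deviation (divisor n) of every
#' ZCM, PIM and speech-feature channel over the *training* records only, so
#' that no information from the development or test periods leaks into the
#' scaling. Channels with zero variance are given a standard deviation of 1
#' (pass-through) and flagged.
#'
#' @param data An EMA record tibble.
#' @param split A split tibble from [partition_by_time()].
#' @return An object of class `ema_stats`: a tibble with columns `channel`,
#'   `mean`, `sd` and `constant`.
#' @export
fit_standardization <- function(data, split) {
  validate_ema(data)
  rows <- split_rows(split, "train")
  if (length(rows) == 0) abort("training split is empty; cannot fit standardization")
  chans <- c(zcm_cols(), pim_cols(), speech_cols(speech_dim(data)))
  x <- as.matrix(data[rows, chans])
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population convention
  constant <- sdev < 1e-12
  sdev[constant] <- 1
  out <- tibble(channel = chans, mean = unname(mu), sd = unname(sdev),
                constant = unname(constant))
  class(out) <- c("ema_stats", class(out))
  out
}

#' Apply fitted standardization to an EMA table
#'
#' Z-scores every ZCM, PIM and speech channel using statistics from
#' [fit_standardization()]. Labels and timestamps are untouched.
#'
#' @param data An EMA record tibble.
#' @param stats An `ema_stats` object.
#' @return The standardized tibble.
#' @export
apply_standardization <- function(data, stats) {
  validate_ema(data)
  chans <- c(zcm_cols(), pim_cols(), speech_cols(speech_dim(data)))
  if (!setequal(chans, stats$channel)) {
    abort("standardization stats do not match the table's channels (dimension mismatch)")
  }
  stats <- stats[match(chans, stats$channel), ]
  x <- as.matrix(data[, chans])
  x <- sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
  data[chans] <- x
  data
}

#' @exportS3Method base::print
print.ema_stats <- function(x, ...) {
  cat(sprintf("<ema_stats> %d channels (%d constant, pass-through)\n",
              nrow(x), sum(x$constant)))
  NextMethod()
}
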