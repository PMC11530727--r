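# Synthetic EMA generator. Each participant carries a latent affect state
# (valence, arousal, distress) evolving as an AR(1) chain across prompts;
# the nine mood labels, the actigraphy windows and the speech embedding are
# all noisy views of that state, with per-participant offsets and loading
# perturbations supplying the between-subject heterogeneity the macro-micro
# model is designed to absorb.

#' Default latent-to-emotion loading matrix
#'
#' Maps the three latent affect dimensions (valence, arousal, distress) to
#' the nine mood dimensions on the logit scale: positive emotions load on
#' +valence, negative ones on +distress, energy-related ones on arousal.
#'
#' @return A 9 x 3 matrix with emotion row names.
#' @export
default_loading_matrix <- function() {
  B <- rbind(
    vigorous   = c( 0.5,  0.3,  0.0),
    gloomy     = c(-0.5,  0.0,  0.3),
    concerned  = c( 0.0,  0.2,  0.5),
    happy      = c( 0.6,  0.1, -0.1),
    unpleasant = c(-0.4,  0.0,  0.4),
    anxious    = c( 0.0,  0.3,  0.5),
    cheerful   = c( 0.6,  0.2,  0.0),
    depressed  = c(-0.5, -0.1,  0.4),
    worried    = c( 0.0,  0.2,  0.6)
  )
  colnames(B) <- c("valence", "arousal", "distress")
  B
}

#' Configuration of the synthetic EMA simulator
#'
#' @param n_participants Number of participants (default 30).
#' @param n_days Days of monitoring (default 14).
#' @param prompts_per_day Prompts per day (default 5: wake, three fixed
#'   clock times with jitter, bed).
#' @param jitter_minutes Uniform jitter around each prompt time (default 10).
#' @param speech_dim Width D of the speech embeddings (default 1024).
#' @param latent_dim Latent affect dimensions q (default 3; the default
#'   loading matrix assumes 3).
#' @param ar_coefficient AR(1) coefficient of the latent chain, in \[0, 1)
#'   (default 0.6); the chain has unit stationary variance.
#' @param loading_matrix 9 x `latent_dim` loading matrix on the logit scale.
#' @param label_intercept Per-emotion intercept on the logit scale
#'   (default 0, centering labels at 50).
#' @param subject_offset_sd SD of per-participant label offsets on the logit
#'   scale (default 0.15).
#' @param subject_loading_sd SD of per-participant loading perturbations
#'   (default 0.1).
#' @param label_noise_sd SD of per-record label noise on the logit scale
#'   (default 0.05).
#' @param zcm_base_rate Poisson rate of ZCM counts at neutral arousal
#'   (default 120 crossings/min).
#' @param pim_base_level Median PIM intensity at neutral arousal
#'   (default 800).
#' @param zcm_gain,pim_gain Arousal coupling of the actigraphy channels at
#'   physiological SNR 1 (defaults 0.5 and 0.4).
#' @param pim_sdlog Log-scale SD of the PIM log-normal (default 0.4).
#' @param modality_snr Named signal-to-noise ratios `c(phys = , speech = )`
#'   (defaults 1 and 1). SNR 0 makes the modality carry no affect signal.
#' @param speech_latent_dims Which latent dimensions the speech embedding
#'   encodes (default all); restricting this makes the modalities
#'   complementary.
#' @param voiceprint_sd SD of the per-participant speech offset (default 0.3).
#' @param dropout_rate Fraction of records dropped uniformly at random
#'   (default 0, i.e. no missingness).
#' @param seed Integer seed; the same configuration always yields the same
#'   dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 30, n_days = 14, prompts_per_day = 5,
                       jitter_minutes = 10, speech_dim = 1024,
                       latent_dim = 3, ar_coefficient = 0.6,
                       loading_matrix = default_loading_matrix(),
                       label_intercept = numeric(9),
                       subject_offset_sd = 0.15, subject_loading_sd = 0.1,
                       label_noise_sd = 0.05,
                       zcm_base_rate = 120, pim_base_level = 800,
                       zcm_gain = 0.5, pim_gain = 0.4, pim_sdlog = 0.4,
                       modality_snr = c(phys = 1, speech = 1),
                       speech_latent_dims = seq_len(latent_dim),
                       voiceprint_sd = 0.3, dropout_rate = 0, seed = 1L) {
  stopifnot(
    n_participants >= 1, n_days >= 1, prompts_per_day >= 1,
    jitter_minutes >= 0, speech_dim >= 1, latent_dim >= 1,
    ar_coefficient >= 0, ar_coefficient < 1,
    nrow(loading_matrix) == 9, ncol(loading_matrix) == latent_dim,
    all(is.finite(loading_matrix)), length(label_intercept) == 9,
    subject_offset_sd >= 0, subject_loading_sd >= 0, label_noise_sd >= 0,
    zcm_base_rate > 0, pim_base_level > 0,
    all(modality_snr >= 0), length(modality_snr) == 2,
    all(speech_latent_dims %in% seq_len(latent_dim)),
    voiceprint_sd >= 0, dropout_rate >= 0, dropout_rate < 1
  )
  structure(as.list(environment()), class = "sim_config")
}

#' @exportS3Method base::print
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d participants x %d days x %d prompts (D = %d, q = %d, seed = %d)\n",
    x$n_participants, x$n_days, x$prompts_per_day, x$speech_dim,
    x$latent_dim, x$seed))
  invisible(x)
}

# Prompt clock times (hours) for one day: wake, evenly spaced fixed times
# in [11, 19], bed. With the default 5 prompts this is the wake / 11 AM /
# 3 PM / 7 PM / bed schedule.
prompt_hours <- function(prompts_per_day) {
  if (prompts_per_day == 1) return(11)
  if (prompts_per_day == 2) return(c(6.75, 22.75))
  n_fix <- prompts_per_day - 2L
  c(6.75, if (n_fix == 1) 15 else seq(11, 19, length.out = n_fix), 22.75)
}

#' Generate a synthetic EMA dataset with ground truth
#'
#' Draws, for every participant, an AR(1) latent affect chain with unit
#' stationary variance; labels are `clip(100 * logistic(B_i z + c + u_i +
#' eps), 0, 100)` with per-participant offset `u_i` and loading matrix
#' `B_i = B + dB_i`; the ZCM window holds 60 Poisson counts whose rate is
#' modulated by arousal, the PIM window 60 log-normal intensities likewise;
#' the speech embedding is a linear mixing of the latent state plus a
#' per-participant voiceprint and SNR-controlled noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `ema_sim` with elements `data` (the EMA record
#'   tibble, raw 0-100 labels) and `truth` (list of tibbles `records` --
#'   latent states and noiseless labels -- and `participants` -- offsets and
#'   loading perturbations).
#' @export
simulate_ema <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  q <- cf$latent_dim
  D <- cf$speech_dim
  phi <- cf$ar_coefficient
  n_prompt <- cf$n_days * cf$prompts_per_day
  snr_p <- cf$modality_snr[["phys"]]
  snr_s <- cf$modality_snr[["speech"]]
  # actigraphy coupling scaled so SNR 1 gives the nominal gains, SNR 0 none
  act_scale <- sqrt(snr_p / (snr_p + 1)) / sqrt(1 / 2)
  sp_signal <- sqrt(snr_s / (snr_s + 1))
  sp_noise <- sqrt(1 / (snr_s + 1))
  # shared speech mixing, restricted to the encoded latent dimensions and
  # scaled to unit per-dimension signal variance
  W <- matrix(0, D, q)
  k <- length(cf$speech_latent_dims)
  W[, cf$speech_latent_dims] <- matrix(rnorm(D * k, 0, sqrt(1 / k)), D, k)
  arousal <- if ("arousal" %in% colnames(cf$loading_matrix)) {
    which(colnames(cf$loading_matrix) == "arousal")
  } else min(2L, q)

  pids <- sprintf("P%03d", seq_len(cf$n_participants))
  day0 <- as.Date("2024-01-01")
  data_rows <- truth_rows <- vector("list", cf$n_participants)
  part_rows <- vector("list", cf$n_participants)

  for (i in seq_along(pids)) {
    u <- rnorm(9, 0, cf$subject_offset_sd)
    dB <- matrix(rnorm(9 * q, 0, cf$subject_loading_sd), 9, q)
    Bi <- cf$loading_matrix + dB
    v <- rnorm(D, 0, cf$voiceprint_sd)

    z <- matrix(0, n_prompt, q)
    z[1, ] <- rnorm(q)
    if (n_prompt > 1) {
      innov <- matrix(rnorm((n_prompt - 1) * q, 0, sqrt(1 - phi^2)),
                      n_prompt - 1, q)
      for (t in 2:n_prompt) z[t, ] <- phi * z[t - 1, ] + innov[t - 1, ]
    }

    hours <- rep(prompt_hours(cf$prompts_per_day), cf$n_days)
    days <- rep(seq_len(cf$n_days) - 1L, each = cf$prompts_per_day)
    secs <- round(hours * 3600 + runif(n_prompt, -60, 60) * cf$jitter_minutes)
    ts_num <- as.numeric(days) * 86400 + secs
    ord <- order(ts_num)
    ts_num <- ts_num[ord]
    dup <- duplicated(ts_num)
    while (any(dup)) {  # jitter ties are possible at minute resolution
      ts_num[dup] <- ts_num[dup] + 1
      ord2 <- order(ts_num)
      ts_num <- ts_num[ord2]
      dup <- duplicated(ts_num)
    }
    stamp <- format(as.POSIXct(ts_num, origin = day0, tz = "UTC"),
                    "%Y-%m-%dT%H:%M:%S")

    logit_clean <- z %*% t(Bi) +
      rep(cf$label_intercept + u, each = n_prompt)
    eps <- matrix(rnorm(n_prompt * 9, 0, cf$label_noise_sd), n_prompt, 9)
    labels <- pmin(pmax(100 * plogis(logit_clean + eps), 0), 100)

    zcm_rate <- cf$zcm_base_rate *
      exp(act_scale * cf$zcm_gain * z[, arousal])
    zcm <- matrix(rpois(n_prompt * 60, rep(zcm_rate, 60)), n_prompt, 60)
    pim_meanlog <- log(cf$pim_base_level) +
      act_scale * cf$pim_gain * z[, arousal] - cf$pim_sdlog^2 / 2
    pim <- matrix(rlnorm(n_prompt * 60, rep(pim_meanlog, 60), cf$pim_sdlog),
                  n_prompt, 60)
    speech <- sp_signal * (z %*% t(W)) +
      rep(v, each = n_prompt) +
      sp_noise * matrix(rnorm(n_prompt * D), n_prompt, D)

    df <- cbind(zcm, pim, speech, labels)
    colnames(df) <- c(zcm_cols(), pim_cols(), speech_cols(D), label_cols())
    data_rows[[i]] <- tibble(participant_id = pids[i], timestamp = stamp,
                             as_tibble(df))
    tz <- as_tibble(z, .name_repair = ~ paste0("z_", seq_len(q)))
    noiseless <- 100 * plogis(logit_clean)
    colnames(noiseless) <- paste0("clean_", label_cols())
    truth_rows[[i]] <- tibble(participant_id = pids[i], timestamp = stamp,
                              tz, as_tibble(noiseless))
    pr <- c(stats::setNames(u, paste0("u_", dams_emotions)),
            stats::setNames(as.vector(dB),
                            paste0("dB_", rep(dams_emotions, q), "_",
                                   rep(seq_len(q), each = 9))))
    part_rows[[i]] <- tibble(participant_id = pids[i], !!!as.list(pr))
  }

  data <- dplyr::bind_rows(data_rows)
  truth_rec <- dplyr::bind_rows(truth_rows)
  if (cf$dropout_rate > 0) {
    keep <- runif(nrow(data)) >= cf$dropout_rate
    data <- data[keep, , drop = FALSE]
    truth_rec <- truth_rec[keep, , drop = FALSE]
  }
  structure(list(
    data = data,
    truth = list(records = truth_rec,
                 participants = dplyr::bind_rows(part_rows))
  ), class = "ema_sim")
}

#' @exportS3Method base::print
print.ema_sim <- function(x, ...) {
  cat(sprintf("<ema_sim> %d records, %d participants, D = %d\n",
              nrow(x$data), length(unique(x$data$participant_id)),
              speech_dim(x$data)))
  invisible(x)
}

#' Export simulator ground truth as JSON
#'
#' Writes the record-level latent states / noiseless labels and the
#' participant-level offsets losslessly (full double precision), aligned
#' with the generated dataset by participant id and timestamp.
#'
#' @param truth The `truth` element of [simulate_ema()]'s result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(records = truth$records, participants = truth$participants),
    path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' Read ground truth written by [export_ground_truth()]
#'
#' @param path JSON path.
#' @return A list of tibbles `records` and `participants`.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(records = as_tibble(obj$records),
       participants = as_tibble(obj$participants))
}
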