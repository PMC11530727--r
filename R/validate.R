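#' Within-individual mixed-model validation
#'
#' For each mood dimension, regresses the observed values on the predicted
#' ones with a participant-level random intercept
#' (`observed ~ predicted + (1 | participant)`, fitted by lme4), and reports
#' the intercept, slope, its standard error, Wald z score and p value, the
#' 95% confidence interval, and the participant (group) and residual
#' variances. A slope near 1 with a significant z indicates that predicted
#' within-person mood changes track observed ones beyond any stable
#' per-person offset. Singular or failed fits are flagged per emotion, not
#' fatal.
#'
#' @param predictions Matrix or data frame of predictions, one column per
#'   mood dimension (9 columns, canonical order).
#' @param observations Matrix or data frame of observed (normalized) labels,
#'   same shape.
#' @param participant_ids Character vector, one id per row.
#' @return A tibble with 9 rows and columns `emotion`, `intercept`, `slope`,
#'   `se`, `z`, `p`, `ci_lower`, `ci_upper`, `group_var`, `resid_var`,
#'   `singular`.
#' @export
within_individual_validation <- function(predictions, observations,
                                         participant_ids) {
  pred <- as.matrix(predictions)
  obs <- as.matrix(observations)
  if (!all(dim(pred) == dim(obs)) || nrow(pred) != length(participant_ids)) {
    abort("predictions, observations and participant_ids must align")
  }
  if (length(unique(participant_ids)) < 2) {
    abort("at least 2 participants are required for the mixed model")
  }
  emotions <- dams_emotions[seq_len(ncol(pred))]
  rows <- lapply(seq_along(emotions), function(k) {
    df <- data.frame(obs = obs[, k], pred = pred[, k],
                     pid = factor(participant_ids))
    na_row <- tibble(emotion = emotions[k], intercept = NA_real_,
                     slope = NA_real_, se = NA_real_, z = NA_real_,
                     p = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                     group_var = NA_real_, resid_var = NA_real_,
                     singular = TRUE)
    tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(obs ~ pred + (1 | pid), data = df, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      ))
      fe <- lme4::fixef(fit)
      # vcov can be indefinite for degenerate fits; report NA errors then
      V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(fit))),
                    error = function(e) matrix(NA_real_, 2, 2))
      se <- suppressWarnings(sqrt(diag(V)))[2]
      est <- unname(fe["pred"])
      z <- est / se
      vc <- as.data.frame(lme4::VarCorr(fit))
      resid_var <- vc$vcov[vc$grp == "Residual"]
      tibble(
        emotion = emotions[k],
        intercept = unname(fe["(Intercept)"]),
        slope = est, se = unname(se), z = unname(z),
        p = unname(2 * stats::pnorm(-abs(z))),
        ci_lower = unname(est - stats::qnorm(0.975) * se),
        ci_upper = unname(est + stats::qnorm(0.975) * se),
        group_var = vc$vcov[vc$grp == "pid"],
        resid_var = resid_var,
        singular = lme4::isSingular(fit) || resid_var < 1e-10 || is.na(se)
      )
    }, error = function(e) na_row)
  })
  dplyr::bind_rows(rows)
}

#' Mixed-model validation of a fitted model on one split part
#'
#' Convenience wrapper: predicts on the given part and runs
#' [within_individual_validation()] against the normalized labels.
#'
#' @param fit An `mf_fit` object.
#' @param data The preprocessed EMA tibble.
#' @param split A split tibble.
#' @param part `"test"` (default), `"dev"` or `"train"`.
#' @return The 9-row validation tibble.
#' @export
validate_fit <- function(fit, data, split, part = c("test", "dev", "train")) {
  part <- match.arg(part)
  rows <- split_rows(split, part)
  mats <- ema_matrices(data)
  pred <- predict_rows(fit$par, fit$model, mats, rows)
  within_individual_validation(pred, mats$Y[rows, , drop = FALSE],
                               mats$pids[rows])
}
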