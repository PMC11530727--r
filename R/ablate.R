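#' Specify one cell of the fusion/personalization/multitask comparison grid
#'
#' @param fusion Fusion strategy, one of
#'   `r paste0('"', mf_fusions, '"', collapse = ", ")`.
#' @param personalization Personalization strategy, one of
#'   `r paste0('"', mf_personalizations, '"', collapse = ", ")`.
#' @param mtl Multitask weighting, one of
#'   `r paste0('"', mf_mtls, '"', collapse = ", ")`.
#' @param modality_mask `"all"` (default) or a single modality.
#' @return An object of class `ablation_spec`.
#' @export
ablation_spec <- function(fusion = "druw", personalization = "macromicro",
                          mtl = "druw", modality_mask = "all") {
  structure(list(
    fusion = match.arg(fusion, mf_fusions),
    personalization = match.arg(personalization, mf_personalizations),
    mtl = match.arg(mtl, mf_mtls),
    modality_mask = match.arg(modality_mask, mf_masks)
  ), class = "ablation_spec")
}

#' @exportS3Method base::print
print.ablation_spec <- function(x, ...) {
  cat(sprintf("<ablation_spec> fusion: %s | personalization: %s | mtl: %s | mask: %s\n",
              x$fusion, x$personalization, x$mtl, x$modality_mask))
  invisible(x)
}

#' The 17-row method comparison grid
#'
#' Enumerates the full fusion x personalization x multitask comparison:
#' six fusion alternatives against the proposed DRUW fusion (each with the
#' baseline FFNN personalization and equal task weighting), the
#' personalization alternatives, the multitask alternatives, and the
#' leave-one-out / all-proposed combinations.
#'
#' @return A tibble with columns `fusion`, `personalization` and `mtl`,
#'   one row per method combination.
#' @export
comparison_grid <- function() {
  g <- rbind(
    c("basic_concat", "basic_ffnn", "equal"),
    c("max", "basic_ffnn", "equal"),
    c("gated", "basic_ffnn", "equal"),
    c("attention", "basic_ffnn", "equal"),
    c("solo_attention", "basic_ffnn", "equal"),
    c("cross_modal", "basic_ffnn", "equal"),
    c("druw", "basic_ffnn", "equal"),
    c("basic_concat", "transformer_only", "equal"),
    c("basic_concat", "adapter", "equal"),
    c("basic_concat", "macromicro", "equal"),
    c("basic_concat", "basic_ffnn", "fixed_weighted"),
    c("basic_concat", "basic_ffnn", "multioutput"),
    c("basic_concat", "basic_ffnn", "druw"),
    c("druw", "macromicro", "equal"),
    c("basic_concat", "macromicro", "druw"),
    c("druw", "basic_ffnn", "druw"),
    c("druw", "macromicro", "druw")
  )
  tibble(fusion = g[, 1], personalization = g[, 2], mtl = g[, 3])
}

#' Train and evaluate one ablation cell
#'
#' Builds the model named by the spec, trains it with the standard schedule
#' and returns the test-set evaluation table. Optionally appends the result
#' to a grid CSV (one row per cell: the spec, the nine per-emotion CCCs,
#' mean and SD).
#'
#' @param data Preprocessed EMA tibble.
#' @param split A split tibble from [partition_by_time()].
#' @param spec An [ablation_spec()].
#' @param config A [train_config()].
#' @param d Embedding width (default 128).
#' @param grid_csv Optional path of a CSV to append the summary row to.
#' @return The test `eval_table`, with the fitted model attached as
#'   attribute `"fit"`.
#' @export
run_ablation <- function(data, split, spec, config = train_config(),
                         d = 128, grid_csv = NULL) {
  stopifnot(inherits(spec, "ablation_spec"))
  model <- mf_model(
    speech_dim = speech_dim(data), d = d,
    fusion = spec$fusion, personalization = spec$personalization,
    mtl = spec$mtl, modality_mask = spec$modality_mask
  )
  fit <- mf_train(data, split, model, config)
  tab <- evaluate(fit, data, split, part = "test")
  if (!is.null(grid_csv)) {
    row <- tibble(
      fusion = spec$fusion, personalization = spec$personalization,
      mtl = spec$mtl, modality_mask = spec$modality_mask,
      !!!stats::setNames(as.list(tab$ccc), tab$emotion),
      mean_ccc = attr(tab, "mean_ccc"), sd_ccc = attr(tab, "sd_ccc")
    )
    readr::write_csv(row, grid_csv, append = file.exists(grid_csv),
                     progress = FALSE)
  }
  attr(tab, "fit") <- fit
  tab
}
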