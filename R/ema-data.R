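#' Read an EMA record table from CSV
#'
#' Reads a wide-format ecological momentary assessment table: one row per
#' prompt, with a participant id, an ISO-8601 timestamp, 60 one-minute
#' zero-crossing-mode (ZCM) actigraphy counts, 60 proportional-integration-mode
#' (PIM) intensities, a fixed-width speech feature vector and the nine mood
#' labels on the raw 0-100 visual-analogue scale. Records are returned sorted
#' by participant and timestamp (stable within ties). Labels are *not*
#' rescaled here; see [normalize_labels()].
#'
#' @param path Path to a UTF-8 CSV file with header columns
#'   `participant_id`, `timestamp`, `zcm_00..zcm_59`, `pim_00..pim_59`,
#'   `sf_0000..sf_{D-1}` and `label_vigorous..label_worried`.
#' @return A tibble of EMA records.
#' @export
read_ema_table <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    timestamp = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed EMA table '%s': %d parsing problem(s), first at row %d (%s)",
      path, nrow(probs), probs$row[1], probs$expected[1]
    ))
  }
  validate_ema(data, source = path)
  sort_ema(data)
}

#' Write an EMA record table to CSV
#'
#' @param data An EMA record tibble (see [read_ema_table()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ema_table <- function(data, path) {
  validate_ema(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# Schema check shared by readers and writers. Errors name the missing or
# unparseable pieces so a malformed export fails loudly, not at training time.
validate_ema <- function(data, source = "EMA table") {
  need <- c("participant_id", "timestamp", zcm_cols(), pim_cols(), label_cols())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      source, paste(missing, collapse = ", ")
    ))
  }
  d <- speech_dim(data)
  if (d < 1) {
    abort(sprintf("%s has no speech feature columns (sf_0000 ...)", source))
  }
  sf <- speech_cols(d)
  missing_sf <- setdiff(sf, names(data))
  if (length(missing_sf) > 0) {
    abort(sprintf(
      "%s speech columns are not contiguous from sf_0000; missing: %s",
      source, paste(head(missing_sf, 5), collapse = ", ")
    ))
  }
  bad_ts <- which(is.na(data$timestamp) |
                    !grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}$",
                           data$timestamp))
  if (length(bad_ts) > 0) {
    abort(sprintf(
      "%s has unparseable timestamp(s), first at row %d: '%s'",
      source, bad_ts[1], data$timestamp[bad_ts[1]]
    ))
  }
  invisible(data)
}

# Stable sort by (participant, timestamp); ISO-8601 strings order
# lexicographically so no datetime arithmetic is needed.
sort_ema <- function(data) {
  ord <- order(data$participant_id, data$timestamp, method = "radix")
  as_tibble(data[ord, , drop = FALSE])
}

#' Drop records with anomalous values
#'
#' Removes records carrying any non-finite value, any negative actigraphy
#' (ZCM/PIM) entry, or any raw label outside the 0-100 visual-analogue range.
#' A record failing several checks is counted once, under the first matching
#' reason in the order non-finite, negative activity, label out of range.
#'
#' @param data An EMA record tibble with raw 0-100 labels.
#' @return The retained records, with a drop report attached as attribute
#'   `"clean_report"` (see [clean_report()]).
#' @export
clean_records <- function(data) {
  validate_ema(data)
  num <- as.matrix(data[, setdiff(names(data), c("participant_id", "timestamp"))])
  act <- as.matrix(data[, c(zcm_cols(), pim_cols())])
  lab <- as.matrix(data[, label_cols()])

  non_finite <- rowSums(!is.finite(num)) > 0
  negative_activity <- !non_finite & rowSums(act < 0, na.rm = TRUE) > 0
  label_range <- !non_finite & !negative_activity &
    rowSums(lab < 0 | lab > 100, na.rm = TRUE) > 0

  keep <- !(non_finite | negative_activity | label_range)
  report <- tibble(
    reason = c("non_finite", "negative_activity", "label_out_of_range"),
    dropped = c(sum(non_finite), sum(negative_activity), sum(label_range))
  )
  out <- as_tibble(data[keep, , drop = FALSE])
  if (nrow(out) == 0) {
    warn("clean_records(): no records survived cleansing")
  }
  attr(out, "clean_report") <- report
  out
}

#' Retrieve the drop report left by [clean_records()]
#'
#' @param data The tibble returned by [clean_records()].
#' @return A tibble with columns `reason` and `dropped`.
#' @export
clean_report <- function(data) {
  rep <- attr(data, "clean_report", exact = TRUE)
  if (is.null(rep)) abort("no clean report attached; run clean_records() first")
  rep
}

#' Rescale raw 0-100 labels to the unit interval
#'
#' Each of the nine mood labels is divided by 100, mapping the visual-analogue
#' scale onto \[0, 1\] as the prediction heads expect. Labels outside
#' \[0, 100\] are an error: run [clean_records()] first.
#'
#' @param data An EMA record tibble with raw labels.
#' @return The tibble with labels in \[0, 1\].
#' @export
normalize_labels <- function(data) {
  validate_ema(data)
  lab <- as.matrix(data[, label_cols()])
  bad <- which(lab < 0 | lab > 100, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "label out of [0, 100] at row %d (%s = %g); run clean_records() first",
      bad[1, 1], label_cols()[bad[1, 2]], lab[bad[1, 1], bad[1, 2]]
    ))
  }
  data[label_cols()] <- lab / 100
  data
}
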