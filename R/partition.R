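#' Time-ordered train/dev/test partition within each participant
#'
#' Splits every participant's records chronologically: the earliest
#' `fractions[1]` share goes to training, the next `fractions[2]` to the
#' development set and the remainder to the test set. Counts use
#' floor(f_train * n) and floor(f_dev * n) with the remainder assigned to
#' test; when a participant has at least three records, every split is
#' guaranteed at least one record (any shortfall is taken from the training
#' share). This per-participant temporal split is what makes dev/test
#' evaluation forecast-like: no future record ever informs the past.
#'
#' @param data An EMA record tibble, as returned by [read_ema_table()].
#' @param fractions Positive train/dev/test fractions summing to 1.
#'   Default `c(0.70, 0.15, 0.15)`.
#' @return A split tibble with one row per record: `participant_id`, `row`
#'   (1-based row index into `data`), `timestamp` and `part`
#'   (`"train"`, `"dev"` or `"test"`).
#' @export
partition_by_time <- function(data, fractions = c(0.70, 0.15, 0.15)) {
  validate_ema(data)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be three positive numbers summing to 1")
  }
  counts <- table(data$participant_id)
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    abort(sprintf(
      "participant(s) with fewer than 3 records cannot be partitioned: %s",
      paste(small, collapse = ", ")
    ))
  }
  idx <- split(seq_len(nrow(data)), data$participant_id)
  parts <- lapply(idx, function(rows) {
    ts <- data$timestamp[rows]
    rows <- rows[order(ts, method = "radix")]  # stable: ties keep input order
    n <- length(rows)
    n_tr <- floor(fractions[1] * n)
    n_de <- floor(fractions[2] * n)
    n_te <- n - n_tr - n_de
    # minimum-occupancy adjustment, shortfall taken from the training share
    if (n_de == 0) { n_de <- 1; n_tr <- n_tr - 1 }
    if (n_te == 0) { n_te <- 1; n_tr <- n_tr - 1 }
    tibble(
      row = rows,
      part = rep(c("train", "dev", "test"), c(n_tr, n_de, n_te))
    )
  })
  out <- dplyr::bind_rows(parts, .id = "participant_id")
  out$timestamp <- data$timestamp[out$row]
  out$part <- factor(out$part, levels = c("train", "dev", "test"))
  out[, c("participant_id", "row", "timestamp", "part")]
}

#' Row indices of one split part
#'
#' @param split A split tibble from [partition_by_time()].
#' @param part One of `"train"`, `"dev"`, `"test"`.
#' @return Integer row indices into the partitioned data.
#' @export
split_rows <- function(split, part = c("train", "dev", "test")) {
  part <- match.arg(part)
  sort(split$row[split$part == part])
}

#' Serialize a split as JSON
#'
#' Writes `{participant_id: {"train": [...], "dev": [...], "test": [...]}}`
#' using 0-based row indices, the interchange form used by the command-line
#' tools.
#'
#' @param split A split tibble from [partition_by_time()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  by_pid <- split(split, split$participant_id)
  obj <- lapply(by_pid, function(s) {
    lapply(stats::setNames(c("train", "dev", "test"), c("train", "dev", "test")),
           function(p) as.integer(s$row[s$part == p] - 1L))
  })
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a split written by [write_split()]
#'
#' @param data The EMA tibble the indices refer to.
#' @param path JSON path.
#' @return A split tibble (see [partition_by_time()]).
#' @export
read_split <- function(data, path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- lapply(names(obj), function(pid) {
    dplyr::bind_rows(lapply(c("train", "dev", "test"), function(p) {
      r <- as.integer(obj[[pid]][[p]]) + 1L
      if (length(r) == 0) return(NULL)
      tibble(participant_id = pid, row = r, part = p)
    }))
  })
  out <- dplyr::bind_rows(rows)
  out$timestamp <- data$timestamp[out$row]
  out$part <- factor(out$part, levels = c("train", "dev", "test"))
  out[, c("participant_id", "row", "timestamp", "part")]
}
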