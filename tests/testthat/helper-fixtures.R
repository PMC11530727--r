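# Shared fixtures: all test data is generated in code, either through the
# package's own simulator or by the tiny hand-built table below.

# A minimal EMA table built by hand (no simulator involved), small enough to
# reason about record-by-record.
make_hand_table <- function(n = 3, D = 4, pid = c("pA", "pA", "pB")) {
  stopifnot(length(pid) == n)
  ts <- sprintf("2024-01-%02dT11:00:00", seq_len(n))
  zcm <- matrix(seq_len(n * 60), n, 60)
  pim <- matrix(seq_len(n * 60) / 2, n, 60)
  sf <- matrix(rnorm(n * D), n, D)
  lab <- matrix(seq(10, 90, length.out = n * 9), n, 9)
  df <- cbind(zcm, pim, sf, lab)
  colnames(df) <- c(sprintf("zcm_%02d", 0:59), sprintf("pim_%02d", 0:59),
                    sprintf("sf_%04d", 0:(D - 1)),
                    paste0("label_", dams_emotions))
  tibble::tibble(participant_id = pid, timestamp = ts,
                 tibble::as_tibble(df))
}

# Small simulated dataset, preprocessed and split, for model-level tests.
make_sim_data <- function(n_participants = 6, n_days = 4, speech_dim = 16,
                          seed = 7, ...) {
  cf <- sim_config(n_participants = n_participants, n_days = n_days,
                   speech_dim = speech_dim, seed = seed, ...)
  simulate_ema(cf)
}

prep_pipeline <- function(data) {
  data <- normalize_labels(clean_records(data))
  split <- partition_by_time(data)
  stats <- fit_standardization(data, split)
  list(data = apply_standardization(data, stats), split = split,
       stats = stats)
}

# Numeric finite-difference gradient of f at v, central differences.
fd_grad <- function(f, v, idx = seq_along(v), h = 1e-5) {
  vapply(idx, function(i) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + h
    vm[i] <- vm[i] - h
    (f(vp) - f(vm)) / (2 * h)
  }, numeric(1))
}

# Access to internal engine helpers used by white-box tests.
mf_ns <- asNamespace("moodfuse")
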