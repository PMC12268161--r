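# Independent oracles and shared fixtures for the test suite.

# Brute-force per-sample burst scan: the reference implementation every
# envelope-level detector is compared against. Deliberately written as a
# plain loop, independent of the package's rle-based code paths.
brute_bursts <- function(env_vals, thr, rate, start = 0) {
  onsets <- offsets <- numeric(0)
  ongoing <- logical(0)
  in_b <- FALSE
  b_start <- NA_real_
  for (i in seq_along(env_vals)) {
    t <- start + (i - 1) / rate
    if (env_vals[i] > thr) {
      if (!in_b) {
        in_b <- TRUE
        b_start <- t
      }
    } else if (in_b) {
      onsets <- c(onsets, b_start)
      offsets <- c(offsets, t)
      ongoing <- c(ongoing, FALSE)
      in_b <- FALSE
    }
  }
  if (in_b) {
    onsets <- c(onsets, b_start)
    offsets <- c(offsets, start + length(env_vals) / rate)
    ongoing <- c(ongoing, TRUE)
  }
  data.frame(onset_s = onsets, offset_s = offsets,
             duration_s = offsets - onsets, ongoing = ongoing)
}

# random piecewise envelope with plateaus above/below a threshold of 1
random_envelope <- function(n, rate = 100) {
  lens <- pmax(1L, stats::rpois(50, n / 25))
  vals <- stats::runif(50, 0, 2)
  env <- rep(vals, lens)[seq_len(n)]
  env[is.na(env)] <- 0
  env
}

# feed values to a tracker/detector in random chunks, collecting all events
chunked_ingest <- function(obj, values, chunk_fn, finalize = TRUE) {
  i <- 1L
  out <- list()
  while (i <= length(values)) {
    j <- min(i + chunk_fn() - 1L, length(values))
    out[[length(out) + 1L]] <-
      if (inherits(obj, "burst_tracker")) tracker_ingest(obj, values[i:j])
      else stream_process(obj, values[i:j])
    i <- j + 1L
  }
  if (finalize && inherits(obj, "burst_detector"))
    out[[length(out) + 1L]] <- detector_finalize(obj)
  if (finalize && inherits(obj, "burst_tracker"))
    out[[length(out) + 1L]] <- burstloop:::tracker_finalize(obj)
  do.call(rbind, out)
}

# shared fitted freeze model (computed once per test session)
.fixture_env <- new.env()
fixture_freeze_model <- function() {
  if (is.null(.fixture_env$model)) {
    corpus <- synth_freeze_corpus(n_trials = 3, freeze_fraction = 0.35,
                                  seed = 300)
    .fixture_env$corpus <- corpus
    .fixture_env$model <- fit_freeze_model(corpus, seed = 301)
  }
  .fixture_env$model
}
fixture_freeze_corpus <- function() {
  fixture_freeze_model()
  .fixture_env$corpus
}

# overlap (s) between one interval and a data frame of start_s/end_s rows
interval_overlap_test <- function(start, end, df) {
  if (!nrow(df)) return(0)
  sum(pmax(0, pmin(end, df$end_s) - pmax(start, df$start_s)))
}
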