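#' Extract the sagittal-plane shank angular velocity
#'
#' Low-passes each gyroscope axis with a zero-phase 8th-order Butterworth
#' (9 Hz cut-off) and projects onto the first principal axis of the 3x3
#' sample covariance; during walking virtually all shank rotation is sagittal,
#' so the first component recovers it in any sensor orientation. The sign is
#' fixed so the dominant swing peaks are positive (positive skewness).
#'
#' @param gyro A 3-channel [multi_channel()] (or n-by-3 matrix plus `rate`)
#'   of angular velocities in deg/s.
#' @param rate Sampling rate, required when `gyro` is a matrix.
#' @return A `ts_series` of sagittal angular velocity with attributes
#'   `var_share` (variance fraction of the first component) and
#'   `low_confidence` (TRUE when `var_share < 0.5`).
#' @export
extract_sagittal <- function(gyro, rate = NULL) {
  if (inherits(gyro, "mc_series")) {
    rate <- gyro$channels[[1L]]$rate
    start <- gyro$channels[[1L]]$start
    m <- do.call(cbind, lapply(gyro$channels, function(ch) ch$values))
  } else {
    m <- as.matrix(gyro)
    if (is.null(rate)) stop("`rate` required for matrix input", call. = FALSE)
    start <- 0
  }
  if (ncol(m) != 3L) stop("need exactly 3 gyroscope axes", call. = FALSE)
  if (nrow(m) < 2 * rate)
    stop("need at least 2 s of gyroscope data", call. = FALSE)
  spec <- design_butter_lowpass(9, 8)
  co <- filter_coefs(spec, rate)
  mf <- apply(m, 2L, zero_phase_filter_values, b = co$b, a = co$a, order = 8L)
  cv <- stats::cov(mf)
  if (sum(diag(cv)) < 1e-12)
    stop("degenerate signal: no angular motion", call. = FALSE)
  eg <- eigen(cv, symmetric = TRUE)
  v <- mf %*% eg$vectors[, 1L]
  sk <- mean(((v - mean(v)) / max(stats::sd(v), 1e-12))^3)
  if (sk < 0) v <- -v
  out <- time_series(as.numeric(v), rate = rate, start = start,
                     units = "deg/s", label = "sagittal")
  attr(out, "var_share") <- eg$values[1L] / sum(eg$values)
  attr(out, "low_confidence") <- attr(out, "var_share") < 0.5
  out
}

#' Segment strides from sagittal shank angular velocity
#'
#' Mid-swing is the maximum of each contiguous region where the angular
#' velocity exceeds 0.4 times the 95th percentile of its positive values (a
#' scale-free criterion that works for slow and fast walkers alike); the
#' swing is bounded by the nearest zero crossings around mid-swing. Stride
#' time is the interval between successive mid-swings of the same leg, the
#' swing angular range is the time integral of angular velocity over the
#' swing (degrees), and the peak velocity is the maximum within the swing.
#'
#' @param sagittal A `ts_series` from [extract_sagittal()].
#' @param peak_frac Peak threshold as a fraction of the 95th percentile of
#'   positive values (default 0.4).
#' @return A `stride_table` data frame: `mid_swing_s`, `swing_start_s`,
#'   `swing_end_s`, `swing_s`, `stride_s` (NA for the first stride),
#'   `swing_range_deg`, `peak_deg_s`.
#' @export
segment_strides_imu <- function(sagittal, peak_frac = 0.4) {
  stopifnot(inherits(sagittal, "ts_series"))
  v <- sagittal$values
  tms <- ts_time(sagittal)
  empty <- data.frame(mid_swing_s = numeric(0), swing_start_s = numeric(0),
                      swing_end_s = numeric(0), swing_s = numeric(0),
                      stride_s = numeric(0), swing_range_deg = numeric(0),
                      peak_deg_s = numeric(0))
  pos <- v[v > 0]
  if (length(pos) < 2L) return(empty)
  thr <- peak_frac * stats::quantile(pos, 0.95, names = FALSE)
  r <- rle(v > thr)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  regions <- which(r$values)
  if (length(regions) < 2L) return(empty)
  mid_i <- vapply(regions, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(v[seg])]
  }, integer(1))
  nonpos <- which(v <= 0)
  rows <- lapply(mid_i, function(i) {
    before <- nonpos[nonpos < i]
    after <- nonpos[nonpos > i]
    if (!length(before) || !length(after)) return(NULL)
    s0 <- before[length(before)] + 1L   # first positive sample of the swing
    s1 <- after[1L] - 1L                # last positive sample
    data.frame(mid_swing_s = tms[i], swing_start_s = tms[s0],
               swing_end_s = tms[s1] + 1 / sagittal$rate,
               swing_s = (s1 - s0 + 1L) / sagittal$rate,
               swing_range_deg = sum(v[s0:s1]) / sagittal$rate,
               peak_deg_s = max(v[s0:s1]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$mid_swing_s), , drop = FALSE]
  out$stride_s <- c(NA_real_, diff(out$mid_swing_s))
  rownames(out) <- NULL
  out[, c("mid_swing_s", "swing_start_s", "swing_end_s", "swing_s",
          "stride_s", "swing_range_deg", "peak_deg_s")]
}

#' Mean peak shank angular velocity across both legs
#'
#' @param tables List of per-leg `stride_table`s.
#' @return Mean of the per-stride peak sagittal angular velocities (deg/s).
#' @export
mean_peak_shank_angular_velocity <- function(tables) {
  peaks <- unlist(lapply(tables, function(tb) tb$peak_deg_s))
  if (!length(peaks)) stop("no strides: metric undefined", call. = FALSE)
  mean(peaks)
}

#' Logistic freezing model
#'
#' Freeze probability from four gait features: arrhythmicity and asymmetry
#' over the last six steps, and the stride time and swing angular range of
#' the last step. Features are standardised by the stored scaling before the
#' linear predictor is applied.
#'
#' @param beta0 Intercept.
#' @param betas Named numeric vector of weights for
#'   `c("arrhythmicity6", "asymmetry6", "stride_time_last",
#'   "swing_range_last")`.
#' @param means,sds Feature scaling parameters (same order as `betas`).
#' @param threshold Freeze probability threshold (default 0.7).
#' @return A `freeze_model` object.
#' @export
freeze_model <- function(beta0, betas, means = rep(0, 4), sds = rep(1, 4),
                         threshold = 0.7) {
  nm <- c("arrhythmicity6", "asymmetry6", "stride_time_last",
          "swing_range_last")
  betas <- stats::setNames(as.numeric(betas), nm)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  structure(list(beta0 = beta0, betas = betas,
                 means = stats::setNames(as.numeric(means), nm),
                 sds = stats::setNames(as.numeric(sds), nm),
                 threshold = threshold),
            class = "freeze_model")
}

#' Freeze probability for one feature vector
#'
#' @param features Named numeric vector (or 1-row data frame) with
#'   `arrhythmicity6`, `asymmetry6`, `stride_time_last`, `swing_range_last`.
#' @param model A [freeze_model()].
#' @return Probability in `[0, 1]`.
#' @export
freeze_probability <- function(features, model) {
  stopifnot(inherits(model, "freeze_model"))
  nm <- names(model$betas)
  features <- unlist(features)
  if (!all(nm %in% names(features)) || any(!is.finite(features[nm])))
    stop("missing or non-finite feature(s): need ",
         paste(nm, collapse = ", "), call. = FALSE)
  z <- (features[nm] - model$means) / model$sds
  eta <- model$beta0 + sum(model$betas * z)
  1 / (1 + exp(-eta))
}

# Pool the two legs' stride tables into a step sequence ordered by mid-swing
# time and compute the rolling 6-step features for each step. Arrhythmicity
# and asymmetry within a window need enough strides on each leg; when a
# window cannot support them the previous value is carried forward.
step_features <- function(left_table, right_table, window = 6L) {
  lt <- left_table; rt <- right_table
  if (!nrow(lt) && !nrow(rt)) return(NULL)
  steps <- rbind(
    if (nrow(lt)) cbind(lt, leg = "left") else NULL,
    if (nrow(rt)) cbind(rt, leg = "right") else NULL
  )
  steps <- steps[order(steps$mid_swing_s), , drop = FALSE]
  n <- nrow(steps)
  arr <- asy <- rep(NA_real_, n)
  prev_arr <- prev_asy <- NA_real_
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  for (i in seq_len(n)) {
    if (i < window) next
    w <- steps[(i - window + 1L):i, ]
    a_legs <- numeric(0)
    for (lg in c("left", "right")) {
      st <- w$stride_s[w$leg == lg]
      st <- st[!is.na(st)]
      if (length(st) >= 2L) a_legs <- c(a_legs, cv(st))
    }
    arr[i] <- if (length(a_legs)) mean(a_legs) else prev_arr
    swl <- w$swing_s[w$leg == "left"]
    swr <- w$swing_s[w$leg == "right"]
    asy[i] <- if (length(swl) && length(swr))
      asymmetry(swl, swr) else prev_asy
    prev_arr <- arr[i]
    prev_asy <- asy[i]
  }
  steps$arrhythmicity6 <- arr
  steps$asymmetry6 <- asy
  steps$stride_time_last <- steps$stride_s
  steps$swing_range_last <- steps$swing_range_deg
  steps
}

#' Detect freezing episodes with the logistic model
#'
#' Evaluates the freeze probability at every step (both legs pooled, ordered
#' by mid-swing time) using the rolling 6-step feature window; contiguous
#' runs of steps with probability above the model threshold become freeze
#' intervals spanning from the first suprathreshold step's swing start to the
#' last one's swing end.
#'
#' @param left_table,right_table Per-leg `stride_table`s.
#' @param model A [freeze_model()].
#' @param trial_duration_s Trial duration for the percent-of-trial figure.
#' @return A `freeze_intervals` object with a `probabilities` attribute (the
#'   per-step probabilities).
#' @export
detect_freezes_logistic <- function(left_table, right_table, model,
                                    trial_duration_s) {
  steps <- step_features(left_table, right_table)
  if (is.null(steps) || nrow(steps) < 7L) {
    warning("fewer than 7 steps: no freeze evaluation possible")
    return(freeze_intervals(NULL, trial_duration_s))
  }
  n <- nrow(steps)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- steps[i, c("arrhythmicity6", "asymmetry6", "stride_time_last",
                    "swing_range_last")]
    if (any(!is.finite(unlist(f)))) next
    p[i] <- freeze_probability(f, model)
  }
  above <- !is.na(p) & p > model$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  mat <- if (length(runs)) {
    cbind(start = steps$swing_start_s[starts[runs]],
          end = steps$swing_end_s[ends[runs]])
  } else NULL
  out <- freeze_intervals(merge_intervals(mat), trial_duration_s)
  attr(out, "probabilities") <- data.frame(mid_swing_s = steps$mid_swing_s,
                                           p = p)
  out
}

#' Fit the logistic freezing model on a labelled stride corpus
#'
#' Standardises the four features, fits a maximum-likelihood logistic
#' regression on a 70% training split, and reports the held-out AUROC on the
#' remaining 30%.
#'
#' @param corpus Data frame with the four feature columns and a binary
#'   `freeze` label (both classes present).
#' @param seed Integer seed for the train/test split.
#' @param holdout Held-out fraction (default 0.3).
#' @return A [freeze_model()] with extra fields `auroc` (held-out) and
#'   `n_train`, `n_test`.
#' @export
fit_freeze_model <- function(corpus, seed = 1, holdout = 0.3) {
  nm <- c("arrhythmicity6", "asymmetry6", "stride_time_last",
          "swing_range_last")
  stopifnot(all(c(nm, "freeze") %in% names(corpus)))
  corpus <- corpus[stats::complete.cases(corpus[, c(nm, "freeze")]), ]
  if (length(unique(corpus$freeze)) < 2L)
    stop("corpus contains a single class: cannot fit", call. = FALSE)
  n <- nrow(corpus)
  test_idx <- with_seed(seed, sample.int(n, size = max(1L, round(holdout * n))))
  train <- corpus[-test_idx, ]
  test <- corpus[test_idx, ]
  means <- vapply(train[nm], mean, numeric(1))
  sds <- pmax(vapply(train[nm], stats::sd, numeric(1)), 1e-9)
  ztr <- as.data.frame(scale(train[nm], center = means, scale = sds))
  ztr$freeze <- train$freeze
  # a cleanly separable corpus saturates the MLE; the induced warnings are
  # expected and the fitted ranking is what detection uses
  fit <- withCallingHandlers(
    stats::glm(freeze ~ ., data = ztr, family = stats::binomial()),
    warning = function(w) {
      if (grepl("did not converge|fitted probabilities", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  model <- freeze_model(beta0 = cf[1L], betas = cf[nm], means = means,
                        sds = sds)
  zte <- as.data.frame(scale(test[nm], center = means, scale = sds))
  eta <- model$beta0 + as.matrix(zte) %*% model$betas
  p <- 1 / (1 + exp(-eta))
  model$auroc <- if (length(unique(test$freeze)) == 2L) {
    as.numeric(pROC::auc(test$freeze, as.numeric(p), quiet = TRUE,
                         direction = "<", levels = c(0, 1)))
  } else NA_real_
  model$n_train <- nrow(train)
  model$n_test <- nrow(test)
  model
}

#' RMS wrist angular velocity (bradykinesia measure)
#'
#' Low-passes the flexion-extension angular velocity with a zero-phase
#' 4th-order Butterworth at 4 Hz and returns the root-mean-square velocity.
#'
#' @param hand A `ts_series` of angular velocity in the flexion-extension
#'   plane (deg/s), at least `min_duration_s` long.
#' @param min_duration_s Minimum accepted duration (default 5 s; the task
#'   itself lasts 30 s).
#' @return Vrms in deg/s.
#' @export
wrist_vrms <- function(hand, min_duration_s = 5) {
  stopifnot(inherits(hand, "ts_series"))
  if (ts_duration(hand) < min_duration_s)
    stop("need at least ", min_duration_s, " s of data", call. = FALSE)
  f <- filter_zero_phase(hand, design_butter_lowpass(4, 4))
  sqrt(mean(f$values^2))
}

#' Wrist flexion-extension rate in cycles per second
#'
#' Counts positive-going zero crossings of the demeaned, low-passed (4 Hz,
#' zero-phase) angular velocity and divides by the duration.
#'
#' @inheritParams wrist_vrms
#' @return Cycle rate in Hz.
#' @export
wrist_cycles_per_second <- function(hand, min_duration_s = 5) {
  stopifnot(inherits(hand, "ts_series"))
  if (ts_duration(hand) < min_duration_s)
    stop("need at least ", min_duration_s, " s of data", call. = FALSE)
  f <- filter_zero_phase(hand, design_butter_lowpass(4, 4))
  v <- f$values - mean(f$values)
  up <- sum(v[-length(v)] <= 0 & v[-1L] > 0)
  up / ts_duration(hand)
}
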