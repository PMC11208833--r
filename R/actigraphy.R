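## Actigraphy: 125 Hz acceleration -> per-epoch activity counts -> Cole
## weighted-sum sleep/wake scoring -> sleep onset and total sleep time.

#' Per-epoch activity counts from accelerometry
#'
#' The activity signal is the sum of the three gravity-removed axes after
#' band-passing to 0.25-3 Hz (4th-order Butterworth, zero-phase). Counts are
#' the number of zero crossings per epoch, with crossings inside a
#' `deadband_g` dead zone ignored (samples with |x| < deadband contribute no
#' sign).
#'
#' @param accel an [accel_series()] on a uniform grid.
#' @param epoch_s epoch length, s (default 60).
#' @param band pass band, Hz.
#' @param deadband_g noise dead zone, g (default 0.01).
#' @return A list of class `activity_counts`: `counts` (integer per epoch),
#'   `epoch_s`.
#' @export
epoch_activity_counts <- function(accel, epoch_s = 60, band = c(0.25, 3),
                                  deadband_g = 0.01) {
  stopifnot(inherits(accel, "accel_series"))
  fs <- accel$fs
  dt <- diff(accel$t_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6)
    stop("non-uniform accelerometry sampling", call. = FALSE)
  dyn <- dynamic_acceleration(accel)$axes
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  s <- signal::filtfilt(bf, dyn[, 1]) + signal::filtfilt(bf, dyn[, 2]) +
    signal::filtfilt(bf, dyn[, 3])
  sgn <- integer(length(s))
  sgn[s > deadband_g] <- 1L
  sgn[s < -deadband_g] <- -1L
  nz <- which(sgn != 0L)
  n_ep <- ceiling(length(s) / (fs * epoch_s))
  counts <- integer(n_ep)
  if (length(nz) > 1) {
    cross <- nz[-1][diff(sgn[nz]) != 0L]      # sample index where sign flips
    ep <- pmin(floor((cross - 1L) / (fs * epoch_s)) + 1L, n_ep)
    tab <- tabulate(ep, nbins = n_ep)
    counts <- as.integer(tab)
  }
  structure(list(counts = counts, epoch_s = epoch_s),
            class = "activity_counts")
}

#' Default Cole scoring kernel
#'
#' The published 1-minute weighted-sum scoring equation: weights for activity
#' counts at epochs t-4 ... t+2, applied with scale 0.001; the epoch is scored
#' sleep when the weighted sum is below 1.
#' @return Numeric length-7 kernel.
#' @export
cole_weights <- function() c(106, 54, 58, 76, 230, 74, 67)

#' Cole sleep/wake scoring of activity counts
#'
#' `D_t = scale * (w1 A_{t-4} + ... + w5 A_t + w6 A_{t+1} + w7 A_{t+2})`;
#' epoch t is SLEEP iff `D_t < threshold`. Missing terms at the record
#' boundaries are zero-padded.
#'
#' @param counts an [epoch_activity_counts()] result (or integer vector).
#' @param weights length-7 kernel (default [cole_weights()]).
#' @param scale multiplier (default 0.001).
#' @param threshold sleep threshold on D (default 1).
#' @param epoch_s epoch length when `counts` is a bare vector.
#' @return A list of class `sleep_wake`: `labels` ("SLEEP"/"WAKE"), `D`,
#'   `counts`, `epoch_s`, `onset_epoch` (NA until [detect_onset()]),
#'   `total_sleep_min` (NA until [total_sleep_time()]).
#' @export
cole_score <- function(counts, weights = cole_weights(), scale = 0.001,
                       threshold = 1, epoch_s = 60) {
  if (inherits(counts, "activity_counts")) {
    epoch_s <- counts$epoch_s
    counts <- counts$counts
  }
  if (length(weights) != 7) stop("Cole kernel must have length 7", call. = FALSE)
  n <- length(counts)
  if (n < 7) stop("need at least 7 epochs to score", call. = FALSE)
  A <- c(0, 0, 0, 0, as.numeric(counts), 0, 0)
  D <- vapply(seq_len(n),
              function(t) scale * sum(weights * A[t:(t + 6L)]),
              numeric(1))
  labels <- ifelse(D < threshold, "SLEEP", "WAKE")
  structure(list(labels = labels, D = D, counts = as.integer(counts),
                 epoch_s = epoch_s, onset_epoch = NA_integer_,
                 total_sleep_min = NA_real_),
            class = "sleep_wake")
}

#' Detect sleep onset from a scored sleep/wake series
#'
#' Onset is the first epoch starting a run of at least `run_len` consecutive
#' SLEEP epochs (a persistence rule suppressing transient false sleep);
#' `NA` when no such run exists.
#'
#' @param sw a [cole_score()] result.
#' @param run_len required run length in epochs (default 10).
#' @return The `sw` with `onset_epoch` set (1-based index or NA).
#' @export
detect_onset <- function(sw, run_len = 10) {
  stopifnot(inherits(sw, "sleep_wake"))
  r <- rle(sw$labels == "SLEEP")
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= run_len)
  sw$onset_epoch <- if (length(i)) as.integer(ends[i[1]] - r$lengths[i[1]] + 1L)
                    else NA_integer_
  sw
}

#' Total sleep time
#'
#' Number of SLEEP epochs at/after onset, in minutes. Without a detected
#' onset the total is 0, with a warning.
#'
#' @param sw a [detect_onset()] result.
#' @return The `sw` with `total_sleep_min` set.
#' @export
total_sleep_time <- function(sw) {
  stopifnot(inherits(sw, "sleep_wake"))
  if (is.na(sw$onset_epoch)) {
    warning("no sleep onset detected; total sleep time set to 0")
    sw$total_sleep_min <- 0
  } else {
    n <- sum(sw$labels[sw$onset_epoch:length(sw$labels)] == "SLEEP")
    sw$total_sleep_min <- n * sw$epoch_s / 60
  }
  sw
}

#' Score a night end-to-end
#'
#' Convenience wrapper: counts -> Cole scoring -> onset -> total sleep time.
#'
#' @inheritParams epoch_activity_counts
#' @inheritParams cole_score
#' @inheritParams detect_onset
#' @return A completed `sleep_wake` object.
#' @export
score_sleep <- function(accel, epoch_s = 60, weights = cole_weights(),
                        scale = 0.001, threshold = 1, run_len = 10) {
  ac <- epoch_activity_counts(accel, epoch_s = epoch_s)
  sw <- cole_score(ac, weights = weights, scale = scale, threshold = threshold)
  total_sleep_time(detect_onset(sw, run_len = run_len))
}

#' @export
print.sleep_wake <- function(x, ...) {
  cat(sprintf("<sleep_wake> %d epochs, onset %s, total sleep %s min\n",
              length(x$labels),
              ifelse(is.na(x$onset_epoch), "none", x$onset_epoch),
              ifelse(is.na(x$total_sleep_min), "?", x$total_sleep_min)))
  invisible(x)
}
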