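## Per-minute LF/HF spectral indices from the uniform tachogram.
##
## Each 60 s window is mean-removed, Hann-tapered, and transformed with the
## FFT; the periodogram is power-normalized (divided by fs * sum(w^2)) so that
## band integrals estimate the variance contribution in ms^2. Band powers are
## Riemann sums over half-open frequency bins [lo, hi), so the 0.15 Hz
## boundary belongs to HF and LF + HF never double-count.

#' Band definition for LF and HF
#'
#' @param lf_lo,lf_hi LF band edges, Hz (defaults 0.05, 0.15).
#' @param hf_lo,hf_hi HF band edges, Hz (defaults 0.15, 0.40).
#' @return A list of class `band_definition`.
#' @export
band_definition <- function(lf_lo = 0.05, lf_hi = 0.15,
                            hf_lo = 0.15, hf_hi = 0.40) {
  if (!(0 < lf_lo && lf_lo < lf_hi && lf_hi <= hf_lo && hf_lo < hf_hi))
    stop("bands must satisfy 0 < lf_lo < lf_hi <= hf_lo < hf_hi", call. = FALSE)
  structure(list(lf_lo = lf_lo, lf_hi = lf_hi, hf_lo = hf_lo, hf_hi = hf_hi),
            class = "band_definition")
}

#' Windowed periodogram of a tachogram
#'
#' Non-overlapping (by default) windows of `window_s` seconds. A window is
#' valid when at least `min_valid_frac` of its grid points are valid; within a
#' valid window, masked points are replaced by the window mean of the valid
#' points (zero after mean removal). Invalid windows carry NA spectra.
#'
#' @param tach a [tachogram()].
#' @param window_s,step_s window and step length, s.
#' @param taper `"hann"` (default) or `"rect"` (for oracle tests).
#' @param min_valid_frac validity rule (default 0.8).
#' @return A list of class `windowed_psd`: `freqs` (Hz, excludes DC), `psd`
#'   (windows x freqs matrix, ms^2/Hz), `valid`, `start_s`, `df`.
#' @export
window_psd <- function(tach, window_s = 60, step_s = window_s,
                       taper = c("hann", "rect"), min_valid_frac = 0.8) {
  stopifnot(inherits(tach, "tachogram"))
  taper <- match.arg(taper)
  fs <- tach$grid_rate
  N <- as.integer(round(window_s * fs))
  if (N < 16) stop("window_s * grid_rate must be >= 16 samples", call. = FALSE)
  step <- as.integer(round(step_s * fs))
  n <- length(tach$values)
  starts <- seq(1L, n - N + 1L, by = step)
  if (n < N) starts <- integer(0)
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / N))
       else rep(1, N)
  W <- sum(w^2)
  nf <- N %/% 2L
  freqs <- (1:nf) * fs / N
  psd <- matrix(NA_real_, length(starts), nf)
  valid <- logical(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + N - 1L)
    vmask <- tach$valid[idx]
    if (mean(vmask) < min_valid_frac) next
    x <- tach$values[idx]
    if (!all(vmask)) x[!vmask] <- mean(x[vmask])
    x <- x - mean(x)
    X <- fft(x * w)
    p <- 2 * Mod(X[2:(nf + 1L)])^2 / (fs * W)
    if (N %% 2L == 0L) p[nf] <- p[nf] / 2   # Nyquist bin is not doubled
    psd[k, ] <- p
    valid[k] <- TRUE
  }
  structure(list(freqs = freqs, psd = psd, valid = valid,
                 start_s = (starts - 1L) / fs, df = fs / N),
            class = "windowed_psd")
}

#' Integrated band power from a periodogram
#'
#' Riemann sum of the PSD over bins with `lo <= f < hi` (half-open, so
#' adjacent bands never share a bin).
#'
#' @param freqs frequency vector, Hz.
#' @param psd PSD values (same length), ms^2/Hz.
#' @param band `c(lo, hi)` in Hz, inside `[0, Nyquist]`.
#' @param df bin width, Hz (default inferred from `freqs`).
#' @return Band power in ms^2.
#' @export
band_power <- function(freqs, psd, band, df = NULL) {
  if (band[2] <= band[1]) stop("inverted band", call. = FALSE)
  df <- df %||% (if (length(freqs) > 1) freqs[2] - freqs[1] else 0)
  sel <- freqs >= band[1] & freqs < band[2]
  sum(psd[sel]) * df
}

#' LF/HF ratio with degenerate-power guard
#'
#' Returns `lf / hf`; when `hf < eps` the ratio is undefined and `NA` is
#' returned (the caller marks the frame invalid rather than propagating an
#' infinity).
#'
#' @param lf_power,hf_power band powers, ms^2 (vectorized).
#' @param eps degeneracy threshold, ms^2.
#' @return Numeric ratio(s), NA where undefined.
#' @export
lf_hf_ratio <- function(lf_power, hf_power, eps = 1e-12) {
  if (any(lf_power < 0 | hf_power < 0, na.rm = TRUE))
    stop("band powers must be >= 0", call. = FALSE)
  ifelse(is.na(hf_power) | hf_power < eps, NA_real_, lf_power / hf_power)
}

#' Per-minute spectral frames
#'
#' One frame per minute: LF and HF band powers, their square-root-of-integral
#' amplitudes (ms), and the LF/HF power ratio. A frame is invalid when its
#' window fails the validity rule or the HF power is degenerate.
#'
#' @param tach a [tachogram()].
#' @param bands a [band_definition()].
#' @param window_s window length, s (one frame per window, no overlap).
#' @param taper passed to [window_psd()].
#' @param ratio_of_amplitudes if TRUE, `lf_hf` is the ratio of amplitudes
#'   rather than of powers (off by default).
#' @return A data.frame of class `spectral_frames` with columns `minute`,
#'   `lf_power`, `hf_power`, `lf_amp`, `hf_amp`, `lf_hf`, `valid`.
#' @export
frame_series <- function(tach, bands = band_definition(), window_s = 60,
                         taper = "hann", ratio_of_amplitudes = FALSE) {
  wp <- window_psd(tach, window_s = window_s, taper = taper)
  nw <- length(wp$valid)
  lf <- hf <- rep(NA_real_, nw)
  for (k in seq_len(nw)) {
    if (!wp$valid[k]) next
    lf[k] <- band_power(wp$freqs, wp$psd[k, ], c(bands$lf_lo, bands$lf_hi), wp$df)
    hf[k] <- band_power(wp$freqs, wp$psd[k, ], c(bands$hf_lo, bands$hf_hi), wp$df)
  }
  ratio <- if (ratio_of_amplitudes) lf_hf_ratio(sqrt(lf), sqrt(hf))
           else lf_hf_ratio(lf, hf)
  d <- data.frame(minute = wp$start_s / 60, lf_power = lf, hf_power = hf,
                  lf_amp = sqrt(lf), hf_amp = sqrt(hf), lf_hf = ratio,
                  valid = wp$valid & !is.na(ratio))
  class(d) <- c("spectral_frames", "data.frame")
  d
}

#' Per-night summary of spectral indices
#'
#' Means of LF amplitude, HF amplitude and LF/HF over valid frames falling in
#' sleep epochs (per the hypnogram), overall and per stage. Frame `minute` m
#' is aligned with hypnogram `epoch_index` m + 1.
#'
#' @param frames a [frame_series()] result.
#' @param hypnogram a `hypnogram` (from [classify_stages()] or
#'   [as_hypnogram()]).
#' @return A list of class `night_summary`: `overall` (named vector `lf_amp`,
#'   `hf_amp`, `lf_hf`, `n_frames`) and `per_stage` (data.frame by stage).
#' @export
night_summary <- function(frames, hypnogram) {
  stopifnot(inherits(frames, "spectral_frames"), inherits(hypnogram, "hypnogram"))
  epoch <- as.integer(round(frames$minute)) + 1L
  lab <- rep(NA_character_, nrow(frames))
  ok <- epoch >= 1L & epoch <= nrow(hypnogram)
  lab[ok] <- hypnogram$label[epoch[ok]]
  use <- frames$valid & !is.na(lab) & lab %in% SLEEP_ONLY
  if (!any(use)) stop("no valid sleep frames to summarize", call. = FALSE)
  mean_of <- function(sel) c(
    lf_amp = mean(frames$lf_amp[sel]), hf_amp = mean(frames$hf_amp[sel]),
    lf_hf = mean(frames$lf_hf[sel]), n_frames = sum(sel))
  per <- lapply(SLEEP_ONLY, function(st) {
    sel <- use & lab == st
    if (!any(sel)) c(lf_amp = NA_real_, hf_amp = NA_real_, lf_hf = NA_real_,
                     n_frames = 0)
    else mean_of(sel)
  })
  per_stage <- data.frame(stage = SLEEP_ONLY, do.call(rbind, per))
  structure(list(overall = mean_of(use), per_stage = per_stage),
            class = "night_summary")
}

#' @export
print.night_summary <- function(x, ...) {
  cat("<night_summary>\n overall: ")
  print(round(x$overall, 3))
  print(x$per_stage, digits = 4)
  invisible(x)
}
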