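## Three-stage autonomic sleep staging from per-minute spectral frames.
##
## Operationalization (the underlying field method is not published as an
## equation): during scored sleep, a minute is S sleep (sympathetic
## dominance) when its LF/HF ratio is at or above a per-night adaptive
## threshold; among the remaining parasympathetic minutes, depth is assigned
## by HF amplitude relative to a per-night quantile. Adaptive per-night
## thresholds make the rule robust to inter-subject HRV scale differences.

#' Classify sleep minutes into S / PS-shallow / PS-deep
#'
#' For each SLEEP epoch (per the actigraphic scoring) with a valid spectral
#' frame: label `S` if `lf_hf >= theta_s`; otherwise `PS_DEEP` if `hf_amp` is
#' at or above a per-night depth threshold; otherwise `PS_SHALLOW`. Epochs
#' with invalid frames inherit the previous epoch's sleep label (PS_SHALLOW
#' if there is none yet). Epochs before onset, or scored WAKE, are labelled
#' WAKE.
#'
#' The depth threshold is found by a 2-means split of the night's
#' parasympathetic-epoch HF amplitudes (midpoint of the two cluster centres):
#' the deep/shallow HF clusters are far apart while the fraction of deep
#' sleep varies night to night, which makes a fixed quantile mislabel
#' shallow sleep on light-sleep-heavy nights. When the two centres are not
#' clearly separated (relative gap < 0.2, e.g. a night without deep sleep or
#' a degenerate constant-amplitude recording) the rule falls back to the
#' `theta_d` quantile of the night's valid sleep-epoch HF amplitudes.
#'
#' @param frames a [frame_series()] result (frame minute m = epoch m + 1).
#' @param sw a scored [detect_onset()] `sleep_wake` with onset present.
#' @param theta_s absolute LF/HF threshold for S sleep; default
#'   `theta_s_scale` times the night's median sleep LF/HF.
#' @param theta_s_scale multiplier for the adaptive default (4). The night
#'   median sits inside the parasympathetic cluster (shallow + deep sleep
#'   dominate most nights), roughly an order of magnitude below the
#'   S-sleep cluster; a multiplier of 4 places the threshold in the gap
#'   between the clusters.
#' @param theta_d HF-amplitude quantile separating deep from shallow PS
#'   sleep in the fallback rule (default 0.60).
#' @param theta_d_method `"cluster"` (default, 2-means midpoint with quantile
#'   fallback) or `"quantile"` (always the quantile rule).
#' @return A `hypnogram` data.frame: `epoch_index`, `label`, and provenance
#'   columns `lf_hf`, `hf_amp`; attributes `epoch_s`, `onset_epoch`,
#'   `theta_s`, `theta_d_value`.
#' @export
classify_stages <- function(frames, sw, theta_s = NULL, theta_s_scale = 4,
                            theta_d = 0.60,
                            theta_d_method = c("cluster", "quantile")) {
  theta_d_method <- match.arg(theta_d_method)
  stopifnot(inherits(frames, "spectral_frames"), inherits(sw, "sleep_wake"))
  if (is.na(sw$onset_epoch))
    stop("sleep onset not detected; cannot stage", call. = FALSE)
  n <- length(sw$labels)
  epoch_of_frame <- as.integer(round(frames$minute)) + 1L
  lf_hf <- hf_amp <- rep(NA_real_, n)
  fvalid <- rep(FALSE, n)
  ok <- epoch_of_frame >= 1L & epoch_of_frame <= n
  lf_hf[epoch_of_frame[ok]] <- frames$lf_hf[ok]
  hf_amp[epoch_of_frame[ok]] <- frames$hf_amp[ok]
  fvalid[epoch_of_frame[ok]] <- frames$valid[ok]
  is_sleep <- sw$labels == "SLEEP" & seq_len(n) >= sw$onset_epoch
  use <- is_sleep & fvalid
  if (!any(use)) stop("no valid sleep frames; cannot stage", call. = FALSE)
  if (is.null(theta_s)) theta_s <- theta_s_scale * median(lf_hf[use])
  hq <- depth_threshold(hf_amp[use & lf_hf < theta_s], hf_amp[use],
                        theta_d, theta_d_method)
  labels <- rep("WAKE", n)
  prev <- NA_character_
  for (e in seq_len(n)) {
    if (!is_sleep[e]) next
    if (fvalid[e]) {
      labels[e] <- if (lf_hf[e] >= theta_s) "S"
                   else if (hf_amp[e] >= hq) "PS_DEEP"
                   else "PS_SHALLOW"
    } else {
      labels[e] <- if (is.na(prev) || prev == "WAKE") "PS_SHALLOW" else prev
    }
    prev <- labels[e]
  }
  h <- data.frame(epoch_index = seq_len(n), label = labels,
                  lf_hf = lf_hf, hf_amp = hf_amp)
  class(h) <- c("hypnogram", "data.frame")
  attr(h, "epoch_s") <- sw$epoch_s
  attr(h, "onset_epoch") <- sw$onset_epoch
  attr(h, "theta_s") <- theta_s
  attr(h, "theta_d_value") <- hq
  h
}

## Depth threshold on HF amplitude: 2-means midpoint over the
## parasympathetic epochs when the clusters are separated, else the
## theta_d quantile over all sleep epochs.
depth_threshold <- function(ps_amp, sleep_amp, theta_d, method) {
  qfall <- quantile(sleep_amp, theta_d, names = FALSE, type = 7)
  if (method == "quantile" || length(unique(ps_amp)) < 8) return(qfall)
  km <- tryCatch(
    stats::kmeans(ps_amp, centers = matrix(quantile(ps_amp, c(0.2, 0.85)), 2, 1),
                  iter.max = 50),
    error = function(e) NULL)
  if (is.null(km)) return(qfall)
  ctr <- sort(as.numeric(km$centers))
  if ((ctr[2] - ctr[1]) / ctr[2] < 0.2) return(qfall)
  mean(ctr)
}

#' Minutes spent in each sleep stage
#'
#' @param h a `hypnogram`.
#' @return Named numeric: `S`, `PS_SHALLOW`, `PS_DEEP`, `total` (minutes;
#'   total = sum of the three, i.e. total sleep time).
#' @export
stage_durations <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  ep_min <- (attr(h, "epoch_s") %||% 60) / 60
  m <- vapply(SLEEP_ONLY, function(st) sum(h$label == st) * ep_min, numeric(1))
  c(m, total = sum(m))
}

#' Plot a staged night (autonomic balance time course + stage band)
#'
#' Two stacked panels: per-minute LF and HF amplitudes, and the hypnogram as
#' a step band over wake / S / shallow PS / deep PS.
#'
#' @param h a `hypnogram` from [classify_stages()].
#' @param frames the matching [frame_series()] result.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `h`.
#' @export
plot_hypnogram <- function(h, frames, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(frames$minute, frames$lf_amp, type = "l", col = "firebrick",
                 xlab = "", ylab = "amplitude (ms)", ...)
  graphics::lines(frames$minute, frames$hf_amp, col = "navy")
  graphics::legend("topright", c("LF", "HF"), lty = 1,
                   col = c("firebrick", "navy"), bty = "n")
  lev <- c(WAKE = 4, S = 3, PS_SHALLOW = 2, PS_DEEP = 1)
  graphics::plot(h$epoch_index - 1L, lev[h$label], type = "s", yaxt = "n",
                 xlab = "minute", ylab = "", ylim = c(0.5, 4.5))
  graphics::axis(2, at = 4:1, labels = c("Wake", "S", "PS sh.", "PS deep"),
                 las = 1, cex.axis = 0.8)
  invisible(h)
}
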