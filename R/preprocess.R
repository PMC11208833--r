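## RRI cleaning: movement-artifact gating against accelerometry, ectopic
## filtering, and resampling onto a uniform tachogram grid for the FFT.

#' Gravity-removed ("dynamic") acceleration
#'
#' Gravity is taken as the per-axis median over the recording (a constant
#' offset for a sensor worn in a fixed orientation); the dynamic component is
#' each axis minus its median.
#'
#' @param accel an [accel_series()].
#' @return A list with `axes` (n x 3 matrix) and `magnitude`
#'   (`sqrt(rowSums(axes^2))`, in g).
#' @export
dynamic_acceleration <- function(accel) {
  stopifnot(inherits(accel, "accel_series"))
  m <- cbind(accel$ax_g - median(accel$ax_g),
             accel$ay_g - median(accel$ay_g),
             accel$az_g - median(accel$az_g))
  colnames(m) <- c("ax", "ay", "az")
  list(axes = m, magnitude = sqrt(rowSums(m^2)))
}

#' Flag movement artifacts in an RRI series
#'
#' An interval is flagged iff any dynamic-acceleration magnitude sample within
#' its span `[t_{i-1}, t_i)` is at or above `threshold_g`. Values are never
#' altered, only the `movement_flag` column (OR-ed with any existing flags).
#'
#' @param rri an [rri_series()].
#' @param accel an [accel_series()] covering the RRI time span.
#' @param threshold_g body-movement detection threshold in g (default 0.5).
#' @return The `rri` with updated `movement_flag`.
#' @export
flag_movement_artifacts <- function(rri, accel, threshold_g = 0.5) {
  stopifnot(inherits(rri, "rri_series"), inherits(accel, "accel_series"))
  stopifnot_scalar_num(threshold_g, "threshold_g", 0)
  t_end_s <- max(rri$t_ms) / 1000
  if (min(accel$t_s) >= t_end_s || max(accel$t_s) <= 0)
    stop("accelerometry and RRI time ranges are disjoint: misaligned recordings",
         call. = FALSE)
  mag <- dynamic_acceleration(accel)$magnitude
  hit_t <- accel$t_s[mag >= threshold_g]
  if (length(hit_t)) {
    breaks <- c(0, rri$t_ms) / 1000
    idx <- findInterval(hit_t, breaks)      # t in [t_{i-1}, t_i) -> i
    idx <- idx[idx >= 1L & idx <= nrow(rri)]
    rri$movement_flag[unique(idx)] <- TRUE
  }
  rri
}

#' Flag ectopic / outlier R-R intervals
#'
#' An interval is flagged when it lies outside `[min_ms, max_ms]` or differs
#' from the median of the 5 previous accepted (unflagged-by-this-pass)
#' intervals by more than `max_rel_jump` of that median. Values are never
#' altered.
#'
#' @param rri an [rri_series()].
#' @param min_ms,max_ms physiological bounds, ms.
#' @param max_rel_jump maximal relative deviation from the running median.
#' @return The `rri` with updated `ectopic_flag`.
#' @export
filter_ectopic <- function(rri, min_ms = 300, max_ms = 2000,
                           max_rel_jump = 0.2) {
  stopifnot(inherits(rri, "rri_series"))
  stopifnot_scalar_num(min_ms, "min_ms", 1)
  stopifnot_scalar_num(max_ms, "max_ms", min_ms)
  stopifnot_scalar_num(max_rel_jump, "max_rel_jump", 0)
  v <- rri$rri_ms
  flag <- rri$ectopic_flag
  buf <- numeric(0)                        # last <=5 accepted values
  for (i in seq_along(v)) {
    bad <- v[i] < min_ms || v[i] > max_ms
    if (!bad && length(buf) >= 5) {
      m <- median(buf)
      bad <- abs(v[i] - m) > max_rel_jump * m
    }
    if (bad) {
      flag[i] <- TRUE
    } else {
      buf <- c(buf, v[i])
      if (length(buf) > 5) buf <- buf[-1]
    }
  }
  rri$ectopic_flag <- flag
  rri
}

#' Uniform tachogram container
#'
#' @param t_s grid times, s (uniform spacing `1/grid_rate`).
#' @param values RR values on the grid, ms.
#' @param valid logical mask of grid points supported by nearby clean beats.
#' @param grid_rate grid rate, Hz.
#' @return Object of class `tachogram`.
#' @export
tachogram <- function(t_s, values, valid = TRUE, grid_rate = 4) {
  n <- length(t_s)
  if (length(values) != n)
    stop("t_s and values must have equal length", call. = FALSE)
  structure(list(t_s = t_s, values = as.numeric(values),
                 valid = rep_len(as.logical(valid), n),
                 grid_rate = grid_rate),
            class = "tachogram")
}

#' Resample a cleaned RRI series onto a uniform grid
#'
#' Cubic-spline interpolation of the unflagged `(t, RR)` pairs onto a
#' `grid_rate` Hz grid starting at t = 0. Grid points whose nearest unflagged
#' beat is more than `max_gap_s` away are masked invalid (no data are
#' fabricated across movement bouts).
#'
#' @param rri an [rri_series()] with flags set.
#' @param grid_rate grid rate, Hz (default 4).
#' @param max_gap_s support radius in seconds (default 5).
#' @return A [tachogram()].
#' @export
resample_evenly <- function(rri, grid_rate = 4, max_gap_s = 5) {
  stopifnot(inherits(rri, "rri_series"))
  stopifnot_scalar_num(grid_rate, "grid_rate", 0.1)
  good <- !rri$movement_flag & !rri$ectopic_flag
  if (sum(good) < 4)
    stop("fewer than 4 usable intervals; cannot resample", call. = FALSE)
  t <- rri$t_ms[good] / 1000
  v <- rri$rri_ms[good]
  t_end <- max(rri$t_ms) / 1000
  grid <- seq(0, t_end, by = 1 / grid_rate)
  y <- spline(t, v, xout = grid, method = "fmm")$y
  # distance from each grid point to the nearest clean beat
  lo <- findInterval(grid, t)
  d_left <- ifelse(lo >= 1, grid - t[pmax(lo, 1)], Inf)
  d_right <- ifelse(lo < length(t), t[pmin(lo + 1, length(t))] - grid, Inf)
  valid <- pmin(d_left, d_right) <= max_gap_s
  tachogram(grid, y, valid, grid_rate)
}
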