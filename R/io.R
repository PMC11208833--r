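## CSV dialects for all intermediate artifacts.

#' Read and write the pipeline's CSV formats
#'
#' RRI: `t_ms` (cumulative integer ms), `rri_ms` (integer ms), plus flag
#' columns when present. Acceleration: `t_s`, `ax_g`, `ay_g`, `az_g`.
#' Hypnogram: `epoch_index`, `label`. Frames: `minute`, `lf_power`,
#' `hf_power`, `lf_amp`, `hf_amp`, `lf_hf`, `valid`. Sleep/wake:
#' `epoch_index`, `counts`, `D`, `label`.
#'
#' @param x object to write.
#' @param path file path.
#' @name somnohrv_io
NULL

#' @rdname somnohrv_io
#' @export
write_rri_csv <- function(x, path) {
  stopifnot(inherits(x, "rri_series"))
  d <- as.data.frame(x)
  d$t_ms <- as.integer(round(d$t_ms))
  d$rri_ms <- as.integer(round(d$rri_ms))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname somnohrv_io
#' @export
read_rri_csv <- function(path) {
  d <- read.csv(path)
  rri_series(d$rri_ms,
             movement_flag = d$movement_flag %||% FALSE,
             ectopic_flag = d$ectopic_flag %||% FALSE)
}

#' @rdname somnohrv_io
#' @export
write_accel_csv <- function(x, path) {
  stopifnot(inherits(x, "accel_series"))
  write.csv(data.frame(t_s = x$t_s, ax_g = x$ax_g, ay_g = x$ay_g,
                       az_g = x$az_g), path, row.names = FALSE)
  invisible(path)
}

#' @rdname somnohrv_io
#' @export
read_accel_csv <- function(path, fs = NULL) {
  d <- read.csv(path)
  fs <- fs %||% round(1 / median(diff(d$t_s)))
  accel_series(d$t_s, d$ax_g, d$ay_g, d$az_g, fs = fs)
}

#' @rdname somnohrv_io
#' @export
write_hypnogram_csv <- function(x, path) {
  stopifnot(inherits(x, "hypnogram"))
  write.csv(data.frame(epoch_index = x$epoch_index, label = x$label),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname somnohrv_io
#' @export
read_hypnogram_csv <- function(path) {
  d <- read.csv(path)
  h <- data.frame(epoch_index = d$epoch_index, label = d$label,
                  lf_hf = NA_real_, hf_amp = NA_real_)
  class(h) <- c("hypnogram", "data.frame")
  attr(h, "epoch_s") <- 60
  h
}

#' @rdname somnohrv_io
#' @export
write_frames_csv <- function(x, path) {
  stopifnot(inherits(x, "spectral_frames"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname somnohrv_io
#' @export
write_sleep_csv <- function(x, path) {
  stopifnot(inherits(x, "sleep_wake"))
  write.csv(data.frame(epoch_index = seq_along(x$labels), counts = x$counts,
                       D = x$D, label = x$labels), path, row.names = FALSE)
  invisible(path)
}
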