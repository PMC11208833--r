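## Synthetic overnight recordings with known ground truth.
##
## The generator is deliberately simple and analytically checkable: the RRI
## tachogram is mean RR plus stage-dependent sinusoidal LF and HF tones plus
## white noise; stage dynamics are a first-order Markov chain; movement is a
## stage-dependent Poisson process of short oscillatory bursts riding on a
## constant 1 g gravity axis.

#' Stage sequence (ground-truth hypnogram skeleton)
#'
#' @param labels character vector over [stage_labels()], one per epoch.
#' @param epoch_s epoch length in seconds (default 60).
#' @param onset_latency_min minutes of leading wake the sequence was generated
#'   with (informational; checked against `labels` when > 0).
#' @return An object of class `stage_sequence`.
#' @export
stage_sequence <- function(labels, epoch_s = 60, onset_latency_min = 0) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), SLEEP_STAGES)
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot_scalar_num(epoch_s, "epoch_s", 1)
  stopifnot_scalar_num(onset_latency_min, "onset_latency_min", 0)
  lat_ep <- floor(onset_latency_min * 60 / epoch_s)
  if (lat_ep > 0 && length(labels) >= 1) {
    lead <- labels[seq_len(min(lat_ep, length(labels)))]
    if (any(lead != "WAKE"))
      stop("onset_latency_min > 0 requires leading WAKE epochs", call. = FALSE)
  }
  structure(list(labels = labels, epoch_s = epoch_s,
                 onset_latency_min = onset_latency_min),
            class = "stage_sequence")
}

#' @export
print.stage_sequence <- function(x, ...) {
  cat(sprintf("<stage_sequence> %d epochs x %ds, onset latency %g min\n",
              length(x$labels), x$epoch_s, x$onset_latency_min))
  print(table(factor(x$labels, levels = SLEEP_STAGES)))
  invisible(x)
}

#' Default stage-transition matrix
#'
#' First-order Markov transition probabilities over
#' WAKE, S, PS_SHALLOW, PS_DEEP (rows = from, columns = to). Dwell times are a
#' couple of minutes; brief nocturnal awakenings are rare (re-entry ~0.3%
#' per sleep epoch, roughly 1-2 brief arousals per full night); the
#' stationary stage mix within sleep is roughly 20% S-sleep, 46% shallow PS
#' and 34% deep PS.
#'
#' @return A 4x4 row-stochastic matrix with dimnames over [stage_labels()].
#' @export
default_transition_matrix <- function() {
  P <- rbind(
    WAKE       = c(0.250, 0.350, 0.300, 0.100),
    S          = c(0.0030, 0.5620, 0.3800, 0.0550),
    PS_SHALLOW = c(0.0030, 0.1650, 0.5500, 0.2820),
    PS_DEEP    = c(0.0025, 0.0500, 0.3445, 0.6030)
  )
  colnames(P) <- SLEEP_STAGES
  P
}

#' Stationary distribution of a stage-transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to one.
#'
#' @param P row-stochastic square matrix.
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  check_transition_matrix(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- rownames(P)
  v
}

check_transition_matrix <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("transition matrix must be square", call. = FALSE)
  if (any(P < 0))
    stop("transition probabilities must be non-negative", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix rows must each sum to 1", call. = FALSE)
  invisible(P)
}

#' Generate a ground-truth hypnogram
#'
#' Simulates per-minute stage labels: `onset_latency_min` leading WAKE epochs,
#' then a first-order Markov chain over the four states. With zero latency the
#' chain starts from its stationary distribution.
#'
#' @param duration_min total number of 1-min epochs.
#' @param transition 4x4 row-stochastic matrix over [stage_labels()].
#' @param onset_latency_min minutes of forced leading wake
#'   (must be <= duration).
#' @param seed optional integer seed.
#' @param epoch_s epoch length in seconds.
#' @return A [stage_sequence()].
#' @export
generate_hypnogram <- function(duration_min,
                               transition = default_transition_matrix(),
                               onset_latency_min = 15,
                               seed = NULL,
                               epoch_s = 60) {
  stopifnot_scalar_num(duration_min, "duration_min", 0)
  stopifnot_scalar_num(onset_latency_min, "onset_latency_min", 0)
  if (onset_latency_min > duration_min)
    stop("duration_min must be >= onset_latency_min", call. = FALSE)
  check_transition_matrix(transition)
  if (!identical(rownames(transition), SLEEP_STAGES))
    stop("transition matrix dimnames must be ",
         paste(SLEEP_STAGES, collapse = ", "), call. = FALSE)
  n <- as.integer(round(duration_min))
  lat <- as.integer(round(onset_latency_min))
  with_seed(seed, {
    labels <- character(n)
    if (n == 0L)
      return(stage_sequence(labels, epoch_s, onset_latency_min))
    if (lat > 0) labels[seq_len(min(lat, n))] <- "WAKE"
    if (lat < n) {
      if (lat > 0) {
        # leave wake into a sleep state according to the WAKE row restricted
        # to sleep states
        w <- transition["WAKE", SLEEP_ONLY]
        state <- if (sum(w) > 0) sample(SLEEP_ONLY, 1, prob = w)
                 else sample(SLEEP_ONLY, 1)
      } else {
        state <- sample(SLEEP_STAGES, 1, prob = stationary_distribution(transition))
      }
      labels[lat + 1L] <- state
      if (lat + 1L < n) {
        for (i in (lat + 2L):n) {
          state <- sample(SLEEP_STAGES, 1, prob = transition[state, ])
          labels[i] <- state
        }
      }
    }
    stage_sequence(labels, epoch_s, onset_latency_min)
  })
}

#' Per-stage autonomic profile for RRI synthesis
#'
#' The tachogram model is
#' `RR(t) = mean_rr + A_LF(stage) sin(2 pi f_lf t) + A_HF(stage) sin(2 pi f_hf t) + e`,
#' with `e ~ N(0, noise_sd^2)` white per beat. Carrier frequencies must lie
#' strictly inside the LF (0.05-0.15 Hz) and HF (0.15-0.40 Hz) bands.
#' Construction rejects parameter sets for which RR <= 0 is reachable
#' (deterministic amplitude sum plus a 6-sigma noise allowance).
#'
#' @param lf_amp,hf_amp modulation amplitude in ms: a scalar or a named vector
#'   over [stage_labels()].
#' @param f_lf,f_hf carrier frequencies in Hz.
#' @param mean_rr mean R-R interval, ms (400-1500).
#' @param noise_sd white-noise SD, ms.
#' @return An object of class `autonomic_profile`.
#' @export
autonomic_profile <- function(lf_amp, hf_amp, f_lf = 0.10, f_hf = 0.25,
                              mean_rr = 900, noise_sd = 20) {
  expand <- function(a, name) {
    if (length(a) == 1L && is.null(names(a)))
      a <- setNames(rep(as.numeric(a), 4L), SLEEP_STAGES)
    if (!all(SLEEP_STAGES %in% names(a)))
      stop(sprintf("`%s` must be scalar or named over all stages", name),
           call. = FALSE)
    a <- a[SLEEP_STAGES]
    if (any(a < 0)) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
    a
  }
  lf_amp <- expand(lf_amp, "lf_amp")
  hf_amp <- expand(hf_amp, "hf_amp")
  stopifnot_scalar_num(f_lf, "f_lf")
  stopifnot_scalar_num(f_hf, "f_hf")
  if (f_lf <= 0.05 || f_lf >= 0.15)
    stop("f_lf must lie strictly inside the LF band (0.05, 0.15) Hz",
         call. = FALSE)
  if (f_hf <= 0.15 || f_hf >= 0.40)
    stop("f_hf must lie strictly inside the HF band (0.15, 0.40) Hz",
         call. = FALSE)
  stopifnot_scalar_num(mean_rr, "mean_rr", 400, 1500)
  stopifnot_scalar_num(noise_sd, "noise_sd", 0)
  if (mean_rr - max(lf_amp + hf_amp) - 6 * noise_sd <= 0)
    stop("modulation amplitudes/noise too large: RR <= 0 would be reachable",
         call. = FALSE)
  structure(list(lf_amp = lf_amp, hf_amp = hf_amp, f_lf = f_lf, f_hf = f_hf,
                 mean_rr = mean_rr, noise_sd = noise_sd),
            class = "autonomic_profile")
}

#' Default autonomic profile
#'
#' Stage-wise tone amplitudes chosen so the realized per-minute band powers
#' reproduce the qualitative autonomic signature of the three sleep stages:
#' S sleep strongly LF-dominant (realized LF/HF ~ 4-5), shallow PS mildly
#' HF-dominant (~0.4), deep PS strongly HF-dominant (~0.05) with the largest
#' HF amplitude. Mean RR 900 ms and beat noise SD 15 ms are plausibility
#' defaults; note that beat noise, resampled onto the tachogram grid,
#' concentrates below the beat Nyquist and so contributes to both bands.
#'
#' @param lf_scale,hf_scale multipliers applied to all stage amplitudes
#'   (used by cohort designs to impose group/day effects).
#' @inheritParams autonomic_profile
#' @return An `autonomic_profile`.
#' @export
default_autonomic_profile <- function(lf_scale = 1, hf_scale = 1,
                                      mean_rr = 900, noise_sd = 15) {
  autonomic_profile(
    lf_amp = lf_scale * c(WAKE = 20, S = 36, PS_SHALLOW = 12, PS_DEEP = 10),
    hf_amp = hf_scale * c(WAKE = 10, S = 10, PS_SHALLOW = 18, PS_DEEP = 55),
    mean_rr = mean_rr, noise_sd = noise_sd)
}

#' R-R interval series container
#'
#' @param rri_ms positive interval lengths, ms (integer ms: the acquisition
#'   timing resolution is 1 kHz).
#' @param movement_flag,ectopic_flag logical per-interval artifact flags.
#' @return Object of class `rri_series`: a data.frame with columns `t_ms`
#'   (cumulative end time of each interval; interval i spans `(t_{i-1}, t_i]`
#'   with the first interval starting at 0), `rri_ms`, `movement_flag`,
#'   `ectopic_flag`.
#' @export
rri_series <- function(rri_ms, movement_flag = FALSE, ectopic_flag = FALSE) {
  rri_ms <- as.numeric(rri_ms)
  if (any(rri_ms <= 0)) stop("rri_ms must be > 0", call. = FALSE)
  d <- data.frame(t_ms = cumsum(rri_ms), rri_ms = rri_ms,
                  movement_flag = rep_len(as.logical(movement_flag), length(rri_ms)),
                  ectopic_flag = rep_len(as.logical(ectopic_flag), length(rri_ms)))
  class(d) <- c("rri_series", "data.frame")
  d
}

#' Generate a synthetic R-R interval series from a stage sequence
#'
#' Each beat's RR is evaluated at the cumulative time of the previous beat:
#' stage-dependent LF and HF sine tones on top of the mean RR, plus white
#' noise, rounded to integer ms.
#'
#' @param stages a [stage_sequence()].
#' @param profile an [autonomic_profile()].
#' @param seed optional integer seed.
#' @return An [rri_series()] covering the stage sequence's duration.
#' @export
generate_rri <- function(stages, profile = default_autonomic_profile(),
                         seed = NULL) {
  stopifnot(inherits(stages, "stage_sequence"),
            inherits(profile, "autonomic_profile"))
  dur_s <- length(stages$labels) * stages$epoch_s
  if (dur_s <= 0) stop("empty stage sequence", call. = FALSE)
  n_guess <- ceiling(dur_s / (profile$mean_rr / 1000) * 1.25) + 16L
  with_seed(seed, {
    noise <- rnorm(n_guess, 0, profile$noise_sd)
    rri <- numeric(n_guess)
    lf <- profile$lf_amp; hf <- profile$hf_amp
    wlf <- 2 * pi * profile$f_lf; whf <- 2 * pi * profile$f_hf
    labs <- stages$labels; ep_s <- stages$epoch_s; n_ep <- length(labs)
    t <- 0; i <- 0L
    while (t < dur_s) {
      i <- i + 1L
      if (i > length(noise)) noise <- c(noise, rnorm(n_guess, 0, profile$noise_sd))
      st <- labs[min(floor(t / ep_s) + 1, n_ep)]
      rr <- profile$mean_rr + lf[[st]] * sin(wlf * t) + hf[[st]] * sin(whf * t) +
        noise[i]
      rr <- round(rr)
      if (rr <= 0) stop("generated RR <= 0; profile amplitudes too large",
                        call. = FALSE)
      rri[i] <- rr
      t <- t + rr / 1000
    }
    rri_series(rri[seq_len(i)])
  })
}

#' Movement-burst specification for synthetic accelerometry
#'
#' Bursts are Hann-enveloped sine packets on the x axis at `freq_hz`; gravity
#' is a constant 1 g on the z axis. Wake movements are frequent, large and
#' long; sleep movements rare, small and short. Per-axis sensor noise is
#' Gaussian with SD `noise_g`.
#'
#' @param rate_per_min named per-stage burst rate (bursts/min).
#' @param amp_range named list of c(lo, hi) burst amplitudes in g per stage.
#' @param dur_range named list of c(lo, hi) burst durations in seconds.
#' @param freq_hz burst oscillation frequency (inside the 0.25-3 Hz activity
#'   band).
#' @param noise_g sensor noise SD in g.
#' @return A list of class `burst_spec`.
#' @export
burst_spec <- function(rate_per_min = c(WAKE = 1.5, S = 0.06,
                                        PS_SHALLOW = 0.06, PS_DEEP = 0.06),
                       amp_range = list(WAKE = c(0.30, 0.70), S = c(0.03, 0.12),
                                        PS_SHALLOW = c(0.03, 0.12),
                                        PS_DEEP = c(0.03, 0.12)),
                       dur_range = list(WAKE = c(0.8, 1.4), S = c(0.25, 0.35),
                                        PS_SHALLOW = c(0.25, 0.35),
                                        PS_DEEP = c(0.25, 0.35)),
                       freq_hz = 2.5, noise_g = 0.002) {
  for (nm in SLEEP_STAGES) {
    if (is.na(rate_per_min[nm]) || rate_per_min[nm] < 0)
      stop("burst rate must be >= 0 for every stage", call. = FALSE)
    if (any(amp_range[[nm]] < 0) || diff(amp_range[[nm]]) < 0)
      stop("amp_range must be non-negative increasing pairs", call. = FALSE)
  }
  stopifnot_scalar_num(freq_hz, "freq_hz", 0.05)
  stopifnot_scalar_num(noise_g, "noise_g", 0)
  structure(list(rate_per_min = rate_per_min, amp_range = amp_range,
                 dur_range = dur_range, freq_hz = freq_hz, noise_g = noise_g),
            class = "burst_spec")
}

#' 3-axis acceleration series container
#'
#' @param t_s sample times, s (uniform grid).
#' @param ax_g,ay_g,az_g per-axis acceleration in g.
#' @param fs sampling rate, Hz.
#' @param bursts optional ground-truth burst table
#'   (`t_start_s`, `duration_s`, `amp_g`, `epoch`, `stage`).
#' @return Object of class `accel_series`.
#' @export
accel_series <- function(t_s, ax_g, ay_g, az_g, fs = 125, bursts = NULL) {
  n <- length(t_s)
  stopifnot(length(ax_g) == n, length(ay_g) == n, length(az_g) == n)
  structure(list(t_s = t_s, ax_g = ax_g, ay_g = ay_g, az_g = az_g,
                 fs = fs, bursts = bursts),
            class = "accel_series")
}

#' Generate synthetic 125 Hz accelerometry for a stage sequence
#'
#' Per epoch, the number of movement bursts is Poisson with the stage's rate;
#' burst start times are uniform in the epoch, amplitudes and durations
#' uniform in the stage's ranges. Every generated burst is returned as ground
#' truth. `scripted_bursts` (a data.frame `t_start_s`, `duration_s`, `amp_g`,
#' optional `envelope` = "hann"/"rect") are injected verbatim in addition to
#' the random ones.
#'
#' @inheritParams generate_rri
#' @param spec a [burst_spec()].
#' @param fs sampling rate, Hz (default 125).
#' @param scripted_bursts optional data.frame of deterministic bursts.
#' @return An [accel_series()] with `$bursts` ground truth.
#' @export
generate_accel <- function(stages, spec = burst_spec(), fs = 125, seed = NULL,
                           scripted_bursts = NULL) {
  stopifnot(inherits(stages, "stage_sequence"), inherits(spec, "burst_spec"))
  ep_s <- stages$epoch_s
  n_ep <- length(stages$labels)
  dur_s <- n_ep * ep_s
  n <- as.integer(round(dur_s * fs))
  t_s <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    ax <- rnorm(n, 0, spec$noise_g)
    ay <- rnorm(n, 0, spec$noise_g)
    az <- 1 + rnorm(n, 0, spec$noise_g)
    truth <- list()
    add_burst <- function(t0, dur, amp, envelope = "hann") {
      i0 <- max(1L, floor(t0 * fs) + 1L)
      i1 <- min(n, floor((t0 + dur) * fs) + 1L)
      if (i1 <= i0) return()
      tt <- t_s[i0:i1] - t0
      env <- if (envelope == "rect") 1 else 0.5 * (1 - cos(2 * pi * tt / dur))
      ax[i0:i1] <<- ax[i0:i1] + amp * env * sin(2 * pi * spec$freq_hz * tt)
    }
    for (e in seq_len(n_ep)) {
      st <- stages$labels[e]
      k <- rpois(1, spec$rate_per_min[[st]] * ep_s / 60)
      if (k == 0) next
      t0 <- (e - 1) * ep_s + runif(k, 0, ep_s)
      amp <- runif(k, spec$amp_range[[st]][1], spec$amp_range[[st]][2])
      dur <- runif(k, spec$dur_range[[st]][1], spec$dur_range[[st]][2])
      for (j in seq_len(k)) add_burst(t0[j], dur[j], amp[j])
      truth[[length(truth) + 1L]] <-
        data.frame(t_start_s = t0, duration_s = dur, amp_g = amp,
                   epoch = e, stage = st)
    }
    if (!is.null(scripted_bursts) && nrow(scripted_bursts)) {
      env <- scripted_bursts$envelope %||% rep("hann", nrow(scripted_bursts))
      for (j in seq_len(nrow(scripted_bursts)))
        add_burst(scripted_bursts$t_start_s[j], scripted_bursts$duration_s[j],
                  scripted_bursts$amp_g[j], env[j])
      ep <- pmin(floor(scripted_bursts$t_start_s / ep_s) + 1L, n_ep)
      truth[[length(truth) + 1L]] <-
        data.frame(t_start_s = scripted_bursts$t_start_s,
                   duration_s = scripted_bursts$duration_s,
                   amp_g = scripted_bursts$amp_g,
                   epoch = ep, stage = stages$labels[ep])
    }
    bursts <- if (length(truth)) do.call(rbind, truth)
              else data.frame(t_start_s = numeric(0), duration_s = numeric(0),
                              amp_g = numeric(0), epoch = integer(0),
                              stage = character(0))
    bursts <- bursts[order(bursts$t_start_s), , drop = FALSE]
    rownames(bursts) <- NULL
    accel_series(t_s, ax, ay, az, fs = fs, bursts = bursts)
  })
}

#' Cohort design for multi-night synthetic studies
#'
#' Two groups (Mi = practicing mindful breathing, nMi = control), measurement
#' days 1, 5 and 9, `n_per_group` subjects each. Group/day effects enter as
#' multipliers on the LF and HF tone amplitudes of the base profile;
#' between-subject heterogeneity as a per-subject lognormal amplitude
#' multiplier (SD `subject_cv` on the log scale, constant across days).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param days measurement days.
#' @param night_min night length in minutes.
#' @param onset_latency_range min/max sleep-onset latency minutes (drawn
#'   uniformly per night).
#' @param lf_scale,hf_scale numeric matrices `groups x days` of amplitude
#'   multipliers (default all 1).
#' @param base_profile base [autonomic_profile()].
#' @param transition stage-transition matrix.
#' @param spec movement [burst_spec()].
#' @param subject_cv between-subject lognormal sigma for amplitudes.
#' @param include_accel generate accelerometry? (Skip for summary-level
#'   statistical simulations where the ground-truth hypnogram is used
#'   directly.)
#' @param master_seed master seed; all per-night seeds derive from it.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 9, days = c(1, 5, 9), night_min = 420,
                          onset_latency_range = c(10, 30),
                          lf_scale = NULL, hf_scale = NULL,
                          base_profile = default_autonomic_profile(),
                          transition = default_transition_matrix(),
                          spec = burst_spec(), subject_cv = 0.10,
                          include_accel = TRUE, master_seed = 20220501) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  groups <- c("Mi", "nMi")
  mk <- function(m) {
    if (is.null(m)) m <- matrix(1, 2, length(days),
                                dimnames = list(groups, as.character(days)))
    if (!all(dim(m) == c(2, length(days))))
      stop("scale matrices must be groups x days", call. = FALSE)
    dimnames(m) <- list(groups, as.character(days))
    m
  }
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 days = days, night_min = night_min,
                 onset_latency_range = onset_latency_range,
                 lf_scale = mk(lf_scale), hf_scale = mk(hf_scale),
                 base_profile = base_profile, transition = transition,
                 spec = spec, subject_cv = subject_cv,
                 include_accel = include_accel,
                 master_seed = as.integer(master_seed)),
            class = "cohort_design")
}

#' Generate a synthetic cohort of overnight recordings
#'
#' One recording per (group, subject, day). Fully reproducible from the
#' design's master seed; each night's RRI, accelerometry, ground-truth stage
#' sequence and movement bursts are returned together with the profile used,
#' so per-cell generating parameters are recoverable for parameter-recovery
#' tests.
#'
#' @param design a [cohort_design()].
#' @return A list of class `cohort`: `$design` and `$nights`, each night a
#'   list with `group`, `subject`, `day`, `rri`, `accel` (or NULL),
#'   `stages`, `onset_latency_min`, `profile`.
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  nights <- list()
  for (gi in seq_along(design$groups)) {
    g <- design$groups[gi]
    for (s in seq_len(design$n_per_group)) {
      subj_mult <- with_seed(derive_seed(design$master_seed, gi, s, 0, 0),
                             exp(rnorm(1, 0, design$subject_cv)))
      for (di in seq_along(design$days)) {
        d <- design$days[di]
        sd_night <- derive_seed(design$master_seed, gi, s, di, 1)
        lat <- with_seed(derive_seed(design$master_seed, gi, s, di, 2),
                         round(runif(1, design$onset_latency_range[1],
                                     design$onset_latency_range[2])))
        lat <- min(lat, floor(design$night_min / 2))
        stages <- generate_hypnogram(design$night_min, design$transition,
                                     onset_latency_min = lat,
                                     seed = derive_seed(design$master_seed,
                                                        gi, s, di, 3))
        bp <- design$base_profile
        prof <- autonomic_profile(
          lf_amp = bp$lf_amp * design$lf_scale[g, as.character(d)] * subj_mult,
          hf_amp = bp$hf_amp * design$hf_scale[g, as.character(d)] * subj_mult,
          f_lf = bp$f_lf, f_hf = bp$f_hf,
          mean_rr = bp$mean_rr, noise_sd = bp$noise_sd)
        rri <- generate_rri(stages, prof, seed = sd_night)
        accel <- if (design$include_accel)
          generate_accel(stages, design$spec,
                         seed = derive_seed(design$master_seed, gi, s, di, 4))
        else NULL
        nights[[length(nights) + 1L]] <-
          list(group = g, subject = s, day = d, rri = rri, accel = accel,
               stages = stages, onset_latency_min = lat, profile = prof)
      }
    }
  }
  structure(list(design = design, nights = nights), class = "cohort")
}

#' Cohort design for the LF effect-recovery experiment
#'
#' A two-group repeated-measurement design in which the intervention group's
#' LF tone amplitude declines across measurement days (S-stage amplitude
#' 30 -> 20 -> 15 ms, all stages scaled proportionally) while the control
#' group stays flat. The base profile uses a 6 ms beat-noise SD and the
#' between-subject CV is 0.06, so the configured amplitude steps correspond
#' to standardized effects in the strongly significant regime the trial
#' statistics are meant to resolve; nights are 60 min (the per-night LF
#' summary stabilizes well below that length).
#'
#' @param master_seed master seed.
#' @param night_min night length in minutes.
#' @return A [cohort_design()].
#' @export
lf_decline_design <- function(master_seed, night_min = 60) {
  cohort_design(
    n_per_group = 9, days = c(1, 5, 9), night_min = night_min,
    onset_latency_range = c(3, 8), include_accel = FALSE, subject_cv = 0.06,
    base_profile = autonomic_profile(
      lf_amp = c(WAKE = 20, S = 30, PS_SHALLOW = 12, PS_DEEP = 10),
      hf_amp = c(WAKE = 10, S = 10, PS_SHALLOW = 18, PS_DEEP = 55),
      noise_sd = 6),
    lf_scale = matrix(c(1, 2 / 3, 0.5, 1, 1, 1), 2, 3, byrow = TRUE,
                      dimnames = list(c("Mi", "nMi"), c("1", "5", "9"))),
    master_seed = master_seed)
}

#' Per-night LF amplitude summaries of a summary-level cohort
#'
#' Resamples each night's RRI, computes per-minute frames, and averages the
#' LF amplitude over the ground-truth sleep epochs. Used by the statistical
#' recovery experiments, which do not involve the actigraphy chain.
#'
#' @param cohort a [generate_cohort()] result (accelerometry not required).
#' @return A data.frame: `group`, `subject`, `day`, `lf`.
#' @export
cohort_lf_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$nights, function(nt) {
    fr <- frame_series(resample_evenly(nt$rri))
    data.frame(group = nt$group, subject = nt$subject, day = nt$day,
               lf = night_summary(fr, as_hypnogram(nt$stages))$overall[["lf_amp"]])
  })
  do.call(rbind, rows)
}

#' Convert a ground-truth stage sequence to a hypnogram object
#'
#' @param stages a [stage_sequence()].
#' @return A `hypnogram` data.frame (`epoch_index`, `label`) as produced by
#'   [classify_stages()], with NA provenance columns.
#' @export
as_hypnogram <- function(stages) {
  stopifnot(inherits(stages, "stage_sequence"))
  n <- length(stages$labels)
  h <- data.frame(epoch_index = seq_len(n), label = stages$labels,
                  lf_hf = rep(NA_real_, n), hf_amp = rep(NA_real_, n))
  class(h) <- c("hypnogram", "data.frame")
  attr(h, "epoch_s") <- stages$epoch_s
  h
}
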