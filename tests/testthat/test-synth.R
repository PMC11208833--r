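test_that("hypnogram generation honours latency, absorbing states, and rejects bad input", {
  # latency consuming the whole night
  h <- generate_hypnogram(10, onset_latency_min = 10, seed = 1)
  expect_identical(h$labels, rep("WAKE", 10))

  # absorbing deep-sleep state
  P <- matrix(0, 4, 4, dimnames = list(stage_labels(), stage_labels()))
  P[, "PS_DEEP"] <- 1
  h <- generate_hypnogram(360, transition = P, onset_latency_min = 0, seed = 2)
  expect_identical(h$labels, rep("PS_DEEP", 360))

  expect_error(generate_hypnogram(5, onset_latency_min = 10), "onset_latency")
  expect_error(generate_hypnogram(-3), "duration_min")
  bad <- default_transition_matrix(); bad[1, 1] <- 2
  expect_error(generate_hypnogram(30, transition = bad), "sum to 1")
})

test_that("stage fractions track the stationary distribution of the chain", {
  P <- default_transition_matrix()
  pi <- stationary_distribution(P)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_equal(as.numeric(pi %*% P), as.numeric(pi), tolerance = 1e-12)
  # horizon long enough that the +-0.05 band is several SDs wide
  # (dwell ~2 epochs gives fraction SDs ~0.045 at 420 epochs, ~0.014 here)
  h <- generate_hypnogram(2000, onset_latency_min = 0, seed = 42)
  emp <- table(factor(h$labels, levels = stage_labels())) / 2000
  expect_true(all(abs(as.numeric(emp) - pi) < 0.05))
})

test_that("hypnogram generation is deterministic under a fixed seed", {
  a <- generate_hypnogram(200, seed = 7)
  b <- generate_hypnogram(200, seed = 7)
  expect_identical(a, b)
})

test_that("RRI generator satisfies its timing contract and degenerate cases", {
  st <- stage_sequence(rep("S", 5))
  flat <- autonomic_profile(0, 0, noise_sd = 0)
  r <- generate_rri(st, flat, seed = 1)
  expect_true(all(r$rri_ms == 900))
  expect_true(all(diff(r$t_ms) > 0))
  expect_equal(diff(c(0, r$t_ms)), r$rri_ms)

  # amplitude large enough to reach RR <= 0 is rejected at construction
  expect_error(autonomic_profile(500, 450, mean_rr = 900, noise_sd = 0),
               "RR <= 0")
})

test_that("RRI generator realizes the configured spectral structure", {
  st <- stage_sequence(rep("S", 10))
  # single LF tone: nearly all in-band power in LF
  lf_only <- autonomic_profile(30, 0, noise_sd = 0)
  r <- generate_rri(st, lf_only, seed = 3)
  fr <- frame_series(resample_evenly(r))
  lf <- sum(fr$lf_power); hf <- sum(fr$hf_power)
  expect_gt(lf / (lf + hf), 0.95)

  # equal tones: Parseval says each band holds a^2/2; ratio 1 within 10%
  eq <- autonomic_profile(20, 20, noise_sd = 0)
  r2 <- generate_rri(st, eq, seed = 4)
  fr2 <- frame_series(resample_evenly(r2))
  expect_equal(mean(fr2$lf_power) / mean(fr2$hf_power), 1, tolerance = 0.10)
  expect_equal(mean(fr2$lf_power), 20^2 / 2, tolerance = 0.10)

  # per-stage band-power ratio ~ A_LF^2 / A_HF^2 on long windows
  two <- autonomic_profile(30, 15, noise_sd = 0)
  r3 <- generate_rri(st, two, seed = 5)
  fr3 <- frame_series(resample_evenly(r3))
  expect_equal(mean(fr3$lf_power) / mean(fr3$hf_power), 4, tolerance = 0.15)
})

test_that("accelerometry generator returns complete ground truth", {
  quiet <- burst_spec(rate_per_min = c(WAKE = 0, S = 0, PS_SHALLOW = 0,
                                       PS_DEEP = 0), noise_g = 0)
  st <- stage_sequence(rep("WAKE", 5))
  acc <- generate_accel(st, quiet, seed = 1)
  expect_equal(max(dynamic_acceleration(acc)$magnitude), 0)
  expect_equal(nrow(acc$bursts), 0)

  # one scripted burst at minute 100 appears verbatim in the truth table
  st2 <- stage_sequence(rep(c("WAKE", "S"), c(10, 100)))
  sb <- data.frame(t_start_s = 100 * 60 + 7, duration_s = 1.0, amp_g = 0.8)
  acc2 <- generate_accel(st2, quiet, seed = 2, scripted_bursts = sb)
  expect_equal(nrow(acc2$bursts), 1)
  expect_equal(acc2$bursts$t_start_s, sb$t_start_s)
  expect_equal(acc2$bursts$amp_g, 0.8)
  expect_equal(acc2$bursts$epoch, 101L)
})

test_that("wake epochs carry more activity than sleep epochs", {
  st <- generate_hypnogram(90, onset_latency_min = 20, seed = 11)
  acc <- generate_accel(st, seed = 12)
  ac <- epoch_activity_counts(acc)
  wake_counts <- ac$counts[st$labels == "WAKE"]
  sleep_counts <- ac$counts[st$labels != "WAKE"]
  expect_gt(mean(wake_counts), median(sleep_counts))
  expect_gt(median(wake_counts), median(sleep_counts))
})

test_that("cohorts are byte-identical under a fixed master seed and carry truth", {
  des <- cohort_design(n_per_group = 2, days = c(1, 5), night_min = 20,
                       onset_latency_range = c(3, 6), include_accel = FALSE,
                       master_seed = 99)
  a <- generate_cohort(des)
  b <- generate_cohort(des)
  expect_identical(a, b)
  expect_length(a$nights, 2 * 2 * 2)
  nt <- a$nights[[1]]
  expect_s3_class(nt$rri, "rri_series")
  expect_s3_class(nt$stages, "stage_sequence")
  expect_s3_class(nt$profile, "autonomic_profile")
})

test_that("identically generated groups give null ANOVA results on LF", {
  # day-wise ANOVA on per-night LF amplitude under identical profiles should
  # reject at ~alpha; over reruns, p > 0.05 much more often than not
  reps <- 30
  ok <- 0L
  for (r in seq_len(reps)) {
    des <- cohort_design(n_per_group = 2, days = c(1, 5, 9), night_min = 20,
                         onset_latency_range = c(2, 4), include_accel = FALSE,
                         master_seed = 5000 + r)
    s <- cohort_lf_summaries(generate_cohort(des))
    p <- one_way_anova(split(s$lf, s$day))$p
    ok <- ok + (p > 0.05)
  }
  expect_gte(ok / reps, 0.8)
})
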