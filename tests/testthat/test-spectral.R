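make_tach <- function(expr_fun, dur_s = 600, rate = 4, mean_rr = 900) {
  t <- seq(0, dur_s, by = 1 / rate)
  tachogram(t, mean_rr + rep_len(expr_fun(t), length(t)), grid_rate = rate)
}

test_that("windowed periodogram: mean removal, Parseval on tones and noise", {
  const <- make_tach(function(t) 0)
  wp <- window_psd(const)
  expect_true(all(wp$valid))
  tot <- vapply(seq_len(nrow(wp$psd)), function(k)
    band_power(wp$freqs, wp$psd[k, ], c(0.05, 0.40), wp$df), numeric(1))
  expect_true(all(tot < 1e-9))

  # pure 0.10 Hz sine of amplitude a: integrated total power a^2/2 within 5%
  a <- 30
  tone <- make_tach(function(t) a * sin(2 * pi * 0.10 * t))
  for (tp in c("hann", "rect")) {
    wp2 <- window_psd(tone, taper = tp)
    tot2 <- vapply(seq_len(nrow(wp2$psd)), function(k)
      band_power(wp2$freqs, wp2$psd[k, ], c(0, 2.01), wp2$df), numeric(1))
    expect_equal(mean(tot2), a^2 / 2, tolerance = 0.05)
  }

  # white noise: mean integrated 0-2 Hz power matches the same windows'
  # sample variance within 10%
  set.seed(1)
  sigma <- 25
  noise <- make_tach(function(t) rnorm(length(t), 0, sigma))
  wp3 <- window_psd(noise, window_s = 60)
  tot3 <- vapply(seq_len(nrow(wp3$psd)), function(k)
    band_power(wp3$freqs, wp3$psd[k, ], c(0, 2.01), wp3$df), numeric(1))
  N <- 60 * 4
  v_or <- vapply(seq_along(tot3), function(k) {
    x <- noise$values[((k - 1) * N + 1):(k * N)]
    mean((x - mean(x))^2)
  }, numeric(1))
  expect_equal(mean(tot3), mean(v_or), tolerance = 0.10)
})

test_that("rectangular-window band powers satisfy Parseval exactly", {
  set.seed(2)
  x <- make_tach(function(t) rnorm(length(t), 0, 10) +
                   20 * sin(2 * pi * 0.13 * t))
  wp <- window_psd(x, taper = "rect")
  N <- 60 * 4
  for (k in seq_len(nrow(wp$psd))) {
    xi <- x$values[((k - 1) * N + 1):(k * N)]
    v <- mean((xi - mean(xi))^2)
    expect_equal(sum(wp$psd[k, ]) * wp$df, v, tolerance = 1e-9)
  }
})

test_that("band powers are additive over the half-open band split", {
  set.seed(3)
  x <- make_tach(function(t) rnorm(length(t), 0, 15))
  wp <- window_psd(x)
  for (k in seq_len(nrow(wp$psd))) {
    lf <- band_power(wp$freqs, wp$psd[k, ], c(0.05, 0.15), wp$df)
    hf <- band_power(wp$freqs, wp$psd[k, ], c(0.15, 0.40), wp$df)
    tot <- band_power(wp$freqs, wp$psd[k, ], c(0.05, 0.40), wp$df)
    expect_lte(lf + hf, tot + 1e-9)
    expect_equal(lf + hf, tot, tolerance = 1e-12)
  }
  expect_error(band_power(wp$freqs, wp$psd[1, ], c(0.4, 0.1)), "inverted")
})

test_that("single HF tone concentrates, and two equal tones balance, band power", {
  hf_tone <- make_tach(function(t) 25 * sin(2 * pi * 0.25 * t))
  fr <- frame_series(hf_tone)
  expect_gt(sum(fr$hf_power) / sum(fr$lf_power + fr$hf_power), 0.95)

  two <- make_tach(function(t) 20 * sin(2 * pi * 0.10 * t) +
                     20 * sin(2 * pi * 0.25 * t))
  fr2 <- frame_series(two)
  expect_true(all(abs(fr2$lf_hf - 1) < 0.10))
})

test_that("scaling fluctuations by c scales powers by c^2 and fixes lf_hf", {
  set.seed(4)
  base <- rnorm(2401, 0, 12)
  t <- seq(0, 600, by = 0.25)
  f1 <- frame_series(tachogram(t, 900 + base))
  f3 <- frame_series(tachogram(t, 900 + 3 * base))
  expect_equal(f3$lf_power, 9 * f1$lf_power, tolerance = 1e-9)
  expect_equal(f3$hf_power, 9 * f1$hf_power, tolerance = 1e-9)
  expect_equal(f3$lf_hf, f1$lf_hf, tolerance = 1e-9)
})

test_that("lf_hf_ratio contract: values, vectorization, degeneracy", {
  expect_equal(lf_hf_ratio(4, 4), 1)
  expect_equal(lf_hf_ratio(2, 1), 2)
  expect_true(is.na(lf_hf_ratio(1, 0)))
  expect_true(is.na(lf_hf_ratio(0, 0)))
  expect_equal(lf_hf_ratio(c(2, 1), c(1, 0)), c(2, NA))
  expect_error(lf_hf_ratio(-1, 2), ">= 0")
})

test_that("frame series has one frame per minute and masks invalid windows", {
  x <- make_tach(function(t) 10 * sin(2 * pi * 0.1 * t) +
                   5 * sin(2 * pi * 0.25 * t))
  fr <- frame_series(x)
  expect_equal(nrow(fr), 10)
  expect_equal(fr$minute, 0:9)
  expect_equal(fr$lf_amp, sqrt(fr$lf_power))
  expect_equal(fr$hf_amp, sqrt(fr$hf_power))

  x2 <- x
  x2$valid[241:480] <- FALSE              # second minute fully masked
  fr2 <- frame_series(x2)
  expect_false(fr2$valid[2])
  expect_true(all(fr2$valid[-2]))
})

test_that("per-stage frame ratios recover the configured balance within 20%", {
  for (cfg in list(c(36, 10), c(12, 18))) {
    st <- stage_sequence(rep("S", 20))
    prof <- autonomic_profile(cfg[1], cfg[2], noise_sd = 0)
    fr <- frame_series(resample_evenly(generate_rri(st, prof, seed = 21)))
    expect_equal(median(fr$lf_hf), cfg[1]^2 / cfg[2]^2, tolerance = 0.20)
  }
})

test_that("night summary averages valid sleep frames only", {
  fr <- data.frame(minute = 0:9, lf_power = 100, hf_power = 25,
                   lf_amp = 10, hf_amp = 5, lf_hf = 4, valid = TRUE)
  class(fr) <- c("spectral_frames", "data.frame")
  h <- as_hypnogram(stage_sequence(rep(c("WAKE", "S"), c(3, 7))))
  s <- night_summary(fr, h)
  expect_equal(unname(s$overall["lf_amp"]), 10)
  expect_equal(unname(s$overall["n_frames"]), 7)

  # frames valid only during S epochs: overall equals the S-stage mean
  h2 <- as_hypnogram(stage_sequence(rep(c("S", "PS_DEEP"), 5)))
  fr2 <- fr
  fr2$valid <- h2$label == "S"
  fr2$lf_amp <- seq(10, 19)
  s2 <- night_summary(fr2, h2)
  ps <- s2$per_stage
  expect_equal(unname(s2$overall["lf_amp"]), ps$lf_amp[ps$stage == "S"])
  expect_equal(ps$n_frames[ps$stage == "PS_DEEP"], 0)

  fr$valid <- FALSE
  expect_error(night_summary(fr, h), "no valid sleep frames")
})
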