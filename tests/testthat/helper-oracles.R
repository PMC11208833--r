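# Independent oracles used across the suite. Each is a from-first-principles
# computation that never calls the code path it checks.

# Studentized-range upper tail by direct nested quadrature of the range CDF:
# P(Q > q) with k means and df error degrees of freedom,
#   F(q) = int_0^inf g_df(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where s is the scaled chi distribution sqrt(chisq_df / df).
ptukey_oracle <- function(q, k, df) {
  inner <- function(u) {
    f <- function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - u))^(k - 1)
    integrate(f, -9, 9, rel.tol = 1e-9, abs.tol = 1e-11)$value
  }
  log_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  g <- function(s) exp(log_c + (df - 1) * log(s) - df * s^2 / 2)
  outer_f <- Vectorize(function(s) g(s) * inner(q * s))
  F_q <- integrate(outer_f, 0, Inf, rel.tol = 1e-7, abs.tol = 1e-9)$value
  1 - F_q
}

# Closed-form Welch t test (statistic, Welch-Satterthwaite df, two-tailed p).
welch_t_oracle <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# One-way ANOVA F by explicit sums of squares.
anova_f_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- length(groups) - 1
  df2 <- length(all) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# Pearson r via the covariance formula.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Brute-force movement-artifact scan: interval i spans [t_{i-1}, t_i) in
# seconds; flag iff any dynamic-magnitude sample in that span >= thr.
brute_force_movement_flags <- function(rri, accel, thr = 0.5) {
  mag <- sqrt((accel$ax_g - median(accel$ax_g))^2 +
                (accel$ay_g - median(accel$ay_g))^2 +
                (accel$az_g - median(accel$az_g))^2)
  t_edges <- c(0, rri$t_ms) / 1000
  vapply(seq_len(nrow(rri)), function(i) {
    sel <- accel$t_s >= t_edges[i] & accel$t_s < t_edges[i + 1]
    any(mag[sel] >= thr)
  }, logical(1))
}

# A processed synthetic night via the full chain; returns truth and results.
make_processed_night <- function(duration_min = 120, latency_min = 15,
                                 seed = 1) {
  st <- generate_hypnogram(duration_min, onset_latency_min = latency_min,
                           seed = seed)
  rri <- generate_rri(st, seed = seed + 10000L)
  acc <- generate_accel(st, seed = seed + 20000L)
  res <- process_night(rri, acc)
  list(truth = st, rri = rri, accel = acc, res = res)
}
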