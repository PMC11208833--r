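test_that("two-tailed t test: identity, separation, and Welch arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  r <- t_test_two_tailed(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  y <- c(1, 2, 3) + 100 + c(1e-6, -1e-6, 0)
  expect_lt(t_test_two_tailed(c(1, 2, 3), y)$p, 1e-6)

  # fixed 5-point fixtures against the closed-form Welch oracle
  a <- c(12.1, 9.8, 11.4, 10.2, 13.0)
  b <- c(8.9, 9.4, 7.2, 10.1, 8.8)
  r2 <- t_test_two_tailed(a, b)
  or <- welch_t_oracle(a, b)
  expect_equal(r2$statistic, or$t, tolerance = 1e-10)
  expect_equal(r2$df, or$df, tolerance = 1e-10)
  expect_equal(r2$p, or$p, tolerance = 1e-10)
  expect_equal(r2$effect, mean(a) - mean(b))

  # degenerate conventions and validation
  expect_equal(t_test_two_tailed(c(5, 5), c(5, 5))$p, 1)
  expect_equal(t_test_two_tailed(c(5, 5), c(7, 7))$p, 0)
  expect_error(t_test_two_tailed(1, c(1, 2)), "n >= 2")
})

test_that("Pearson correlation: exact lines and the covariance oracle", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$effect, 1)
  expect_equal(pearson_r(x, -x)$effect, -1)

  set.seed(10)
  u <- rnorm(9); v <- 0.6 * u + rnorm(9)
  r <- pearson_r(u, v)
  expect_equal(r$effect, pearson_oracle(u, v), tolerance = 1e-10)
  expect_equal(r$statistic, r$effect * sqrt(7 / (1 - r$effect^2)),
               tolerance = 1e-10)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "n >= 3")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("one-way ANOVA: F = t^2 at k = 2 and the sums-of-squares oracle", {
  set.seed(11)
  g1 <- rnorm(8, 10); g2 <- rnorm(8, 11)
  a <- one_way_anova(list(g1, g2))
  tt <- t_test_two_tailed(g1, g2, variant = "student")
  expect_equal(a$statistic, tt$statistic^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p, tolerance = 1e-9)

  fix <- list(c(4.1, 5.2, 3.9, 4.8, 5.0),
              c(6.3, 5.9, 6.8, 6.1, 6.6),
              c(5.1, 4.7, 5.5, 5.2, 4.9))
  a2 <- one_way_anova(fix)
  or <- anova_f_oracle(fix)
  expect_equal(a2$statistic, or$F, tolerance = 1e-10)
  expect_equal(a2$df, c(or$df1, or$df2))
  expect_equal(a2$p, or$p, tolerance = 1e-10)

  expect_error(one_way_anova(list(rep(1, 4), rep(1, 5))),
               class = "somnohrv_degenerate")
  expect_error(one_way_anova(list(1:3)), ">= 2 groups")
})

test_that("Games-Howell: Welch identity at k = 2, identical groups, quadrature", {
  set.seed(12)
  g1 <- rnorm(9, 0, 1); g2 <- rnorm(9, 0.8, 2)
  gh <- games_howell(list(a = g1, b = g2))
  wt <- t_test_two_tailed(g1, g2)
  expect_equal(gh$p, wt$p, tolerance = 1e-3)
  expect_equal(gh$q, abs(wt$statistic) * sqrt(2), tolerance = 1e-9)
  expect_equal(gh$df, wt$df, tolerance = 1e-9)

  same <- rnorm(6)
  gh2 <- games_howell(list(same, same, same))
  expect_true(all(gh2$p >= 0.999))
  gh3 <- games_howell(list(rep(2, 4), rep(2, 5)))
  expect_equal(gh3$p, 1)

  # fixed 3-group fixture vs direct numerical integration of the
  # studentized-range CDF
  fix <- list(x = c(10.2, 11.5, 9.8, 10.9, 11.1),
              y = c(12.4, 13.1, 12.9, 13.8),
              z = c(9.1, 9.9, 8.5, 10.4, 9.6, 9.2))
  gh4 <- games_howell(fix)
  for (r in seq_len(nrow(gh4))) {
    expect_equal(gh4$p[r], ptukey_oracle(gh4$q[r], 3, gh4$df[r]),
                 tolerance = 1e-4)
  }
})

test_that("Bonferroni adjustment is uncapped by default and linear in p", {
  expect_equal(bonferroni_adjust(0.996, 3), 2.988)
  expect_equal(bonferroni_adjust(0, 5), 0)
  expect_equal(bonferroni_adjust(0.05, 3, cap = TRUE), 0.15)
  expect_equal(bonferroni_adjust(0.7, 3, cap = TRUE), 1)
  p <- c(0.01, 0.2, 0.9)
  expect_equal(bonferroni_adjust(p, 3), 3 * p)
  expect_true(all(bonferroni_adjust(p, 4) >= p))
  expect_error(bonferroni_adjust(1.2, 2), "in \\[0, 1\\]")
  expect_error(bonferroni_adjust(0.5, 0), "k")
})

test_that("type-I error of every test is near nominal under the null", {
  set.seed(13)
  reps <- 200
  hit_t <- hit_f <- hit_gh <- 0L
  for (r in seq_len(reps)) {
    g <- replicate(3, rnorm(9), simplify = FALSE)
    hit_t <- hit_t + (t_test_two_tailed(g[[1]], g[[2]])$p < 0.05)
    hit_f <- hit_f + (one_way_anova(g)$p < 0.05)
    hit_gh <- hit_gh + (any(games_howell(g)$p < 0.05))
  }
  for (h in c(hit_t, hit_f, hit_gh)) {
    expect_gte(h / reps, 0.025)
    expect_lte(h / reps, 0.10)
  }
})

make_summaries <- function(n = 6, days = c(1, 5, 9), seed = 14,
                           mi_lf = c(30, 30, 30)) {
  set.seed(seed)
  rows <- list()
  for (g in c("Mi", "nMi")) for (s in seq_len(n)) for (di in seq_along(days)) {
    lf <- if (g == "Mi") mi_lf[di] else 30
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, group = g, day = days[di],
      total_min = rnorm(1, 330, 30), s_min = rnorm(1, 60, 10),
      ps_shallow_min = rnorm(1, 180, 20), ps_deep_min = rnorm(1, 70, 10),
      lf = rnorm(1, lf, 3), hf = rnorm(1, 20, 3),
      lf_hf = rnorm(1, 1.2, 0.2))
  }
  do.call(rbind, rows)
}

test_that("table builders produce the three report shapes", {
  s <- make_summaries()
  tb <- build_tables(s)
  expect_named(tb, c("group_table", "between_table", "stage_table",
                     "day_table"))
  expect_equal(nrow(tb$group_table), 3 * 7)     # days x measures
  expect_false(anyNA(tb$group_table))
  expect_false(anyNA(tb$between_table$p))
  expect_equal(nrow(tb$stage_table), 2 * 3 * 6) # groups x days x stage pairs
  expect_equal(nrow(tb$day_table), 2 * 3 * 3)   # groups x measures x day pairs
  expect_equal(tb$day_table$bonferroni, 3 * tb$day_table$p)

  # a declining Mi LF across days surfaces as significant day contrasts
  s2 <- make_summaries(n = 9, mi_lf = c(30, 20, 15), seed = 15)
  tb2 <- build_tables(s2)
  mi_lf_rows <- tb2$day_table[tb2$day_table$group == "Mi" &
                                tb2$day_table$measure == "lf", ]
  expect_true(all(mi_lf_rows$p < 0.05))

  # missing cells and degenerate sizes are errors
  expect_error(build_tables(s[s$group != "nMi" | s$day != 5, ]),
               "missing cells")
  one <- s[s$subject == 1, ]
  expect_error(build_tables(one), "n >= 2")
  expect_error(build_tables(s[, -4]), "missing column")
})
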