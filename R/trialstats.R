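## Trial statistics layer: two-tailed t tests, Pearson correlation, one-way
## ANOVA, Games-Howell post-hoc contrasts, and uncapped Bonferroni
## correction, plus builders for the three trial-report tables.

#' Test-result container
#'
#' @param statistic test statistic.
#' @param df degrees of freedom (possibly fractional; length 2 for F).
#' @param p two-tailed p value.
#' @param effect effect size (Pearson r or mean difference).
#' @param label contrast description.
#' @param method method name.
#' @return Object of class `test_result`.
#' @export
test_result <- function(statistic, df, p, effect = NA_real_, label = "",
                        method = "") {
  structure(list(statistic = statistic, df = df, p = p, effect = effect,
                 label = label, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> %s: stat = %.4g, df = %s, p = %.4g, effect = %.4g\n",
              x$method, x$label, x$statistic,
              paste(round(x$df, 2), collapse = ", "), x$p, x$effect))
  invisible(x)
}

#' Two-tailed two-sample t test
#'
#' Welch (default) or pooled-variance Student variant. With zero variance in
#' both samples, equal means give p = 1 by convention (and unequal means
#' p = 0 with an infinite statistic).
#'
#' @param x,y numeric samples (each n >= 2).
#' @param variant `"welch"` or `"student"`.
#' @return A [test_result()]; `effect` is the mean difference `mean(x) - mean(y)`.
#' @export
t_test_two_tailed <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs n >= 2", call. = FALSE)
  diff <- mean(x) - mean(y)
  if (var(x) + var(y) == 0) {
    return(test_result(ifelse(diff == 0, 0, sign(diff) * Inf),
                       length(x) + length(y) - 2,
                       ifelse(diff == 0, 1, 0), diff,
                       "x vs y", paste0(variant, " t")))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value, diff,
              "x vs y", paste0(variant, " t"))
}

#' Pearson correlation with two-tailed test
#'
#' @param x,y paired numeric samples of equal length (n >= 3), each with
#'   non-zero variance.
#' @return A [test_result()]; `effect` and `statistic` carry r and the t
#'   statistic `r * sqrt((n - 2) / (1 - r^2))`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("samples must be paired", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              unname(ht$estimate), "x vs y", "pearson r")
}

#' One-way ANOVA
#'
#' Classic fixed-effects F test (`MS_between / MS_within`, df k-1 and N-k).
#' All-identical observations leave F undefined and raise a classed error
#' (`somnohrv_degenerate`).
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return A [test_result()] with `df = c(df1, df2)`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (var(vals) == 0)
    stop(structure(class = c("somnohrv_degenerate", "error", "condition"),
                   list(message = "all observations identical: F undefined",
                        call = sys.call())))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              NA_real_, "between groups", "one-way ANOVA")
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' For each pair (i, j): `SE = sqrt(s_i^2/n_i + s_j^2/n_j)`,
#' `q = |xbar_i - xbar_j| * sqrt(2) / SE`, Welch-Satterthwaite df, p from the
#' studentized-range distribution with `k` groups. Unequal variances and
#' sizes are allowed. With zero variance in both members of a pair, equal
#' means give p = 1.
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @return A data.frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `se`, `q`, `df`, `p`.
#' @export
games_howell <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  nm <- names(groups) %||% as.character(seq_len(k))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  n <- vapply(groups, length, numeric(1))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    diff <- m[i] - m[j]
    se2 <- v[i] / n[i] + v[j] / n[j]
    if (se2 == 0) {
      out[[length(out) + 1L]] <- data.frame(
        group1 = nm[i], group2 = nm[j], mean_diff = diff, se = 0,
        q = ifelse(diff == 0, 0, Inf), df = n[i] + n[j] - 2,
        p = ifelse(diff == 0, 1, 0))
      next
    }
    se <- sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(diff) * sqrt(2) / se
    p <- stud_range_p(q, k, df)
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j], mean_diff = diff, se = se,
      q = q, df = df, p = p)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("games_howell", "data.frame")
  res
}

## Upper tail of the studentized-range distribution. stats::ptukey performs
## the numerical integration but returns NaN for df < 2 (reachable with
## Welch df from n = 2 groups); there we integrate the range CDF directly:
## F(q) = int g_df(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds,
## s being the scaled chi variate sqrt(chisq_df / df).
stud_range_p <- function(q, k, df) {
  if (df >= 2)
    return(stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  inner <- function(u) {
    stats::integrate(function(z)
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - u))^(k - 1),
      -9, 9, rel.tol = 1e-8)$value
  }
  log_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  outer_f <- Vectorize(function(s)
    exp(log_c + (df - 1) * log(s) - df * s^2 / 2) * inner(q * s))
  F_q <- stats::integrate(outer_f, 0, Inf, rel.tol = 1e-6)$value
  max(0, min(1, 1 - F_q))
}

#' Bonferroni correction (uncapped by default)
#'
#' Returns `p * k`. The trial-report convention prints the raw product, which
#' may exceed 1 (equivalent to testing against alpha / k); set `cap = TRUE`
#' for `min(1, p * k)`.
#'
#' @param p raw p value(s) in [0, 1].
#' @param k number of comparisons (>= 1).
#' @param cap cap at 1? (default FALSE).
#' @return Adjusted value(s).
#' @export
bonferroni_adjust <- function(p, k, cap = FALSE) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  adj <- p * k
  if (cap) pmin(1, adj) else adj
}

## ---- table builders -------------------------------------------------------

MEASURES_DUR <- c("total_min", "s_min", "ps_shallow_min", "ps_deep_min")
MEASURES_HRV <- c("lf", "hf", "lf_hf")

#' Build the three trial-report tables from per-night summaries
#'
#' Input is one row per (subject, group, day) with columns `subject`, `group`
#' ("Mi"/"nMi"), `day`, the stage durations `total_min`, `s_min`,
#' `ps_shallow_min`, `ps_deep_min` (minutes), and the spectral indices `lf`,
#' `hf` (ms) and `lf_hf`.
#'
#' Outputs:
#' \describe{
#'   \item{group_table}{per (day, measure): group means/SDs and n.}
#'   \item{between_table}{per (day, duration measure): Welch t p between
#'     groups and the Pearson r of within-group subject-order paired values
#'     (NA with a warning when group sizes differ: the pairing of two
#'     independent groups is a reporting convention, not an estimand).}
#'   \item{stage_table}{per (group, day): Games-Howell contrasts among the
#'     four duration measures.}
#'   \item{day_table}{per (group, HRV measure): Games-Howell day contrasts
#'     with raw and uncapped Bonferroni-adjusted p (k = number of day pairs).}
#' }
#'
#' @param summaries data.frame as described above.
#' @param t_variant t-test variant for the between-group tests.
#' @param bonferroni_cap cap adjusted p at 1? (default FALSE).
#' @return A list of class `trial_tables` with the four data.frames.
#' @export
build_tables <- function(summaries, t_variant = "welch",
                         bonferroni_cap = FALSE) {
  need <- c("subject", "group", "day", MEASURES_DUR, MEASURES_HRV)
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stop("summaries missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  days <- sort(unique(summaries$day))
  groups <- c("Mi", "nMi")
  cells <- expand.grid(group = groups, day = days, stringsAsFactors = FALSE)
  n_cell <- mapply(function(g, d) sum(summaries$group == g & summaries$day == d),
                   cells$group, cells$day)
  if (any(n_cell == 0))
    stop("missing cells: ",
         paste(sprintf("(%s, day %s)", cells$group[n_cell == 0],
                       cells$day[n_cell == 0]), collapse = ", "),
         call. = FALSE)
  if (any(n_cell < 2)) stop("every (group, day) cell needs n >= 2", call. = FALSE)

  pick <- function(g, d, m) {
    s <- summaries[summaries$group == g & summaries$day == d, ]
    s <- s[order(s$subject), ]
    s[[m]]
  }
  all_meas <- c(MEASURES_DUR, MEASURES_HRV)

  ## group table: means/SDs per (day, measure) + between-group tests
  g1 <- list(); g2 <- list()
  for (d in days) for (m in all_meas) {
    xm <- pick("Mi", d, m); xn <- pick("nMi", d, m)
    g1[[length(g1) + 1L]] <- data.frame(
      day = d, measure = m,
      mi_mean = mean(xm), mi_sd = sd(xm), mi_n = length(xm),
      nmi_mean = mean(xn), nmi_sd = sd(xn), nmi_n = length(xn))
    tt <- t_test_two_tailed(xm, xn, variant = t_variant)
    r <- if (length(xm) == length(xn) && length(xm) >= 3 &&
             var(xm) > 0 && var(xn) > 0) {
      pr <- pearson_r(xm, xn)
      c(pr$effect, pr$p)
    } else {
      if (length(xm) != length(xn))
        warning("unequal group sizes: subject-order Pearson pairing undefined")
      c(NA_real_, NA_real_)
    }
    g2[[length(g2) + 1L]] <- data.frame(
      day = d, measure = m, t = tt$statistic, df = tt$df, p = tt$p,
      pearson_r = r[1], pearson_p = r[2])
  }
  group_table <- do.call(rbind, g1)
  between_table <- do.call(rbind, g2)

  ## stage table: within-group Games-Howell among the duration measures
  g3 <- list()
  for (g in groups) for (d in days) {
    gh <- games_howell(setNames(lapply(MEASURES_DUR, function(m) pick(g, d, m)),
                                MEASURES_DUR))
    g3[[length(g3) + 1L]] <- cbind(group = g, day = d, as.data.frame(gh))
  }
  stage_table <- do.call(rbind, g3)

  ## day table: within-group day contrasts of LF, HF, LF/HF
  g4 <- list()
  for (g in groups) for (m in MEASURES_HRV) {
    gh <- games_howell(setNames(
      lapply(days, function(d) pick(g, d, m)), paste0("day", days)))
    k <- nrow(gh)
    gh$bonferroni <- bonferroni_adjust(gh$p, k, cap = bonferroni_cap)
    g4[[length(g4) + 1L]] <- cbind(group = g, measure = m, as.data.frame(gh))
  }
  day_table <- do.call(rbind, g4)
  rownames(group_table) <- rownames(between_table) <-
    rownames(stage_table) <- rownames(day_table) <- NULL
  structure(list(group_table = group_table, between_table = between_table,
                 stage_table = stage_table, day_table = day_table),
            class = "trial_tables")
}
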