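## Internal helpers: seeding, validation.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under `set.seed(seed)` without disturbing the caller's RNG
## stream. seed = NULL runs code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in a cohort flows from one master seed; each night's seed is
#' a documented arithmetic function of (master, group, subject, day, salt), so
#' any single night can be regenerated in isolation. Result is in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... non-negative integer indices (group, subject, day, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647          # 2^31 - 1, Mersenne prime
  s <- as.numeric(master) %% m
  mult <- c(48271, 69621, 40692, 10007, 75181, 65413)
  for (i in seq_along(idx)) {
    a <- mult[((i - 1L) %% length(mult)) + 1L]
    s <- (s * a + as.numeric(idx[i]) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
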