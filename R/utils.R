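# Shared simple-regression core: slope/intercept via stats::lm, with the
# F statistic reported on the (1, n-2) identity F = r2/(1-r2) * (n-2).
ols_fit <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 points for a regression")
  if (stats::var(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                F = NA_real_, df = c(1L, n - 2L), p = NA_real_, n = n))
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  Fstat <- if (is.na(r2)) NA_real_
           else if (r2 >= 1) Inf
           else r2 / (1 - r2) * (n - 2)
  p <- if (is.na(Fstat)) NA_real_
       else stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, F = Fstat, df = c(1L, n - 2L), p = p, n = n)
}

# Deterministic 31-bit string hash (polynomial rolling hash modulo the
# Mersenne prime 2^31 - 1). Used to derive independent, order-free
# substream seeds for Monte-Carlo work from a master seed plus identifiers.
hash_seed <- function(..., master_seed = 0L) {
  s <- paste(c(..., master_seed), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

sample_int_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}
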