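# Internal helpers: seed sub-streams, validators, truncated normal.

# Derive n reproducible sub-stream seeds from one master seed without
# disturbing the caller's RNG state. Stages seeded from sub-streams are
# independently reproducible (re-running one stage never shifts another).
sub_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  rs <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483646L))
  sample.int(2147483646L, n)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("configuration error: '%s' must be probabilities in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (!is.numeric(x) || anyNA(x) || bad) {
    stop(sprintf("configuration error: '%s' must be %s", name,
                 if (strict) "> 0" else ">= 0"), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    stop(sprintf("configuration error: '%s' must be an integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(x)
}

# Inverse-CDF truncated normal draw on [lo, hi].
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(pmin(pmax(rep_len(mean, n), lo), hi))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Mean of a normal truncated to [lo, hi].
trunc_norm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter such that the truncated normal has the target mean
# (truncation at the utility ceiling would otherwise bias state means down).
trunc_norm_location <- function(target, sd, lo, hi) {
  if (sd <= 0) return(target)
  stats::uniroot(function(mu) trunc_norm_mean(mu, sd, lo, hi) - target,
                 interval = c(target - 1e-6, target + 5 * sd),
                 extendInt = "yes", tol = 1e-10)$root
}
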