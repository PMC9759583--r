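#' @keywords internal
#' @import stats
"_PACKAGE"

# Truncated-normal sampling via inverse-CDF; avoids rejection loops for
# tight one-sided truncations (e.g. HOMA-IR above a cutoff).
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) {
    x <- rep(mean, n)
    runif(n) # keep RNG stream advancing consistently
    return(pmin(pmax(x, lower), upper))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

truncnorm_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  # far-tail truncation: the mass piles up against the nearer bound
  if (!is.finite(z) || z < 1e-12) return(if (a > 0) lower else upper)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

# Location parameter such that the (lower, upper)-truncated normal with
# scale `sd` has expectation `target`.
calibrate_truncnorm_location <- function(target, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lower, upper) - target
  span <- 10 * sd + abs(target) + 1
  uniroot(f, c(target - span, target + span), tol = 1e-10)$root
}

# Counter-based seed derivation: one user-facing seed fans out to
# per-stage streams that stay below 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  stages <- c("abundance", "clinical", "tree", "split", "cv", "smote",
              "ga", "rf", "boot", "pipeline")
  idx <- match(stage, stages)
  if (is.na(idx)) idx <- 1000L + (sum(utf8ToInt(stage)) %% 1000L)
  as.integer((as.numeric(seed) * 1009 + idx * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
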