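# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 1-D two-means clustering: exhaustive search over the sorted
# split that minimizes within-cluster sum of squares. No RNG, so repeated
# calls are identical. Returns the two cluster means (lower, upper) and the
# membership of each point.
two_means_1d <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("two_means_1d needs at least 2 finite values")
  xs <- sort(x)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kbest <- which.min(ss_lo + ss_hi)
  split_val <- (xs[kbest] + xs[kbest + 1L]) / 2
  lower <- mean(xs[seq_len(kbest)])
  upper <- mean(xs[(kbest + 1L):n])
  list(lower = lower, upper = upper, split = split_val,
       upper_member = x > split_val)
}

# Fraction-of-window sums via cumulative sums; x numeric, width in samples.
# Returns sum over (i - width, i] for each i >= width, NA before.
rolling_sum <- function(x, width) {
  n <- length(x)
  if (width > n) return(rep(NA_real_, n))
  cs <- cumsum(x)
  out <- rep(NA_real_, n)
  out[width:n] <- cs[width:n] - c(0, cs)[(width:n) - width + 1L]
  out
}

# Linear interpolation of a per-tick (1 Hz) envelope onto a sample grid.
interp_envelope <- function(env, fs, n_samples) {
  n_ticks <- length(env)
  tick_t <- (seq_len(n_ticks) - 0.5)          # tick centers, seconds
  sample_t <- (seq_len(n_samples) - 0.5) / fs
  stats::approx(tick_t, env, xout = sample_t, rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format seconds as ZT hours given a zeitgeber offset (hours at t = 0).
zt_at <- function(time_s, zt0 = 0) (zt0 + time_s / 3600) %% 24

# TRUE where ZT is in the light phase of a 12/12 schedule with lights on at
# ZT 0 and off at ZT 12.
is_light_zt <- function(zt, lights_on = 0, lights_off = 12) {
  zt <- zt %% 24
  if (lights_on < lights_off) zt >= lights_on & zt < lights_off
  else zt >= lights_on | zt < lights_off
}
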