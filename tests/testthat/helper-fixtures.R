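# Shared fixtures (memoized per test run) and independent oracles.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_params3 <- function() fx("p3", sim_params())
fx_params4 <- function() fx("p4", sim_params(states = c("AW", "QW", "NREM", "REM")))

# 2-h three-state recording shared by feature/classifier tests
fx_psg2h <- function() fx("psg2h", {
  p <- fx_params3()
  ss <- generate_state_sequence(p, duration_h = 2, seed = 11)
  list(seq = ss, rec = synthesize_polysomnography(ss, p, fs = 200, seed = 12))
})

# 24-h benchmark (default parameters, pinned seed) shared by the
# acceptance tests
fx_benchmark <- function() fx("benchmark", {
  p <- fx_params3()
  ss <- generate_state_sequence(p, duration_h = 24, seed = 1)
  rec <- synthesize_polysomnography(ss, p, fs = 200, seed = 2)
  rt <- run_realtime(rec)
  truth10 <- resample_hypnogram(ss, 10)
  list(params = p, seq = ss, rec = rec, realtime = rt, truth10 = truth10,
       agreement = score_agreement(rt, truth10))
})

# shared 1-h laminar fEPSP run (4-state, default gains)
fx_fepsp <- function() fx("fepsp_run", {
  p <- fx_params4()
  ss <- generate_state_sequence(p, duration_h = 1, seed = 131)
  fe <- synthesize_fepsp_experiment(ss, p, n_channels = 8, fs = 1000,
                                    seed = 132)
  filt <- fepsp_preprocess(fe$lfp, fe$fs)
  ssw <- extract_sweeps(filt, fe$fs, fe$stim_times_s)
  list(p = p, seq = ss, fe = fe, ssw = ssw, meas = measure_sweeps(ssw))
})

# --- independent oracles -------------------------------------------------

# Brute-force dense-epoch scan: evaluates both window fractions directly
# with sum() over explicit slices; returns qualifying window ends (epochs).
oracle_dense_ends <- function(labels, target, epoch_s, min_dur_h, density,
                              last_hour_density = NULL) {
  x <- as.numeric(labels %in% target)
  L <- round(min_dur_h * 3600 / epoch_s)
  n <- length(x)
  if (n < L) return(integer(0))
  H <- min(L, round(3600 / epoch_s))
  ok <- logical(n)
  for (e in L:n) {
    f <- sum(x[(e - L + 1):e]) / L
    pass <- f > density
    if (pass && !is.null(last_hour_density)) {
      pass <- sum(x[(e - H + 1):e]) / H > last_hour_density
    }
    ok[e] <- pass
  }
  which(ok)
}

# first qualifying end of each merged run (gap > L starts a new epoch)
oracle_first_crossings <- function(ends, L) {
  if (!length(ends)) return(numeric(0))
  as.numeric(ends[c(TRUE, diff(ends) > L)])
}

# membership union of (e - L, e] over qualifying ends
oracle_dense_membership <- function(ends, n, L) {
  mem <- logical(n)
  for (e in ends) mem[(e - L + 1):e] <- TRUE
  mem
}

# Welch band power recomputed with a plain fft loop (independent of the
# package's vectorized mvfft path).
oracle_welch_band <- function(x, fs, epoch_len_s, lo, hi, seg_len_s = 2) {
  n_epoch <- round(fs * epoch_len_s)
  seg <- round(fs * seg_len_s); step <- seg %/% 2
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg - 1) / (seg - 1))
  n_ep <- length(x) %/% n_epoch
  freqs <- (seq_len(seg %/% 2 + 1) - 1) * fs / seg
  bin <- which(freqs >= lo & freqs < hi)
  out <- numeric(n_ep)
  for (e in seq_len(n_ep)) {
    seg_starts <- seq(1, n_epoch - seg + 1, by = step) + (e - 1) * n_epoch
    pows <- vapply(seg_starts, function(s0) {
      v <- x[s0:(s0 + seg - 1)]
      v <- (v - mean(v)) * w
      X <- fft(v)[seq_len(seg %/% 2 + 1)]
      pw <- 2 * Mod(X)^2 / (sum(w^2) * seg)
      pw[1] <- pw[1] / 2
      if (seg %% 2 == 0) pw[length(pw)] <- pw[length(pw)] / 2
      sum(pw[bin])
    }, numeric(1))
    out[e] <- mean(pows)
  }
  out
}

# Majority vote over 1-s ticks, straightforward loop version.
oracle_majority <- function(labels_1s, width_s) {
  n_out <- length(labels_1s) %/% width_s
  vapply(seq_len(n_out), function(i) {
    v <- labels_1s[((i - 1) * width_s + 1):(i * width_s)]
    tb <- table(v)
    win <- names(tb)[tb == max(tb)]
    if (length(win) > 1) win <- v[v %in% win][1]
    win
  }, character(1))
}

# Greedy matching of detected events to truth within a tolerance.
match_events <- function(det_t, truth_t, tol_s = 0.002) {
  used <- rep(FALSE, length(det_t))
  hit <- rep(NA_integer_, length(truth_t))
  for (i in seq_along(truth_t)) {
    d <- abs(det_t - truth_t[i])
    j <- which(d < tol_s & !used)
    if (length(j)) {
      j <- j[which.min(d[j])]
      hit[i] <- j
      used[j] <- TRUE
    }
  }
  hit
}

# Random bout-structured hypnogram for property tests.
random_hypnogram <- function(n_epochs, epoch_s, states = c("WAKE", "NREM", "REM"),
                             sleep_bias = runif(1, 0.3, 0.8),
                             mean_bout = 12) {
  n_epochs <- round(n_epochs)
  labs <- character(0)
  while (length(labs) < n_epochs) {
    s <- if (runif(1) < sleep_bias) sample(c("NREM", "REM"), 1, prob = c(0.8, 0.2))
         else "WAKE"
    labs <- c(labs, rep(s, 1 + rgeom(1, 1 / mean_bout)))
  }
  hypnogram(labs[seq_len(n_epochs)], epoch_len_s = epoch_s, states = states)
}
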