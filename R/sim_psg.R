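#' Synthesize a polysomnography recording from a state sequence
#'
#' Builds EEG, nuchal EMG and a video pixel-movement series whose statistics
#' track the behavioral state at every 1-s tick. The EEG is a sum of
#' band-limited Gaussian noise components (delta/theta/beta/gamma, produced
#' by Fourier masking of white noise) whose per-band variance follows the
#' state's band-power profile, with a ~1-s linear crossfade at state
#' transitions, plus a small broadband floor. The EMG is Gaussian baseline
#' noise plus Hann-enveloped high-variance bursts arriving at a
#' state-dependent Poisson rate (zero in NREM/REM, emulating atonia).
#' Movement is a per-frame Poisson count, near zero during sleep.
#'
#' @param states A `state_sequence` from [generate_state_sequence()].
#' @param params The [sim_params()] used (band-power profiles, rates).
#' @param fs Sampling rate, Hz (>= 100; >= twice the beta band upper edge).
#' @param seed Integer seed (independent of the state-sequence seed).
#' @return An object of class `psg_recording`: list with `eeg`, `emg`
#'   (microvolts), `fs`, `movement` (pixels/frame), `movement_fs`, `truth`
#'   (the input state sequence) and `start_zt`.
#' @examples
#' p <- sim_params()
#' ss <- generate_state_sequence(p, duration_h = 0.5, seed = 1)
#' rec <- synthesize_polysomnography(ss, p, fs = 200, seed = 2)
#' @export
synthesize_polysomnography <- function(states, params, fs = 200, seed = 1) {
  stopifnot(inherits(states, "hypnogram"), inherits(params, "sim_params"))
  if (fs < 100) stop("fs must be at least 100 Hz")
  beta_hi <- params$bands$high_hz[params$bands$name == "beta"]
  if (length(beta_hi) && fs / 2 <= max(beta_hi)) {
    stop("fs too low to represent the beta band")
  }
  labels <- states$labels
  n_ticks <- length(labels)
  n <- as.integer(n_ticks * fs)
  st_idx <- match(labels, params$states)

  eeg <- with_seed(seed, {
    white <- stats::rnorm(n)
    X <- stats::fft(white)
    rm(white)
    freqs <- (seq_len(n) - 1L) / n * fs
    freqs <- pmin(freqs, fs - freqs)          # two-sided frequency axis
    acc <- if (params$broadband_power > 0) {
      stats::rnorm(n, sd = sqrt(params$broadband_power))
    } else numeric(n)
    decay_env <- NULL
    if (!identical(params$delta_decay_factor, 1)) {
      decay_env <- sqrt(seq(1, params$delta_decay_factor, length.out = n))
    }
    for (b in seq_len(nrow(params$bands))) {
      lo <- params$bands$low_hz[b]
      hi <- min(params$bands$high_hz[b], 0.98 * fs / 2)
      keep <- freqs >= lo & freqs < hi
      if (!any(keep)) next
      Y <- X
      Y[!keep] <- 0
      y <- Re(stats::fft(Y, inverse = TRUE)) / n
      rm(Y)
      y <- y / stats::sd(y)
      env <- sqrt(params$band_power[st_idx, params$bands$name[b]])
      env_s <- interp_envelope(env, fs, n)
      if (params$bands$name[b] == "delta" && !is.null(decay_env)) {
        env_s <- env_s * decay_env
      }
      acc <- acc + y * env_s
      rm(y, env_s)
    }
    acc
  })

  emg <- with_seed(seed + 1L, {
    base <- stats::rnorm(n, sd = params$emg_noise_uv)
    rates <- params$emg_burst_rate_hz[params$states][st_idx]
    n_bursts <- stats::rpois(n_ticks, rates)
    ticks <- rep(seq_len(n_ticks), n_bursts)
    if (length(ticks)) {
      t0 <- (ticks - 1) + stats::runif(length(ticks))
      len <- as.integer(round(params$emg_burst_dur_s * fs))
      envb <- hann_window(len) * params$emg_burst_gain * params$emg_noise_uv
      for (s0 in as.integer(t0 * fs)) {
        ii <- (s0 + 1L):min(s0 + len, n)
        base[ii] <- base[ii] + stats::rnorm(length(ii)) * envb[seq_along(ii)]
      }
    }
    base
  })

  movement <- with_seed(seed + 2L, {
    stats::rpois(n_ticks, params$movement_rate[params$states][st_idx])
  })

  structure(list(eeg = eeg, emg = emg, fs = fs,
                 movement = as.numeric(movement), movement_fs = 1,
                 truth = states, start_zt = states$start_zt,
                 units = c(eeg = "uV", emg = "uV", movement = "px")),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %.2f h at %g Hz (EEG+EMG), movement at %g Hz\n",
              length(x$eeg) / x$fs / 3600, x$fs, x$movement_fs))
  cat(sprintf("  start ZT %.1f h; truth states: %s\n", x$start_zt,
              paste(x$truth$states, collapse = "/")))
  invisible(x)
}
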