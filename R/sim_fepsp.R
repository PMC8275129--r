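#' Synthesize a laminar evoked-fEPSP experiment
#'
#' Generates a continuous multichannel LFP recording with an evoked field
#' potential after every stimulus. The response template is an
#' alpha-function trough (latency ~3 ms, trough ~4 ms later) scaled by the
#' behavioral-state gain at stimulation time (and an optional slow trend),
#' and embedded across channels with a dipole-like laminar profile: one
#' "sink" channel carries the full negative trough, flanking channels carry
#' opposite-sign return currents. Gaussian channel noise is added. The
#' truth table records each stimulus' state, gain and the sink channel.
#'
#' @param states A `state_sequence` (4-state recommended so NREM/QW/AW/REM
#'   gains differ).
#' @param params A [sim_params()]; component `fepsp` supplies per-state
#'   gain, stimulation period, template amplitude and noise RMS. `trend`
#'   may be a function of time (s) returning a multiplicative gain.
#' @param n_channels Number of laminar channels (>= 3 for CSD).
#' @param fs Sampling rate (Hz; > 900 so the 5-450 Hz band is defined).
#' @param seed Integer seed.
#' @return list of class `fepsp_recording`: `lfp` (channels x samples
#'   matrix, microvolts), `fs`, `stim_times_s`, `truth` (data.frame:
#'   stim_time_s, state, gain), `sink_channel`, `states`, `start_zt`.
#' @export
synthesize_fepsp_experiment <- function(states, params, n_channels = 8,
                                        fs = 1000, seed = 1) {
  stopifnot(inherits(states, "hypnogram"), inherits(params, "sim_params"))
  if (n_channels < 3L) stop("need at least 3 channels for CSD")
  fp <- params$fepsp
  dur <- hypnogram_duration_s(states)
  sweep_len_s <- 0.18
  if (fp$stim_period_s <= sweep_len_s) {
    stop("stim_period_s must exceed the sweep length (overlapping sweeps)")
  }
  stim <- seq(fp$stim_period_s, dur - 0.2, by = fp$stim_period_s)
  st <- state_at(states, stim)
  gain <- fp$gain[st]
  if (!is.null(fp$trend)) gain <- gain * fp$trend(stim)

  n <- as.integer(round(dur * fs))
  sink <- if (is.finite(fp$sink_channel %||% NA)) fp$sink_channel
          else as.integer(ceiling(n_channels / 2))
  profile <- numeric(n_channels)
  profile[sink] <- 1
  for (d in 1:2) {
    coef <- c(-0.45, 0.15)[d]
    for (ch in c(sink - d, sink + d)) {
      if (ch >= 1L && ch <= n_channels) profile[ch] <- coef
    }
  }
  # alpha-function trough, unit peak
  lat_s <- fp$latency_ms / 1000
  tau_s <- 0.004
  kern_t <- seq(0, 0.06, by = 1 / fs)
  kern <- -((kern_t / tau_s) * exp(1 - kern_t / tau_s))
  on_s <- as.integer(round(lat_s * fs))

  lfp <- with_seed(seed, {
    s0 <- as.integer(round(stim * fs)) + on_s
    ok <- s0 + length(kern) <= n
    idx <- as.vector(outer(seq_along(kern), s0[ok], `+`))
    vals <- as.vector(kern %o% (fp$amp_uv * gain[ok]))
    m <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      v <- stats::rnorm(n, sd = fp$noise_rms_uv)
      if (profile[ch] != 0) v[idx] <- v[idx] + profile[ch] * vals
      m[ch, ] <- v
    }
    m
  })
  structure(list(lfp = lfp, fs = fs, stim_times_s = stim,
                 truth = data.frame(stim_time_s = stim, state = st,
                                    gain = gain),
                 sink_channel = sink, states = states,
                 start_zt = states$start_zt),
            class = "fepsp_recording")
}

#' @export
print.fepsp_recording <- function(x, ...) {
  cat(sprintf("<fepsp_recording> %d ch x %.2f h at %g Hz, %d stimuli, sink ch %d\n",
              nrow(x$lfp), ncol(x$lfp) / x$fs / 3600, x$fs,
              length(x$stim_times_s), x$sink_channel))
  invisible(x)
}
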