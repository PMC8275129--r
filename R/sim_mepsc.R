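#' Canonical mEPSC kernel and template
#'
#' Difference-of-exponentials event shape
#' `k(t) = exp(-t/decay) - exp(-t/rise)`, rescaled so its peak equals -1.
#' An event of amplitude A pA is `A * k(t)` added to the trace, so the
#' kernel peak is calibrated to the drawn amplitude and truth tables are
#' directly comparable to measured amplitudes.
#'
#' @param rise_tau_ms,decay_tau_ms Kinetic time constants (ms, decay > rise).
#' @param length_ms Template length (ms).
#' @param fs Sampling rate (Hz).
#' @return Object of class `mini_template`: list with `kernel` (unit-peak,
#'   negative), `fs`, taus, and the kernel's 20-80% rise time (ms).
#' @export
mini_template <- function(rise_tau_ms = 0.5, decay_tau_ms = 3,
                          length_ms = 20, fs = 10000) {
  if (decay_tau_ms <= rise_tau_ms) stop("decay_tau must exceed rise_tau")
  t_ms <- (seq_len(as.integer(round(length_ms / 1000 * fs))) - 1) / fs * 1000
  k <- exp(-t_ms / decay_tau_ms) - exp(-t_ms / rise_tau_ms)
  k <- -k / max(k)
  structure(list(kernel = k, fs = fs, rise_tau_ms = rise_tau_ms,
                 decay_tau_ms = decay_tau_ms, length_ms = length_ms,
                 rise_20_80_ms = kernel_rise_ms(k, fs)),
            class = "mini_template")
}

kernel_rise_ms <- function(k, fs) {
  peak <- which.min(k)
  mag <- -k[seq_len(peak)]
  t20 <- stats::approx(mag, seq_len(peak), xout = 0.2 * max(mag))$y
  t80 <- stats::approx(mag, seq_len(peak), xout = 0.8 * max(mag))$y
  (t80 - t20) / fs * 1000
}

#' Synthesize a voltage-clamp trace with ground-truth mEPSCs
#'
#' Events arrive as a homogeneous Poisson process; each adds a
#' difference-of-exponentials kernel scaled by a lognormally drawn
#' amplitude, on top of white Gaussian noise of the stated RMS. The truth
#' table lists onset time, amplitude, kernel 20-80% rise time and decay tau
#' per event.
#'
#' @param duration_s Trace duration (s, > 0).
#' @param params A [sim_params()] (component `mepsc`).
#' @param fs Sampling rate, Hz (10 kHz typical acquisition).
#' @param seed Integer seed.
#' @return list of class `mepsc_recording`: `trace` (pA, negative-going
#'   events), `fs`, `events` (truth data.frame: time_s, amplitude_pa,
#'   rise_ms, decay_ms), `template` (the generating [mini_template()]).
#' @examples
#' r <- synthesize_mepsc_trace(10, sim_params(), seed = 7)
#' nrow(r$events)
#' @export
synthesize_mepsc_trace <- function(duration_s, params, fs = 10000, seed = 1) {
  stopifnot(inherits(params, "sim_params"), duration_s > 0)
  mp <- params$mepsc
  tpl <- mini_template(mp$rise_tau_ms, mp$decay_tau_ms, fs = fs)
  n <- as.integer(round(duration_s * fs))
  with_seed(seed, {
    trace <- if (mp$noise_rms_pa > 0) stats::rnorm(n, sd = mp$noise_rms_pa)
             else numeric(n)
    n_ev <- stats::rpois(1L, mp$rate_hz * duration_s)
    ev <- data.frame(time_s = numeric(0), amplitude_pa = numeric(0),
                     rise_ms = numeric(0), decay_ms = numeric(0))
    if (n_ev > 0L) {
      times <- sort(stats::runif(n_ev, 0, duration_s))
      amps <- stats::rlnorm(n_ev, mp$amp_meanlog, mp$amp_sdlog)
      for (i in seq_len(n_ev)) {
        s0 <- as.integer(round(times[i] * fs))
        ii <- (s0 + 1L):min(s0 + length(tpl$kernel), n)
        trace[ii] <- trace[ii] + amps[i] * tpl$kernel[seq_along(ii)]
      }
      ev <- data.frame(time_s = times, amplitude_pa = amps,
                       rise_ms = tpl$rise_20_80_ms, decay_ms = mp$decay_tau_ms)
    }
    structure(list(trace = trace, fs = fs, events = ev, template = tpl),
              class = "mepsc_recording")
  })
}
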