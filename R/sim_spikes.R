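#' Synthesize stimulus-locked spike trains with known responsiveness
#'
#' Each unit fires as an inhomogeneous Poisson process whose rate follows
#' the behavioral state (with an absolute refractory period enforced by
#' thinning). For responsive units, every stimulus independently adds one
#' evoked spike with the state's evoked-spike probability, at a uniform
#' latency inside the post-stimulus window. The truth table flags
#' responsiveness and records the per-state probabilities.
#'
#' @param states A `state_sequence` covering the recording.
#' @param stim_times_s Stimulation times (s), inside the sequence span.
#' @param params A [sim_params()] (component `spikes`).
#' @param n_units Number of units.
#' @param prop_responsive Fraction of units that respond to stimulation.
#' @param seed Integer seed.
#' @return list of class `spike_data`: `units` (list of sorted spike-time
#'   vectors), `truth` (data.frame: unit, responsive), `evoked_prob`
#'   (per-state), `stim_times_s`, `duration_s`, `states`.
#' @export
synthesize_spike_data <- function(states, stim_times_s, params, n_units = 10,
                                  prop_responsive = 0.5, seed = 1) {
  stopifnot(inherits(states, "hypnogram"), inherits(params, "sim_params"))
  dur <- hypnogram_duration_s(states)
  if (any(stim_times_s < 0 | stim_times_s > dur)) {
    stop("stimulation times outside the state-sequence span")
  }
  sp <- params$spikes
  if (any(sp$baseline_fr_hz < 0)) stop("negative baseline rates")
  rate_per_tick <- sp$baseline_fr_hz[states$labels]
  n_ticks <- length(states$labels)
  st_at_stim <- state_at(states, stim_times_s)
  p_evoked <- sp$evoked_prob[st_at_stim]
  refr <- sp$refractory_ms / 1000
  lat <- sp$evoked_latency_ms / 1000

  with_seed(seed, {
    responsive <- seq_len(n_units) <= round(prop_responsive * n_units)
    units <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      counts <- stats::rpois(n_ticks, rate_per_tick)
      base <- rep(seq_len(n_ticks) - 1L, counts) + stats::runif(sum(counts))
      spikes <- base
      if (responsive[u]) {
        hit <- stats::runif(length(stim_times_s)) < p_evoked
        ev <- stim_times_s[hit] + stats::runif(sum(hit), lat[1], lat[2])
        spikes <- c(spikes, ev)
      }
      spikes <- sort(spikes)
      if (length(spikes) > 1L) {
        # enforce refractory period by thinning
        keep <- c(TRUE, diff(spikes) >= refr)
        while (!all(keep)) {
          spikes <- spikes[keep]
          keep <- c(TRUE, diff(spikes) >= refr)
        }
      }
      units[[u]] <- spikes
    }
    structure(list(units = units,
                   truth = data.frame(unit = seq_len(n_units),
                                      responsive = responsive),
                   evoked_prob = sp$evoked_prob,
                   stim_times_s = stim_times_s, duration_s = dur,
                   states = states),
              class = "spike_data")
  })
}
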