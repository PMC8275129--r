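#' Simulation parameters for synthetic recordings
#'
#' Bundles every knob of the synthetic-data generators: the behavioral-state
#' model (per-photoperiod jump matrices and mean dwell times), state-dependent
#' EEG band-power profiles, EMG burst and movement rates, the miniature-EPSC
#' event model, the evoked field potential model, and the evoked-spiking
#' model. Defaults emulate a juvenile rat on a 12/12 light-dark schedule:
#' roughly 60% of light-phase time asleep and 40% of dark-phase time asleep,
#' NREM bouts of ~160 s, wake bouts of ~2-5 min, REM bouts of ~1.5 min,
#' NREM rich in delta (0.5-4 Hz), REM rich in theta (5-8 Hz) with muscle
#' atonia, and wake desynchronized with high EMG/movement.
#'
#' @param states Character vector of behavioral states. Either the 3-state
#'   set `c("WAKE","NREM","REM")` (default) or the 4-state set
#'   `c("AW","QW","NREM","REM")` with wake split into active/quiet.
#' @param ... Named overrides for any default component (see Details).
#'
#' @details Components (all overridable via `...`):
#' \describe{
#'   \item{`transition`}{list with `light` and `dark` jump matrices: row
#'     state to column state probabilities of the embedded chain (diagonal 0,
#'     rows sum to 1). Sojourn times are geometric with mean `dwell_s`.}
#'   \item{`dwell_s`}{list with `light`/`dark` named vectors of mean dwell
#'     seconds per state.}
#'   \item{`band_power`}{state x band matrix of target EEG variance
#'     (microvolt^2) in delta/theta/beta/gamma.}
#'   \item{`emg_burst_rate_hz`, `movement_rate`}{per-state EMG burst rates
#'     (Hz) and mean video movement (pixels per 1-s frame).}
#'   \item{`mepsc`}{Poisson rate (Hz), lognormal amplitude (meanlog, sdlog,
#'     pA), kinetics (rise/decay tau, ms) and noise RMS (pA).}
#'   \item{`fepsp`}{per-state evoked gain, stimulation period (s), template
#'     amplitude (microvolt) and channel noise RMS.}
#'   \item{`spikes`}{per-state evoked-spike probability and baseline firing
#'     rates (Hz).}
#' }
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' p4 <- sim_params(states = c("AW", "QW", "NREM", "REM"))
#' @export
sim_params <- function(states = c("WAKE", "NREM", "REM"), ...) {
  states <- match.arg(paste(states, collapse = ","),
                      c("WAKE,NREM,REM", "AW,QW,NREM,REM"))
  states <- strsplit(states, ",")[[1]]
  p <- if (length(states) == 3L) default_params_3state() else default_params_4state()
  p$states <- states
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown sim_params component: ", nm)
    if (is.list(p[[nm]]) && is.list(dots[[nm]]) && !is.null(names(dots[[nm]]))) {
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  validate_sim_params(p)
}

default_bands <- function() {
  data.frame(name = c("delta", "theta", "beta", "gamma"),
             low_hz = c(0.5, 5, 20, 35),
             high_hz = c(4, 8, 35, 80),
             stringsAsFactors = FALSE)
}

jump_matrix <- function(states, rows) {
  m <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  for (from in names(rows)) m[from, names(rows[[from]])] <- rows[[from]]
  m
}

default_params_3state <- function() {
  st <- c("WAKE", "NREM", "REM")
  light <- jump_matrix(st, list(
    WAKE = c(NREM = 1),
    NREM = c(WAKE = 0.5, REM = 0.5),
    REM  = c(WAKE = 0.6, NREM = 0.4)))
  dark <- jump_matrix(st, list(
    WAKE = c(NREM = 1),
    NREM = c(WAKE = 0.6, REM = 0.4),
    REM  = c(WAKE = 0.7, NREM = 0.3)))
  band_power <- rbind(
    WAKE = c(delta = 120, theta = 50, beta = 200, gamma = 200),
    NREM = c(delta = 2000, theta = 150, beta = 100, gamma = 50),
    REM  = c(delta = 100, theta = 1000, beta = 100, gamma = 150))
  list(
    states = st,
    transition = list(light = light, dark = dark),
    dwell_s = list(light = c(WAKE = 180, NREM = 160, REM = 90),
                   dark = c(WAKE = 300, NREM = 130, REM = 70)),
    band_power = band_power,
    broadband_power = 20,
    emg_burst_rate_hz = c(WAKE = 1.0, NREM = 0, REM = 0),
    emg_burst_dur_s = 0.2,
    emg_burst_gain = 12,
    emg_noise_uv = 10,
    movement_rate = c(WAKE = 40, NREM = 0.3, REM = 0.1),
    bands = default_bands(),
    lights_on_zt = 0, lights_off_zt = 12,
    transition_smooth_s = 1,
    delta_decay_factor = 1,
    mepsc = list(rate_hz = 2, amp_meanlog = log(10), amp_sdlog = 0.3,
                 rise_tau_ms = 0.5, decay_tau_ms = 3, noise_rms_pa = 1.8),
    fepsp = list(gain = c(WAKE = 1.0, NREM = 1.2, REM = 1.0),
                 stim_period_s = 10, amp_uv = 150, noise_rms_uv = 10,
                 latency_ms = 3, sink_channel = NA_integer_,
                 trend = NULL),
    spikes = list(evoked_prob = c(WAKE = 0.05, NREM = 0.2, REM = 0.1),
                  baseline_fr_hz = c(WAKE = 5, NREM = 3, REM = 4),
                  refractory_ms = 2.5, evoked_latency_ms = c(2, 10))
  )
}

default_params_4state <- function() {
  st <- c("AW", "QW", "NREM", "REM")
  light <- jump_matrix(st, list(
    AW   = c(QW = 0.8, NREM = 0.2),
    QW   = c(AW = 0.4, NREM = 0.6),
    NREM = c(QW = 0.35, AW = 0.1, REM = 0.55),
    REM  = c(AW = 0.25, QW = 0.35, NREM = 0.4)))
  dark <- jump_matrix(st, list(
    AW   = c(QW = 0.8, NREM = 0.2),
    QW   = c(AW = 0.55, NREM = 0.45),
    NREM = c(QW = 0.4, AW = 0.2, REM = 0.4),
    REM  = c(AW = 0.35, QW = 0.35, NREM = 0.3)))
  band_power <- rbind(
    AW   = c(delta = 80, theta = 60, beta = 250, gamma = 300),
    QW   = c(delta = 150, theta = 50, beta = 150, gamma = 100),
    NREM = c(delta = 2000, theta = 150, beta = 100, gamma = 50),
    REM  = c(delta = 100, theta = 1000, beta = 100, gamma = 150))
  p <- default_params_3state()
  p$states <- st
  p$transition <- list(light = light, dark = dark)
  p$dwell_s <- list(light = c(AW = 110, QW = 80, NREM = 160, REM = 90),
                    dark = c(AW = 220, QW = 80, NREM = 130, REM = 70))
  p$band_power <- band_power
  p$emg_burst_rate_hz <- c(AW = 1.5, QW = 0.3, NREM = 0, REM = 0)
  p$movement_rate <- c(AW = 60, QW = 1.5, NREM = 0.3, REM = 0.1)
  p$fepsp$gain <- c(AW = 0.8, QW = 1.0, NREM = 1.2, REM = 1.0)
  p$spikes$evoked_prob <- c(AW = 0.04, QW = 0.06, NREM = 0.2, REM = 0.1)
  p$spikes$baseline_fr_hz <- c(AW = 6, QW = 5, NREM = 3, REM = 4)
  p
}

validate_sim_params <- function(p) {
  st <- p$states
  for (ph in c("light", "dark")) {
    m <- p$transition[[ph]]
    if (!is.matrix(m) || !identical(rownames(m), st) ||
        !identical(colnames(m), st)) {
      stop("transition$", ph, " must be a ", length(st), "x", length(st),
           " matrix with states as dimnames")
    }
    if (any(m < 0) || any(m > 1) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stop("transition$", ph, " rows must be probabilities summing to 1")
    }
    if (any(diag(m) != 0)) stop("transition$", ph,
                                " diagonal must be 0 (jump matrix)")
    if (any(p$dwell_s[[ph]][st] <= 0)) stop("dwell_s must be positive")
  }
  if (any(p$band_power < 0)) stop("band powers must be nonnegative")
  if (any(p$emg_burst_rate_hz < 0) || any(p$movement_rate < 0)) {
    stop("rates must be nonnegative")
  }
  with(p$mepsc, {
    if (rate_hz < 0) stop("mepsc rate must be nonnegative")
    if (rise_tau_ms <= 0 || decay_tau_ms <= 0) stop("mepsc taus must be > 0")
    if (decay_tau_ms <= rise_tau_ms) stop("mepsc decay_tau must exceed rise_tau")
  })
  if (any(p$spikes$evoked_prob < 0 | p$spikes$evoked_prob > 1)) {
    stop("evoked_prob must be in [0, 1]")
  }
  if (any(p$spikes$baseline_fr_hz < 0)) stop("baseline rates must be nonnegative")
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", length(x$states), "-state model: ",
      paste(x$states, collapse = "/"), "\n", sep = "")
  cat("  dwell (light, s):",
      paste(sprintf("%s=%g", x$states, x$dwell_s$light[x$states]),
            collapse = ", "), "\n")
  cat("  mEPSC:", x$mepsc$rate_hz, "Hz, lognormal(",
      round(x$mepsc$amp_meanlog, 2), ",", x$mepsc$amp_sdlog, ") pA\n")
  cat("  fEPSP gains:",
      paste(sprintf("%s=%g", names(x$fepsp$gain), x$fepsp$gain),
            collapse = ", "), "\n")
  invisible(x)
}
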