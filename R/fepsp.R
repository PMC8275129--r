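#' Band-pass filter an LFP recording for fEPSP analysis
#'
#' Order-2 Butterworth band-pass, 5-450 Hz, applied with zero phase so
#' trough latencies are not shifted. The forward-backward pass is realized
#' exactly in the frequency domain: the spectrum of each channel is
#' multiplied by the squared Butterworth magnitude response (which is what
#' a forward-backward time-domain pass applies, without its edge
#' transients).
#'
#' @param lfp Channels x samples matrix (or a vector for one channel).
#' @param fs Sampling rate; must exceed 2 x the low-pass corner.
#' @param high_pass_hz,low_pass_hz,order Filter settings.
#' @return Filtered matrix of the same shape.
#' @export
fepsp_preprocess <- function(lfp, fs, high_pass_hz = 5, low_pass_hz = 450,
                             order = 2) {
  if (fs <= 2 * low_pass_hz) stop("fs must exceed twice the low-pass corner")
  vec_in <- !is.matrix(lfp)
  if (vec_in) lfp <- matrix(lfp, nrow = 1)
  n <- ncol(lfp)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)
  # squared magnitude of an analog Butterworth band-pass (forward+backward)
  h2 <- 1 / (1 + (high_pass_hz / pmax(f, 1e-12))^(2 * order)) *
    1 / (1 + (f / low_pass_hz)^(2 * order))
  out <- lfp
  for (ch in seq_len(nrow(lfp))) {
    out[ch, ] <- Re(stats::fft(stats::fft(lfp[ch, ]) * h2, inverse = TRUE)) / n
  }
  if (vec_in) out <- as.vector(out)
  out
}

#' Extract and quality-control stimulus-locked sweeps
#'
#' Cuts a window of -100 ms to +80 ms around every stimulus,
#' baseline-subtracts the pre-stimulus mean per channel, and rejects
#' sweeps whose analysis-channel baseline SD over the last 5 ms before the
#' stimulus exceeds 200 microvolts ("baseline_sd") or in which no evoked
#' trough of magnitude strictly greater than 30 microvolts can be found in
#' the search window ("no_trough"). Sweeps overlapping the previous sweep
#' or running off the recording are rejected ("truncated").
#'
#' @param lfp Filtered channels x samples matrix (see
#'   [fepsp_preprocess()]).
#' @param fs Sampling rate (Hz).
#' @param stim_times_s Stimulation times (s).
#' @param channel Analysis channel; NULL selects it automatically from the
#'   mean sweep by joint rank of trough amplitude and (shortest) latency,
#'   mirroring the choice of the largest, shortest-latency response.
#' @param pre_ms,post_ms Window (ms).
#' @param baseline_sd_uv,trough_min_uv QC cutoffs (exclusive).
#' @param blank_ms,search_max_ms Trough search window after the stimulus.
#' @return list of class `sweep_set`: `sweeps` (n_stim x channels x time
#'   array, baseline-subtracted), `time_ms`, `fs`, `stim_times_s`,
#'   `channel`, `qc` (data.frame: stim_time_s, qc_pass, reason).
#' @export
extract_sweeps <- function(lfp, fs, stim_times_s, channel = NULL,
                           pre_ms = 100, post_ms = 80,
                           baseline_sd_uv = 200, trough_min_uv = 30,
                           blank_ms = 1.5, search_max_ms = 30) {
  if (!is.matrix(lfp)) lfp <- matrix(lfp, nrow = 1)
  n <- ncol(lfp); nch <- nrow(lfp)
  npre <- as.integer(round(pre_ms / 1000 * fs))
  npost <- as.integer(round(post_ms / 1000 * fs))
  nt <- npre + npost + 1L
  time_ms <- (seq_len(nt) - npre - 1L) / fs * 1000
  ns <- length(stim_times_s)
  sweeps <- array(NA_real_, c(ns, nch, nt))
  reason <- rep(NA_character_, ns)
  prev_end <- -Inf
  for (i in seq_len(ns)) {
    s0 <- as.integer(round(stim_times_s[i] * fs))
    ii <- (s0 - npre):(s0 + npost)
    if (ii[1L] < 1L || ii[nt] > n || ii[1L] <= prev_end) {
      reason[i] <- "truncated"
      next
    }
    prev_end <- ii[nt]
    seg <- lfp[, ii, drop = FALSE]
    seg <- seg - rowMeans(seg[, seq_len(npre), drop = FALSE])
    sweeps[i, , ] <- seg
  }
  ok <- is.na(reason)

  if (is.null(channel)) {
    channel <- select_analysis_channel(sweeps[ok, , , drop = FALSE], time_ms,
                                       blank_ms, search_max_ms)
  }
  base_idx <- which(time_ms >= -5 & time_ms < 0)
  search <- which(time_ms > blank_ms & time_ms <= search_max_ms)
  for (i in which(ok)) {
    v <- sweeps[i, channel, ]
    if (stats::sd(v[base_idx]) > baseline_sd_uv) {
      reason[i] <- "baseline_sd"
    } else if (-min(v[search]) <= trough_min_uv) {
      reason[i] <- "no_trough"
    }
  }
  structure(list(sweeps = sweeps, time_ms = time_ms, fs = fs,
                 stim_times_s = stim_times_s, channel = channel,
                 qc = data.frame(stim_time_s = stim_times_s,
                                 qc_pass = is.na(reason), reason = reason)),
            class = "sweep_set")
}

# Joint rank of trough magnitude (larger better) and latency (shorter
# better) on the channel-mean sweep.
select_analysis_channel <- function(sweeps, time_ms, blank_ms = 1.5,
                                    search_max_ms = 30) {
  if (!length(sweeps)) return(1L)
  mean_sweep <- apply(sweeps, c(2, 3), mean)
  search <- which(time_ms > blank_ms & time_ms <= search_max_ms)
  amp <- apply(mean_sweep[, search, drop = FALSE], 1, function(v) -min(v))
  lat <- apply(mean_sweep[, search, drop = FALSE], 1, which.min)
  score <- rank(-amp) + rank(lat)
  which.min(score)
}

#' Measure one fEPSP sweep
#'
#' The trough is the first local minimum below `-trough_min_uv` after the
#' stimulus-artifact blanking period; amplitude is its magnitude relative
#' to the (already subtracted) pre-stimulus baseline, latency is the time
#' from stimulus to trough, and the slope is the least-squares line over
#' the falling-phase samples between 20% and 80% of the trough amplitude,
#' reported as a positive magnitude in microvolts/ms. A 20-80% segment
#' shorter than 3 samples leaves the slope flagged undefined.
#'
#' @param v One sweep on the analysis channel (baseline-subtracted,
#'   microvolts).
#' @param time_ms Time axis (ms relative to the stimulus).
#' @param blank_ms,search_max_ms Trough search window.
#' @param trough_min_uv Minimum trough magnitude (exclusive).
#' @return list: `trough_amplitude_uv`, `slope_uv_per_ms`, `latency_ms`,
#'   `trough_index` (NA throughout when no qualifying trough exists).
#' @export
measure_fepsp <- function(v, time_ms, blank_ms = 1.5, search_max_ms = 30,
                          trough_min_uv = 30) {
  search <- which(time_ms > blank_ms & time_ms <= search_max_ms)
  vs <- v[search]
  nloc <- length(vs)
  is_min <- vs < c(Inf, vs[-nloc]) & vs <= c(vs[-1L], Inf) & -vs > trough_min_uv
  if (!any(is_min)) {
    return(list(trough_amplitude_uv = NA_real_, slope_uv_per_ms = NA_real_,
                latency_ms = NA_real_, trough_index = NA_integer_))
  }
  k <- search[which(is_min)[1L]]
  amp <- -v[k]
  lat <- time_ms[k]
  # falling phase: walk back from the trough to the last sample above -20%
  lev20 <- -0.2 * amp; lev80 <- -0.8 * amp
  j <- k
  while (j > 1L && v[j - 1L] < lev20 && time_ms[j - 1L] > 0) j <- j - 1L
  seg <- j:k
  use <- seg[v[seg] <= lev20 & v[seg] >= lev80]
  slope <- NA_real_
  if (length(use) >= 3L) {
    fit <- stats::lm.fit(cbind(1, time_ms[use]), v[use])
    slope <- abs(fit$coefficients[2L])
  }
  list(trough_amplitude_uv = amp, slope_uv_per_ms = unname(slope),
       latency_ms = lat, trough_index = k)
}

#' Measure all accepted sweeps of a sweep set
#'
#' @param ss A `sweep_set` from [extract_sweeps()].
#' @param channel Channel to measure (defaults to the set's analysis
#'   channel).
#' @param ... Passed to [measure_fepsp()].
#' @return data.frame of class `fepsp_measurements`: `stim_time_s`,
#'   `channel`, `amplitude_uv`, `slope_uv_per_ms`, `latency_ms`,
#'   `qc_pass`, `reason`.
#' @export
measure_sweeps <- function(ss, channel = NULL, ...) {
  channel <- channel %||% ss$channel
  ns <- nrow(ss$qc)
  amp <- slp <- lat <- rep(NA_real_, ns)
  for (i in which(ss$qc$qc_pass)) {
    m <- measure_fepsp(ss$sweeps[i, channel, ], ss$time_ms, ...)
    amp[i] <- m$trough_amplitude_uv
    slp[i] <- m$slope_uv_per_ms
    lat[i] <- m$latency_ms
  }
  out <- data.frame(stim_time_s = ss$stim_times_s, channel = channel,
                    amplitude_uv = amp, slope_uv_per_ms = slp,
                    latency_ms = lat, qc_pass = ss$qc$qc_pass,
                    reason = ss$qc$reason)
  class(out) <- c("fepsp_measurements", "data.frame")
  out
}

#' Current-source-density analysis of a mean sweep
#'
#' Second spatial derivative across uniformly spaced laminar channels:
#' `CSD_i = -(V_{i-1} - 2 V_i + V_{i+1}) / dz^2`. Edge channels are
#' undefined. The sink is the channel with the most negative CSD at the
#' fEPSP trough time (the time of the most negative interior-channel CSD).
#'
#' @param mean_sweep Channels x time matrix (microvolts).
#' @param spacing_um Electrode spacing (micrometers, uniform).
#' @param time_ms Optional time axis; restrict the sink search to t > 0.
#' @return list of class `csd_map`: `csd` (channels x time, mV/mm^2-like
#'   arbitrary units), `sink_channel`, `trough_time_index`.
#' @export
csd <- function(mean_sweep, spacing_um = 100, time_ms = NULL) {
  nch <- nrow(mean_sweep)
  if (nch < 3L) stop("CSD needs at least 3 channels")
  if (length(spacing_um) != 1L || spacing_um <= 0) {
    stop("spacing must be a single positive value (uniform)")
  }
  dz2 <- (spacing_um / 1000)^2
  inner <- 2:(nch - 1L)
  m <- -(mean_sweep[inner - 1L, , drop = FALSE] -
           2 * mean_sweep[inner, , drop = FALSE] +
           mean_sweep[inner + 1L, , drop = FALSE]) / dz2
  out <- matrix(NA_real_, nch, ncol(mean_sweep))
  out[inner, ] <- m
  cols <- if (!is.null(time_ms)) which(time_ms > 0) else seq_len(ncol(out))
  idx <- arrayInd(which.min(out[inner, cols, drop = FALSE]),
                  c(length(inner), length(cols)))
  structure(list(csd = out, sink_channel = inner[idx[1L]],
                 trough_time_index = cols[idx[2L]]),
            class = "csd_map")
}

measurement_states <- function(meas, hypnogram4) {
  state_at(hypnogram4, meas$stim_time_s)
}

#' Normalize per-state fEPSP amplitudes to light-period quiet wake
#'
#' Tags every accepted measurement with the behavioral state at its
#' stimulus time and divides per-state mean amplitudes by the mean over
#' quiet-wake measurements in the light period.
#'
#' @param meas A `fepsp_measurements` table.
#' @param hypnogram4 A 4-state [hypnogram()] covering the stimuli.
#' @param lights_on,lights_off Light schedule (ZT hours).
#' @return data.frame: `state`, `n`, `mean_uv`, `sem_uv`, `norm_to_light_qw`.
#' @export
state_normalize <- function(meas, hypnogram4, lights_on = 0, lights_off = 12) {
  ok <- meas$qc_pass & is.finite(meas$amplitude_uv)
  st <- measurement_states(meas, hypnogram4)
  zt <- zt_at(meas$stim_time_s, hypnogram4$start_zt)
  light <- is_light_zt(zt, lights_on, lights_off)
  ref <- ok & !is.na(st) & st == "QW" & light
  if (!any(ref)) stop("no light-period quiet-wake measurements to normalize to")
  ref_mean <- mean(meas$amplitude_uv[ref])
  sel <- ok & !is.na(st)
  agg <- lapply(split(meas$amplitude_uv[sel], st[sel]), function(v) {
    c(n = length(v), mean_uv = mean(v),
      sem_uv = stats::sd(v) / sqrt(length(v)))
  })
  df <- as.data.frame(do.call(rbind, agg))
  df <- cbind(state = rownames(df), df, row.names = NULL)
  df$norm_to_light_qw <- df$mean_uv / ref_mean
  df
}

#' fEPSP time course across dense epochs
#'
#' Within each dense epoch, keeps measurements made in the filter state,
#' averages them in `bin_min`-minute bins from epoch start, and normalizes
#' to the mean over the first `norm_window_min` minutes (truncated to the
#' epoch length). Epochs spanning a light-dark transition are renormalized
#' so the first bin after the transition matches the last bin before it.
#'
#' @param meas `fepsp_measurements`.
#' @param epochs `dense_epochs` (65% or 75% criteria).
#' @param hypnogram4 4-state hypnogram for state tagging.
#' @param state Filter state ("NREM", "REM", "AW", "QW").
#' @param bin_min Bin width (minutes).
#' @param norm_window_min Normalization window (minutes, default 60).
#' @param lights_on,lights_off Light schedule for the transition
#'   renormalization.
#' @return data.frame: `epoch`, `bin`, `t_min` (bin center from epoch
#'   start), `n`, `value` (normalized amplitude). Epochs without
#'   measurements in the normalization window are skipped with a warning.
#' @export
epoch_timecourse <- function(meas, epochs, hypnogram4, state = "NREM",
                             bin_min = 10, norm_window_min = 60,
                             lights_on = 0, lights_off = 12) {
  st <- measurement_states(meas, hypnogram4)
  out <- list()
  for (e in seq_len(nrow(epochs))) {
    t0 <- epochs$start_s[e]; t1 <- epochs$span_end_s[e]
    sel <- which(meas$qc_pass & is.finite(meas$amplitude_uv) &
                   !is.na(st) & st == state &
                   meas$stim_time_s >= t0 & meas$stim_time_s < t1)
    if (!length(sel)) next
    rel_min <- (meas$stim_time_s[sel] - t0) / 60
    bin <- floor(rel_min / bin_min) + 1L
    vals <- tapply(meas$amplitude_uv[sel], bin, mean)
    ns <- tapply(meas$amplitude_uv[sel], bin, length)
    bins <- as.integer(names(vals))
    nw <- max(1, min(norm_window_min, (t1 - t0) / 60))
    norm_bins <- bins[(bins - 1L) * bin_min < nw]
    if (!length(norm_bins)) {
      warning("epoch ", e, " has no measurements in the normalization window")
      next
    }
    v <- as.numeric(vals) / mean(vals[as.character(norm_bins)])
    # light-dark transition renormalization
    zt_bins <- zt_at(t0 + (bins - 0.5) * bin_min * 60, hypnogram4$start_zt)
    lightb <- is_light_zt(zt_bins, lights_on, lights_off)
    if (length(unique(lightb)) > 1L) {
      flip <- which(diff(lightb) != 0)[1L] + 1L
      v[flip:length(v)] <- v[flip:length(v)] * v[flip - 1L] / v[flip]
    }
    out[[length(out) + 1L]] <- data.frame(
      epoch = e, bin = bins, t_min = (bins - 0.5) * bin_min,
      n = as.integer(ns), value = v)
  }
  if (!length(out)) {
    return(data.frame(epoch = integer(0), bin = integer(0),
                      t_min = numeric(0), n = integer(0), value = numeric(0)))
  }
  do.call(rbind, out)
}

#' Sandwich analysis: fEPSP change across dense epochs
#'
#' Compares mean fEPSP amplitude in matched-state flanking windows (default
#' 1 h) before and after each dense epoch: measurements are taken in NREM
#' for the flanks of wake-dense epochs and in quiet wake for the flanks of
#' sleep-dense epochs (the flanks themselves are opposite-state time), with
#' REM/AW selectable via `flank_state`. The normalized change is
#' `post/pre - 1`; changes are tested against zero with a Wilcoxon
#' signed-rank test and regressed on epoch duration.
#'
#' @param meas `fepsp_measurements`.
#' @param epochs `dense_epochs` (e.g. the >30 min / >75% criterion).
#' @param hypnogram4 4-state hypnogram.
#' @param flank_s Flanking window (s, default 3600).
#' @param flank_state Optional explicit flank measurement state; default
#'   NREM for wake epochs, QW for sleep epochs.
#' @param min_flank_n Minimum accepted measurements per flank.
#' @return list of class `sandwich_result`: `changes` (data.frame: epoch,
#'   state, duration_h, pre_mean_uv, post_mean_uv, normalized_change,
#'   flank_state), `wilcoxon` (htest or NULL), `regression`
#'   ([correlate_behavior()] output), `dropped` (epoch indices without
#'   qualifying flank measurements).
#' @export
fepsp_sandwich <- function(meas, epochs, hypnogram4, flank_s = 3600,
                           flank_state = NULL, min_flank_n = 1L) {
  st <- measurement_states(meas, hypnogram4)
  ok <- meas$qc_pass & is.finite(meas$amplitude_uv) & !is.na(st)
  rows <- list(); dropped <- integer(0)
  for (e in seq_len(nrow(epochs))) {
    fstate <- flank_state %||%
      (if (epochs$state[e] %in% c("wake", "AW", "QW")) "NREM" else "QW")
    t0 <- epochs$start_s[e]; t1 <- epochs$span_end_s[e]
    pre <- ok & st == fstate &
      meas$stim_time_s >= t0 - flank_s & meas$stim_time_s < t0
    post <- ok & st == fstate &
      meas$stim_time_s >= t1 & meas$stim_time_s < t1 + flank_s
    if (sum(pre) < min_flank_n || sum(post) < min_flank_n) {
      dropped <- c(dropped, e)
      next
    }
    pm <- mean(meas$amplitude_uv[pre]); qm <- mean(meas$amplitude_uv[post])
    rows[[length(rows) + 1L]] <- data.frame(
      epoch = e, state = epochs$state[e], duration_h = (t1 - t0) / 3600,
      pre_mean_uv = pm, post_mean_uv = qm,
      normalized_change = qm / pm - 1, flank_state = fstate)
  }
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(epoch = integer(0), state = character(0),
               duration_h = numeric(0), pre_mean_uv = numeric(0),
               post_mean_uv = numeric(0), normalized_change = numeric(0),
               flank_state = character(0))
  wt <- if (nrow(changes) >= 3L && stats::sd(changes$normalized_change) > 0) {
    stats::wilcox.test(changes$normalized_change, mu = 0, exact = FALSE)
  } else NULL
  reg <- if (nrow(changes) >= 3L) {
    correlate_behavior(changes$duration_h, changes$normalized_change)
  } else NULL
  structure(list(changes = changes, wilcoxon = wt, regression = reg,
                 dropped = dropped),
            class = "sandwich_result")
}

#' @export
print.sandwich_result <- function(x, ...) {
  cat(sprintf("<sandwich_result> %d epochs (%d dropped), mean change %.2f%%\n",
              nrow(x$changes), length(x$dropped),
              100 * mean(x$changes$normalized_change)))
  if (!is.null(x$wilcoxon)) {
    cat(sprintf("  Wilcoxon signed-rank vs 0: V = %g, p = %.3g\n",
                x$wilcoxon$statistic, x$wilcoxon$p.value))
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  change ~ duration: slope %.4f /h, R2 = %.3f, p = %.3g\n",
                x$regression$slope, x$regression$r_squared,
                x$regression$p_value))
  }
  invisible(x)
}
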