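#' Moving fraction of time awake
#'
#' For each epoch end t, the fraction of the preceding `window_h` hours
#' labelled wake (AW and QW count as wake in the 4-state set). Undefined
#' (`NA`) before the first full window.
#'
#' @param h A [hypnogram()].
#' @param window_h Window length in hours (default 4).
#' @return data.frame with `end_s` and `fraction_awake`.
#' @export
moving_wake_fraction <- function(h, window_h = 4) {
  w_ep <- as.integer(round(window_h * 3600 / h$epoch_len_s))
  if (length(h$labels) < w_ep) stop("hypnogram shorter than the window")
  x <- as.numeric(h$labels %in% wake_states(h))
  frac <- rolling_sum(x, w_ep) / w_ep
  data.frame(end_s = seq_along(x) * h$epoch_len_s, fraction_awake = frac)
}

state_indicator <- function(h, state) {
  target <- switch(state,
                   sleep = sleep_states(h),
                   wake = wake_states(h),
                   state)
  if (!length(intersect(target, h$states))) {
    stop("state '", state, "' not in hypnogram state set")
  }
  as.numeric(h$labels %in% target)
}

#' Detect sleep- or wake-dense epochs
#'
#' Finds periods in which a target state (or pooled state class: "sleep" =
#' NREM+REM, "wake" = WAKE or AW+QW) dominates. A window end `e` qualifies
#' when the state fraction over the preceding `min_dur_h` hours exceeds
#' `density` and, if `last_hour_density` is given, the fraction over the
#' final hour exceeds it too (the 4 h / >65% / last hour >70% criterion).
#' Overlapping qualifying windows are merged into one dense epoch whose
#' `end_s` is the first qualifying crossing (the experimental endpoint) and
#' whose `span_end_s` is the last. [detect_sandwich_epochs()] is the
#' >30 min / >75% variant without the last-hour clause.
#'
#' @param h A [hypnogram()].
#' @param state "sleep", "wake", or a single state name.
#' @param min_dur_h Window length (hours).
#' @param density Required state fraction over the window (exclusive, >).
#' @param last_hour_density Required fraction over the final hour, or NULL.
#' @return data.frame of class `dense_epochs` with columns `state`,
#'   `start_s`, `end_s`, `span_end_s`, `density`, `last_hour_density`,
#'   `photoperiod`. Zero rows when nothing qualifies.
#' @examples
#' h <- hypnogram(rep("NREM", 1500), epoch_len_s = 10)
#' detect_dense_epochs(h, "sleep")
#' @export
detect_dense_epochs <- function(h, state = c("sleep", "wake"), min_dur_h = 4,
                                density = 0.65, last_hour_density = 0.70) {
  if (is.character(state) && length(state) > 1L) state <- match.arg(state)
  stopifnot(density > 0, density <= 1)
  w <- h$epoch_len_s
  L <- as.integer(round(min_dur_h * 3600 / w))
  x <- state_indicator(h, state)
  frac_L <- rolling_sum(x, L) / L
  ok <- !is.na(frac_L) & frac_L > density
  lh <- rep(NA_real_, length(x))
  if (!is.null(last_hour_density)) {
    H <- min(L, as.integer(round(3600 / w)))
    frac_H <- rolling_sum(x, H) / H
    ok <- ok & !is.na(frac_H) & frac_H > last_hour_density
    lh <- frac_H
  }
  qe <- which(ok)
  out <- data.frame(state = character(0), start_s = numeric(0),
                    end_s = numeric(0), span_end_s = numeric(0),
                    density = numeric(0), last_hour_density = numeric(0),
                    photoperiod = character(0))
  if (length(qe)) {
    new_run <- c(TRUE, diff(qe) > L)   # gap > L means windows do not overlap
    run_id <- cumsum(new_run)
    firsts <- qe[new_run]
    lasts <- tapply(qe, run_id, max)
    out <- data.frame(
      state = state,
      start_s = (firsts - L) * w,
      end_s = firsts * w,
      span_end_s = as.numeric(lasts) * w,
      density = frac_L[firsts],
      last_hour_density = lh[firsts],
      photoperiod = hypnogram_photoperiod(h)[firsts])
  }
  attr(out, "epoch_len_s") <- w
  attr(out, "criteria") <- list(min_dur_h = min_dur_h, density = density,
                                last_hour_density = last_hour_density)
  class(out) <- c("dense_epochs", "data.frame")
  out
}

#' @rdname detect_dense_epochs
#' @export
detect_sandwich_epochs <- function(h, state = c("sleep", "wake"),
                                   min_dur_h = 0.5, density = 0.75) {
  detect_dense_epochs(h, state, min_dur_h = min_dur_h, density = density,
                      last_hour_density = NULL)
}

#' Per-epoch dense-epoch membership trace
#'
#' TRUE for epochs inside the union of qualifying windows of
#' [detect_dense_epochs()] (from each merged epoch's `start_s` to its
#' `span_end_s`). Used to compare dense-epoch on/off times between two
#' hypnograms.
#'
#' @param h A [hypnogram()].
#' @param ... Passed to [detect_dense_epochs()].
#' @return Logical vector, one element per epoch of `h`.
#' @export
dense_membership <- function(h, ...) {
  de <- detect_dense_epochs(h, ...)
  member <- rep(FALSE, length(h$labels))
  for (i in seq_len(nrow(de))) {
    i0 <- floor(de$start_s[i] / h$epoch_len_s) + 1L
    i1 <- ceiling(de$span_end_s[i] / h$epoch_len_s)
    member[i0:i1] <- TRUE
  }
  member
}

#' Bout duration statistics
#'
#' A bout is a maximal run of one state label. Returns the mean and SEM of
#' bout durations per state, optionally restricted to bouts starting inside
#' given dense epochs.
#'
#' @param h A [hypnogram()].
#' @param within Optional `dense_epochs` to restrict to.
#' @return list with `bouts` (data.frame: state, start_s, duration_s) and
#'   `summary` (data.frame: state, n, mean_s, sem_s).
#' @export
bout_durations <- function(h, within = NULL) {
  r <- rle(h$labels)
  ends <- cumsum(r$lengths)
  starts_s <- (ends - r$lengths) * h$epoch_len_s
  bouts <- data.frame(state = r$values, start_s = starts_s,
                      duration_s = r$lengths * h$epoch_len_s)
  if (!is.null(within) && nrow(within)) {
    keep <- rep(FALSE, nrow(bouts))
    for (i in seq_len(nrow(within))) {
      keep <- keep | (bouts$start_s >= within$start_s[i] &
                        bouts$start_s < within$span_end_s[i])
    }
    bouts <- bouts[keep, , drop = FALSE]
  }
  summ <- do.call(rbind, lapply(split(bouts$duration_s, bouts$state),
    function(d) data.frame(n = length(d), mean_s = mean(d),
                           sem_s = stats::sd(d) / sqrt(length(d)))))
  summ <- cbind(state = rownames(summ), summ)
  rownames(summ) <- NULL
  list(bouts = bouts, summary = summ)
}

#' Time-in-state proportions by photoperiod
#'
#' @param h A [hypnogram()].
#' @param lights_on,lights_off Zeitgeber hours of the 12/12 schedule.
#' @return data.frame with one row per photoperiod present: per-state
#'   fractions (summing to 1) plus pooled `sleep` and `wake` fractions.
#' @export
state_proportions <- function(h, lights_on = 0, lights_off = 12) {
  ph <- hypnogram_photoperiod(h, lights_on, lights_off)
  out <- lapply(split(seq_along(h$labels), ph), function(ii) {
    tab <- table(factor(h$labels[ii], levels = h$states))
    frac <- as.numeric(tab) / length(ii)
    names(frac) <- h$states
    c(frac, sleep = sum(frac[sleep_states(h)]),
      wake = sum(frac[wake_states(h)]))
  })
  df <- as.data.frame(do.call(rbind, out))
  cbind(photoperiod = rownames(df), df, row.names = NULL)
}

#' NREM delta-power series normalized to its daily minimum
#'
#' Extracts delta-band power per epoch from the EEG (Welch FFT in 10-s
#' windows), keeps NREM epochs only (the time-of-day correction: averages
#' are computed within NREM epochs, weighting epochs equally), and
#' normalizes to the mean over the baseline zeitgeber window where delta
#' power tends to be lowest (ZT 7-11).
#'
#' @param eeg EEG trace (microvolts).
#' @param fs Sampling rate (Hz).
#' @param h Hypnogram covering the trace.
#' @param baseline_zt Baseline window in ZT hours, `c(from, to)`.
#' @param epoch_len_s FFT window (s).
#' @param bands Band table; only `delta` is used.
#' @return data.frame of class `delta_power_series`: `time_s`, `zt`,
#'   `delta_uv2`, `normalized_pct` for each NREM epoch.
#' @export
delta_power_homeostasis <- function(eeg, fs, h, baseline_zt = c(7, 11),
                                    epoch_len_s = 10,
                                    bands = band_definitions()) {
  bp <- compute_band_powers(eeg, fs, epoch_len_s, bands)
  n_ep <- nrow(bp)
  h10 <- resample_hypnogram(h, epoch_len_s)
  n_ep <- min(n_ep, length(h10$labels))
  nrem <- which(h10$labels[seq_len(n_ep)] == "NREM")
  if (!length(nrem)) stop("no NREM epochs in hypnogram")
  time_s <- (nrem - 0.5) * epoch_len_s
  zt <- zt_at(time_s, h$start_zt)
  delta <- bp[nrem, "delta"]
  in_base <- zt_window(zt, baseline_zt)
  if (!any(in_base)) stop("no NREM epochs in the baseline ZT window")
  base <- mean(delta[in_base])
  out <- data.frame(time_s = time_s, zt = zt, delta_uv2 = delta,
                    normalized_pct = 100 * delta / base)
  class(out) <- c("delta_power_series", "data.frame")
  attr(out, "baseline_uv2") <- base
  out
}

zt_window <- function(zt, win) {
  a <- win[1] %% 24; b <- win[2] %% 24
  if (a <= b) zt >= a & zt < b else zt >= a | zt < b
}

#' Overnight drop in NREM delta power
#'
#' Percentage drop from the NREM delta power in an early-night window
#' (default ZT 23.5-1.5) to the last hour of sleep at the end of the series
#' (the pre-endpoint hour).
#'
#' @param series A `delta_power_series` from [delta_power_homeostasis()].
#' @param early_window_zt Early comparison window (ZT hours, may wrap).
#' @param final_hour_s Length of the final window (s, default 3600),
#'   anchored at the last NREM epoch.
#' @return list with `drop_pct` (100 x (early - final) / early),
#'   `early_mean`, `final_mean` (normalized %).
#' @export
delta_drop <- function(series, early_window_zt = c(23.5, 1.5),
                       final_hour_s = 3600) {
  early <- series$normalized_pct[zt_window(series$zt, early_window_zt)]
  if (!length(early)) stop("no NREM epochs in the early window")
  t_last <- max(series$time_s)
  fin <- series$normalized_pct[series$time_s > t_last - final_hour_s]
  e <- mean(early); f <- mean(fin)
  list(drop_pct = 100 * (e - f) / e, early_mean = e, final_mean = f)
}
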