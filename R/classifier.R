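#' Threshold set for the real-time decision tree
#'
#' Holds the four adjustable thresholds of the real-time classifier. The
#' delta and theta thresholds are expressed on the linear power-ratio scale
#' (delta/beta and theta/delta); state-history adaptation multiplies them,
#' which corresponds to an additive bias on the log scale shown in feature
#' plots.
#'
#' @param delta_thr delta/beta ratio above which an epoch is NREM-like.
#' @param theta_thr theta/delta ratio above which a non-NREM, atonic epoch
#'   is REM-like.
#' @param move_thr Movement (px/epoch) above which an epoch is wake.
#' @param emg_thr EMG deflection count above which an epoch is wake.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(delta_thr, theta_thr, move_thr, emg_thr = 0) {
  stopifnot(is.finite(delta_thr), is.finite(theta_thr),
            is.finite(move_thr), is.finite(emg_thr))
  structure(list(delta_thr = delta_thr, theta_thr = theta_thr,
                 move_thr = move_thr, emg_thr = emg_thr),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(paste0("<threshold_set> delta/beta > %.3g (log10 %.2f), ",
                     "theta/delta > %.3g (log10 %.2f),\n  movement > %.3g px, ",
                     "EMG > %.3g deflections\n"),
              x$delta_thr, log10(x$delta_thr), x$theta_thr, log10(x$theta_thr),
              x$move_thr, x$emg_thr))
  invisible(x)
}

#' Calibrate classifier thresholds from an unlabelled feature sample
#'
#' Initializes the four thresholds from the feature distributions of a
#' calibration window (default: the first hour of a recording). Each
#' log-ratio is split by deterministic 1-D two-means clustering; the decision
#' threshold is then placed at the ratio a 50/50 mixture of the two cluster
#' mean band-power profiles would produce, so that a transition epoch is
#' labelled by whichever state occupies most of it. Movement and EMG
#' thresholds are midpoints of their two-means cluster means. If a ratio
#' shows no bimodal separation (cluster gap below `min_gap` log10 units or
#' too few epochs in the upper cluster), the corresponding threshold is
#' placed above everything observed so the branch stays inactive.
#'
#' @param features An [epoch_features()] table from the calibration window.
#' @param min_gap Minimum log10 separation between cluster means.
#' @param min_upper Minimum epochs in the upper cluster.
#' @return A [threshold_set()].
#' @export
calibrate_thresholds <- function(features, min_gap = 0.5, min_upper = 3L) {
  f <- features
  ldb <- f$log_delta_beta[is.finite(f$log_delta_beta)]
  if (length(ldb) < 6L) stop("calibration window too short")

  cl_d <- two_means_1d(f$log_delta_beta)
  nrem_like <- is.finite(f$log_delta_beta) & f$log_delta_beta > cl_d$split
  have_nrem <- (cl_d$upper - cl_d$lower) >= min_gap && sum(nrem_like) >= min_upper
  mean_bands <- function(sel) {
    c(delta = mean(f$delta_power[sel], na.rm = TRUE),
      theta = mean(f$theta_power[sel], na.rm = TRUE),
      beta = mean(f$beta_power[sel], na.rm = TRUE))
  }
  if (have_nrem) {
    bn <- mean_bands(nrem_like)
    bo <- mean_bands(!nrem_like)
    delta_thr <- (bn["delta"] + bo["delta"]) / (bn["beta"] + bo["beta"])
  } else {
    delta_thr <- max(f$delta_beta_ratio, na.rm = TRUE) * 4
  }

  rest <- which(!nrem_like & is.finite(f$log_theta_delta))
  theta_thr <- NA_real_
  if (length(rest) >= 6L) {
    cl_t <- two_means_1d(f$log_theta_delta[rest])
    rem_like <- rep(FALSE, nrow(f))
    rem_like[rest] <- f$log_theta_delta[rest] > cl_t$split
    if ((cl_t$upper - cl_t$lower) >= min_gap && sum(rem_like) >= min_upper) {
      br <- mean_bands(rem_like)
      bref <- if (have_nrem) mean_bands(nrem_like) else mean_bands(!rem_like)
      theta_thr <- (br["theta"] + bref["theta"]) / (br["delta"] + bref["delta"])
    }
  }
  if (!is.finite(theta_thr)) {
    theta_thr <- max(f$theta_delta_ratio, na.rm = TRUE) * 2
  }

  mid_or_max <- function(x, ratio_guard = 5) {
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2L) return(max(x, 0) + 1)
    cl <- two_means_1d(x)
    if (cl$upper < ratio_guard * (cl$lower + 1)) return(max(x) * 1.5 + 1)
    (cl$upper + cl$lower) / 2
  }
  move_thr <- mid_or_max(f$movement_px)
  emg_thr <- mid_or_max(f$emg_deflection_score)
  threshold_set(unname(delta_thr), unname(theta_thr), move_thr, emg_thr)
}

#' Adapt thresholds from recent state history
#'
#' Applies a multiplicative persistence bias to the base thresholds given
#' the most recent classified state: after NREM the delta threshold is
#' lowered (NREM is likelier after NREM), after REM the theta threshold is
#' lowered, and after wake both spectral thresholds are raised. Multipliers
#' are clamped to `clamp`.
#'
#' @param base Base [threshold_set()].
#' @param history Character vector of recent labels (most recent last); may
#'   be empty, in which case `base` is returned unchanged.
#' @param persist Multiplier applied for state persistence (default 0.8).
#' @param exit Multiplier applied to spectral thresholds after wake
#'   (default 1.2).
#' @param clamp Allowed multiplier range.
#' @return A [threshold_set()].
#' @export
adapt_thresholds <- function(base, history, persist = 0.8, exit = 1.2,
                             clamp = c(0.5, 2)) {
  if (length(history) == 0L || is.na(history[length(history)])) return(base)
  cl <- function(m) min(max(m, clamp[1]), clamp[2])
  prev <- history[length(history)]
  thr <- base
  if (prev == "NREM") {
    thr$delta_thr <- base$delta_thr * cl(persist)
  } else if (prev == "REM") {
    thr$theta_thr <- base$theta_thr * cl(persist)
  } else {                               # any wake state
    thr$delta_thr <- base$delta_thr * cl(exit)
    thr$theta_thr <- base$theta_thr * cl(exit)
  }
  thr
}

#' Classify one epoch with the decision tree
#'
#' Decision order: movement or EMG above threshold is wake; otherwise a
#' delta/beta ratio above the delta threshold is NREM; otherwise a
#' theta/delta ratio above the theta threshold with EMG at or below the EMG
#' threshold is REM; anything else (including missing spectral features) is
#' wake, the safe fallback. Ties (both ratios above threshold) go to NREM
#' because delta is checked first.
#'
#' @param features One-row data.frame (or list) with `delta_beta_ratio`,
#'   `theta_delta_ratio`, `movement_px`, `emg_deflection_score`.
#' @param thresholds A [threshold_set()] (already adapted if desired).
#' @return One of "WAKE", "NREM", "REM".
#' @export
classify_epoch <- function(features, thresholds) {
  mov <- features$movement_px
  emg <- features$emg_deflection_score
  db <- features$delta_beta_ratio
  td <- features$theta_delta_ratio
  if ((!is.na(mov) && mov > thresholds$move_thr) ||
      (!is.na(emg) && emg > thresholds$emg_thr)) return("WAKE")
  if (!is.na(db) && db > thresholds$delta_thr) return("NREM")
  if (!is.na(td) && td > thresholds$theta_thr &&
      (is.na(emg) || emg <= thresholds$emg_thr)) return("REM")
  "WAKE"
}

#' Run the real-time sleep/wake classifier over a recording
#'
#' Emulates the online acquisition loop: the recording is consumed in
#' 4-min chunks of 10-s epochs. Spectral and movement features of an epoch
#' use only that epoch's samples; the EMG deflection score uses an
#' expanding-window SD estimate (data seen so far), since a real-time system
#' cannot see the future. Thresholds are calibrated once from the first
#' `calibrate_h` hours ([calibrate_thresholds()]); epochs inside the
#' calibration window are labelled when it completes (bootstrap phase), and
#' from there on each epoch is classified causally with history-adapted
#' thresholds. Epochs containing non-finite EEG are labelled `NA` (missing).
#'
#' @param rec A `psg_recording` (or list with `eeg`, `emg`, `movement`,
#'   `fs`, `movement_fs`).
#' @param epoch_len_s Epoch width (s, default 10).
#' @param chunk_s Acquisition cycle length (s, default 240).
#' @param calibrate_h Calibration window (hours, default 1).
#' @param thresholds Optional fixed [threshold_set()]; skips calibration.
#' @param bands,z_threshold Passed to feature extraction.
#' @param adapt Adaptation settings, list(persist, exit, clamp); NULL
#'   disables adaptation.
#' @param keep_features Attach the feature table as an attribute.
#' @return A [hypnogram()] (10-s epochs, provenance "realtime") with
#'   attributes `thresholds` (the calibrated base set) and optionally
#'   `features`.
#' @export
run_realtime <- function(rec, epoch_len_s = 10, chunk_s = 240,
                         calibrate_h = 1, thresholds = NULL,
                         bands = band_definitions(), z_threshold = 3.5,
                         adapt = list(persist = 0.8, exit = 1.2,
                                      clamp = c(0.5, 2)),
                         keep_features = TRUE) {
  fs <- rec$fs
  n_epoch <- as.integer(round(fs * epoch_len_s))
  n_ep <- length(rec$eeg) %/% n_epoch
  if (n_ep * epoch_len_s < chunk_s) stop("recording shorter than one chunk")
  ep_per_chunk <- max(1L, as.integer(chunk_s / epoch_len_s))

  # spectral + movement features are epoch-local, so computed in one pass
  feats <- epoch_features(rec$eeg, emg = NULL, movement = rec$movement,
                          fs = fs, movement_fs = rec$movement_fs %||% 1,
                          epoch_len_s = epoch_len_s, bands = bands, lags = 0)
  n_ep <- nrow(feats)

  # expanding-window EMG normalization, chunk by chunk (causal); running
  # moments avoid rescanning the past at every cycle
  emg_score <- rep(NA_integer_, n_ep)
  if (!is.null(rec$emg)) {
    emg <- rec$emg
    cs1 <- cumsum(emg); cs2 <- cumsum(emg^2)
    chunk_starts <- seq(1L, n_ep, by = ep_per_chunk)
    for (cs in chunk_starts) {
      ce <- min(cs + ep_per_chunk - 1L, n_ep)
      ns <- ce * n_epoch
      m <- cs1[ns] / ns
      s <- sqrt(max(0, (cs2[ns] - ns * m^2) / (ns - 1)))
      sc <- emg_deflections(emg[((cs - 1L) * n_epoch + 1L):(ce * n_epoch)],
                            fs, epoch_len_s, z_threshold,
                            sd_value = s, center = m)
      emg_score[cs:ce] <- sc
    }
  }
  feats$emg_deflection_score <- emg_score

  if (is.null(thresholds)) {
    n_cal <- min(n_ep, max(6L, as.integer(calibrate_h * 3600 / epoch_len_s)))
    thresholds <- calibrate_thresholds(feats[seq_len(n_cal), , drop = FALSE])
  }

  missing_ep <- !is.finite(feats$delta_beta_ratio) &
    !is.finite(feats$theta_delta_ratio)
  fvec <- list(db = feats$delta_beta_ratio, td = feats$theta_delta_ratio,
               mov = feats$movement_px, emg = feats$emg_deflection_score)
  labels <- rep(NA_character_, n_ep)
  hist_lab <- character(0)
  for (k in seq_len(n_ep)) {
    if (missing_ep[k]) next
    thr <- if (is.null(adapt)) thresholds else {
      adapt_thresholds(thresholds, hist_lab, adapt$persist, adapt$exit,
                       adapt$clamp)
    }
    labels[k] <- classify_epoch(list(delta_beta_ratio = fvec$db[k],
                                     theta_delta_ratio = fvec$td[k],
                                     movement_px = fvec$mov[k],
                                     emg_deflection_score = fvec$emg[k]), thr)
    hist_lab <- labels[k]
  }
  h <- hypnogram(labels, epoch_len_s = epoch_len_s,
                 states = c("WAKE", "NREM", "REM"), provenance = "realtime",
                 start_zt = rec$start_zt %||% 0)
  attr(h, "thresholds") <- thresholds
  if (keep_features) attr(h, "features") <- feats
  h
}
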