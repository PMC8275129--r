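#' EEG frequency band definitions
#'
#' Default bands: delta 0.5-4 Hz, theta 5-8 Hz, beta 20-35 Hz, gamma
#' 35-80 Hz. Band edges are treated as `[low, high)` when summing
#' periodogram bins.
#'
#' @param name,low_hz,high_hz Vectors defining custom bands.
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function(name = NULL, low_hz = NULL, high_hz = NULL) {
  if (is.null(name)) return(default_bands())
  df <- data.frame(name = name, low_hz = low_hz, high_hz = high_hz,
                   stringsAsFactors = FALSE)
  if (any(df$low_hz <= 0) || any(df$high_hz <= df$low_hz)) {
    stop("bands need 0 < low_hz < high_hz")
  }
  df
}

#' Per-epoch EEG band powers
#'
#' Splits a trace into fixed-width epochs (trailing partial epoch dropped)
#' and estimates power in each frequency band. The default estimator is
#' Welch's method within each epoch (2-s Hann segments, 50% overlap), which
#' reduces variance relative to a single periodogram without changing band
#' totals materially; `method = "periodogram"` uses one FFT over the whole
#' epoch. Powers are scaled so that the sum over a partition of the spectrum
#' approximates the signal variance (Parseval).
#'
#' @param x Numeric trace (e.g. EEG, microvolts).
#' @param fs Sampling rate (Hz).
#' @param epoch_len_s Epoch length in seconds (default 10).
#' @param bands Band table from [band_definitions()].
#' @param method "welch" or "periodogram".
#' @param seg_len_s Welch segment length (seconds).
#' @return Matrix (epochs x bands) of band powers; attribute `total_power`
#'   holds the full-spectrum power per epoch.
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 2 * seq(0, 10, by = 1 / fs))  # 2 Hz tone: delta band
#' p <- compute_band_powers(x, fs, epoch_len_s = 10)
#' p[, "delta"] / sum(p[1, ])
#' @export
compute_band_powers <- function(x, fs, epoch_len_s = 10,
                                bands = band_definitions(),
                                method = c("welch", "periodogram"),
                                seg_len_s = 2) {
  method <- match.arg(method)
  if (any(bands$high_hz > fs / 2 + 1e-9)) {
    stop("band upper edge exceeds Nyquist frequency (fs/2)")
  }
  n_epoch <- as.integer(round(fs * epoch_len_s))
  if (length(x) < n_epoch) stop("signal shorter than one epoch")
  n_ep <- length(x) %/% n_epoch

  if (method == "periodogram") {
    seg <- n_epoch; step <- n_epoch; w <- rep(1, seg)
  } else {
    seg <- as.integer(round(fs * seg_len_s))
    if (seg > n_epoch) { seg <- n_epoch }
    step <- max(1L, seg %/% 2L)
    w <- hann_window(seg)
  }
  n_seg <- (n_epoch - seg) %/% step + 1L
  freqs <- (seq_len(seg %/% 2L + 1L) - 1L) * fs / seg
  scale <- 2 / (seg * sum(w^2) / seg)   # one-sided, window-compensated
  band_idx <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands$low_hz[b] & freqs < bands$high_hz[b])
  })
  keep <- seq_len(seg %/% 2L + 1L)

  out <- matrix(0, n_ep, nrow(bands),
                dimnames = list(NULL, bands$name))
  total <- numeric(n_ep)
  block <- max(1L, 512L %/% max(1L, n_seg))
  seg_off <- (seq_len(n_seg) - 1L) * step
  for (b0 in seq(1L, n_ep, by = block)) {
    eps <- b0:min(n_ep, b0 + block - 1L)
    starts <- rep((eps - 1L) * n_epoch, each = n_seg) +
      rep(seg_off, length(eps))
    idx <- outer(seq_len(seg), starts, `+`)
    m <- matrix(x[idx], nrow = seg)
    m <- (m - rep(colMeans(m), each = seg)) * w
    X <- stats::mvfft(m)[keep, , drop = FALSE]
    pw <- (Mod(X)^2) * scale / seg
    pw[1L, ] <- pw[1L, ] / 2                       # DC not doubled
    if (seg %% 2L == 0L) pw[nrow(pw), ] <- pw[nrow(pw), ] / 2
    grp <- rep(seq_along(eps), each = n_seg)
    for (b in seq_along(band_idx)) {
      bp <- colSums(pw[band_idx[[b]], , drop = FALSE])
      out[eps, b] <- tapply(bp, grp, mean)
    }
    total[eps] <- tapply(colSums(pw), grp, mean)
  }
  attr(out, "total_power") <- total
  attr(out, "epoch_len_s") <- epoch_len_s
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Band-power ratios used for state classification
#'
#' Computes the delta/beta and theta/delta power ratios per epoch. A zero
#' denominator yields `NA` (flagged undefined), never an error.
#'
#' @param band_powers Matrix from [compute_band_powers()] with at least
#'   `delta`, `theta` and `beta` columns.
#' @return data.frame with `delta_beta_ratio` and `theta_delta_ratio`.
#' @export
compute_ratios <- function(band_powers) {
  stopifnot(all(c("delta", "theta", "beta") %in% colnames(band_powers)))
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  data.frame(
    delta_beta_ratio = safe_div(band_powers[, "delta"], band_powers[, "beta"]),
    theta_delta_ratio = safe_div(band_powers[, "theta"], band_powers[, "delta"]))
}

#' Per-epoch EMG deflection score
#'
#' Normalizes the EMG to standard-deviation units and counts distinct
#' large deflections per epoch: an excursion begins when `|z|` crosses
#' `z_threshold` (3-4 SD; default 3.5) and is merged with any further
#' suprathreshold samples until the signal re-crosses `exit_z` (1 SD).
#' Each excursion is assigned to the epoch containing its first
#' suprathreshold sample.
#'
#' @param emg Numeric EMG trace.
#' @param fs Sampling rate (Hz).
#' @param epoch_len_s Epoch length (seconds).
#' @param z_threshold Deflection threshold in SD units.
#' @param exit_z Excursion termination level in SD units.
#' @param sd_value Optional externally supplied SD (e.g. an expanding-window
#'   estimate in real-time mode); defaults to the whole-trace SD.
#' @param center Optional externally supplied mean paired with `sd_value`.
#' @return Integer vector of per-epoch deflection counts. A constant trace
#'   (zero SD) yields all-zero scores with attribute `zero_sd = TRUE`.
#' @export
emg_deflections <- function(emg, fs, epoch_len_s = 10, z_threshold = 3.5,
                            exit_z = 1, sd_value = NULL, center = NULL) {
  n_epoch <- as.integer(round(fs * epoch_len_s))
  n_ep <- length(emg) %/% n_epoch
  if (n_ep < 1L) stop("EMG shorter than one epoch")
  emg <- emg[seq_len(n_ep * n_epoch)]
  s <- sd_value %||% stats::sd(emg)
  scores <- integer(n_ep)
  if (!is.finite(s) || s == 0) {
    attr(scores, "zero_sd") <- TRUE
    return(scores)
  }
  z <- abs((emg - (center %||% mean(emg))) / s)
  supra <- which(z >= z_threshold)
  if (length(supra)) {
    below <- cumsum(z < exit_z)           # same count <=> no 1-SD re-cross
    starts <- supra[!duplicated(below[supra])]
    ep <- (starts - 1L) %/% n_epoch + 1L
    tab <- tabulate(ep, nbins = n_ep)
    scores <- as.integer(tab)
  }
  scores
}

#' Per-epoch movement
#'
#' Sums per-frame pixel-movement counts within epochs. Frames flagged `NA`
#' (missing video) mark the whole epoch as missing rather than zero. For
#' log-axis display, [movement_display_values()] maps zeros to the smallest
#' observed positive value.
#'
#' @param movement Numeric vector of per-frame changed-pixel counts.
#' @param frame_rate_hz Frames per second (default 1).
#' @param epoch_len_s Epoch length (seconds).
#' @return Numeric vector of per-epoch summed movement (NA where frames are
#'   missing).
#' @export
movement_per_epoch <- function(movement, frame_rate_hz = 1, epoch_len_s = 10) {
  per_epoch <- as.integer(round(frame_rate_hz * epoch_len_s))
  n_ep <- length(movement) %/% per_epoch
  if (n_ep < 1L) stop("movement series shorter than one epoch")
  m <- matrix(movement[seq_len(n_ep * per_epoch)], nrow = per_epoch)
  out <- colSums(m)                       # NA frames propagate to the epoch
  as.numeric(out)
}

#' @rdname movement_per_epoch
#' @param x Per-epoch movement values.
#' @export
movement_display_values <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (!length(pos)) return(x)
  ifelse(is.finite(x) & x == 0, min(pos), x)
}

#' Naive frame-difference movement fallback
#'
#' Computes a pixel-movement series from a stack of grayscale frames as the
#' count of pixels whose absolute difference from the previous frame exceeds
#' `diff_threshold`. A stand-in for dedicated video blob tracking.
#'
#' @param frames 3-D array (rows x cols x frames) of grayscale values.
#' @param diff_threshold Absolute intensity change counting as movement.
#' @return Numeric vector of length `dim(frames)[3]` (first frame 0).
#' @export
frame_difference_movement <- function(frames, diff_threshold = 10) {
  stopifnot(length(dim(frames)) == 3L)
  nf <- dim(frames)[3]
  out <- numeric(nf)
  for (i in seq_len(nf - 1L) + 1L) {
    out[i] <- sum(abs(frames[, , i] - frames[, , i - 1L]) > diff_threshold)
  }
  out
}

#' Assemble the per-epoch classifier feature table
#'
#' Combines spectral ratios (and their log10 transforms), band proportions,
#' EMG deflection scores, movement, and the epoch min/max EEG into one row
#' per epoch, with lagged copies of each feature up to `lags` epochs back
#' (lags at the start of the recording repeat the first value).
#'
#' @param eeg,emg Numeric traces (microvolts).
#' @param movement Per-frame movement counts (or NULL).
#' @param fs EEG/EMG sampling rate (Hz).
#' @param movement_fs Movement frame rate (Hz).
#' @param epoch_len_s Epoch length (seconds, default 10).
#' @param bands Band table ([band_definitions()]).
#' @param z_threshold EMG deflection threshold (SD units).
#' @param emg_sd Optional fixed EMG SD (see [emg_deflections()]).
#' @param lags Number of lagged copies (default 3).
#' @return A data.frame of class `epoch_features`, one row per complete
#'   epoch.
#' @export
epoch_features <- function(eeg, emg = NULL, movement = NULL, fs,
                           movement_fs = 1, epoch_len_s = 10,
                           bands = band_definitions(), z_threshold = 3.5,
                           emg_sd = NULL, lags = 3) {
  bp <- compute_band_powers(eeg, fs, epoch_len_s, bands)
  n_ep <- nrow(bp)
  ratios <- compute_ratios(bp)
  tot <- rowSums(bp)
  props <- bp / ifelse(tot > 0, tot, NA_real_)
  colnames(props) <- paste0(colnames(bp), "_prop")
  powers <- bp
  colnames(powers) <- paste0(colnames(bp), "_power")

  n_epoch <- as.integer(round(fs * epoch_len_s))
  idx <- seq_len(n_ep * n_epoch)
  eeg_m <- matrix(eeg[idx], nrow = n_epoch)
  eeg_min <- apply(eeg_m, 2, min)
  eeg_max <- apply(eeg_m, 2, max)

  emg_score <- if (is.null(emg)) rep(NA_integer_, n_ep) else {
    s <- emg_deflections(emg, fs, epoch_len_s, z_threshold, sd_value = emg_sd)
    length(s) <- n_ep
    s
  }
  mov <- if (is.null(movement)) rep(NA_real_, n_ep) else {
    m <- movement_per_epoch(movement, movement_fs, epoch_len_s)
    length(m) <- n_ep
    m
  }

  df <- data.frame(
    epoch_index = seq_len(n_ep),
    delta_beta_ratio = ratios$delta_beta_ratio,
    theta_delta_ratio = ratios$theta_delta_ratio,
    log_delta_beta = log10(ratios$delta_beta_ratio),
    log_theta_delta = log10(ratios$theta_delta_ratio),
    props,
    powers,
    emg_deflection_score = emg_score,
    movement_px = mov,
    eeg_min = eeg_min,
    eeg_max = eeg_max)

  lag_cols <- setdiff(names(df), "epoch_index")
  if (lags > 0L) {
    for (k in seq_len(lags)) {
      shifted <- df[pmax(seq_len(n_ep) - k, 1L), lag_cols, drop = FALSE]
      names(shifted) <- paste0(lag_cols, "_lag", k)
      df <- cbind(df, shifted)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("epoch_features", "data.frame")
  attr(df, "epoch_len_s") <- epoch_len_s
  df
}
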