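#' Detect mEPSC candidates by sliding-template matching
#'
#' Slides a canonical event template along the trace; at every offset the
#' optimal scale and offset minimizing the squared error are computed in
#' closed form, and the detection criterion is the fitted scale divided by
#' the residual RMS inflated by a size-bias term,
#' `DC = scale / (sqrt(SSE/N) * (1 + size_bias * scale))`,
#' which discounts larger events for their larger absolute fit error.
#' Local maxima of the criterion above `threshold` become candidates;
#' peaks closer than half the template length are merged (largest
#' criterion wins). The trace and the template are first low-pass filtered
#' (`lowpass_hz`), which leaves the fitted amplitude unbiased — filtering
#' is linear, so a filtered event is the true amplitude times the filtered
#' kernel.
#'
#' @param trace Current trace (pA; events negative-going).
#' @param fs Sampling rate (Hz).
#' @param template A [mini_template()] (defaults to rise 0.5 ms, decay
#'   3 ms, 20 ms length).
#' @param threshold Detection-criterion cutoff (default 3.5).
#' @param size_bias Large-event error coefficient (default 0.05 / pA).
#' @param lowpass_hz Pre-detection low-pass corner (Hz); NULL to skip.
#' @return data.frame of candidates: `time_s` (event onset),
#'   `amplitude_pa` (fitted scale), `detection_score`, `flag` ("auto").
#' @examples
#' r <- synthesize_mepsc_trace(5, sim_params(), seed = 7)
#' cand <- detect_candidates(r$trace, r$fs)
#' @export
detect_candidates <- function(trace, fs, template = NULL, threshold = 3.5,
                              size_bias = 0.05, lowpass_hz = 1000) {
  if (all(!is.finite(trace))) stop("trace contains no finite samples")
  template <- template %||% mini_template(fs = fs)
  tpl <- template$kernel
  N <- length(tpl)
  if (N >= length(trace)) stop("template longer than trace")

  x <- trace
  if (!is.null(lowpass_hz)) {
    bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
    tpl <- signal::filtfilt(bf, c(tpl, numeric(N)))[seq_len(N)]
  }
  St <- sum(tpl); St2 <- sum(tpl^2)
  denom <- St2 - St^2 / N
  n_off <- length(x) - N + 1L
  conv <- stats::filter(x, rev(tpl), method = "convolution", sides = 1)
  Std <- as.numeric(conv)[N:length(x)]
  Sd <- rolling_sum(x, N)[N:length(x)]
  Sd2 <- rolling_sum(x^2, N)[N:length(x)]
  s <- (Std - St * Sd / N) / denom
  c0 <- (Sd - s * St) / N
  sse <- Sd2 + s^2 * St2 + N * c0^2 - 2 * s * Std - 2 * c0 * Sd +
    2 * s * c0 * St
  sse[sse < 0] <- 0
  dc <- s / (sqrt(sse / N) * (1 + size_bias * pmax(s, 0)))
  dc[!is.finite(dc)] <- -Inf

  peak <- which(dc > threshold &
                  dc >= c(-Inf, dc[-n_off]) & dc > c(dc[-1L], -Inf))
  if (!length(peak)) {
    return(data.frame(time_s = numeric(0), amplitude_pa = numeric(0),
                      detection_score = numeric(0), flag = character(0)))
  }
  # refractory merging: peaks closer than half the template keep the best
  refr <- N %/% 2L
  ord <- peak[order(-dc[peak])]
  keep <- logical(length(x))
  taken <- rep(FALSE, length(ord))
  sel <- integer(0)
  occupied <- integer(0)
  for (pk in ord) {
    if (!length(occupied) || all(abs(occupied - pk) >= refr)) {
      sel <- c(sel, pk)
      occupied <- c(occupied, pk)
    }
  }
  sel <- sort(sel)
  data.frame(time_s = (sel - 1L) / fs, amplitude_pa = s[sel],
             detection_score = dc[sel], flag = "auto",
             stringsAsFactors = FALSE)
}

#' Validate detected events against mEPSC hallmark criteria
#'
#' Re-measures each candidate on the band-limited trace and applies the
#' standard inclusion filters: amplitude must exceed `amp_min_pa` (5 pA),
#' the 20-80% rise time must be under `rise_max_ms` (3 ms), the event must
#' not be saturated (consecutive samples pinned at the digitizer rails),
#' and the decay must be fit by a single exponential. Amplitude is the
#' least-squares template scale re-fit at the candidate offset (baseline
#' handled by the fitted offset term; the mean of the 2 ms before onset is
#' reported as `baseline_pa`). Exclusion reasons are recorded, never
#' silently dropped.
#'
#' @param candidates data.frame from [detect_candidates()] (or manual
#'   review rows with at least `time_s`; flag "manually_added").
#' @param trace,fs The current trace and sampling rate.
#' @param template The [mini_template()] used for re-fitting.
#' @param amp_min_pa,rise_max_ms Inclusion cutoffs (exclusive; events with
#'   amplitude <= 5 pA or rise >= 3 ms are excluded).
#' @param rails Optional digitizer rails `c(lo, hi)` (pA) for the
#'   saturation check.
#' @param lowpass_hz Measurement band limit (Hz).
#' @param baseline_ms Pre-onset baseline window (ms).
#' @return data.frame of class `mini_events`: per event `time_s`,
#'   `amplitude_pa`, `rise_ms`, `decay_ms`, `baseline_pa`,
#'   `detection_score`, `flag`, `included`, `reason`.
#' @export
validate_events <- function(candidates, trace, fs, template = NULL,
                            amp_min_pa = 5, rise_max_ms = 3, rails = NULL,
                            lowpass_hz = 1000, baseline_ms = 2) {
  template <- template %||% mini_template(fs = fs)
  x <- trace
  tpl <- template$kernel
  N <- length(tpl)
  if (!is.null(lowpass_hz)) {
    bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
    tpl <- signal::filtfilt(bf, c(tpl, numeric(N)))[seq_len(N)]
  }
  nb <- as.integer(round(baseline_ms / 1000 * fs))
  n <- length(x)
  out <- candidates[order(candidates$time_s), , drop = FALSE]
  m <- nrow(out)
  amp <- rise <- decay <- basev <- rep(NA_real_, m)
  reason <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    s0 <- as.integer(round(out$time_s[i] * fs))
    ii <- (s0 + 1L):min(s0 + N, n)
    seg <- x[ii]
    tt <- tpl[seq_along(seg)]
    # least-squares re-fit of scale + offset at this position
    fit <- stats::lm.fit(cbind(1, tt), seg)
    amp[i] <- fit$coefficients[2L]
    basev[i] <- mean(x[max(1L, s0 - nb + 1L):max(1L, s0)])
    if (!is.null(rails) && has_saturation(trace, ii, rails)) {
      reason[i] <- "saturated"
      next
    }
    pk <- which.min(seg)
    mag <- basev[i] - seg            # positive-going deflection magnitude
    r <- rise_20_80(mag[seq_len(pk)], fs)
    rise[i] <- r
    decay[i] <- fit_decay_tau(seg[pk:length(seg)] - basev[i], fs)
    # kinetic check first: the template-fit amplitude is only meaningful
    # for template-conforming events
    if (!is.finite(rise[i]) || rise[i] >= rise_max_ms) {
      reason[i] <- "rise_time"
    } else if (!is.finite(amp[i]) || amp[i] <= amp_min_pa) {
      reason[i] <- "amplitude"
    } else if (!is.finite(decay[i])) {
      reason[i] <- "decay_fit"
    }
  }
  out$amplitude_pa <- amp
  out$rise_ms <- rise
  out$decay_ms <- decay
  out$baseline_pa <- basev
  if (is.null(out$detection_score)) out$detection_score <- NA_real_
  if (is.null(out$flag)) out$flag <- "manually_added"
  out$included <- is.na(reason)
  out$reason <- reason
  class(out) <- c("mini_events", "data.frame")
  out
}

has_saturation <- function(trace, ii, rails) {
  at_rail <- trace[ii] <= rails[1] | trace[ii] >= rails[2]
  any(at_rail & c(at_rail[-1L], FALSE))      # two consecutive rail samples
}

rise_20_80 <- function(mag, fs) {
  pk <- max(mag)
  if (pk <= 0 || length(mag) < 3L) return(NA_real_)
  i20 <- which(mag >= 0.2 * pk)[1L]
  i80 <- which(mag >= 0.8 * pk)[1L]
  interp_cross <- function(i, level) {
    if (i <= 1L) return(i)
    i - 1L + (level - mag[i - 1L]) / (mag[i] - mag[i - 1L])
  }
  (interp_cross(i80, 0.8 * pk) - interp_cross(i20, 0.2 * pk)) / fs * 1000
}

# Single-exponential decay fit (amplitude analytic, tau by 1-D optimization).
fit_decay_tau <- function(seg, fs, max_tau_ms = 50) {
  if (length(seg) < 5L || seg[1L] >= 0) return(NA_real_)
  t_ms <- (seq_along(seg) - 1L) / fs * 1000
  sse_for <- function(tau) {
    b <- exp(-t_ms / tau)
    a <- sum(b * seg) / sum(b^2)
    sum((seg - a * b)^2)
  }
  opt <- stats::optimize(sse_for, c(0.05, max_tau_ms))
  tau <- opt$minimum
  if (tau >= max_tau_ms * 0.99) return(NA_real_)
  tau
}

#' Per-cell mEPSC summary
#'
#' Aggregates included events into the per-cell quantities used for group
#' comparisons: mean amplitude, frequency (events per analyzed second),
#' inter-event intervals, and a peak-aligned (optionally peak-scaled) mean
#' waveform. Cells with fewer than `min_events` included events are
#' flagged and should be excluded from group statistics.
#'
#' @param events A `mini_events` table from [validate_events()].
#' @param duration_s Artifact-free analyzed trace time (s).
#' @param trace,fs Optional trace for the mean waveform.
#' @param min_events Minimum included events (default 10).
#' @param peak_scaled Scale each event to its peak before averaging.
#' @param window_ms Waveform window around the peak (pre, post).
#' @return list of class `cell_summary`: `n_events`, `mean_amplitude_pa`,
#'   `frequency_hz`, `ieis_s`, `mean_rise_ms`, `mean_decay_ms`,
#'   `mean_waveform`, `flagged`.
#' @export
summarize_cell <- function(events, duration_s, trace = NULL, fs = NULL,
                           min_events = 10, peak_scaled = TRUE,
                           window_ms = c(5, 15)) {
  inc <- events[which(events$included), , drop = FALSE]
  n <- nrow(inc)
  wf <- NULL
  if (!is.null(trace) && !is.null(fs) && n > 0L) {
    pre <- as.integer(round(window_ms[1] / 1000 * fs))
    post <- as.integer(round(window_ms[2] / 1000 * fs))
    segs <- lapply(inc$time_s, function(t0) {
      s0 <- as.integer(round(t0 * fs))
      ii <- (s0 - pre + 1L):(s0 + post)
      if (ii[1L] < 1L || ii[length(ii)] > length(trace)) return(NULL)
      seg <- trace[ii] - mean(trace[ii[seq_len(max(1L, pre %/% 2L))]])
      if (peak_scaled) seg / max(1e-12, -min(seg)) else seg
    })
    segs <- segs[!vapply(segs, is.null, logical(1))]
    if (length(segs)) wf <- Reduce(`+`, segs) / length(segs)
  }
  structure(list(
    n_events = n,
    mean_amplitude_pa = if (n) mean(inc$amplitude_pa) else NA_real_,
    frequency_hz = n / duration_s,
    ieis_s = if (n > 1L) diff(inc$time_s) else numeric(0),
    mean_rise_ms = if (n) mean(inc$rise_ms, na.rm = TRUE) else NA_real_,
    mean_decay_ms = if (n) mean(inc$decay_ms, na.rm = TRUE) else NA_real_,
    amplitudes_pa = inc$amplitude_pa,
    mean_waveform = wf,
    flagged = n < min_events), class = "cell_summary")
}

#' Cell record with recording-quality inclusion rule
#'
#' @param id Cell identifier.
#' @param condition Experimental condition (e.g. "sleep_dense",
#'   "light_wake_dense", "dark_wake_dense").
#' @param summary A [summarize_cell()] result.
#' @param rs_mohm Series resistance (MOhm); cells above `rs_max` excluded.
#' @param vm_mv Resting potential (mV); cells above `vm_max` excluded.
#' @param rs_max,vm_max Inclusion cutoffs (25 MOhm, -50 mV).
#' @return list of class `cell_record` with an `included` flag and reason.
#' @export
cell_record <- function(id, condition, summary, rs_mohm = NA, vm_mv = NA,
                        rs_max = 25, vm_max = -50) {
  reason <- NULL
  if (is.finite(rs_mohm) && rs_mohm > rs_max) reason <- c(reason, "Rs")
  if (is.finite(vm_mv) && vm_mv > vm_max) reason <- c(reason, "Vm")
  if (isTRUE(summary$flagged)) reason <- c(reason, "too_few_events")
  structure(list(id = id, condition = condition, summary = summary,
                 rs_mohm = rs_mohm, vm_mv = vm_mv,
                 included = is.null(reason),
                 reason = paste(reason, collapse = "+")),
            class = "cell_record")
}

#' Compare mEPSC measures across behavioral-history conditions
#'
#' Cell means are compared with a Kruskal-Wallis test. For distribution
#' comparisons, the same number of events (the minimum per-cell count) is
#' randomly subsampled from every neuron (seeded), pooled by condition, and
#' condition pairs are compared with two-sample Kolmogorov-Smirnov tests
#' under Bonferroni correction.
#'
#' @param cells list of `cell_record`s (excluded cells are dropped).
#' @param measure "amplitude" (pA), "frequency" (Hz) or "iei" (s).
#' @param seed Seed for the event subsample.
#' @return list of class `condition_comparison`: `kruskal` (htest on cell
#'   means), `cell_means` (data.frame), `ks` (data.frame: pair, D, p_raw,
#'   p_bonferroni), `subsampled` (per-condition pooled values; NULL for
#'   frequency), `n_subsample`.
#' @export
compare_conditions <- function(cells, measure = c("amplitude", "frequency",
                                                  "iei"), seed = 1) {
  measure <- match.arg(measure)
  cells <- Filter(function(cr) cr$included, cells)
  cond <- vapply(cells, function(cr) cr$condition, character(1))
  if (length(unique(cond)) < 2L) stop("need at least 2 conditions")
  if (any(table(cond) < 2L)) stop("every condition needs at least 2 cells")
  cell_value <- vapply(cells, function(cr) switch(measure,
    amplitude = cr$summary$mean_amplitude_pa,
    frequency = cr$summary$frequency_hz,
    iei = mean(cr$summary$ieis_s)), numeric(1))
  kw <- stats::kruskal.test(cell_value, factor(cond))

  per_cell_values <- switch(measure,
    amplitude = lapply(cells, function(cr) cr$summary$amplitudes_pa),
    iei = lapply(cells, function(cr) cr$summary$ieis_s),
    frequency = NULL)
  ks_df <- NULL; pooled <- NULL; n_sub <- NA_integer_
  if (!is.null(per_cell_values)) {
    n_sub <- min(vapply(per_cell_values, length, integer(1)))
    sub <- with_seed(seed, lapply(per_cell_values, function(v) {
      if (length(v) == n_sub) v else sample(v, n_sub)
    }))
    pooled <- lapply(split(sub, cond), function(l) unlist(l, use.names = FALSE))
    prs <- utils::combn(names(pooled), 2, simplify = FALSE)
    ks_df <- do.call(rbind, lapply(prs, function(pr) {
      kt <- suppressWarnings(stats::ks.test(pooled[[pr[1]]], pooled[[pr[2]]]))
      data.frame(pair = paste(pr, collapse = " vs "),
                 D = unname(kt$statistic), p_raw = kt$p.value)
    }))
    ks_df$p_bonferroni <- pmin(1, ks_df$p_raw * nrow(ks_df))
  }
  structure(list(kruskal = kw,
                 cell_means = data.frame(condition = cond, value = cell_value),
                 ks = ks_df, subsampled = pooled, n_subsample = n_sub,
                 measure = measure),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("<condition_comparison> %s: Kruskal-Wallis H = %.3g, p = %.3g\n",
              x$measure, x$kruskal$statistic, x$kruskal$p.value))
  if (!is.null(x$ks)) {
    cat(sprintf("  KS (Bonferroni x%d), %d events/cell subsampled:\n",
                nrow(x$ks), x$n_subsample))
    for (i in seq_len(nrow(x$ks))) {
      cat(sprintf("    %s: D = %.3f, p = %.3g\n", x$ks$pair[i], x$ks$D[i],
                  x$ks$p_bonferroni[i]))
    }
  }
  invisible(x)
}

#' Correlate a cellular measure with a behavioral covariate
#'
#' Ordinary least squares of `y` on `x` (e.g. endpoint mEPSC amplitude on
#' prior wake density or delta-power drop), reporting slope, R-squared and
#' the slope t-test p-value. A constant covariate yields a flagged
#' undefined slope rather than an error.
#'
#' @param x Behavioral covariate per cell/animal.
#' @param y Cellular measure per cell/animal.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `undefined` (TRUE when the covariate has no variance).
#' @export
correlate_behavior <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                p_value = NA_real_, n = length(x), undefined = TRUE))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2L, 4L],
       n = length(x), undefined = FALSE)
}
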