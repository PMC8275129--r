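#' Hypnogram: fixed-width behavioral state labels
#'
#' A hypnogram is an ordered sequence of behavioral-state labels at a fixed
#' epoch width (1 s for reviewed/truth scoring, 10 s for classifier output).
#'
#' @param labels Character vector of state labels.
#' @param epoch_len_s Epoch width in seconds.
#' @param states Allowed state set; defaults to the unique sorted labels
#'   intersected with the canonical sets.
#' @param provenance One of "realtime", "posthoc", "manual", "truth".
#' @param start_zt Zeitgeber time (hours) of the first epoch's start.
#' @return An object of class `hypnogram`.
#' @examples
#' h <- hypnogram(rep(c("WAKE", "NREM"), each = 6), epoch_len_s = 10)
#' state_proportions(h)
#' @export
hypnogram <- function(labels, epoch_len_s = 10,
                      states = NULL, provenance = "truth", start_zt = 0) {
  labels <- as.character(labels)
  if (is.null(states)) {
    states <- if (any(labels %in% c("AW", "QW"))) c("AW", "QW", "NREM", "REM")
              else c("WAKE", "NREM", "REM")
  }
  bad <- setdiff(unique(labels[!is.na(labels)]), states)
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  if (epoch_len_s <= 0) stop("epoch_len_s must be positive")
  structure(list(labels = labels, epoch_len_s = epoch_len_s, states = states,
                 provenance = provenance, start_zt = start_zt),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<hypnogram> %d epochs x %gs = %.2f h (%s), states: %s\n",
              n, x$epoch_len_s, n * x$epoch_len_s / 3600, x$provenance,
              paste(x$states, collapse = "/")))
  tab <- table(factor(x$labels, levels = x$states))
  cat(" ", paste(sprintf("%s %.1f%%", names(tab), 100 * tab / n),
                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$labels)

hypnogram_duration_s <- function(h) length(h$labels) * h$epoch_len_s

#' Resample a hypnogram to a different epoch width by majority vote
#'
#' Each target epoch takes the label occupying the most time within it; ties
#' break toward the label occurring first in the epoch.
#'
#' @param h A [hypnogram()].
#' @param epoch_len_s Target epoch width (seconds).
#' @return A resampled `hypnogram`.
#' @export
resample_hypnogram <- function(h, epoch_len_s) {
  if (epoch_len_s == h$epoch_len_s) return(h)
  dur <- hypnogram_duration_s(h)
  n_out <- floor(dur / epoch_len_s)
  if (n_out < 1L) stop("hypnogram shorter than one target epoch")
  # label at every 1-s (or finer) tick, then vote within target epochs
  tick <- min(h$epoch_len_s, epoch_len_s, 1)
  times <- seq(0, n_out * epoch_len_s - tick, by = tick) + tick / 2
  src <- pmin(length(h$labels), floor(times / h$epoch_len_s) + 1L)
  lab <- h$labels[src]
  grp <- floor(times / epoch_len_s) + 1L
  out <- vapply(split(lab, grp), function(v) {
    tb <- table(v)
    win <- names(tb)[tb == max(tb)]
    if (length(win) > 1L) win <- v[v %in% win][1L]  # first-in-epoch tiebreak
    win
  }, character(1))
  hypnogram(unname(out), epoch_len_s = epoch_len_s, states = h$states,
            provenance = h$provenance, start_zt = h$start_zt)
}

#' Read/write hypnograms as CSV
#'
#' CSV dialect: header `onset_s,duration_s,label`, one row per epoch (or per
#' run of equal labels on write with `collapse = TRUE`), UTF-8, '.' decimal.
#'
#' @param path File path.
#' @param h A [hypnogram()].
#' @param collapse Write one row per maximal run of a single label.
#' @param states,provenance,start_zt Passed to [hypnogram()] on read.
#' @return `read_hypnogram` returns a `hypnogram`; `write_hypnogram`
#'   invisibly returns `path`.
#' @export
write_hypnogram <- function(h, path, collapse = FALSE) {
  if (collapse) {
    r <- rle(h$labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    df <- data.frame(onset_s = starts * h$epoch_len_s,
                     duration_s = r$lengths * h$epoch_len_s,
                     label = r$values)
  } else {
    n <- length(h$labels)
    df <- data.frame(onset_s = (seq_len(n) - 1L) * h$epoch_len_s,
                     duration_s = rep(h$epoch_len_s, n),
                     label = h$labels)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, states = NULL, provenance = "manual",
                           start_zt = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns onset_s, duration_s, label")
  }
  df <- df[order(df$onset_s), , drop = FALSE]
  if (nrow(df) > 1L &&
      any(df$onset_s[-1L] < (df$onset_s + df$duration_s)[-nrow(df)] - 1e-9)) {
    stop("overlapping hypnogram rows")
  }
  widths <- unique(df$duration_s)
  epoch <- if (length(widths) == 1L) widths[1L] else {
    g <- widths[1L]; for (w in widths[-1L]) g <- pgcd(g, w); g
  }
  reps <- as.integer(round(df$duration_s / epoch))
  hypnogram(rep(df$label, reps), epoch_len_s = epoch, states = states,
            provenance = provenance, start_zt = start_zt)
}

pgcd <- function(a, b) {
  while (b > 1e-9) { t <- a %% b; a <- b; b <- t }
  a
}

# Map each epoch of a hypnogram to light/dark given its start ZT.
hypnogram_photoperiod <- function(h, lights_on = 0, lights_off = 12) {
  mid <- h$start_zt + ((seq_along(h$labels) - 0.5) * h$epoch_len_s) / 3600
  ifelse(is_light_zt(mid, lights_on, lights_off), "light", "dark")
}

# State label at arbitrary times (seconds from hypnogram start).
state_at <- function(h, time_s) {
  idx <- floor(time_s / h$epoch_len_s) + 1L
  idx[idx < 1L | idx > length(h$labels)] <- NA_integer_
  h$labels[idx]
}

wake_states <- function(h) intersect(c("WAKE", "AW", "QW"), h$states)
sleep_states <- function(h) intersect(c("NREM", "REM"), h$states)
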