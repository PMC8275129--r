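#' Score agreement between two hypnograms
#'
#' Compares a test hypnogram against a reference over their common span.
#' The test is resampled to the reference epoch width by majority vote.
#' Reports overall percent agreement, per-state agreement (percent of
#' reference epochs of each state matched), the confusion matrix, and —
#' when the span allows it — agreement on sleep- and wake-dense epoch
#' on/off times (percent of time both hypnograms agree on dense-epoch
#' membership).
#'
#' @param test,reference [hypnogram()]s covering the same span (the longer
#'   is truncated; non-overlapping spans are an error).
#' @param dense_args Arguments for [detect_dense_epochs()] used for the
#'   dense on/off comparison (list; set to NULL to skip).
#' @return list of class `hypnogram_agreement`: `overall_pct`,
#'   `per_state_pct`, `confusion`, `dense_pct` (named: sleep, wake),
#'   `n_epochs`.
#' @examples
#' a <- hypnogram(rep(c("WAKE", "NREM"), each = 30), epoch_len_s = 10)
#' score_agreement(a, a)$overall_pct
#' @export
score_agreement <- function(test, reference,
                            dense_args = list(min_dur_h = 4, density = 0.65,
                                              last_hour_density = 0.70)) {
  if (hypnogram_duration_s(test) <= 0 || hypnogram_duration_s(reference) <= 0) {
    stop("empty hypnogram")
  }
  span <- min(hypnogram_duration_s(test), hypnogram_duration_s(reference))
  if (span < max(test$epoch_len_s, reference$epoch_len_s)) {
    stop("hypnograms do not overlap by at least one epoch")
  }
  tr <- resample_hypnogram(test, reference$epoch_len_s)
  n <- min(length(tr$labels), length(reference$labels))
  a <- tr$labels[seq_len(n)]
  b <- reference$labels[seq_len(n)]
  ok <- !is.na(a) & !is.na(b)
  overall <- 100 * mean(a[ok] == b[ok])
  per_state <- vapply(reference$states, function(s) {
    sel <- ok & b == s
    if (!any(sel)) return(NA_real_)
    100 * mean(a[sel] == s)
  }, numeric(1))
  confusion <- table(reference = factor(b[ok], levels = reference$states),
                     test = factor(a[ok], levels = union(tr$states,
                                                         reference$states)))
  dense <- c(sleep = NA_real_, wake = NA_real_)
  if (!is.null(dense_args)) {
    need <- (dense_args$min_dur_h %||% 4) * 3600
    if (n * reference$epoch_len_s >= need) {
      for (s in c("sleep", "wake")) {
        m1 <- do.call(dense_membership, c(list(h = tr, state = s), dense_args))
        m2 <- do.call(dense_membership,
                      c(list(h = reference, state = s), dense_args))
        dense[s] <- 100 * mean(m1[seq_len(n)] == m2[seq_len(n)])
      }
    }
  }
  structure(list(overall_pct = overall, per_state_pct = per_state,
                 confusion = confusion, dense_pct = dense, n_epochs = n),
            class = "hypnogram_agreement")
}

#' @export
print.hypnogram_agreement <- function(x, ...) {
  cat(sprintf("<hypnogram_agreement> overall %.1f%% over %d epochs\n",
              x$overall_pct, x$n_epochs))
  cat("  per state:",
      paste(sprintf("%s %.1f%%", names(x$per_state_pct), x$per_state_pct),
            collapse = ", "), "\n")
  if (any(is.finite(x$dense_pct))) {
    cat("  dense on/off:",
        paste(sprintf("%s %.1f%%", names(x$dense_pct), x$dense_pct),
              collapse = ", "), "\n")
  }
  invisible(x)
}
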