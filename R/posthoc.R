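#' Train the post hoc random-forest state scorer
#'
#' Fits a random forest (200-300 trees; default 256) to labelled epoch
#' features — the band ratios, band powers and proportions, min/max EEG,
#' EMG score, movement, and their lagged copies up to three epochs back —
#' reproducing the semi-automated post hoc scoring stage in which a
#' threshold-classified and reviewed initial segment bootstraps a forest
#' that scores the remainder of the recording.
#'
#' @param features An [epoch_features()] table.
#' @param labels A [hypnogram()] (same epoch width) or character vector of
#'   state labels aligned to `features` rows.
#' @param n_trees Number of trees (default 256; range 200-300 typical).
#' @param seed Integer seed pinning the forest fit.
#' @return Object of class `posthoc_model` wrapping the fitted forest.
#' @export
train_posthoc <- function(features, labels, n_trees = 256, seed = 1) {
  lab <- if (inherits(labels, "hypnogram")) labels$labels else
    as.character(labels)
  n <- min(nrow(features), length(lab))
  x <- posthoc_feature_matrix(features[seq_len(n), , drop = FALSE])
  y <- factor(lab[seq_len(n)])
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- droplevels(y[keep])
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  rf <- with_seed(seed, {
    randomForest::randomForest(x, y, ntree = n_trees, na.action = stats::na.omit)
  })
  structure(list(forest = rf, feature_names = colnames(x),
                 states = levels(y), n_trees = n_trees,
                 version = "posthoc_model/1"),
            class = "posthoc_model")
}

posthoc_feature_matrix <- function(features) {
  drop <- "epoch_index"
  x <- as.data.frame(features)[, setdiff(names(features), drop), drop = FALSE]
  x <- x[vapply(x, is.numeric, logical(1))]
  # the forest cannot take NA/Inf: impute with column medians
  for (j in seq_along(x)) {
    v <- x[[j]]
    v[!is.finite(v)] <- stats::median(v[is.finite(v)])
    x[[j]] <- v
  }
  as.matrix(x)
}

#' @rdname train_posthoc
#' @param model A fitted `posthoc_model`.
#' @param start_zt Zeitgeber start hour for the output hypnogram.
#' @return `predict_posthoc` returns a [hypnogram()] (provenance
#'   "posthoc") with the class-probability matrix in attribute `prob` for
#'   review hooks.
#' @export
predict_posthoc <- function(model, features, start_zt = 0) {
  stopifnot(inherits(model, "posthoc_model"))
  x <- posthoc_feature_matrix(features)
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  prob <- stats::predict(model$forest, x, type = "prob")
  lab <- model$states[max.col(prob, ties.method = "first")]
  h <- hypnogram(lab, epoch_len_s = attr(features, "epoch_len_s") %||% 10,
                 states = if (any(model$states %in% c("AW", "QW")))
                   c("AW", "QW", "NREM", "REM") else c("WAKE", "NREM", "REM"),
                 provenance = "posthoc", start_zt = start_zt)
  attr(h, "prob") <- prob
  h
}

#' Persist / restore a fitted post hoc model
#'
#' Serializes the model with its version tag; `load_posthoc_model` refuses
#' files without a recognized tag.
#'
#' @param model A `posthoc_model`.
#' @param path File path.
#' @export
save_posthoc_model <- function(model, path) {
  stopifnot(inherits(model, "posthoc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_posthoc_model
#' @export
load_posthoc_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "posthoc_model") || !identical(m$version, "posthoc_model/1")) {
    stop("not a recognized posthoc model file")
  }
  m
}

#' Split wake into active and quiet wake
#'
#' Relabels WAKE epochs as active wake (AW) when the animal is moving
#' (movement above `move_thr`) or the EEG is especially desynchronized
#' (gamma proportion above `gamma_cut` with delta proportion below
#' `delta_cut`); remaining WAKE epochs become quiet wake (QW). Sleep labels
#' pass through unchanged.
#'
#' @param h A 3-state [hypnogram()].
#' @param features Matching [epoch_features()] (same epoch width).
#' @param move_thr Movement threshold (px/epoch).
#' @param gamma_cut,delta_cut Band-proportion cutoffs.
#' @return A 4-state [hypnogram()] (AW/QW/NREM/REM).
#' @export
split_wake_substates <- function(h, features, move_thr,
                                 gamma_cut = 0.3, delta_cut = 0.2) {
  n <- min(length(h$labels), nrow(features))
  lab <- h$labels[seq_len(n)]
  mov <- features$movement_px[seq_len(n)]
  gam <- features$gamma_prop[seq_len(n)]
  del <- features$delta_prop[seq_len(n)]
  wake <- !is.na(lab) & lab == "WAKE"
  active <- wake & ((!is.na(mov) & mov > move_thr) |
                      (!is.na(gam) & !is.na(del) &
                         gam > gamma_cut & del < delta_cut))
  lab[active] <- "AW"
  lab[wake & !active] <- "QW"
  hypnogram(lab, epoch_len_s = h$epoch_len_s,
            states = c("AW", "QW", "NREM", "REM"),
            provenance = h$provenance, start_zt = h$start_zt)
}
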