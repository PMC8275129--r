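#' Read and write multichannel recordings
#'
#' CSV is the text interchange format: a `time_s` column plus one column
#' per channel, sampling rate inferred from the time axis. EDF (European
#' Data Format, the standard polysomnography container) is supported
#' natively: 16-bit samples with per-signal physical scaling, so a round
#' trip is exact up to the quantization step
#' `(phys_max - phys_min) / (dig_max - dig_min)`.
#'
#' @param path File path.
#' @param format "csv" or "edf"; default inferred from the extension.
#' @return `read_recording` returns a list of class `recording`:
#'   `channels` (named list of numeric vectors), `fs`, `units` (named
#'   character).
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "edf")) stop("unsupported format: ", format)
  if (format == "csv") read_recording_csv(path) else read_edf(path)
}

#' @rdname read_recording
#' @param rec A `recording` (or list with `channels`, `fs`, `units`).
#' @export
write_recording <- function(rec, path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("csv", "edf")) stop("unsupported format: ", format)
  if (format == "csv") write_recording_csv(rec, path) else write_edf(rec, path)
  invisible(path)
}

read_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!nrow(df)) stop("empty recording file: ", path)
  if (!"time_s" %in% names(df)) stop("recording CSV needs a time_s column")
  dt <- diff(df$time_s)
  if (!length(dt) || any(dt <= 0)) stop("time_s must be strictly increasing")
  fs <- 1 / stats::median(dt)
  ch <- as.list(df[setdiff(names(df), "time_s")])
  if (!length(ch)) stop("recording CSV has no channel columns")
  structure(list(channels = ch, fs = fs,
                 units = stats::setNames(rep(NA_character_, length(ch)),
                                         names(ch))),
            class = "recording")
}

write_recording_csv <- function(rec, path) {
  n <- length(rec$channels[[1L]])
  if (!all(vapply(rec$channels, length, integer(1)) == n)) {
    stop("channel lengths differ")
  }
  df <- data.frame(time_s = (seq_len(n) - 1L) / rec$fs)
  for (nm in names(rec$channels)) df[[nm]] <- rec$channels[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = -width)
}

#' @rdname read_recording
#' @export
write_edf <- function(rec, path) {
  ch <- rec$channels
  ns <- length(ch)
  fs <- rec$fs
  spr <- as.integer(round(fs))               # 1-s data records
  n_rec <- min(vapply(ch, length, integer(1))) %/% spr
  if (n_rec < 1L) stop("recording shorter than one EDF data record")
  units <- rec$units %||% stats::setNames(rep("uV", ns), names(ch))

  pmin_ <- pmax_ <- numeric(ns)
  dig <- matrix(0L, spr * n_rec, ns)
  for (j in seq_len(ns)) {
    x <- ch[[j]][seq_len(spr * n_rec)]
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    pmin_[j] <- r[1]; pmax_[j] <- r[2]
    dig[, j] <- as.integer(round((x - r[1]) / (r[2] - r[1]) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("sleepephys", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1L), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (j in seq_len(ns)) wr(names(ch)[j], 16)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(units[[names(ch)[j]]] %||% "uV", 8)
  for (j in seq_len(ns)) wr(format(pmin_[j], digits = 7), 8)
  for (j in seq_len(ns)) wr(format(pmax_[j], digits = 7), 8)
  for (j in seq_len(ns)) wr(-32768L, 8)
  for (j in seq_len(ns)) wr(32767L, 8)
  for (j in seq_len(ns)) wr("", 80)
  for (j in seq_len(ns)) wr(spr, 8)
  for (j in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      writeBin(dig[((r - 1L) * spr + 1L):(r * spr), j], con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname read_recording
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                       # version
  rd(80); rd(80); rd(8); rd(8)
  as.integer(rd(8))                           # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  ch <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[j], size = 2L, signed = TRUE,
                   endian = "little")
      ch[[j]][((r - 1L) * spr[j] + 1L):(r * spr[j])] <-
        pmin_[j] + (d - dmin[j]) / (dmax[j] - dmin[j]) * (pmax_[j] - pmin_[j])
    }
  }
  names(ch) <- labels
  structure(list(channels = ch, fs = spr[1L] / rec_dur,
                 units = stats::setNames(units, labels)),
            class = "recording")
}

#' EDF quantization step per channel
#'
#' The worst-case round-trip error of an EDF write/read is half this step.
#'
#' @param rec A `recording` about to be written.
#' @return Named numeric vector of physical units per digital count.
#' @export
edf_resolution <- function(rec) {
  vapply(rec$channels, function(x) {
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    (r[2] - r[1]) / 65535
  }, numeric(1))
}
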