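test_that("a pure 2 Hz tone concentrates power in the delta band", {
  fs <- 200
  x <- sin(2 * pi * 2 * (seq_len(10 * fs) - 1) / fs)
  bp <- compute_band_powers(x, fs, epoch_len_s = 10)
  props <- bp[1, ] / sum(bp[1, ])
  expect_gt(props["delta"], 0.99)
  expect_lt(props["theta"], 0.01)
})

test_that("equal-amplitude 2 Hz and 6 Hz tones give equal delta and theta power", {
  fs <- 200
  t <- (seq_len(10 * fs) - 1) / fs
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 6 * t)
  bp <- compute_band_powers(x, fs, epoch_len_s = 10)
  expect_lt(abs(bp[1, "delta"] - bp[1, "theta"]) / bp[1, "delta"], 0.01)
})

test_that("band powers match an independent Welch implementation on noise", {
  fs <- 200
  set.seed(21)
  x <- rnorm(30 * fs)
  bp <- compute_band_powers(x, fs, epoch_len_s = 10)
  for (b in seq_len(nrow(band_definitions()))) {
    bd <- band_definitions()[b, ]
    oracle <- oracle_welch_band(x, fs, 10, bd$low_hz, bd$high_hz)
    expect_equal(unname(bp[, bd$name]), oracle, tolerance = 1e-10)
  }
})

test_that("band powers are nonnegative and additive over disjoint bands", {
  fs <- 200
  set.seed(22)
  x <- rnorm(20 * fs)
  # partition of the analyzable spectrum into contiguous bands
  part <- band_definitions(name = c("a", "b", "c"),
                           low_hz = c(0.5, 10, 50), high_hz = c(10, 50, 100))
  whole <- band_definitions(name = "all", low_hz = 0.5, high_hz = 100)
  bp <- compute_band_powers(x, fs, 10, part)
  bw <- compute_band_powers(x, fs, 10, whole)
  expect_true(all(bp >= 0))
  expect_equal(unname(rowSums(bp)), unname(bw[, "all"]), tolerance = 1e-10)
})

test_that("feature extraction is pure and shift-invariant", {
  fs <- 200
  set.seed(23)
  x <- rnorm(40 * fs)
  f1 <- compute_band_powers(x, fs, 10)
  f2 <- compute_band_powers(x, fs, 10)
  expect_identical(f1, f2)
  pre <- rnorm(20 * fs)                      # two whole epochs prepended
  f3 <- compute_band_powers(c(pre, x), fs, 10)
  expect_equal(unname(f3[3:6, ]), unname(f1[1:4, ]), tolerance = 1e-12)
})

test_that("ratios handle zero denominators as flagged missing values", {
  bp <- cbind(delta = c(4, 1, 0), theta = c(1, 1, 2), beta = c(1, 0, 1),
              gamma = c(1, 1, 1))
  r <- compute_ratios(bp)
  expect_equal(r$delta_beta_ratio[1], 4)
  expect_equal(r$theta_delta_ratio[2], 1)
  expect_true(is.na(r$delta_beta_ratio[2]))  # beta 0
  expect_true(is.na(r$theta_delta_ratio[3])) # delta 0
})

test_that("EMG deflection scores count distinct excursions per epoch", {
  fs <- 200
  # flat EMG with one large pulse in epoch 3
  emg <- numeric(40 * fs)
  emg[(2 * 10 * fs) + 500 + (0:20)] <- 1
  sc <- emg_deflections(emg, fs, 10, z_threshold = 3.5)
  expect_equal(sc, c(0L, 0L, 1L, 0L))
  # constant signal: zero SD flagged, all-zero scores
  sc0 <- emg_deflections(rep(1, 20 * fs), fs, 10)
  expect_equal(as.integer(sc0), c(0L, 0L))
  expect_true(isTRUE(attr(sc0, "zero_sd")))
})

test_that("unimodal Poisson pulses are counted near their rate", {
  # pulses that stay above 1 SD throughout count as exactly one excursion,
  # so the per-epoch score follows the Poisson expectation
  fs <- 200
  set.seed(25)
  n_ep <- 40
  emg <- rnorm(n_ep * 10 * fs) * 0.05
  # short pulses keep the duty cycle low so the whole-trace SD stays well
  # below the pulse amplitude and every pulse crosses 3.5 SD
  n_pulse <- rpois(n_ep * 10, 1)             # rate 1/s
  for (s in rep(seq_along(n_pulse), n_pulse)) {
    i0 <- (s - 1) * fs + sample.int(fs - 10, 1)
    emg[i0 + (0:4)] <- emg[i0 + (0:4)] + 3
  }
  sc <- emg_deflections(emg, fs, 10, z_threshold = 3.5)
  expected <- sum(n_pulse) / n_ep
  se <- sqrt(expected / n_ep)
  expect_lt(abs(mean(sc) - expected), 3 * se + 0.3)
})

test_that("movement per epoch sums frames and flags missing video", {
  expect_equal(movement_per_epoch(rep(0, 30), 1, 10), c(0, 0, 0))
  m <- rep(0, 30); m[12] <- 100
  expect_equal(movement_per_epoch(m, 1, 10), c(0, 100, 0))
  m[25] <- NA
  out <- movement_per_epoch(m, 1, 10)
  expect_true(is.na(out[3]) && !is.na(out[2]))
  expect_equal(movement_display_values(c(0, 5, 2)), c(2, 5, 2))
})

test_that("synthetic states separate in the expected features", {
  b <- fx_psg2h()
  f <- epoch_features(b$rec$eeg, b$rec$emg, b$rec$movement, fs = 200)
  lab <- resample_hypnogram(b$seq, 10)$labels[seq_len(nrow(f))]
  med <- function(v, s) median(v[lab == s], na.rm = TRUE)
  expect_gt(med(f$delta_beta_ratio, "NREM"), med(f$delta_beta_ratio, "WAKE"))
  expect_gt(med(f$theta_delta_ratio, "REM"), med(f$theta_delta_ratio, "NREM"))
  expect_gt(med(f$movement_px, "WAKE"), 10 * max(1, med(f$movement_px, "NREM")))
  # REM shows motor atonia: essentially no EMG deflections
  expect_lt(mean(f$emg_deflection_score[lab == "REM"]), 1)
  # rank separation (AUROC by brute-force rank comparison) > 0.9
  auroc <- function(pos, neg) mean(outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`))
  expect_gt(auroc(f$delta_beta_ratio[lab == "NREM"],
                  f$delta_beta_ratio[lab == "WAKE"]), 0.9)
  expect_gt(auroc(f$theta_delta_ratio[lab == "REM"],
                  f$theta_delta_ratio[lab == "NREM"]), 0.9)
})

test_that("lagged features repeat the first value at the sequence start", {
  fs <- 200
  set.seed(26)
  f <- epoch_features(rnorm(50 * fs), fs = fs, lags = 3)
  expect_equal(f$delta_beta_ratio_lag1[1], f$delta_beta_ratio[1])
  expect_equal(f$delta_beta_ratio_lag3[2], f$delta_beta_ratio[1])
  expect_equal(f$delta_beta_ratio_lag1[3], f$delta_beta_ratio[2])
})

test_that("bands above the Nyquist frequency are rejected", {
  expect_error(compute_band_powers(rnorm(2000), fs = 100, epoch_len_s = 10),
               "Nyquist")
})
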