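test_that("the band-pass response matches the Butterworth magnitude", {
  fs <- 1000
  t <- (seq_len(10 * fs) - 1) / fs
  amp_out <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    y <- fepsp_preprocess(x, fs)
    # steady-state gain away from the edges (ratio cancels the sampling
    # grid's offset from the true sine peaks)
    sec <- (2 * fs):(8 * fs)
    max(abs(y[sec])) / max(abs(x[sec]))
  }
  expect_lt(amp_out(1), 0.10)          # 1 Hz attenuated by >= 90%
  expect_gt(amp_out(100), 0.95)        # 100 Hz passed within 5%
  expect_equal(fepsp_preprocess(numeric(1000), fs), numeric(1000))
  expect_error(fepsp_preprocess(numeric(1000), fs = 800), "twice")
})

test_that("sweep QC rejects noisy baselines and absent troughs", {
  fs <- 1000
  x <- fx_fepsp()
  stim <- x$fe$stim_times_s
  lfp <- fepsp_preprocess(x$fe$lfp, fs)
  # inject a 300 uV noise burst into the last 5 ms before stimulus 3
  bad <- lfp
  i0 <- round(stim[3] * fs)
  bad[x$fe$sink_channel, (i0 - 5):i0] <- c(300, -300, 300, -300, 300, -300)
  ssw <- extract_sweeps(bad, fs, stim, channel = x$fe$sink_channel)
  expect_false(ssw$qc$qc_pass[3])
  expect_equal(ssw$qc$reason[3], "baseline_sd")
  # a sweep with max trough below 30 uV is rejected with reason no_trough
  flat <- matrix(rnorm(3 * 4000, sd = 2), nrow = 3)
  ssw2 <- extract_sweeps(flat, fs, c(1, 2, 3), channel = 2)
  expect_true(all(!ssw2$qc$qc_pass))
  expect_true(all(ssw2$qc$reason == "no_trough"))
  # clean synthetic sweeps (~150 uV troughs) are accepted
  expect_gt(mean(x$ssw$qc$qc_pass), 0.95)
})

test_that("a trough of exactly 30 uV fails the exclusive criterion", {
  fs <- 1000
  n <- 4000
  lfp <- matrix(0, 1, n)
  i0 <- round(2 * fs)
  lfp[1, i0 + 5 + (0:8)] <- -c(10, 20, 30, 30, 30, 30, 20, 10, 5)
  ssw <- extract_sweeps(lfp, fs, 2, channel = 1)
  expect_false(ssw$qc$qc_pass[1])
  lfp[1, i0 + 5 + (0:8)] <- lfp[1, i0 + 5 + (0:8)] * 1.01  # just over 30
  ssw2 <- extract_sweeps(lfp, fs, 2, channel = 1)
  expect_true(ssw2$qc$qc_pass[1])
})

test_that("an ideal linear ramp gives the closed-form 20-80% slope", {
  fs <- 10000
  time_ms <- seq(-100, 80, by = 1000 / fs / 10)
  time_ms <- seq(-100, 80, by = 0.1)
  v <- numeric(length(time_ms))
  ramp <- time_ms > 2 & time_ms <= 6
  v[ramp] <- -100 * (time_ms[ramp] - 2) / 4    # to -100 uV over 4 ms
  after <- time_ms > 6
  v[after] <- -100 * pmax(0, 1 - (time_ms[after] - 6) / 20)
  m <- measure_fepsp(v, time_ms)
  expect_equal(m$trough_amplitude_uv, 100, tolerance = 0.01)
  expect_lt(abs(m$slope_uv_per_ms - 25) / 25, 0.02)
  expect_equal(m$latency_ms, 6, tolerance = 0.11)
})

test_that("measurement is linear in gain with latency unchanged", {
  x <- fx_fepsp()
  i <- which(x$ssw$qc$qc_pass)[1]
  v <- x$ssw$sweeps[i, x$ssw$channel, ]
  m1 <- measure_fepsp(v, x$ssw$time_ms)
  m2 <- measure_fepsp(3 * v, x$ssw$time_ms)
  expect_equal(m2$trough_amplitude_uv, 3 * m1$trough_amplitude_uv,
               tolerance = 1e-9)
  expect_equal(m2$slope_uv_per_ms, 3 * m1$slope_uv_per_ms, tolerance = 1e-9)
  expect_equal(m2$latency_ms, m1$latency_ms)
})

test_that("raising the trough criterion never accepts a rejected sweep", {
  x <- fx_fepsp()
  lfp <- fepsp_preprocess(x$fe$lfp, x$fe$fs)
  loose <- extract_sweeps(lfp, x$fe$fs, x$fe$stim_times_s,
                          channel = x$fe$sink_channel, trough_min_uv = 30)
  strict <- extract_sweeps(lfp, x$fe$fs, x$fe$stim_times_s,
                           channel = x$fe$sink_channel, trough_min_uv = 120)
  expect_true(all(strict$qc$qc_pass <= loose$qc$qc_pass))
})

test_that("CSD localizes the sink and is linear", {
  # second difference of a linear-in-depth profile vanishes
  prof <- matrix(rep(seq_len(6), 50), nrow = 6)
  cm <- csd(prof)
  expect_true(all(abs(cm$csd[2:5, ]) < 1e-12))
  # synthetic dipole: sink at the generator channel
  x <- fx_fepsp()
  ms <- apply(x$ssw$sweeps[x$ssw$qc$qc_pass, , , drop = FALSE], c(2, 3), mean)
  cm2 <- csd(ms, time_ms = x$ssw$time_ms)
  expect_equal(cm2$sink_channel, x$fe$sink_channel)
  # sign flip of the input flips the CSD
  cm3 <- csd(-ms, time_ms = x$ssw$time_ms)
  expect_equal(cm3$csd, -cm2$csd)
  expect_error(csd(prof[1:2, , drop = FALSE]), "3 channels")
  expect_error(csd(prof, spacing_um = c(50, 100)), "uniform")
})

test_that("state normalization recovers the configured gains", {
  x <- fx_fepsp()
  sn <- state_normalize(x$meas, x$seq)
  g <- x$p$fepsp$gain
  for (s in sn$state) {
    est <- sn$norm_to_light_qw[sn$state == s]
    se_rel <- sn$sem_uv[sn$state == s] / sn$mean_uv[sn$state == s] +
      sn$sem_uv[sn$state == "QW"] / sn$mean_uv[sn$state == "QW"]
    expect_lt(abs(est - g[[s]]), 3 * se_rel * g[[s]] + 0.02)
  }
  # missing light-period quiet wake denominator errors
  dark <- x$seq
  dark$start_zt <- 13
  meas_dark <- x$meas
  expect_error(state_normalize(meas_dark, dark), "quiet-wake")
})

test_that("epoch time courses normalize to the first hour", {
  # constructed measurements: stationary then a 1.2x drift epoch
  h <- hypnogram(rep("NREM", 4 * 3600), epoch_len_s = 1,
                 states = c("AW", "QW", "NREM", "REM"))
  ep <- data.frame(state = "sleep", start_s = 0, end_s = 14400,
                   span_end_s = 14400, density = 1, last_hour_density = 1,
                   photoperiod = "light")
  class(ep) <- c("dense_epochs", "data.frame")
  tt <- seq(5, 14395, by = 10)
  stat <- data.frame(stim_time_s = tt, channel = 1, amplitude_uv = 150,
                     slope_uv_per_ms = 10, latency_ms = 7, qc_pass = TRUE,
                     reason = NA)
  tc <- epoch_timecourse(stat, ep, h, state = "NREM")
  expect_true(all(abs(tc$value - 1) < 1e-12))
  drift <- stat
  drift$amplitude_uv <- 150 * (1 + 0.2 * tt / 14400)
  tc2 <- epoch_timecourse(drift, ep, h, state = "NREM")
  expect_lt(abs(tail(tc2$value, 1) - 1.2 / mean(1 + 0.2 * seq(0.0035, 0.246, length.out = 6))), 0.03)
  # single-bin epoch normalizes to itself
  ep1 <- ep; ep1$end_s <- ep1$span_end_s <- 600
  tc3 <- epoch_timecourse(stat, ep1, h, state = "NREM")
  expect_equal(tc3$value, 1)
})

test_that("the sandwich statistic sees steps and not stationary noise", {
  h_lab <- rep(c(rep("NREM", 3600), rep("AW", 3600)), 4)
  h <- hypnogram(h_lab, epoch_len_s = 1, states = c("AW", "QW", "NREM", "REM"))
  ep <- data.frame(state = "wake",
                   start_s = c(3600, 10800, 18000),
                   end_s = c(7200, 14400, 21600),
                   span_end_s = c(7200, 14400, 21600),
                   density = 1, last_hour_density = NA, photoperiod = "light")
  class(ep) <- c("dense_epochs", "data.frame")
  tt <- seq(5, 28795, by = 10)
  base <- data.frame(stim_time_s = tt, channel = 1, amplitude_uv = 150,
                     slope_uv_per_ms = 10, latency_ms = 7, qc_pass = TRUE,
                     reason = NA)
  sw <- fepsp_sandwich(base, ep, h)
  expect_equal(nrow(sw$changes), 3L)
  expect_true(all(sw$changes$normalized_change == 0))
  expect_true(all(sw$changes$flank_state == "NREM"))
  # persistent +20% step after the second epoch
  step <- base
  step$amplitude_uv[tt >= 14400] <- 180
  sw2 <- fepsp_sandwich(step, ep, h)
  ch2 <- sw2$changes$normalized_change[sw2$changes$epoch == 2]
  expect_equal(ch2, 0.2, tolerance = 1e-9)
  # epochs without qualifying flank measurements are dropped with a record
  no_pre <- base[base$stim_time_s > 4000, ]
  sw3 <- fepsp_sandwich(no_pre, ep, h)
  expect_true(1 %in% sw3$dropped)
})

test_that("the sandwich null rejects near the nominal rate", {
  h_lab <- rep(c(rep("NREM", 1800), rep("AW", 1800)), 20)
  h <- hypnogram(h_lab, epoch_len_s = 1, states = c("AW", "QW", "NREM", "REM"))
  starts <- seq(1800, by = 3600, length.out = 19)
  ep <- data.frame(state = "wake", start_s = starts, end_s = starts + 1800,
                   span_end_s = starts + 1800, density = 1,
                   last_hour_density = NA, photoperiod = "light")
  class(ep) <- c("dense_epochs", "data.frame")
  tt <- seq(5, 20 * 3600 - 5, by = 10)
  set.seed(133)
  rej <- vapply(1:150, function(r) {
    m <- data.frame(stim_time_s = tt, channel = 1,
                    amplitude_uv = 150 + rnorm(length(tt), sd = 15),
                    slope_uv_per_ms = 10, latency_ms = 7, qc_pass = TRUE,
                    reason = NA)
    fepsp_sandwich(m, ep, h)$wilcoxon$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.06)
})
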