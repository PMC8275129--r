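test_that("isolation windows implement the hourly ISI contamination rule", {
  set.seed(141)
  # clean 5 Hz train with a 2.5 ms refractory period passes every hour
  p <- fx_params4()
  h <- hypnogram(rep("QW", 4 * 3600), epoch_len_s = 1,
                 states = c("AW", "QW", "NREM", "REM"))
  sd_ <- synthesize_spike_data(h, numeric(0), p, n_units = 1,
                               prop_responsive = 0, seed = 141)
  iso <- isolation_windows(sd_$units[[1]], sd_$duration_s)
  expect_true(all(iso$pass))
  # inject 10% of ISIs at 1 ms into hour 3 (0-based hour 2)
  sp <- sd_$units[[1]]
  in_h3 <- sp[sp >= 2 * 3600 & sp < 3 * 3600]
  contaminated <- sort(c(sp, in_h3[seq(1, length(in_h3), by = 9)] + 0.001))
  iso2 <- isolation_windows(contaminated, sd_$duration_s)
  expect_false(iso2$pass[3])
  expect_true(all(iso2$pass[-3]))
  # an empty train yields no usable windows
  iso3 <- isolation_windows(numeric(0), 7200)
  expect_true(all(!iso3$pass))
  expect_error(isolation_windows(1:10, 1800), "1 h")
})

test_that("the response formula has the documented analytic behavior", {
  stim <- seq(100, 1900, by = 10)
  # no spikes at all: response identically zero
  er0 <- evoked_response(numeric(0), stim)
  expect_true(all(er0$per_stim$response == 0))
  # deterministic 5 Hz baseline (grid offsets avoid every response window)
  # + one evoked spike per stimulus: response = 1 - 5 * 0.02 = 0.9
  base <- seq(0.05, 2000, by = 0.2)
  spikes <- sort(c(base, stim + 0.01))
  er <- evoked_response(spikes, stim)
  expect_lt(abs(er$mean_response - 0.9), 0.02)
  # window additivity: doubling the window doubles the correction exactly
  er1 <- evoked_response(spikes, stim, window_s = 0.02)
  er2 <- evoked_response(spikes, stim, window_s = 0.04)
  corr1 <- er1$per_stim$count - er1$per_stim$response
  corr2 <- er2$per_stim$count - er2$per_stim$response
  expect_equal(corr2, 2 * corr1, tolerance = 1e-12)
})

test_that("the estimator recovers the per-state evoked probability", {
  p <- fx_params4()
  ss <- generate_state_sequence(p, duration_h = 3, seed = 142)
  stim <- seq(30, 3 * 3600 - 30, by = 5)
  sd_ <- synthesize_spike_data(ss, stim, p, n_units = 2,
                               prop_responsive = 1, seed = 143)
  er <- evoked_response(sd_$units[[1]], stim, hypnogram = ss)
  sm <- er$state_means
  for (s in sm$state) {
    truth <- p$spikes$evoked_prob[[s]]
    row <- sm[sm$state == s, ]
    expect_lt(abs(row$mean_response - truth), 3 * row$sem + 0.01)
  }
})

test_that("the bootstrap null is centered and gates responsiveness", {
  p <- fx_params4()
  ss <- generate_state_sequence(p, duration_h = 2, seed = 144)
  stim <- seq(30, 2 * 3600 - 30, by = 10)
  sd_ <- synthesize_spike_data(ss, stim, p, n_units = 2,
                               prop_responsive = 0.5, seed = 145)
  resp_unit <- sd_$units[[1]]
  null_unit <- sd_$units[[2]]
  bn <- bootstrap_null(null_unit, stim, sd_$duration_s, n_samples = 400,
                       seed = 146)
  expect_lt(abs(mean(bn$null_means)), 0.01)
  er_r <- evoked_response(resp_unit, stim)
  er_n <- evoked_response(null_unit, stim)
  bn_r <- bootstrap_null(resp_unit, stim, sd_$duration_s, n_samples = 400,
                         seed = 146)
  expect_true(classify_responsive(er_r$mean_response, bn_r)$responsive)
  expect_false(classify_responsive(er_n$mean_response, bn)$responsive)
})

test_that("the 95th-percentile gate is calibrated near 5%", {
  p <- fx_params4()
  h <- hypnogram(rep("QW", 3600), epoch_len_s = 1,
                 states = c("AW", "QW", "NREM", "REM"))
  stim <- seq(20, 3580, by = 10)
  n_rep <- 120
  flags <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sd_ <- synthesize_spike_data(h, stim, p, n_units = 1,
                                 prop_responsive = 0, seed = 2000 + r)
    er <- evoked_response(sd_$units[[1]], stim)
    bn <- bootstrap_null(sd_$units[[1]], stim, sd_$duration_s,
                         n_samples = 300, seed = 3000 + r)
    flags[r] <- classify_responsive(er$mean_response, bn)$responsive
  }
  # false-responsive rate approximately 5% (3 binomial SEs)
  expect_lt(abs(mean(flags) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.01)
})

test_that("truly responsive units are flagged nearly always", {
  p <- fx_params4()
  h <- hypnogram(rep("NREM", 2500), epoch_len_s = 1,
                 states = c("AW", "QW", "NREM", "REM"))
  stim <- seq(20, 2400, by = 10)       # >= 200 NREM stimuli, p = 0.2
  n_rep <- 40
  flags <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sd_ <- synthesize_spike_data(h, stim, p, n_units = 1,
                                 prop_responsive = 1, seed = 4000 + r)
    er <- evoked_response(sd_$units[[1]], stim)
    bn <- bootstrap_null(sd_$units[[1]], stim, sd_$duration_s,
                         n_samples = 300, seed = 5000 + r)
    flags[r] <- classify_responsive(er$mean_response, bn)$responsive
  }
  expect_gte(mean(flags), 0.95)
})

test_that("state comparisons use the log scale and guard degenerate input", {
  set.seed(149)
  sm_same <- data.frame(unit = rep(1:10, 2),
                        state = rep(c("NREM", "QW"), each = 10),
                        mean_response = rep(exp(rnorm(10, -2, 0.3)), 2))
  out <- compare_states(sm_same)
  expect_gt(out$p_value, 0.99)
  set.seed(147)
  sm_diff <- data.frame(unit = rep(1:30, 2),
                        state = rep(c("NREM", "AW"), each = 30),
                        mean_response = c(exp(rnorm(30, log(0.2), 0.4)),
                                          exp(rnorm(30, log(0.2) - log(2), 0.4))))
  expect_lt(compare_states(sm_diff)$p_value, 0.05)
  one <- data.frame(unit = 1, state = c("NREM", "QW"),
                    mean_response = c(0.2, 0.1))
  expect_error(compare_states(one), "fewer than 2")
  neg <- rbind(sm_same, data.frame(unit = 99, state = "NREM",
                                   mean_response = -0.1))
  expect_warning(compare_states(neg), "nonpositive")
})

test_that("evoked sandwich detects induced changes and not stationarity", {
  p <- fx_params4()
  lab <- rep(c(rep("NREM", 2700), rep("AW", 2700)), 4)
  h <- hypnogram(lab, epoch_len_s = 1, states = c("AW", "QW", "NREM", "REM"))
  h$seed <- 1; class(h) <- c("state_sequence", class(h))
  stim <- seq(30, length(lab) - 30, by = 10)
  sd_ <- synthesize_spike_data(h, stim, p, n_units = 6,
                               prop_responsive = 1, seed = 148)
  ep <- detect_sandwich_epochs(resample_hypnogram(h, 10), "wake")
  sw <- sandwich_evoked(sd_, ep)
  expect_gt(nrow(sw$per_epoch), 0)
  se <- sd(sw$per_epoch$change) / sqrt(nrow(sw$per_epoch))
  expect_lt(abs(mean(sw$per_epoch$change)), 3 * se + 0.02)
  # doubling the evoked probability after an epoch produces positive change
  sd2 <- sd_
  set.seed(150)
  boost <- stim[stim > 3 * 5400]
  for (u in seq_along(sd2$units)) {
    extra <- boost[runif(length(boost)) < 0.25] + 0.01
    sd2$units[[u]] <- sort(c(sd2$units[[u]], extra))
  }
  sw2 <- sandwich_evoked(sd2, ep)
  late <- sw2$per_epoch[sw2$per_epoch$epoch == max(sw2$per_epoch$epoch), ]
  expect_gt(mean(late$change), 0.1)
  # empty epoch list gives an empty result
  sw0 <- sandwich_evoked(sd_, ep[0, ])
  expect_equal(nrow(sw0$per_epoch), 0L)
})
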