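test_that("event features recover constants and template means", {
  fs <- 1000
  mag <- scalar_series(c(rep(0, 100), rep(2, 100), rep(0, 100)), fs)
  jerk <- scalar_series(rep(0, 300), fs)
  ev <- data.frame(event_index = 1L, onset_s = 0.100, offset_s = 0.198)
  f <- event_features(mag, jerk, ev)
  expect_equal(f$norm_accel_magnitude, 2)
  expect_equal(f$jerk_mean, 0)
  expect_equal(f$duration_ms, 98)
  # per-ms variant divides by duration in ms
  f2 <- event_features(mag, jerk, ev, normalize = "per_ms")
  expect_equal(f2$norm_accel_magnitude, 2 / 98)
  expect_error(event_features(mag, jerk,
                              data.frame(event_index = 1, onset_s = 0.2,
                                         offset_s = 0.2)), "duration")

  # synthetic burst: mean |a| over the support matches the analytic
  # template mean integral(|A e^(-t^2/2s^2) cos|)/(4s) within 1%
  p <- block_sim_params(noise_sd = 0, drift_amplitude = 0, amplitude_cv = 0,
                        interval_cv = 0, rng_seed = 3)
  blk <- simulate_block(p)
  mag_b <- vector_magnitude(blk$trace)
  jerk_b <- jerk_series(mag_b)
  sigma <- p$burst_width_ms / 1000 / 4
  f_c <- 1000 / p$burst_width_ms
  tt <- seq(-2 * sigma, 2 * sigma, length.out = 20001)
  analytic <- mean(abs(p$burst_amplitude * exp(-tt^2 / (2 * sigma^2)) *
                         cos(2 * pi * f_c * tt)))
  got <- event_features(mag_b, jerk_b,
                        blk$truth[5, ])
  expect_lt(abs(got$norm_accel_magnitude - analytic) / analytic, 0.01)
})

test_that("inter-movement intervals are peak-to-peak differences in ms", {
  ev <- data.frame(peak_s = c(0, 0.25, 0.5))
  expect_equal(inter_movement_intervals(ev), c(250, 250))
  expect_equal(inter_movement_intervals(data.frame(peak_s = c(0.1, 0.4))),
               300)
  expect_warning(out <- inter_movement_intervals(data.frame(peak_s = 0.1)),
                 "fewer than 2")
  expect_length(out, 0)
  expect_true(attr(out, "insufficient"))
})

test_that("coefficient of variation matches hand arithmetic and the oracle", {
  expect_equal(coefficient_of_variation(rep(5, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2)
  set.seed(8)
  for (rep in 1:5) {
    x <- rlnorm(sample(5:50, 1))
    expect_equal(coefficient_of_variation(x), oracle_cv(x), tolerance = 1e-9)
    expect_equal(coefficient_of_variation(3.7 * x),
                 coefficient_of_variation(x), tolerance = 1e-9)
  }
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(1), "at least 2")
})

test_that("block features aggregate event features as specified", {
  evf <- data.frame(event_index = 1:2, norm_accel_magnitude = c(1, 3),
                    jerk_mean = c(2, 2), duration_ms = c(50, 50))
  bf <- block_features(evf, imis = c(250, 250))
  expect_equal(bf$accel_mean, 2)
  expect_equal(bf$accel_cv, 100 * sqrt(2) / 2)
  expect_equal(bf$imi_cv, 0)
  expect_equal(bf$jerk_cv, 0)
  expect_identical(bf$n_events, 2L)
  expect_error(block_features(evf[1, ], numeric(0)), "at least 2")
})

test_that("planted amplitude jitter is recovered in the block CV", {
  # oracle events from the generator's ground truth: with fixed-width
  # windows the per-event mean magnitude is proportional to the planted
  # amplitude, so the block CV matches the planted 10%
  cvs <- vapply(1:40, function(i) {
    p <- block_sim_params(amplitude_cv = 0.10, interval_cv = 0,
                          noise_sd = 0.1, drift_amplitude = 0,
                          rng_seed = 4000 + i)
    blk <- simulate_block(p)
    mag <- vector_magnitude(blk$trace)
    jerk <- jerk_series(mag)
    f <- vapply(seq_len(nrow(blk$truth)), function(k) {
      event_features(mag, jerk,
                     blk$truth[k, ])$norm_accel_magnitude
    }, numeric(1))
    coefficient_of_variation(f)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 10), 2)
})

test_that("constant features give zero slopes; single subject matches OLS", {
  tt <- expand.grid(subject_id = c("a", "b"), event_index = 1:10)
  tt$med_state <- "ON"; tt$stim_state <- "ON"
  tt$movement_type <- "finger_tapping"
  tt$norm_accel_magnitude <- 5
  sl <- kinematic_slopes(tt, "norm_accel_magnitude")
  expect_equal(sl$slope, c(0, 0))

  one <- data.frame(subject_id = "a", med_state = "ON", stim_state = "ON",
                    movement_type = "finger_tapping", event_index = 1:20,
                    norm_accel_magnitude = 10 - 0.1 * (1:20))
  sl1 <- kinematic_slopes(one, "norm_accel_magnitude")
  expect_identical(sl1$method, "ols")
  expect_equal(sl1$slope, cor(one$norm_accel_magnitude, one$event_index),
               tolerance = 1e-9)
  expect_equal(sl1$slope, -1, tolerance = 1e-9)
})

test_that("mixed-model slopes recover planted per-subject decrements", {
  set.seed(99)
  n_subj <- 15; n_tr <- 40
  planted <- rnorm(n_subj, -0.02, 0.02)
  d <- do.call(rbind, lapply(seq_len(n_subj), function(s) {
    data.frame(subject_id = sprintf("S%02d", s), med_state = "OFF",
               stim_state = "OFF", movement_type = "finger_tapping",
               event_index = 1:n_tr,
               norm_accel_magnitude = 5 + planted[s] * (1:n_tr) +
                 rnorm(n_tr, 0, 0.5))
  }))
  sl <- kinematic_slopes(d, "norm_accel_magnitude")
  sl <- sl[order(sl$subject_id), ]
  expect_gt(cor(sl$slope, planted), 0.85)
  # fixed-trend sign is preserved
  expect_lt(mean(sl$slope), 0)
})

test_that("features are invariant to time shift and scale appropriately", {
  p <- block_sim_params(noise_sd = 0, drift_amplitude = 0, amplitude_cv = 0,
                        interval_cv = 0, rng_seed = 12)
  blk <- simulate_block(p)
  mag <- vector_magnitude(blk$trace)
  jerk <- jerk_series(mag)
  ev <- blk$truth[3, ]
  base <- event_features(mag, jerk, ev)
  # uniform gain scales the magnitude feature linearly
  mag2 <- scalar_series(2 * mag$values, mag$sampling_rate_hz)
  jerk2 <- jerk_series(mag2)
  scaled <- event_features(mag2, jerk2, ev)
  expect_equal(scaled$norm_accel_magnitude, 2 * base$norm_accel_magnitude,
               tolerance = 1e-9)
  # IMIs are gain invariant by construction (peak times unchanged)
  ev_all <- detect_events(blk$trace)
  imi <- inter_movement_intervals(ev_all)
  tr2 <- blk$trace
  tr2$ax <- 2 * tr2$ax; tr2$ay <- 2 * tr2$ay; tr2$az <- 2 * tr2$az
  expect_equal(inter_movement_intervals(detect_events(tr2)), imi,
               tolerance = 1e-9)
})
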