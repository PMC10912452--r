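test_that("noiseless jitter-free block realizes exactly rate x duration events", {
  p <- block_sim_params(noise_sd = 0, drift_amplitude = 0, amplitude_cv = 0,
                        interval_cv = 0, movement_rate_hz = 4,
                        duration_s = 10, rng_seed = 1)
  blk <- simulate_block(p)
  expect_identical(nrow(blk$truth), 40L)
  expect_equal(length(blk$trace$ax), 10 * 1000)
  # vector-magnitude peak within one sample of each annotated peak
  mag <- vector_magnitude(blk$trace)
  fs <- blk$trace$sampling_rate_hz
  for (i in seq_len(nrow(blk$truth))) {
    lo <- round(blk$truth$onset_s[i] * fs) + 1L
    hi <- round(blk$truth$offset_s[i] * fs) + 1L
    local_peak <- lo - 1L + which.max(mag$values[lo:hi])
    expect_lte(abs(local_peak - (round(blk$truth$peak_s[i] * fs) + 1L)), 1L)
  }
  expect_true(all(blk$truth$onset_s < blk$truth$peak_s))
  expect_true(all(blk$truth$peak_s < blk$truth$offset_s))
  expect_true(all(diff(blk$truth$peak_s) > 0))
})

test_that("identical seeds reproduce blocks and cohorts bit for bit", {
  p <- block_sim_params(rng_seed = 77)
  b1 <- simulate_block(p)
  b2 <- simulate_block(p)
  expect_identical(b1$trace$ax, b2$trace$ax)
  expect_identical(b1$truth, b2$truth)
  c1 <- simulate_cohort(n_subjects = 3, rng_seed = 5)
  c2 <- simulate_cohort(n_subjects = 3, rng_seed = 5)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$blocks[[10]]$trace$az, c2$blocks[[10]]$trace$az)
})

test_that("interval jitter realizes the requested coefficient of variation", {
  # 1000 short blocks at 200 Hz; pooled true inter-event intervals
  ivs <- unlist(lapply(seq_len(1000), function(i) {
    p <- block_sim_params(duration_s = 5, sampling_rate_hz = 200,
                          interval_cv = 0.1, noise_sd = 0,
                          drift_amplitude = 0, rng_seed = 20000 + i)
    simulate_block(p)$truth$interval_ms
  }))
  ivs <- ivs[!is.na(ivs)]
  cv <- sd(ivs) / mean(ivs)
  expect_gt(length(ivs), 15000)
  expect_lt(abs(cv - 0.1), 0.005)
})

test_that("invalid block parameters name the offending field", {
  expect_error(block_sim_params(duration_s = -1), "duration_s")
  expect_error(block_sim_params(sampling_rate_hz = 100), "sampling_rate_hz")
  expect_error(block_sim_params(movement_rate_hz = 0.1), "movement_rate_hz")
  expect_error(block_sim_params(noise_sd = -0.5), "noise_sd")
  expect_error(block_sim_params(burst_width_ms = 0), "burst_width_ms")
})

test_that("default effect multipliers order OFF/OFF worst to ON/ON best", {
  em <- effect_multipliers()
  key <- paste(em$med_state, em$stim_state, sep = "/")
  amp <- setNames(em$amplitude_gain, key)
  expect_lt(amp[["OFF/OFF"]], amp[["ON/OFF"]])
  expect_lt(amp[["OFF/OFF"]], amp[["OFF/ON"]])
  expect_lt(amp[["ON/OFF"]], amp[["ON/ON"]])
  expect_lt(amp[["OFF/ON"]], amp[["ON/ON"]])
  iv <- setNames(em$interval_gain, key)
  expect_gt(iv[["OFF/OFF"]], iv[["ON/ON"]])
  expect_error(effect_multipliers(data.frame(med_state = "OFF",
                                             stim_state = "OFF")),
               "missing column")
  bad <- effect_multipliers()
  bad$amplitude_gain[1] <- -1
  expect_error(effect_multipliers(bad), "> 0")
})

test_that("cohort design arithmetic and ground-truth conservation hold", {
  co <- simulate_cohort(n_subjects = 4, rng_seed = 9)
  keys <- names(co$blocks)
  for (mt in c("finger_tapping", "pronation_supination")) {
    expect_identical(sum(grepl(mt, keys, fixed = TRUE)), 4L * 4L)
  }
  expect_identical(nrow(co$clinical), 4L * 4L)
  item_cols <- grep("^item", names(co$clinical), value = TRUE)
  vals <- as.matrix(co$clinical[, item_cols])
  expect_true(all(vals == round(vals) & vals >= 0 & vals <= 4))
  # realized per-state mean amplitudes follow the multiplier ordering
  bp <- co$block_params
  amp_by_state <- tapply(bp$burst_amplitude,
                         paste(bp$med_state, bp$stim_state, sep = "/"), mean)
  expect_lt(amp_by_state[["OFF/OFF"]], amp_by_state[["ON/OFF"]])
  expect_lt(amp_by_state[["ON/OFF"]], amp_by_state[["ON/ON"]])
  expect_lt(amp_by_state[["OFF/ON"]], amp_by_state[["ON/ON"]])
  expect_error(simulate_cohort(n_subjects = 1), ">= 2")
})

test_that("zero laterality offsets yield exactly zero laterality indices", {
  coup <- severity_coupling(laterality_sd = 0)
  co <- simulate_cohort(n_subjects = 5, coupling = coup, rng_seed = 3,
                        movement_types = "finger_tapping")
  expect_true(all(laterality_index(co$clinical) == 0))
})

test_that("amplitude gain ratio across states propagates to the generator", {
  co <- simulate_cohort(n_subjects = 12, rng_seed = 31,
                        movement_types = "finger_tapping")
  bp <- co$block_params
  m <- tapply(bp$burst_amplitude,
              paste(bp$med_state, bp$stim_state, sep = "/"), mean)
  # default amplitude_gain is 1.5 for ON/ON vs 1.0 for OFF/OFF; severity
  # modulation cancels in the within-subject ratio
  expect_lt(abs(m[["ON/ON"]] / m[["OFF/OFF"]] - 1.5), 1e-8)
})

test_that("block SNR helpers are mutually consistent", {
  p <- block_sim_params()
  expect_equal(snr_db(block_sim_params(noise_sd =
                                         noise_sd_for_snr(p, 10))), 10,
               tolerance = 1e-9)
  expect_identical(snr_db(block_sim_params(noise_sd = 0)), Inf)
})

test_that("a cohort writes to delimited text and traces round-trip", {
  co <- simulate_cohort(n_subjects = 2, rng_seed = 8,
                        movement_types = "finger_tapping",
                        base_params = block_sim_params(duration_s = 2,
                                                       sampling_rate_hz = 200))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "clinical_records.tsv")))
  expect_true(file.exists(file.path(dir, "simulation_params.json")))
  traces <- list.files(file.path(dir, "traces"), full.names = TRUE)
  expect_length(traces, 8L)
  back <- read_trace(traces[1L])
  expect_identical(length(back$ax), 400L)
})
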