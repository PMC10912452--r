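#' Simulation parameters for one accelerometer movement block
#'
#' Describes a ~10 s block of repetitive hand movements (finger taps or
#' pronation-supination rotations) recorded with a triaxial accelerometer.
#' Each movement is a smooth biphasic burst — a Gaussian-windowed sinusoid —
#' projected onto the three axes by a fixed unit orientation vector, with
#' optional additive white noise, low-frequency baseline drift, and a
#' sinusoidal tremor contaminant.
#'
#' @param duration_s block duration in seconds (default 10).
#' @param sampling_rate_hz sampling rate in Hz (default 1000; must be at
#'   least 200 so that 100 ms peak spacing is resolvable).
#' @param movement_rate_hz mean movement rate in events/s (default 4, a
#'   typical brisk finger-tapping pace; use ~2 for rotations).
#' @param burst_amplitude peak acceleration of the event template in m/s^2
#'   (default 10).
#' @param amplitude_cv per-event amplitude jitter as a coefficient of
#'   variation (log-normal multiplier; default 0.1).
#' @param interval_cv inter-event interval jitter as a coefficient of
#'   variation (log-normal; default 0.1).
#' @param amplitude_slope_per_event fractional amplitude change per event
#'   (sequence-decrement model; default 0).
#' @param noise_sd additive white noise SD per axis in m/s^2 (default 0.5).
#' @param drift_amplitude low-frequency (< 0.5 Hz) baseline drift amplitude
#'   in m/s^2 (default 0.2).
#' @param tremor_amplitude amplitude of an optional 4-6 Hz tremor
#'   contaminant in m/s^2 (default 0 = none).
#' @param tremor_freq_hz tremor frequency in Hz (default 5).
#' @param burst_width_ms event template width in ms (default 80; the
#'   Gaussian envelope SD is a quarter of this, so the support is about
#'   +/- half the width around the peak).
#' @param burst_cycles carrier cycles per burst (default 1: one biphasic
#'   acceleration-deceleration pair, as in an index-to-thumb tap; use 2 for
#'   movements with two phases such as pronation then supination).
#' @param orientation length-3 numeric giving the movement axis; normalized
#'   internally.
#' @param rng_seed integer seed; if `NULL` the current RNG stream is used.
#' @return An object of class `block_sim_params`.
#' @export
block_sim_params <- function(duration_s = 10, sampling_rate_hz = 1000,
                             movement_rate_hz = 4, burst_amplitude = 10,
                             amplitude_cv = 0.1, interval_cv = 0.1,
                             amplitude_slope_per_event = 0, noise_sd = 0.5,
                             drift_amplitude = 0.2, tremor_amplitude = 0,
                             tremor_freq_hz = 5, burst_width_ms = 80,
                             burst_cycles = 1,
                             orientation = c(0.7, 0.5, 0.5),
                             rng_seed = NULL) {
  p <- list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
            movement_rate_hz = movement_rate_hz,
            burst_amplitude = burst_amplitude, amplitude_cv = amplitude_cv,
            interval_cv = interval_cv,
            amplitude_slope_per_event = amplitude_slope_per_event,
            noise_sd = noise_sd, drift_amplitude = drift_amplitude,
            tremor_amplitude = tremor_amplitude,
            tremor_freq_hz = tremor_freq_hz, burst_width_ms = burst_width_ms,
            burst_cycles = burst_cycles,
            orientation = orientation, rng_seed = rng_seed)
  sim_param_error <- function(field, msg) {
    stop(sprintf("block_sim_params: invalid '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(duration_s) || duration_s <= 0)
    sim_param_error("duration_s", "must be > 0")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz < 200)
    sim_param_error("sampling_rate_hz", "must be >= 200 Hz")
  if (!is.numeric(movement_rate_hz) ||
      movement_rate_hz * duration_s < 2)
    sim_param_error("movement_rate_hz",
                    "movement_rate_hz * duration_s must be >= 2")
  for (f in c("burst_amplitude", "amplitude_cv", "interval_cv", "noise_sd",
              "drift_amplitude", "tremor_amplitude")) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0) sim_param_error(f, "must be >= 0")
  }
  if (!is.numeric(burst_width_ms) || burst_width_ms <= 0)
    sim_param_error("burst_width_ms", "must be > 0")
  if (!is.numeric(burst_cycles) || burst_cycles < 1)
    sim_param_error("burst_cycles", "must be >= 1")
  if (!is.numeric(tremor_freq_hz) || tremor_freq_hz <= 0)
    sim_param_error("tremor_freq_hz", "must be > 0")
  if (length(orientation) != 3L || all(orientation == 0))
    sim_param_error("orientation", "must be a non-zero length-3 vector")
  p$orientation <- orientation / sqrt(sum(orientation^2))
  structure(p, class = "block_sim_params")
}

# log-normal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one accelerometer movement block with ground-truth events
#'
#' Generates `floor(movement_rate_hz * duration_s)` burst templates at
#' jittered times and amplitudes, projects them onto three axes, and adds
#' noise, drift and (optionally) tremor. Events whose support would extend
#' beyond the block are dropped from both the signal and the ground truth,
#' so annotated events always equal injected ones.
#'
#' @param params a [block_sim_params()] object.
#' @return A list with elements `trace` (an [accel_trace()]) and `truth`
#'   (a data.frame of per-event `onset_s`, `peak_s`, `offset_s`,
#'   `amplitude`, and `interval_ms` to the previous event), plus `params`.
#' @export
simulate_block <- function(params) {
  stopifnot(inherits(params, "block_sim_params"))
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  fs <- params$sampling_rate_hz
  n <- round(params$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs

  mean_iv <- 1 / params$movement_rate_hz
  n_ev <- floor(params$movement_rate_hz * params$duration_s)
  intervals <- mean_iv * rlnorm_cv(n_ev - 1L, params$interval_cv)
  peaks <- mean_iv / 2 + c(0, cumsum(intervals))

  base_amp <- params$burst_amplitude *
    pmax(0, 1 + params$amplitude_slope_per_event * (seq_len(n_ev) - 1L))
  amps <- base_amp * rlnorm_cv(n_ev, params$amplitude_cv)

  sigma <- params$burst_width_ms / 1000 / 4   # envelope SD in s
  half_support <- 2 * sigma
  keep <- peaks - half_support >= 0 & peaks + half_support <= params$duration_s
  peaks <- peaks[keep]
  amps <- amps[keep]

  sig <- numeric(n)
  f_carrier <- params$burst_cycles * 1000 / params$burst_width_ms
  for (i in seq_along(peaks)) {
    lo <- max(1L, floor((peaks[i] - 3 * sigma) * fs) + 1L)
    hi <- min(n, ceiling((peaks[i] + 3 * sigma) * fs) + 1L)
    dt <- t[lo:hi] - peaks[i]
    sig[lo:hi] <- sig[lo:hi] +
      amps[i] * exp(-dt^2 / (2 * sigma^2)) * cos(2 * pi * f_carrier * dt)
  }

  ov <- params$orientation
  ax <- sig * ov[1L]; ay <- sig * ov[2L]; az <- sig * ov[3L]

  if (params$drift_amplitude > 0) {
    for (axis in 1:3) {
      f_d <- stats::runif(1, 0.05, 0.4)
      ph <- stats::runif(1, 0, 2 * pi)
      d <- params$drift_amplitude * sin(2 * pi * f_d * t + ph)
      if (axis == 1L) ax <- ax + d else if (axis == 2L) ay <- ay + d else az <- az + d
    }
  }
  if (params$tremor_amplitude > 0) {
    tv <- stats::rnorm(3); tv <- tv / sqrt(sum(tv^2))
    ph <- stats::runif(1, 0, 2 * pi)
    tr <- params$tremor_amplitude * sin(2 * pi * params$tremor_freq_hz * t + ph)
    ax <- ax + tr * tv[1L]; ay <- ay + tr * tv[2L]; az <- az + tr * tv[3L]
  }
  if (params$noise_sd > 0) {
    ax <- ax + stats::rnorm(n, 0, params$noise_sd)
    ay <- ay + stats::rnorm(n, 0, params$noise_sd)
    az <- az + stats::rnorm(n, 0, params$noise_sd)
  }

  truth <- data.frame(
    event_index = seq_along(peaks),
    onset_s = peaks - half_support,
    peak_s = peaks,
    offset_s = peaks + half_support,
    amplitude = amps,
    interval_ms = c(NA_real_, diff(peaks) * 1000)
  )
  trace <- accel_trace(t, ax, ay, az, sampling_rate_hz = fs, meta = list())
  list(trace = trace, truth = truth, params = params)
}

#' Signal-to-noise ratio of a block simulation
#'
#' Block SNR in dB, defined as the ratio of the expected signal power of
#' the burst train (time-average of the squared template train over the
#' block, summed across axes) to the total white-noise power (3 sigma^2).
#' The default parameters (40 bursts of 10 m/s^2 peak, 80 ms width, noise
#' SD 0.5 m/s^2 per axis) sit at about 9.8 dB.
#'
#' @param params a [block_sim_params()] object.
#' @return SNR in dB (`Inf` for a noiseless block).
#' @export
snr_db <- function(params) {
  stopifnot(inherits(params, "block_sim_params"))
  if (params$noise_sd == 0) return(Inf)
  sigma_t <- params$burst_width_ms / 1000 / 4
  n_ev <- floor(params$movement_rate_hz * params$duration_s)
  # integral of (A exp(-dt^2/(2 s^2)) cos(2 pi f dt))^2 ~= A^2/2 * s*sqrt(pi)
  p_sig <- n_ev * params$burst_amplitude^2 / 2 * sigma_t * sqrt(pi) /
    params$duration_s
  p_noise <- 3 * params$noise_sd^2
  10 * log10(p_sig / p_noise)
}

#' Noise level achieving a target block SNR
#'
#' Inverse of [snr_db()]: the per-axis white-noise SD that puts a block at
#' the requested SNR.
#'
#' @param params a [block_sim_params()] object (its `noise_sd` is ignored).
#' @param target_snr_db target SNR in dB.
#' @return Noise SD in m/s^2.
#' @export
noise_sd_for_snr <- function(params, target_snr_db) {
  stopifnot(inherits(params, "block_sim_params"))
  sigma_t <- params$burst_width_ms / 1000 / 4
  n_ev <- floor(params$movement_rate_hz * params$duration_s)
  p_sig <- n_ev * params$burst_amplitude^2 / 2 * sigma_t * sqrt(pi) /
    params$duration_s
  sqrt(p_sig / 10^(target_snr_db / 10) / 3)
}

#' Therapy-state effect multipliers
#'
#' Dimensionless multipliers applied to baseline block parameters in each of
#' the four medication x stimulation states. Defaults are ordered so that
#' OFF/OFF is the worst state and ON/ON the best: effective therapy raises
#' movement amplitude (`amplitude_gain`), shortens inter-movement intervals
#' (`interval_gain` < 1), reduces amplitude/pacing variability
#' (`variability_gain` < 1), and increases movement smoothness
#' (`smoothness_gain`, realized as a proportionally narrower, higher-jerk
#' burst — in this feature vocabulary higher jerk means brisker, smoother
#' execution).
#'
#' @param table optional data.frame overriding the defaults; must contain
#'   columns `med_state`, `stim_state`, `amplitude_gain`, `interval_gain`,
#'   `variability_gain`, `smoothness_gain` and all four states.
#' @return A data.frame of class `effect_multipliers`, one row per state.
#' @export
effect_multipliers <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      med_state       = c("OFF", "ON", "OFF", "ON"),
      stim_state      = c("OFF", "OFF", "ON", "ON"),
      amplitude_gain  = c(1.00, 1.20, 1.25, 1.50),
      interval_gain   = c(1.00, 0.92, 0.90, 0.75),
      variability_gain = c(1.00, 0.80, 0.80, 0.60),
      smoothness_gain = c(1.00, 1.10, 1.10, 1.25),
      stringsAsFactors = FALSE
    )
  }
  need <- c("med_state", "stim_state", "amplitude_gain", "interval_gain",
            "variability_gain", "smoothness_gain")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop(sprintf("effect_multipliers: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  states <- paste(table$med_state, table$stim_state, sep = "/")
  want <- c("OFF/OFF", "ON/OFF", "OFF/ON", "ON/ON")
  missing_states <- setdiff(want, states)
  if (length(missing_states)) {
    stop(sprintf("effect_multipliers: missing therapy state(s): %s",
                 paste(missing_states, collapse = ", ")), call. = FALSE)
  }
  gains <- as.matrix(table[, need[-(1:2)]])
  if (any(!is.finite(gains)) || any(gains <= 0)) {
    stop("effect_multipliers: all gains must be finite and > 0", call. = FALSE)
  }
  class(table) <- c("effect_multipliers", "data.frame")
  table
}

#' Severity-to-clinic coupling parameters
#'
#' Controls how the per-subject latent motor severity (standard normal) maps
#' to block kinematics and to ordinal MDS-UPDRS item scores. Item scores are
#' produced by binning `latent + state offset + item noise` at fixed cut
#' points into 0-4; left/right asymmetry enters as +/- half the subject's
#' laterality offset (item noise is shared between the two sides of an item,
#' so a zero offset yields exactly symmetric scores).
#'
#' @param amp_sev amplitude log-scale decrease per severity SD (default 0.15).
#' @param interval_sev interval log-scale increase per severity SD (0.08).
#' @param variability_sev variability log-scale increase per severity SD (0.15).
#' @param item_noise_sd SD of the shared per-item latent noise (default 0.3).
#' @param cutpoints 4 increasing cut points binning the latent into 0-4.
#' @param state_offsets named latent shifts per therapy state (OFF/OFF worst).
#' @param tremor_shift latent shift for tremor items (default -1.2, matching
#'   a predominantly akinetic-rigid cohort).
#' @param laterality_sd SD of the per-subject laterality offset (default 0.5).
#' @param updrs_sev latent-severity weight for item generation (default 0.8).
#' @return A list of class `severity_coupling`.
#' @export
severity_coupling <- function(amp_sev = 0.15, interval_sev = 0.08,
                              variability_sev = 0.15, item_noise_sd = 0.3,
                              cutpoints = c(-0.5, 0.5, 1.5, 2.5),
                              state_offsets = c("OFF/OFF" = 1.1,
                                                "ON/OFF" = 0.45,
                                                "OFF/ON" = 0.35,
                                                "ON/ON" = -0.7),
                              tremor_shift = -1.2, laterality_sd = 0.5,
                              updrs_sev = 0.8) {
  if (is.unsorted(cutpoints, strictly = TRUE) || length(cutpoints) != 4L) {
    stop("severity_coupling: cutpoints must be 4 strictly increasing values",
         call. = FALSE)
  }
  structure(list(amp_sev = amp_sev, interval_sev = interval_sev,
                 variability_sev = variability_sev,
                 item_noise_sd = item_noise_sd, cutpoints = cutpoints,
                 state_offsets = state_offsets, tremor_shift = tremor_shift,
                 laterality_sd = laterality_sd, updrs_sev = updrs_sev),
            class = "severity_coupling")
}

bin_item <- function(latent, cutpoints) {
  findInterval(latent, cutpoints)  # 0..4, integer
}

#' Simulate a synthetic Parkinson's disease cohort
#'
#' Generates `n_subjects` subjects, each observed in all four medication x
#' stimulation states and two movement types (finger tapping at the tapping
#' rate, pronation-supination at half of it by default), with one
#' accelerometer block plus ground-truth events per subject x state x type
#' and one clinical record (MDS-UPDRS Part III items) per subject x state.
#' Block parameters are the baseline modulated by the state's effect
#' multipliers and the subject's latent severity; all realized parameters
#' are recorded in the output so tests can use them as oracles.
#'
#' @param n_subjects number of subjects (>= 2; default 20).
#' @param effects an [effect_multipliers()] table.
#' @param base_params baseline [block_sim_params()] (its `movement_rate_hz`
#'   is used for finger tapping; rotations run at `rotation_rate_hz`).
#' @param coupling a [severity_coupling()] object.
#' @param rotation_rate_hz pronation-supination rate in events/s (default 2).
#' @param rotation_burst_width_ms event width for rotations (default 250 ms:
#'   a full pronation-supination cycle is a much longer movement than an
#'   index-to-thumb tap, giving the higher duty cycle that the lower 80/85
#'   detection percentiles for rotational movements presuppose).
#' @param rotation_burst_cycles carrier cycles per rotation event (default
#'   2: pronation then supination, each an acceleration-deceleration pair).
#' @param movement_types movement types to simulate.
#' @param rng_seed integer seed for the whole cohort.
#' @return A list of class `synthetic_cohort` with elements `blocks` (list
#'   of `simulate_block()` results keyed `subject|med|stim|type`), `clinical`
#'   (data.frame of item scores per subject x state), `subjects` (latent
#'   severity and laterality offset), `block_params` (realized per-block
#'   simulation parameters) and `design` (the generation settings).
#' @export
simulate_cohort <- function(n_subjects = 20, effects = effect_multipliers(),
                            base_params = block_sim_params(),
                            coupling = severity_coupling(),
                            rotation_rate_hz = 2,
                            rotation_burst_width_ms = 250,
                            rotation_burst_cycles = 2,
                            movement_types = c("finger_tapping",
                                               "pronation_supination"),
                            rng_seed = NULL) {
  if (n_subjects < 2) stop("simulate_cohort: n_subjects must be >= 2",
                           call. = FALSE)
  effects <- effect_multipliers(effects)
  stopifnot(inherits(coupling, "severity_coupling"))
  if (!is.null(rng_seed)) set.seed(rng_seed)

  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    severity = stats::rnorm(n_subjects),
    laterality_offset = stats::rnorm(n_subjects, 0, coupling$laterality_sd)
  )
  # per-block seeds derived from the cohort stream, kept below 2^31
  states <- effects[, c("med_state", "stim_state")]

  blocks <- list()
  bp_rows <- list()
  for (si in seq_len(n_subjects)) {
    sev <- subjects$severity[si]
    for (st in seq_len(nrow(states))) {
      med <- states$med_state[st]; stim <- states$stim_state[st]
      g <- effects[effects$med_state == med & effects$stim_state == stim, ]
      for (mt in movement_types) {
        rate0 <- if (mt == "finger_tapping") base_params$movement_rate_hz
                 else rotation_rate_hz
        width0 <- if (mt == "finger_tapping") base_params$burst_width_ms
                  else rotation_burst_width_ms
        p <- base_params
        if (mt != "finger_tapping") p$burst_cycles <- rotation_burst_cycles
        p$movement_rate_hz <- rate0 /
          (g$interval_gain * exp(coupling$interval_sev * sev))
        p$burst_amplitude <- base_params$burst_amplitude * g$amplitude_gain *
          exp(-coupling$amp_sev * sev)
        vfac <- g$variability_gain * exp(coupling$variability_sev * sev)
        p$amplitude_cv <- base_params$amplitude_cv * vfac
        p$interval_cv <- base_params$interval_cv * vfac
        p$burst_width_ms <- width0 / g$smoothness_gain
        p$rng_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        blk <- simulate_block(p)
        blk$trace$meta <- list(subject_id = subjects$subject_id[si],
                               movement_type = mt, med_state = med,
                               stim_state = stim, hand = "right")
        key <- paste(subjects$subject_id[si], med, stim, mt, sep = "|")
        blocks[[key]] <- blk
        bp_rows[[key]] <- data.frame(
          subject_id = subjects$subject_id[si], med_state = med,
          stim_state = stim, movement_type = mt,
          movement_rate_hz = p$movement_rate_hz,
          burst_amplitude = p$burst_amplitude,
          amplitude_cv = p$amplitude_cv, interval_cv = p$interval_cv,
          burst_width_ms = p$burst_width_ms, rng_seed = p$rng_seed
        )
      }
    }
  }

  brady_items <- c("3_4", "3_5", "3_6", "3_7", "3_8")
  tremor_items <- c("3_15", "3_16", "3_17", "3_18")
  clin_rows <- list()
  for (si in seq_len(n_subjects)) {
    sev <- subjects$severity[si]
    lat <- subjects$laterality_offset[si]
    for (st in seq_len(nrow(states))) {
      med <- states$med_state[st]; stim <- states$stim_state[st]
      off <- coupling$state_offsets[[paste(med, stim, sep = "/")]]
      latent0 <- coupling$updrs_sev * sev + off
      row <- list(subject_id = subjects$subject_id[si],
                  med_state = med, stim_state = stim)
      for (it in brady_items) {
        eps <- stats::rnorm(1, 0, coupling$item_noise_sd)  # shared L/R
        row[[paste0("item", it, "_right")]] <-
          bin_item(latent0 - lat / 2 + eps, coupling$cutpoints)
        row[[paste0("item", it, "_left")]] <-
          bin_item(latent0 + lat / 2 + eps, coupling$cutpoints)
      }
      row[["item3_14"]] <- bin_item(
        latent0 + stats::rnorm(1, 0, coupling$item_noise_sd),
        coupling$cutpoints)
      for (it in tremor_items) {
        row[[paste0("item", it)]] <- bin_item(
          0.3 * latent0 + coupling$tremor_shift +
            stats::rnorm(1, 0, coupling$item_noise_sd),
          coupling$cutpoints)
      }
      item_cols <- setdiff(names(row), c("subject_id", "med_state", "stim_state"))
      row$updrs3_total <- sum(unlist(row[item_cols]))
      clin_rows[[length(clin_rows) + 1L]] <- as.data.frame(row)
    }
  }
  clinical <- do.call(rbind, clin_rows)
  rownames(clinical) <- NULL

  structure(list(blocks = blocks, clinical = clinical, subjects = subjects,
                 block_params = do.call(rbind, c(bp_rows,
                                                 list(make.row.names = FALSE))),
                 design = list(n_subjects = n_subjects, effects = effects,
                               base_params = base_params, coupling = coupling,
                               rotation_rate_hz = rotation_rate_hz,
                               rotation_burst_width_ms = rotation_burst_width_ms,
                               movement_types = movement_types,
                               rng_seed = rng_seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x 4 therapy states x %d movement type(s)\n",
              x$design$n_subjects, length(x$design$movement_types)))
  cat(sprintf("  %d accelerometer blocks, %d clinical records\n",
              length(x$blocks), nrow(x$clinical)))
  invisible(x)
}

#' Write a simulated cohort to delimited text files
#'
#' Persists traces in the trace-file dialect, ground-truth events and
#' clinical records as tab-separated tables, and the generation settings as
#' a JSON sidecar for provenance.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  truth_rows <- list()
  for (key in names(cohort$blocks)) {
    blk <- cohort$blocks[[key]]
    fname <- paste0(gsub("[|]", "_", key), ".tsv")
    write_trace(blk$trace, file.path(dir, "traces", fname))
    tr <- blk$truth
    tr$block <- key
    truth_rows[[key]] <- tr
  }
  utils::write.table(do.call(rbind, truth_rows),
                     file.path(dir, "ground_truth_events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical_records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$block_params, file.path(dir, "block_params.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  design <- cohort$design
  design$base_params <- unclass(design$base_params)
  design$coupling <- unclass(design$coupling)
  design$effects <- as.data.frame(design$effects)
  jsonlite::write_json(design, file.path(dir, "simulation_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
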