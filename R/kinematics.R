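#' Per-event kinematic features
#'
#' For one confirmed movement event, computes the duration-normalized
#' acceleration magnitude (the mean of the vector magnitude over the
#' onset-offset window, i.e. the time integral divided by duration, which
#' keeps the stated unit m/s^2), the mean absolute jerk over the window
#' (m/s^3), and the event duration in ms. A per-millisecond variant
#' (integral divided by duration in ms, changing the unit) is available via
#' `normalize = "per_ms"`.
#'
#' @param mag a [scalar_series()] vector magnitude.
#' @param jerk a [scalar_series()] jerk series on the same grid.
#' @param event one-row data.frame (or list) with `onset_s`, `offset_s`,
#'   `event_index`.
#' @param normalize `"mean"` (default) or `"per_ms"`.
#' @return A one-row data.frame with `event_index`, `norm_accel_magnitude`,
#'   `jerk_mean`, `duration_ms`.
#' @export
event_features <- function(mag, jerk, event, normalize = c("mean", "per_ms")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(mag, "scalar_series"), inherits(jerk, "scalar_series"))
  fs <- mag$sampling_rate_hz
  lo <- max(1L, round(event$onset_s * fs) + 1L)
  hi <- min(length(mag$values), round(event$offset_s * fs) + 1L)
  if (hi < lo) stop("event_features: empty event window", call. = FALSE)
  dur_ms <- (event$offset_s - event$onset_s) * 1000
  if (dur_ms <= 0) stop("event_features: non-positive event duration",
                        call. = FALSE)
  m <- mean(mag$values[lo:hi])
  if (normalize == "per_ms") m <- m / dur_ms
  data.frame(event_index = event$event_index,
             norm_accel_magnitude = m,
             jerk_mean = mean(abs(jerk$values[lo:hi])),
             duration_ms = dur_ms)
}

#' Inter-movement intervals from an event set
#'
#' Successive peak-to-peak differences in ms (movement pacing; the inverse
#' of movement frequency). With fewer than two events an empty series is
#' returned with attribute `insufficient = TRUE` and a warning.
#'
#' @param events an `event_set` (or data.frame with ordered `peak_s`).
#' @return Numeric vector of length `nrow(events) - 1` in ms.
#' @export
inter_movement_intervals <- function(events) {
  if (nrow(events) < 2L) {
    warning("inter_movement_intervals: fewer than 2 events; returning empty series")
    return(structure(numeric(0), insufficient = TRUE))
  }
  diff(events$peak_s) * 1000
}

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) SD, measuring within-block
#' consistency of a kinematic metric.
#'
#' @param x numeric vector with at least 2 values and non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2L) {
    stop("coefficient_of_variation: need at least 2 values", call. = FALSE)
  }
  m <- mean(x)
  if (m == 0) stop("coefficient_of_variation: undefined for zero mean",
                   call. = FALSE)
  100 * stats::sd(x) / m
}

#' Block-level kinematic summary
#'
#' Means and coefficients of variation of the per-event acceleration
#' magnitude, inter-movement interval and jerk across one movement block.
#' The two decrement slopes are estimated across blocks by
#' [kinematic_slopes()] and filled in separately.
#'
#' @param ev_feats data.frame of per-event features (rows from
#'   [event_features()]).
#' @param imis inter-movement intervals in ms from
#'   [inter_movement_intervals()].
#' @return One-row data.frame with `accel_mean`, `accel_cv`, `imi_mean`,
#'   `imi_cv`, `jerk_mean`, `jerk_cv`, `accel_slope` (NA), `imi_slope` (NA),
#'   `n_events`.
#' @export
block_features <- function(ev_feats, imis) {
  if (nrow(ev_feats) < 2L) {
    stop("block_features: need at least 2 events", call. = FALSE)
  }
  data.frame(
    accel_mean = mean(ev_feats$norm_accel_magnitude),
    accel_cv = coefficient_of_variation(ev_feats$norm_accel_magnitude),
    imi_mean = if (length(imis)) mean(imis) else NA_real_,
    imi_cv = if (length(imis) >= 2L) coefficient_of_variation(imis) else NA_real_,
    jerk_mean = mean(ev_feats$jerk_mean),
    jerk_cv = coefficient_of_variation(ev_feats$jerk_mean),
    accel_slope = NA_real_,
    imi_slope = NA_real_,
    n_events = nrow(ev_feats)
  )
}

# z-score that maps a zero-variance vector to zeros instead of NaN
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Per-subject standardized decrement slopes
#'
#' For each therapy state x movement type group, fits a linear mixed model
#' of the z-standardized feature on the z-standardized trial number (the
#' 1-based event index) with a random intercept and random slope by
#' subject, and returns one standardized slope per subject: the fixed slope
#' plus the subject's conditional (shrunken) slope deviation. Negative
#' acceleration slopes reflect amplitude decrement over the block; positive
#' inter-movement-interval slopes reflect pacing decrement (slowing). When
#' the mixed fit is singular or fails, the group falls back to per-subject
#' ordinary least squares slopes, flagged in the `method` column.
#'
#' @param trial_table long-format data.frame with columns `subject_id`,
#'   `med_state`, `stim_state`, `movement_type`, `event_index`, and the
#'   feature column.
#' @param feature feature column name: `"norm_accel_magnitude"` or
#'   `"imi_ms"`.
#' @return data.frame with `subject_id`, `med_state`, `stim_state`,
#'   `movement_type`, `slope`, `method` (`"lme"` or `"ols"`).
#' @export
kinematic_slopes <- function(trial_table,
                             feature = c("norm_accel_magnitude", "imi_ms")) {
  feature <- match.arg(feature)
  need <- c("subject_id", "med_state", "stim_state", "movement_type",
            "event_index", feature)
  missing_cols <- setdiff(need, names(trial_table))
  if (length(missing_cols)) {
    stop(sprintf("kinematic_slopes: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dat <- trial_table[!is.na(trial_table[[feature]]), need]
  groups <- unique(dat[, c("med_state", "stim_state", "movement_type")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- dat[dat$med_state == groups$med_state[g] &
                 dat$stim_state == groups$stim_state[g] &
                 dat$movement_type == groups$movement_type[g], ]
    sub$z_y <- zscore(sub[[feature]])
    sub$z_t <- zscore(sub$event_index)
    subjects <- unique(sub$subject_id)
    slopes <- NULL
    method <- "lme"
    if (length(subjects) >= 2L && all(abs(sub$z_y) < Inf) &&
        stats::sd(sub$z_t) > 0) {
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(z_y ~ z_t + (z_t | subject_id), data = sub,
                     control = lme4::lmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
      if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
        fe <- lme4::fixef(fit)[["z_t"]]
        re <- lme4::ranef(fit)$subject_id
        slopes <- data.frame(subject_id = rownames(re),
                             slope = fe + re[["z_t"]])
      }
    }
    if (is.null(slopes)) {
      method <- "ols"
      slopes <- do.call(rbind, lapply(subjects, function(s) {
        d <- sub[sub$subject_id == s, ]
        sl <- if (nrow(d) >= 2L && stats::sd(d$event_index) > 0 &&
                  stats::sd(d[[feature]]) > 0) {
          stats::cor(d[[feature]], d$event_index)
        } else 0
        data.frame(subject_id = s, slope = sl)
      }))
    }
    slopes$med_state <- groups$med_state[g]
    slopes$stim_state <- groups$stim_state[g]
    slopes$movement_type <- groups$movement_type[g]
    slopes$method <- method
    out[[g]] <- slopes
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("subject_id", "med_state", "stim_state", "movement_type",
          "slope", "method")]
}

#' Single-trial feature table for one detected block
#'
#' Convenience wrapper running feature extraction over all events of one
#' block: per-event features plus the inter-movement interval assigned to
#' the later event of each pair (first event NA).
#'
#' @param trace an [accel_trace()] (used for preprocessing).
#' @param events an `event_set` from [detect_events()].
#' @param filter_order,filter_cutoff_hz preprocessing settings (must match
#'   detection).
#' @return data.frame with block metadata columns, `event_index`,
#'   `norm_accel_magnitude`, `jerk_mean`, `duration_ms`, `imi_ms`.
#' @export
block_trial_features <- function(trace, events, filter_order = 3L,
                                 filter_cutoff_hz = 1.0) {
  stopifnot(inherits(trace, "accel_trace"))
  filt <- highpass_filter(trace, order = filter_order,
                          cutoff_hz = filter_cutoff_hz)
  mag <- vector_magnitude(filt)
  jerk <- jerk_series(mag)
  if (nrow(events) == 0L) return(NULL)
  feats <- do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    event_features(mag, jerk, events[i, ])
  }))
  feats$imi_ms <- c(NA_real_,
                    if (nrow(events) >= 2L) diff(events$peak_s) * 1000)
  meta <- trace$meta
  cbind(data.frame(subject_id = meta$subject_id %||% NA_character_,
                   med_state = meta$med_state %||% NA_character_,
                   stim_state = meta$stim_state %||% NA_character_,
                   movement_type = meta$movement_type %||% NA_character_),
        feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
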