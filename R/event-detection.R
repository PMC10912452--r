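#' Detection configuration for the two-stage event detector
#'
#' Stage one thresholds the RMS envelope and the absolute jerk of the
#' (high-pass filtered) accelerometer vector at per-block percentiles to
#' delimit candidate movement windows; stage two confirms windows by peak
#' prominence and a minimum peak distance. Percentile presets follow the
#' movement type: 90/95 (RMS/jerk) for finger tapping, 80/85 for
#' pronation-supination rotations.
#'
#' @param movement_type `"finger_tapping"` or `"pronation_supination"`;
#'   selects the percentile preset. Ignored when both percentiles are given.
#' @param rms_percentile,jerk_percentile percentile thresholds in (0, 100).
#' @param prominence_sd peak prominence threshold as a multiple of the SD of
#'   the full-block magnitude series (default 2.5).
#' @param min_peak_distance_ms minimum spacing between confirmed peaks
#'   (default 100 ms).
#' @param merge_gap_ms candidate windows closer than this are merged
#'   (default 50 ms).
#' @param min_event_duration_ms candidate windows shorter than this are
#'   dropped (default 30 ms).
#' @param combine how the two thresholds define an active sample: `"or"`
#'   (default; a sample is active when either series exceeds its threshold)
#'   or `"and"`.
#' @param confirm_on confirm peaks on the filtered vector `"magnitude"`
#'   (default) or on its `"rms"` envelope.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(movement_type = "finger_tapping",
                             rms_percentile = NULL, jerk_percentile = NULL,
                             prominence_sd = 2.5, min_peak_distance_ms = 100,
                             merge_gap_ms = 50, min_event_duration_ms = 30,
                             combine = c("or", "and"),
                             confirm_on = c("magnitude", "rms")) {
  combine <- match.arg(combine)
  confirm_on <- match.arg(confirm_on)
  presets <- list(finger_tapping = c(90, 95), pronation_supination = c(80, 85))
  if (is.null(rms_percentile) || is.null(jerk_percentile)) {
    if (!movement_type %in% names(presets)) {
      stop(sprintf("detection_config: no preset for movement_type '%s'",
                   movement_type), call. = FALSE)
    }
    pr <- presets[[movement_type]]
    if (is.null(rms_percentile)) rms_percentile <- pr[1L]
    if (is.null(jerk_percentile)) jerk_percentile <- pr[2L]
  }
  if (rms_percentile <= 0 || rms_percentile >= 100 ||
      jerk_percentile <= 0 || jerk_percentile >= 100) {
    stop("detection_config: percentiles must be in (0, 100)", call. = FALSE)
  }
  if (prominence_sd <= 0) stop("detection_config: prominence_sd must be > 0",
                               call. = FALSE)
  if (min_peak_distance_ms < 0 || merge_gap_ms < 0 || min_event_duration_ms < 0) {
    stop("detection_config: distances must be >= 0", call. = FALSE)
  }
  structure(list(movement_type = movement_type,
                 rms_percentile = rms_percentile,
                 jerk_percentile = jerk_percentile,
                 prominence_sd = prominence_sd,
                 min_peak_distance_ms = min_peak_distance_ms,
                 merge_gap_ms = merge_gap_ms,
                 min_event_duration_ms = min_event_duration_ms,
                 combine = combine, confirm_on = confirm_on),
            class = "detection_config")
}

#' Candidate movement windows from percentile thresholds
#'
#' A sample is "active" when the RMS envelope is at or above its per-block
#' percentile threshold, or (`combine = "or"`, the default) the absolute
#' jerk is at or above its own. Maximal runs of active samples form
#' candidate windows; windows separated by less than `merge_gap_ms` are
#' merged, and windows shorter than `min_event_duration_ms` are dropped.
#' Percentiles use the linear-interpolation definition (R type 7).
#'
#' @param rms a [scalar_series()] RMS envelope.
#' @param jerk a [scalar_series()] jerk series of the same length.
#' @param config a [detection_config()].
#' @return A data.frame with columns `onset_s`, `offset_s` (sample times of
#'   the first/last active sample in each window).
#' @export
candidate_windows <- function(rms, jerk, config) {
  stopifnot(inherits(rms, "scalar_series"), inherits(jerk, "scalar_series"),
            inherits(config, "detection_config"))
  x <- rms$values
  j <- abs(jerk$values)
  if (length(x) == 0L) stop("candidate_windows: empty series", call. = FALSE)
  if (length(x) != length(j)) {
    stop("candidate_windows: rms and jerk must have equal length", call. = FALSE)
  }
  fs <- rms$sampling_rate_hz
  t_rms <- stats::quantile(x, config$rms_percentile / 100, names = FALSE,
                           type = 7)
  t_jerk <- stats::quantile(j, config$jerk_percentile / 100, names = FALSE,
                            type = 7)
  # strictly above threshold, so a constant (e.g. all-zero) block has no
  # active samples; for continuous-valued data this is a.s. identical to >=
  active <- if (config$combine == "or") (x > t_rms | j > t_jerk)
            else (x > t_rms & j > t_jerk)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  if (length(on) == 0L) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  }
  # merge windows separated by < merge_gap_ms
  gap_samples <- config$merge_gap_ms / 1000 * fs
  if (length(on) > 1L) {
    keep_start <- c(TRUE, (on[-1L] - off[-length(off)] - 1L) >= gap_samples)
    grp <- cumsum(keep_start)
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  dur_ok <- (off - on + 1L) / fs * 1000 >= config$min_event_duration_ms
  on <- on[dur_ok]; off <- off[dur_ok]
  data.frame(onset_s = (as.numeric(on) - 1) / fs,
             offset_s = (as.numeric(off) - 1) / fs)
}

#' Local maxima with topographic prominence
#'
#' Finds samples strictly greater than both neighbours and computes each
#' peak's topographic prominence: its height above the higher of the two
#' lowest points separating it from higher ground (or the series edge) on
#' either side.
#'
#' @param x numeric vector.
#' @return data.frame with `index`, `height`, `prominence`.
#' @export
find_local_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    h <- x[i]
    jl <- i - 1L; lmin <- x[jl]
    while (jl >= 1L && x[jl] <= h) { if (x[jl] < lmin) lmin <- x[jl]; jl <- jl - 1L }
    jr <- i + 1L; rmin <- x[jr]
    while (jr <= n && x[jr] <= h) { if (x[jr] < rmin) rmin <- x[jr]; jr <- jr + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

# Greedy retention of peaks under a minimum-distance rule: tallest first,
# ties broken by earlier index.
enforce_min_distance <- function(peaks, min_dist_samples) {
  if (nrow(peaks) <= 1L || min_dist_samples <= 0) return(peaks)
  ord <- order(-peaks$height, peaks$index)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(peaks$index[i] - peaks$index[kept]) >= min_dist_samples)) {
      kept <- c(kept, i)
    }
  }
  out <- peaks[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirm candidate windows by peak prominence and spacing
#'
#' Finds peaks of the magnitude series with topographic prominence of at
#' least `prominence_sd` times the SD of the full-block series, thins them
#' greedily (tallest first) to satisfy the minimum peak distance, and keeps
#' each candidate window that contains at least one surviving peak. Each
#' kept window becomes one movement event whose peak is the highest
#' confirmed peak inside it.
#'
#' @param mag a [scalar_series()] (vector magnitude, or RMS envelope when
#'   configured so).
#' @param windows data.frame from [candidate_windows()].
#' @param config a [detection_config()].
#' @return An `event_set`: data.frame with columns `event_index`, `onset_s`,
#'   `peak_s`, `offset_s`, `peak_magnitude`; the config is attached as an
#'   attribute.
#' @export
confirm_events <- function(mag, windows, config) {
  stopifnot(inherits(mag, "scalar_series"), inherits(config, "detection_config"))
  x <- mag$values
  fs <- mag$sampling_rate_hz
  if (is.unsorted(windows$onset_s)) {
    stop("confirm_events: windows must be time-ordered", call. = FALSE)
  }
  prom_thr <- config$prominence_sd * stats::sd(x)
  peaks <- find_local_peaks(x)
  peaks <- peaks[peaks$prominence >= prom_thr, , drop = FALSE]
  peaks <- enforce_min_distance(peaks, config$min_peak_distance_ms / 1000 * fs)
  ev <- list()
  for (w in seq_len(nrow(windows))) {
    lo <- windows$onset_s[w]; hi <- windows$offset_s[w]
    tpk <- (peaks$index - 1L) / fs
    inside <- which(tpk >= lo & tpk <= hi)
    if (length(inside) == 0L) next
    best <- inside[which.max(peaks$height[inside])]
    ev[[length(ev) + 1L]] <- data.frame(
      onset_s = lo, peak_s = (peaks$index[best] - 1L) / fs, offset_s = hi,
      peak_magnitude = peaks$height[best])
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(onset_s = numeric(0), peak_s = numeric(0),
               offset_s = numeric(0), peak_magnitude = numeric(0))
  out <- out[order(out$peak_s), , drop = FALSE]
  out <- cbind(event_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("event_set", "data.frame"), config = config)
}

#' Detect movement events in an accelerometer block
#'
#' Full two-stage detector: zero-phase Butterworth high-pass (order 3, 1 Hz),
#' vector magnitude, RMS envelope and jerk, percentile-threshold candidate
#' windows, then prominence/spacing confirmation. The percentile preset is
#' chosen from `trace$meta$movement_type` unless a config is supplied.
#' The candidate-stage jerk is the first difference of the vector
#' magnitude, so its upper percentiles select genuine burst flanks only
#' when the movement's jerk exceeds the differentiated-noise floor
#' (noise SD times sampling rate over sqrt(2)); see the methods vignette
#' for the implications at low SNR.
#'
#' @param trace an [accel_trace()].
#' @param config optional [detection_config()]; default uses the trace's
#'   movement-type preset.
#' @param filter_order,filter_cutoff_hz preprocessing filter settings.
#' @param rms_window_ms RMS envelope window (default 50 ms).
#' @return An `event_set` (see [confirm_events()]) with the block metadata
#'   attached as attribute `meta`.
#' @export
detect_events <- function(trace, config = NULL, filter_order = 3L,
                          filter_cutoff_hz = 1.0, rms_window_ms = 50) {
  stopifnot(inherits(trace, "accel_trace"))
  if (is.null(config)) {
    mt <- trace$meta$movement_type
    if (is.null(mt)) mt <- "finger_tapping"
    config <- detection_config(movement_type = mt)
  }
  filt <- highpass_filter(trace, order = filter_order,
                          cutoff_hz = filter_cutoff_hz)
  mag <- vector_magnitude(filt)
  rms <- rms_envelope(mag, window_ms = rms_window_ms)
  jerk <- jerk_series(mag)
  windows <- candidate_windows(rms, jerk, config)
  confirm_series <- if (config$confirm_on == "rms") rms else mag
  ev <- confirm_events(confirm_series, windows, config)
  attr(ev, "meta") <- trace$meta
  ev
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching of detected peak times to ground-truth peak
#' times within a tolerance, used by the detection benchmark.
#'
#' @param detected an `event_set` (or data.frame with `peak_s`).
#' @param truth data.frame with `peak_s` (e.g. from [simulate_block()]).
#' @param tol_ms matching tolerance in ms (default 30).
#' @return List with `n_matched`, `sensitivity` (matched / truth events) and
#'   `ppv` (matched / detected events).
#' @export
match_events <- function(detected, truth, tol_ms = 30) {
  dp <- detected$peak_s
  tp <- truth$peak_s
  used <- rep(FALSE, length(dp))
  n_matched <- 0L
  for (tt in tp) {
    cand <- which(!used & abs(dp - tt) <= tol_ms / 1000)
    if (length(cand)) {
      used[cand[which.min(abs(dp[cand] - tt))]] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  list(n_matched = n_matched,
       sensitivity = if (length(tp)) n_matched / length(tp) else NA_real_,
       ppv = if (length(dp)) n_matched / length(dp) else NA_real_)
}
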