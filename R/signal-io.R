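#' Construct a triaxial accelerometer trace
#'
#' An `accel_trace` holds one movement block: a uniform time grid and three
#' acceleration channels in m/s^2, plus block metadata (subject, movement
#' type, therapy state, hand).
#'
#' @param time numeric vector of sample times in seconds, strictly increasing
#'   on a uniform grid of step `1/sampling_rate_hz` (tolerance 1e-6 s).
#' @param ax,ay,az acceleration channels in m/s^2, same length as `time`.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param meta named list with any of `subject_id`, `movement_type`
#'   (`"finger_tapping"` or `"pronation_supination"`), `med_state`,
#'   `stim_state` (`"ON"`/`"OFF"`), `hand`.
#' @return An object of class `accel_trace`.
#' @export
accel_trace <- function(time, ax, ay, az, sampling_rate_hz, meta = list()) {
  n <- length(time)
  if (n < 2L) stop("accel_trace: need at least 2 samples", call. = FALSE)
  lens <- c(length(ax), length(ay), length(az))
  if (any(lens != n)) {
    stop(sprintf("accel_trace: channel lengths (%s) differ from time length %d",
                 paste(lens, collapse = ", "), n), call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("accel_trace: sampling_rate_hz must be a positive scalar", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("accel_trace: time must be strictly increasing", call. = FALSE)
  if (any(abs(dt - 1 / sampling_rate_hz) > 1e-6)) {
    stop("accel_trace: non-uniform time grid (step must be 1/sampling_rate_hz to 1e-6 s)",
         call. = FALSE)
  }
  known_mt <- c("finger_tapping", "pronation_supination")
  if (!is.null(meta$movement_type) && !meta$movement_type %in% known_mt) {
    stop(sprintf("accel_trace: unknown movement_type '%s'", meta$movement_type),
         call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), ax = as.numeric(ax), ay = as.numeric(ay),
         az = as.numeric(az), sampling_rate_hz = as.numeric(sampling_rate_hz),
         meta = meta),
    class = "accel_trace"
  )
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$time), x$sampling_rate_hz,
              length(x$time) / x$sampling_rate_hz))
  m <- x$meta
  if (length(m)) {
    cat("  meta:", paste(names(m), unlist(m), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a scalar series derived from a trace
#'
#' Holds per-sample scalar derivations of an accelerometer block: the vector
#' magnitude (m/s^2), its RMS envelope (m/s^2), or jerk (m/s^3), all on the
#' same sampling grid as the parent trace.
#'
#' @param values numeric vector.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param units unit string, e.g. `"m/s^2"` or `"m/s^3"`.
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values, sampling_rate_hz, units = "m/s^2") {
  if (!is.numeric(values)) stop("scalar_series: values must be numeric", call. = FALSE)
  structure(list(values = as.numeric(values),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 units = units),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d samples @ %g Hz [%s]\n",
              length(x$values), x$sampling_rate_hz, x$units))
  invisible(x)
}

# --- trace file dialect -----------------------------------------------------
# Plain delimited text. Header lines start with "#" and carry key=value
# metadata (sampling_rate_hz is mandatory); then a column-name line and
# tab-separated columns time_s, ax, ay, az.

#' Write an accelerometer trace to a delimited text file
#'
#' @param trace an [accel_trace()].
#' @param path output file path.
#' @param digits significant digits used for formatting (default 12, which
#'   round-trips doubles of this dynamic range to well below 1e-9).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, digits = 12L) {
  stopifnot(inherits(trace, "accel_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", trace$sampling_rate_hz), con)
  for (key in names(trace$meta)) {
    writeLines(sprintf("# %s=%s", key, as.character(trace$meta[[key]])), con)
  }
  writeLines("time_s\tax\tay\taz", con)
  fmt <- sprintf("%%.%dg", digits)
  rows <- sprintf(paste(fmt, fmt, fmt, fmt, sep = "\t"),
                  trace$time, trace$ax, trace$ay, trace$az)
  writeLines(rows, con)
  invisible(path)
}

#' Read an accelerometer trace from a delimited text file
#'
#' Parses the dialect written by [write_trace()]: "#"-prefixed key=value
#' header lines followed by tab-separated `time_s`, `ax`, `ay`, `az` columns.
#'
#' @param path input file path.
#' @return An [accel_trace()] with metadata parsed from the header.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_trace: no such file '%s'", path),
                               call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
    }
  }
  if (is.null(meta$sampling_rate_hz)) {
    stop("read_trace: header lacks sampling_rate_hz", call. = FALSE)
  }
  fs <- as.numeric(meta$sampling_rate_hz)
  meta$sampling_rate_hz <- NULL
  body <- lines[setdiff(seq_along(lines), hdr)]
  body <- body[nzchar(body)]
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("time_s", "ax", "ay", "az")
  missing_cols <- setdiff(need, cols)
  if (length(missing_cols)) {
    stop(sprintf("read_trace: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dat <- utils::read.table(text = body[-1L], sep = "\t", col.names = cols,
                           colClasses = "numeric")
  accel_trace(dat$time_s, dat$ax, dat$ay, dat$az, sampling_rate_hz = fs,
              meta = meta)
}

# --- Butterworth high-pass (zero-phase) -------------------------------------

# Polynomial coefficients (descending powers) from roots, real part taken.
poly_from_roots <- function(r) {
  coefs <- c(1 + 0i)
  for (root in r) coefs <- c(coefs, 0i) - c(0i, coefs * root)
  Re(coefs)
}

# Digital Butterworth high-pass via analog prototype + bilinear transform.
# Returns list(b, a), a[1] == 1.
butter_highpass_coef <- function(order, cutoff_hz, fs) {
  if (cutoff_hz >= fs / 2) {
    stop("butter_highpass: cutoff_hz must be below the Nyquist frequency",
         call. = FALSE)
  }
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # |p| = 1, Re < 0
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)              # prewarped rad/s
  p_hp <- warped / p_lp                                    # s -> warped/s
  z_hp <- rep(0 + 0i, order)
  # prototype has no zeros; lp->hp gain factor Re(prod(-z)/prod(-p)) = 1
  fs2 <- 2 * fs
  p_d <- (fs2 + p_hp) / (fs2 - p_hp)
  z_d <- (fs2 + z_hp) / (fs2 - z_hp)
  k_d <- Re(prod(fs2 - z_hp) / prod(fs2 - p_hp))
  b <- k_d * poly_from_roots(z_d)
  a <- poly_from_roots(p_d)
  list(b = b / a[1L], a = a / a[1L])
}

# Direct-form II transposed IIR filter with initial state zi (length
# length(a)-1). Returns the filtered signal.
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- length(a)
  z <- if (is.null(zi)) numeric(nfilt - 1L) else as.numeric(zi)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    for (j in seq_len(nfilt - 2L)) {
      z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    }
    z[nfilt - 1L] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial conditions for a unit step input (lfilter_zi).
filter_zi <- function(b, a) {
  n <- length(a)
  A <- diag(1, n - 1L)
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(A - t(comp), B)
}

# Zero-phase filtering: forward-backward pass with odd-extension padding and
# steady-state initial conditions, as in the common filtfilt formulation.
filtfilt_hp <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 4L)
  ext <- c(2 * x[1L] - x[(padlen + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1L])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' High-pass filter an accelerometer trace (zero phase)
#'
#' Applies a Butterworth high-pass filter to each axis, forward and backward
#' (zero-phase), so that event onset and peak timing is not biased by filter
#' delay. Note that the two passes square the magnitude response, doubling
#' the stop-band attenuation in dB and moving the effective -3 dB point
#' slightly above the design cutoff.
#'
#' @param trace an [accel_trace()].
#' @param order filter order (default 3).
#' @param cutoff_hz cutoff frequency in Hz (default 1); must be below Nyquist.
#' @return A filtered [accel_trace()] of the same length.
#' @export
highpass_filter <- function(trace, order = 3L, cutoff_hz = 1.0) {
  stopifnot(inherits(trace, "accel_trace"))
  fs <- trace$sampling_rate_hz
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("highpass_filter: cutoff_hz = %g is not below Nyquist (%g Hz)",
                 cutoff_hz, fs / 2), call. = FALSE)
  }
  co <- butter_highpass_coef(order, cutoff_hz, fs)
  out <- trace
  out$ax <- filtfilt_hp(co$b, co$a, trace$ax)
  out$ay <- filtfilt_hp(co$b, co$a, trace$ay)
  out$az <- filtfilt_hp(co$b, co$a, trace$az)
  out
}

#' Per-sample vector magnitude of a trace
#'
#' @param trace an [accel_trace()].
#' @return A [scalar_series()] with `sqrt(ax^2 + ay^2 + az^2)` in m/s^2.
#' @export
vector_magnitude <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  scalar_series(sqrt(trace$ax^2 + trace$ay^2 + trace$az^2),
                trace$sampling_rate_hz, units = "m/s^2")
}

#' Jerk (rate of change of acceleration) of a magnitude series
#'
#' Central first difference scaled by the sampling rate; one-sided
#' differences at the endpoints. Output is on the same grid as the input.
#'
#' @param mag a [scalar_series()] of acceleration magnitude (m/s^2).
#' @return A [scalar_series()] in m/s^3.
#' @export
jerk_series <- function(mag) {
  stopifnot(inherits(mag, "scalar_series"))
  x <- mag$values
  n <- length(x)
  if (n < 2L) stop("jerk_series: need at least 2 samples", call. = FALSE)
  fs <- mag$sampling_rate_hz
  j <- numeric(n)
  if (n > 2L) j[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  j[1L] <- (x[2L] - x[1L]) * fs
  j[n] <- (x[n] - x[n - 1L]) * fs
  scalar_series(j, fs, units = "m/s^3")
}

#' Centered sliding-window RMS envelope
#'
#' Root mean square over a centered window; windows are truncated at the
#' series edges so the output has the same length as the input. A window of
#' one sample returns `abs(x)`.
#'
#' @param mag a [scalar_series()].
#' @param window_ms window length in milliseconds (default 50).
#' @return A [scalar_series()] of the same length and units.
#' @export
rms_envelope <- function(mag, window_ms = 50) {
  stopifnot(inherits(mag, "scalar_series"))
  x <- mag$values
  n <- length(x)
  fs <- mag$sampling_rate_hz
  w <- max(1L, round(window_ms / 1000 * fs))
  if (w > n) {
    stop(sprintf("rms_envelope: window (%d samples) longer than series (%d)",
                 w, n), call. = FALSE)
  }
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  scalar_series(sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)), fs,
                units = mag$units)
}

#' Flag clipped samples in a trace
#'
#' Automated stand-in for visual artifact screening: marks a block whose
#' acceleration exceeds an absolute bound on any axis (sensor saturation).
#'
#' @param trace an [accel_trace()].
#' @param max_abs absolute clip bound in m/s^2 (default 50).
#' @return Logical scalar with attribute `n_clipped` (number of samples over
#'   the bound).
#' @export
flag_clipped <- function(trace, max_abs = 50) {
  stopifnot(inherits(trace, "accel_trace"))
  n_clip <- sum(abs(trace$ax) > max_abs | abs(trace$ay) > max_abs |
                  abs(trace$az) > max_abs)
  structure(n_clip > 0L, n_clipped = n_clip)
}
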