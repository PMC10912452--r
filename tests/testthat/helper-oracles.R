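# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive each quantity with the most naive correct
# algorithm, sharing no code with the implementation under test.

# naive per-sample windowed RMS, O(n * w)
oracle_rms <- function(x, w) {
  n <- length(x)
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_l); hi <- min(n, i + half_r)
    sqrt(mean(x[lo:hi]^2))
  }, numeric(1))
}

# independent central-difference jerk
oracle_jerk <- function(x, fs) {
  n <- length(x)
  j <- numeric(n)
  for (i in seq_len(n)) {
    j[i] <- if (i == 1L) (x[2L] - x[1L]) * fs
    else if (i == n) (x[n] - x[n - 1L]) * fs
    else (x[i + 1L] - x[i - 1L]) * fs / 2
  }
  j
}

# independent active-sample scan + run merge + duration filter
oracle_windows <- function(rms, jerk, fs, rms_pct, jerk_pct, merge_gap_ms,
                           min_dur_ms, combine = "or") {
  t_rms <- as.numeric(stats::quantile(rms, rms_pct / 100, type = 7))
  t_jerk <- as.numeric(stats::quantile(abs(jerk), jerk_pct / 100, type = 7))
  active <- if (combine == "or") rms > t_rms | abs(jerk) > t_jerk
            else rms > t_rms & abs(jerk) > t_jerk
  runs <- list()
  i <- 1L; n <- length(active)
  while (i <= n) {
    if (active[i]) {
      j <- i
      while (j < n && active[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(onset_s = numeric(0),
                                       offset_s = numeric(0)))
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    if ((r[1L] - last[2L] - 1L) < merge_gap_ms / 1000 * fs) {
      merged[[length(merged)]] <- c(last[1L], r[2L])
    } else merged[[length(merged) + 1L]] <- r
  }
  keep <- Filter(function(r) (r[2L] - r[1L] + 1L) / fs * 1000 >= min_dur_ms,
                 merged)
  data.frame(onset_s = vapply(keep, function(r) (r[1L] - 1L) / fs, 0),
             offset_s = vapply(keep, function(r) (r[2L] - 1L) / fs, 0))
}

# exhaustive topographic prominence: for every strict local maximum, walk
# out to the nearest strictly higher sample on each side and take the
# minimum of the intervening samples (series edge if no higher ground)
oracle_prominence <- function(x) {
  n <- length(x)
  out <- list()
  for (i in seq(2L, n - 1L)) {
    if (!(x[i] > x[i - 1L] && x[i] > x[i + 1L])) next
    left_higher <- which(x[seq_len(i - 1L)] > x[i])
    lo_l <- if (length(left_higher)) max(left_higher) + 1L else 1L
    lmin <- min(x[lo_l:(i - 1L)])
    right_higher <- which(x[seq(i + 1L, n)] > x[i]) + i
    hi_r <- if (length(right_higher)) min(right_higher) - 1L else n
    rmin <- min(x[(i + 1L):hi_r])
    out[[length(out) + 1L]] <- data.frame(index = i, height = x[i],
                                          prominence = x[i] - max(lmin, rmin))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(index = integer(0), height = numeric(0),
               prominence = numeric(0))
}

# classical Tukey HSD from group means and the pooled MSE (balanced layout)
oracle_tukey_hsd <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  ns <- tapply(y, g, length)
  stopifnot(length(unique(ns)) == 1L)
  n <- ns[[1L]]
  means <- tapply(y, g, mean)
  mse <- sum((y - ave(y, g))^2) / (length(y) - k)
  df <- length(y) - k
  pairs <- utils::combn(k, 2L)
  data.frame(
    contrast = apply(pairs, 2L, function(p) paste(levels(g)[p[1L]], "-",
                                                  levels(g)[p[2L]])),
    estimate = apply(pairs, 2L, function(p) means[p[1L]] - means[p[2L]]),
    p_adj = apply(pairs, 2L, function(p) {
      q <- abs(means[p[1L]] - means[p[2L]]) / sqrt(mse / n)
      stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }))
}

# two-pass CV evaluation
oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  100 * sqrt(sum((x - m)^2) / (length(x) - 1)) / m
}

# single-factor data generator: x_j = lambda_j * f + sqrt(1 - lambda_j^2) e_j
gen_factor_data <- function(n, lambdas, names = NULL) {
  f <- stats::rnorm(n)
  x <- vapply(lambdas, function(l) l * f + sqrt(1 - l^2) * stats::rnorm(n),
              numeric(n))
  colnames(x) <- if (is.null(names)) sprintf("f%02d", seq_along(lambdas))
                 else names
  x
}

# small noise-only trace
gen_noise_trace <- function(n = 4000, fs = 1000, sd = 0.5,
                            movement_type = "finger_tapping") {
  accel_trace((seq_len(n) - 1L) / fs, stats::rnorm(n, 0, sd),
              stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd), fs,
              meta = list(movement_type = movement_type))
}

# minimal clinical record data.frame builder (defaults all zeros)
gen_clinical <- function(n = 1L, ...) {
  cols <- c(paste0("item3_", 4:8, "_right"), paste0("item3_", 4:8, "_left"),
            "item3_14", paste0("item3_", 15:18))
  rec <- as.data.frame(matrix(0L, nrow = n, ncol = length(cols),
                              dimnames = list(NULL, cols)))
  over <- list(...)
  for (k in names(over)) rec[[k]] <- over[[k]]
  rec
}
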