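## Time- and frequency-domain feature battery, computed per window on the
## low-pass-filtered channels. 19 time-domain features x 3 channels = 57,
## 4 frequency-domain features x 3 channels = 12.

## The 19 time-domain feature names. The published feature list enumerates 18
## distinct names while counting 19 per channel; the 19th is taken to be the
## mean absolute value, which appears throughout the reported component
## loadings. Isolated here so the convention lives in one place.
TIME_FEATURE_NAMES <- c(
  "crosscorr", "mean_diff", "variance", "local_min_count", "local_max_count",
  "peak", "minimum",
  "p1", "p10", "p25", "p50", "p75", "p90", "p99",
  "zero_crossings", "mean", "mean_abs", "rms", "jerk"
)

FREQ_FEATURE_NAMES <- c("freq1", "freq2", "amp1", "amp2")

PERCENTILE_LEVELS <- c(1, 10, 25, 50, 75, 90, 99) / 100

## Count of strict local maxima/minima (plateaus counted once).
local_extrema_count <- function(x, maxima = TRUE) {
  s <- sign(diff(x))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) == if (maxima) -2 else 2)
}

## Sign changes of the mean-centered signal, exact zeros skipped.
zero_crossing_count <- function(x) {
  s <- sign(x - mean(x))
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Time-domain features of one window (57 values)
#'
#' Computes, per channel, the 19 time-domain features of the battery on the
#' filtered samples: the cross-correlation coefficient and mean difference of
#' the cyclically paired channels (X vs Y, Y vs Z, Z vs X), variance, local
#' minima and maxima counts, peak, minimum, amplitude percentiles
#' (1/10/25/50/75/90/99), zero crossings about the window mean, mean, mean
#' absolute value, RMS, and jerk (mean absolute first difference times the
#' sampling rate). A constant channel yields a cross-correlation of 0
#' (flagged) rather than NaN.
#'
#' @param window A `sib_window`.
#' @return Named numeric vector of length 57 (`<feature>_<channel>`).
#' @export
time_domain_features <- function(window) {
  stopifnot(inherits(window, "sib_window"))
  x <- window$filtered
  if (nrow(x) < 2) stop("window must contain at least 2 samples", call. = FALSE)
  flags <- character(0)
  out <- numeric(0)
  for (ci in seq_along(CHANNELS)) {
    ch <- CHANNELS[ci]
    v <- x[, ci]
    pi2 <- match(CHANNEL_PAIR[[ch]], CHANNELS)
    v2 <- x[, pi2]
    if (stats::sd(v) == 0 || stats::sd(v2) == 0) {
      cc <- 0
      flags <- c(flags, paste0("constant_channel_", ch))
    } else {
      cc <- stats::cor(v, v2)
    }
    q <- unname(stats::quantile(v, PERCENTILE_LEVELS))
    vals <- c(
      crosscorr = cc,
      mean_diff = mean(v - v2),
      variance = stats::var(v),
      local_min_count = local_extrema_count(v, maxima = FALSE),
      local_max_count = local_extrema_count(v, maxima = TRUE),
      peak = max(v),
      minimum = min(v),
      p1 = q[1], p10 = q[2], p25 = q[3], p50 = q[4],
      p75 = q[5], p90 = q[6], p99 = q[7],
      zero_crossings = zero_crossing_count(v),
      mean = mean(v),
      mean_abs = mean(abs(v)),
      rms = sqrt(mean(v^2)),
      jerk = mean(abs(diff(v))) * window$rate_hz
    )
    names(vals) <- paste0(TIME_FEATURE_NAMES, "_", ch)
    out <- c(out, vals)
  }
  if (length(flags)) out <- set_flag(out, flags)
  out
}

## Indices of local maxima of a magnitude spectrum (DC already excluded);
## boundary bins qualify against their single neighbor; ties resolved toward
## the lower frequency by the stable ordering downstream.
spectral_peaks <- function(mag) {
  n <- length(mag)
  if (n == 1) return(1L)
  left <- c(-Inf, mag[-n])
  right <- c(mag[-1], -Inf)
  which(mag >= left & mag >= right & (mag > left | mag > right))
}

#' Frequency-domain features of one window (12 values)
#'
#' Per channel, the magnitude spectrum of the mean-removed filtered window is
#' scanned for its two largest local maxima (DC excluded, ties broken toward
#' the lower frequency); the corresponding frequencies and amplitudes give
#' `freq1`, `freq2`, `amp1`, `amp2`, ordered by descending amplitude. When
#' fewer than two peaks exist (e.g. a constant window) the missing slots are
#' 0 and the result is flagged.
#'
#' @param window A `sib_window`.
#' @return Named numeric vector of length 12 (`<feature>_<channel>`).
#' @export
frequency_domain_features <- function(window) {
  stopifnot(inherits(window, "sib_window"))
  x <- window$filtered
  w <- nrow(x)
  if (w < 4) stop("window must contain at least 4 samples", call. = FALSE)
  nb <- floor(w / 2)
  freqs <- (1:nb) * window$rate_hz / w
  flags <- character(0)
  out <- numeric(0)
  for (ci in seq_along(CHANNELS)) {
    ch <- CHANNELS[ci]
    v <- x[, ci] - mean(x[, ci])
    vals <- c(freq1 = 0, freq2 = 0, amp1 = 0, amp2 = 0)
    if (stats::sd(v) > 0) {
      mag <- Mod(stats::fft(v))[2:(nb + 1)]   # drop DC
      pk <- spectral_peaks(mag)
      if (length(pk)) {
        ## stable order: descending amplitude, ties toward lower frequency
        pk <- pk[order(-mag[pk], pk)]
        vals["freq1"] <- freqs[pk[1]]
        vals["amp1"] <- 2 * mag[pk[1]] / w
        if (length(pk) >= 2) {
          vals["freq2"] <- freqs[pk[2]]
          vals["amp2"] <- 2 * mag[pk[2]] / w
        } else {
          flags <- c(flags, paste0("single_spectral_peak_", ch))
        }
      } else {
        flags <- c(flags, paste0("no_spectral_peak_", ch))
      }
    } else {
      flags <- c(flags, paste0("constant_channel_", ch))
    }
    names(vals) <- paste0(FREQ_FEATURE_NAMES, "_", ch)
    out <- c(out, vals)
  }
  if (length(flags)) out <- set_flag(out, flags)
  out
}

#' All linear (time + frequency) features of one window (69 values)
#'
#' @param window A `sib_window`.
#' @return Named numeric vector of length 69.
#' @export
linear_features <- function(window) {
  td <- time_domain_features(window)
  fd <- frequency_domain_features(window)
  out <- c(unclass(td), unclass(fd))
  flags <- c(get_flags(td), get_flags(fd))
  if (length(flags)) out <- set_flag(out, flags)
  out
}
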