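#' Inter-beat intervals from an R-peak train
#'
#' @param timestamps Strictly increasing R-peak times in seconds (an
#'   `rpeak_train` or plain numeric vector).
#' @return Numeric vector of consecutive intervals (length n - 1); empty if
#'   fewer than two peaks.
#' @export
intervals_from_rpeaks <- function(timestamps) {
  ts <- as.numeric(timestamps)
  if (length(ts) < 2) return(numeric(0))
  if (any(diff(ts) <= 0)) stop("R-peak timestamps must be strictly increasing")
  diff(ts)
}

#' Artifact correction of inter-beat intervals within one epoch
#'
#' Two single-pass rules, applied left to right within an epoch:
#' \itemize{
#'   \item an interval below 0.33 s (heart rate above ~180 bpm, usually a
#'     spurious detection) is replaced by the midpoint (arithmetic mean) of
#'     that interval and the previous interval;
#'   \item an interval above 1.33 s (below ~46 bpm, usually a missed beat) is
#'     split uniformly into `n = max(1, round(T / T_mean))` equal
#'     sub-intervals of length `T/n`, where `T_mean` is the mean of the
#'     epoch's raw intervals.
#' }
#' A first interval with no predecessor falls back to the epoch mean in the
#' short-interval rule.
#'
#' @param intervals Numeric vector of raw intervals for one epoch (s).
#' @param short_s,long_s Rule thresholds; defaults 0.33 and 1.33 s.
#' @return Numeric vector of corrected intervals (possibly longer than the
#'   input when long intervals are split).
#' @export
correct_intervals <- function(intervals, short_s = 0.33, long_s = 1.33) {
  if (!length(intervals)) return(numeric(0))
  if (any(intervals <= 0)) stop("intervals must be positive")
  t_mean <- mean(intervals)
  out <- vector("list", length(intervals))
  prev <- NA_real_
  for (i in seq_along(intervals)) {
    T <- intervals[i]
    if (T < short_s) {
      ref <- if (is.na(prev)) t_mean else prev
      val <- (T + ref) / 2
      out[[i]] <- val
      prev <- val
    } else if (T > long_s) {
      n <- max(1, floor(T / t_mean + 0.5))  # round half up
      out[[i]] <- rep(T / n, n)
      prev <- T / n
    } else {
      out[[i]] <- T
      prev <- T
    }
  }
  unlist(out, use.names = FALSE)
}

#' Epoch HRM/HRSD with two-standard-deviation outlier rejection
#'
#' Computes mean and sample SD of the epoch's IHR values, discards values
#' outside mean +/- 2 SD in a single pass, and recomputes mean and SD on the
#' survivors. A single value yields that value with SD 0.
#'
#' @param ihr Instantaneous heart-rate values for one epoch (bpm).
#' @return Named numeric `c(hrm=, hrsd=)`; both NA for an empty epoch.
#' @export
epoch_hr_stats <- function(ihr) {
  ihr <- ihr[!is.na(ihr)]
  if (!length(ihr)) return(c(hrm = NA_real_, hrsd = NA_real_))
  if (length(ihr) == 1) return(c(hrm = ihr, hrsd = 0))
  m <- mean(ihr); s <- sd(ihr)
  keep <- abs(ihr - m) <= 2 * s
  ihr <- ihr[keep]
  if (!length(ihr)) return(c(hrm = NA_real_, hrsd = NA_real_))
  c(hrm = mean(ihr), hrsd = if (length(ihr) > 1) sd(ihr) else 0)
}

#' Per-epoch HRM/HRSD from an R-peak train
#'
#' The full cardiac preprocessing chain: intervals from consecutive R-peaks,
#' epoch assignment by the time of the terminating peak (half-open 30-s
#' windows), per-epoch artifact interval correction, conversion to IHR
#' (60 / interval, bpm), and two-SD outlier rejection.
#'
#' @param train An `rpeak_train` or numeric timestamp vector (s).
#' @param n_epochs Number of epochs to produce; default: derived from the
#'   train's `duration_s` attribute or the last timestamp.
#' @param epoch_s Epoch duration, seconds.
#' @return data.frame with columns `epoch` (1-based), `hrm`, `hrsd`
#'   (NA where the epoch holds no beats).
#' @export
ihr_from_rpeaks <- function(train, n_epochs = NULL, epoch_s = 30) {
  ts <- as.numeric(train)
  if (is.null(n_epochs)) {
    dur <- attr(train, "duration_s") %||% max(ts)
    n_epochs <- ceiling(dur / epoch_s)
  }
  iv <- intervals_from_rpeaks(ts)
  ep <- 1L + floor(ts[-1] / epoch_s)        # epoch of the terminating peak
  ep[ep > n_epochs] <- n_epochs
  hrm <- rep(NA_real_, n_epochs); hrsd <- rep(NA_real_, n_epochs)
  for (e in unique(ep)) {
    corrected <- correct_intervals(iv[ep == e])
    st <- epoch_hr_stats(60 / corrected)
    hrm[e] <- st[["hrm"]]; hrsd[e] <- st[["hrsd"]]
  }
  data.frame(epoch = seq_len(n_epochs), hrm = hrm, hrsd = hrsd)
}

#' Upsample 60-s activity counts to 30-s epochs
#'
#' Each 60-s count is replicated into two adjacent 30-s epochs, matching the
#' resolution of the PSG labels and cardiac channels.
#'
#' @param counts Numeric vector of 60-s activity counts.
#' @return Numeric vector of length `2 * length(counts)`.
#' @export
upsample_activity <- function(counts) {
  if (!length(counts)) return(numeric(0))
  rep(counts, each = 2L)
}

#' Convert raw z-axis accelerometry to activity counts
#'
#' Band-pass filters the z-component to remove the gravitational rotation
#' signal, quantises the absolute filtered amplitude into 128 uniform bins
#' over `[0, max_g]`, and sums the bin indices over each 15-s window to give
#' one count per 15-s epoch. Band edges and `max_g` are configurable since
#' devices differ.
#'
#' @param z Numeric vector of z-axis acceleration samples (g).
#' @param fs Sampling rate, Hz; must exceed twice the upper band edge.
#' @param band Passband in Hz; default `c(0.5, 3.5)` covers voluntary limb
#'   movement while rejecting DC/gravity.
#' @param order Butterworth filter order (default 4).
#' @param max_g Full-scale amplitude for binning (default 2 g).
#' @param window_s Aggregation window, seconds (default 15).
#' @return Numeric vector of counts, one per complete window; empty if the
#'   signal is shorter than one window.
#' @export
accel_to_counts <- function(z, fs, band = c(0.5, 3.5), order = 4,
                            max_g = 2, window_s = 15) {
  stopifnot(fs > 2 * band[2], band[1] > 0, band[1] < band[2])
  spw <- as.integer(round(window_s * fs))
  if (length(z) < spw) return(numeric(0))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  f <- signal::filtfilt(bf, z - mean(z))  # demean to tame edge transients
  bins <- pmin(127, floor(abs(f) / max_g * 128))
  nwin <- length(z) %/% spw
  idx <- rep(seq_len(nwin), each = spw)
  as.numeric(tapply(bins[seq_len(nwin * spw)], idx, sum))
}

#' Align two channels by cross-correlation
#'
#' Finds the integer epoch lag in `[-max_lag, max_lag]` that maximises the
#' Pearson cross-correlation between the two series, then trims both to their
#' overlap after shifting. A positive lag means `y` is delayed by that many
#' epochs relative to `x` (`y` must be advanced to align).
#'
#' @param x,y Numeric channel vectors on the same epoch grid.
#' @param max_lag Maximum absolute lag to search, epochs.
#' @return List with `lag`, `x`, `y` (aligned, equal length).
#' @export
align_by_crosscorr <- function(x, y, max_lag = 10) {
  stopifnot(length(x) >= 2 * max_lag + 2, length(y) >= 2 * max_lag + 2)
  if (sd(x, na.rm = TRUE) == 0 || sd(y, na.rm = TRUE) == 0) {
    warning("zero-variance input; returning lag 0")
    n <- min(length(x), length(y))
    return(list(lag = 0L, x = x[seq_len(n)], y = y[seq_len(n)]))
  }
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(y) - l, length(x))
      suppressWarnings(cor(x[seq_len(n)], y[(l + 1):(l + n)],
                           use = "complete.obs"))
    } else {
      n <- min(length(y), length(x) + l)
      suppressWarnings(cor(x[(-l + 1):(-l + n)], y[seq_len(n)],
                           use = "complete.obs"))
    }
  }, numeric(1))
  cc[is.na(cc)] <- -Inf
  lag <- lags[which.max(cc)]
  if (lag >= 0) {
    n <- min(length(y) - lag, length(x))
    list(lag = lag, x = x[seq_len(n)], y = y[(lag + 1):(lag + n)])
  } else {
    n <- min(length(y), length(x) + lag)
    list(lag = lag, x = x[(-lag + 1):(-lag + n)], y = y[seq_len(n)])
  }
}
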