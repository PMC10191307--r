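#' One subject-night of aligned 30-s epoch channels
#'
#' The central data container: activity counts, HRM and HRSD per epoch, the
#' epoch clock time, and (when known, e.g. for training) the PSG stage label.
#' Missing values are carried as NA plus an explicit logical mask.
#'
#' @param subject_id Subject identifier.
#' @param activity Nonnegative activity counts per epoch (NA allowed).
#' @param hrm Heart-rate mean per epoch, bpm (NA allowed).
#' @param hrsd Heart-rate standard deviation per epoch, bpm (NA allowed).
#' @param clock_s Seconds since midnight at epoch start; monotone with
#'   `epoch_s` steps. Default: 30-s grid from 22:00.
#' @param stage Optional character stage labels (requires `scheme`).
#' @param scheme Optional `stage_scheme` for `stage`.
#' @param epoch_s Epoch duration in seconds.
#' @return An `epoch_series` object.
#' @export
epoch_series <- function(subject_id, activity, hrm, hrsd,
                         clock_s = NULL, stage = NULL, scheme = NULL,
                         epoch_s = 30) {
  n <- length(activity)
  if (length(hrm) != n || length(hrsd) != n)
    stop("activity, hrm, hrsd must have equal length")
  if (is.null(clock_s)) clock_s <- 79200 + (seq_len(n) - 1L) * epoch_s
  if (length(clock_s) != n) stop("clock_s length mismatch")
  if (any(activity < 0, na.rm = TRUE)) stop("activity must be nonnegative")
  if (any(hrm <= 0, na.rm = TRUE)) stop("hrm must be positive where observed")
  if (!is.null(stage)) {
    if (is.null(scheme)) stop("stage labels require a scheme")
    stage <- hypnogram(stage, scheme, epoch_s)
  }
  structure(list(subject_id = as.character(subject_id),
                 epoch_s = epoch_s,
                 activity = as.numeric(activity),
                 hrm = as.numeric(hrm),
                 hrsd = as.numeric(hrsd),
                 clock_s = as.numeric(clock_s),
                 stage = stage,
                 mask = !(is.na(activity) | is.na(hrm) | is.na(hrsd))),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> subject %s: %d epochs of %gs (%.1f h), %s stage labels\n",
              x$subject_id, n_epochs(x), x$epoch_s,
              n_epochs(x) * x$epoch_s / 3600,
              if (is.null(x$stage)) "no" else "with"))
  invisible(x)
}

#' Number of epochs in an epoch series
#' @param series An `epoch_series`.
#' @return Integer count.
#' @export
n_epochs <- function(series) length(series$activity)

#' Extract the channel matrix of an epoch series
#'
#' @param series An `epoch_series`.
#' @param channels Character subset of `c("activity", "hrm", "hrsd",
#'   "clock")`. The clock channel is seconds-since-midnight rescaled to
#'   [0, 1] over the day.
#' @return Numeric matrix, epochs x channels.
#' @export
series_channels <- function(series,
                            channels = c("activity", "hrm", "hrsd")) {
  stopifnot(inherits(series, "epoch_series"))
  cols <- lapply(channels, function(ch) switch(ch,
    activity = series$activity,
    hrm = series$hrm,
    hrsd = series$hrsd,
    clock = (series$clock_s %% 86400) / 86400,
    stop("unknown channel: ", ch)))
  m <- do.call(cbind, cols)
  colnames(m) <- channels
  m
}
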