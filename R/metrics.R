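#' Confusion matrix between predicted and reference hypnograms
#'
#' Rows are predicted stages, columns are true stages, so each column sums to
#' the number of reference epochs of that stage (and to 100% in the
#' normalised display).
#'
#' @param pred,true `hypnogram` objects (or character vectors with
#'   `scheme` supplied) of equal length on the same scheme.
#' @param scheme Optional `stage_scheme` when plain vectors are given.
#' @return A `confusion_matrix`: integer K x K matrix (predicted x true).
#' @export
confusion <- function(pred, true, scheme = NULL) {
  if (is.null(scheme)) {
    scheme <- hyp_scheme(pred) %||% hyp_scheme(true)
    if (is.null(scheme)) stop("supply a scheme or hypnogram inputs")
  }
  if (inherits(pred, "hypnogram") && inherits(true, "hypnogram") &&
      !identical(hyp_scheme(pred)$name, hyp_scheme(true)$name))
    stop("predicted and reference hypnograms use different schemes")
  if (length(pred) != length(true))
    stop("predicted and reference hypnograms differ in length")
  lv <- scheme$labels
  p <- factor(as.character(pred), levels = lv)
  t <- factor(as.character(true), levels = lv)
  if (anyNA(p) || anyNA(t)) stop("labels outside the scheme")
  m <- table(predicted = p, true = t)
  structure(unclass(m), class = "confusion_matrix", scheme = scheme)
}

#' Column-normalised confusion matrix (percent)
#'
#' @param cm A `confusion_matrix`.
#' @return Numeric matrix of percentages; each column sums to 100.
#' @export
confusion_percent <- function(cm) {
  cs <- colSums(cm)
  cs[cs == 0] <- NA_real_
  sweep(unclass(cm), 2, cs, "/") * 100
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "scheme") <- NULL
  cat("<confusion_matrix> predicted (rows) x true (cols), counts:\n")
  print(m)
  p <- round(confusion_percent(x), 1)
  attr(p, "scheme") <- NULL
  cat("column-normalised %:\n")
  print(p)
  invisible(x)
}

mcc_binary <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  (tp * tn - fp * fn) / den
}

#' Classifier performance metrics from a confusion matrix
#'
#' Per-class one-vs-rest sensitivity (recall), specificity, precision, F1 and
#' Matthews correlation, plus overall accuracy and macro / support-weighted
#' aggregates. Classes with zero true support are excluded (NA) from
#' aggregates.
#'
#' @param cm A `confusion_matrix` (predicted rows x true columns).
#' @return List with `overall_accuracy`, `per_class` data.frame, and
#'   aggregates `macro_sensitivity`, `macro_specificity`, `macro_precision`,
#'   `weighted_f1`, `macro_f1`, `macro_mcc`, `weighted_mcc`.
#' @export
classifier_metrics <- function(cm) {
  m <- unclass(cm)
  K <- nrow(m); tot <- sum(m)
  if (tot == 0) stop("empty confusion matrix")
  support <- colSums(m)
  per <- data.frame(class = colnames(m), support = as.numeric(support),
                    sensitivity = NA_real_, specificity = NA_real_,
                    precision = NA_real_, f1 = NA_real_, mcc = NA_real_)
  for (k in seq_len(K)) {
    tp <- m[k, k]
    fn <- support[k] - tp
    fp <- sum(m[k, ]) - tp
    tn <- tot - tp - fn - fp
    sens <- if (support[k] > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else if (support[k] > 0) 0 else NA_real_
    f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
      2 * prec * sens / (prec + sens) else if (support[k] > 0) 0 else NA_real_
    per$sensitivity[k] <- sens; per$specificity[k] <- spec
    per$precision[k] <- prec; per$f1[k] <- f1
    per$mcc[k] <- if (support[k] > 0) mcc_binary(tp, fp, fn, tn) else NA_real_
  }
  ok <- support > 0
  w <- support[ok] / sum(support[ok])
  list(overall_accuracy = sum(diag(m)) / tot,
       per_class = per,
       macro_sensitivity = mean(per$sensitivity[ok]),
       macro_specificity = mean(per$specificity[ok]),
       macro_precision = mean(per$precision[ok]),
       macro_f1 = mean(per$f1[ok]),
       weighted_f1 = sum(w * per$f1[ok]),
       macro_mcc = mean(per$mcc[ok], na.rm = TRUE),
       weighted_mcc = sum(w * ifelse(is.na(per$mcc[ok]), 0, per$mcc[ok])))
}

#' Sleep onset latency
#'
#' Time from the start of the recording to the first run of at least three
#' consecutive sleep (non-wake) epochs — the most stringent common
#' definition.
#'
#' @param hyp A `hypnogram`.
#' @return Latency in minutes; NA if no such run exists.
#' @export
sleep_onset_latency <- function(hyp) {
  i <- sleep_onset_epoch(hyp)
  if (is.na(i)) return(NA_real_)
  (i - 1) * hyp_epoch_s(hyp) / 60
}

# 1-based index of the first epoch of the first run of >= 3 sleep epochs
sleep_onset_epoch <- function(hyp, min_run = 3L) {
  s <- is_sleep_stage(unclass(hyp))
  if (length(s) < min_run) return(NA_integer_)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Sleep transition index
#'
#' Time spent in stage transitions after sleep onset, normalised by the time
#' spent asleep after onset. A transition contributes one epoch whenever an
#' epoch's stage differs from the previous epoch's stage (any stage pair,
#' including into and out of wake).
#'
#' @param hyp A `hypnogram`.
#' @return Fraction (epochs in transition / sleep epochs post-onset); NA if
#'   there is no sleep onset.
#' @export
sleep_transition_index <- function(hyp) {
  on <- sleep_onset_epoch(hyp)
  if (is.na(on)) return(NA_real_)
  s <- unclass(hyp)[on:length(hyp)]
  n_sleep <- sum(is_sleep_stage(s))
  if (n_sleep == 0) return(NA_real_)
  transitions <- sum(s[-1] != s[-length(s)])
  transitions / n_sleep
}

#' Clinical sleep metrics for one night
#'
#' Derived from the hypnogram alone: total sleep time, sleep efficiency
#' (sleep time over total recording time), onset latency (first run of three
#' consecutive sleep epochs), sleep fragmentation (post-onset sleep-to-wake
#' transitions per hour of total sleep time), the sleep transition index,
#' and per-stage times (hours) and fractions of sleep time.
#'
#' @param hyp A `hypnogram`.
#' @return A `clinical_metrics` list; sleep-dependent entries are NA for an
#'   all-wake night.
#' @export
clinical_metrics <- function(hyp) {
  sch <- hyp_scheme(hyp)
  eh <- hyp_epoch_s(hyp) / 3600          # epoch length in hours
  s <- unclass(hyp)
  n <- length(s)
  sleep <- is_sleep_stage(s)
  tst <- sum(sleep) * eh
  trt <- n * eh
  on <- sleep_onset_epoch(hyp)
  stage_time <- vapply(sch$labels, function(l) sum(s == l) * eh, numeric(1))
  sleep_labels <- setdiff(sch$labels, "W")
  stage_fraction <- if (tst > 0) stage_time[sleep_labels] / tst
                    else setNames(rep(NA_real_, length(sleep_labels)), sleep_labels)
  frag <- NA_real_
  if (!is.na(on) && tst > 0) {
    post <- s[on:n]
    sw <- sum(is_sleep_stage(post[-length(post)]) & !is_sleep_stage(post[-1]))
    frag <- sw / tst
  }
  structure(list(
    total_sleep_time_h = tst,
    total_recording_time_h = trt,
    sleep_efficiency = if (trt > 0) tst / trt else NA_real_,
    sleep_onset_latency_min = sleep_onset_latency(hyp),
    sleep_fragmentation = frag,
    sleep_transition_index = sleep_transition_index(hyp),
    stage_time_h = stage_time,
    stage_fraction_of_sleep = stage_fraction),
    class = "clinical_metrics")
}

#' @export
print.clinical_metrics <- function(x, ...) {
  cat(sprintf("<clinical_metrics> TST %.2f h, efficiency %.2f, onset %.1f min\n",
              x$total_sleep_time_h, x$sleep_efficiency,
              x$sleep_onset_latency_min))
  cat(sprintf("  fragmentation %.3f /h, transition index %.3f\n",
              x$sleep_fragmentation, x$sleep_transition_index))
  st <- paste(sprintf("%s %.2fh", names(x$stage_time_h), x$stage_time_h),
              collapse = ", ")
  cat("  stage times:", st, "\n")
  invisible(x)
}

#' Mean absolute error of clinical metrics across subjects
#'
#' Pairs predicted and reference `clinical_metrics` per subject and reports,
#' for every scalar metric and every per-stage time/fraction, the mean and SD
#' of the absolute errors. Subjects where either side is NA for a metric are
#' excluded pairwise and the retained count reported.
#'
#' @param pred,ref Lists of `clinical_metrics`, same order and length.
#' @return data.frame with columns `metric`, `mae`, `sd`, `n`.
#' @export
mae_of_metrics <- function(pred, ref) {
  stopifnot(length(pred) == length(ref), length(pred) >= 1)
  flat <- function(cm) {
    c(sleep_efficiency = cm$sleep_efficiency,
      sleep_onset_latency_min = cm$sleep_onset_latency_min,
      sleep_fragmentation = cm$sleep_fragmentation,
      sleep_transition_index = cm$sleep_transition_index,
      total_sleep_time_h = cm$total_sleep_time_h,
      setNames(as.numeric(cm$stage_time_h),
               paste0(names(cm$stage_time_h), "_time_h")),
      setNames(as.numeric(cm$stage_fraction_of_sleep),
               paste0(names(cm$stage_fraction_of_sleep), "_fraction")))
  }
  P <- do.call(rbind, lapply(pred, flat))
  R <- do.call(rbind, lapply(ref, flat))
  err <- abs(P - R)
  out <- data.frame(metric = colnames(err),
                    mae = NA_real_, sd = NA_real_, n = NA_integer_,
                    row.names = NULL)
  for (j in seq_len(ncol(err))) {
    e <- err[, j]; e <- e[!is.na(e)]
    out$n[j] <- length(e)
    if (length(e)) {
      out$mae[j] <- mean(e)
      out$sd[j] <- if (length(e) > 1) sd(e) else 0
    }
  }
  out
}
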