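#' Write epoch series to a CSV/TSV epoch table
#'
#' Columns: `subject_id, epoch_index, clock_s, activity, hrm, hrsd, stage`.
#' Epoch indices are 0-based and contiguous per subject; stages are stored as
#' scheme labels (empty string when unknown).
#'
#' @param series An `epoch_series` or list of them.
#' @param path Output file; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(series, path) {
  if (inherits(series, "epoch_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(subject_id = s$subject_id,
               epoch_index = seq_len(n_epochs(s)) - 1L,
               clock_s = s$clock_s,
               activity = s$activity, hrm = s$hrm, hrsd = s$hrsd,
               stage = if (is.null(s$stage)) "" else as.character(s$stage))
  })
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch table into epoch series
#'
#' @param path CSV/TSV written by [write_epoch_table()] (or by any tool
#'   producing the same header).
#' @param scheme `stage_scheme` used to validate the stage column (required
#'   when stages are present).
#' @param activity_60s If TRUE each table row is a 60-s epoch (the coarser
#'   actigraph grid); every channel is replicated onto the 30-s grid, so the
#'   series doubles in length.
#' @return List of `epoch_series`, one per subject in file order.
#' @export
read_epoch_table <- function(path, scheme = NULL, activity_60s = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  need <- c("subject_id", "epoch_index", "clock_s", "activity", "hrm",
            "hrsd", "stage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("epoch table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (id in unique(df$subject_id)) {
    d <- df[df$subject_id == id, ]
    d <- d[order(d$epoch_index), ]
    if (!all(diff(d$epoch_index) == 1))
      stop("epoch_index not contiguous for subject ", id)
    if (activity_60s) {
      d <- data.frame(subject_id = d$subject_id[1],
                      epoch_index = seq_len(2 * nrow(d)) - 1L,
                      clock_s = rep(d$clock_s, each = 2) + c(0, 30),
                      activity = upsample_activity(d$activity),
                      hrm = rep(d$hrm, each = 2),
                      hrsd = rep(d$hrsd, each = 2),
                      stage = rep(d$stage, each = 2))
    }
    act <- d$activity
    stage <- NULL
    has_stage <- any(nzchar(d$stage) & !is.na(d$stage))
    if (has_stage) {
      if (is.null(scheme)) stop("stage labels present; supply a scheme")
      bad <- setdiff(unique(d$stage), c(scheme$labels, "", NA))
      if (length(bad))
        stop("unknown stage label(s) for subject ", id, ": ",
             paste(bad, collapse = ", "))
      stage <- d$stage
    }
    out[[length(out) + 1L]] <- epoch_series(
      subject_id = id, activity = act, hrm = d$hrm, hrsd = d$hrsd,
      clock_s = d$clock_s, stage = stage, scheme = scheme)
  }
  out
}

#' Write / read an R-peak train (one timestamp per line)
#' @param train An `rpeak_train` or numeric timestamp vector (s).
#' @param path File path.
#' @return `path` invisibly (write); an `rpeak_train` (read).
#' @export
write_rpeaks <- function(train, path) {
  writeLines(format(as.numeric(train), trim = TRUE, digits = 15), path)
  invisible(path)
}

#' @rdname write_rpeaks
#' @export
read_rpeaks <- function(path) {
  ts <- as.numeric(readLines(path))
  if (anyNA(ts)) stop("non-numeric timestamp in ", path)
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  structure(ts, duration_s = max(ts), class = "rpeak_train")
}

#' Write a predicted hypnogram to CSV
#' @param hyp A `hypnogram`.
#' @param path Output CSV (`epoch_index`, `stage`).
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.csv(data.frame(epoch_index = seq_along(hyp) - 1L,
                              stage = as.character(hyp)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles a format version, the model and training
#' configuration, the parameter arrays, the normalisation statistics of the
#' training split, and the loss weights, so inference metadata records the
#' training objective.
#'
#' @param fit A `stager_fit`.
#' @param path Checkpoint file path (.rds).
#' @return `path` invisibly (save); a `stager_fit` (load).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "stager_fit"))
  saveRDS(list(format = "somnseq-checkpoint-1", fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "somnseq-checkpoint-1"))
    stop("unrecognised checkpoint format")
  obj$fit
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `scheme`, `channels`, `window`, `conv_width`, `hidden`,
#' `attention`, `loss`, `lr`, `batch_size`, `n_opt_epochs`, `finetune_lr`,
#' `selection`, `seed`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `train_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("scheme", "channels", "window", "conv_width", "hidden",
             "attention", "loss", "lr", "batch_size", "n_opt_epochs",
             "finetune_lr", "selection", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sch <- stage_scheme(y$scheme %||% "three")
  mc <- stager_config(scheme = sch,
                      channels = y$channels %||% c("activity", "hrm", "hrsd"),
                      L = y$window %||% 12,
                      conv_width = y$conv_width %||% 64,
                      hidden = y$hidden %||% 128,
                      attention = y$attention %||% "general")
  train_config(model = mc, loss = y$loss %||% "if",
               lr = y$lr %||% 0.00015,
               batch_size = y$batch_size %||% 50,
               n_opt_epochs = y$n_opt_epochs %||% 200,
               finetune_lr = y$finetune_lr %||% 0.00001,
               selection = y$selection %||% "weighted_f1",
               seed = y$seed %||% 1)
}
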