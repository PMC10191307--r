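# Shared fixtures for the test suite. Everything is generated in code; no
# data files are read.

# Three-class emissions with stage locations separated by >= 3 SD in at
# least one channel, for parameter-recovery experiments.
separable_emissions_three <- function() {
  emission_model(stage_scheme("three"), params = data.frame(
    stage    = c("W", "NREM", "REM"),
    act_mean = c(200, 20, 5),  act_sd  = c(20, 10, 5),
    hrm_mean = c(75, 55, 70),  hrm_sd  = c(2, 2, 2),
    hrsd_mean = c(6, 2, 5),    hrsd_sd = c(0.5, 0.5, 0.5)))
}

# A tiny network configuration that keeps forward/backward passes cheap.
tiny_config <- function(scheme = stage_scheme("three"),
                        channels = c("activity", "hrm"), L = 5) {
  stager_config(scheme, channels = channels, L = L,
                conv_width = 3, hidden = 4)
}

# Flatten a nested parameter list to named numeric leaves (for gradient
# comparisons). Unnamed list elements get positional names.
flatten_param_tree <- function(tree, prefix = "") {
  nms <- names(tree)
  if (is.null(nms)) nms <- as.character(seq_along(tree))
  out <- list()
  for (i in seq_along(tree)) {
    key <- paste0(prefix, nms[i])
    v <- tree[[i]]
    if (is.list(v)) out <- c(out, flatten_param_tree(v, paste0(key, ".")))
    else out[[key]] <- v
  }
  out
}

# Modify one leaf of a parameter tree by path (character vector) and flat
# index; used by finite-difference checks.
poke_param <- function(params, path, i, delta) {
  ref <- params
  if (length(path) == 2) {
    ref[[path[1]]][[path[2]]][i] <- ref[[path[1]]][[path[2]]][i] + delta
  } else {
    p1 <- path[1]; p2 <- suppressWarnings(as.integer(path[2]))
    if (is.na(p2)) p2 <- path[2]
    ref[[p1]][[p2]][[path[3]]][i] <- ref[[p1]][[p2]][[path[3]]][i] + delta
  }
  ref
}

# Aggregate confusion matrix of a fit over a list of labelled series.
pooled_confusion <- function(fit, series_list) {
  cm <- Reduce(`+`, lapply(series_list, function(s)
    unclass(confusion(predict_hypnogram(s, fit), s$stage))))
  structure(cm, class = "confusion_matrix",
            scheme = fit$config$model$scheme)
}
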