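#' Subject-wise train/validation/test split
#'
#' Splits are disjoint by subject so no subject-night contributes epochs to
#' more than one partition. By default the training set receives
#' `floor(f_train * n)` subjects and the remainder is divided evenly between
#' validation and test (validation first). Studies often instead fix the
#' absolute validation/test sizes (e.g. 100 subjects each, remainder to
#' training); pass `n_val`/`n_test` for that convention.
#'
#' @param subject_ids Character or numeric vector of unique subject ids.
#' @param fractions Train/val/test fractions summing to 1; default
#'   `c(0.75, 0.125, 0.125)`.
#' @param n_val,n_test Optional absolute validation/test sizes; when given,
#'   training receives all remaining subjects.
#' @param seed Integer seed; assignment is a seeded random permutation.
#' @return List with `train`, `val`, `test` id vectors.
#' @export
split_subjects <- function(subject_ids, fractions = c(0.75, 0.125, 0.125),
                           n_val = NULL, n_test = NULL, seed = 1) {
  ids <- unique(subject_ids)
  n <- length(ids)
  if (n < 3) stop("need at least 3 subjects to split")
  if (is.null(n_val) != is.null(n_test))
    stop("give both n_val and n_test or neither")
  if (is.null(n_val)) {
    stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
              all(fractions > 0))
    n_train <- floor(fractions[1] * n)
    rem <- n - n_train
    n_val <- ceiling(rem / 2)
    n_test <- rem - n_val
  } else {
    n_train <- n - n_val - n_test
  }
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("split sizes must all be at least 1")
  perm <- with_seed(seed, sample(ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, learning rate
#' 0.00015, batch size 50, 200 optimisation epochs, and fine-tuning at
#' learning rate 0.00001.
#'
#' @param model A `stager_config`.
#' @param loss `"if"` (inverse-frequency weighting) or `"rw"` (real-world
#'   weighting).
#' @param lr Learning rate.
#' @param batch_size Windows per optimisation step.
#' @param n_opt_epochs Passes over the training windows.
#' @param finetune_lr Learning rate used by `fine_tune()`.
#' @param selection Validation selection metric: `"weighted_f1"` (default),
#'   `"accuracy"` or `"loss"`.
#' @param seed Integer seed for initialisation and batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(model = stager_config(), loss = c("if", "rw"),
                         lr = 0.00015, batch_size = 50, n_opt_epochs = 200,
                         finetune_lr = 0.00001,
                         selection = c("weighted_f1", "accuracy", "loss"),
                         seed = 1) {
  stopifnot(lr > 0, batch_size >= 1, n_opt_epochs >= 0, finetune_lr > 0)
  structure(list(model = model, loss = match.arg(loss), lr = lr,
                 batch_size = as.integer(batch_size),
                 n_opt_epochs = as.integer(n_opt_epochs),
                 finetune_lr = finetune_lr,
                 selection = match.arg(selection), seed = seed),
            class = "train_config")
}

#' Assemble a window dataset from labelled epoch series
#'
#' Builds sliding windows per subject-night (windows never cross
#' subject-night boundaries), z-scores every channel with the supplied or
#' freshly computed statistics, and one-hot encodes the stage labels.
#'
#' @param series_list List of labelled `epoch_series` on one scheme.
#' @param config A `stager_config`.
#' @param norm Optional list with `mean`/`sd` per channel (training-split
#'   statistics); computed from `series_list` when NULL.
#' @return List with `x` (B x L x C), `y` (B x L integer class indices),
#'   `norm`, `subjects` (per-window subject id), `class_counts`.
#' @export
build_dataset <- function(series_list, config, norm = NULL) {
  stopifnot(length(series_list) >= 1)
  ch <- config$channels
  if (is.null(norm)) {
    all_m <- do.call(rbind, lapply(series_list, series_channels, channels = ch))
    norm <- list(mean = colMeans(all_m, na.rm = TRUE),
                 sd = pmax(apply(all_m, 2, sd, na.rm = TRUE), 1e-8))
  }
  xs <- list(); ys <- list(); subj <- character(0)
  counts <- setNames(rep(0, config$K), config$scheme$labels)
  for (s in series_list) {
    if (is.null(s$stage)) stop("all series must carry stage labels for training")
    m <- series_channels(s, ch)
    m <- sweep(sweep(m, 2, norm$mean), 2, norm$sd, "/")
    w <- make_windows(m, config$L)
    lab <- match(unclass(s$stage), config$scheme$labels)
    if (anyNA(lab)) stop("stage labels outside the configured scheme")
    y <- matrix(lab[w$epoch_map], nrow(w$epoch_map), config$L)
    xs[[length(xs) + 1L]] <- w$x
    ys[[length(ys) + 1L]] <- y
    subj <- c(subj, rep(s$subject_id, dim(w$x)[1]))
    tb <- table(factor(config$scheme$labels[lab], levels = config$scheme$labels))
    counts <- counts + as.numeric(tb)
  }
  B <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  x <- array(0, c(B, config$L, config$C))
  y <- matrix(0L, B, config$L)
  at <- 0L
  for (i in seq_along(xs)) {
    b <- dim(xs[[i]])[1]
    x[at + seq_len(b), , ] <- xs[[i]]
    y[at + seq_len(b), ] <- ys[[i]]
    at <- at + b
  }
  list(x = x, y = y, norm = norm, subjects = subj, class_counts = counts)
}

# one-hot targets (B*L) x K from the B x L index matrix, rows b + (t-1)B
flatten_targets <- function(y, K) {
  n <- length(y)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  Y
}

# elementwise tree ops over nested parameter lists
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else f(a, b)
}
tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    attributes(out) <- attributes(a)
    out
  } else f(a)
}

adam_init <- function(params) list(m = tree_map(params, function(x) x * 0),
                                   v = tree_map(params, function(x) x * 0),
                                   t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map2(params,
                      tree_map2(state$m, state$v,
                                function(m, v) (m / bc1) / (sqrt(v / bc2) + eps)),
                      function(p, upd) p - lr * upd)
  list(params = params, state = state)
}

batch_loss_grad <- function(params, config, xb, yb, loss_kind, weights) {
  fw <- stager_forward(xb, params, config, cache = TRUE)
  P <- flatten_probs(fw$probs)
  Y <- flatten_targets(yb, config$K)
  lg <- if (loss_kind == "if") loss_if(P, Y, w = weights$w, grad = TRUE)
        else loss_rw(P, Y, rw = weights, grad = TRUE)
  grads <- stager_backward(lg$dlogits, params, config, fw$cache)
  list(loss = lg$loss, grads = grads)
}

eval_selection <- function(params, config, data, metric, weights, loss_kind,
                           batch = 256L) {
  B <- dim(data$x)[1]
  if (metric == "loss") {
    tot <- 0
    for (i in seq.int(1L, B, by = batch)) {
      j <- i:min(B, i + batch - 1L)
      p <- stager_forward(data$x[j, , , drop = FALSE], params, config)
      P <- flatten_probs(p)
      Y <- flatten_targets(data$y[j, , drop = FALSE], config$K)
      l <- if (loss_kind == "if") loss_if(P, Y, w = weights$w)
           else loss_rw(P, Y, rw = weights)
      tot <- tot + l * length(j)
    }
    return(-tot / B)                      # higher is better, uniformly
  }
  pred <- integer(0); truth <- integer(0)
  for (i in seq.int(1L, B, by = batch)) {
    j <- i:min(B, i + batch - 1L)
    p <- stager_forward(data$x[j, , , drop = FALSE], params, config)
    pred <- c(pred, max.col(flatten_probs(p)))
    truth <- c(truth, as.integer(data$y[j, , drop = FALSE]))
  }
  lv <- config$scheme$labels
  cm <- confusion(lv[pred], lv[truth], scheme = config$scheme)
  met <- classifier_metrics(cm)
  if (metric == "accuracy") met$overall_accuracy else met$weighted_f1
}

#' Train the stager network
#'
#' Mini-batch Adam on the configured loss, with the snapshot achieving the
#' best validation selection metric returned. The training log records the
#' mean train loss and the validation metric for every optimisation epoch.
#'
#' @param train_series,val_series Lists of labelled `epoch_series`.
#' @param config A `train_config`.
#' @param init Optional `stager_params` to start from (used by
#'   [fine_tune()]); default: fresh initialisation from the config seed.
#' @param lr Optional learning-rate override.
#' @param verbose Print per-epoch progress.
#' @return A `stager_fit`: `params` (best snapshot), `log` (data.frame),
#'   `norm`, `weights`, `config`.
#' @export
train_model <- function(train_series, val_series, config, init = NULL,
                        lr = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  mc <- config$model
  lr <- lr %||% config$lr
  data <- build_dataset(train_series, mc)
  vdata <- build_dataset(val_series, mc, norm = data$norm)
  freq <- data$class_counts
  weights <- if (config$loss == "if") list(w = if_weights(freq))
             else rw_weight_matrices(freq / sum(freq))
  params <- init %||% init_params(mc, seed = config$seed)
  state <- adam_init(params)
  B <- dim(data$x)[1]
  bs <- min(config$batch_size, B)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_metric = numeric(0))
  best <- list(metric = -Inf, params = params)
  if (config$n_opt_epochs == 0)
    return(structure(list(params = params, log = log, norm = data$norm,
                          weights = weights, config = config),
                     class = "stager_fit"))
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$n_opt_epochs)) {
      ord <- sample.int(B)
      tot <- 0; nb <- 0L
      for (i in seq.int(1L, B, by = bs)) {
        j <- ord[i:min(B, i + bs - 1L)]
        bl <- batch_loss_grad(params, mc,
                              data$x[j, , , drop = FALSE],
                              data$y[j, , drop = FALSE],
                              config$loss, weights)
        if (!is.finite(bl$loss))
          stop("training diverged (non-finite loss) at optimisation epoch ", ep)
        up <- adam_step(params, bl$grads, state, lr)
        params <- up$params; state <- up$state
        tot <- tot + bl$loss; nb <- nb + 1L
      }
      vm <- eval_selection(params, mc, vdata, config$selection, weights,
                           config$loss)
      log <- rbind(log, data.frame(epoch = ep, train_loss = tot / nb,
                                   val_metric = vm))
      if (vm > best$metric) best <- list(metric = vm, params = params)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val %.4f", ep, tot / nb, vm))
    }
  })
  structure(list(params = best$params, log = log, norm = data$norm,
                 weights = weights, config = config),
            class = "stager_fit")
}

#' @export
print.stager_fit <- function(x, ...) {
  cat(sprintf("<stager_fit> %s loss, %d optimisation epochs logged, best val %.4f\n",
              x$config$loss, nrow(x$log),
              if (nrow(x$log)) max(x$log$val_metric) else NA))
  invisible(x)
}

#' Fine-tune a pretrained stager on new data
#'
#' Transfer learning: the entire pretrained parameter set stays trainable and
#' training continues on the new cohort at the reduced fine-tuning learning
#' rate (default 0.00001).
#'
#' @param fit A `stager_fit` from [train_model()] (the source-domain model).
#' @param train_series,val_series Target-domain labelled series.
#' @param config A `train_config`; must use the same model scheme/channels as
#'   the pretrained fit.
#' @return A new `stager_fit`.
#' @export
fine_tune <- function(fit, train_series, val_series, config) {
  stopifnot(inherits(fit, "stager_fit"), inherits(config, "train_config"))
  pm <- attr(fit$params, "config")
  mc <- config$model
  if (!identical(pm$K, mc$K) || !identical(pm$C, mc$C) ||
      !identical(pm$L, mc$L) || !identical(pm$conv_width, mc$conv_width) ||
      !identical(pm$hidden, mc$hidden))
    stop("pretrained parameters are incompatible with the fine-tune config")
  train_model(train_series, val_series, config, init = fit$params,
              lr = config$finetune_lr)
}

#' Subject-wise k-fold cross-validation
#'
#' Subjects are partitioned into k folds of near-equal size (larger folds
#' first); each fold serves once as the test set while the remaining
#' subjects are split 85/15 into training and validation.
#'
#' @param series_list Labelled `epoch_series` list.
#' @param k Number of folds.
#' @param config A `train_config`.
#' @param seed Fold-assignment seed.
#' @return List with `fold_accuracy`, `mean`, `sd`, `folds` (id lists).
#' @export
cross_validate <- function(series_list, k, config, seed = 1) {
  ids <- vapply(series_list, function(s) s$subject_id, character(1))
  u <- unique(ids)
  if (k > length(u)) stop("k exceeds the number of subjects")
  perm <- with_seed(seed, sample(u))
  sizes <- rep(length(u) %/% k, k)
  extra <- length(u) %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(perm, rep(seq_len(k), times = sizes))
  acc <- numeric(k)
  for (i in seq_len(k)) {
    test_ids <- folds[[i]]
    rest <- setdiff(u, test_ids)
    n_val <- max(1L, round(0.15 * length(rest)))
    val_ids <- rest[seq_len(n_val)]
    train_ids <- setdiff(rest, val_ids)
    fit <- train_model(series_list[ids %in% train_ids],
                       series_list[ids %in% val_ids], config)
    test_series <- series_list[ids %in% test_ids]
    pred <- lapply(test_series, predict_hypnogram, fit = fit)
    cm <- Reduce(`+`, Map(function(p, s) unclass(confusion(p, s$stage)),
                          pred, test_series))
    acc[i] <- sum(diag(cm)) / sum(cm)
  }
  list(fold_accuracy = acc, mean = mean(acc),
       sd = if (k > 1) sd(acc) else 0, folds = folds)
}
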