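#' Collect per-epoch votes from overlapping window predictions
#'
#' With stride 1 and window length L, every interior epoch is covered by
#' exactly L windows (so is labelled L times); the first and last L - 1
#' epochs receive fewer votes.
#'
#' @param probs Array B x L x K of window stage probabilities.
#' @param epoch_map B x L matrix of epoch indices from [make_windows()].
#' @param n_epochs Total number of epochs in the series.
#' @return A `vote_table`: list per epoch of data.frames with columns
#'   `window`, `label` (argmax class index) and the K probability columns.
#' @export
collect_votes <- function(probs, epoch_map, n_epochs) {
  d <- dim(probs)
  if (length(d) != 3 || !all(dim(epoch_map) == d[1:2]))
    stop("probs and epoch_map disagree in shape")
  B <- d[1]; L <- d[2]; K <- d[3]
  votes <- vector("list", n_epochs)
  P <- flatten_probs(probs)               # rows b + (t-1)B
  lab <- max.col(P)
  win <- rep(seq_len(B), times = L)
  ep <- as.integer(epoch_map)             # same b + (t-1)B ordering
  ord <- order(ep)
  runs <- split(ord, ep[ord])
  for (e in names(runs)) {
    i <- runs[[e]]
    votes[[as.integer(e)]] <- list(window = win[i], label = lab[i],
                                   probs = P[i, , drop = FALSE])
  }
  structure(votes, class = "vote_table", K = K)
}

#' Mode vote over a vote table
#'
#' Each epoch's final label is the most frequent vote among the windows that
#' cover it. Ties are broken in favour of the tied class with the highest
#' mean predicted probability across the contributing windows; a residual
#' tie falls back to the earliest class in scheme order.
#'
#' @param votes A `vote_table`.
#' @param scheme The `stage_scheme` naming the classes.
#' @return A `hypnogram` of length equal to the vote table.
#' @export
mode_vote <- function(votes, scheme) {
  stopifnot(inherits(votes, "vote_table"), inherits(scheme, "stage_scheme"))
  K <- attr(votes, "K")
  if (K != scheme$K) stop("vote table and scheme disagree on class count")
  lab <- vapply(votes, function(v) {
    if (is.null(v) || !length(v$label)) return(NA_integer_)
    cnt <- tabulate(v$label, nbins = K)
    top <- which(cnt == max(cnt))
    if (length(top) == 1L) return(top)
    mp <- colMeans(v$probs[, top, drop = FALSE])
    top[which.max(mp)]                    # which.max takes the earliest on ties
  }, integer(1))
  if (anyNA(lab)) stop("every epoch needs at least one vote")
  hypnogram(scheme$labels[lab], scheme)
}

#' Predict the hypnogram of one subject-night
#'
#' Standardises the series with the fit's training statistics, slides the
#' L-epoch window at stride 1, runs the network on every window, and
#' combines the overlapping predictions by mode voting.
#'
#' @param series An `epoch_series`.
#' @param fit A `stager_fit` from [train_model()].
#' @param batch Windows evaluated per forward call.
#' @param return_probs If TRUE, also return the per-epoch mean probability
#'   matrix across covering windows.
#' @return A `hypnogram` (or list with `hypnogram` and `probs`).
#' @export
predict_hypnogram <- function(series, fit, batch = 256L,
                              return_probs = FALSE) {
  stopifnot(inherits(fit, "stager_fit"))
  mc <- fit$config$model
  m <- series_channels(series, mc$channels)
  m <- sweep(sweep(m, 2, fit$norm$mean), 2, fit$norm$sd, "/")
  w <- make_windows(m, mc$L)
  B <- dim(w$x)[1]
  probs <- array(0, c(B, mc$L, mc$K))
  for (i in seq.int(1L, B, by = batch)) {
    j <- i:min(B, i + batch - 1L)
    probs[j, , ] <- stager_forward(w$x[j, , , drop = FALSE], fit$params, mc)
  }
  votes <- collect_votes(probs, w$epoch_map, w$n_epochs)
  hyp <- mode_vote(votes, mc$scheme)
  if (!return_probs) return(hyp)
  mp <- t(vapply(votes, function(v) colMeans(v$probs), numeric(mc$K)))
  colnames(mp) <- mc$scheme$labels
  list(hypnogram = hyp, probs = mp)
}
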