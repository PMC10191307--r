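#' Inverse-frequency class weights
#'
#' Weights proportional to the reciprocal of each class's epoch frequency in
#' the training data, normalised so the mean weight is 1 (keeping loss
#' magnitudes comparable across weighting schemes).
#'
#' @param class_counts Positive per-class epoch counts (or frequencies),
#'   length K, optionally named.
#' @return Numeric weight vector of length K, mean 1.
#' @export
if_weights <- function(class_counts) {
  if (any(class_counts <= 0))
    stop("every class needs a positive count; merge or drop absent stages ",
         "before weighting")
  f <- class_counts / sum(class_counts)
  w <- 1 / f
  w / mean(w)
}

#' Real-world weight matrices for the false-positive-aware loss
#'
#' The false-negative vector is the inverse class frequency, `w_fn^k = 1/f_k`
#' (so that a zero false-positive matrix reduces this loss to the
#' inverse-frequency loss). The false-positive matrix penalises predicting
#' class l when the truth is class k by the square root of the paired inverse
#' frequencies, `w_fp^{kl} = sqrt(1/(f_k f_l))`, with a zero diagonal. Both
#' are normalised so their mean nonzero entry is 1.
#'
#' @param class_frequencies Positive per-class frequencies summing to 1 (raw
#'   counts are renormalised), length K, optionally named.
#' @return List of class `rw_weights` with `w_fn` (length K) and `w_fp`
#'   (K x K, zero diagonal).
#' @export
rw_weight_matrices <- function(class_frequencies) {
  if (any(class_frequencies <= 0))
    stop("every class needs positive frequency")
  f <- class_frequencies / sum(class_frequencies)
  K <- length(f)
  w_fn <- 1 / f
  w_fn <- w_fn / mean(w_fn)
  w_fp <- sqrt(outer(1 / f, 1 / f))
  diag(w_fp) <- 0
  off <- w_fp[row(w_fp) != col(w_fp)]
  w_fp <- w_fp / mean(off)
  if (!is.null(names(f))) dimnames(w_fp) <- list(names(f), names(f))
  structure(list(w_fn = w_fn, w_fp = w_fp), class = "rw_weights")
}

# flatten a B x L x K (or n x K) probability/target array to n x K
flatten_probs <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) return(as.matrix(x))
  if (length(d) == 3) return(matrix(aperm(x, c(1, 2, 3)), d[1] * d[2], d[3]))
  stop("expected an n x K matrix or B x L x K array")
}

#' Inverse-frequency-weighted cross-entropy loss
#'
#' Mean over examples of `-w^k log p_k` at the true class k, with
#' probabilities clamped below at `eps`. With equal weights this is the
#' standard categorical cross-entropy.
#'
#' @param probs Predicted probabilities: n x K matrix or B x L x K array.
#' @param targets One-hot targets of the same shape (or an integer class
#'   index vector of length n).
#' @param w Class weight vector (length K); default all 1.
#' @param eps Probability clamp floor.
#' @param grad If TRUE, also return the analytic gradient with respect to the
#'   pre-softmax logits (same shape as the flattened probs).
#' @return Scalar loss, or `list(loss=, dlogits=)` when `grad = TRUE`.
#' @export
loss_if <- function(probs, targets, w = NULL, eps = 1e-7, grad = FALSE) {
  P <- flatten_probs(probs)
  Y <- as_one_hot(targets, ncol(P), nrow(P))
  K <- ncol(P)
  if (is.null(w)) w <- rep(1, K)
  if (length(w) != K) stop("weight length does not match class count")
  Pc <- pmin(pmax(P, eps), 1)
  n <- nrow(P)
  wk <- as.numeric(Y %*% w)               # weight of each example's true class
  loss <- -sum(wk * log(rowSums(Pc * Y))) / n
  if (!grad) return(loss)
  dlogits <- (P - Y) * wk / n             # softmax+weighted-CE gradient
  list(loss = loss, dlogits = dlogits)
}

#' Real-world-weighted cross-entropy loss
#'
#' Per example with true class k:
#' `-( w_fn^k log p_k + sum_{l != k} w_fp^{kl} log(1 - p_l) )`,
#' averaged over examples. The second term charges probability mass placed on
#' wrong classes, penalising false positives of rare stages.
#'
#' @param probs Predicted probabilities: n x K matrix or B x L x K array.
#' @param targets One-hot targets of the same shape or class index vector.
#' @param rw An `rw_weights` list (`w_fn`, `w_fp`).
#' @param eps Probability clamp (both tails).
#' @param grad If TRUE, also return the gradient with respect to logits.
#' @return Scalar loss, or `list(loss=, dlogits=)`.
#' @export
loss_rw <- function(probs, targets, rw, eps = 1e-7, grad = FALSE) {
  P <- flatten_probs(probs)
  Y <- as_one_hot(targets, ncol(P), nrow(P))
  K <- ncol(P)
  stopifnot(length(rw$w_fn) == K, all(dim(rw$w_fp) == c(K, K)))
  Pc <- pmin(pmax(P, eps), 1 - eps)
  n <- nrow(P)
  wk <- as.numeric(Y %*% rw$w_fn)
  Wrow <- Y %*% rw$w_fp                   # row k of w_fp for each example
  fn_term <- wk * log(rowSums(Pc * Y))
  fp_term <- rowSums(Wrow * log1p(-Pc) * (1 - Y))
  loss <- -sum(fn_term + fp_term) / n
  if (!grad) return(loss)
  # dJ/dp then chain through the softmax Jacobian
  dJdp <- -(Y * wk / Pc) + (1 - Y) * Wrow / (1 - Pc)
  dJdp <- dJdp / n
  dlogits <- P * (dJdp - rowSums(dJdp * P))
  list(loss = loss, dlogits = dlogits)
}

as_one_hot <- function(targets, K, n) {
  if (is.matrix(targets) || length(dim(targets)) == 3) {
    Y <- flatten_probs(targets)
    if (!all(dim(Y) == c(n, K))) stop("target shape does not match probabilities")
    if (any(abs(rowSums(Y) - 1) > 1e-9) || any(Y < 0))
      stop("targets must be one-hot")
    return(Y)
  }
  idx <- as.integer(targets)
  if (length(idx) != n || any(idx < 1) || any(idx > K))
    stop("target index vector does not match probabilities")
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), idx)] <- 1
  Y
}

#' Softmax over the last dimension
#' @param x Numeric matrix (n x K): logits.
#' @return Matrix of probabilities, rows summing to 1.
#' @export
softmax <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}
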