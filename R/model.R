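#' Stager network configuration
#'
#' A compact description of the sequence-to-sequence stager: three 1-D
#' convolutional layers (kernel 9, padding 4, stride 1 — length-preserving:
#' L + 2*4 - 9 + 1 = L) with leaky-ReLU activations, an LSTM encoder, an
#' LSTM decoder with multiplicative attention over the encoder states, and a
#' softmax output head giving one stage probability vector per epoch of the
#' window.
#'
#' @param scheme A `stage_scheme` (sets K, the output classes).
#' @param channels Input channel names, a subset of
#'   `c("activity", "hrm", "hrsd", "clock")`.
#' @param L Window length in epochs; 9, 12 (default) or 15 are the widths
#'   studied, but any L >= 1 is accepted.
#' @param conv_width Feature channels of each convolutional layer (default 64).
#' @param hidden LSTM hidden size for encoder and decoder (default 128).
#' @param attention `"general"` (bilinear score, default) or `"dot"`.
#' @param leaky_slope Negative slope of the leaky ReLU (default 0.01).
#' @return A `stager_config` list.
#' @export
stager_config <- function(scheme = stage_scheme("three"),
                          channels = c("activity", "hrm", "hrsd"),
                          L = 12, conv_width = 64, hidden = 128,
                          attention = c("general", "dot"),
                          leaky_slope = 0.01) {
  stopifnot(inherits(scheme, "stage_scheme"), L >= 1, conv_width >= 1,
            hidden >= 1)
  channels <- match.arg(channels, c("activity", "hrm", "hrsd", "clock"),
                        several.ok = TRUE)
  structure(list(scheme = scheme, channels = channels, C = length(channels),
                 K = scheme$K, L = as.integer(L),
                 conv_width = as.integer(conv_width),
                 hidden = as.integer(hidden),
                 kernel = 9L, pad = 4L,
                 attention = match.arg(attention),
                 leaky_slope = leaky_slope),
            class = "stager_config")
}

#' @export
print.stager_config <- function(x, ...) {
  cat(sprintf(paste0("<stager_config> %d-class (%s), channels [%s], L=%d, ",
                     "conv %d, hidden %d, %s attention\n"),
              x$K, x$scheme$name, paste(x$channels, collapse = ","),
              x$L, x$conv_width, x$hidden, x$attention))
  invisible(x)
}

uinit <- function(nr, nc, fan_in) {
  r <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -r, r), nr, nc)
}

#' Initialise network parameters
#'
#' Uniform initialisation in +/- 1/sqrt(fan_in) per tensor, the common
#' default for small recurrent networks.
#'
#' @param config A `stager_config`.
#' @param seed Integer seed for reproducible initialisation.
#' @return A `stager_params` list of weight arrays.
#' @export
init_params <- function(config, seed = NULL) {
  C <- config$C; F <- config$conv_width; H <- config$hidden
  K <- config$K; KW <- config$kernel
  with_seed(seed, {
    conv <- list()
    cin <- C
    for (i in 1:3) {
      conv[[i]] <- list(W = uinit(F, KW * cin, KW * cin), b = rep(0, F))
      cin <- F
    }
    p <- list(
      conv = conv,
      enc = list(Wx = uinit(F, 4 * H, F), Wh = uinit(H, 4 * H, H),
                 b = rep(0, 4 * H)),
      dec = list(Wx = uinit(F + H, 4 * H, F + H), Wh = uinit(H, 4 * H, H),
                 b = rep(0, 4 * H)),
      att = if (config$attention == "general")
              list(Wa = uinit(H, H, H)) else list(),
      out = list(Wo = uinit(2 * H, K, 2 * H), bo = rep(0, K)))
    structure(p, class = "stager_params", config = config)
  })
}

#' Slice an epoch series into overlapping windows
#'
#' @param series An `epoch_series`, or a plain numeric matrix
#'   (epochs x channels).
#' @param L Window length in epochs.
#' @param stride Window stride in epochs (default 1; consecutive windows then
#'   overlap in L - 1 epochs).
#' @param channels Channels to extract when `series` is an `epoch_series`.
#' @return List with `x` (array B x L x C), `epoch_map` (B x L matrix of
#'   1-based epoch indices) and `n_epochs`.
#' @export
make_windows <- function(series, L = 12, stride = 1,
                         channels = c("activity", "hrm", "hrsd")) {
  m <- if (inherits(series, "epoch_series"))
    series_channels(series, channels) else as.matrix(series)
  N <- nrow(m)
  if (N < L) stop("series has ", N, " epochs; need at least L = ", L)
  starts <- seq.int(1L, N - L + 1L, by = stride)
  B <- length(starts)
  x <- array(NA_real_, c(B, L, ncol(m)))
  for (j in seq_len(L)) x[, j, ] <- m[starts + j - 1L, , drop = FALSE]
  epoch_map <- outer(starts, 0:(L - 1L), "+")
  list(x = x, epoch_map = epoch_map, n_epochs = N)
}

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# im2col for a [B, L, C] array with the fixed kernel/pad of the config
conv_im2col <- function(X, KW, pad) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  Xpad <- array(0, c(B, L + 2 * pad, C))
  Xpad[, pad + seq_len(L), ] <- X
  M <- matrix(0, B * L, KW * C)
  for (t in seq_len(L))
    M[(t - 1L) * B + seq_len(B), ] <- matrix(Xpad[, t:(t + KW - 1L), , drop = FALSE],
                                             B, KW * C)
  M
}

conv_col2im <- function(dM, B, L, C, KW, pad) {
  dXpad <- array(0, c(B, L + 2 * pad, C))
  for (t in seq_len(L)) {
    blk <- array(dM[(t - 1L) * B + seq_len(B), ], c(B, KW, C))
    dXpad[, t:(t + KW - 1L), ] <- dXpad[, t:(t + KW - 1L), ] + blk
  }
  dXpad[, pad + seq_len(L), , drop = FALSE]
}

#' Convolutional feature extraction
#'
#' Applies the three length-preserving 1-D convolutions with leaky-ReLU
#' activations to a window batch.
#'
#' @param x Array B x L x C of (standardised) inputs.
#' @param params A `stager_params`.
#' @param config The matching `stager_config`; default taken from `params`.
#' @param cache If TRUE, return intermediates needed for backpropagation.
#' @return Array B x L x F of features (or a list with `out` and `cache`).
#' @export
cnn_features <- function(x, params, config = attr(params, "config"),
                         cache = FALSE) {
  d <- dim(x)
  if (length(d) != 3) stop("x must be a B x L x C array")
  if (d[3] != config$C)
    stop("input has ", d[3], " channels; config expects ", config$C)
  B <- d[1]; L <- d[2]
  cur <- x
  caches <- vector("list", 3)
  for (i in 1:3) {
    M <- conv_im2col(cur, config$kernel, config$pad)
    Z <- M %*% t(params$conv[[i]]$W)
    Z <- sweep(Z, 2, params$conv[[i]]$b, "+")
    A <- lrelu(Z, config$leaky_slope)
    caches[[i]] <- list(M = M, Z = Z, Cin = dim(cur)[3])
    cur <- array(A, c(B, L, config$conv_width))
  }
  if (cache) list(out = cur, cache = caches) else cur
}

cnn_backward <- function(dU, caches, params, config, B, L) {
  # dU: B x L x F gradient of the conv output
  slope <- config$leaky_slope
  grads <- vector("list", 3)
  dA <- matrix(dU, B * L, config$conv_width)
  for (i in 3:1) {
    ch <- caches[[i]]
    dZ <- dA * lrelu_grad(ch$Z, slope)
    grads[[i]] <- list(W = t(dZ) %*% ch$M, b = colSums(dZ))
    dM <- dZ %*% params$conv[[i]]$W
    dX <- conv_col2im(dM, B, L, ch$Cin, config$kernel, config$pad)
    dA <- matrix(dX, B * L, ch$Cin)
  }
  list(grads = grads, dx = array(dA, c(B, L, caches[[1]]$Cin)))
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_step <- function(x, h, c, W) {
  z <- x %*% W$Wx + h %*% W$Wh
  z <- sweep(z, 2, W$b, "+")
  H <- ncol(h)
  i <- sigm(z[, seq_len(H), drop = FALSE])
  f <- sigm(z[, H + seq_len(H), drop = FALSE])
  g <- tanh(z[, 2 * H + seq_len(H), drop = FALSE])
  o <- sigm(z[, 3 * H + seq_len(H), drop = FALSE])
  c_new <- f * c + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new,
       cache = list(x = x, h_prev = h, c_prev = c, i = i, f = f, g = g,
                    o = o, c_new = c_new))
}

lstm_step_backward <- function(dh, dc, cache, W) {
  tc <- tanh(cache$c_new)
  do <- dh * tc
  dc_total <- dc + dh * cache$o * (1 - tc^2)
  di <- dc_total * cache$g
  df <- dc_total * cache$c_prev
  dg <- dc_total * cache$i
  dc_prev <- dc_total * cache$f
  dzi <- di * cache$i * (1 - cache$i)
  dzf <- df * cache$f * (1 - cache$f)
  dzg <- dg * (1 - cache$g^2)
  dzo <- do * cache$o * (1 - cache$o)
  dz <- cbind(dzi, dzf, dzg, dzo)
  list(dx = dz %*% t(W$Wx),
       dh_prev = dz %*% t(W$Wh),
       dc_prev = dc_prev,
       dWx = t(cache$x) %*% dz,
       dWh = t(cache$h_prev) %*% dz,
       db = colSums(dz))
}

#' Attention over encoder states
#'
#' Alignment scores compare the decoder state with each encoder state
#' (bilinear `d' Wa e_j` for `"general"`, plain dot product for `"dot"`);
#' a softmax turns scores into attention weights, and the context vector is
#' the weight-averaged encoder state.
#'
#' @param decoder_state Matrix B x H, the current decoder hidden state.
#' @param encoder_states Array B x L x H of encoder hidden states.
#' @param Wa Optional H x H bilinear form (NULL for dot attention).
#' @return List with `context` (B x H) and `weights` (B x L, rows sum to 1).
#' @export
attend <- function(decoder_state, encoder_states, Wa = NULL) {
  d <- dim(encoder_states)
  if (length(d) != 3 || d[1] != nrow(decoder_state) || d[3] != ncol(decoder_state))
    stop("encoder_states must be B x L x H matching decoder_state")
  B <- d[1]; L <- d[2]
  A <- if (is.null(Wa)) decoder_state else decoder_state %*% Wa
  scores <- matrix(0, B, L)
  for (j in seq_len(L))
    scores[, j] <- rowSums(A * matrix(encoder_states[, j, ], B, d[3]))
  alpha <- softmax(scores)
  context <- matrix(0, B, d[3])
  for (j in seq_len(L))
    context <- context + alpha[, j] * matrix(encoder_states[, j, ], B, d[3])
  list(context = context, weights = alpha)
}

#' Forward pass of the stager network
#'
#' CNN features feed the LSTM encoder; the decoder is initialised with the
#' encoder's final state and unrolled for L steps, each step consuming the
#' epoch's CNN feature concatenated with the previous context vector (input
#' feeding). Each decoder state attends over all encoder states, and the
#' concatenated (decoder state, context) is projected to stage logits.
#'
#' @param x Array B x L x C of standardised window inputs.
#' @param params A `stager_params`.
#' @param config The matching `stager_config`.
#' @param cache If TRUE, return every intermediate needed for the backward
#'   pass.
#' @return Array B x L x K of stage probabilities (each length-K vector sums
#'   to 1), or a list with `probs` and `cache`.
#' @export
stager_forward <- function(x, params, config = attr(params, "config"),
                           cache = FALSE) {
  B <- dim(x)[1]; L <- dim(x)[2]
  F <- config$conv_width; H <- config$hidden; K <- config$K
  cv <- cnn_features(x, params, config, cache = TRUE)
  U <- cv$out                              # B x L x F
  # encoder
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  E <- array(0, c(B, L, H))
  enc_caches <- vector("list", L)
  for (t in seq_len(L)) {
    st <- lstm_step(matrix(U[, t, ], B, F), h, c, params$enc)
    h <- st$h; c <- st$c
    E[, t, ] <- h
    enc_caches[[t]] <- st$cache
  }
  # decoder with attention
  Wa <- params$att$Wa
  ctx <- matrix(0, B, H)
  probs <- array(0, c(B, L, K))
  dec_caches <- vector("list", L)
  dh <- h; dc <- c                         # decoder state init = encoder final
  for (t in seq_len(L)) {
    xin <- cbind(matrix(U[, t, ], B, F), ctx)
    st <- lstm_step(xin, dh, dc, params$dec)
    dh <- st$h; dc <- st$c
    at <- attend(dh, E, Wa)
    comb <- cbind(dh, at$context)
    logits <- sweep(comb %*% params$out$Wo, 2, params$out$bo, "+")
    probs[, t, ] <- softmax(logits)
    dec_caches[[t]] <- list(lstm = st$cache, alpha = at$weights,
                            context = at$context, d = dh, comb = comb)
    ctx <- at$context
  }
  if (!cache) return(probs)
  list(probs = probs,
       cache = list(conv = cv$cache, U = U, E = E, enc = enc_caches,
                    dec = dec_caches, B = B, L = L))
}

# Full backward pass. dlogits: (B*L) x K gradient (rows ordered b + (t-1)B,
# matching flatten_probs). Returns gradients with the same structure as
# params.
stager_backward <- function(dlogits, params, config, fw) {
  B <- fw$B; L <- fw$L
  F <- config$conv_width; H <- config$hidden; K <- config$K
  E <- fw$E; U <- fw$U
  Wa <- params$att$Wa
  dWo <- matrix(0, 2 * H, K); dbo <- rep(0, K)
  dWa <- if (!is.null(Wa)) matrix(0, H, H) else NULL
  dec_g <- list(dWx = matrix(0, F + H, 4 * H), dWh = matrix(0, H, 4 * H),
                db = rep(0, 4 * H))
  enc_g <- list(dWx = matrix(0, F, 4 * H), dWh = matrix(0, H, 4 * H),
                db = rep(0, 4 * H))
  dE <- array(0, c(B, L, H))
  dU <- array(0, c(B, L, F))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dctx_next <- matrix(0, B, H)             # grad flowing into step t's output context
  for (t in L:1) {
    dcc <- fw$dec[[t]]
    dl <- dlogits[(t - 1L) * B + seq_len(B), , drop = FALSE]
    dWo <- dWo + t(dcc$comb) %*% dl
    dbo <- dbo + colSums(dl)
    dcomb <- dl %*% t(params$out$Wo)
    dd <- dcomb[, seq_len(H), drop = FALSE] + dh_next
    dctx <- dcomb[, H + seq_len(H), drop = FALSE] + dctx_next
    # attention backward: context = sum_j alpha_j E_j, scores = (d [Wa]) . E_j
    alpha <- dcc$alpha
    A <- if (is.null(Wa)) dcc$d else dcc$d %*% Wa
    dalpha <- matrix(0, B, L)
    for (j in seq_len(L)) {
      Ej <- matrix(E[, j, ], B, H)
      dalpha[, j] <- rowSums(dctx * Ej)
      dE[, j, ] <- dE[, j, ] + alpha[, j] * dctx
    }
    dscore <- alpha * (dalpha - rowSums(dalpha * alpha))
    dA <- matrix(0, B, H)
    for (j in seq_len(L)) {
      Ej <- matrix(E[, j, ], B, H)
      dA <- dA + dscore[, j] * Ej
      dE[, j, ] <- dE[, j, ] + dscore[, j] * A
    }
    if (is.null(Wa)) {
      dd <- dd + dA
    } else {
      dd <- dd + dA %*% t(Wa)
      dWa <- dWa + t(dcc$d) %*% dA
    }
    bk <- lstm_step_backward(dd, dc_next, dcc$lstm, params$dec)
    dec_g$dWx <- dec_g$dWx + bk$dWx
    dec_g$dWh <- dec_g$dWh + bk$dWh
    dec_g$db <- dec_g$db + bk$db
    dU[, t, ] <- dU[, t, ] + bk$dx[, seq_len(F), drop = FALSE]
    dctx_next <- bk$dx[, F + seq_len(H), drop = FALSE]
    dh_next <- bk$dh_prev
    dc_next <- bk$dc_prev
  }
  # decoder init state = encoder final state; dctx for step 1 input is zero
  # (context_0 is a constant), so dctx_next is dropped here.
  dh_enc <- dh_next; dc_enc <- dc_next
  for (t in L:1) {
    dh <- dh_enc + matrix(dE[, t, ], B, H)
    bk <- lstm_step_backward(dh, dc_enc, fw$enc[[t]], params$enc)
    enc_g$dWx <- enc_g$dWx + bk$dWx
    enc_g$dWh <- enc_g$dWh + bk$dWh
    enc_g$db <- enc_g$db + bk$db
    dU[, t, ] <- dU[, t, ] + bk$dx
    dh_enc <- bk$dh_prev
    dc_enc <- bk$dc_prev
  }
  cb <- cnn_backward(dU, fw$conv, params, config, B, L)
  list(conv = lapply(cb$grads, function(g) list(W = g$W, b = g$b)),
       enc = list(Wx = enc_g$dWx, Wh = enc_g$dWh, b = enc_g$db),
       dec = list(Wx = dec_g$dWx, Wh = dec_g$dWh, b = dec_g$db),
       att = if (is.null(dWa)) list() else list(Wa = dWa),
       out = list(Wo = dWo, bo = dbo))
}
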