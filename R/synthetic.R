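#' @importFrom stats rnorm runif sd cor setNames
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Markov hypnogram model
#'
#' Stage dynamics are a first-order Markov chain over the scheme's labels.
#' The default transition matrix is built from target stationary fractions
#' `pi` and a persistence parameter `rho`: `P = rho * I + (1 - rho) * 1 pi'`,
#' whose stationary distribution is exactly `pi`. Setting `deep_decay > 0`
#' multiplies the transition probability into the deep stage by
#' `exp(-deep_decay * t / T_night)` (rows renormalised), concentrating deep
#' sleep in the first half of the night as observed on real PSG.
#'
#' @param scheme A `stage_scheme` (default four-class).
#' @param stationary_fractions Per-stage stationary probabilities, in scheme
#'   label order. Defaults: four-class 0.33/0.47/0.09/0.11 (W/Light/Deep/REM)
#'   and three-class 0.33/0.56/0.11 (W/NREM/REM), matching large-cohort PSG
#'   stage prevalence.
#' @param rho Persistence (probability mass kept on the current stage beyond
#'   the stationary mixture); default 0.9, giving mean bout lengths of
#'   minutes, as in scored hypnograms.
#' @param transition_matrix Optional explicit row-stochastic K x K matrix;
#'   overrides `stationary_fractions`/`rho`.
#' @param deep_decay Nonnegative scalar for the clock-time deep-sleep decay;
#'   default 0 (time-homogeneous chain).
#' @param epoch_s Epoch duration, seconds.
#' @return A `hypnogram_model` object.
#' @export
hypnogram_model <- function(scheme = stage_scheme("four"),
                            stationary_fractions = NULL,
                            rho = 0.9,
                            transition_matrix = NULL,
                            deep_decay = 0,
                            epoch_s = 30) {
  stopifnot(inherits(scheme, "stage_scheme"))
  K <- scheme$K
  if (is.null(stationary_fractions)) {
    stationary_fractions <- switch(scheme$name,
      four  = c(0.33, 0.47, 0.09, 0.11),
      three = c(0.33, 0.56, 0.11),
      five  = c(0.33, 0.06, 0.41, 0.09, 0.11),
      two   = c(0.33, 0.67))
  }
  pi <- stationary_fractions
  if (length(pi) != K || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("stationary_fractions must be length K, nonnegative, sum to 1")
  if (is.null(transition_matrix)) {
    stopifnot(rho >= 0, rho < 1)
    transition_matrix <- rho * diag(K) + (1 - rho) * matrix(pi, K, K, byrow = TRUE)
  }
  P <- as.matrix(transition_matrix)
  if (!all(dim(P) == c(K, K)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition_matrix must be K x K row-stochastic")
  dimnames(P) <- list(scheme$labels, scheme$labels)
  if (deep_decay < 0) stop("deep_decay must be nonnegative")
  structure(list(scheme = scheme, stationary_fractions = setNames(pi, scheme$labels),
                 transition_matrix = P, deep_decay = deep_decay,
                 epoch_s = epoch_s),
            class = "hypnogram_model")
}

#' Stationary distribution of a hypnogram model's chain
#'
#' Computed by eigen-decomposition of the transposed transition matrix
#' (the left eigenvector at eigenvalue 1, normalised to sum 1).
#'
#' @param model A `hypnogram_model`.
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(model) {
  P <- model$transition_matrix
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  setNames(v / sum(v), rownames(P))
}

#' Simulate a hypnogram from a Markov model
#'
#' @param model A `hypnogram_model`.
#' @param n_epochs Number of 30-s epochs (>= 1); default 960 (8 h).
#' @param seed Integer seed; the draw is bit-reproducible given the seed.
#' @param start Optional starting stage label; default: drawn from the
#'   stationary distribution.
#' @return A `hypnogram`.
#' @export
gen_hypnogram <- function(model, n_epochs = 960, seed = NULL, start = NULL) {
  stopifnot(inherits(model, "hypnogram_model"), n_epochs >= 1)
  sch <- model$scheme
  P <- model$transition_matrix
  K <- sch$K
  deep_idx <- match("Deep", sch$labels)  # NA for schemes without a deep stage
  with_seed(seed, {
    pi0 <- model$stationary_fractions
    s <- integer(n_epochs)
    s[1] <- if (is.null(start)) sample.int(K, 1, prob = pi0)
            else match(start, sch$labels)
    if (is.na(s[1])) stop("invalid start stage")
    for (t in seq_len(n_epochs - 1L)) {
      p <- P[s[t], ]
      if (model$deep_decay > 0 && !is.na(deep_idx)) {
        p[deep_idx] <- p[deep_idx] * exp(-model$deep_decay * t / n_epochs)
        p <- p / sum(p)
      }
      s[t + 1L] <- sample.int(K, 1, prob = p)
    }
    hypnogram(sch$labels[s], sch, epoch_s = model$epoch_s)
  })
}

#' Stage-conditional emission model for the coarse channels
#'
#' Per-stage location/scale for activity counts (Gaussian truncated at zero),
#' HRM (Gaussian, bpm) and HRSD (Gaussian truncated at zero, bpm). Defaults
#' emulate the qualitative structure of wearable data: wake has high activity
#' and elevated heart rate; NREM has low activity and slowed heart rate, with
#' deep sleep the slowest and least variable; REM has wake-like cardiac
#' measures but near-zero activity (muscle atonia).
#'
#' @param scheme A `stage_scheme`.
#' @param params Optional data.frame with columns `stage`, `act_mean`,
#'   `act_sd`, `hrm_mean`, `hrm_sd`, `hrsd_mean`, `hrsd_sd`; one row per
#'   scheme label. Defaults supplied for all schemes.
#' @param family Noise family tag; only `"gaussian"` is implemented.
#' @return An `emission_model`.
#' @export
emission_model <- function(scheme = stage_scheme("four"), params = NULL,
                           family = "gaussian") {
  stopifnot(inherits(scheme, "stage_scheme"))
  if (family != "gaussian") stop("only the gaussian family is implemented")
  if (is.null(params)) {
    base <- list(
      W     = c(150, 80, 70, 6.0, 5.0, 1.5),
      N1    = c( 25, 20, 62, 5.0, 3.5, 1.0),
      N2    = c( 12, 12, 60, 5.0, 3.0, 1.0),
      N3    = c(  8,  8, 55, 4.0, 2.0, 0.8),
      Light = c( 15, 15, 60, 5.0, 3.0, 1.0),
      Deep  = c(  8,  8, 55, 4.0, 2.0, 0.8),
      NREM  = c( 12, 12, 59, 5.0, 2.8, 1.0),
      Sleep = c( 10, 12, 61, 5.5, 3.0, 1.0),
      REM   = c(  5,  6, 68, 6.0, 4.5, 1.2))
    m <- do.call(rbind, base[scheme$labels])
    params <- data.frame(stage = scheme$labels,
                         act_mean = m[, 1], act_sd = m[, 2],
                         hrm_mean = m[, 3], hrm_sd = m[, 4],
                         hrsd_mean = m[, 5], hrsd_sd = m[, 6],
                         row.names = NULL)
  }
  need <- c("stage", "act_mean", "act_sd", "hrm_mean", "hrm_sd",
            "hrsd_mean", "hrsd_sd")
  if (!all(need %in% names(params)))
    stop("params must have columns: ", paste(need, collapse = ", "))
  if (!setequal(params$stage, scheme$labels))
    stop("params must cover every stage of the scheme exactly once")
  structure(list(scheme = scheme, params = params, family = family),
            class = "emission_model")
}

emission_row <- function(em, stage) em$params[match(stage, em$params$stage), ]

#' Simulate per-epoch channels for a hypnogram
#'
#' Draws activity (truncated at zero), HRM and HRSD for each epoch from the
#' stage-conditional emission model. Clock time advances in 30-s steps from
#' `clock_start_s` (seconds since midnight).
#'
#' @param hyp A `hypnogram`.
#' @param em An `emission_model` over the same scheme.
#' @param seed Integer seed.
#' @param subject_id Subject identifier stored in the result.
#' @param clock_start_s Clock time of the first epoch, seconds since
#'   midnight; default 22:00 (79200 s).
#' @return An `epoch_series`.
#' @export
gen_signals <- function(hyp, em, seed = NULL, subject_id = "synthetic",
                        clock_start_s = 79200) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(em, "emission_model"))
  if (!identical(hyp_scheme(hyp)$name, em$scheme$name))
    stop("hypnogram and emission model use different schemes")
  n <- length(hyp)
  idx <- match(unclass(hyp), em$params$stage)
  if (anyNA(idx)) stop("hypnogram contains stages missing from the emission model")
  p <- em$params[idx, ]
  epoch_s <- hyp_epoch_s(hyp)
  with_seed(seed, {
    activity <- pmax(0, rnorm(n, p$act_mean, p$act_sd))
    hrm <- pmax(30, rnorm(n, p$hrm_mean, p$hrm_sd))
    hrsd <- pmax(0, rnorm(n, p$hrsd_mean, p$hrsd_sd))
    epoch_series(subject_id = subject_id,
                 activity = activity, hrm = hrm, hrsd = hrsd,
                 clock_s = clock_start_s + (seq_len(n) - 1L) * epoch_s,
                 stage = unclass(hyp), scheme = hyp_scheme(hyp),
                 epoch_s = epoch_s)
  })
}

#' Simulate an R-peak train consistent with a hypnogram
#'
#' Beats are laid down sequentially: during each epoch the instantaneous
#' heart rate is the stage's HRM plus Gaussian jitter with the stage's HRSD,
#' and the next inter-beat interval is 60/IHR seconds. With
#' `artifact_rate > 0`, each beat is independently subjected to an artifact:
#' half the artifacts insert a spurious beat (splitting the interval 1:9 so
#' one piece falls below 0.33 s), half drop the beat (merging two intervals
#' into one above 1.33 s).
#'
#' @param hyp A `hypnogram`.
#' @param em An `emission_model` over the same scheme.
#' @param artifact_rate Artifact probability per beat, in [0, 0.5).
#' @param seed Integer seed.
#' @param ihr_jitter_sd Within-epoch IHR jitter in bpm; default uses the
#'   stage's `hrsd_mean`. Pass 0 for metronomic beats.
#' @return An `rpeak_train`: strictly increasing timestamps (s) spanning the
#'   night, with attribute `duration_s`.
#' @export
gen_rpeaks <- function(hyp, em, artifact_rate = 0, seed = NULL,
                       ihr_jitter_sd = NULL) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(em, "emission_model"))
  if (artifact_rate < 0 || artifact_rate >= 0.5)
    stop("artifact_rate must be in [0, 0.5)")
  epoch_s <- hyp_epoch_s(hyp)
  duration <- length(hyp) * epoch_s
  idx <- match(unclass(hyp), em$params$stage)
  if (anyNA(idx)) stop("hypnogram contains stages missing from the emission model")
  hrm <- em$params$hrm_mean[idx]
  jit <- if (is.null(ihr_jitter_sd)) em$params$hrsd_mean[idx]
         else rep(ihr_jitter_sd, length(hyp))
  with_seed(seed, {
    # generous preallocation: max plausible beat count at 180 bpm
    ts <- numeric(ceiling(duration * 3.2))
    n <- 0L
    t <- 0
    while (t < duration) {
      ep <- min(length(hyp), 1L + floor(t / epoch_s))
      ihr <- max(35, hrm[ep] + rnorm(1, 0, jit[ep]))
      gap <- 60 / ihr
      u <- runif(1)
      if (u < artifact_rate / 2 && n >= 1L) {
        # spurious beat: split the gap 1:9 -> short interval < 0.33 s
        n <- n + 1L; ts[n] <- t + 0.1 * gap
        t <- t + gap
        n <- n + 1L; ts[n] <- t
      } else if (u < artifact_rate) {
        # dropped beat: skip ahead two gaps with no intermediate peak
        t <- t + 2 * gap
        n <- n + 1L; ts[n] <- t
      } else {
        t <- t + gap
        n <- n + 1L; ts[n] <- t
      }
    }
    out <- ts[seq_len(n)]
    out <- out[out <= duration]
    structure(out, duration_s = duration, class = "rpeak_train")
  })
}

#' @export
print.rpeak_train <- function(x, ...) {
  cat(sprintf("<rpeak_train> %d beats over %.0f s (mean rate %.1f bpm)\n",
              length(x), attr(x, "duration_s"),
              60 * (length(x) - 1) / diff(range(unclass(x)))))
  invisible(x)
}

#' Simulate a cohort of subject-nights
#'
#' Convenience wrapper: draws one hypnogram and matching channel series per
#' subject. Seeds for each subject are derived deterministically from `seed`.
#'
#' @param n_subjects Number of subject-nights.
#' @param model A `hypnogram_model`.
#' @param em An `emission_model`.
#' @param n_epochs Epochs per night (default 960).
#' @param seed Integer seed.
#' @return List of `epoch_series`, one per subject.
#' @export
gen_cohort <- function(n_subjects, model = hypnogram_model(),
                       em = emission_model(model$scheme),
                       n_epochs = 960, seed = 1) {
  lapply(seq_len(n_subjects), function(i) {
    s <- (seed * 1000L + i) %% .Machine$integer.max
    hyp <- gen_hypnogram(model, n_epochs, seed = s)
    gen_signals(hyp, em, seed = s + 500L,
                subject_id = sprintf("S%03d", i))
  })
}
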