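test_that("window slicing counts and epoch map are exact", {
  m <- matrix(rnorm(20 * 3), 20, 3)
  w <- make_windows(m, L = 12)
  expect_equal(dim(w$x), c(9, 12, 3))
  # epoch 12 (1-based) appears in all 9 windows
  expect_true(all(apply(w$epoch_map, 1, function(r) 12 %in% r)))
  w1 <- make_windows(m[1:12, ], L = 12)
  expect_equal(dim(w1$x)[1], 1)
  expect_error(make_windows(m[1:11, ], L = 12), "at least L")
  # index map is exact: window b covers epochs b..b+11
  expect_equal(w$epoch_map[3, ], 3:14)
})

test_that("the conv stack preserves temporal length and is deterministic", {
  for (L in c(9, 12, 15)) {
    cfg <- stager_config(stage_scheme("three"), L = L, conv_width = 4,
                         hidden = 4)
    p <- init_params(cfg, seed = 1)
    x <- array(rnorm(2 * L * 3), c(2, L, 3))
    f1 <- cnn_features(x, p, cfg)
    expect_equal(dim(f1), c(2, L, 4))     # L + 2*4 - 9 + 1 = L
    expect_identical(f1, cnn_features(x, p, cfg))
  }
  # all-zero input with zero biases stays zero
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 2)
  x0 <- array(0, c(2, cfg$L, cfg$C))
  expect_equal(max(abs(cnn_features(x0, p, cfg))), 0)
  expect_error(cnn_features(array(0, c(2, cfg$L, 5)), p, cfg), "channels")
})

test_that("attention weights are a distribution and contexts are convex", {
  B <- 3; L <- 4; H <- 5
  set.seed(5)
  d <- matrix(rnorm(B * H), B, H)
  E <- array(rnorm(B * L * H), c(B, L, H))
  at <- attend(d, E)
  expect_equal(rowSums(at$weights), rep(1, B), tolerance = 1e-6)
  expect_true(all(at$weights >= 0))
  # identical encoder states -> context equals that state
  E1 <- array(rep(matrix(1:15, B, H), L), c(B, H, L))
  E1 <- aperm(E1, c(1, 3, 2))
  at1 <- attend(d, E1)
  expect_equal(at1$context, matrix(as.numeric(1:15), B, H))
  # uniform scores with L = 2 states u, v -> context (u + v) / 2
  E2 <- array(rnorm(B * 2 * H), c(B, 2, H))
  at2 <- attend(matrix(0, B, H), E2)
  expect_equal(at2$context, (E2[, 1, ] + E2[, 2, ]) / 2)
  # dominant score -> one-hot weights, context -> that encoder state
  Ebig <- array(c(1, -1, 0.3, 0.7), c(1, 2, 2))
  dbig <- matrix(c(50, 0), 1, 2)
  at3 <- attend(dbig, Ebig, Wa = diag(2) * 10)
  expect_gt(at3$weights[1, 1], 0.999)
  expect_equal(as.numeric(at3$context), as.numeric(Ebig[, 1, ]),
               tolerance = 1e-2)
  expect_error(attend(matrix(0, 2, 3), E), "B x L x H")
})

test_that("forward pass emits one softmax-normalised vector per epoch", {
  for (sname in c("three", "four")) {
    cfg <- tiny_config(stage_scheme(sname))
    p <- init_params(cfg, seed = 3)
    x <- array(rnorm(4 * cfg$L * cfg$C), c(4, cfg$L, cfg$C))
    pr <- stager_forward(x, p, cfg)
    expect_equal(dim(pr), c(4, cfg$L, cfg$K))
    sums <- apply(pr, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_identical(pr, stager_forward(x, p, cfg))
  }
})

test_that("an untrained network is calibrated near chance", {
  cfg <- stager_config(stage_scheme("four"), L = 12, conv_width = 8,
                       hidden = 8)
  p <- init_params(cfg, seed = 4)
  set.seed(6)
  x <- array(rnorm(200 * 12 * 3), c(200, 12, 3))
  pr <- stager_forward(x, p, cfg)
  mean_max <- mean(apply(pr, c(1, 2), max))
  expect_gte(mean_max, 1 / cfg$K)
  expect_lt(mean_max, 1 / cfg$K + 0.1)
})

test_that("analytic network gradients match finite differences", {
  cfg <- tiny_config()
  p <- init_params(cfg, seed = 7)
  # scale up so gradients are far from the finite-difference noise floor
  p <- rapply(p, function(x) 3 * x, how = "replace")
  attr(p, "config") <- cfg
  set.seed(8)
  B <- 2
  x <- array(rnorm(B * cfg$L * cfg$C), c(B, cfg$L, cfg$C))
  y <- matrix(sample(1:3, B * cfg$L, replace = TRUE), B, cfg$L)
  w <- if_weights(c(3, 2, 1))
  loss_of <- function(params) {
    P <- somnseq:::flatten_probs(stager_forward(x, params, cfg))
    loss_if(P, somnseq:::flatten_targets(y, 3), w = w)
  }
  fw <- stager_forward(x, p, cfg, cache = TRUE)
  lg <- loss_if(somnseq:::flatten_probs(fw$probs),
                somnseq:::flatten_targets(y, 3), w = w, grad = TRUE)
  g <- somnseq:::stager_backward(lg$dlogits, p, cfg, fw$cache)
  ga <- flatten_param_tree(g)
  pa <- flatten_param_tree(p)
  eps <- 1e-5
  set.seed(9)
  for (nm in names(pa)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    for (i in sample(length(pa[[nm]]), min(4, length(pa[[nm]])))) {
      fp <- loss_of(poke_param(p, path, i, eps))
      fm <- loss_of(poke_param(p, path, i, -eps))
      fd <- (fp - fm) / (2 * eps)
      an <- ga[[nm]][i]
      denom <- max(abs(fd) + abs(an), 1e-4)
      expect_lt(abs(fd - an) / denom, 1e-4)
    }
  }
})
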