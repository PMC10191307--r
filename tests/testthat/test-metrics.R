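test_that("confusion matrices count predicted x true with column support", {
  sch <- stage_scheme("two")
  pred <- c("W", "W", "Sleep", "Sleep", "W", "Sleep", "W", "Sleep", "W", "W")
  true <- c("W", "Sleep", "Sleep", "Sleep", "W", "W", "W", "Sleep", "Sleep", "W")
  cm <- confusion(pred, true, scheme = sch)
  expect_equal(unclass(cm)[, ],
               matrix(c(4, 1, 2, 3), 2, 2,
                      dimnames = list(predicted = c("W", "Sleep"),
                                      true = c("W", "Sleep"))))
  expect_equal(sum(cm), 10)
  expect_equal(colSums(confusion_percent(cm)), c(W = 100, Sleep = 100))
  # perfect prediction is diagonal
  cmd <- confusion(true, true, scheme = sch)
  expect_equal(sum(unclass(cmd)) - sum(diag(unclass(cmd))), 0)
  expect_error(confusion(pred[1:5], true, scheme = sch), "length")
})

test_that("classifier metrics match closed forms on a binary table", {
  cm <- structure(matrix(c(40, 10, 10, 40), 2, 2,
                         dimnames = list(c("W", "Sleep"), c("W", "Sleep"))),
                  class = "confusion_matrix", scheme = stage_scheme("two"))
  met <- classifier_metrics(cm)
  expect_equal(met$overall_accuracy, 0.8)
  expect_equal(met$per_class$mcc, c(0.6, 0.6))
  expect_equal(met$macro_mcc, 0.6)
  expect_equal(met$weighted_f1, 0.8)
  # perfect predictions
  cmp <- structure(diag(c(5, 5, 5)), class = "confusion_matrix",
                   dimnames = list(1:3, 1:3))
  metp <- classifier_metrics(cmp)
  expect_equal(metp$overall_accuracy, 1)
  expect_equal(metp$macro_mcc, 1)
  expect_equal(metp$weighted_f1, 1)
})

test_that("macro MCC equals a brute-force one-vs-rest oracle", {
  # oracle: rebuild label vectors from the table and use cor() on the
  # one-vs-rest indicators
  oracle_mcc <- function(m) {
    K <- nrow(m)
    pred <- rep(rep(seq_len(K), K), times = as.integer(m))
    true <- rep(rep(seq_len(K), each = K), times = as.integer(m))
    vals <- vapply(seq_len(K), function(k)
      suppressWarnings(cor(as.numeric(pred == k), as.numeric(true == k))),
      numeric(1))
    mean(vals[colSums(m) > 0], na.rm = TRUE)
  }
  set.seed(77)
  for (r in 1:200) {
    K <- sample(2:4, 1)
    m <- matrix(rpois(K * K, 5), K, K)
    if (any(colSums(m) == 0) || sum(m) == 0) next
    cm <- structure(m, class = "confusion_matrix",
                    dimnames = list(seq_len(K), seq_len(K)))
    got <- classifier_metrics(cm)$macro_mcc
    expect_equal(got, oracle_mcc(m), tolerance = 1e-10)
  }
})

test_that("sleep onset latency uses the three-consecutive-epoch rule", {
  sch <- stage_scheme("three")
  h <- hypnogram(c("W", "W", "NREM", "W", rep("NREM", 3), "W"), sch)
  expect_equal(sleep_onset_latency(h), 2.0)   # onset at epoch 5 -> 4 * 0.5 min
  expect_equal(sleep_onset_latency(hypnogram(rep("NREM", 5), sch)), 0)
  expect_true(is.na(sleep_onset_latency(hypnogram(rep("W", 10), sch))))
})

test_that("sleep transition index counts post-onset stage changes", {
  sch <- stage_scheme("three")
  # constant NREM after onset -> 0
  expect_equal(sleep_transition_index(hypnogram(rep("NREM", 10), sch)), 0)
  # post-onset N N R R N N: 2 changes / 6 sleep epochs
  h <- hypnogram(c("NREM", "NREM", "REM", "REM", "NREM", "NREM"), sch)
  expect_equal(sleep_transition_index(h), 2 / 6)
  expect_true(is.na(sleep_transition_index(hypnogram(rep("W", 6), sch))))
})

test_that("clinical metrics match hand computation on a crafted night", {
  sch <- stage_scheme("four")
  # 20 epochs: 4 wake, then 12 sleep, 2 wake, 2 sleep
  lab <- c(rep("W", 4), rep("Light", 6), rep("Deep", 2), rep("REM", 4),
           rep("W", 2), rep("Light", 2))
  h <- hypnogram(lab, sch)
  cm <- clinical_metrics(h)
  expect_equal(cm$total_sleep_time_h, 14 * 30 / 3600)
  expect_equal(cm$total_recording_time_h, 20 * 30 / 3600)
  expect_equal(cm$sleep_efficiency, 14 / 20)
  expect_equal(cm$sleep_onset_latency_min, 2.0)     # onset at epoch 5
  expect_equal(sum(cm$stage_time_h), cm$total_recording_time_h)
  expect_equal(sum(cm$stage_fraction_of_sleep), 1)
  expect_equal(unname(cm$stage_time_h["Deep"]), 2 * 30 / 3600)
  # one sleep->wake transition after onset (epoch 16->17... index 16)
  expect_equal(cm$sleep_fragmentation, 1 / cm$total_sleep_time_h)
  # stage changes post-onset: L->D, D->R, R->W, W->L = 4 over 14 sleep epochs
  expect_equal(cm$sleep_transition_index, 4 / 14)
})

test_that("big-night arithmetic: 720 sleep epochs of 960 is 6 h at 75%", {
  sch <- stage_scheme("three")
  lab <- c(rep("NREM", 720), rep("W", 240))
  cm <- clinical_metrics(hypnogram(lab, sch))
  expect_equal(cm$total_sleep_time_h, 6)
  expect_equal(cm$sleep_efficiency, 0.75)
})

test_that("MAE over subjects averages absolute errors pairwise", {
  sch <- stage_scheme("three")
  ref <- list(clinical_metrics(hypnogram(c(rep("NREM", 8), rep("W", 2)), sch)),
              clinical_metrics(hypnogram(c(rep("NREM", 6), rep("W", 4)), sch)))
  expect_true(all(mae_of_metrics(ref, ref)$mae[
    !is.na(mae_of_metrics(ref, ref)$mae)] == 0))
  pred <- list(clinical_metrics(hypnogram(c(rep("NREM", 9), "W"), sch)),
               clinical_metrics(hypnogram(c(rep("NREM", 9), "W"), sch)))
  out <- mae_of_metrics(pred, ref)
  tst <- out[out$metric == "total_sleep_time_h", ]
  # errors are {1, 3} epochs = {1, 3} * 30/3600 h -> MAE 2 * 30/3600
  expect_equal(tst$mae, 2 * 30 / 3600)
  expect_equal(tst$sd, sd(c(1, 3) * 30 / 3600))
  expect_equal(tst$n, 2)
  # the generic two-error arithmetic: {0.1, 0.3} -> 0.2 (0.141)
  expect_equal(mean(abs(c(0.1, 0.3))), 0.2)
  expect_equal(sd(c(0.1, 0.3)), 0.1414, tolerance = 1e-3)
})

test_that("uniform random prediction yields chance-level diagonals", {
  sch <- stage_scheme("three")
  set.seed(99)
  n <- 30000
  true <- sample(sch$labels, n, replace = TRUE, prob = c(0.33, 0.56, 0.11))
  pred <- sample(sch$labels, n, replace = TRUE)
  pc <- confusion_percent(confusion(pred, true, scheme = sch))
  expect_true(all(abs(diag(pc) - 100 / 3) < 2))
})
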