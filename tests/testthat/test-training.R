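test_that("subject splits are disjoint, exhaustive and deterministic", {
  ids <- sprintf("S%03d", 1:40)
  sp <- split_subjects(ids, seed = 4)
  expect_length(sp$train, 30)             # floor(0.75 * 40)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, split_subjects(ids, seed = 4))
  # 8 subjects -> 6/1/1 under the fraction rule
  sp8 <- split_subjects(letters[1:8], seed = 1)
  expect_equal(lengths(sp8[c("train", "val", "test")]),
               c(train = 6L, val = 1L, test = 1L))
  expect_error(split_subjects(letters[1:2]), "at least 3")
})

test_that("cohort-sized splits with fixed val/test reproduce study sizes", {
  sp <- split_subjects(seq_len(808), n_val = 100, n_test = 100, seed = 1)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 608L, val = 100L, test = 100L))
  sp <- split_subjects(seq_len(817), n_val = 100, n_test = 100, seed = 1)
  expect_equal(length(sp$train), 617L)
})

test_that("zero optimisation epochs return the initial parameters", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(3, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 60, seed = 30)
  mc <- stager_config(sch, conv_width = 3, hidden = 4)
  cfg <- train_config(mc, n_opt_epochs = 0, seed = 11)
  fit <- train_model(cohort[1:2], cohort[3], cfg)
  expect_identical(fit$params, init_params(mc, seed = 11))
  expect_equal(nrow(fit$log), 0)
})

test_that("training is deterministic given a fixed seed", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(4, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 60, seed = 31)
  mc <- stager_config(sch, conv_width = 3, hidden = 4)
  cfg <- train_config(mc, n_opt_epochs = 2, batch_size = 20, lr = 0.002,
                      seed = 12)
  f1 <- train_model(cohort[1:3], cohort[4], cfg)
  f2 <- train_model(cohort[1:3], cohort[4], cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
})

test_that("the returned snapshot achieves the best logged validation metric", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(5, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 40, seed = 32)
  mc <- stager_config(sch, conv_width = 4, hidden = 8)
  cfg <- train_config(mc, n_opt_epochs = 3, batch_size = 30, lr = 0.003,
                      seed = 13)
  fit <- train_model(cohort[1:4], cohort[5], cfg)
  vd <- build_dataset(cohort[5], mc, norm = fit$norm)
  best <- somnseq:::eval_selection(fit$params, mc, vd, "weighted_f1",
                                   fit$weights, "if")
  expect_gte(best + 1e-9, max(fit$log$val_metric))
})

test_that("loss trajectory trends downward on separable data", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(6, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 60, seed = 33)
  mc <- stager_config(sch, conv_width = 4, hidden = 8)
  cfg <- train_config(mc, n_opt_epochs = 5, batch_size = 50, lr = 0.002,
                      seed = 14)
  fit <- train_model(cohort[1:5], cohort[6], cfg)
  rho <- cor(fit$log$epoch, fit$log$train_loss, method = "spearman")
  expect_lt(rho, 0)
})

test_that("fine-tuning with zero epochs leaves parameters unchanged", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(4, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 150, seed = 34)
  mc <- stager_config(sch, conv_width = 3, hidden = 4)
  fit <- train_model(cohort[1:2], cohort[3],
                     train_config(mc, n_opt_epochs = 1, batch_size = 20,
                                  seed = 15))
  ft <- fine_tune(fit, cohort[3], cohort[4],
                  train_config(mc, n_opt_epochs = 0, seed = 15))
  expect_identical(ft$params, fit$params)
  # incompatible architecture is rejected
  mc2 <- stager_config(sch, conv_width = 5, hidden = 4)
  expect_error(fine_tune(fit, cohort[3], cohort[4],
                         train_config(mc2, n_opt_epochs = 1, seed = 1)),
               "incompatible")
})

test_that("pretraining helps a small shifted-domain cohort", {
  sch <- stage_scheme("three")
  em_src <- separable_emissions_three()
  # target domain: different device -> halved activity scale, +6 bpm HR
  pars <- em_src$params
  pars$act_mean <- pars$act_mean * 0.5; pars$act_sd <- pars$act_sd * 0.5
  pars$hrm_mean <- pars$hrm_mean + 6
  em_tgt <- emission_model(sch, params = pars)
  hm <- hypnogram_model(sch)
  src <- gen_cohort(12, hm, em_src, n_epochs = 80, seed = 40)
  mc <- stager_config(sch, conv_width = 8, hidden = 16)
  pre <- train_model(src[1:10], src[11:12],
                     train_config(mc, n_opt_epochs = 6, batch_size = 50,
                                  lr = 0.002, seed = 16))
  acc_of <- function(fit, test) classifier_metrics(
    pooled_confusion(fit, test))$overall_accuracy
  accs <- vapply(1:5, function(s) {
    tgt <- gen_cohort(6, hm, em_tgt, n_epochs = 60, seed = 100 + s)
    cfg <- train_config(mc, n_opt_epochs = 2, batch_size = 50,
                        lr = 0.00015, seed = s)
    direct <- train_model(tgt[1:3], tgt[4], cfg)
    tuned <- fine_tune(pre, tgt[1:3], tgt[4], cfg)
    acc_of(tuned, tgt[5:6]) - acc_of(direct, tgt[5:6])
  }, numeric(1))
  expect_gte(mean(accs), 0)
})

test_that("cross-validation folds are subject-disjoint and near-equal", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(10, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 30, seed = 35)
  mc <- stager_config(sch, conv_width = 3, hidden = 4)
  cfg <- train_config(mc, n_opt_epochs = 1, batch_size = 50, lr = 0.002,
                      seed = 17)
  cv <- cross_validate(cohort, 3, cfg, seed = 5)
  expect_equal(sort(unname(lengths(cv$folds)), decreasing = TRUE), c(4, 3, 3))
  expect_setequal(unlist(cv$folds),
                  vapply(cohort, function(s) s$subject_id, character(1)))
  expect_equal(cv$mean, mean(cv$fold_accuracy))
  expect_equal(cv$sd, sd(cv$fold_accuracy))
  expect_error(cross_validate(cohort, 11, cfg), "exceeds")
})

test_that("five folds of a 31-subject cohort have sizes 7,6,6,6,6", {
  sch <- stage_scheme("three")
  cohort <- gen_cohort(31, hypnogram_model(sch),
                       separable_emissions_three(), n_epochs = 20, seed = 36)
  mc <- stager_config(sch, L = 12, conv_width = 3, hidden = 4)
  cfg <- train_config(mc, n_opt_epochs = 0, seed = 18)
  cv <- cross_validate(cohort, 5, cfg, seed = 6)
  expect_equal(sort(unname(lengths(cv$folds)), decreasing = TRUE),
               c(7L, 6L, 6L, 6L, 6L))
})
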