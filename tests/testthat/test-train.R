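test_that("split_pairs partitions exactly at the default fractions", {
  co <- generate_cohort(small_cohort_config(n_pairs = 120L))
  ts <- cohort_tensorset(co)$ts
  ts <- ts_subset(ts, 1:100)
  sp <- split_pairs(ts, split_spec(seed = 4L))
  expect_equal(ts_n(sp$train), 70L)
  expect_equal(ts_n(sp$val), 10L)
  expect_equal(ts_n(sp$test), 20L)
  # disjoint and exhaustive over pair keys
  keys <- function(t) paste(t$pair_keys$cell_line_id, t$pair_keys$drug_id)
  all_keys <- c(keys(sp$train), keys(sp$val), keys(sp$test))
  expect_equal(sort(all_keys), sort(keys(ts)))
  expect_equal(anyDuplicated(all_keys), 0L)
})

test_that("splits are reproducible by seed and stratified by label", {
  co <- generate_cohort(small_cohort_config(seed = 12L))
  ts <- cohort_tensorset(co)$ts
  s1 <- split_pairs(ts, split_spec(seed = 8L))
  s2 <- split_pairs(ts, split_spec(seed = 8L))
  expect_identical(s1$train$pair_keys, s2$train$pair_keys)
  s3 <- split_pairs(ts, split_spec(seed = 9L))
  expect_false(identical(s1$train$pair_keys, s3$train$pair_keys))
  # stratification: each part's positive count within 2 of its expected share
  prev <- mean(ts$y)
  for (part in s1) {
    expect_lte(abs(sum(part$y) - prev * ts_n(part)), 2)
  }
  expect_error(split_pairs(ts_subset(ts, 1:5), split_spec()), "at least 10")
})

test_that("training runs the configured number of epochs and logs history", {
  co <- generate_cohort(small_cohort_config())
  ts <- cohort_tensorset(co)$ts
  sp <- split_pairs(ts, split_spec(seed = 1L))
  cfg <- small_model_config(ts, epochs = 6L)
  fit <- train_model(cfg, sp$train, sp$val)
  expect_equal(nrow(fit$history), 6L)
  expect_equal(fit$history$epoch, 1:6)
  expect_true(all(is.finite(fit$history$total)))
  expect_true(all(is.finite(fit$history$val_auprc)))
  # loss components are all present and non-negative
  expect_true(all(fit$history$l_cell_ae >= 0))
  expect_true(all(fit$history$l_drug_ae >= 0))
  expect_true(all(fit$history$l_classifier >= 0))
  # same seed twice -> identical training trajectory
  fit2 <- train_model(cfg, sp$train, sp$val)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("optional early stopping halts on stalled validation AUPRC", {
  co <- generate_cohort(small_cohort_config())
  ts <- cohort_tensorset(co)$ts
  sp <- split_pairs(ts, split_spec(seed = 1L))
  cfg <- small_model_config(ts, epochs = 30L, early_stopping_patience = 2L)
  fit <- train_model(cfg, sp$train, sp$val)
  expect_lte(nrow(fit$history), 30L)
})

test_that("config/tensor dimension mismatches are rejected", {
  co <- generate_cohort(small_cohort_config())
  ts <- cohort_tensorset(co)$ts
  sp <- split_pairs(ts, split_spec(seed = 1L))
  bad <- deepdra_config(5L, 5L, seed = 1L, epochs = 1L)
  expect_error(train_model(bad, sp$train), "do not match config")
})

test_that("scaling statistics stored in the model come from the training part only", {
  co <- generate_cohort(small_cohort_config())
  ts <- cohort_tensorset(co)$ts
  sp <- split_pairs(ts, split_spec(seed = 6L))
  cfg <- small_model_config(ts, epochs = 1L, scaling = "zscore")
  fit <- train_model(cfg, sp$train, sp$val)
  expect_equal(fit$model$scaler_cell$offset, colMeans(sp$train$X_cell))
  expect_equal(fit$model$scaler_drug$offset, colMeans(sp$train$X_drug))
  # and they travel with the checkpoint
  f <- tempfile(fileext = ".rds")
  save_model(fit$model, f)
  expect_equal(load_model(f)$scaler_cell$offset, colMeans(sp$train$X_cell))
})

test_that("k-fold folds are disjoint, exhaustive, seeded and leak-free", {
  co <- generate_cohort(small_cohort_config(seed = 3L))
  ts <- cohort_tensorset(co)$ts
  ts <- ts_subset(ts, 1:100)
  cfg <- small_model_config(ts, epochs = 2L)
  cv <- kfold_cv(cfg, ts, k = 5L, seed = 17L)
  expect_length(cv$folds, 5L)
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_equal(tabulate(cv$assignments, 5L), rep(20L, 5L))
  expect_length(cv$assignments, 100L)
  # same seed -> identical assignment
  cv2 <- kfold_cv(cfg, ts, k = 5L, seed = 17L)
  expect_identical(cv$assignments, cv2$assignments)
  # summary lies within fold range
  accs <- vapply(cv$folds, function(f) f$accuracy, numeric(1))
  m <- cv$summary$mean[cv$summary$metric == "accuracy"]
  expect_gte(m, min(accs))
  expect_lte(m, max(accs))
})

test_that("cross-cohort evaluation rejects mismatched feature spaces", {
  pair <- make_shifted_pair(small_cohort_config(seed = 21L))
  ts_a <- cohort_tensorset(pair$a)$ts
  cfg <- small_model_config(ts_a, epochs = 1L)
  ts_bad <- cohort_tensorset(pair$b, drug_mode = "descriptors")$ts
  expect_error(cross_cohort_eval(cfg, ts_a, ts_bad), "drug feature spaces differ")
  co2 <- generate_cohort(synthetic_config(
    n_cell_lines = 60L, n_drugs = 30L, latent_dim = 4L,
    n_expression = 50L, n_mutation = 30L, n_cnv = 30L,
    n_descriptors = 10L, n_fingerprint_bits = 32L, n_pairs = 700L, seed = 22L
  ))
  ts_c <- cohort_tensorset(co2)$ts
  expect_error(cross_cohort_eval(cfg, ts_a, ts_c), "cell feature spaces differ")
})

test_that("shift-free cohorts share identical feature IDs and evaluate cleanly", {
  pair <- make_shifted_pair(small_cohort_config(seed = 31L))
  ts_a <- cohort_tensorset(pair$a)$ts
  ts_b <- cohort_tensorset(pair$b)$ts
  expect_identical(ts_a$cell_feature_ids, ts_b$cell_feature_ids)
  cfg <- small_model_config(ts_a, epochs = 3L)
  rep <- cross_cohort_eval(cfg, ts_a, ts_b)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n, ts_n(ts_b))
})
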