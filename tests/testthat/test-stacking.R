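test_that("fold plans are contiguous, chronological and balanced", {
  plan <- plan_folds(1090, 5)
  expect_equal(lengths(plan), rep(218L, 5))
  expect_equal(unlist(plan), 1:1090)
  plan <- plan_folds(7, 3)
  expect_equal(lengths(plan), c(3L, 2L, 2L))  # extras go to earlier folds
  expect_error(plan_folds(4, 5), "at least")
})

test_that("constant learners propagate through the meta features", {
  split <- small_split(n_days = 60L)
  specs <- list(base_learner_spec("constant", params = list(value = 7),
                                  label = "c7"),
                base_learner_spec("constant", params = list(value = -2),
                                  label = "cm2"))
  meta <- generate_meta_features(specs, split, plan_folds(length(split$train$y), 3))
  expect_true(all(meta$M[, "c7"] == 7))
  expect_true(all(meta$N[, "c7"] == 7))
  expect_true(all(meta$N[, "cm2"] == -2))
  expect_equal(nrow(meta$fit_log), 6L)  # 2 learners x 3 folds
})

test_that("test-side meta features are the mean of the per-fold predictions", {
  split <- small_split(n_days = 80L)
  specs <- list(base_learner_spec("ridge"),
                base_learner_spec("gbdt", params = list(nrounds = 30)))
  meta <- generate_meta_features(specs, split,
                                 plan_folds(length(split$train$y), 4))
  for (j in 1:2) {
    naive <- rowMeans(meta$Q[, , j])
    expect_lt(max(abs(meta$N[, j] - naive)), 1e-9)
  }
})

test_that("out-of-fold generation matches a naive double-loop reference", {
  split <- small_split(n_days = 73L)  # 60 usable rows after the lag drop
  n_train <- length(split$train$y)
  expect_gte(n_train + length(split$test$y), 60L)
  specs <- list(
    base_learner_spec("ridge", params = list(lambda = 0.5)),
    base_learner_spec("custom",
                      fit = function(X, y) lm.fit(cbind(1, X[, 1:5]), y),
                      predict = function(m, X)
                        as.numeric(cbind(1, X[, 1:5]) %*% m$coefficients),
                      label = "ols5")
  )
  plan <- plan_folds(n_train, 3)
  meta <- generate_meta_features(specs, split, plan, seed = 4L)
  ref <- naive_meta_reference(specs, split, plan, seed = 4L)
  expect_lt(max(abs(meta$M - ref$M)), 1e-9)
  expect_lt(max(abs(meta$N - ref$N)), 1e-9)
})

test_that("a fold's out-of-fold values never depend on its own rows", {
  split <- small_split(n_days = 70L)
  spec <- list(base_learner_spec("ridge"))
  plan <- plan_folds(length(split$train$y), 3)
  meta <- generate_meta_features(spec, split, plan)
  # corrupt fold 2's labels; its own out-of-fold predictions must not move
  # (they are made by a model fitted without fold 2)
  corrupted <- split
  corrupted$train$y[plan[[2]]] <- 0
  meta2 <- generate_meta_features(spec, corrupted, plan)
  expect_equal(meta$M[plan[[2]], 1], meta2$M[plan[[2]], 1], tolerance = 1e-12)
})

test_that("heterogeneity of the four families is enforced", {
  split <- small_split(n_days = 60L)
  specs <- list(base_learner_spec("ridge"), base_learner_spec("ridge"))
  expect_error(generate_meta_features(specs, split), "distinct")
})

test_that("second-phase designs have the documented layout", {
  split <- small_split(n_days = 80L)
  specs <- list(base_learner_spec("constant", params = list(value = 1)),
                base_learner_spec("custom", fit = function(X, y) mean(y),
                                  predict = function(m, X) rep(m, nrow(X)),
                                  label = "mean"))
  meta <- generate_meta_features(specs, split,
                                 plan_folds(length(split$train$y), 3))
  key <- default_key_columns(split)
  sn <- assemble_new_datasets(meta, split, key)
  expect_equal(ncol(sn$train$X), 2 + length(key))
  expect_identical(colnames(sn$train$X), colnames(sn$test$X))
  expect_equal(colnames(sn$train$X)[1:2], c("constant", "mean"))
  expect_equal(nrow(sn$train$X), length(split$train$y))
  expect_equal(nrow(sn$test$X), length(split$test$y))
  sn0 <- assemble_new_datasets(meta, split, character(0))
  expect_equal(ncol(sn0$train$X), 2L)
  expect_error(assemble_new_datasets(meta, split, "no_such_column"),
               "no_such_column")
})

test_that("elastic net with zero penalties solves the normal equations", {
  set.seed(1)
  X <- cbind(x1 = rnorm(5), x2 = rnorm(5))
  y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(5, 0, 0.1)
  fit <- fit_meta_learner(list(X = X, y = y),
                          spec = meta_learner_spec(alpha = 0.5, lambda = 0))
  ols <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_lt(max(abs(coef(fit) - ols)), 1e-6)
})

test_that("weighting the meta learner behaves like replication", {
  set.seed(2)
  X <- cbind(x1 = rnorm(8), x2 = rnorm(8))
  y <- 3 + X[, 1] + rnorm(8, 0, 0.2)
  spec <- meta_learner_spec(alpha = 0.5, lambda = 0.1)
  f_eq <- fit_meta_learner(list(X = X, y = y), weights = rep(2, 8), spec = spec)
  f_un <- fit_meta_learner(list(X = X, y = y), spec = spec)
  expect_lt(max(abs(coef(f_eq) - coef(f_un))), 1e-8)
  f_dup <- fit_meta_learner(list(X = rbind(X, X[3, , drop = FALSE]),
                                 y = c(y, y[3])), spec = spec)
  w <- rep(1, 8); w[3] <- 2
  f_w <- fit_meta_learner(list(X = X, y = y), weights = w, spec = spec)
  expect_lt(max(abs(coef(f_dup) - coef(f_w))), 1e-8)
  expect_error(fit_meta_learner(list(X = X, y = y), weights = rep(1, 3)),
               "misaligned")
  expect_error(fit_meta_learner(list(X = X, y = y), weights = c(rep(1, 7), 0)),
               "positive")
})

test_that("the scoring path reproduces the assembled test design", {
  split <- small_split(n_days = 80L)
  specs <- list(base_learner_spec("ridge"),
                base_learner_spec("gbdt", params = list(nrounds = 30)))
  meta <- generate_meta_features(specs, split,
                                 plan_folds(length(split$train$y), 3))
  key <- default_key_columns(split)
  sn <- assemble_new_datasets(meta, split, key)
  fit <- fit_meta_learner(sn$train)
  model <- stacked_model(meta, fit, key)
  direct <- hastack:::predict_meta(fit, sn$test$X)
  via_raw <- predict_stacked(model, split$test$X)
  expect_lt(max(abs(direct - via_raw)), 1e-9)
  expect_true(all(is.finite(via_raw)))
  expect_error(predict_stacked(model, split$test$X[, 1:3]), "missing feature")
})

test_that("a constant ensemble with a constant target predicts the constant", {
  split <- small_split(n_days = 60L)
  specs <- list(base_learner_spec("constant", params = list(value = 7),
                                  label = "a"),
                base_learner_spec("constant", params = list(value = 7),
                                  label = "b"))
  meta <- generate_meta_features(specs, split,
                                 plan_folds(length(split$train$y), 3))
  sn <- assemble_new_datasets(meta, split, character(0))
  sn$train$y <- rep(7, length(sn$train$y))
  fit <- fit_meta_learner(sn$train, spec = meta_learner_spec(0.5, 0))
  model <- stacked_model(meta, fit, character(0))
  expect_equal(predict_stacked(model, split$test$X),
               rep(7, length(split$test$y)), tolerance = 1e-8)
})

test_that("holdout grid search selects by MAE with grid-order tie-breaks", {
  set.seed(3)
  n <- 100
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 5 + 2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.3)
  spec <- base_learner_spec("ridge", grid = list(lambda = c(0.01, 1, 100)))
  tuned <- grid_tune(spec, X, y, seed = 1L)
  expect_equal(tuned$results$holdout_mae[tuned$best],
               min(tuned$results$holdout_mae))
  # exhaustive evaluation: every grid point received a holdout MAE
  expect_equal(nrow(tuned$results), 3L)
  expect_true(all(is.finite(tuned$results$holdout_mae)))
  # single-point grid selects without comparison
  single <- grid_tune(base_learner_spec("ridge", grid = list(lambda = 0.7)),
                      X, y)
  expect_equal(single$spec$params$lambda, 0.7)
  # duplicated grid point: the earlier one wins
  dup <- grid_tune(base_learner_spec("ridge",
                                     grid = list(lambda = c(0.5, 0.5))),
                   X, y)
  expect_equal(dup$best, 1L)
  expect_error(grid_tune(base_learner_spec("ridge", grid = list()), X, y),
               "empty")
})

test_that("fits are reproducible for fixed seeds", {
  split <- small_split(n_days = 80L)
  specs <- light_learners()
  m1 <- generate_meta_features(specs, split,
                               plan_folds(length(split$train$y), 3), seed = 5L)
  m2 <- generate_meta_features(specs, split,
                               plan_folds(length(split$train$y), 3), seed = 5L)
  expect_equal(m1$M, m2$M, tolerance = 1e-12)
  expect_equal(m1$N, m2$N, tolerance = 1e-12)
})
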