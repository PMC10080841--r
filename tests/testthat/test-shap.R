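# a hand-built variable-level report for the aggregation/decomposition ops
fake_report <- function(values, phi0 = 10) {
  structure(list(phi0 = phi0, values = values,
                 prediction = phi0 + rowSums(values),
                 X_explain = matrix(0, nrow(values), ncol(values),
                                    dimnames = list(NULL, colnames(values))),
                 background_size = 1L, level = "variable"),
            class = "ha_shap_report")
}

fake_groups <- function(vars, parts) {
  structure(list(variable_of = setNames(vars, vars),
                 part_of = setNames(parts, vars)),
            class = "ha_feature_groups")
}

test_that("linear models are attributed in closed form", {
  f <- function(X) 2 * X[, "x1"] + 3
  bg <- matrix(c(0, 2), ncol = 1, dimnames = list(NULL, "x1"))  # mean 1
  ex <- matrix(4, ncol = 1, dimnames = list(NULL, "x1"))
  rep1 <- shapley_attributions(f, bg, ex, n_permutations = 1L)
  expect_equal(rep1$phi0, 5)
  expect_equal(unname(rep1$values[1, "x1"]), 6)
  expect_equal(rep1$prediction, 11)
  # multivariate: attribution = coefficient * (x - background mean)
  set.seed(12)
  d <- 6
  beta <- rnorm(d)
  f <- function(X) as.numeric(X %*% beta) + 1
  bg <- matrix(rnorm(30 * d), 30, d,
               dimnames = list(NULL, paste0("f", 1:d)))
  ex <- matrix(rnorm(3 * d), 3, d, dimnames = list(NULL, paste0("f", 1:d)))
  rep2 <- shapley_attributions(f, bg, ex, n_permutations = 1L)
  want <- sweep(sweep(ex, 2, colMeans(bg)), 2, beta, `*`)
  expect_equal(rep2$values, want, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate explanations vanish", {
  bg <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  const <- function(X) rep(4.2, nrow(X))
  rep1 <- shapley_attributions(const, bg, bg[1:2, ])
  expect_true(all(rep1$values == 0))
  expect_equal(rep1$phi0, 4.2)
  # explained row identical to the single background row
  f <- function(X) X[, "a"]^2 + X[, "b"]
  rep2 <- shapley_attributions(f, bg[1, , drop = FALSE],
                               bg[1, , drop = FALSE])
  expect_true(all(abs(rep2$values) < 1e-12))
})

test_that("additivity holds exactly for nonlinear models", {
  set.seed(13)
  bg <- matrix(rnorm(40), 8, 5, dimnames = list(NULL, paste0("v", 1:5)))
  ex <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, paste0("v", 1:5)))
  f <- function(X) X[, 1] * X[, 2] + sin(X[, 3]) + exp(X[, 4] / 3)
  rep1 <- shapley_attributions(f, bg, ex, n_permutations = 2L, seed = 3L)
  recon <- rep1$phi0 + rowSums(rep1$values)
  expect_equal(recon, rep1$prediction, tolerance = 1e-9)
  expect_equal(rep1$prediction, f(ex), tolerance = 1e-12)
  # seed determinism
  rep2 <- shapley_attributions(f, bg, ex, n_permutations = 2L, seed = 3L)
  expect_identical(rep1$values, rep2$values)
  expect_error(shapley_attributions(function(X) rep(NaN, nrow(X)), bg, ex),
               "non-finite")
})

test_that("variable aggregation conserves total attribution", {
  vals <- matrix(c(1, -2, 0.5, 2, 1, -1), 2, 3,
                 dimnames = list(NULL, c("tem_lag_1", "tem_lag_2", "has_lag_1")))
  rep1 <- fake_report(vals); rep1$level <- "feature"
  groups <- structure(list(
    variable_of = c(tem_lag_1 = "tem", tem_lag_2 = "tem",
                    has_lag_1 = "HAs"),
    part_of = c(tem = "environmental", HAs = "HAs")),
    class = "ha_feature_groups")
  agg <- aggregate_variable_shap(rep1, groups)
  expect_equal(sort(colnames(agg$values)), c("HAs", "tem"))
  # column-major fill: tem_lag_1 = (1, -2), tem_lag_2 = (0.5, 2)
  expect_equal(unname(agg$values[, "tem"]), c(1.5, 0))
  expect_equal(rowSums(agg$values), rowSums(vals))  # conservation
  # singleton groups act as the identity
  solo <- fake_groups(colnames(vals),
                      c("environmental", "environmental", "HAs"))
  agg2 <- aggregate_variable_shap(rep1, solo)
  expect_equal(agg2$values[, colnames(vals)], vals)
  bad <- structure(list(variable_of = c(tem_lag_1 = "tem"),
                        part_of = c(tem = "environmental")),
                   class = "ha_feature_groups")
  expect_error(aggregate_variable_shap(rep1, bad), "unmapped")
})

test_that("global importance is a ranked mean absolute attribution", {
  vals <- matrix(c(2, -2, 0, 0, 1, 1), 2, 3,
                 dimnames = list(NULL, c("b", "a", "c")))
  imp <- global_importance(fake_report(vals))
  expect_equal(imp$variable, c("b", "c", "a"))  # |2|,|−2| -> 2, not 0
  expect_equal(imp$importance, c(2, 1, 0))
  imp2 <- global_importance(fake_report(2 * vals))
  expect_equal(imp2$importance, 2 * imp$importance)  # homogeneity
})

test_that("the three-part decomposition reconstructs every prediction", {
  vals <- matrix(c(3, 1, -1, 2, 0.5, -0.25), 2, 3,
                 dimnames = list(NULL, c("HAs", "DOW", "tem")))
  groups <- fake_groups(c("HAs", "DOW", "tem"),
                        c("HAs", "calendar", "environmental"))
  rep1 <- fake_report(vals)
  dec <- three_part_decomposition(rep1, groups)
  expect_equal(dec$regular, vals[, "HAs"] + vals[, "DOW"], ignore_attr = TRUE)
  expect_equal(dec$volatile, vals[, "tem"], ignore_attr = TRUE)
  expect_equal(dec$phi0 + dec$regular + dec$volatile, dec$prediction,
               tolerance = 1e-9)
  # no environmental attribution -> volatile identically zero
  vals0 <- vals; vals0[, "tem"] <- 0
  expect_equal(three_part_decomposition(fake_report(vals0), groups)$volatile,
               c(0, 0), ignore_attr = TRUE)
  expect_error(three_part_decomposition(
    fake_report(cbind(vals, xx = c(1, 1))), groups), "unmapped")
})

test_that("partial-prediction accounting has the right sign and zero point", {
  groups <- fake_groups(c("HAs", "tem"), c("HAs", "environmental"))
  y <- c(12.5, 15)  # partial predictions 12 and 14 are close but imperfect
  # volatile == 0: partial equals full, improvements all zero
  vals0 <- matrix(c(2, 4, 0, 0), 2, 2, dimnames = list(NULL, c("HAs", "tem")))
  out0 <- partial_prediction_metrics(
    three_part_decomposition(fake_report(vals0), groups), y)
  expect_equal(unname(out0$improvement), rep(0, 4))
  # helpful environmental part -> positive improvement
  vals <- matrix(c(2, 4, 0.3, 0.8), 2, 2,
                 dimnames = list(NULL, c("HAs", "tem")))
  out <- partial_prediction_metrics(
    three_part_decomposition(fake_report(vals), groups), y)
  expect_lt(out$full$mae, out$partial$mae)
  expect_gt(out$improvement[["mae"]], 0)
  expect_error(partial_prediction_metrics(
    three_part_decomposition(fake_report(vals), groups), c(1, 2, 3)),
    "misaligned")
})

test_that("waterfalls accumulate environmental terms to the prediction", {
  vals <- matrix(c(65, 3, -1), 1, 3,
                 dimnames = list(NULL, c("HAs", "tem", "rh")))
  groups <- fake_groups(c("HAs", "tem", "rh"),
                        c("HAs", "environmental", "environmental"))
  rep1 <- fake_report(vals, phi0 = 15)  # new baseline 15 + 65 = 80
  dec <- three_part_decomposition(rep1, groups)
  wf <- local_waterfall(dec, rep1, groups, 1L)[["1"]]
  expect_equal(attr(wf, "new_baseline"), 80)
  expect_equal(wf$variable, c("tem", "rh"))  # |3| then |-1|
  expect_equal(attr(wf, "final_prediction"), 82)
  expect_true(all(diff(abs(wf$value)) <= 0))
  # empty environmental part
  g2 <- fake_groups("HAs", "HAs")
  rep2 <- fake_report(vals[, "HAs", drop = FALSE], phi0 = 15)
  wf2 <- local_waterfall(three_part_decomposition(rep2, g2), rep2, g2, 1L)[["1"]]
  expect_equal(nrow(wf2), 0L)
  expect_equal(attr(wf2, "final_prediction"), 80)
  expect_error(local_waterfall(dec, rep1, groups, 99L), "unknown sample")
})

test_that("dependence exports one pair per explained sample", {
  vals <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  rep1 <- fake_report(vals)
  rep1$X_explain <- matrix(c(rep(1, 5), rnorm(5)), 5, 2,
                           dimnames = list(NULL, c("a", "b")))
  dep <- dependence_export(rep1, "b")
  expect_equal(nrow(dep), 5L)
  expect_equal(dep$attribution, unname(vals[, "b"]))
  # constant feature -> a single x value
  expect_equal(unique(dependence_export(rep1, "a")$value), 1)
  expect_error(dependence_export(rep1, "zz"), "unknown feature")
})
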