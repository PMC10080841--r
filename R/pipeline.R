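#' Configuration of an end-to-end experiment
#'
#' A single global seed is fanned out to named sub-seeds (generator, learner
#' x fold, permutation explainer) so every stage can be reproduced in
#' isolation.
#'
#' @param generator A [generator_config()] (or \code{NULL} when
#'   \code{panel} is supplied to [run_experiment()]).
#' @param spec A [lag_spec()].
#' @param split_date First test day (default 2018-01-01: the last of four
#'   years is the test year).
#' @param base_learners List of [base_learner_spec()]s.
#' @param meta_spec A [meta_learner_spec()].
#' @param lds An [lds_config()], or \code{NULL} to disable re-weighting.
#' @param tune Holdout grid-search protocol: \code{"none"} (default) uses
#'   the specs' fixed hyperparameters throughout; \code{"meta"} tunes the
#'   elastic-net meta learner on the last 20\% of the new training set;
#'   \code{"full"} also grid-searches every base learner on the last 20\%
#'   of the original training set.
#' @param explain Run the Shapley explanation stage (costly; default
#'   \code{FALSE}).
#' @param background_size,n_explain,n_permutations Explanation settings:
#'   background subsample size, number of test rows explained, permutation
#'   pairs per row.
#' @param seed Global integer seed.
#' @return Object of class \code{ha_run_config}.
#' @export
run_config <- function(generator = generator_config(),
                       spec = lag_spec(),
                       split_date = "2018-01-01",
                       base_learners = default_base_learners(),
                       meta_spec = meta_learner_spec(),
                       lds = lds_config(),
                       tune = c("none", "meta", "full"),
                       explain = FALSE,
                       background_size = 100L,
                       n_explain = 50L,
                       n_permutations = 2L,
                       seed = 42L) {
  tune <- match.arg(tune)
  structure(list(generator = generator, spec = spec,
                 split_date = as.Date(split_date),
                 base_learners = base_learners, meta_spec = meta_spec,
                 lds = lds, tune = tune, explain = explain,
                 background_size = as.integer(background_size),
                 n_explain = as.integer(n_explain),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "ha_run_config")
}

#' Run the full forecasting experiment
#'
#' Executes simulate (unless a panel is given) -> preprocess -> (optional)
#' tune -> out-of-fold stacking -> LDS re-weighting -> meta fits (weighted
#' and unweighted) -> four-metric evaluation of every base learner and both
#' stacked variants -> (optional) Shapley explanation with grouped
#' aggregation and the three-part decomposition.  Every base-learner fit is
#' logged with learner, fold and training-row count (the 4 x 5 = 20-fit
#' audit trail under the defaults).
#'
#' @param config An [run_config()].
#' @param panel Optional pre-built \code{ha_panel} overriding the
#'   generator.
#' @return Object of class \code{ha_experiment}: the split, meta features
#'   (with \code{fit_log}), fitted models, \code{weights}, prediction
#'   table, \code{comparison} table, \code{metrics} list and (optionally)
#'   \code{explanation}.
#' @export
run_experiment <- function(config = run_config(), panel = NULL) {
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop(sprintf(
      "stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  panel <- panel %||% stage("simulate", {
    gen <- config$generator
    gen$seed <- derive_seed(seed, 1L)
    generate_panel(gen)
  })

  split <- stage("preprocess", {
    design <- build_design(panel, config$spec)
    chronological_split(design, config$split_date)
  })

  specs <- config$base_learners
  meta_spec <- config$meta_spec
  if (identical(config$tune, "full")) {
    specs <- stage("tune", lapply(specs, function(s) {
      grid_tune(s, split$train$X, split$train$y,
                seed = derive_seed(seed, 2L))$spec
    }))
  }

  meta <- stage("stack", generate_meta_features(
    specs, split, seed = derive_seed(seed, 3L)))
  key_cols <- default_key_columns(split)
  s_new <- assemble_new_datasets(meta, split, key_cols)
  if (config$tune %in% c("meta", "full")) {
    meta_spec <- stage("tune_meta", grid_tune(
      meta_spec, s_new$train$X, s_new$train$y)$spec)
  }

  weights <- if (!is.null(config$lds)) stage("lds", compute_weights(
    split$train$y, as.integer(strftime(split$train$dates, "%Y")),
    config$lds))

  fit_plain <- stage("fit", fit_meta_learner(s_new$train, spec = meta_spec))
  fit_lds <- if (!is.null(weights))
    stage("fit", fit_meta_learner(s_new$train, weights, meta_spec))

  predictions <- stage("evaluate", {
    out <- stats::setNames(
      lapply(seq_along(specs), function(j) meta$N[, j]),
      vapply(specs, `[[`, "", "label"))
    out[["stacking"]] <- predict_meta(fit_plain, s_new$test$X)
    if (!is.null(fit_lds))
      out[["stacking_lds"]] <- predict_meta(fit_lds, s_new$test$X)
    out
  })
  stacked_names <- intersect(c("stacking", "stacking_lds"),
                             names(predictions))
  comparison <- stage("evaluate", comparison_table(
    predictions, split$test$y, stacked = stacked_names))
  metrics <- lapply(predictions,
                    function(p) compute_metrics(split$test$y, p,
                                                keep_errors = FALSE))

  final_fit <- fit_lds %||% fit_plain
  model <- stacked_model(meta, final_fit, key_cols)

  explanation <- NULL
  if (isTRUE(config$explain)) {
    explanation <- stage("explain", {
      set.seed(derive_seed(seed, 5L))
      bg_idx <- sample.int(nrow(split$train$X),
                           min(config$background_size,
                               nrow(split$train$X)))
      ex_idx <- seq_len(min(config$n_explain, nrow(split$test$X)))
      report <- shapley_attributions(
        function(X) predict_stacked(model, X),
        split$train$X[bg_idx, , drop = FALSE],
        split$test$X[ex_idx, , drop = FALSE],
        n_permutations = config$n_permutations,
        seed = derive_seed(seed, 6L))
      groups <- feature_groups(split)
      agg <- aggregate_variable_shap(report, groups)
      decomp <- three_part_decomposition(agg, groups)
      list(report = agg, groups = groups, decomposition = decomp,
           importance = global_importance(agg),
           partial = partial_prediction_metrics(decomp,
                                                split$test$y[ex_idx]))
    })
  }

  structure(list(panel = panel, split = split, meta = meta,
                 fit_log = meta$fit_log, weights = weights,
                 model = model, predictions = predictions,
                 comparison = comparison, metrics = metrics,
                 explanation = explanation, config = config),
            class = "ha_experiment")
}

#' @export
print.ha_experiment <- function(x, ...) {
  cat(sprintf("<ha_experiment> %d base-learner fits; test rows: %d\n",
              nrow(x$fit_log), length(x$split$test$y)))
  print(x$comparison[c("model", "mae", "rmse", "mape", "r2")], digits = 4)
  invisible(x)
}

#' Export the machine-readable metrics of an experiment
#'
#' @param experiment An [run_experiment()] result.
#' @param path Output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_metrics_json <- function(experiment, path) {
  out <- lapply(experiment$metrics, function(m)
    list(MAE = m$mae, RMSE = m$rmse, MAPE = m$mape, R2 = m$r2))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
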