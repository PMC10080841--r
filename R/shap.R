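#' Feature-to-variable and variable-to-part mappings
#'
#' Maps every design column to its underlying variable (all \code{tem_lag_*}
#' columns and the cumulative-lag mean/SD to \code{"tem"}, the one-hot
#' \code{dow_*} indicators to \code{"DOW"}, ...) and every variable to one
#' of the three additive parts: \code{"HAs"}, \code{"calendar"} or
#' \code{"environmental"}.
#'
#' @param split An \code{ha_split} (carries the column tags).
#' @return Object of class \code{ha_feature_groups}: named character
#'   vectors \code{variable_of} (column -> variable) and \code{part_of}
#'   (variable -> part).
#' @export
feature_groups <- function(split) {
  variable_of <- split$variable_of
  part_of <- tapply(unname(split$groups), variable_of[names(split$groups)],
                    function(g) g[1])
  part_of <- stats::setNames(as.character(part_of), names(part_of))
  structure(list(variable_of = variable_of, part_of = part_of),
            class = "ha_feature_groups")
}

#' Permutation-estimated Shapley attributions
#'
#' Estimates per-feature Shapley values of \code{predict_fn} for each row of
#' \code{X_explain} against a background set: features are switched one at a
#' time, in random permutation order, from background values to the
#' explained row's values, and each feature is credited with the mean
#' prediction change it causes; forward and reverse passes of every
#' permutation are averaged (antithetic sampling).  Because each pass
#' telescopes from the background mean to the explained prediction, the
#' additivity identity \code{phi0 + sum(attributions) = prediction} holds
#' exactly by construction, and for a purely linear model the estimate
#' equals \code{coefficient * (x - background mean)} for any number of
#' permutations.
#'
#' @param predict_fn Function: numeric feature matrix -> numeric
#'   predictions (e.g. a [predict_stacked()] closure).
#' @param X_background Background rows (numeric matrix); the base value
#'   \code{phi0} is the mean prediction over this set.
#' @param X_explain Rows to explain (numeric matrix, same columns).
#' @param n_permutations Number of antithetic permutation pairs per row
#'   (default 2).
#' @param seed Integer seed for the permutation draws.
#' @return Object of class \code{ha_shap_report}: \code{phi0}, matrix
#'   \code{values} (rows x features), \code{prediction},
#'   \code{X_explain}, background size and level \code{"feature"}.
#' @export
shapley_attributions <- function(predict_fn, X_background, X_explain,
                                 n_permutations = 2L, seed = 1L) {
  if (!nrow(X_background)) stop("background set is empty", call. = FALSE)
  X_background <- as.matrix(X_background)
  X_explain <- as.matrix(X_explain)
  d <- ncol(X_explain)
  b <- nrow(X_background)
  bg_pred <- predict_fn(X_background)
  if (any(!is.finite(bg_pred)))
    stop("predict_fn returned non-finite values", call. = FALSE)
  phi0 <- mean(bg_pred)

  set.seed(derive_seed(seed, 404L))
  values <- matrix(0, nrow(X_explain), d,
                   dimnames = list(NULL, colnames(X_explain)))
  prediction <- numeric(nrow(X_explain))
  for (r in seq_len(nrow(X_explain))) {
    x <- X_explain[r, ]
    phi <- numeric(d)
    n_pass <- 0L
    for (p in seq_len(n_permutations)) {
      perm <- sample.int(d)
      for (ord in list(perm, rev(perm))) {
        # stage s = background with features ord[1..s] switched to x;
        # stack all d+1 stages and predict in one batch
        stages <- matrix(NA_real_, b * (d + 1L), d)
        cur <- X_background
        stages[seq_len(b), ] <- cur
        for (s in seq_len(d)) {
          cur[, ord[s]] <- x[ord[s]]
          stages[s * b + seq_len(b), ] <- cur
        }
        colnames(stages) <- colnames(X_explain)
        pred <- predict_fn(stages)
        if (any(!is.finite(pred)))
          stop("predict_fn returned non-finite values", call. = FALSE)
        stage_mean <- vapply(seq_len(d + 1L),
                             function(s) mean(pred[(s - 1L) * b + seq_len(b)]),
                             0)
        phi[ord] <- phi[ord] + diff(stage_mean)
        n_pass <- n_pass + 1L
        prediction[r] <- stage_mean[d + 1L]  # all features switched = f(x)
      }
    }
    values[r, ] <- phi / n_pass
  }
  structure(list(phi0 = phi0, values = values, prediction = prediction,
                 X_explain = X_explain, background_size = b,
                 level = "feature"),
            class = "ha_shap_report")
}

#' @export
print.ha_shap_report <- function(x, ...) {
  cat(sprintf(
    "<ha_shap_report> %d sample(s) x %d %s(s); phi0 = %.3f (background n = %d)\n",
    nrow(x$values), ncol(x$values), x$level, x$phi0, x$background_size))
  invisible(x)
}

#' Aggregate column-level attributions per underlying variable
#'
#' A variable's attribution on a sample is the sum of the attributions of
#' all its member columns (all single-day lags plus the cumulative-lag
#' mean/SD), rendering its contribution over the whole lag window;
#' additivity is preserved at the variable level.
#'
#' @param report A feature-level [shapley_attributions()] report.
#' @param groups An [feature_groups()] mapping covering every column.
#' @return The report with variable-level \code{values} (and the original
#'   kept as \code{feature_values}).
#' @export
aggregate_variable_shap <- function(report, groups) {
  cols <- colnames(report$values)
  unmapped <- setdiff(cols, names(groups$variable_of))
  if (length(unmapped))
    stop(paste("unmapped column(s):", paste(unmapped, collapse = ", ")),
         call. = FALSE)
  vars <- groups$variable_of[cols]
  agg <- t(rowsum(t(report$values), group = vars))
  report$feature_values <- report$values
  report$values <- agg
  report$level <- "variable"
  report
}

#' Global importance ranking
#'
#' \code{importance(v) = mean over samples of |attribution of v|}, in
#' descending order, ties broken alphabetically.
#'
#' @param report A (typically variable-level) shap report.
#' @return \code{data.frame(variable, importance)}, ranked.
#' @export
global_importance <- function(report) {
  imp <- colMeans(abs(report$values))
  ord <- order(-imp, names(imp))
  data.frame(variable = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Three-part additive decomposition of the forecasts
#'
#' Splits every explained prediction into the base value \code{phi0}
#' (roughly the average prediction), a \emph{regular} difference carried by
#' the calendar and historical-admissions variables, and a \emph{volatile}
#' difference carried by the environmental variables:
#' \code{prediction = phi0 + regular + volatile}.
#'
#' @param report A variable-level report (see [aggregate_variable_shap()]).
#' @param groups The [feature_groups()] mapping.
#' @return \code{data.frame(phi0, regular, volatile, prediction)}, one row
#'   per explained sample.
#' @export
three_part_decomposition <- function(report, groups) {
  vars <- colnames(report$values)
  unmapped <- setdiff(vars, names(groups$part_of))
  if (length(unmapped))
    stop(paste("unmapped variable(s):", paste(unmapped, collapse = ", ")),
         call. = FALSE)
  part <- groups$part_of[vars]
  env <- part == "environmental"
  regular <- rowSums(report$values[, !env, drop = FALSE])
  volatile <- rowSums(report$values[, env, drop = FALSE])
  data.frame(phi0 = report$phi0, regular = regular, volatile = volatile,
             prediction = report$phi0 + regular + volatile)
}

#' Improvement attributable to the environmental part
#'
#' Evaluates the four metrics for the partial prediction
#' \code{phi0 + regular} (baseline plus calendar/HAs attributions) and for
#' the full prediction, and reports the per-metric relative improvement of
#' full over partial — the share of performance carried by the
#' environmental features.
#'
#' @param decomposition A [three_part_decomposition()] table.
#' @param y Observed counts aligned to its rows.
#' @return List \code{partial}, \code{full} (both \code{ha_eval}) and
#'   \code{improvement} (named percents).
#' @export
partial_prediction_metrics <- function(decomposition, y) {
  if (nrow(decomposition) != length(y))
    stop("decomposition and y are misaligned", call. = FALSE)
  partial <- compute_metrics(y, decomposition$phi0 + decomposition$regular)
  full <- compute_metrics(y, decomposition$prediction)
  improvement <- c(
    mae = relative_improvement(partial$mae, full$mae, "decrease"),
    rmse = relative_improvement(partial$rmse, full$rmse, "decrease"),
    mape = relative_improvement(partial$mape, full$mape, "decrease"),
    r2 = relative_improvement(partial$r2, full$r2, "increase")
  )
  list(partial = partial, full = full, improvement = improvement)
}

#' Local waterfall listing for selected samples
#'
#' Sets \code{phi0 + regular} as a new per-sample baseline and lists the
#' environmental variables by decreasing absolute attribution; the
#' cumulative sum ends at the final prediction.
#'
#' @param decomposition The [three_part_decomposition()] table.
#' @param report The variable-level report it came from.
#' @param groups The [feature_groups()] mapping.
#' @param sample_ids Row indices to list.
#' @return Named list (one element per sample) of
#'   \code{data.frame(variable, value, cumulative)} with attributes
#'   \code{new_baseline} and \code{final_prediction}.
#' @export
local_waterfall <- function(decomposition, report, groups,
                            sample_ids = seq_len(nrow(decomposition))) {
  if (any(sample_ids < 1L | sample_ids > nrow(decomposition)))
    stop("unknown sample id", call. = FALSE)
  env_vars <- names(groups$part_of)[groups$part_of == "environmental"]
  env_vars <- intersect(colnames(report$values), env_vars)
  lapply(stats::setNames(sample_ids, sample_ids), function(r) {
    base <- decomposition$phi0[r] + decomposition$regular[r]
    vals <- report$values[r, env_vars]
    ord <- order(-abs(vals))
    out <- data.frame(variable = env_vars[ord], value = unname(vals[ord]),
                      stringsAsFactors = FALSE)
    out$cumulative <- base + cumsum(out$value)
    attr(out, "new_baseline") <- base
    attr(out, "final_prediction") <-
      if (nrow(out)) out$cumulative[nrow(out)] else base
    out
  })
}

#' Dependence export for one feature
#'
#' Per-sample (feature value, attribution) pairs for a named column (on a
#' feature-level report) or variable (on an aggregated report), ready for a
#' dependence plot; no smoothing applied.
#'
#' @param report A shap report.
#' @param feature Column/variable name.
#' @param feature_values Optional numeric vector overriding the x values
#'   (e.g. the un-normalized lag values for a variable-level report).
#' @return \code{data.frame(value, attribution)}.
#' @export
dependence_export <- function(report, feature, feature_values = NULL) {
  attribution <- if (feature %in% colnames(report$values)) {
    report$values[, feature]
  } else if (!is.null(report$feature_values) &&
             feature %in% colnames(report$feature_values)) {
    report$feature_values[, feature]  # column-level on an aggregated report
  } else stop(sprintf("unknown feature '%s'", feature), call. = FALSE)
  x <- feature_values %||%
    if (feature %in% colnames(report$X_explain)) report$X_explain[, feature]
    else stop(sprintf(
      "no stored values for '%s'; supply feature_values", feature),
      call. = FALSE)
  data.frame(value = as.numeric(x),
             attribution = as.numeric(attribution))
}
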