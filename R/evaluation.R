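#' Four-metric forecast evaluation
#'
#' Mean absolute error, root mean square error, mean absolute percentage
#' error (reported as a fraction, e.g. 0.145 = 14.5\%) and the coefficient
#' of determination \code{R2 = 1 - SS_res / SS_tot}, all on the raw count
#' scale.
#'
#' @param y Observed counts (positive; a zero observation is an error
#'   unless \code{eps > 0} guards the MAPE denominator).
#' @param yhat Predicted values, same length.
#' @param eps Optional denominator guard for MAPE (default 0 = strict).
#' @param keep_errors Keep the per-day loss vectors (absolute, squared,
#'   absolute-percentage) for paired testing.
#' @return Object of class \code{ha_eval}: list with \code{mae},
#'   \code{rmse}, \code{mape}, \code{r2}, \code{n} and (optionally)
#'   \code{errors}.
#' @export
compute_metrics <- function(y, yhat, eps = 0, keep_errors = TRUE) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(y <= 0) && eps <= 0)
    stop("non-positive observation; MAPE undefined (set eps > 0 to guard)",
         call. = FALSE)
  abs_err <- abs(y - yhat)
  sq_err <- (y - yhat)^2
  ape <- abs_err / pmax(y, eps)
  out <- list(mae = mean(abs_err), rmse = sqrt(mean(sq_err)),
              mape = mean(ape),
              r2 = 1 - sum(sq_err) / sum((y - mean(y))^2),
              n = length(y))
  if (keep_errors)
    out$errors <- list(absolute = abs_err, squared = sq_err,
                       absolute_percentage = ape)
  structure(out, class = "ha_eval")
}

#' @export
print.ha_eval <- function(x, ...) {
  cat(sprintf("MAE %.3f  RMSE %.3f  MAPE %.3f  R2 %.3f  (n = %d)\n",
              x$mae, x$rmse, x$mape, x$r2, x$n))
  invisible(x)
}

#' Paired t-test on per-day loss vectors
#'
#' Two-sided paired t-test of the difference between two models' per-day
#' losses over the same test days (absolute errors for MAE comparisons,
#' squared for RMSE, absolute-percentage for MAPE).
#'
#' @param errors_a,errors_b Equal-length loss vectors (length >= 3).
#' @return List \code{t}, \code{p}, \code{df}.  A zero-variance difference
#'   with nonzero mean reports \code{p = 0} with a warning; with zero mean,
#'   \code{t = 0, p = 1}.
#' @export
paired_error_t_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("loss vectors must have equal length", call. = FALSE)
  n <- length(errors_a)
  if (n < 3L) stop("need at least 3 paired losses", call. = FALSE)
  d <- errors_a - errors_b
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1L))
    warning("zero-variance nonzero difference; p reported as 0",
            call. = FALSE)
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1L), df = n - 1L)
}

#' Relative improvement in percent
#'
#' \code{decrease}: \code{100 * (reference - achieved) / reference} (error
#' metrics, smaller is better); \code{increase}: \code{100 * (achieved -
#' reference) / reference} (R2).
#'
#' @param reference Non-zero reference value (the best individual model).
#' @param achieved The improved model's value.
#' @param direction \code{"decrease"} or \code{"increase"}.
#' @return Percent improvement (positive = better).
#' @export
relative_improvement <- function(reference, achieved,
                                 direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (reference == 0) stop("reference value is zero", call. = FALSE)
  if (direction == "decrease") 100 * (reference - achieved) / reference
  else 100 * (achieved - reference) / reference
}

#' Multi-model comparison table
#'
#' One row per model with the four metrics; the best value per metric is
#' flagged, and each model named in \code{stacked} gets a significance star
#' per error metric when the paired t-test against the best individual
#' (non-stacked) model rejects at \code{p < 0.05}.
#'
#' @param predictions Named list of prediction vectors, all aligned to
#'   \code{y}; row order follows the list order.
#' @param y Observed counts.
#' @param stacked Names of ensemble models (excluded when choosing the
#'   best-individual reference).
#' @return \code{data.frame} with metrics, \code{best_*} flags and
#'   \code{signif_*} stars.
#' @export
comparison_table <- function(predictions, y, stacked = character()) {
  if (!length(predictions)) stop("empty model set", call. = FALSE)
  if (is.null(names(predictions)) || any(names(predictions) == ""))
    stop("predictions must be a fully named list", call. = FALSE)
  evals <- lapply(predictions, function(p) compute_metrics(y, p))
  tab <- data.frame(
    model = names(predictions),
    mae = vapply(evals, `[[`, 0, "mae"),
    rmse = vapply(evals, `[[`, 0, "rmse"),
    mape = vapply(evals, `[[`, 0, "mape"),
    r2 = vapply(evals, `[[`, 0, "r2"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (m in c("mae", "rmse", "mape", "r2")) {
    best <- if (m == "r2") max(tab[[m]]) else min(tab[[m]])
    tab[[paste0("best_", m)]] <- tab[[m]] == best
  }
  individuals <- setdiff(tab$model, stacked)
  loss_of <- c(mae = "absolute", rmse = "squared",
               mape = "absolute_percentage")
  for (m in names(loss_of)) {
    stars <- rep("", nrow(tab))
    if (length(individuals) && length(stacked)) {
      ref_model <- individuals[which.min(tab[[m]][tab$model %in% individuals])]
      for (s in intersect(stacked, tab$model)) {
        tt <- paired_error_t_test(evals[[ref_model]]$errors[[loss_of[m]]],
                                  evals[[s]]$errors[[loss_of[m]]])
        if (tt$p < 0.05) stars[tab$model == s] <- "*"
      }
    }
    tab[[paste0("signif_", m)]] <- stars
  }
  tab
}
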