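#' Base-learner specification
#'
#' One of the four heterogeneous first-phase regressors (or a custom/constant
#' learner for testing).  Families:
#' \describe{
#'   \item{ridge}{linear regression with an L2 penalty (glmnet, alpha = 0);
#'     params: \code{lambda}.}
#'   \item{random_forest}{ranger regression forest; params:
#'     \code{num_trees}, \code{mtry_frac}, \code{min_node_size}.}
#'   \item{gbdt}{gradient-boosted regression trees (xgboost); params:
#'     \code{nrounds}, \code{eta}, \code{max_depth}, \code{subsample}.}
#'   \item{ann}{single-hidden-layer feedforward network (nnet, logistic
#'     hidden units, linear output, BFGS with weight decay); params:
#'     \code{size}, \code{decay}, \code{maxit}.}
#'   \item{constant}{always predicts \code{params$value} (testing aid).}
#'   \item{custom}{user-supplied \code{fit(X, y)} / \code{predict(model, X)}.}
#' }
#'
#' @param family Learner family string.
#' @param params Named list of hyperparameters (defaults filled in).
#' @param grid Named list of candidate values for [grid_tune()]; crossed in
#'   list order.
#' @param fit,predict Functions for \code{family = "custom"}.
#' @param label Display label (defaults to the family name).
#' @return An object of class \code{ha_learner_spec}.
#' @export
base_learner_spec <- function(family = c("ridge", "random_forest", "gbdt",
                                         "ann", "constant", "custom"),
                              params = list(), grid = NULL,
                              fit = NULL, predict = NULL, label = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    ridge = list(lambda = 0.1),
    random_forest = list(num_trees = 300, mtry_frac = 1 / 3,
                         min_node_size = 5),
    gbdt = list(nrounds = 300, eta = 0.05, max_depth = 3, subsample = 0.8),
    ann = list(size = 16, decay = 0.1, maxit = 200),
    constant = list(value = 0),
    custom = list()
  )
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults, grid = grid,
                 fit = fit, predict = predict,
                 label = label %||% family),
            class = "ha_learner_spec")
}

#' The default four-learner ensemble
#'
#' Ridge, random forest, gradient-boosted trees and a feedforward network —
#' pairwise distinct families, as the heterogeneity of the ensemble requires.
#'
#' @param ann_size,ann_maxit Network size/iteration overrides (the costliest
#'   fits; exposed for quick experiments).
#' @return List of four [base_learner_spec()] objects.
#' @export
default_base_learners <- function(ann_size = 16, ann_maxit = 200) {
  list(
    base_learner_spec("ridge",
                      grid = list(lambda = c(0.01, 0.1, 1))),
    base_learner_spec("random_forest",
                      grid = list(num_trees = c(200, 300),
                                  min_node_size = c(5, 10))),
    base_learner_spec("gbdt",
                      grid = list(nrounds = c(150, 300),
                                  max_depth = c(2, 3))),
    base_learner_spec("ann", params = list(size = ann_size,
                                           maxit = ann_maxit),
                      grid = list(decay = c(0.05, 0.1, 0.5)))
  )
}

# fit one learner on (X, y); `seed` pins every stochastic component
fit_learner <- function(spec, X, y, seed = 1L) {
  p <- spec$params
  model <- switch(spec$family,
    ridge = {
      fit_glmnet_path(X, y, alpha = 0, lambda = p$lambda)
    },
    random_forest = {
      ranger::ranger(
        x = as.data.frame(X), y = y,
        num.trees = p$num_trees,
        mtry = max(1L, floor(p$mtry_frac * ncol(X))),
        min.node.size = p$min_node_size,
        seed = seed, num.threads = 1L)
    },
    gbdt = {
      xgboost::xgboost(
        x = X, y = y, nrounds = p$nrounds,
        learning_rate = p$eta, max_depth = p$max_depth,
        subsample = p$subsample, objective = "reg:squarederror",
        nthreads = 1L, seed = seed, verbosity = 0L)
    },
    ann = {
      set.seed(seed)
      nnet::nnet(x = X, y = y, size = p$size, decay = p$decay,
                 maxit = p$maxit, linout = TRUE, trace = FALSE,
                 MaxNWts = 100000L)
    },
    constant = p$value,
    custom = spec$fit(X, y)
  )
  structure(list(spec = spec, model = model, features = colnames(X)),
            class = "ha_fitted_learner")
}

predict_learner <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  spec <- fit$spec
  pred <- switch(spec$family,
    ridge = predict_glmnet_path(fit$model, X),
    random_forest = stats::predict(fit$model, data = as.data.frame(X),
                                   num.threads = 1L)$predictions,
    gbdt = stats::predict(fit$model, X),
    ann = as.numeric(stats::predict(fit$model, X)),
    constant = rep(fit$model, nrow(X)),
    custom = spec$predict(fit$model, X)
  )
  pred <- as.numeric(pred)
  if (any(!is.finite(pred)))
    stop(sprintf("learner '%s' produced non-finite predictions", spec$label),
         call. = FALSE)
  pred
}

# glmnet fitted along a short decreasing lambda path ending at the target
# value (a lone small lambda converges poorly in coordinate descent)
fit_glmnet_path <- function(X, y, alpha, lambda, weights = NULL) {
  if (stats::sd(y) == 0)  # degenerate constant target
    return(list(fit = NULL, lambda = lambda, constant = y[1], p = ncol(X)))
  lam_path <- sort(unique(c(max(lambda, 1e-4) * c(100, 10), lambda)),
                   decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam_path,
                        weights = weights, standardize = TRUE,
                        thresh = 1e-16, maxit = 1e7)
  list(fit = fit, lambda = lambda)
}

predict_glmnet_path <- function(model, X) {
  if (!is.null(model$constant)) return(rep(model$constant, nrow(X)))
  as.numeric(stats::predict(model$fit, newx = X, s = model$lambda,
                            exact = FALSE))
}

#' Plan contiguous chronological cross-validation folds
#'
#' Splits \code{n_rows} chronologically ordered rows into \code{k}
#' contiguous, non-overlapping blocks whose sizes differ by at most one;
#' when the division is uneven the earlier folds receive the extra rows.
#'
#' @param n_rows Number of training rows.
#' @param k Fold count (default 5).
#' @return Object of class \code{ha_fold_plan}: list of integer row-index
#'   vectors.
#' @export
plan_folds <- function(n_rows, k = 5L) {
  n_rows <- as.integer(n_rows); k <- as.integer(k)
  if (n_rows < k) stop("need at least k rows to form k folds", call. = FALSE)
  base <- n_rows %/% k
  sizes <- rep(base, k) + c(rep(1L, n_rows %% k), rep(0L, k - n_rows %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  structure(Map(function(s, e) s:e, starts, ends), class = "ha_fold_plan")
}

#' Generate out-of-fold meta features from the base learners
#'
#' First stacking phase.  For each base learner j and fold i, the learner is
#' trained on every training fold except fold i (chronologically later folds
#' included, unless \code{forward_chaining}) and predicts fold i; the
#' concatenated out-of-fold predictions form meta feature \code{M_j} on the
#' training rows.  The same per-fold model also predicts the test rows
#' (\code{Q_ji}); their arithmetic mean over folds is the test-side meta
#' feature \code{N_j}.  With 4 learners and 5 folds this performs exactly 20
#' fits, each logged with learner, fold and training-row count.
#'
#' @param specs List of [base_learner_spec()]s (pairwise distinct families).
#' @param split An [chronological_split()] result.
#' @param plan A [plan_folds()] plan for the training rows.
#' @param seed Integer; each (learner, fold) fit gets a derived sub-seed.
#' @param forward_chaining If \code{TRUE}, fold i's model is trained only on
#'   folds before i (fold 1 then uses all other folds, to keep one model per
#'   fold); default \code{FALSE}, the all-other-folds scheme.
#' @return Object of class \code{ha_meta_features}: matrices \code{M}
#'   (train rows x learners), \code{N} (test rows x learners), array
#'   \code{Q} (test rows x folds x learners), the per-fold fitted models,
#'   and the \code{fit_log} data.frame.
#' @export
generate_meta_features <- function(specs, split, plan = NULL, seed = 1L,
                                   forward_chaining = FALSE) {
  fams <- vapply(specs, `[[`, "", "family")
  if (anyDuplicated(fams[fams != "custom" & fams != "constant"]))
    stop("base-learner families must be pairwise distinct", call. = FALSE)
  n_train <- length(split$train$y)
  plan <- plan %||% plan_folds(n_train, 5L)
  k <- length(plan)
  J <- length(specs)
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) labels <- sprintf("%s_%d", labels, seq_len(J))

  M <- matrix(NA_real_, n_train, J, dimnames = list(NULL, labels))
  Q <- array(NA_real_, dim = c(length(split$test$y), k, J),
             dimnames = list(NULL, NULL, labels))
  models <- vector("list", J)
  log_rows <- list()
  for (j in seq_len(J)) {
    models[[j]] <- vector("list", k)
    for (i in seq_len(k)) {
      train_idx <- if (forward_chaining && i > 1L) {
        unlist(plan[seq_len(i - 1L)])
      } else {
        unlist(plan[-i])
      }
      fit <- tryCatch(
        fit_learner(specs[[j]], split$train$X[train_idx, , drop = FALSE],
                    split$train$y[train_idx],
                    seed = derive_seed(seed, j, i)),
        error = function(e) stop(sprintf(
          "base learner '%s' failed on fold %d: %s", labels[j], i,
          conditionMessage(e)), call. = FALSE))
      M[plan[[i]], j] <-
        predict_learner(fit, split$train$X[plan[[i]], , drop = FALSE])
      Q[, i, j] <- predict_learner(fit, split$test$X)
      models[[j]][[i]] <- fit
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        learner = labels[j], fold = i, n_train_rows = length(train_idx))
    }
  }
  N <- apply(Q, c(1, 3), mean)
  structure(list(M = M, N = N, Q = Q, models = models, plan = plan,
                 labels = labels, fit_log = do.call(rbind, log_rows)),
            class = "ha_meta_features")
}

#' Default key-feature columns
#'
#' All calendar-group and HAs-group columns of the design — the original
#' features passed through to the meta learner alongside the meta features.
#'
#' @param split An \code{ha_split}.
#' @return Character vector of column names.
#' @export
default_key_columns <- function(split) {
  names(split$groups)[split$groups %in% c("calendar", "HAs")]
}

#' Assemble the second-phase design matrices
#'
#' \code{X_new_train = (M_1..M_J, key features)} on training rows and
#' \code{X_new_test = (N_1..N_J, key features)} on test rows; labels carried
#' through unchanged.
#'
#' @param meta An [generate_meta_features()] result.
#' @param split The originating \code{ha_split}.
#' @param key_columns Character vector of pass-through columns (may be
#'   empty).
#' @return List \code{train} and \code{test}, each \code{(X, y, dates)}.
#' @export
assemble_new_datasets <- function(meta, split,
                                  key_columns = default_key_columns(split)) {
  missing_cols <- setdiff(key_columns, colnames(split$train$X))
  if (length(missing_cols))
    stop(paste("key column(s) not in design:",
               paste(missing_cols, collapse = ", ")), call. = FALSE)
  list(
    train = list(X = cbind(meta$M,
                           split$train$X[, key_columns, drop = FALSE]),
                 y = split$train$y, dates = split$train$dates),
    test = list(X = cbind(meta$N,
                          split$test$X[, key_columns, drop = FALSE]),
                y = split$test$y, dates = split$test$dates)
  )
}

#' Meta-learner specification (elastic net)
#'
#' @param alpha Mixing parameter in \code{[0, 1]} (0 = ridge, 1 = lasso).
#' @param lambda Penalty strength.
#' @param grid Candidate values for [grid_tune()].
#' @return Object of class \code{ha_meta_spec}.
#' @export
meta_learner_spec <- function(alpha = 0.5, lambda = 0.5,
                              grid = list(alpha = c(0.1, 0.5, 0.9),
                                          lambda = c(0.1, 0.5, 1))) {
  structure(list(alpha = alpha, lambda = lambda, grid = grid),
            class = "ha_meta_spec")
}

#' Fit the elastic-net meta learner
#'
#' Minimizes the (optionally sample-weighted) squared error plus the
#' combined L1 + L2 penalty on the second-phase design.  With equal weights
#' the fit coincides with the unweighted one.
#'
#' @param s_new_train List \code{(X, y)} from [assemble_new_datasets()].
#' @param weights Optional positive weights aligned to training rows (e.g.
#'   [compute_weights()]).
#' @param spec A [meta_learner_spec()].
#' @return Object of class \code{ha_meta_fit} with \code{coef()} support.
#' @export
fit_meta_learner <- function(s_new_train, weights = NULL,
                             spec = meta_learner_spec()) {
  if (!is.null(weights)) {
    w <- if (inherits(weights, "ha_sample_weights")) weights$weight
         else as.numeric(weights)
    if (length(w) != length(s_new_train$y))
      stop("weights are misaligned with the training rows", call. = FALSE)
    if (any(!is.finite(w)) || any(w <= 0))
      stop("weights must be strictly positive and finite", call. = FALSE)
  } else w <- NULL
  model <- fit_glmnet_path(s_new_train$X, s_new_train$y,
                           alpha = spec$alpha, lambda = spec$lambda,
                           weights = w)
  structure(list(model = model, spec = spec,
                 features = colnames(s_new_train$X)),
            class = "ha_meta_fit")
}

#' @export
coef.ha_meta_fit <- function(object, ...) {
  if (!is.null(object$model$constant))
    return(c(object$model$constant, rep(0, object$model$p)))
  as.numeric(stats::coef(object$model$fit, s = object$model$lambda))
}

predict_meta <- function(fit, X) {
  predict_glmnet_path(fit$model, X[, fit$features, drop = FALSE])
}

#' Bundle a fitted stacked model
#'
#' Everything needed to score raw design rows: the per-fold base models, the
#' fitted meta learner and the key-feature list.
#'
#' @param meta An [generate_meta_features()] result.
#' @param meta_fit An [fit_meta_learner()] result.
#' @param key_columns Pass-through column names.
#' @return Object of class \code{ha_stacked_model}.
#' @export
stacked_model <- function(meta, meta_fit, key_columns) {
  structure(list(meta = meta, meta_fit = meta_fit,
                 key_columns = key_columns),
            class = "ha_stacked_model")
}

#' Score raw design rows through the full stacked pipeline
#'
#' For each base learner the k fold models are scored and averaged (the
#' test-side \code{N_j} construction), the key features are appended, and
#' the meta learner produces the final real-valued forecast (not rounded:
#' the evaluation metrics are computed on real values).
#'
#' @param model An [stacked_model()].
#' @param X Numeric matrix of preprocessed design rows (all original
#'   feature columns).
#' @return Numeric vector of predicted daily counts.
#' @export
predict_stacked <- function(model, X) {
  missing_cols <- setdiff(model$key_columns, colnames(X))
  if (length(missing_cols))
    stop(paste("missing feature column(s):",
               paste(missing_cols, collapse = ", ")), call. = FALSE)
  J <- length(model$meta$models)
  Nmat <- matrix(NA_real_, nrow(X), J,
                 dimnames = list(NULL, model$meta$labels))
  for (j in seq_len(J)) {
    preds <- vapply(model$meta$models[[j]],
                    function(f) predict_learner(f, X), numeric(nrow(X)))
    preds <- matrix(preds, nrow = nrow(X))
    Nmat[, j] <- rowMeans(preds)
  }
  X_new <- cbind(Nmat, X[, model$key_columns, drop = FALSE])
  predict_meta(model$meta_fit, X_new)
}

#' @export
print.ha_stacked_model <- function(x, ...) {
  cat(sprintf(
    "<ha_stacked_model> %d base learners x %d folds; meta elastic net (alpha=%g, lambda=%g); %d key features\n",
    length(x$meta$models), length(x$meta$plan),
    x$meta_fit$spec$alpha, x$meta_fit$spec$lambda, length(x$key_columns)))
  invisible(x)
}

#' Holdout grid search over hyperparameters
#'
#' Fits each grid point on the first \code{1 - holdout_fraction} of the
#' chronologically ordered rows, evaluates mean absolute error on the
#' remaining holdout block, and returns the spec updated with the
#' MAE-minimizing combination (ties broken by grid order).  No refit is
#' performed here; the selected hyperparameters are used by the subsequent
#' cross-validation fits.
#'
#' @param spec A [base_learner_spec()] or [meta_learner_spec()] carrying a
#'   non-empty \code{grid}.
#' @param X,y The chronologically ordered design and target.
#' @param holdout_fraction Fraction of rows held out (default 0.2, the last
#'   fifth).
#' @param seed Seed for stochastic learners.
#' @return List: \code{spec} (updated), \code{results} (one row per grid
#'   point with its holdout MAE, in evaluation order).
#' @export
grid_tune <- function(spec, X, y, holdout_fraction = 0.2, seed = 1L) {
  grid <- spec$grid
  if (is.null(grid) || !length(grid) || !nrow(expand.grid(grid)))
    stop("tuning grid is empty", call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  n <- length(y)
  n_fit <- floor((1 - holdout_fraction) * n)
  if (n_fit < 1L || n_fit >= n)
    stop("holdout split leaves an empty part", call. = FALSE)
  fit_idx <- seq_len(n_fit); hold_idx <- (n_fit + 1L):n

  maes <- numeric(nrow(combos))
  for (g in seq_len(nrow(combos))) {
    params <- as.list(combos[g, , drop = FALSE])
    if (inherits(spec, "ha_meta_spec")) {
      cand <- spec; cand[names(params)] <- params
      fit <- fit_meta_learner(list(X = X[fit_idx, , drop = FALSE],
                                   y = y[fit_idx]), spec = cand)
      pred <- predict_meta(fit, X[hold_idx, , drop = FALSE])
    } else {
      cand <- spec; cand$params[names(params)] <- params
      fit <- fit_learner(cand, X[fit_idx, , drop = FALSE], y[fit_idx],
                         seed = derive_seed(seed, 900L, g))
      pred <- predict_learner(fit, X[hold_idx, , drop = FALSE])
    }
    maes[g] <- mean(abs(y[hold_idx] - pred))
  }
  best <- which.min(maes)  # first minimum = earliest grid point on ties
  params <- as.list(combos[best, , drop = FALSE])
  if (inherits(spec, "ha_meta_spec")) spec[names(params)] <- params
  else spec$params[names(params)] <- params
  list(spec = spec,
       results = cbind(combos, holdout_mae = maes),
       best = best)
}
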