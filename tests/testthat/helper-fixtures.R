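# Fixtures are built in code: small panels from the generator, plus light
# learner specs so multi-fit tests stay fast.

light_learners <- function() {
  list(
    base_learner_spec("ridge", params = list(lambda = 0.1)),
    base_learner_spec("random_forest", params = list(num_trees = 50)),
    base_learner_spec("gbdt", params = list(nrounds = 50)),
    base_learner_spec("ann", params = list(size = 4, maxit = 60))
  )
}

small_config <- function(n_days = 200L, seed = 1L, ...) {
  generator_config(n_days = n_days, seed = seed, ...)
}

small_split <- function(n_days = 120L, seed = 1L, split_frac = 0.75) {
  panel <- generate_panel(small_config(n_days, seed))
  design <- build_design(panel)
  suppressWarnings(
    chronological_split(design, design$date[ceiling(split_frac * nrow(design))]))
}

# hand-built panel with explicit environmental values (all ten columns)
make_panel_df <- function(values, ha = NULL, start = "2020-01-01") {
  n <- if (length(values)) length(values[[1]]) else length(ha)
  out <- data.frame(date = seq(as.Date(start), by = "day", length.out = n),
                    ha_count = as.integer(ha %||% rep(5L, n)))
  for (v in env_variables()) out[[v]] <- values[[v]] %||% rep(1, n)
  class(out) <- c("ha_panel", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent naive double-loop reference for the out-of-fold stacking phase
naive_meta_reference <- function(specs, split, plan, seed = 1L) {
  n_test <- length(split$test$y)
  M <- matrix(NA_real_, length(split$train$y), length(specs))
  N <- matrix(0, n_test, length(specs))
  for (j in seq_along(specs)) {
    for (i in seq_along(plan)) {
      idx <- sort(unlist(plan[-i]))
      fit <- hastack:::fit_learner(specs[[j]],
                                   split$train$X[idx, , drop = FALSE],
                                   split$train$y[idx],
                                   seed = hastack:::derive_seed(seed, j, i))
      M[plan[[i]], j] <- hastack:::predict_learner(
        fit, split$train$X[plan[[i]], , drop = FALSE])
      N[, j] <- N[, j] +
        hastack:::predict_learner(fit, split$test$X) / length(plan)
    }
  }
  list(M = M, N = N)
}
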