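#' Label-distribution-smoothing configuration
#'
#' Parameters of the effective-label-density re-weighting: daily counts are
#' binned, the empirical bin density is convolved with a symmetric kernel
#' (accounting for the information shared by nearby labels), and each
#' training row is weighted by the inverse effective density of its label's
#' bin, stratified by calendar year by default (the count distribution
#' shifts upward year over year).
#'
#' @param bin_width Positive bin width on the count scale (default 1: labels
#'   are integer counts).
#' @param kernel One of \code{"gaussian"}, \code{"triangular"},
#'   \code{"laplace"}, \code{"delta"} (delta = no smoothing, classical
#'   inverse-frequency weighting).
#' @param kernel_size Odd window length in bins (default 5).
#' @param sigma Kernel scale in bins (default 2).
#' @param per_year Stratify the density estimate by calendar year
#'   (default \code{TRUE}).
#' @param normalize_mean_to_one Rescale the final weights to mean 1
#'   (default \code{TRUE}).
#' @param max_weight Optional clip applied before the mean-1 rescaling.
#' @return Object of class \code{ha_lds_config}.
#' @export
lds_config <- function(bin_width = 1, kernel = c("gaussian", "triangular",
                                                 "laplace", "delta"),
                       kernel_size = 5L, sigma = 2, per_year = TRUE,
                       normalize_mean_to_one = TRUE, max_weight = NULL) {
  kernel <- match.arg(kernel)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L)
    stop_cfg("kernel_size", "must be a positive odd integer")
  if (!is.numeric(sigma) || sigma <= 0) stop_cfg("sigma", "must be positive")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_cfg("bin_width", "must be positive")
  structure(list(bin_width = bin_width, kernel = kernel,
                 kernel_size = kernel_size, sigma = sigma,
                 per_year = isTRUE(per_year),
                 normalize_mean_to_one = isTRUE(normalize_mean_to_one),
                 max_weight = max_weight),
            class = "ha_lds_config")
}

# symmetric kernel weights over offsets -h..h, normalized to sum 1
kernel_weights <- function(kernel, kernel_size, sigma) {
  h <- (kernel_size - 1L) %/% 2L
  off <- -h:h
  w <- switch(kernel,
    gaussian = exp(-off^2 / (2 * sigma^2)),
    triangular = pmax(h + 1 - abs(off), 0),
    laplace = exp(-abs(off) / sigma),
    delta = as.numeric(off == 0L))
  w / sum(w)
}

#' Bin labels into an empirical density table
#'
#' Bins of the given width spanning \code{[floor(min y), ceil(max y)]};
#' density = bin count / n, so the densities sum to one.
#'
#' @param y Non-empty finite label vector.
#' @param bin_width Positive bin width.
#' @return \code{data.frame(center, density)}, one row per bin (empty bins
#'   included), with attribute \code{"bin_of"}: each label's bin index.
#' @export
bin_labels <- function(y, bin_width = 1) {
  if (!length(y)) stop("label vector is empty", call. = FALSE)
  if (any(!is.finite(y))) stop("labels must be finite", call. = FALSE)
  lo <- floor(min(y)); hi <- ceiling(max(y))
  n_bins <- max(1L, floor((hi - lo) / bin_width) + 1L)
  idx <- pmin(floor((y - lo) / bin_width) + 1L, n_bins)
  dens <- tabulate(idx, nbins = n_bins) / length(y)
  out <- data.frame(center = lo + (seq_len(n_bins) - 1L) * bin_width,
                    density = dens)
  attr(out, "bin_of") <- idx
  out
}

#' Smooth an empirical label density into an effective density
#'
#' Discrete convolution of the empirical bin densities with the configured
#' symmetric kernel, truncated at the label-range boundary without
#' renormalization.  The delta kernel returns the empirical density
#' unchanged.
#'
#' @param empirical Output of [bin_labels()].
#' @param config An [lds_config()].
#' @return The table with an added \code{effective} column.
#' @export
smooth_density <- function(empirical, config = lds_config()) {
  w <- kernel_weights(config$kernel, config$kernel_size, config$sigma)
  h <- (config$kernel_size - 1L) %/% 2L
  d <- empirical$density
  n <- length(d)
  eff <- numeric(n)
  for (k in seq_len(n)) {
    off <- max(1L, k - h):min(n, k + h)
    eff[k] <- sum(d[off] * w[off - k + h + 1L])
  }
  empirical$effective <- eff
  empirical
}

#' Inverse-effective-density sample weights
#'
#' Within each year stratum the labels are binned and smoothed, and each row
#' receives weight \code{1 / effective_density(bin of its label)}; weights
#' are then optionally clipped and globally rescaled to mean one (global,
#' not per-stratum, so strata with rarer labels genuinely up-weight).
#' A stratum with fewer than two distinct labels falls back to uniform
#' weights with a warning.
#'
#' @param y_train Training labels (counts).
#' @param years Per-row year stratum (any vector alignable to
#'   \code{y_train}); ignored when \code{config$per_year} is \code{FALSE}.
#' @param config An [lds_config()].
#' @return Object of class \code{ha_sample_weights}: \code{data.frame}-like
#'   list with per-row \code{weight}, \code{effective_density},
#'   \code{stratum}, plus the per-stratum density tables.
#' @export
compute_weights <- function(y_train, years = NULL, config = lds_config()) {
  n <- length(y_train)
  if (config$per_year) {
    if (is.null(years)) stop("years is required when per_year = TRUE",
                             call. = FALSE)
    if (length(years) != n)
      stop("years vector is misaligned with y_train", call. = FALSE)
    strata <- as.character(years)
  } else strata <- rep("all", n)

  weight <- numeric(n)
  eff_dens <- numeric(n)
  tables <- list()
  for (s in unique(strata)) {
    idx <- which(strata == s)
    ys <- y_train[idx]
    if (length(unique(ys)) < 2L) {
      warning(sprintf(
        "stratum '%s' has fewer than 2 distinct labels; uniform weights", s),
        call. = FALSE)
      weight[idx] <- 1; eff_dens[idx] <- NA_real_
      next
    }
    tab <- smooth_density(bin_labels(ys, config$bin_width), config)
    bin_of <- attr(tab, "bin_of")
    eff_dens[idx] <- tab$effective[bin_of]
    weight[idx] <- 1 / eff_dens[idx]
    tables[[s]] <- tab
  }
  if (!is.null(config$max_weight))
    weight <- pmin(weight, config$max_weight)
  if (config$normalize_mean_to_one)
    weight <- weight / mean(weight)
  structure(list(weight = weight, effective_density = eff_dens,
                 stratum = strata, tables = tables, config = config),
            class = "ha_sample_weights")
}

#' @export
print.ha_sample_weights <- function(x, ...) {
  cat(sprintf(
    "<ha_sample_weights> %d rows, %d stratum(a), kernel=%s; weight range [%.3f, %.3f], mean %.3f\n",
    length(x$weight), length(unique(x$stratum)), x$config$kernel,
    min(x$weight), max(x$weight), mean(x$weight)))
  invisible(x)
}
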