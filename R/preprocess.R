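# ISO day of week, Monday = 1 .. Sunday = 7
dow_monday1 <- function(dates) {
  w <- as.POSIXlt(dates)$wday  # Sunday = 0
  ifelse(w == 0L, 7L, w)
}

#' Lag specification
#'
#' Maximum lag \code{L} (days) for the single-day lag features (lags 1..L)
#' and the cumulative window \code{[1, L]} used by the moving mean/SD
#' features.  The default \code{L = 6} captures the short-term effect window
#' conventional in environmental epidemiology.
#'
#' @param L Positive integer maximum lag.
#' @return An object of class \code{ha_lag_spec}.
#' @export
lag_spec <- function(L = 6L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("L must be a positive integer", call. = FALSE)
  structure(list(L = L, single_day_lags = seq_len(L)),
            class = "ha_lag_spec")
}

#' Fill missing environmental cells by linear interpolation in time
#'
#' Interior missing runs are replaced by straight-line interpolation between
#' the nearest non-missing neighbours; leading/trailing runs are filled by
#' nearest-value extension (interpolation needs two anchors).  The count
#' column is never touched.
#'
#' @param panel An \code{ha_panel}.
#' @return The panel with complete environmental columns.
#' @export
interpolate_missing <- function(panel) {
  for (v in intersect(env_variables(), names(panel))) {
    x <- panel[[v]]
    if (!anyNA(x)) next
    if (all(is.na(x)))
      stop(sprintf("environmental column '%s' is entirely missing", v),
           call. = FALSE)
    panel[[v]] <- if (sum(!is.na(x)) == 1L) {
      rep(x[!is.na(x)], length(x))  # a single anchor extends everywhere
    } else {
      stats::approx(seq_along(x), x, xout = seq_along(x),
                    method = "linear", rule = 2)$y
    }
  }
  panel
}

# lag block for one series: <name>_lag_x, x = 1..L, plus moving mean and
# sample SD over the previous 1..L days; first L rows carry NA history
lag_block <- function(x, name, L) {
  n <- length(x)
  out <- matrix(NA_real_, nrow = n, ncol = L + 2L)
  colnames(out) <- c(sprintf("%s_lag_%d", name, seq_len(L)),
                     sprintf("%s_lag_1%d_mean", name, L),
                     sprintf("%s_lag_1%d_std", name, L))
  for (x_lag in seq_len(L))
    out[(x_lag + 1):n, x_lag] <- x[1:(n - x_lag)]
  lag_cols <- out[, seq_len(L), drop = FALSE]
  out[, L + 1L] <- rowMeans(lag_cols)
  out[, L + 2L] <- apply(lag_cols, 1, stats::sd)
  out
}

#' Build the lagged feature block of the supervised design
#'
#' For the admission count and each environmental variable: single-day lags
#' 1..L, the moving average over the previous 1..L days, and the sample SD
#' (ddof = 1) over the same window.  The first L rows, which lack full
#' history, are dropped.  Count-derived columns carry group tag \code{"HAs"},
#' environmental ones \code{"environmental"}.
#'
#' @param panel An \code{ha_panel} with no missing environmental values.
#' @param spec A [lag_spec()].
#' @return A \code{data.frame} (dates, target \code{y}, lag columns) with a
#'   \code{"groups"} attribute naming each feature column's group, and a
#'   \code{"variable_of"} attribute naming its source series.
#' @export
make_lag_features <- function(panel, spec = lag_spec()) {
  L <- spec$L
  if (nrow(panel) < L + 1L)
    stop(sprintf("panel needs at least L+1 = %d rows", L + 1L), call. = FALSE)
  env <- intersect(env_variables(), names(panel))
  if (anyNA(panel[env]))
    stop("environmental columns contain missing values; interpolate first",
         call. = FALSE)
  blocks <- c(list(lag_block(panel$ha_count, "has", L)),
              lapply(env, function(v) lag_block(panel[[v]], v, L)))
  X <- do.call(cbind, blocks)
  keep <- (L + 1L):nrow(panel)
  out <- data.frame(date = panel$date[keep], y = panel$ha_count[keep])
  out <- cbind(out, as.data.frame(X[keep, , drop = FALSE]))
  feat <- colnames(X)
  src <- rep(c("HAs", env), each = L + 2L)
  attr(out, "groups") <- stats::setNames(
    ifelse(src == "HAs", "HAs", "environmental"), feat)
  attr(out, "variable_of") <- stats::setNames(src, feat)
  out
}

#' Calendar features for a run of consecutive dates
#'
#' Integer-coded day of week (Monday = 1), month, season (meteorological:
#' Mar--May = 1 spring, Jun--Aug = 2 summer, Sep--Nov = 3 fall,
#' Dec--Feb = 4 winter), ordinal year (first year = 1), serial timestamp
#' \code{ts} (1..n), plus binary \code{hol} (holiday), \code{wd} (workday:
#' neither weekend nor holiday), and \code{fwd}/\code{lwd} (first/last
#' workday of a workday run: a workday whose previous/next calendar day is
#' not a workday).  All columns are tagged group \code{"calendar"}.
#'
#' @param dates Consecutive \code{Date} vector.
#' @param holidays \code{Date} vector of holidays.
#' @return A \code{data.frame} with \code{"groups"} and \code{"variable_of"}
#'   attributes.
#' @export
make_calendar_features <- function(dates, holidays = default_holidays(
  unique(as.integer(strftime(dates, "%Y"))))) {
  if (length(dates) > 1 && any(diff(dates) != 1))
    stop("dates must be consecutive calendar days", call. = FALSE)
  # extend one day each side so fwd/lwd are well defined at the boundaries
  ext <- c(dates[1] - 1, dates, dates[length(dates)] + 1)
  wd_ext <- dow_monday1(ext) <= 5L & !(ext %in% holidays)
  n <- length(dates)
  wd <- wd_ext[2:(n + 1)]
  mon <- as.integer(strftime(dates, "%m"))
  year0 <- as.integer(strftime(dates[1], "%Y"))
  out <- data.frame(
    dow = dow_monday1(dates),
    mon = mon,
    sea = c(4L, 4L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L)[mon],
    year = as.integer(strftime(dates, "%Y")) - year0 + 1L,
    ts = seq_len(n),
    hol = as.integer(dates %in% holidays),
    wd = as.integer(wd),
    fwd = as.integer(wd & !wd_ext[1:n]),
    lwd = as.integer(wd & !wd_ext[3:(n + 2)])
  )
  attr(out, "groups") <- stats::setNames(rep("calendar", ncol(out)),
                                         names(out))
  attr(out, "variable_of") <- stats::setNames(toupper(names(out)),
                                              names(out))
  out
}

#' One-hot expand integer-coded columns using training categories
#'
#' Each listed column is replaced by one indicator per category observed in
#' the training rows (full encoding, no dropped level).  The category set is
#' frozen from training rows; a test value unseen in training yields all-zero
#' indicators and a warning.
#'
#' @param train,test Data.frames holding the listed columns.
#' @param columns Columns to expand (default \code{dow, mon, sea, year}).
#' @return List with expanded \code{train}, \code{test} and the frozen
#'   \code{categories} (named list).
#' @export
one_hot_expand <- function(train, test = NULL,
                           columns = c("dow", "mon", "sea", "year")) {
  columns <- intersect(columns, names(train))
  categories <- lapply(stats::setNames(columns, columns),
                       function(v) sort(unique(train[[v]])))
  expand <- function(df, warn_unseen) {
    for (v in columns) {
      cats <- categories[[v]]
      if (warn_unseen && any(!df[[v]] %in% cats))
        warning(sprintf(
          "column '%s': %d test value(s) outside training categories; %s",
          v, sum(!df[[v]] %in% cats), "indicators set to all-zero"),
          call. = FALSE)
      ind <- vapply(cats, function(k) as.integer(df[[v]] == k),
                    integer(nrow(df)))
      ind <- matrix(ind, nrow = nrow(df),
                    dimnames = list(NULL, sprintf("%s_%d", v, cats)))
      pos <- match(v, names(df))
      df <- cbind(df[seq_len(pos - 1)], as.data.frame(ind),
                  df[seq(pos + 1, length.out = ncol(df) - pos)])
    }
    df
  }
  list(train = expand(train, FALSE),
       test = if (!is.null(test)) expand(test, TRUE),
       categories = categories)
}

#' Min--max normalization with training-set statistics
#'
#' \code{x' = (x - min(x_train)) / (max(x_train) - min(x_train))}.  Test
#' values are scaled with the training minimum and maximum and may fall
#' outside \code{[0, 1]} (no clipping).  A constant training column cannot be
#' scaled and is mapped to all-zeros with a warning.
#'
#' @param train,test Numeric vectors (\code{test} may be \code{NULL}).
#' @return List \code{train}, \code{test}, \code{record} (train min/max).
#' @export
minmax_scale <- function(train, test = NULL) {
  lo <- min(train); hi <- max(train)
  if (hi == lo) {
    warning("constant training column scaled to all-zeros", call. = FALSE)
    return(list(train = rep(0, length(train)),
                test = if (!is.null(test)) rep(0, length(test)),
                record = c(min = lo, max = hi)))
  }
  list(train = (train - lo) / (hi - lo),
       test = if (!is.null(test)) (test - lo) / (hi - lo),
       record = c(min = lo, max = hi))
}

#' Assemble the full supervised design from a daily panel
#'
#' Interpolates missing environmental cells, builds the lagged and calendar
#' feature blocks on the full panel (so every row keeps its true history),
#' and returns the un-normalized design ready for [chronological_split()].
#'
#' @param panel An \code{ha_panel}.
#' @param spec A [lag_spec()].
#' @param holidays Holiday \code{Date} vector.
#' @return A design \code{data.frame} (date, y, features) with group tags.
#' @export
build_design <- function(panel, spec = lag_spec(), holidays = NULL) {
  panel <- interpolate_missing(panel)
  holidays <- holidays %||% default_holidays(
    unique(as.integer(strftime(panel$date, "%Y"))))
  lags <- make_lag_features(panel, spec)
  cal <- make_calendar_features(panel$date, holidays)
  keep <- (spec$L + 1L):nrow(panel)
  cal_kept <- cal[keep, , drop = FALSE]
  rownames(cal_kept) <- NULL
  out <- cbind(lags, cal_kept)
  attr(out, "groups") <- c(attr(lags, "groups"), attr(cal, "groups"))
  attr(out, "variable_of") <- c(attr(lags, "variable_of"),
                                attr(cal, "variable_of"))
  out
}

#' Chronological train/test split with training-fitted preprocessing
#'
#' Rows dated before \code{split_date} form the training part, the rest the
#' test part.  One-hot category sets and min--max records are fitted on the
#' training rows only and applied to both parts; binary indicator columns
#' are left unscaled (min--max is a no-op on \{0,1\}).  The target stays on
#' the raw count scale so predictions are comparable to observed counts.
#'
#' @param design Output of [build_design()].
#' @param split_date First test day (\code{Date} or ISO string).
#' @param normalize Logical; apply min--max scaling (default \code{TRUE}).
#' @return An object of class \code{ha_split}: lists \code{train} and
#'   \code{test}, each with \code{dates}, \code{X} (numeric matrix) and
#'   \code{y}; plus \code{groups}, \code{variable_of}, \code{records}
#'   (normalization) and \code{categories} (one-hot).
#' @export
chronological_split <- function(design, split_date, normalize = TRUE) {
  split_date <- as.Date(split_date)
  if (split_date <= min(design$date) || split_date > max(design$date))
    stop("split_date must lie strictly inside the feature date range",
         call. = FALSE)
  is_train <- design$date < split_date
  groups <- attr(design, "groups")
  variable_of <- attr(design, "variable_of")

  feat <- setdiff(names(design), c("date", "y"))
  oh <- one_hot_expand(design[is_train, feat, drop = FALSE],
                       design[!is_train, feat, drop = FALSE])
  tr <- oh$train; te <- oh$test
  # propagate group/variable tags onto the indicator columns
  tag_of <- function(cols, tab) {
    src <- sub("_(\\d+)$", "", cols)
    out <- ifelse(cols %in% names(tab), tab[cols], tab[src])
    stats::setNames(out, cols)
  }
  groups <- tag_of(names(tr), groups)
  variable_of <- tag_of(names(tr), variable_of)

  records <- list()
  if (normalize) {
    for (v in names(tr)) {
      vals <- unique(tr[[v]])
      if (all(vals %in% c(0, 1))) next  # indicator column
      sc <- minmax_scale(tr[[v]], te[[v]])
      tr[[v]] <- sc$train; te[[v]] <- sc$test
      records[[v]] <- sc$record
    }
  }
  structure(list(
    train = list(dates = design$date[is_train],
                 X = as.matrix(tr), y = design$y[is_train]),
    test = list(dates = design$date[!is_train],
                X = as.matrix(te), y = design$y[!is_train]),
    split_date = split_date,
    groups = groups, variable_of = variable_of,
    records = records, categories = oh$categories
  ), class = "ha_split")
}

#' @export
print.ha_split <- function(x, ...) {
  cat(sprintf(
    "<ha_split> %d train rows (to %s), %d test rows (from %s), %d features\n",
    length(x$train$y), max(x$train$dates), length(x$test$y),
    min(x$test$dates), ncol(x$train$X)))
  invisible(x)
}
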