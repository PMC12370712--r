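#' Preprocessing specification
#'
#' Bundles the preprocessing choices applied to raw tables and sensor
#' streams before hypergraph construction: mean imputation for numeric
#' columns; mode or explicit-"Unknown" imputation for categorical columns;
#' optional z-scoring to zero mean and unit variance; the maximum sensor gap
#' (seconds) bridged by linear interpolation; and the fixed window length
#' (seconds) used for time-series summarization.
#'
#' @param numeric_impute currently `"mean"`.
#' @param categorical_impute `"mode"` or `"unknown"` (a dedicated
#'   `"Unknown"` category).
#' @param normalize `"zscore"` (population standard deviation) or `"none"`.
#' @param gap_interpolation_max nonnegative seconds; gaps strictly shorter
#'   are filled by linear interpolation, longer gaps invalidate overlapping
#'   windows. Default 5.
#' @param window_length positive seconds; default 30.
#' @return An object of class `"preprocess_spec"`.
#' @export
preprocess_spec <- function(numeric_impute = "mean",
                            categorical_impute = c("mode", "unknown"),
                            normalize = c("zscore", "none"),
                            gap_interpolation_max = 5,
                            window_length = 30) {
  numeric_impute <- match.arg(numeric_impute, "mean")
  categorical_impute <- match.arg(categorical_impute)
  normalize <- match.arg(normalize)
  if (window_length <= 0) stopf("window_length must be positive")
  if (gap_interpolation_max < 0) stopf("gap_interpolation_max must be >= 0")
  structure(list(numeric_impute = numeric_impute,
                 categorical_impute = categorical_impute,
                 normalize = normalize,
                 gap_interpolation_max = gap_interpolation_max,
                 window_length = window_length),
            class = "preprocess_spec")
}

#' Per-modality feature table
#'
#' A numeric node-by-feature matrix with aligned subject identifiers; the
#' unit every downstream step (KNN construction, fusion, the model) consumes.
#'
#' @param modality_name label, e.g. `"physiological"`.
#' @param node_ids ordered unique subject ids (rownames of `features`).
#' @param features numeric matrix, no missing values.
#' @return An object of class `"modality_table"`.
#' @export
modality_table <- function(modality_name, node_ids, features) {
  features <- as.matrix(features)
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stopf("duplicate node ids")
  if (nrow(features) != length(node_ids)) {
    stopf("features has %d rows for %d node ids", nrow(features),
          length(node_ids))
  }
  if (anyNA(features)) stopf("modality_table features must not contain NA")
  storage.mode(features) <- "double"
  rownames(features) <- node_ids
  structure(list(modality_name = modality_name, node_ids = node_ids,
                 features = features),
            class = "modality_table")
}

#' @export
print.modality_table <- function(x, ...) {
  cat(sprintf("Modality '%s': %d subjects x %d features\n",
              x$modality_name, nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Clean a raw mixed-type table into a numeric modality table
#'
#' Imputation and normalization statistics are computed on the `fit_ids`
#' subset only (the training fold), then applied to every row; permuting or
#' changing the non-fit rows cannot leak into the statistics. Numeric
#' missing values are replaced by the fit-subset column mean; categorical
#' missing values by the fit-subset mode, or by an explicit `"Unknown"`
#' category. Categorical columns are one-hot encoded over the levels
#' observed on `fit_ids` (values outside those levels encode as all-zero).
#' Z-scoring uses the population standard deviation; constant columns get a
#' unit divisor.
#'
#' @param raw_table data frame with a `node_id` column (or the first column
#'   treated as ids) and arbitrary numeric/character columns, possibly with
#'   `NA`s.
#' @param spec a [preprocess_spec()].
#' @param fit_ids node ids whose rows define the imputation/scaling
#'   statistics; defaults to all rows.
#' @param modality_name label for the result.
#' @return A [modality_table()].
#' @export
preprocess_table <- function(raw_table, spec = preprocess_spec(),
                             fit_ids = NULL, modality_name = "other") {
  raw_table <- as.data.frame(raw_table)
  id_col <- if ("node_id" %in% names(raw_table)) "node_id" else names(raw_table)[1]
  node_ids <- as.character(raw_table[[id_col]])
  if (anyDuplicated(node_ids)) stopf("duplicate node ids in raw table")
  if (is.null(fit_ids)) fit_ids <- node_ids
  fit_rows <- node_ids %in% fit_ids
  if (!any(fit_rows)) stopf("fit_ids matches no rows")

  cols <- setdiff(names(raw_table), id_col)
  blocks <- list()
  for (cn in cols) {
    col <- raw_table[[cn]]
    if (is.numeric(col)) {
      fit_vals <- col[fit_rows]
      if (all(is.na(fit_vals))) {
        stopf("column '%s' is entirely missing on the fit subset", cn)
      }
      mu <- mean(fit_vals, na.rm = TRUE)
      col[is.na(col)] <- mu
      if (spec$normalize == "zscore") {
        fit_after <- col[fit_rows]
        s <- sqrt(mean((fit_after - mean(fit_after))^2))
        if (s == 0) s <- 1
        col <- (col - mean(fit_after)) / s
      }
      blocks[[cn]] <- matrix(col, ncol = 1, dimnames = list(NULL, cn))
    } else {
      col <- as.character(col)
      fit_vals <- col[fit_rows]
      if (all(is.na(fit_vals)) && spec$categorical_impute == "mode") {
        stopf("column '%s' is entirely missing on the fit subset", cn)
      }
      if (spec$categorical_impute == "mode") {
        tab <- table(fit_vals[!is.na(fit_vals)])
        mode_val <- names(tab)[which.max(tab)]
        col[is.na(col)] <- mode_val
      } else {
        col[is.na(col)] <- "Unknown"
      }
      levels_fit <- sort(unique(col[fit_rows]))
      onehot <- vapply(levels_fit, function(lv) as.numeric(col == lv),
                       numeric(length(col)))
      onehot <- matrix(onehot, ncol = length(levels_fit),
                       dimnames = list(NULL, paste(cn, levels_fit, sep = ".")))
      blocks[[cn]] <- onehot
    }
  }
  features <- do.call(cbind, blocks)
  modality_table(modality_name, node_ids, features)
}

#' Summarize a gappy sensor stream into window statistics
#'
#' The stream is regridded at its native sampling interval (the smallest
#' observed timestamp spacing). Gaps shorter than
#' `spec$gap_interpolation_max` seconds are bridged by linear interpolation;
#' longer gaps are excluded, and every fixed-length window that overlaps an
#' excluded gap is dropped. The per-window mean and population variance are
#' averaged over the retained windows into a length-2 feature vector.
#'
#' @param time numeric timestamps in seconds, sorted ascending (or a
#'   two-column data frame `(time, value)`).
#' @param value numeric samples, same length as `time`.
#' @param spec a [preprocess_spec()] supplying `gap_interpolation_max` and
#'   `window_length`.
#' @return Named numeric vector `c(mean = ..., variance = ...)`.
#' @export
summarize_timeseries <- function(time, value = NULL,
                                 spec = preprocess_spec()) {
  if (is.null(value)) {
    stopifnot(is.data.frame(time), ncol(time) >= 2)
    value <- time[[2]]
    time <- time[[1]]
  }
  if (length(time) < 2) stopf("need at least two samples")
  if (is.unsorted(time, strictly = TRUE)) stopf("timestamps must be strictly increasing")
  dt <- min(diff(time))
  if (dt <= 0) stopf("non-positive sampling interval")

  grid <- seq(time[1], time[length(time)], by = dt)
  filled <- approx(time, value, xout = grid, method = "linear")$y

  # Long gaps: intervals between consecutive samples exceeding the
  # interpolation threshold; grid points strictly inside are invalid.
  gaps <- diff(time)
  long <- which(gaps >= spec$gap_interpolation_max & gaps > dt * 1.5)
  bad <- rep(FALSE, length(grid))
  for (g in long) {
    bad <- bad | (grid > time[g] & grid < time[g + 1])
  }

  wlen <- spec$window_length
  last_start <- time[length(time)] - wlen + dt
  if (last_start < time[1]) stopf("signal shorter than one window")
  starts <- seq(time[1], last_start, by = wlen)
  means <- vars <- numeric(0)
  for (s in starts) {
    in_w <- grid >= s & grid < s + wlen
    if (!any(in_w) || any(bad[in_w])) next    # window overlaps a long gap
    v <- filled[in_w]
    means <- c(means, mean(v))
    vars <- c(vars, mean((v - mean(v))^2))
  }
  if (!length(means)) stopf("no windows retained after gap exclusion")
  c(mean = mean(means), variance = mean(vars))
}
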