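# Explanatory-variable suite: long-term means ("facilitators") and linear
# trends ("drivers"), bespoke climate statistics (extreme-rainfall counts,
# precipitation concentration index, variability), edaphic aggregation,
# terrain ruggedness, and boosted-tree hind/fore-casting.

#' Long-term mean and linear trend per group
#'
#' For each group (e.g. grid cell, or covariate x pixel), computes the
#' temporal mean and the OLS slope of the value against time — the
#' facilitator/driver pair used throughout the driver analysis.
#'
#' @param series Tibble with a time column, a value column and optional
#'   grouping columns.
#' @param value,time Column names (defaults `"value"`, `"year"`).
#' @param by Character vector of grouping columns (default: none).
#' @return A tibble with the grouping columns plus `mean`, `slope`,
#'   `p_value`, `n`.
#' @export
mean_and_trend <- function(series, value = "value", time = "year", by = NULL) {
  if (all(!is.finite(series[[value]]))) abort("all-missing series")
  series %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      mean = mean(.data[[value]], na.rm = TRUE),
      {
        fit <- ols_line(.data[[time]], .data[[value]])
        tibble::tibble(slope = fit$slope, p_value = fit$p_value, n = fit$n)
      },
      .groups = "drop"
    )
}

#' Annual counts of extreme multi-day rainfall events
#'
#' Computes sliding `window`-day rainfall sums (stride 1), sets the extreme
#' threshold at the `threshold_quantile` quantile of all window sums in the
#' full record, and counts per year the sums strictly exceeding it (windows
#' are assigned to the year of their start date). Because the threshold is a
#' function of the full record, appending later data can change earlier
#' years' counts.
#'
#' @param daily Tibble of contiguous daily observations.
#' @param value Rainfall column (default `"rain"`).
#' @param date Date column (`Date` or decimal year; default `"date"`).
#' @param window Window length in days (default 5).
#' @param threshold_quantile Quantile defining "extreme" (default 0.95).
#' @return A tibble (`year`, `count`), with attributes `threshold`,
#'   `n_windows` and `trend` (the OLS fit of count on year).
#' @export
extreme_rainfall_counts <- function(daily, value = "rain", date = "date",
                                    window = 5, threshold_quantile = 0.95) {
  v <- daily[[value]]
  if (length(v) < window) abort(sprintf("series shorter than %d days", window))
  d <- daily[[date]]
  yr <- if (inherits(d, "Date")) as.integer(format(d, "%Y")) else floor(as.numeric(d))
  cs <- cumsum(c(0, v))
  n <- length(v)
  sums <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  start_year <- yr[1:(n - window + 1)]
  threshold <- quantile(sums, threshold_quantile, type = 7, names = FALSE)
  counts <- tibble::tibble(year = start_year, exceed = sums > threshold) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(count = sum(.data$exceed), .groups = "drop")
  attr(counts, "threshold") <- threshold
  attr(counts, "n_windows") <- length(sums)
  attr(counts, "trend") <- ols_line(counts$year, counts$count)
  counts
}

#' Precipitation concentration index
#'
#' `PCI = 100 * sum(p_i^2) / (sum(p_i))^2` over twelve monthly totals.
#' Multi-year inputs are first reduced to mean monthly totals. Uniform
#' months give the lower bound 100/12; all rain in one month gives 100.
#' Zero annual rainfall yields a missing value.
#'
#' @param monthly A numeric vector of 12 monthly totals, or a tibble with
#'   `month` and a value column.
#' @param value Value column when `monthly` is a tibble (default `"rain"`).
#' @return The PCI (scalar), in \[100/12, 100\], or `NA` for a zero total.
#' @examples
#' precipitation_concentration_index(rep(100, 12)) # 100/12
#' @export
precipitation_concentration_index <- function(monthly, value = "rain") {
  p <- if (is.data.frame(monthly)) {
    monthly %>%
      dplyr::group_by(.data$month) %>%
      dplyr::summarise(p = mean(.data[[value]]), .groups = "drop") %>%
      dplyr::pull("p")
  } else {
    monthly
  }
  if (length(p) != 12) abort("PCI requires 12 monthly totals")
  if (any(p < 0)) abort("monthly totals must be non-negative")
  tot <- sum(p)
  if (tot == 0) return(NA_real_)
  100 * sum(p^2) / tot^2
}

#' Rainfall variability at annual and sub-daily scales
#'
#' Population standard deviation of (i) annual rainfall totals and (ii) the
#' raw sub-daily observations, reported separately.
#'
#' @param series Tibble of rainfall observations.
#' @param value Rainfall column (default `"rain"`).
#' @param time Time column (`Date` or decimal year; default `"time"`).
#' @return A tibble with `scale` ("annual", "subdaily") and `sd`.
#' @export
rainfall_variability <- function(series, value = "rain", time = "time") {
  v <- series[[value]]
  t <- series[[time]]
  yr <- if (inherits(t, "Date")) as.integer(format(t, "%Y")) else floor(as.numeric(t))
  annual <- tapply(v, yr, sum)
  psd <- function(x) sqrt(pvar(as.numeric(x)))
  tibble::tibble(scale = c("annual", "subdaily"),
                 sd = c(psd(annual), psd(v)))
}

#' Depth-weighted soil-profile aggregation
#'
#' Aggregates per-depth-interval soil values to a single number by weighting
#' each layer by its thickness: `sum(v_i * th_i) / sum(th_i)`.
#'
#' @param values Layer values (one per depth interval).
#' @param top,bottom Interval bounds (same units, e.g. cm); intervals must be
#'   contiguous with positive thickness.
#' @return The depth-weighted average (scalar).
#' @examples
#' depth_weighted_soil(c(10, 20), top = c(0, 5), bottom = c(5, 20)) # 17.5
#' @export
depth_weighted_soil <- function(values, top, bottom) {
  stopifnot(length(values) == length(top), length(top) == length(bottom))
  th <- bottom - top
  if (any(th <= 0)) abort("depth intervals must have positive thickness")
  if (length(top) > 1 && any(abs(top[-1] - bottom[-length(bottom)]) > 1e-9)) {
    abort("depth intervals must be contiguous")
  }
  tot <- sum(th)
  if (tot == 0) abort("zero total thickness")
  sum(values * th) / tot
}

#' Terrain ruggedness index
#'
#' Change in elevation between each pixel and its eight neighbours. The
#' default Riley formulation is the square root of the summed squared
#' differences; the `"sum_abs"` variant is the literal sum of absolute
#' differences. Edge pixels use their available neighbours.
#'
#' @param dem Tibble with `x`, `y` and an elevation column.
#' @param value Elevation column (default `"elevation"`).
#' @param method `"riley"` (default) or `"sum_abs"`.
#' @return A tibble `x`, `y`, `tri`.
#' @export
terrain_ruggedness <- function(dem, value = "elevation",
                               method = c("riley", "sum_abs")) {
  method <- match.arg(method)
  m <- grid_to_matrix(dem, value)
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(NA_real_, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  acc <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(ny + 1)) + dy, (2:(nx + 1)) + dx]
    d <- m - nb
    d[is.na(d)] <- 0
    acc <- acc + if (method == "riley") d^2 else abs(d)
  }
  tri <- if (method == "riley") sqrt(acc) else acc
  out <- matrix_to_grid(tri, "tri")
  dplyr::left_join(dem[, c("x", "y")], out, by = c("x", "y"))
}

#' Hind- and fore-cast a response with a boosted-tree model
#'
#' Fits a boosted regression tree on the reference epoch's observed response
#' and applies it to every epoch's predictors, yielding a modelled response
#' time series per cell and its per-cell linear trend. Epochs other than the
#' reference that carry an observed response are used for cross-epoch
#' validation (R-squared of predicted vs observed).
#'
#' @param data Tibble with `cell`, `epoch`, a response column (may be `NA`
#'   outside observed epochs) and predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor columns.
#' @param reference_epoch Epoch id whose observed response trains the model.
#' @param epoch_years Optional named vector (epoch -> year) for the trend
#'   abscissa; defaults to the epoch ids themselves.
#' @param params A [brt_params()].
#' @return A `hindcast_model`: list with `model` (a `driver_model`),
#'   `reference_epoch`, `contributions` (relative importance, sums to 100),
#'   `predictions` (cell x epoch), `trend` (per-cell slope) and `validation`
#'   (per-epoch R-squared).
#' @export
fit_hindcast <- function(data, response, predictors, reference_epoch,
                         epoch_years = NULL, params = brt_params()) {
  epochs <- sort(unique(data$epoch))
  if (!reference_epoch %in% epochs) abort("reference epoch not present in data")
  for (e in epochs) {
    d <- data[data$epoch == e, ]
    if (!all(predictors %in% names(d)) || any(!stats::complete.cases(d[predictors]))) {
      abort(sprintf("missing predictor values for epoch %s", e))
    }
  }
  ref <- data[data$epoch == reference_epoch & !is.na(data[[response]]), ]
  model <- fit_brt(ref, response = response, predictors = predictors,
                   params = params)
  preds <- data %>%
    dplyr::mutate(predicted = predict_brt(model, data)) %>%
    dplyr::select("cell", "epoch", dplyr::all_of(response), "predicted")
  validation <- preds %>%
    dplyr::filter(.data$epoch != reference_epoch, !is.na(.data[[response]])) %>%
    dplyr::group_by(.data$epoch) %>%
    dplyr::summarise(
      r2 = 1 - sum((.data[[response]] - .data$predicted)^2) /
        sum((.data[[response]] - mean(.data[[response]]))^2),
      n = dplyr::n(), .groups = "drop"
    )
  if (is.null(epoch_years)) {
    epoch_years <- stats::setNames(as.numeric(epochs), epochs)
  }
  wide <- tidyr::pivot_wider(preds[, c("cell", "epoch", "predicted")],
                             names_from = "epoch", values_from = "predicted")
  yrs <- unname(epoch_years[names(wide)[-1]])
  tr <- ols_rows(as.matrix(wide[, -1]), yrs)
  trend <- tibble::tibble(cell = wide$cell, slope = tr$slope)
  structure(list(
    model = model, reference_epoch = reference_epoch,
    contributions = relative_importance(model),
    predictions = preds, trend = trend, validation = validation
  ), class = "hindcast_model")
}

#' @export
print.hindcast_model <- function(x, ...) {
  cat(sprintf("Hindcast BRT (reference epoch %s): CV deviance explained %.2f\n",
              x$reference_epoch, x$model$cv_deviance_explained))
  if (nrow(x$validation) > 0) {
    cat("  cross-epoch validation R2:",
        paste(sprintf("%s: %.2f", x$validation$epoch, x$validation$r2),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble the coarse-grid covariate table (drivers and facilitators)
#'
#' For every time-varying covariate, estimates the per-pixel long-term mean
#' and OLS trend from its observed annual series, then aggregates both to the
#' coarse grid (mean of valid pixels per cell); static covariates contribute
#' their mean field only. Trend columns (`<name>_trend`) are tagged as
#' drivers, mean columns (`<name>_mean`) as facilitators, following the
#' temporal-component split used in driver attribution.
#'
#' @param covariates A `covariate_set` from [generate_covariates()].
#' @param cell_size Coarse-cell edge length in pixels; defaults to the
#'   config's.
#' @return A `CovariateTable` tibble: `cell`, `cx`, `cy` plus one column per
#'   variable; attribute `"roles"` is a tibble (`variable`, `role`,
#'   `provenance`).
#' @export
build_covariate_table <- function(covariates, cell_size = NULL) {
  stopifnot(inherits(covariates, "covariate_set"))
  cell_size <- cell_size %||% covariates$config$cell_size
  specs <- covariates$config$covariate_specs
  out <- NULL
  roles <- list()
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    if (specs$time_varying[i]) {
      ser <- dplyr::filter(covariates$series, .data$covariate == nm)
      wide <- tidyr::pivot_wider(ser, id_cols = c("x", "y"),
                                 names_from = "year", values_from = "value")
      yrs <- as.numeric(names(wide)[-(1:2)])
      tr <- ols_rows(as.matrix(wide[, -(1:2)]), yrs)
      pix <- dplyr::mutate(wide[, c("x", "y")],
                           mean_v = rowMeans(as.matrix(wide[, -(1:2)])),
                           trend_v = tr$slope)
      cols <- list(mean = "mean_v", trend = "trend_v")
    } else {
      pix <- dplyr::filter(covariates$fields, .data$covariate == nm) %>%
        dplyr::select("x", "y", mean_v = "mean_true")
      cols <- list(mean = "mean_v")
    }
    for (what in names(cols)) {
      agg <- aggregate_to_grid(pix, value = cols[[what]],
                               native_resolution = 30, cell_size = cell_size)
      col_name <- paste0(nm, "_", what)
      agg <- dplyr::rename(agg, !!col_name := "value")
      out <- if (is.null(out)) agg else
        dplyr::left_join(out, agg, by = c("cell", "cx", "cy"))
      roles[[col_name]] <- if (what == "trend") "driver" else "facilitator"
    }
  }
  attr(out, "roles") <- tibble::tibble(
    variable = names(roles), role = unname(unlist(roles)),
    provenance = "observed"
  )
  out
}
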