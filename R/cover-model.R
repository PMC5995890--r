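# Fractional-cover regression: assemble quadrat training tables, fit a
# random-forest regressor per sensor collection, validate on an independent
# hold-out, and predict per-pixel cover for every epoch.

#' Assemble a quadrat training table
#'
#' Joins each photo-interpretation quadrat to its pixel/epoch metric vector
#' and applies the exclusion rules: quadrats flagged uncertain are dropped,
#' as are quadrats whose acquisition date falls outside their epoch's date
#' range, and quadrats with no valid observations (no metrics). Per-rule drop
#' counts are attached as attribute `"dropped"`.
#'
#' @param quadrats Tibble from [sample_quadrats()] (needs `pixel_id`,
#'   `epoch`, `date`, `label`, `uncertain`).
#' @param metric_cube A `MetricCube` from [epoch_metrics()].
#' @param epochs Epoch table with `epoch`, `start`, `end`.
#' @param sensor_of_epoch Named character vector mapping epoch id to sensor
#'   collection; default: epochs 1-3 "TM", later epochs "ETM".
#' @return A `TrainingTable` tibble: quadrat metadata + `sensor` + metric
#'   feature columns; attribute `"dropped"` holds the per-rule counts.
#' @export
assemble_training <- function(quadrats, metric_cube, epochs,
                              sensor_of_epoch = NULL) {
  if (!all(quadrats$pixel_id %in% metric_cube$pixel_id)) {
    abort("quadrat outside raster extent: pixel not present in metric cube")
  }
  if (is.null(sensor_of_epoch)) {
    sensor_of_epoch <- stats::setNames(
      ifelse(epochs$epoch <= 3, "TM", "ETM"), epochs$epoch
    )
  }
  n0 <- nrow(quadrats)
  q <- dplyr::filter(quadrats, !.data$uncertain)
  n_unc <- n0 - nrow(q)
  q <- dplyr::left_join(q, epochs[, c("epoch", "start", "end")], by = "epoch")
  in_range <- q$date >= q$start & q$date <= q$end
  n_date <- sum(!in_range)
  q <- q[in_range, ]
  q <- dplyr::select(q, -"start", -"end")
  tab <- dplyr::left_join(
    q, dplyr::select(metric_cube, -"x", -"y"),
    by = c("pixel_id", "epoch")
  )
  feature_cols <- metric_feature_cols(metric_cube)
  has_metrics <- !is.na(tab$n_obs) & tab$n_obs > 0 &
    stats::complete.cases(tab[feature_cols])
  n_nometric <- sum(!has_metrics)
  tab <- tab[has_metrics, ]
  tab$sensor <- unname(sensor_of_epoch[as.character(tab$epoch)])
  attr(tab, "dropped") <- list(uncertain = n_unc, date = n_date,
                               no_metrics = n_nometric)
  tab
}

# Internal: the metric feature columns of a cube or training table.
metric_feature_cols <- function(df) {
  meta <- c("pixel_id", "x", "y", "epoch", "n_obs", "quadrat_id", "date",
            "true_cover", "label", "uncertain", "sensor")
  setdiff(names(df), meta)
}

#' Fit a fractional-cover random-forest regressor
#'
#' Fits a random-forest regression of the quantized quadrat label on the
#' time-series metric features, with dual validation: internal out-of-bag
#' R-squared, and R-squared/RMSE on an independent hold-out split (stratified
#' by label class, disjoint from the training rows). Predictions are clipped
#' to \[0, 1\].
#'
#' @param training_table A `TrainingTable` from [assemble_training()].
#' @param sensor_group Optional sensor collection to subset to (e.g. "TM");
#'   `NULL` fits on all rows.
#' @param n_trees Number of trees (default 500).
#' @param holdout_fraction Hold-out fraction, stratified by label (default
#'   0.2).
#' @param seed Integer seed (controls split and forest).
#' @param min_rows Minimum rows required after the split (default 50).
#' @return A `cover_regressor`: fitted forest, feature list, sensor group and
#'   validation statistics (`oob_r2`, `holdout_r2`, `holdout_rmse`,
#'   `n_train`, `n_holdout`).
#' @export
fit_cover_regressor <- function(training_table, sensor_group = NULL,
                                n_trees = 500, holdout_fraction = 0.2,
                                seed = 1L, min_rows = 50) {
  tab <- training_table
  if (!is.null(sensor_group)) {
    tab <- dplyr::filter(tab, .data$sensor == sensor_group)
  }
  features <- metric_feature_cols(tab)
  if (length(unique(tab$label)) < 2) {
    abort("labels are constant: cover regression is undefined")
  }
  local_seed(sub_seed(seed, 17L), {
    hold_idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$label), function(idx) {
      k <- round(holdout_fraction * length(idx))
      if (k > 0) sample(idx, k) else integer(0)
    }))
    train <- tab[-hold_idx, ]
    hold <- tab[hold_idx, ]
    if (nrow(train) < min_rows) {
      abort(sprintf("too few training rows after split (%d < %d)",
                    nrow(train), min_rows))
    }
    fit <- ranger::ranger(
      x = as.data.frame(train[features]), y = train$label,
      num.trees = n_trees, importance = "impurity",
      seed = sub_seed(seed, 18L), num.threads = 1
    )
    oob_r2 <- fit$r.squared
    pred <- clip01(predict(fit, data = as.data.frame(hold[features]),
                           num.threads = 1)$predictions)
    ss_res <- sum((hold$label - pred)^2)
    ss_tot <- sum((hold$label - mean(hold$label))^2)
    structure(list(
      model = fit, features = features, sensor_group = sensor_group,
      stats = list(
        oob_r2 = oob_r2,
        holdout_r2 = 1 - ss_res / ss_tot,
        holdout_rmse = sqrt(mean((hold$label - pred)^2)),
        n_train = nrow(train), n_holdout = nrow(hold)
      ),
      seed = seed
    ), class = "cover_regressor")
  })
}

#' @export
print.cover_regressor <- function(x, ...) {
  s <- x$stats
  cat("Fractional-cover random-forest regressor\n")
  cat(sprintf("  sensor group: %s\n", x$sensor_group %||% "(all)"))
  cat(sprintf("  features: %d | train n = %d | hold-out n = %d\n",
              length(x$features), s$n_train, s$n_holdout))
  cat(sprintf("  OOB R2 = %.3f | hold-out R2 = %.3f | hold-out RMSE = %.3f\n",
              s$oob_r2, s$holdout_r2, s$holdout_rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cover regressor: per-feature impurity importance
#' @param x A `cover_regressor`.
#' @param ... Unused.
#' @return Tibble with `variable`, `importance`, sorted descending.
#' @export
tidy.cover_regressor <- function(x, ...) {
  imp <- x$model$variable.importance
  tibble::tibble(variable = names(imp), importance = unname(imp)) %>%
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Glance at a cover regressor: one-row validation summary
#' @param x A `cover_regressor`.
#' @param ... Unused.
#' @return One-row tibble of validation statistics.
#' @export
glance.cover_regressor <- function(x, ...) {
  tibble::as_tibble(x$stats)
}

#' Predict fractional woody cover from a metric cube
#'
#' Applies a fitted cover regressor to every pixel x epoch row with complete
#' metric features; rows with missing metrics (including masked pixels)
#' receive a missing prediction. Predictions are clipped to \[0, 1\].
#'
#' @param regressor A `cover_regressor`.
#' @param metric_cube A `MetricCube` from [epoch_metrics()].
#' @return A `CoverSeries` tibble: `pixel_id`, `x`, `y`, `epoch`, `cover`.
#' @export
predict_cover <- function(regressor, metric_cube) {
  miss <- setdiff(regressor$features, names(metric_cube))
  if (length(miss) > 0) {
    abort(sprintf("metric cube lacks trained feature(s): %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  X <- metric_cube[regressor$features]
  ok <- stats::complete.cases(X)
  cover <- rep(NA_real_, nrow(metric_cube))
  if (any(ok)) {
    cover[ok] <- clip01(predict(regressor$model,
                                data = as.data.frame(X[ok, , drop = FALSE]),
                                num.threads = 1)$predictions)
  }
  dplyr::mutate(metric_cube[, c("pixel_id", "x", "y", "epoch")], cover = cover)
}
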