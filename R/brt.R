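# Driver attribution with weighted Gaussian boosted regression trees:
# aggregation to the coarse grid, collinearity filtering, k-fold
# cross-validated tree-count selection and deviance explained, relative
# importance, backward simplification, partial dependence, and the
# permuted-response sanity check.

#' Boosted-regression-tree parameters
#'
#' The Gaussian BRT configuration used throughout driver attribution:
#' tree complexity (interaction depth) 5, learning rate 0.01, bag fraction
#' 0.5, 10-fold cross-validation.
#'
#' @param tree_complexity Interaction depth of each tree (default 5).
#' @param learning_rate Shrinkage per boosting step (default 0.01).
#' @param bag_fraction Per-iteration subsample fraction in (0, 1\] (default
#'   0.5).
#' @param n_folds Cross-validation folds (default 10).
#' @param max_trees Upper bound on the CV-selected ensemble size (default
#'   1500).
#' @param min_trees Floor below which a CV-selected tree count is considered
#'   trivial ("failed to resolve"; default 50).
#' @param seed Integer seed governing fold assignment and subsampling.
#' @return A `brt_params` list.
#' @export
brt_params <- function(tree_complexity = 5, learning_rate = 0.01,
                       bag_fraction = 0.5, n_folds = 10,
                       max_trees = 1500, min_trees = 50, seed = 1L) {
  if (learning_rate <= 0) abort("learning rate must be positive")
  if (n_folds < 2) abort("need at least 2 cross-validation folds")
  if (bag_fraction <= 0 || bag_fraction > 1) abort("bag fraction must be in (0, 1]")
  structure(list(tree_complexity = as.integer(tree_complexity),
                 learning_rate = learning_rate, bag_fraction = bag_fraction,
                 n_folds = as.integer(n_folds), max_trees = as.integer(max_trees),
                 min_trees = as.integer(min_trees), seed = as.integer(seed)),
            class = "brt_params")
}

# Internal: xgboost parameter list for one fit.
xgb_param_list <- function(params, seed) {
  xgboost::xgb.params(
    max_depth = params$tree_complexity,
    learning_rate = params$learning_rate,
    subsample = params$bag_fraction,
    objective = "reg:squarederror",
    nthread = 1,
    seed = seed
  )
}

# Internal: default predictor columns = numeric, non-meta.
default_predictors <- function(data, response, weights) {
  meta <- c(response, weights, "cell", "cx", "cy", "x", "y", "pixel_id",
            "epoch", "weight")
  nums <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(nums, meta)
}

#' Aggregate a fine raster to the coarse analysis grid
#'
#' Applies the resolution-dependent rule: layers with native resolution
#' greater than 500 m are resampled by bilinear interpolation at the coarse
#' cell centroid; layers at 500 m or finer are reduced to the mean of valid
#' pixels per cell. Masked (missing) pixels are excluded from means and
#' bilinear weights are renormalised over valid corners; cells with no valid
#' support are missing.
#'
#' @param raster Tibble with `x`, `y` and a value column.
#' @param value Value column name (default `"value"`).
#' @param native_resolution Native resolution of the layer, in metres.
#' @param cell_size Coarse-cell edge length in pixels.
#' @return A tibble `cell`, `cx`, `cy`, `value`.
#' @export
aggregate_to_grid <- function(raster, value = "value", native_resolution,
                              cell_size) {
  if (missing(native_resolution) || is.null(native_resolution)) {
    abort("native_resolution metadata is required")
  }
  m <- grid_to_matrix(raster, value)
  ny <- nrow(m); nx <- ncol(m)
  ncx <- ceiling(nx / cell_size); ncy <- ceiling(ny / cell_size)
  cells <- tidyr::expand_grid(cy = seq_len(ncy), cx = seq_len(ncx))
  if (native_resolution <= 500) {
    agg <- raster %>%
      dplyr::mutate(cx = ceiling(.data$x / cell_size),
                    cy = ceiling(.data$y / cell_size)) %>%
      dplyr::group_by(.data$cx, .data$cy) %>%
      dplyr::summarise(
        value = if (all(is.na(.data[[value]]))) NA_real_ else
          mean(.data[[value]], na.rm = TRUE),
        .groups = "drop"
      )
    out <- dplyr::left_join(cells, agg, by = c("cx", "cy"))
  } else {
    # bilinear sample at the cell centroid, in pixel-centre coordinates
    gx <- (cells$cx - 1) * cell_size + (cell_size + 1) / 2
    gy <- (cells$cy - 1) * cell_size + (cell_size + 1) / 2
    x0 <- pmin(pmax(floor(gx), 1L), nx - 1L); x1 <- x0 + 1L
    y0 <- pmin(pmax(floor(gy), 1L), ny - 1L); y1 <- y0 + 1L
    fx <- pmin(pmax(gx - x0, 0), 1); fy <- pmin(pmax(gy - y0, 0), 1)
    vals <- cbind(m[cbind(y0, x0)], m[cbind(y0, x1)],
                  m[cbind(y1, x0)], m[cbind(y1, x1)])
    wts <- cbind((1 - fx) * (1 - fy), fx * (1 - fy),
                 (1 - fx) * fy, fx * fy)
    wts[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    wsum <- rowSums(wts)
    v <- ifelse(wsum > 0, rowSums(vals * wts) / wsum, NA_real_)
    out <- dplyr::mutate(cells, value = v)
  }
  out %>%
    dplyr::arrange(.data$cy, .data$cx) %>%
    dplyr::mutate(cell = dplyr::row_number()) %>%
    dplyr::relocate("cell", "cx", "cy")
}

#' Filter strongly collinear variable groups
#'
#' Computes pairwise Pearson correlations on complete cases, joins variables
#' into groups by transitive closure over `|r| > threshold` edges, and keeps
#' a single variable per group: the highest-priority one (position in
#' `priority`, then alphabetical). Constant columns have undefined
#' correlations and are treated as uncorrelated, with a warning.
#'
#' @param covariate_table Tibble of candidate variables (plus any metadata
#'   columns, which are passed through untouched).
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @param priority Character vector: ordered keep-preference list.
#' @param predictors Columns to consider; default: numeric non-metadata
#'   columns.
#' @return The table with losing variables removed; attributes `"groups"`
#'   (list of collinear groups) and `"removed"` (character) report the
#'   decisions.
#' @export
collinearity_filter <- function(covariate_table, threshold = 0.7,
                                priority = NULL, predictors = NULL) {
  vars <- predictors %||% default_predictors(covariate_table, character(), character())
  X <- covariate_table[vars]
  const <- vapply(X, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                    !is.finite(stats::var(v, na.rm = TRUE)), logical(1))
  if (any(const)) {
    warn(sprintf("constant column(s) treated as uncorrelated: %s",
                 paste(vars[const], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  # union-find over |r| > threshold edges
  parent <- seq_along(vars)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(vars)) for (j in seq_len(i - 1L)) {
    if (abs(r[i, j]) > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_along(vars), find, integer(1))
  groups <- split(vars, root)
  groups <- groups[vapply(groups, length, integer(1)) > 1]
  rank_of <- function(v) {
    p <- match(v, priority)
    p[is.na(p)] <- length(priority) + 1L
    order(p, v)
  }
  removed <- unlist(lapply(groups, function(g) g[rank_of(g)][-1]))
  out <- covariate_table[, setdiff(names(covariate_table), removed)]
  attr(out, "groups") <- unname(groups)
  attr(out, "removed") <- unname(removed %||% character())
  out
}

#' Fit a weighted Gaussian boosted regression tree model
#'
#' Stagewise gradient boosting of depth-`tree_complexity` regression trees
#' with shrinkage `learning_rate`, per-iteration subsampling `bag_fraction`
#' and observation weights in the squared-error loss. The ensemble size is
#' chosen at the minimum of the k-fold cross-validated weighted predictive
#' deviance; CV deviance explained is `1 - CV residual deviance / weighted
#' total deviance`, computed on the held-out CV predictions (never the
#' training fit). Deterministic given the seed in `params`.
#'
#' @param data Tibble containing response, optional weights and predictors.
#' @param response Response column name.
#' @param weights Optional weights column name (`NULL` = unweighted).
#' @param predictors Predictor column names; default: numeric non-metadata
#'   columns.
#' @param params A [brt_params()].
#' @param family_tag Label for the model family (`"combined"`,
#'   `"facilitator"`, `"driver"` or `"reduced"`); bookkeeping only.
#' @return A `driver_model`: fitted ensemble, CV-selected tree count,
#'   CV deviance explained and its fold-level standard error, per-variable
#'   relative importance (sums to 100), CV predictions, and the training
#'   data (kept for simplification and partial dependence).
#' @export
fit_brt <- function(data, response = "response", weights = NULL,
                    predictors = NULL, params = brt_params(),
                    family_tag = "combined") {
  predictors <- predictors %||% default_predictors(data, response, weights)
  y <- data[[response]]
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  if (any(w < 0)) abort("weights must be non-negative")
  # normalise to mean 1: the weighted loss is scale-invariant, and this keeps
  # split regularisation (min child weight) independent of the weight scale
  w <- w / mean(w)
  n <- length(y)
  if (n < params$n_folds) abort("fewer rows than cross-validation folds")
  if (stats::var(y) == 0) abort("response is constant: deviance undefined")
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"

  fold <- local_seed(sub_seed(params$seed, 31L),
                     sample(rep(seq_len(params$n_folds), length.out = n)))
  ybar_w <- sum(w * y) / sum(w)
  total_dev <- sum(w * (y - ybar_w)^2)

  cv_mse <- matrix(NA_real_, nrow = params$max_trees, ncol = params$n_folds)
  fold_models <- vector("list", params$n_folds)
  fold_wsum <- numeric(params$n_folds)
  for (f in seq_len(params$n_folds)) {
    tr <- fold != f
    dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                   weight = w[tr], nthread = 1)
    dtest <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], label = y[!tr],
                                  weight = w[!tr], nthread = 1)
    m <- xgboost::xgb.train(
      xgb_param_list(params, sub_seed(params$seed, 1000L + f)),
      dtrain, nrounds = params$max_trees,
      evals = list(test = dtest), verbose = 0
    )
    el <- attributes(m)$evaluation_log
    cv_mse[, f] <- el$test_rmse^2
    fold_models[[f]] <- m
    fold_wsum[f] <- sum(w[!tr])
  }
  cv_curve <- as.vector(cv_mse %*% fold_wsum) / sum(fold_wsum)
  best_trees <- which.min(cv_curve)

  cv_pred <- numeric(n)
  for (f in seq_len(params$n_folds)) {
    cv_pred[fold == f] <- predict(fold_models[[f]], X[fold == f, , drop = FALSE],
                                  iterationrange = c(1, best_trees))
  }
  cv_resid_dev <- sum(w * (y - cv_pred)^2)
  cv_dev_expl <- 1 - cv_resid_dev / total_dev
  fold_dev <- vapply(seq_len(params$n_folds), function(f) {
    i <- fold == f
    1 - sum(w[i] * (y[i] - cv_pred[i])^2) / sum(w[i] * (y[i] - ybar_w)^2)
  }, numeric(1))
  cv_se <- stats::sd(fold_dev) / sqrt(params$n_folds)

  dall <- xgboost::xgb.DMatrix(X, label = y, weight = w, nthread = 1)
  final <- xgboost::xgb.train(xgb_param_list(params, sub_seed(params$seed, 999L)),
                              dall, nrounds = best_trees, verbose = 0)

  # split-gain importance straight from the tree dump: squared-error
  # improvement summed over all splits and trees, normalised to 100
  splits <- xgboost::xgb.model.dt.tree(model = final)
  splits <- splits[splits$Feature != "Leaf", c("Feature", "Gain")]
  gain <- stats::setNames(rep(0, length(predictors)), predictors)
  agg <- tapply(splits$Gain, splits$Feature, sum)
  gain[names(agg)] <- agg
  total_gain <- sum(gain)
  importance <- tibble::tibble(
    variable = predictors,
    importance = if (total_gain > 0) 100 * unname(gain) / total_gain else
      rep(100 / length(predictors), length(predictors))
  ) %>%
    dplyr::arrange(dplyr::desc(.data$importance))

  structure(list(
    model = final, params = params, predictors = predictors,
    response = response, weights = weights, n = n,
    best_trees = best_trees,
    cv_deviance_explained = cv_dev_expl, cv_se = cv_se,
    cv_predictions = cv_pred, cv_curve = cv_curve,
    importance = importance, family_tag = family_tag, data = data
  ), class = "driver_model")
}

#' Predict from a fitted driver model
#'
#' @param model A `driver_model`.
#' @param newdata Tibble containing the model's predictor columns.
#' @return Numeric predictions.
#' @export
predict_brt <- function(model, newdata) {
  X <- as.matrix(newdata[model$predictors])
  storage.mode(X) <- "double"
  predict(model$model, X)
}

#' @export
print.driver_model <- function(x, ...) {
  cat("Weighted Gaussian boosted regression trees\n")
  cat(sprintf("  n = %d | predictors = %d | CV-selected trees = %d\n",
              x$n, length(x$predictors), x$best_trees))
  cat(sprintf("  CV deviance explained = %.3f (fold SE %.3f)\n",
              x$cv_deviance_explained, x$cv_se))
  invisible(x)
}

#' Relative importance of driver-model predictors
#'
#' Split-selection gain (squared-error reduction summed over all splits and
#' trees) per variable, normalised to total 100.
#'
#' @param model A `driver_model`.
#' @return Tibble `variable`, `importance` (percent, sums to 100), sorted
#'   descending.
#' @export
relative_importance <- function(model) {
  model$importance
}

#' Tidy a driver model: relative importances
#' @param x A `driver_model`.
#' @param ... Unused.
#' @return Tibble `variable`, `importance`.
#' @export
tidy.driver_model <- function(x, ...) relative_importance(x)

#' Glance at a driver model
#' @param x A `driver_model`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_predictors`, `best_trees`,
#'   `cv_deviance_explained`, `cv_se`.
#' @export
glance.driver_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_predictors = length(x$predictors),
                 best_trees = x$best_trees,
                 cv_deviance_explained = x$cv_deviance_explained,
                 cv_se = x$cv_se)
}

#' Simplify a driver model by backward elimination
#'
#' Iteratively drops the lowest-importance variable and refits, recording
#' the change in cross-validated deviance explained. Elimination stops (and
#' the last drop is undone) once the reduced model's CV deviance explained
#' falls more than one fold-level standard error below the full model's.
#' The full elimination trace is attached so alternative stopping rules can
#' be audited.
#'
#' @param model A `driver_model` from [fit_brt()].
#' @param params Optional [brt_params()] (defaults to the model's).
#' @return The reduced `driver_model`, with attribute `"trace"` (tibble:
#'   step, dropped variable, remaining count, CV deviance explained).
#' @export
simplify_model <- function(model, params = NULL) {
  params <- params %||% model$params
  floor_dev <- model$cv_deviance_explained - model$cv_se
  current <- model
  trace <- tibble::tibble(step = 0L, dropped = NA_character_,
                          n_vars = length(model$predictors),
                          cv_deviance_explained = model$cv_deviance_explained)
  step <- 0L
  while (length(current$predictors) > 1L) {
    imp <- relative_importance(current)
    drop_var <- imp$variable[nrow(imp)]
    reduced_predictors <- setdiff(current$predictors, drop_var)
    candidate <- fit_brt(model$data, response = model$response,
                         weights = model$weights,
                         predictors = reduced_predictors, params = params)
    step <- step + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, dropped = drop_var, n_vars = length(reduced_predictors),
      cv_deviance_explained = candidate$cv_deviance_explained
    ))
    if (candidate$cv_deviance_explained < floor_dev) break
    current <- candidate
  }
  current$family_tag <- "reduced"
  attr(current, "trace") <- trace
  current
}

#' Partial dependence of the response on one variable
#'
#' Evaluates the model on a grid over the 5th-95th percentile of the
#' variable's data, at each grid value averaging predictions over the
#' empirical distribution of all other variables. Data deciles and the
#' interquartile band are attached for plotting.
#'
#' @param model A `driver_model`.
#' @param variable Predictor name.
#' @param n_points Grid size (default 25).
#' @return A `partial_dependence` tibble (`variable`, `value`, `yhat`) with
#'   attributes `deciles` and `iqr`.
#' @export
partial_dependence <- function(model, variable, n_points = 25) {
  if (!variable %in% model$predictors) {
    abort(sprintf("unknown variable '%s'", variable))
  }
  v <- model$data[[variable]]
  clip <- quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
  grid <- if (clip[1] == clip[2]) clip[1] else
    seq(clip[1], clip[2], length.out = n_points)
  base <- model$data
  yhat <- vapply(grid, function(g) {
    base[[variable]] <- g
    mean(predict_brt(model, base))
  }, numeric(1))
  out <- tibble::tibble(variable = variable, value = grid, yhat = yhat)
  attr(out, "deciles") <- quantile(v, seq(0.1, 0.9, 0.1), type = 7, names = FALSE)
  attr(out, "iqr") <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  class(out) <- c("partial_dependence", class(out))
  out
}

#' Permuted-response sanity check
#'
#' Randomly permutes the response across cells and refits the model. A
#' permuted fit "fails to resolve" when cross-validation selects a trivial
#' ensemble (at most `min_trees` trees) or the CV deviance explained is at
#' most 0.05 — confirming that the unpermuted results are not chance.
#'
#' @param data,response,weights,predictors,params As in [fit_brt()].
#' @param seed Integer seed for the permutations.
#' @param n_perm Number of independent permutations (default 2).
#' @return Tibble: `perm`, `best_trees`, `cv_deviance_explained`,
#'   `failed_to_resolve`.
#' @export
permutation_sanity <- function(data, response = "response", weights = NULL,
                               predictors = NULL, params = brt_params(),
                               seed = 1L, n_perm = 2) {
  purrr::map_dfr(seq_len(n_perm), function(i) {
    d <- data
    d[[response]] <- local_seed(sub_seed(seed, 500L + i),
                                sample(d[[response]]))
    p <- params
    p$seed <- sub_seed(seed, 600L + i)
    m <- fit_brt(d, response = response, weights = weights,
                 predictors = predictors, params = p)
    tibble::tibble(
      perm = i, best_trees = m$best_trees,
      cv_deviance_explained = m$cv_deviance_explained,
      failed_to_resolve = m$best_trees <= params$min_trees |
        m$cv_deviance_explained <= 0.05
    )
  })
}
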