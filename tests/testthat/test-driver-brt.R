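# Coarse-grid aggregation, collinearity filtering, and the weighted
# Gaussian boosted-regression-tree driver model.

test_that("aggregation dispatches on the 500 m resolution rule", {
  r <- tidyr::expand_grid(x = 1:8, y = 1:8)
  r$value <- 3.7
  fine <- aggregate_to_grid(r, native_resolution = 30, cell_size = 4)
  coarse <- aggregate_to_grid(r, native_resolution = 1000, cell_size = 4)
  expect_equal(fine$value, rep(3.7, 4))
  expect_equal(coarse$value, rep(3.7, 4), tolerance = 1e-12)
  expect_error(aggregate_to_grid(r, native_resolution = NULL, cell_size = 4),
               "native_resolution")
})

test_that("fine-resolution means skip missing pixels", {
  r <- tidyr::expand_grid(x = 1:2, y = 1:2)
  r$value <- c(1, 2, 3, NA)
  out <- aggregate_to_grid(r, native_resolution = 30, cell_size = 2)
  expect_equal(out$value, 2)
  r$value <- NA_real_
  expect_true(is.na(aggregate_to_grid(r, native_resolution = 30,
                                      cell_size = 2)$value))
})

test_that("bilinear sampling of a linear ramp is exact at cell centroids", {
  r <- tidyr::expand_grid(x = 1:12, y = 1:12)
  r$value <- 2 * r$x + 3 * r$y + 1
  out <- aggregate_to_grid(r, native_resolution = 1000, cell_size = 4)
  centroid <- function(c) (c - 1) * 4 + 2.5
  expect_equal(out$value, 2 * centroid(out$cx) + 3 * centroid(out$cy) + 1,
               tolerance = 1e-10)
})

test_that("collinearity filter removes exactly one of a duplicated pair", {
  withr::with_seed(1, {
    tab <- tibble::tibble(a = rnorm(200), b = rnorm(200))
    tab$dup <- tab$a
  })
  out <- collinearity_filter(tab)
  expect_equal(sort(setdiff(c("a", "b", "dup"), names(out))), "dup")
  expect_equal(attr(out, "removed"), "dup")
})

test_that("independent columns survive; chains group transitively", {
  withr::with_seed(2, {
    ind <- tibble::tibble(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  })
  expect_equal(length(attr(collinearity_filter(ind), "removed")), 0)
  # chain: A~B ~ 0.8, B~C ~ 0.8, A~C ~ 0.64 < 0.7 — one transitive group
  withr::with_seed(3, {
    b <- rnorm(800)
    chain <- tibble::tibble(
      a = b + rnorm(800, 0, 0.75),
      b = b,
      c = b + rnorm(800, 0, 0.75)
    )
  })
  stopifnot(abs(cor(chain$a, chain$c)) < 0.7)  # construction sanity
  out <- collinearity_filter(chain, priority = c("b"))
  expect_equal(sort(attr(out, "removed")), c("a", "c"))
  expect_equal(attr(out, "groups")[[1]], c("a", "b", "c"))
  # constant column warning
  expect_warning(collinearity_filter(dplyr::mutate(ind, k = 1)), "constant")
})

brt_fixture <- function(seed = 1, n = 400) {
  withr::with_seed(seed, {
    tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n),
      response = 2 * x1 + x2 + rnorm(n, 0, 0.4),
      weight = runif(n, 0.5, 1.5)
    )
  })
}

fast_params <- function(seed = 1, max_trees = 400) {
  brt_params(n_folds = 5, max_trees = max_trees, seed = seed)
}

test_that("pure-noise responses explain (almost) nothing", {
  withr::with_seed(4, {
    tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(500 * 10), ncol = 10)))
    tab$response <- rnorm(500)
  })
  m <- fit_brt(tab, params = fast_params(max_trees = 200))
  expect_lte(m$cv_deviance_explained, 0.05)
})

test_that("a dominant linear signal is found and ranked first", {
  m <- fit_brt(brt_fixture(), weights = "weight", params = fast_params())
  expect_gte(m$cv_deviance_explained, 0.8)
  imp <- relative_importance(m)
  expect_equal(imp$variable[1], "x1")
  expect_equal(sum(imp$importance), 100, tolerance = 1e-6)
  expect_true(all(imp$importance >= 0))
})

test_that("weights scale out of the loss: doubling them changes nothing", {
  tab <- brt_fixture()
  m1 <- fit_brt(tab, weights = "weight", params = fast_params())
  tab2 <- dplyr::mutate(tab, weight = 2 * weight)
  m2 <- fit_brt(tab2, weights = "weight", params = fast_params())
  expect_equal(m1$cv_deviance_explained, m2$cv_deviance_explained,
               tolerance = 1e-9)
  expect_equal(m1$best_trees, m2$best_trees)
  expect_equal(predict_brt(m1, tab), predict_brt(m2, tab), tolerance = 1e-9)
})

test_that("fitting is deterministic given the seed and validates inputs", {
  tab <- brt_fixture()
  m1 <- fit_brt(tab, params = fast_params(seed = 7, max_trees = 150))
  m2 <- fit_brt(tab, params = fast_params(seed = 7, max_trees = 150))
  expect_equal(m1$cv_deviance_explained, m2$cv_deviance_explained)
  expect_equal(predict_brt(m1, tab), predict_brt(m2, tab))
  expect_error(fit_brt(tab[1:3, ], params = fast_params()), "fewer rows")
  expect_error(fit_brt(dplyr::mutate(tab, response = 1),
                       params = fast_params()), "constant")
  expect_error(brt_params(learning_rate = 0), "learning rate")
  expect_error(brt_params(n_folds = 1), "folds")
  expect_error(brt_params(bag_fraction = 0), "bag fraction")
})

test_that("relative importance: unused predictors score zero, sums hit 100", {
  withr::with_seed(5, {
    tab <- tibble::tibble(x1 = rnorm(300), response = NA_real_)
    tab$response <- tab$x1^2 + rnorm(300, 0, 0.1)
  })
  m <- fit_brt(tab, predictors = "x1", params = fast_params(max_trees = 200))
  imp <- relative_importance(m)
  expect_equal(imp$importance, 100)
  # two predictors with 4:1 variance contributions: ratio within [2, 8]
  m2 <- fit_brt(brt_fixture(seed = 21), predictors = c("x1", "x2"),
                params = fast_params(seed = 2))
  imp2 <- relative_importance(m2)
  ratio <- imp2$importance[imp2$variable == "x1"] /
    imp2$importance[imp2$variable == "x2"]
  expect_gte(ratio, 2)
  expect_lte(ratio, 8)
})

test_that("simplification strips noise predictors and keeps signal", {
  tab <- brt_fixture(seed = 31)
  m <- fit_brt(tab, weights = "weight", params = fast_params(seed = 3))
  red <- simplify_model(m)
  expect_true(all(c("x1", "x2") %in% red$predictors))
  expect_false(any(c("x3", "x4") %in% red$predictors))
  tr <- attr(red, "trace")
  expect_equal(tr$step, seq_len(nrow(tr)) - 1L)
  # single-variable models pass through untouched
  m1 <- fit_brt(tab, predictors = "x1", params = fast_params(max_trees = 150))
  expect_equal(simplify_model(m1)$predictors, "x1")
})

test_that("partial dependence matches a brute-force average and trends right", {
  tab <- brt_fixture(seed = 41)
  m <- fit_brt(tab, params = fast_params(seed = 4))
  pd <- partial_dependence(m, "x1", n_points = 7)
  # brute-force oracle at three grid points
  for (i in c(1, 4, 7)) {
    probe <- tab
    probe$x1 <- pd$value[i]
    expect_equal(pd$yhat[i], mean(predict_brt(m, probe)), tolerance = 1e-10)
  }
  # monotone-increasing signal in x1 (allowing flat boosting artefacts)
  fit <- ols_line(pd$value, pd$yhat)
  expect_gt(fit$slope, 0)
  expect_true(all(diff(pd$value) > 0))
  # grid clipped to the 5th-95th percentile
  expect_gte(min(pd$value), quantile(tab$x1, 0.05) - 1e-12)
  expect_lte(max(pd$value), quantile(tab$x1, 0.95) + 1e-12)
  expect_error(partial_dependence(m, "nope"), "unknown variable")
})

test_that("zero-importance variables have flat partial dependence", {
  withr::with_seed(6, {
    tab <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300))
    tab$response <- 3 * tab$x1 + rnorm(300, 0.05)
  })
  m <- fit_brt(tab, params = fast_params(max_trees = 300))
  pd2 <- partial_dependence(m, "x2")
  expect_lte(max(pd2$yhat) - min(pd2$yhat),
             0.05 * diff(range(tab$response)))
})

test_that("permuting the response destroys the fit; the original resolves", {
  tab <- brt_fixture(seed = 51)
  p <- fast_params(seed = 5)
  base <- fit_brt(tab, weights = "weight", params = p)
  sanity <- permutation_sanity(tab, weights = "weight", params = p,
                               seed = 50, n_perm = 2)
  expect_true(all(sanity$failed_to_resolve))
  expect_true(all(sanity$cv_deviance_explained < base$cv_deviance_explained))
  expect_gte(base$cv_deviance_explained, 0.8)
  expect_equal(nrow(sanity), 2)
})

test_that("tidy/glance/autoplot work on driver models", {
  m <- fit_brt(brt_fixture(), params = fast_params(max_trees = 100))
  expect_equal(sum(tidy(m)$importance), 100, tolerance = 1e-6)
  g <- glance(m)
  expect_equal(g$n, 400)
  expect_s3_class(autoplot(m), "ggplot")
  pd <- partial_dependence(m, "x1", n_points = 5)
  expect_s3_class(autoplot(pd), "ggplot")
})

test_that("combined models explain at least as much as driver-only models", {
  withr::with_seed(61, {
    tab <- tibble::tibble(
      rain_trend = rnorm(400), fire_trend = rnorm(400),
      soil_mean = rnorm(400), elev_mean = rnorm(400)
    )
    tab$response <- tab$rain_trend - tab$fire_trend + 0.8 * tab$soil_mean +
      rnorm(400, 0, 0.4)
  })
  combined <- fit_brt(tab, params = fast_params(seed = 6), family_tag = "combined")
  driver_only <- fit_brt(tab, predictors = c("rain_trend", "fire_trend"),
                         params = fast_params(seed = 6), family_tag = "driver")
  expect_gte(combined$cv_deviance_explained,
             driver_only$cv_deviance_explained)
  expect_equal(combined$family_tag, "combined")
  expect_equal(simplify_model(driver_only)$family_tag, "reduced")
})
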