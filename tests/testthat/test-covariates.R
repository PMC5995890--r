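# Covariate suite: means and trends, extreme rainfall, PCI, variability,
# depth-weighted soils, terrain ruggedness, BRT hindcasting.

test_that("mean_and_trend matches trivial and oracle cases", {
  const <- tibble::tibble(year = 0:4, value = 7)
  out <- mean_and_trend(const)
  expect_equal(out$mean, 7)
  expect_equal(out$slope, 0)
  lin <- tibble::tibble(year = 0:2, value = c(10, 12, 14))
  out <- mean_and_trend(lin)
  expect_equal(out$mean, 12)
  expect_equal(out$slope, 2, tolerance = 1e-12)
  withr::with_seed(2, rnd <- tibble::tibble(year = 1:10, value = rnorm(10)))
  expect_equal(mean_and_trend(rnd)$slope, oracle_slope(rnd$year, rnd$value),
               tolerance = 1e-12)
  expect_error(mean_and_trend(tibble::tibble(year = 1:3, value = NA_real_)),
               "all-missing")
})

test_that("extreme rainfall: constant record has zero strict exceedances", {
  d <- tibble::tibble(date = as.Date("2000-01-01") + 0:999, rain = 5)
  out <- extreme_rainfall_counts(d)
  expect_true(all(out$count == 0))
})

test_that("a single 5-day storm is counted in its year only", {
  set.seed(0)
  days <- as.Date("2000-01-01") + 0:(365 * 10 - 1)
  rain <- rep(1, length(days))
  storm <- which(format(days, "%Y") == "2004")[100:104]
  rain[storm] <- 60
  out <- extreme_rainfall_counts(tibble::tibble(date = days, rain = rain))
  expect_gte(out$count[out$year == 2004], 1)
  expect_true(all(out$count[out$year != 2004] == 0))
})

test_that("a 365-day record has 361 sliding 5-day windows", {
  d <- tibble::tibble(date = as.Date("2000-01-01") + 0:364, rain = runif(365))
  expect_equal(attr(extreme_rainfall_counts(d), "n_windows"), 361L)
  expect_error(extreme_rainfall_counts(d[1:4, ]), "shorter")
})

test_that("extending the record can revise earlier years' counts", {
  withr::with_seed(11, {
    base <- tibble::tibble(date = as.Date("2000-01-01") + 0:(365 * 3 - 1),
                           rain = rexp(365 * 3, 1))
    wet <- tibble::tibble(date = max(base$date) + 1:365,
                          rain = rexp(365, 1 / 8))
  })
  short <- extreme_rainfall_counts(base)
  long <- extreme_rainfall_counts(dplyr::bind_rows(base, wet))
  joint <- dplyr::inner_join(short, long, by = "year")
  expect_gt(attr(long, "threshold"), attr(short, "threshold"))
  expect_false(all(joint$count.x == joint$count.y))
})

test_that("PCI hits its bounds and the hand-derived value", {
  expect_equal(precipitation_concentration_index(rep(50, 12)), 100 / 12)
  expect_equal(precipitation_concentration_index(c(120, rep(0, 11))), 100)
  expect_equal(precipitation_concentration_index(c(100, 50, 50, rep(0, 9))), 37.5)
  expect_true(is.na(precipitation_concentration_index(rep(0, 12))))
  expect_error(precipitation_concentration_index(1:5), "12 monthly")
})

test_that("PCI stays within [100/12, 100] on random month vectors", {
  withr::with_seed(13, {
    for (i in 1:200) {
      p <- rexp(12) * sample(c(1, 10), 12, replace = TRUE)
      pci <- precipitation_concentration_index(p)
      expect_gte(pci, 100 / 12 - 1e-12)
      expect_lte(pci, 100 + 1e-12)
    }
  })
})

test_that("multi-year monthly tables reduce to mean months first", {
  mt <- tidyr::expand_grid(year = 2000:2002, month = 1:12)
  mt$rain <- ifelse(mt$month == 1, 120, 0)
  expect_equal(precipitation_concentration_index(mt), 100)
})

test_that("rainfall variability reports population SDs at both scales", {
  s <- tibble::tibble(time = c(2000.1, 2000.6, 2001.2, 2001.7),
                      rain = c(400, 500, 600, 500))
  out <- rainfall_variability(s)
  expect_equal(out$sd[out$scale == "annual"], 100)  # totals 900, 1100
  expect_equal(out$sd[out$scale == "subdaily"], sqrt(mean((s$rain - 500)^2)))
  const <- rainfall_variability(tibble::tibble(time = 2000:2003 + 0.5, rain = 2))
  expect_equal(const$sd, c(0, 0))
})

test_that("depth-weighted soil aggregation is a thickness-weighted mean", {
  expect_equal(depth_weighted_soil(c(10, 20), c(0, 5), c(5, 20)), 17.5)
  expect_equal(depth_weighted_soil(rep(4, 6), 0:5, 1:6), 4)
  withr::with_seed(3, {
    v <- rnorm(6); b <- cumsum(runif(6, 1, 10))
    top <- c(0, b[-6])
    naive <- sum(v * (b - top)) / sum(b - top)
    expect_equal(depth_weighted_soil(v, top, b), naive, tolerance = 1e-12)
    expect_gte(depth_weighted_soil(v, top, b), min(v))
    expect_lte(depth_weighted_soil(v, top, b), max(v))
  })
  expect_error(depth_weighted_soil(1:2, c(0, 4), c(5, 8)), "contiguous")
  expect_error(depth_weighted_soil(1, 5, 5), "positive thickness")
})

test_that("TRI is zero on flat terrain and matches the single-step case", {
  flat <- tidyr::expand_grid(x = 1:5, y = 1:5)
  flat$elevation <- 100
  expect_true(all(terrain_ruggedness(flat)$tri == 0))
  one <- tidyr::expand_grid(x = 1:3, y = 1:3)
  one$elevation <- ifelse(one$x == 1 & one$y == 1, 13, 10)
  tri_r <- terrain_ruggedness(one)
  tri_a <- terrain_ruggedness(one, method = "sum_abs")
  centre <- function(df) df$tri[df$x == 2 & df$y == 2]
  expect_equal(centre(tri_r), 3)   # sqrt(3^2)
  expect_equal(centre(tri_a), 3)   # |(-3)|
})

test_that("TRI matches brute-force neighbour loops on a random DEM", {
  withr::with_seed(9, {
    dem <- tidyr::expand_grid(x = 1:5, y = 1:5)
    dem$elevation <- rnorm(25, 500, 50)
  })
  m <- matrix(NA_real_, 5, 5)
  m[cbind(dem$y, dem$x)] <- dem$elevation
  brute <- function(fun, red) {
    out <- dem
    out$tri <- NA_real_
    for (i in seq_len(nrow(dem))) {
      cx <- dem$x[i]; cy <- dem$y[i]
      acc <- 0
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        nx <- cx + dx; ny <- cy + dy
        if (nx < 1 || nx > 5 || ny < 1 || ny > 5) next
        acc <- acc + fun(m[cy, cx] - m[ny, nx])
      }
      out$tri[i] <- red(acc)
    }
    out
  }
  riley <- brute(function(d) d^2, sqrt)
  absv <- brute(abs, identity)
  expect_equal(terrain_ruggedness(dem)$tri, riley$tri, tolerance = 1e-10)
  expect_equal(terrain_ruggedness(dem, method = "sum_abs")$tri, absv$tri,
               tolerance = 1e-10)
  # invariance to a constant shift; non-negativity
  shifted <- dem; shifted$elevation <- shifted$elevation + 1000
  expect_equal(terrain_ruggedness(shifted)$tri, riley$tri, tolerance = 1e-9)
  expect_true(all(riley$tri >= 0))
})

hindcast_fixture <- function(noise = 0) {
  # response is a known function of one predictor; predictor values are
  # redrawn each epoch from a common range (trees cannot extrapolate, so the
  # cross-epoch check stays within the trained support)
  withr::with_seed(19, {
    cells <- 1:150
    purrr::map_dfr(1:4, function(e) {
      x1 <- runif(150, 0, 1)
      x2 <- rnorm(150)
      tibble::tibble(cell = cells, epoch = e, x1 = x1, x2 = x2,
                     density = 3 * x1 + rnorm(150, 0, noise))
    })
  })
}

test_that("hindcast recovers a deterministic predictor relation", {
  d <- hindcast_fixture()
  hm <- fit_hindcast(d, response = "density", predictors = c("x1", "x2"),
                     reference_epoch = 2,
                     params = brt_params(n_folds = 5, max_trees = 600, seed = 3))
  expect_true(all(hm$validation$r2 >= 0.95))
  expect_equal(sum(hm$contributions$importance), 100, tolerance = 1e-6)
  expect_gt(hm$contributions$importance[hm$contributions$variable == "x1"], 90)
})

test_that("constant predictors give a constant hindcast and zero slope", {
  d <- hindcast_fixture()
  d$x1 <- rep(d$x1[d$epoch == 2], times = 4)
  d$x2 <- rep(d$x2[d$epoch == 2], times = 4)
  d$density[d$epoch != 2] <- NA
  hm <- fit_hindcast(d, response = "density", predictors = c("x1", "x2"),
                     reference_epoch = 2,
                     params = brt_params(n_folds = 5, max_trees = 200, seed = 3))
  expect_equal(hm$trend$slope, rep(0, 150), tolerance = 1e-9)
})

test_that("hindcasting is deterministic and validates its inputs", {
  d <- hindcast_fixture(noise = 0.2)
  p <- brt_params(n_folds = 5, max_trees = 150, seed = 11)
  a <- fit_hindcast(d, "density", c("x1", "x2"), reference_epoch = 2, params = p)
  b <- fit_hindcast(d, "density", c("x1", "x2"), reference_epoch = 2, params = p)
  expect_equal(a$predictions$predicted, b$predictions$predicted)
  d2 <- d
  d2$x1[d2$epoch == 3] <- NA
  expect_error(fit_hindcast(d2, "density", c("x1", "x2"), reference_epoch = 2,
                            params = p), "missing predictor")
})

test_that("the covariate table tags drivers and facilitators correctly", {
  cv <- generate_covariates(tiny_config())
  tab <- build_covariate_table(cv)
  roles <- attr(tab, "roles")
  expect_false(any(duplicated(roles$variable)))
  expect_true(all(roles$role[grepl("_trend$", roles$variable)] == "driver"))
  expect_true(all(roles$role[grepl("_mean$", roles$variable)] == "facilitator"))
  # statics contribute means only
  expect_false("soil_clay_trend" %in% names(tab))
  expect_true(all(c("soil_clay_mean", "rainfall_trend", "rainfall_mean") %in%
                    names(tab)))
  expect_equal(nrow(tab), (16 / 4)^2)
  # estimated cell trends track the generating truth
  true_cells <- cv$fields |>
    dplyr::filter(covariate == "rainfall") |>
    dplyr::mutate(cx = ceiling(x / 4), cy = ceiling(y / 4)) |>
    dplyr::group_by(cx, cy) |>
    dplyr::summarise(t = mean(trend_true), .groups = "drop")
  joined <- dplyr::left_join(tab, true_cells, by = c("cx", "cy"))
  expect_gte(cor(joined$rainfall_trend, joined$t), 0.95)
})
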