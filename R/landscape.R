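# Synthetic landscape: a seeded toy subcontinent with known covariate trends,
# known cover dynamics and a spectral observation model. Provides ground truth
# for the mask -> metrics -> cover model -> trend -> driver attribution chain.

# Internal: evaluate expr under a temporary RNG state; the caller's
# .Random.seed is restored afterwards so generators are pure in (config, seed).
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Fixed six-band endmember spectra (blue, green, red, NIR, SWIR1, SWIR2).
# Woody canopy keeps high NIR / low red year-round; the herbaceous layer
# swings between a green and a senescent state, which is what makes temporal
# variance and range informative for separating the two.
BAND_NAMES <- c("blue", "green", "red", "nir", "swir1", "swir2")

ENDMEMBER_WOODY <- c(blue = 0.04, green = 0.07, red = 0.05,
                     nir = 0.32, swir1 = 0.16, swir2 = 0.08)
ENDMEMBER_GRASS_GREEN <- c(blue = 0.05, green = 0.10, red = 0.08,
                           nir = 0.45, swir1 = 0.26, swir2 = 0.13)
ENDMEMBER_GRASS_DRY <- c(blue = 0.10, green = 0.15, red = 0.20,
                         nir = 0.28, swir1 = 0.34, swir2 = 0.24)

#' Default five-year epoch layout
#'
#' Six non-overlapping five-year epochs spanning 1986-2016, the layout the
#' whole pipeline assumes. The epoch midpoint is the time coordinate used for
#' each epoch's cover value in trend regressions.
#'
#' @param start First year (default 1986).
#' @param n_epochs Number of epochs (default 6).
#' @param length_years Epoch length in years (default 5).
#' @return A tibble with `epoch`, `start`, `end`, `midpoint`.
#' @export
default_epochs <- function(start = 1986, n_epochs = 6, length_years = 5) {
  s <- start + length_years * (seq_len(n_epochs) - 1)
  tibble::tibble(
    epoch = seq_len(n_epochs),
    start = s,
    end = s + length_years,
    midpoint = s + length_years / 2
  )
}

#' Default synthetic covariate specifications
#'
#' One row per covariate: its long-term mean level and spatial variation,
#' per-year trend field parameters, interannual observation noise, spatial
#' smoothness (Gaussian kernel sd, in pixels) and whether it varies in time.
#' Units are conventional for the variable (mm/yr rainfall, degrees C
#' temperature, burned fraction per year, persons/km^2, animals/km^2, %, m).
#'
#' @return A tibble of covariate specs consumed by [landscape_config()].
#' @export
default_covariate_specs <- function() {
  tibble::tribble(
    ~name,               ~mean_level, ~mean_sd, ~trend_mean, ~trend_sd, ~noise_sd, ~sigma, ~time_varying,
    "rainfall",            650,        180,       1.0,         5.0,       40,        6,      TRUE,
    "temperature",          22,          2,       0.01,        0.025,      0.15,     8,      TRUE,
    "burned_area",           0.25,       0.10,   -0.002,       0.004,      0.02,     5,      TRUE,
    "population",           25,         12,       0.3,         0.6,        0.5,      6,      TRUE,
    "herbivore_density",    12,          5,       0.0,         0.15,       0.4,      6,      TRUE,
    "soil_clay",            25,          8,       0,           0,          0,        5,      FALSE,
    "elevation",           800,        250,       0,           0,          0,       10,      FALSE
  )
}

#' Default cover-dynamics coefficients
#'
#' Effects of (scaled) covariate fields on the per-epoch cover increment.
#' Trend terms carry the causal structure the driver model must recover:
#' burned-area decline and wetter/warmer climates favour woody encroachment,
#' and population growth has a hump-shaped effect (positive linear term plus
#' a negative quadratic `_trend_sq` term). Several covariates are deliberate
#' nulls (zero coefficient) so driver-recovery tests have negative controls.
#'
#' @return A named numeric vector of coefficients.
#' @export
default_coefficients <- function() {
  c(
    rainfall_trend = 0.09,
    temperature_trend = 0.06,
    burned_area_trend = -0.09,
    population_trend = 0.02,
    population_trend_sq = -0.04,
    herbivore_density_trend = 0,
    soil_clay_mean = 0,
    elevation_mean = 0
  )
}

#' Configuration for the synthetic landscape
#'
#' Bundles grid dimensions, epoch layout, covariate specifications, cover
#' dynamics coefficients and the spectral observation model into a validated
#' config object. All generators are pure functions of (config, seed).
#'
#' @param nx,ny Fine-grid dimensions in pixels.
#' @param cell_size Coarse-cell edge length in pixels (coarse grid for driver
#'   attribution; e.g. 8 gives an 8x8-cell grid from a 64x64-pixel grid).
#' @param epochs Epoch table as from [default_epochs()].
#' @param covariate_specs Covariate spec tibble ([default_covariate_specs()]).
#' @param coefficients Named coefficient vector ([default_coefficients()]);
#'   must reference known covariates and include at least one zero effect.
#' @param initial_cover_mean,initial_cover_sd Mean and spatial sd of the
#'   epoch-1 cover field (unit fraction).
#' @param cover_sigma Spatial smoothness of the initial cover field (pixels).
#' @param cover_noise_sd SD of the per-pixel, per-step noise added to the
#'   cover forcing (0 gives fully deterministic dynamics).
#' @param obs_per_epoch Scene observations per pixel per epoch.
#' @param cloud_prob Probability an observation is cloud-flagged, in \[0, 1\].
#' @param refl_noise_sd SD of Gaussian reflectance noise per band.
#' @param secondary_sensor `NULL`, or a list with `name`, `epochs` (epoch ids
#'   it contributes to), `fraction` of observations it supplies, and per-band
#'   `gain` / `bias` of its linear radiometric offset.
#' @param seed Integer seed governing every random draw.
#' @return A `landscape_config` object (a validated list).
#' @export
landscape_config <- function(nx = 64, ny = 64, cell_size = 8,
                             epochs = default_epochs(),
                             covariate_specs = default_covariate_specs(),
                             coefficients = default_coefficients(),
                             initial_cover_mean = 0.45,
                             initial_cover_sd = 0.18,
                             cover_sigma = 5,
                             cover_noise_sd = 0.01,
                             obs_per_epoch = 15,
                             cloud_prob = 0.25,
                             refl_noise_sd = 0.01,
                             secondary_sensor = list(
                               name = "OLI", epochs = 6L, fraction = 0.5,
                               gain = 1.05, bias = 0.01
                             ),
                             seed = 1L) {
  if (nx < 1 || ny < 1) abort("grid dimensions must be positive")
  if (cloud_prob < 0 || cloud_prob > 1) abort("cloud_prob must be in [0, 1]")
  ep <- dplyr::arrange(epochs, .data$start)
  if (any(ep$end[-nrow(ep)] > ep$start[-1])) {
    abort("epochs must be non-overlapping and ordered")
  }
  check_coefficient_names(coefficients, covariate_specs$name)
  if (!any(coefficients == 0)) {
    abort("at least one zero-effect (null) covariate coefficient is required")
  }
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), cell_size = as.integer(cell_size),
    epochs = ep, covariate_specs = covariate_specs, coefficients = coefficients,
    initial_cover_mean = initial_cover_mean, initial_cover_sd = initial_cover_sd,
    cover_sigma = cover_sigma, cover_noise_sd = cover_noise_sd,
    obs_per_epoch = as.integer(obs_per_epoch), cloud_prob = cloud_prob,
    refl_noise_sd = refl_noise_sd, secondary_sensor = secondary_sensor,
    seed = as.integer(seed)
  ), class = "landscape_config")
}

# Internal: coefficient names must be <covariate>_trend, <covariate>_mean or
# <covariate>_trend_sq for a known covariate.
check_coefficient_names <- function(coefficients, covariate_names) {
  allowed <- c(
    paste0(covariate_names, "_trend"),
    paste0(covariate_names, "_mean"),
    paste0(covariate_names, "_trend_sq")
  )
  bad <- setdiff(names(coefficients), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown coefficient name(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Generate synthetic covariate fields and series
#'
#' Draws a smooth spatial field for each covariate's long-term mean and
#' per-year trend, then (for time-varying covariates) an annual series
#' `mean + trend * (year - midpoint_year) + noise` per pixel. The true mean
#' and trend fields are stored alongside the observed series, so downstream
#' mean-and-trend estimation can be checked against ground truth.
#'
#' @param config A [landscape_config()].
#' @return A `covariate_set`: list with `fields` (tibble: covariate, x, y,
#'   mean_true, trend_true), `series` (tibble: covariate, x, y, year, value;
#'   time-varying covariates only), `years`, and the config.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nx <- config$nx; ny <- config$ny
  years <- seq(min(config$epochs$start), max(config$epochs$end))
  year_ref <- mean(years)
  local_seed(sub_seed(config$seed, 101L), {
    grid <- matrix_to_grid(matrix(0, ny, nx))[, c("x", "y")]
    fields <- purrr::pmap(config$covariate_specs, function(name, mean_level, mean_sd,
                                                           trend_mean, trend_sd,
                                                           noise_sd, sigma, time_varying) {
      mean_true <- mean_level + mean_sd * as.vector(gaussian_field(ny, nx, sigma))
      if (mean_level > 0) mean_true <- pmax(mean_true, 0.05 * mean_level)
      trend_true <- if (time_varying) {
        trend_mean + trend_sd * as.vector(gaussian_field(ny, nx, sigma))
      } else {
        rep(0, nx * ny)
      }
      dplyr::mutate(grid, covariate = name, mean_true = mean_true,
                    trend_true = trend_true, .before = 1)
    })
    fields <- dplyr::bind_rows(fields)

    tv <- config$covariate_specs[config$covariate_specs$time_varying, ]
    series <- purrr::map(tv$name, function(nm) {
      f <- dplyr::filter(fields, .data$covariate == nm)
      noise_sd <- tv$noise_sd[tv$name == nm]
      tidyr::crossing(f, year = years) %>%
        dplyr::mutate(
          value = .data$mean_true + .data$trend_true * (.data$year - year_ref) +
            if (noise_sd > 0) rnorm(dplyr::n(), 0, noise_sd) else 0
        ) %>%
        dplyr::select("covariate", "x", "y", "year", "value")
    })
    series <- dplyr::bind_rows(series)

    structure(list(fields = fields, series = series, years = years,
                   year_ref = year_ref, config = config),
              class = "covariate_set")
  })
}

# Internal: per-pixel forcing from coefficient vector and true fields.
# Trend terms are scaled by the field sd (not centred: zero trend is a
# meaningful origin); mean terms are centred and scaled. `_trend_sq` terms
# apply to the squared scaled trend, giving hump-shaped responses.
forcing_field <- function(covariates, coefficients) {
  fields <- covariates$fields
  npix <- sum(fields$covariate == fields$covariate[1])
  f <- numeric(npix)
  scaled <- function(nm, what) {
    v <- fields[fields$covariate == nm, ][[what]]
    s <- sd(v)
    if (what == "trend_true") {
      if (s > 0) v / s else v
    } else {
      if (s > 0) (v - mean(v)) / s else v - mean(v)
    }
  }
  for (cn in names(coefficients)) {
    beta <- coefficients[[cn]]
    if (beta == 0) next
    if (grepl("_trend_sq$", cn)) {
      nm <- sub("_trend_sq$", "", cn)
      f <- f + beta * scaled(nm, "trend_true")^2
    } else if (grepl("_trend$", cn)) {
      f <- f + beta * scaled(sub("_trend$", "", cn), "trend_true")
    } else {
      f <- f + beta * scaled(sub("_mean$", "", cn), "mean_true")
    }
  }
  f
}

#' Generate true fractional woody cover dynamics
#'
#' Starting from a smooth initial cover field, cover evolves across epochs by
#' logistic-bounded increments: the per-step change is the coefficient-weighted
#' combination of covariate trend/mean fields (plus optional noise), scaled by
#' `cover * (1 - cover)` and clipped to \[0, 1\]. The stored true slope is the
#' OLS slope of the epoch covers against epoch midpoints, so the generator is
#' self-consistent with the pipeline's definition of change.
#'
#' @param covariates A `covariate_set` from [generate_covariates()].
#' @param coefficients Named coefficient vector; defaults to the config's.
#' @param config A [landscape_config()]; defaults to the covariate set's.
#' @return A `true_state`: list with `cover` (tibble: pixel_id, x, y, epoch,
#'   cover), `slope` (tibble: pixel_id, x, y, slope_true), `forcing`,
#'   `coefficients` and the config.
#' @export
generate_true_cover <- function(covariates, coefficients = NULL, config = NULL) {
  stopifnot(inherits(covariates, "covariate_set"))
  config <- config %||% covariates$config
  coefficients <- coefficients %||% config$coefficients
  check_coefficient_names(coefficients, config$covariate_specs$name)
  nx <- config$nx; ny <- config$ny
  npix <- nx * ny
  n_ep <- nrow(config$epochs)
  local_seed(sub_seed(config$seed, 202L), {
    c0 <- clip01(config$initial_cover_mean +
                   config$initial_cover_sd *
                     as.vector(gaussian_field(ny, nx, config$cover_sigma)))
    f <- forcing_field(covariates, coefficients)
    cover <- matrix(NA_real_, nrow = npix, ncol = n_ep)
    cover[, 1] <- c0
    for (e in seq_len(n_ep - 1L)) {
      eps <- if (config$cover_noise_sd > 0) {
        rnorm(npix, 0, config$cover_noise_sd)
      } else {
        0
      }
      cover[, e + 1L] <- clip01(cover[, e] + (f + eps) * cover[, e] * (1 - cover[, e]))
    }
    grid <- matrix_to_grid(matrix(0, ny, nx))[, c("x", "y")]
    grid$pixel_id <- seq_len(npix)
    cover_df <- tibble::tibble(
      pixel_id = rep(seq_len(npix), each = n_ep),
      epoch = rep(config$epochs$epoch, times = npix),
      cover = as.vector(t(cover))
    )
    cover_df <- dplyr::left_join(cover_df, grid, by = "pixel_id")
    tr <- ols_rows(cover, config$epochs$midpoint)
    slope_df <- dplyr::mutate(grid, pixel_id = dplyr::row_number(),
                              slope_true = tr$slope)
    structure(list(
      cover = dplyr::select(cover_df, "pixel_id", "x", "y", "epoch", "cover"),
      slope = dplyr::select(slope_df, "pixel_id", "x", "y", "slope_true"),
      forcing = f, coefficients = coefficients, config = config
    ), class = "true_state")
  })
}

# Internal: herbaceous endmember at fractional-year time t (seasonal green-up).
grass_endmember <- function(t) {
  g <- 0.5 + 0.45 * sin(2 * pi * t)
  outer(g, ENDMEMBER_GRASS_GREEN - ENDMEMBER_GRASS_DRY) +
    matrix(ENDMEMBER_GRASS_DRY, nrow = length(t), ncol = 6, byrow = TRUE)
}

#' Simulate a scene stack from true cover
#'
#' Emits the configured number of dated observations per pixel per epoch.
#' Reflectance is a linear mixture of the woody and (seasonally varying)
#' herbaceous endmember spectra weighted by true cover, with optional
#' secondary-sensor linear band offsets, Gaussian noise, and independent
#' cloud flags.
#'
#' @param true_state A `true_state` from [generate_true_cover()].
#' @param config A [landscape_config()]; defaults to the true state's.
#' @return A `SceneStack` tibble: pixel_id, x, y, epoch, date, sensor, valid,
#'   and the six band columns blue..swir2.
#' @export
simulate_scenes <- function(true_state, config = NULL) {
  stopifnot(inherits(true_state, "true_state"))
  config <- config %||% true_state$config
  ep <- config$epochs
  n_obs <- config$obs_per_epoch
  npix <- config$nx * config$ny
  sec <- config$secondary_sensor
  local_seed(sub_seed(config$seed, 303L), {
    per_epoch <- purrr::map(seq_len(nrow(ep)), function(e) {
      dates <- sort(runif(n_obs, ep$start[e], ep$end[e]))
      cov_e <- true_state$cover$cover[true_state$cover$epoch == ep$epoch[e]]
      obs <- tidyr::crossing(
        dplyr::tibble(pixel_id = seq_len(npix)),
        dplyr::tibble(date = dates)
      )
      cover <- cov_e[obs$pixel_id]
      grass <- grass_endmember(obs$date - floor(obs$date))
      refl <- cover %o% ENDMEMBER_WOODY + (1 - cover) * grass
      colnames(refl) <- BAND_NAMES
      sensor <- rep(if (e <= 3) "TM" else "ETM", nrow(obs))
      if (!is.null(sec) && ep$epoch[e] %in% sec$epochs) {
        take <- runif(nrow(obs)) < sec$fraction
        sensor[take] <- sec$name
        gain <- rep_len(sec$gain, 6)
        bias <- rep_len(sec$bias, 6)
        refl[take, ] <- sweep(sweep(refl[take, , drop = FALSE], 2, gain, `*`),
                              2, bias, `+`)
      }
      if (config$refl_noise_sd > 0) {
        refl <- refl + matrix(rnorm(length(refl), 0, config$refl_noise_sd),
                              nrow = nrow(refl))
      }
      valid <- runif(nrow(obs)) >= config$cloud_prob
      dplyr::bind_cols(
        dplyr::tibble(pixel_id = obs$pixel_id, epoch = ep$epoch[e],
                      date = obs$date, sensor = sensor, valid = valid),
        tibble::as_tibble(refl)
      )
    })
    stack <- dplyr::bind_rows(per_epoch)
    grid <- dplyr::distinct(true_state$cover[, c("pixel_id", "x", "y")])
    dplyr::left_join(stack, grid, by = "pixel_id") %>%
      dplyr::select("pixel_id", "x", "y", "epoch", "date", "sensor", "valid",
                    dplyr::all_of(BAND_NAMES))
  })
}

#' Quantize fractional cover to photo-interpretation classes
#'
#' Rounds to the nearest of \{0, 0.25, 0.5, 0.75, 1\}; exact midpoints
#' (0.125, 0.375, ...) round half up. Values are clipped to \[0, 1\] first.
#'
#' @param cover Numeric fractional cover.
#' @return Quantized cover in the five classes.
#' @examples
#' quantize_cover(c(0.6, 0.875)) # 0.5, 1
#' @export
quantize_cover <- function(cover) {
  floor(clip01(cover) * 4 + 0.5) / 4
}

#' Sample labelled photo-interpretation quadrats
#'
#' Samples `n` pixel locations (without replacement) from the unmasked area,
#' assigns each an epoch and an acquisition date, and labels it with the true
#' cover (plus optional interpreter noise) quantized to the nearest quarter
#' class. A configurable fraction is flagged uncertain, and a configurable
#' fraction receives a date outside its epoch range, to exercise the
#' training-assembly exclusion rules.
#'
#' @param true_state A `true_state`.
#' @param n Number of quadrats (default 4000).
#' @param seed Integer seed.
#' @param label_noise_sd SD of Gaussian interpreter noise added to true cover
#'   before quantization (default 0).
#' @param uncertain_frac Fraction flagged uncertain (default 0).
#' @param date_outside_frac Fraction dated outside their epoch (default 0).
#' @param mask Optional analysis-mask tibble (x, y, excluded); excluded
#'   pixels are not sampled.
#' @return A tibble: quadrat_id, pixel_id, x, y, epoch, date, true_cover,
#'   label, uncertain.
#' @export
sample_quadrats <- function(true_state, n = 4000, seed = 1L,
                            label_noise_sd = 0, uncertain_frac = 0,
                            date_outside_frac = 0, mask = NULL) {
  stopifnot(inherits(true_state, "true_state"), n >= 1)
  config <- true_state$config
  grid <- dplyr::distinct(true_state$cover[, c("pixel_id", "x", "y")])
  if (!is.null(mask)) {
    keep <- dplyr::filter(mask, !.data$excluded)[, c("x", "y")]
    grid <- dplyr::semi_join(grid, keep, by = c("x", "y"))
  }
  if (n > nrow(grid)) {
    abort(sprintf("n = %d exceeds the %d available unmasked pixels", n, nrow(grid)))
  }
  ep <- config$epochs
  local_seed(seed, {
    picked <- grid[sample(nrow(grid), n), ]
    picked$quadrat_id <- seq_len(n)
    picked$epoch <- sample(ep$epoch, n, replace = TRUE)
    i <- match(picked$epoch, ep$epoch)
    picked$date <- runif(n, ep$start[i], ep$end[i])
    outside <- runif(n) < date_outside_frac
    picked$date[outside] <- ep$start[i][outside] - runif(sum(outside), 0.1, 2)
    picked <- dplyr::left_join(picked, true_state$cover,
                               by = c("pixel_id", "x", "y", "epoch"))
    noise <- if (label_noise_sd > 0) rnorm(n, 0, label_noise_sd) else 0
    picked$label <- quantize_cover(picked$cover + noise)
    picked$uncertain <- runif(n) < uncertain_frac
    dplyr::select(dplyr::rename(picked, true_cover = "cover"),
                  "quadrat_id", "pixel_id", "x", "y", "epoch", "date",
                  "true_cover", "label", "uncertain")
  })
}

#' Simulate a complete synthetic landscape
#'
#' Convenience wrapper chaining [generate_covariates()],
#' [generate_true_cover()] and [simulate_scenes()].
#'
#' @param config A [landscape_config()].
#' @return A list with `covariates`, `truth` and `scenes`.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  covariates <- generate_covariates(config)
  truth <- generate_true_cover(covariates)
  scenes <- simulate_scenes(truth)
  list(covariates = covariates, truth = truth, scenes = scenes)
}

#' Simulate a coarse-grid driver table with known active and null drivers
#'
#' Generates smooth, mutually independent standardized trend fields on a
#' coarse cell grid, a response that is a known linear combination of the
#' active fields plus Gaussian noise, and per-cell quality weights. This is
#' the controlled setting for driver-attribution tests: every active driver
#' should out-rank every null in relative importance, and partial-dependence
#' slopes should match the generating signs.
#'
#' @param n_cells_x,n_cells_y Coarse grid dimensions (default 20 x 20).
#' @param active Named vector of generating coefficients on standardized
#'   fields (default: rainfall trend +1, temperature trend +0.7, burned-area
#'   trend -1, mirroring wetting/warming gains and fire-decline-driven gains).
#' @param null_names Names of zero-effect covariates (default 3).
#' @param noise_sd SD of response noise (response signal has sd
#'   `sqrt(sum(active^2))`; default 0.4).
#' @param sigma Spatial smoothness of the fields in cells (default 2).
#' @param seed Integer seed.
#' @return A tibble: cell, x, y, weight, response, and one column per
#'   covariate; attributes `active` (named coefficients) and `null_names`.
#' @export
simulate_driver_table <- function(n_cells_x = 20, n_cells_y = 20,
                                  active = c(rainfall_trend = 1,
                                             temperature_trend = 0.7,
                                             burned_area_trend = -1),
                                  null_names = c("windspeed_trend",
                                                 "soil_moisture_trend",
                                                 "evaporation_trend"),
                                  noise_sd = 0.4, sigma = 2, seed = 1L) {
  stopifnot(length(null_names) >= 1, length(active) >= 1)
  local_seed(sub_seed(seed, 404L), {
    vars <- c(names(active), null_names)
    fields <- purrr::map(vars, function(v) {
      as.vector(gaussian_field(n_cells_y, n_cells_x, sigma))
    })
    names(fields) <- vars
    tab <- dplyr::bind_cols(
      matrix_to_grid(matrix(0, n_cells_y, n_cells_x))[, c("x", "y")],
      tibble::as_tibble(fields)
    )
    tab$cell <- seq_len(nrow(tab))
    signal <- as.matrix(tab[names(active)]) %*% active
    tab$response <- as.vector(signal) + rnorm(nrow(tab), 0, noise_sd)
    tab$weight <- runif(nrow(tab), 0.8, 1.2)
    out <- dplyr::select(tab, "cell", "x", "y", "weight", "response",
                         dplyr::all_of(vars))
    attr(out, "active") <- active
    attr(out, "null_names") <- null_names
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write or read a landscape configuration as YAML
#'
#' Persists every scalar field plus the epoch and covariate-spec tables so a
#' simulation can be reproduced outside the R session that defined it.
#'
#' @param config A [landscape_config()].
#' @param path File path.
#' @return `write_landscape_config()` returns `path` invisibly;
#'   `read_landscape_config()` returns a validated `landscape_config`.
#' @export
write_landscape_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required to write configs")
  }
  out <- unclass(config)
  out$epochs <- as.list(config$epochs)
  out$covariate_specs <- as.list(config$covariate_specs)
  out$coefficients <- as.list(config$coefficients)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_landscape_config
#' @export
read_landscape_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required to read configs")
  }
  raw <- yaml::read_yaml(path)
  raw$epochs <- tibble::as_tibble(raw$epochs)
  raw$covariate_specs <- tibble::as_tibble(raw$covariate_specs)
  raw$coefficients <- unlist(raw$coefficients)
  if (length(raw$secondary_sensor) == 0) raw$secondary_sensor <- NULL
  do.call(landscape_config, raw)
}
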