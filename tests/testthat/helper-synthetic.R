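# Shared fixtures: a small synthetic landscape, built once per test run.

tiny_config <- function(...) {
  args <- list(nx = 16, ny = 16, cell_size = 4, obs_per_epoch = 8,
               cloud_prob = 0.2, refl_noise_sd = 0.01,
               cover_noise_sd = 0.01, seed = 7)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(landscape_config, args)
}

.fixtures <- new.env()

tiny_landscape <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- simulate_landscape(tiny_config())
  }
  .fixtures$tiny
}

# Brute-force metric oracle, deliberately independent of the package's
# internals: stats::quantile(type = 7) plus naive loops.
oracle_metrics <- function(v, window = "value") {
  ps <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  q <- unname(stats::quantile(v, ps, type = 7))
  wins <- list(c(0.10, 0.25), c(0.25, 0.50), c(0.50, 0.75),
               c(0.75, 0.90), c(0.25, 0.75))
  wm <- sapply(wins, function(wn) {
    if (window == "value") {
      lo <- unname(stats::quantile(v, wn[1], type = 7))
      hi <- unname(stats::quantile(v, wn[2], type = 7))
      keep <- c()
      for (x in v) if (x >= lo && x <= hi) keep <- c(keep, x)
      if (length(keep)) mean(keep) else NA_real_
    } else {
      vs <- sort(v)
      n <- length(vs)
      mean(vs[ceiling(1 + (n - 1) * wn[1]):ceiling(1 + (n - 1) * wn[2])])
    }
  })
  c(min = min(v), max = max(v),
    p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
    m10_25 = wm[1], m25_50 = wm[2], m50_75 = wm[3], m75_90 = wm[4],
    m25_75 = wm[5],
    var = mean((v - mean(v))^2), range = max(v) - min(v))
}

within_config <- function(cfg, ...) {
  mods <- list(...)
  for (n in names(mods)) cfg[[n]] <- mods[[n]]
  cfg
}

# Closed-form OLS slope oracle.
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# One-pixel-per-series scene stack so epoch_metrics can be exercised on
# arbitrary series collections.
series_stack <- function(series_list) {
  dplyr::bind_rows(lapply(seq_along(series_list), function(i) {
    v <- series_list[[i]]
    tibble::tibble(pixel_id = i, x = i, y = 1L, epoch = 1L,
                   date = seq_along(v), sensor = "TM", valid = TRUE,
                   red = v, ndvi = v)
  }))
}
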