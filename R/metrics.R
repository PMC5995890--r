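# Per-epoch time-series spectral metrics: cloud filtering, vegetation
# indices, sensor harmonization, and the percentile / windowed-mean /
# variance feature set computed per pixel and epoch.

INDEX_NAMES <- c("ndvi", "savi", "evi")

#' Add vegetation indices to a scene table
#'
#' NDVI = (NIR - red) / (NIR + red); SAVI = (1 + L) (NIR - red) /
#' (NIR + red + L) with L = 0.5; EVI = G (NIR - red) /
#' (NIR + C1 red - C2 blue + 1) with G = 2.5, C1 = 6, C2 = 7.5.
#' Observations with a zero denominator get a missing index value.
#'
#' @param scene Tibble with at least `blue`, `red`, `nir` columns.
#' @return The input with `ndvi`, `savi`, `evi` columns appended.
#' @examples
#' vegetation_indices(tibble::tibble(blue = 0.05, red = 0.1, nir = 0.5))
#' @export
vegetation_indices <- function(scene) {
  miss <- setdiff(c("blue", "red", "nir"), names(scene))
  if (length(miss) > 0) {
    abort(sprintf("missing required band(s): %s", paste(miss, collapse = ", ")))
  }
  safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  L <- 0.5
  dplyr::mutate(
    scene,
    ndvi = safe_div(.data$nir - .data$red, .data$nir + .data$red),
    savi = safe_div((1 + L) * (.data$nir - .data$red), .data$nir + .data$red + L),
    evi = safe_div(2.5 * (.data$nir - .data$red),
                   .data$nir + 6 * .data$red - 7.5 * .data$blue + 1)
  )
}

#' Retain cloud-free observations
#'
#' Keeps only observations flagged valid, preserving order. Per-pixel valid
#' counts are recomputed downstream by [epoch_metrics()].
#'
#' @param scene_stack Scene tibble with a logical `valid` column.
#' @return The valid-only subset.
#' @export
cloud_filter <- function(scene_stack) {
  if (!"valid" %in% names(scene_stack)) {
    abort("scene_stack must carry a logical `valid` flag")
  }
  dplyr::filter(scene_stack, .data$valid)
}

#' Harmonize a secondary sensor onto the primary radiometric scale
#'
#' Applies the band-wise linear transform `gain * x + bias` to every
#' observation from a non-primary sensor, then returns the stack in
#' chronological order within pixel. Every non-primary sensor present in the
#' stack must have coefficients for every band.
#'
#' @param scene_stack Scene tibble with `sensor` and band columns.
#' @param coefficients Tibble with columns `sensor`, `band`, `gain`, `bias`.
#' @param primary Character vector of primary sensor names (left untouched).
#' @return The harmonized stack, ordered by pixel, epoch, date.
#' @export
harmonize_sensors <- function(scene_stack, coefficients, primary = c("TM", "ETM")) {
  secondary <- setdiff(unique(scene_stack$sensor), primary)
  bands <- intersect(BAND_NAMES, names(scene_stack))
  for (s in secondary) {
    cs <- coefficients[coefficients$sensor == s, ]
    if (!all(bands %in% cs$band)) {
      abort(sprintf("missing harmonization coefficients for sensor '%s'", s))
    }
    rows <- scene_stack$sensor == s
    for (b in bands) {
      cb <- cs[cs$band == b, ]
      scene_stack[[b]][rows] <- cb$gain[1] * scene_stack[[b]][rows] + cb$bias[1]
    }
  }
  dplyr::arrange(scene_stack, .data$pixel_id, .data$epoch, .data$date)
}

# Internal: full metric vector for one observation series. Percentiles use
# type-7 linear interpolation; windowed means come in two flavours:
#  - "value": mean of observations whose values fall inside [q_lo, q_hi]
#    (inclusive); empty windows give NA.
#  - "rank": mean of the sorted observations at ranks
#    ceiling(1 + (n-1) p_lo) .. ceiling(1 + (n-1) p_hi).
# Variance is the population variance.
series_metrics <- function(v, with_var = FALSE, window = "value") {
  vs <- sort(v)
  n <- length(vs)
  q <- q7_sorted(vs, c(0.10, 0.25, 0.50, 0.75, 0.90))
  wins <- list(c(0.10, 0.25), c(0.25, 0.50), c(0.50, 0.75),
               c(0.75, 0.90), c(0.25, 0.75))
  wm <- vapply(wins, function(w) {
    if (window == "value") {
      b <- q7_sorted(vs, w)
      sel <- vs >= b[1] & vs <= b[2]
      if (any(sel)) mean(vs[sel]) else NA_real_
    } else {
      h <- 1 + (n - 1) * w
      mean(vs[ceiling(h[1]):ceiling(h[2])])
    }
  }, numeric(1))
  out <- c(min = vs[1], max = vs[n],
           p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
           m10_25 = wm[1], m25_50 = wm[2], m50_75 = wm[3], m75_90 = wm[4],
           m25_75 = wm[5])
  if (with_var) out <- c(out, var = pvar(v), range = vs[n] - vs[1])
  out
}

metric_names <- function(with_var) {
  base <- c("min", "max", "p10", "p25", "p50", "p75", "p90",
            "m10_25", "m25_50", "m50_75", "m75_90", "m25_75")
  if (with_var) c(base, "var", "range") else base
}

#' Per-pixel, per-epoch time-series metrics
#'
#' For each pixel x epoch, computes for every reflectance band and vegetation
#' index the minimum, maximum, the 10/25/50/75/90th percentiles, and the mean
#' of observations between selected percentile pairs (10-25, 25-50, 50-75,
#' 75-90, 25-75); vegetation indices additionally get their temporal variance
#' and range. The per-pixel valid-observation count is recorded as `n_obs`.
#'
#' @param valid_stack Cloud-filtered scene tibble (see [cloud_filter()]);
#'   vegetation indices are computed on the fly if absent.
#' @param bands Reflectance band columns to summarise.
#' @param indices Vegetation-index columns to summarise (get var/range too).
#' @param window Windowed-mean convention: `"value"` (observations whose
#'   values lie inside the percentile interval; default) or `"rank"`
#'   (observations at the interpolated rank range).
#' @param grid Optional pixel table (`pixel_id`, `x`, `y`): when supplied,
#'   every pixel x epoch combination appears in the output, with missing
#'   metrics and `n_obs = 0` where no valid observations exist.
#' @param epochs Optional epoch ids for completion (defaults to those
#'   present in the stack).
#' @return A `MetricCube` tibble: `pixel_id`, `x`, `y`, `epoch`, `n_obs`,
#'   and one column per variable-metric pair (e.g. `ndvi_p50`, `red_m25_75`).
#' @export
epoch_metrics <- function(valid_stack, bands = BAND_NAMES,
                          indices = INDEX_NAMES,
                          window = c("value", "rank"),
                          grid = NULL, epochs = NULL) {
  window <- match.arg(window)
  if (length(indices) > 0 && !all(indices %in% names(valid_stack))) {
    valid_stack <- vegetation_indices(valid_stack)
  }
  vars <- c(bands, indices)
  with_var <- stats::setNames(vars %in% indices, vars)

  g <- dplyr::group_by(valid_stack, .data$pixel_id, .data$epoch)
  keys <- dplyr::group_keys(g)
  rows <- dplyr::group_rows(g)
  n_grp <- nrow(keys)

  out <- keys
  out$n_obs <- vapply(rows, length, integer(1))
  for (v in vars) {
    col <- valid_stack[[v]]
    nm <- metric_names(with_var[[v]])
    m <- vapply(rows, function(idx) {
      vv <- col[idx]
      vv <- vv[is.finite(vv)]
      if (length(vv) == 0L) {
        rep(NA_real_, length(nm))
      } else {
        series_metrics(vv, with_var = with_var[[v]], window = window)
      }
    }, numeric(length(nm)))
    m <- t(m)
    colnames(m) <- paste(v, nm, sep = "_")
    out <- dplyr::bind_cols(out, tibble::as_tibble(m))
  }

  coords <- dplyr::distinct(valid_stack[, c("pixel_id", "x", "y")])
  if (!is.null(grid)) {
    epochs <- epochs %||% sort(unique(valid_stack$epoch))
    full <- tidyr::expand_grid(pixel_id = grid$pixel_id, epoch = epochs)
    out <- dplyr::left_join(full, out, by = c("pixel_id", "epoch"))
    out$n_obs[is.na(out$n_obs)] <- 0L
    coords <- grid[, c("pixel_id", "x", "y")]
  }
  dplyr::left_join(out, coords, by = "pixel_id") %>%
    dplyr::relocate("pixel_id", "x", "y", "epoch", "n_obs")
}
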