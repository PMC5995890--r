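# Per-pixel cover change: OLS slope of fractional cover against epoch
# midpoint year, an optional logit-scale variant, and the cell-level quality
# weighting that feeds the driver model.

# Internal: resolve an epoch->midpoint mapping from a named vector or an
# epoch table with `epoch` and `midpoint` columns.
midpoints_of <- function(epoch_midpoints, epochs_present) {
  if (is.data.frame(epoch_midpoints)) {
    epoch_midpoints <- stats::setNames(epoch_midpoints$midpoint,
                                       epoch_midpoints$epoch)
  }
  mp <- epoch_midpoints[as.character(epochs_present)]
  if (any(is.na(mp))) abort("epoch midpoints missing for some epochs")
  unname(mp)
}

#' Per-pixel cover trend (OLS slope of cover on year)
#'
#' Fits ordinary least squares of fractional cover on epoch midpoint year
#' for each pixel, skipping missing epochs pairwise. Pixels with fewer than
#' two non-missing epochs get missing estimates. The two-sided p-value comes
#' from the usual t statistic on the slope.
#'
#' @param cover_series Tibble: `pixel_id`, `x`, `y`, `epoch`, `cover`.
#' @param epoch_midpoints Named vector (epoch -> midpoint year) or an epoch
#'   table with `epoch` and `midpoint` columns.
#' @return A `TrendMap` tibble: `pixel_id`, `x`, `y`, `slope`
#'   (fraction per year), `intercept`, `p_value`, `n`.
#' @export
pixel_trend <- function(cover_series, epoch_midpoints) {
  wide <- tidyr::pivot_wider(cover_series[, c("pixel_id", "epoch", "cover")],
                             names_from = "epoch", values_from = "cover")
  epochs_present <- as.integer(names(wide)[-1])
  mp <- midpoints_of(epoch_midpoints, epochs_present)
  Y <- as.matrix(wide[, -1])
  tr <- ols_rows(Y, mp)
  coords <- dplyr::distinct(cover_series[, c("pixel_id", "x", "y")])
  out <- dplyr::left_join(tibble::tibble(pixel_id = wide$pixel_id), coords,
                          by = "pixel_id")
  dplyr::bind_cols(out, tr)
}

#' Per-pixel cover trend on the logit scale
#'
#' Clamps cover to `[eps, 1 - eps]`, applies the logit transform
#' `log(p / (1 - p))`, then fits the same per-pixel OLS as [pixel_trend()].
#'
#' @param cover_series As in [pixel_trend()].
#' @param epoch_midpoints As in [pixel_trend()].
#' @param eps Clamping bound in (0, 0.5); default 0.005.
#' @return A `TrendMap` tibble on the logit scale.
#' @export
logit_trend <- function(cover_series, epoch_midpoints, eps = 0.005) {
  if (!(eps > 0 && eps < 0.5)) abort("eps must lie in (0, 0.5)")
  p <- pmin(pmax(cover_series$cover, eps), 1 - eps)
  cover_series$cover <- log(p / (1 - p))
  pixel_trend(cover_series, epoch_midpoints)
}

#' Flag low-quality scores below a quantile threshold
#'
#' Scores strictly below the `exclusion_quantile` quantile (type-7) of all
#' scores are flagged for exclusion. With a degenerate (all-equal) score
#' distribution nothing is excluded.
#'
#' @param scores Numeric quality scores.
#' @param exclusion_quantile Quantile defining the cut (default 0.25).
#' @return Logical vector: `TRUE` = excluded.
#' @export
exclude_low_quality <- function(scores, exclusion_quantile = 0.25) {
  scores < quantile(scores, exclusion_quantile, na.rm = TRUE, type = 7)
}

#' Cell-level quality weights for driver modelling
#'
#' Each pixel gets a quality score: the product of its normalized trend
#' timepoint count and its normalized valid-observation count (each scaled
#' by the grid maximum). The per-cell score is the mean pixel quality of
#' unmasked pixels times the unmasked fraction of the cell; fully masked
#' cells score 0. Cells whose score falls below the `exclusion_quantile`
#' quantile of all cell scores are flagged excluded; the remaining scores
#' serve as observation weights in the driver model.
#'
#' @param quality_layers Tibble: `x`, `y`, `n_timepoints` (epochs available
#'   for the trend regression), `n_obs` (total valid observations used for
#'   metrics), `masked` (logical).
#' @param cell_size Coarse-cell edge length in pixels.
#' @param exclusion_quantile Quantile defining exclusion (default 0.25).
#' @return A `QualityWeights` tibble: `cell`, `cx`, `cy`, `n_pixels`,
#'   `n_unmasked`, `score`, `weight`, `excluded`.
#' @export
quality_weights <- function(quality_layers, cell_size,
                            exclusion_quantile = 0.25) {
  if (nrow(quality_layers) == 0) abort("empty cell set")
  max_tp <- max(quality_layers$n_timepoints, 1)
  max_obs <- max(quality_layers$n_obs, 1)
  q <- quality_layers %>%
    dplyr::mutate(
      cx = ceiling(.data$x / cell_size),
      cy = ceiling(.data$y / cell_size),
      pixel_quality = (.data$n_timepoints / max_tp) * (.data$n_obs / max_obs)
    )
  cells <- q %>%
    dplyr::group_by(.data$cx, .data$cy) %>%
    dplyr::summarise(
      n_pixels = dplyr::n(),
      n_unmasked = sum(!.data$masked),
      score = ifelse(
        sum(!.data$masked) == 0, 0,
        mean(.data$pixel_quality[!.data$masked]) *
          (sum(!.data$masked) / dplyr::n())
      ),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      cell = dplyr::row_number(),
      weight = .data$score,
      excluded = exclude_low_quality(.data$score, exclusion_quantile) |
        .data$n_unmasked == 0
    ) %>%
    dplyr::relocate("cell")
  cells
}
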