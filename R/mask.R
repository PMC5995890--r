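# Analysis mask: exclude closed forest (>40% cover by tall trees), forestry
# (pixels that both lost and gained woody cover over the reference period)
# and non-natural landcover, before any cover or trend estimation.

#' Build the combined analysis mask
#'
#' A pixel is excluded iff it is closed forest (tree cover strictly greater
#' than `forest_cover_threshold` AND tall class), forestry (loss AND gain
#' flags both set), or its landcover class is in `excluded_classes`.
#'
#' @param mask_inputs Tibble with columns `x`, `y`, `tree_cover` (unit
#'   fraction), `tall` (logical: trees taller than the height cutoff),
#'   `loss`, `gain` (logical change flags) and `landcover` (categorical).
#' @param forest_cover_threshold Strict lower bound for closed forest
#'   (default 0.40).
#' @param excluded_classes Character vector of landcover classes to exclude
#'   (e.g. urban, water, wetland, cropland, cropland mosaic).
#' @param landcover_levels Optional vector of known landcover codes; when
#'   omitted, the codes present in `mask_inputs` are taken as known. An
#'   excluded class outside the known set is an error.
#' @return An `analysis_mask` tibble: `x`, `y`, per-reason logicals
#'   `forest`, `forestry`, `landcover_excluded`, and `excluded`; a
#'   per-reason count summary (with overlaps) is attached as attribute
#'   `"summary"` and shown by [mask_summary()].
#' @examples
#' inp <- tibble::tibble(x = 1:2, y = 1, tree_cover = c(0.45, 0.2),
#'                       tall = c(TRUE, TRUE), loss = FALSE, gain = FALSE,
#'                       landcover = "savanna")
#' build_mask(inp, excluded_classes = "savanna"[0])$excluded
#' @export
build_mask <- function(mask_inputs, forest_cover_threshold = 0.40,
                       excluded_classes = character(),
                       landcover_levels = NULL) {
  need <- c("x", "y", "tree_cover", "tall", "loss", "gain", "landcover")
  miss <- setdiff(need, names(mask_inputs))
  if (length(miss) > 0) {
    abort(sprintf("mask_inputs is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(mask_inputs$tree_cover < 0 | mask_inputs$tree_cover > 1, na.rm = TRUE)) {
    abort("tree_cover must be a unit fraction in [0, 1]")
  }
  known <- landcover_levels %||% unique(mask_inputs$landcover)
  bad <- setdiff(excluded_classes, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown landcover code(s) in excluded set: %s",
                  paste(bad, collapse = ", ")))
  }
  out <- mask_inputs %>%
    dplyr::mutate(
      forest = .data$tree_cover > forest_cover_threshold & .data$tall,
      forestry = .data$loss & .data$gain,
      landcover_excluded = .data$landcover %in% excluded_classes,
      excluded = .data$forest | .data$forestry | .data$landcover_excluded
    ) %>%
    dplyr::select("x", "y", "forest", "forestry", "landcover_excluded", "excluded")
  summary <- list(
    n_pixels = nrow(out),
    n_excluded = sum(out$excluded),
    n_forest = sum(out$forest),
    n_forestry = sum(out$forestry),
    n_landcover = sum(out$landcover_excluded),
    n_multiple_reasons = sum(out$forest + out$forestry + out$landcover_excluded > 1)
  )
  attr(out, "summary") <- summary
  class(out) <- c("analysis_mask", class(out))
  out
}

#' Per-reason exclusion counts of an analysis mask
#'
#' @param mask An `analysis_mask` from [build_mask()].
#' @return A one-row tibble of counts (total, per reason, multi-reason
#'   overlap).
#' @export
mask_summary <- function(mask) {
  s <- attr(mask, "summary")
  if (is.null(s)) abort("not an analysis_mask: no summary attribute")
  tibble::as_tibble(s)
}

#' Apply an analysis mask to a gridded layer
#'
#' Sets excluded pixels' value columns to `NA`; valid pixels are unchanged.
#' Idempotent: applying the mask twice equals applying it once.
#'
#' @param raster Tibble with `x`, `y` and one or more value columns.
#' @param analysis_mask An `analysis_mask` on the same grid.
#' @param value_cols Columns to blank; default: all non-coordinate columns.
#' @return The input tibble with excluded pixels set to missing.
#' @export
apply_mask <- function(raster, analysis_mask, value_cols = NULL) {
  check_same_grid(raster, analysis_mask, "raster and mask")
  value_cols <- value_cols %||% setdiff(names(raster), c("x", "y", "pixel_id"))
  m <- dplyr::left_join(raster[, c("x", "y")],
                        analysis_mask[, c("x", "y", "excluded")],
                        by = c("x", "y"))
  for (cl in value_cols) {
    raster[[cl]][m$excluded] <- NA
  }
  raster
}
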