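#' @importFrom rlang .data abort warn :=
#' @importFrom stats quantile pt sd var cor predict setNames rnorm runif
#' @importFrom dplyr %>%
NULL

# Internal: long (x, y, value) tibble -> matrix with [y, x] indexing.
grid_to_matrix <- function(df, value, nx = max(df$x), ny = max(df$y)) {
  m <- matrix(NA_real_, nrow = ny, ncol = nx)
  m[cbind(df$y, df$x)] <- df[[value]]
  m
}

matrix_to_grid <- function(m, value = "value") {
  out <- tibble::tibble(
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    y = rep(seq_len(nrow(m)), times = ncol(m))
  )
  out[[value]] <- as.vector(m)
  out
}

# Internal: check two gridded tibbles index the same pixel set.
check_same_grid <- function(a, b, what = "rasters") {
  ka <- paste(a$x, a$y)
  kb <- paste(b$x, b$y)
  if (length(ka) != length(kb) || !setequal(ka, kb)) {
    abort(sprintf("grid mismatch: %s are not on the same pixel grid", what))
  }
  invisible(TRUE)
}

#' Ordinary-least-squares slope, intercept and p-value
#'
#' Closed-form simple linear regression of `y` on `x`, the workhorse behind
#' per-pixel cover trends and covariate trend layers. Missing values are
#' dropped pairwise; fewer than two complete pairs (or zero variance in `x`)
#' yields `NA` estimates.
#'
#' @param x Numeric predictor (e.g. decimal year).
#' @param y Numeric response.
#' @return A list with `slope`, `intercept`, `p_value` and `n`.
#' @examples
#' ols_line(c(1988.5, 1993.5, 1998.5), c(0.2, 0.3, 0.4))$slope
#' @export
ols_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_, n = n))
  }
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_, n = n))
  }
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  p <- NA_real_
  if (n > 2L) {
    rss <- sum((y - intercept - slope * x)^2)
    se <- sqrt(rss / (n - 2L) / sxx)
    p <- if (se == 0) {
      if (slope == 0) 1 else 0
    } else {
      2 * pt(abs(slope / se), df = n - 2L, lower.tail = FALSE)
    }
  }
  list(slope = slope, intercept = intercept, p_value = p, n = n)
}

# Internal: row-wise OLS of Y (units x timepoints, NAs allowed) on x.
# Returns a tibble of slope / intercept / p_value / n per row. Vectorised
# version of ols_line() used for whole-raster trend fields.
ols_rows <- function(Y, x) {
  stopifnot(ncol(Y) == length(x))
  V <- is.finite(Y)
  X <- matrix(x, nrow = nrow(Y), ncol = length(x), byrow = TRUE)
  X[!V] <- NA_real_
  n <- rowSums(V)
  xb <- rowMeans(X, na.rm = TRUE)
  yb <- rowMeans(Y, na.rm = TRUE)
  Xc <- X - xb
  Yc <- Y - yb
  sxx <- rowSums(Xc * Xc, na.rm = TRUE)
  sxy <- rowSums(Xc * Yc, na.rm = TRUE)
  slope <- ifelse(n >= 2L & sxx > 0, sxy / sxx, NA_real_)
  intercept <- yb - slope * xb
  fit <- intercept + slope * X
  rss <- rowSums((Y - fit)^2, na.rm = TRUE)
  se2 <- rss / pmax(n - 2L, 1L) / sxx
  tstat <- abs(slope) / sqrt(se2)
  p <- 2 * pt(tstat, df = pmax(n - 2L, 1L), lower.tail = FALSE)
  p[se2 == 0 & !is.na(slope)] <- ifelse(slope[se2 == 0 & !is.na(slope)] == 0, 1, 0)
  p[n <= 2L] <- NA_real_
  tibble::tibble(slope = slope, intercept = intercept, p_value = p, n = as.integer(n))
}

# Internal: type-7 quantile (linear interpolation between closest ranks) on a
# sorted vector. h = 1 + (n - 1) p. Kept separate from stats::quantile so the
# test suite can use the latter as an independent oracle.
q7_sorted <- function(vs, p) {
  n <- length(vs)
  if (n == 1L) return(rep(vs, length(p)))
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  vs[lo] + (h - lo) * (vs[hi] - vs[lo])
}

# Internal: population variance.
pvar <- function(v) {
  if (length(v) == 0L) return(NA_real_)
  mean((v - mean(v))^2)
}

# Internal: smooth a white-noise matrix with a separable Gaussian kernel,
# edge-renormalised, then rescale to zero mean / unit sd across the grid.
# Used to build spatially autocorrelated covariate fields.
gaussian_field <- function(ny, nx, sigma) {
  z <- matrix(rnorm(ny * nx), nrow = ny)
  if (sigma <= 0) return(z)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  smooth_axis <- function(m, kern) {
    nr <- nrow(m)
    out <- matrix(0, nrow = nr, ncol = ncol(m))
    wsum <- numeric(nr)
    r <- (length(kern) - 1L) / 2L
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      src <- seq_len(nr) + off
      keep <- src >= 1L & src <= nr
      out[keep, ] <- out[keep, ] + kern[j] * m[src[keep], ]
      wsum[keep] <- wsum[keep] + kern[j]
    }
    out / wsum
  }
  z <- smooth_axis(z, k)
  z <- t(smooth_axis(t(z), k))
  sdz <- sd(as.vector(z))
  if (sdz > 0) z <- (z - mean(z)) / sdz
  z
}

# Internal: deterministic sub-seed derived from a base seed, kept < 2^31.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) * 7919L
}

clip01 <- function(v) pmin(pmax(v, 0), 1)
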