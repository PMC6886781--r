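#' Median-filter an image channel by channel
#'
#' Replaces every pixel (voxel) by the median of its square (2D input) or
#' cubic (3D input) neighborhood, independently per channel, with reflect
#' padding at the borders.  Applied before clustering so that spatially
#' isolated noise pixels adopt the spectral signature of their surroundings;
#' the caller keeps the unfiltered image because output intensities are
#' always taken from the raw data.
#'
#' @param image a [multichannel_image].
#' @param window odd window edge length, 3 or 5 (giving 3x3/5x5 neighborhoods
#'   on single planes and 3x3x3/5x5x5 on z-stacks).
#' @return a filtered [multichannel_image] of identical shape.
#' @export
median_filter <- function(image, window = 3L) {
  stopifnot(inherits(image, "multichannel_image"))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window %% 2L == 0L || window <= 0L)
    stop("'window' must be an odd positive integer")
  if (!window %in% c(3L, 5L))
    stop("'window' must be 3 or 5")
  sd <- spatial_dim(image)
  C <- n_channels(image)
  out <- image$data
  npix <- prod(sd)
  for (c in seq_len(C)) {
    idx <- (c - 1L) * npix + seq_len(npix)
    out[idx] <- .median_filter_cpp(image$data[idx], sd, window)
  }
  multichannel_image(out, image$channel_names)
}

#' Scale each pixel's channel vector to intensity ratios
#'
#' Divides a pixel's intensity in each channel by that pixel's summed
#' intensity across all channels, so pixels with the same spectral shape but
#' different net brightness (e.g. across imaging depths) map to the same
#' feature vector.  Pixels whose across-channel sum is zero are left as the
#' zero vector.  Not always desirable: pixels with equal ratios but different
#' raw intensities may be genuinely different structures, so this transform
#' is off by default in [lumos()].
#'
#' @param image a [multichannel_image].
#' @return a numeric array of the same shape as `image$data`, rows of
#'   per-pixel channel values summing to 1 (or all zero).
#' @export
scale_pixel_ratios <- function(image) {
  stopifnot(inherits(image, "multichannel_image"))
  m <- as_feature_matrix(image)
  s <- rowSums(m)
  nz <- s > 0
  m[nz, ] <- m[nz, , drop = FALSE] / s[nz]
  array(m, dim = dim(image$data))
}

#' Z-score features per channel
#'
#' Centers and scales every channel by its overall mean and population
#' standard deviation over all pixels, so no channel dominates the clustering
#' distance by brightness alone.  Channels with zero variance (dead
#' detectors) map to all-zero rather than dividing by zero.
#'
#' @param x a [multichannel_image] or a numeric array with the channel axis
#'   last (e.g. the output of [scale_pixel_ratios()]).
#' @return a list with `features` (array, same shape) and `stats` (list with
#'   per-channel `mu` and `sigma`).
#' @export
zscore_normalize <- function(x) {
  data <- if (inherits(x, "multichannel_image")) x$data else x
  stopifnot(is.array(data))
  C <- dim(data)[length(dim(data))]
  m <- matrix(data, ncol = C)
  mu <- colMeans(m)
  n <- nrow(m)
  sigma <- sqrt(colMeans(m^2) - mu^2)          # population sd (ddof = 0)
  sigma[sigma < 0] <- 0                        # guard tiny negative rounding
  for (c in seq_len(C)) {
    m[, c] <- if (sigma[c] > 0) (m[, c] - mu[c]) / sigma[c] else 0
  }
  list(features = array(m, dim = dim(data)),
       stats = list(mu = mu, sigma = sigma))
}

#' Build the clustering feature space from a raw image
#'
#' The preprocessing pipeline behind [lumos()]: median filter on the raw
#' intensities, then optional per-pixel ratio scaling, then per-channel
#' z-scoring.  The raw image itself is never modified; output reconstruction
#' always reads intensities from it.
#'
#' @param image a [multichannel_image].
#' @param median_window 3, 5, or 0 to skip the median filter.
#' @param ratio_scale logical; apply per-pixel ratio scaling before z-scoring.
#' @return a list with `features` (pixels x channels matrix), `stats`
#'   (z-score normalization statistics) and `provenance` (record of the
#'   applied transforms).
#' @export
preprocess_features <- function(image, median_window = 3L, ratio_scale = FALSE) {
  stopifnot(inherits(image, "multichannel_image"))
  filtered <- if (median_window %in% c(3L, 5L)) median_filter(image, median_window)
              else if (identical(as.integer(median_window), 0L)) image
              else stop("'median_window' must be 3, 5 or 0")
  x <- if (ratio_scale) scale_pixel_ratios(filtered) else filtered$data
  z <- zscore_normalize(x)
  list(features = matrix(z$features, ncol = n_channels(image)),
       stats = z$stats,
       provenance = list(median_window = as.integer(median_window),
                         ratio_scaled = isTRUE(ratio_scale),
                         zscored = TRUE))
}
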