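#' Multichannel fluorescence image container
#'
#' Wraps a nonnegative intensity array recorded in `C` detection channels over
#' a 2D (`Y x X`) or 3D (`Y x X x Z`) field of view.  The channel axis is
#' always last, so `matrix(x$data, ncol = n_channels(x))` yields the
#' pixels-by-channels feature matrix that clustering operates on.
#'
#' @param data numeric array: `Y x X x C` for a single plane or
#'   `Y x X x Z x C` for a z-stack.  A plain matrix is treated as a
#'   single-channel plane.  All values must be finite and `>= 0`.
#' @param channel_names optional character vector of length `C`.
#' @return an object of class `multichannel_image` with elements `data`
#'   (the array) and `channel_names`.
#' @examples
#' img <- multichannel_image(array(runif(4 * 5 * 2), c(4, 5, 2)))
#' n_channels(img)
#' @export
multichannel_image <- function(data, channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("'data' must be a Y x X x C or Y x X x Z x C array")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("intensities must be finite numbers")
  if (any(data < 0)) stop("intensities must be nonnegative")
  C <- dim(data)[length(dim(data))]
  if (!is.null(channel_names)) {
    channel_names <- as.character(channel_names)
    if (length(channel_names) != C)
      stop("'channel_names' must have one entry per channel")
  }
  structure(list(data = data, channel_names = channel_names),
            class = "multichannel_image")
}

#' @rdname multichannel_image
#' @param x a `multichannel_image`.
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "multichannel_image"))
  d <- dim(x$data)
  d[length(d)]
}

#' @rdname multichannel_image
#' @export
spatial_dim <- function(x) {
  stopifnot(inherits(x, "multichannel_image"))
  d <- dim(x$data)
  d[-length(d)]
}

# pixels-by-channels matrix view (column-major pixel order)
as_feature_matrix <- function(x) {
  stopifnot(inherits(x, "multichannel_image"))
  matrix(x$data, ncol = n_channels(x))
}

#' Select a subset of channels
#'
#' @param x a `multichannel_image`.
#' @param channels integer vector of 1-based channel indices to keep.
#' @return a `multichannel_image` with the selected channels, in the given order.
#' @export
select_channels <- function(x, channels) {
  stopifnot(inherits(x, "multichannel_image"))
  C <- n_channels(x)
  channels <- as.integer(channels)
  if (any(channels < 1L | channels > C))
    stop("channel indices must lie in 1..", C)
  nd <- length(dim(x$data))
  data <- if (nd == 3L) x$data[, , channels, drop = FALSE]
          else x$data[, , , channels, drop = FALSE]
  multichannel_image(data, x$channel_names[channels])
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- spatial_dim(x)
  cat("<multichannel_image> ", n_channels(x), " channel(s), ",
      paste(d, collapse = " x "),
      if (length(d) == 3L) " (z-stack)" else "", "\n", sep = "")
  cat("  intensity range: [", format(min(x$data)), ", ",
      format(max(x$data)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$data)
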