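#' Read a multichannel TIFF
#'
#' Accepts plain multipage TIFFs (one page per channel, or per channel and
#' slice) and the ImageJ hyperstack dialect, whose `channels=`/`slices=`
#' description tag resolves how pages map to axes.  A JSON sidecar written
#' by [write_image()] (`<path>.meta.json`) takes precedence when present and
#' restores float scaling, channel names and role tags losslessly.  Integer
#' 8/16-bit and float TIFFs are accepted; integer data are read as-is.
#'
#' @param path TIFF file path.
#' @param layout_hint how pages are ordered when metadata does not say:
#'   `"auto"` (use sidecar/ImageJ metadata, else treat every page as a
#'   channel), `"CZYX"` (all slices of channel 1, then channel 2, ...) or
#'   `"ZCYX"` (channels interleaved within each slice — the ImageJ default).
#'   With a hint, `channels` must be given too.
#' @param channels channel count, required with an explicit `layout_hint`.
#' @return a [multichannel_image].
#' @export
read_image <- function(path, layout_hint = c("auto", "CZYX", "ZCYX"),
                       channels = NULL) {
  layout_hint <- match.arg(layout_hint)
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample") %||% 32L
    if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1L]
    # 8/16-bit pages hold integers scaled to [0, 1]; 32-bit pages are float
    if (bits < 32L) round(p * (2^bits - 1)) else p
  })
  if (length(dim(pages[[1]])) == 3L) {
    # single page with a sample axis: samples are the channels
    stopifnot(length(pages) == 1L)
    return(multichannel_image(pages[[1]]))
  }
  n_pages <- length(pages)
  meta_path <- paste0(path, ".meta.json")
  scale <- 1
  channel_names <- NULL
  C <- Z <- NULL
  order_tag <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    scale <- meta$scale %||% 1
    C <- meta$channels
    Z <- meta$slices %||% 1L
    order_tag <- meta$page_order %||% "ZCYX"
    if (!is.null(meta$channel_names) && !all(is.na(meta$channel_names)))
      channel_names <- meta$channel_names
  } else {
    desc <- attr(pages[[1]], "description")
    if (!is.null(desc) && grepl("channels=", desc)) {
      C <- as.integer(sub(".*channels=([0-9]+).*", "\\1", desc))
      Z <- if (grepl("slices=", desc))
             as.integer(sub(".*slices=([0-9]+).*", "\\1", desc)) else 1L
      order_tag <- "ZCYX"  # ImageJ writes channel-fastest page order
    }
  }
  if (is.null(C)) {
    if (layout_hint == "auto") {
      C <- n_pages
      Z <- 1L
      order_tag <- "ZCYX"
    } else {
      if (is.null(channels))
        stop("cannot resolve the axis layout of ", path,
             ": pass 'channels' together with layout_hint")
      C <- as.integer(channels)
      Z <- n_pages %/% C
      order_tag <- layout_hint
    }
  }
  if (C * Z != n_pages)
    stop("page count ", n_pages, " does not factor into ", C,
         " channel(s) x ", Z, " slice(s)")
  yx <- dim(pages[[1]])
  page_at <- function(z, c) {
    if (order_tag == "CZYX") pages[[(c - 1L) * Z + z]]
    else pages[[(z - 1L) * C + c]]
  }
  data <- if (Z == 1L) {
    arr <- array(0, c(yx, C))
    for (c in seq_len(C)) arr[, , c] <- page_at(1L, c)
    arr
  } else {
    arr <- array(0, c(yx, Z, C))
    for (c in seq_len(C)) for (z in seq_len(Z)) arr[, , z, c] <- page_at(z, c)
    arr
  }
  multichannel_image(data * scale, channel_names = channel_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multichannel image (or unmixing output) to TIFF
#'
#' Writes one page per channel (and slice; channels vary fastest, the ImageJ
#' hyperstack page order) plus a JSON sidecar `<path>.meta.json` recording
#' the axis layout, any float scaling, channel names and channel role tags,
#' so [read_image()] round-trips the values.  Whole-number data up to 65535
#' are stored as 16-bit integers (lossless); other data as 32-bit float,
#' divided by a power-of-two scale so the stored values lie in [0, 1]
#' (round-trip exact to 32-bit float precision).
#'
#' @param image a [multichannel_image] or the `unmixed_image` held by a
#'   [lumos()] fit.
#' @param path output TIFF path.
#' @param remove_background for an `unmixed_image`, drop the background
#'   channel before writing.
#' @param roles optional per-channel role tags to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, remove_background = FALSE, roles = NULL) {
  if (inherits(image, "unmixed_image")) {
    roles <- roles %||% image$roles
    data <- image$data
    if (remove_background && !is.na(image$background_index)) {
      keep <- setdiff(seq_len(dim(data)[length(dim(data))]),
                      image$background_index)
      data <- if (length(dim(data)) == 3L) data[, , keep, drop = FALSE]
              else data[, , , keep, drop = FALSE]
      roles <- roles[keep]
    }
    image <- multichannel_image(data)
  }
  stopifnot(inherits(image, "multichannel_image"))
  d <- dim(image$data)
  nd <- length(d)
  C <- d[nd]
  Z <- if (nd == 4L) d[3] else 1L
  mx <- max(image$data)
  integral <- mx <= 65535 && all(image$data == round(image$data))
  if (integral) {
    bits <- 16L
    scale <- 65535
  } else {
    bits <- 32L
    scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  }
  pages <- vector("list", C * Z)
  for (z in seq_len(Z)) for (c in seq_len(C)) {
    pg <- if (nd == 3L) image$data[, , c] else image$data[, , z, c]
    pages[[(z - 1L) * C + c]] <- pg / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- list(format_version = 1L,
               dtype = if (integral) "uint16" else "float32",
               scale = if (integral) 1 else scale,
               page_order = "ZCYX", channels = C, slices = Z,
               channel_names = image$channel_names %||% NA,
               roles = roles %||% NA)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Write the spectral-signature table of a fit to CSV
#'
#' One row per saved output channel: the cluster's relative intensity in
#' each input channel plus a `role` column.
#'
#' @param fit a [lumos()] fit (or a `spectral_signatures` object together
#'   with `roles`).
#' @param path output CSV path.
#' @param remove_background drop the background row.
#' @param roles per-row roles when `fit` is a bare signature table.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(fit, path, remove_background = FALSE,
                             roles = NULL) {
  if (inherits(fit, "lumos")) {
    sig <- fit$signatures$matrix
    roles <- fit$roles
  } else {
    sig <- if (inherits(fit, "spectral_signatures")) fit$matrix else as.matrix(fit)
    if (is.null(roles)) roles <- rep(NA_character_, nrow(sig))
  }
  df <- data.frame(role = roles, sig, check.names = FALSE)
  if (remove_background) df <- df[df$role != "background", , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Record and restore run configurations
#'
#' A `run_config` captures every option of an unmixing run (clustering
#' options, preprocessing flags, channel selection, paths) and is written as
#' JSON next to each output so runs can be reproduced exactly.  Serialization
#' round-trips to an identical object.
#'
#' @param n_fluorophores,extra_clusters,channels,median_window,ratio_scale
#'   see [lumos()].
#' @param replicates,max_iter,seed see [lumos()].
#' @param remove_background drop the background channel when saving.
#' @param input,output optional file paths.
#' @return a `run_config` list.
#' @export
run_config <- function(n_fluorophores, extra_clusters = 0L, channels = NA,
                       median_window = 3L, ratio_scale = FALSE,
                       replicates = 10L, max_iter = 100L, seed = NA,
                       remove_background = FALSE, input = NA, output = NA) {
  structure(list(n_fluorophores = as.integer(n_fluorophores),
                 extra_clusters = as.integer(extra_clusters),
                 channels = if (all(is.na(channels))) NA else as.integer(channels),
                 median_window = as.integer(median_window),
                 ratio_scale = isTRUE(ratio_scale),
                 replicates = as.integer(replicates),
                 max_iter = as.integer(max_iter),
                 seed = if (all(is.na(seed))) NA_integer_ else as.integer(seed),
                 remove_background = isTRUE(remove_background),
                 input = as.character(input), output = as.character(output)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, lapply(x, function(v) if (is.null(v)) NA else v))
}
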