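#' Configuration of a synthetic benchmark scene
#'
#' Collects every knob of the synthetic image generator.  The defaults are
#' the benchmark's reference conditions: a 512 x 512 four-channel image of 8
#' fluorophores whose Weibull emission spectra (shape 1.7, scale 100 nm) peak
#' at evenly spaced wavelengths across 420-685 nm, a minor strip one fifth
#' the area of the major strips, SNR 10, per-pixel spectral jitter of 10 nm,
#' Gaussian background of mean 2 and sd 1 on empty pixels, Poisson shot noise
#' on signal pixels, 0.5 px Gaussian blur and a final 3 x 3 median filter.
#'
#' SNR is operationalized through the shot noise: the expected intensity of a
#' fluorophore's brightest channel is set to `snr^2`, so Poisson noise alone
#' gives signal / sqrt(signal) = snr there.
#'
#' @param n_fluorophores number of fluorophore strips.
#' @param image_size spatial size in pixels, `c(rows, cols)`.
#' @param cluster_size_ratio area of the minor (furthest-red) strip divided
#'   by the area of a major strip, in (0, 1].
#' @param snr signal-to-noise ratio of the brightest channel.
#' @param jitter_sd per-pixel emission-peak jitter sd in nm.
#' @param background_mean,background_sd Gaussian background on empty pixels.
#' @param blur_sd Gaussian blur sd in px.
#' @param postfilter_window median window applied after blur (0 to skip).
#' @param peak_range wavelength range the peaks are spread over, nm.
#' @param a,b Weibull shape and scale of every emission spectrum.
#' @param bands a [detector_bank()].
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_fluorophores = 8L, image_size = c(512L, 512L),
                              cluster_size_ratio = 0.2, snr = 10,
                              jitter_sd = 10, background_mean = 2,
                              background_sd = 1, blur_sd = 0.5,
                              postfilter_window = 3L,
                              peak_range = c(420, 685), a = 1.7, b = 100,
                              bands = detector_bank()) {
  n_fluorophores <- as.integer(n_fluorophores)
  image_size <- as.integer(image_size)
  stopifnot(n_fluorophores >= 1L, length(image_size) == 2L,
            all(image_size >= 1L),
            cluster_size_ratio > 0, cluster_size_ratio <= 1,
            snr > 0, jitter_sd >= 0, background_sd >= 0, blur_sd >= 0,
            length(peak_range) == 2L, peak_range[1] < peak_range[2],
            a > 1, b > 0)
  structure(list(n_fluorophores = n_fluorophores, image_size = image_size,
                 cluster_size_ratio = cluster_size_ratio, snr = snr,
                 jitter_sd = jitter_sd, background_mean = background_mean,
                 background_sd = background_sd, blur_sd = blur_sd,
                 postfilter_window = as.integer(postfilter_window),
                 peak_range = as.numeric(peak_range), a = a, b = b,
                 bands = bands),
            class = "simulation_config")
}

#' Lay out the ground-truth grid scene
#'
#' Each successive fluorophore occupies an alternating vertical or horizontal
#' strip on a background canvas: fluorophore 1 a vertical strip at the left,
#' fluorophore 2 a horizontal strip at the top, and so on, interleaved so the
#' strips form a grid.  Major strips span the full image and are
#' `floor(min(image_size) / 2 / n)` pixels wide; the minor strip — the
#' furthest-red fluorophore `n` — keeps that width but its length is
#' `round(cluster_size_ratio * span)`, so minor area / major area equals the
#' requested ratio.  Strips are painted in fluorophore order with later
#' strips taking precedence at crossings, which keeps the minor strip's area
#' exact.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_scene`: list with `labels` (integer matrix, 0 =
#'   background, 1..n = fluorophores), `spectra` (list of
#'   [weibull_spectrum()] models in peak order) and `config`.
#' @export
generate_grid_scene <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_fluorophores
  size <- config$image_size
  w <- floor(min(size) / 2 / n)
  if (w < 1L) stop("image too small for ", n, " strips")
  labels <- matrix(0L, nrow = size[1], ncol = size[2])
  for (i in seq_len(n)) {
    vertical <- i %% 2L == 1L
    slot <- if (vertical) (i - 1L) %/% 2L else (i - 2L) %/% 2L
    band <- if (vertical) (2L * slot) * w + seq_len(w)
            else (2L * slot + 1L) * w + seq_len(w)
    span <- if (vertical) size[1] else size[2]
    len <- if (i == n) round(config$cluster_size_ratio * span) else span
    if (len < 1L)
      stop("cluster_size_ratio ", config$cluster_size_ratio,
           " gives the minor strip zero pixels")
    if (max(band) > (if (vertical) size[2] else size[1]))
      stop("strips do not fit inside the image; enlarge it or reduce n")
    ## minor strip anchored at the far end of its span, clear of the blocks
    ## the major strips occupy, so a short minor strip sits on background
    pos <- if (len == span) seq_len(len) else span - len + seq_len(len)
    if (vertical) labels[pos, band] <- i
    else labels[band, pos] <- i
  }
  peaks <- evenly_spaced_peaks(n, config$peak_range[1], config$peak_range[2])
  spectra <- lapply(peaks, weibull_spectrum, a = config$a, b = config$b)
  structure(list(labels = labels, spectra = spectra, config = config),
            class = "synthetic_scene")
}

#' Render a synthetic scene into a noisy multichannel image
#'
#' Every signal pixel gets its own emission spectrum — the fluorophore's
#' spectrum shifted by a Normal(0, `jitter_sd`) wavelength draw — which is
#' integrated over the detector bandpasses and scaled so the ideal spectrum's
#' brightest channel has expectation `snr^2`; Poisson shot noise is then
#' drawn per channel.  Empty pixels receive Gaussian background (mean 2,
#' sd 1 by default) truncated at 0.  Finally each channel is blurred
#' (Gaussian, `blur_sd` px) and median-filtered (3 x 3 by default) to mimic
#' diffusion during acquisition, and clipped at 0.
#'
#' @param scene a `synthetic_scene` from [generate_grid_scene()].
#' @param seed optional integer seed making the render reproducible.
#' @return list with `image` (a [multichannel_image]) and `scene`.
#' @export
render_scene <- function(scene, seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- scene$config
  lab <- scene$labels
  C <- nrow(cfg$bands)
  n_pix <- length(lab)
  m <- matrix(0, nrow = n_pix, ncol = C)
  for (f in seq_len(cfg$n_fluorophores)) {
    pix <- which(lab == f)
    if (!length(pix)) next
    sp <- scene$spectra[[f]]
    amp <- cfg$snr^2 / max(channel_response(sp, cfg$bands))
    shift <- rnorm(length(pix), 0, cfg$jitter_sd)
    for (j in seq_len(C)) {
      lo <- pmax(cfg$bands[j, "low"] - sp$c - shift, 0)
      hi <- pmax(cfg$bands[j, "high"] - sp$c - shift, 0)
      mu <- amp * (pweibull(hi, cfg$a, cfg$b) - pweibull(lo, cfg$a, cfg$b))
      m[pix, j] <- rpois(length(pix), mu)
    }
  }
  bg <- which(lab == 0L)
  if (length(bg))
    m[bg, ] <- pmax(matrix(rnorm(length(bg) * C, cfg$background_mean,
                                 cfg$background_sd),
                           ncol = C), 0)
  out <- array(0, dim = c(dim(lab), C))
  for (j in seq_len(C)) {
    ch <- matrix(m[, j], nrow = nrow(lab))
    if (cfg$blur_sd > 0) ch <- EBImage::gblur(ch, sigma = cfg$blur_sd)
    if (cfg$postfilter_window >= 3L)
      ch <- matrix(.median_filter_cpp(as.numeric(ch), dim(ch),
                                      cfg$postfilter_window),
                   nrow = nrow(lab))
    out[, , j] <- pmax(ch, 0)
  }
  list(image = multichannel_image(out, channel_names = rownames(cfg$bands)),
       scene = scene)
}

#' Generate and render a scene in one call
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return list with `image`, `scene`.
#' @export
simulate_scene <- function(config = simulation_config(), seed = NULL) {
  render_scene(generate_grid_scene(config), seed = seed)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_scene> ", cfg$n_fluorophores, " fluorophore strip(s), ",
      paste(cfg$image_size, collapse = " x "), " px\n", sep = "")
  cat("  cluster size ratio ", cfg$cluster_size_ratio, ", SNR ", cfg$snr,
      ", jitter sd ", cfg$jitter_sd, " nm\n", sep = "")
  invisible(x)
}
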