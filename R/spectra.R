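#' Model fluorophore emission as a shifted Weibull spectrum
#'
#' Real fluorochromes emit over an asymmetric band with a long tail toward
#' longer wavelengths; a Weibull density with shape `a` and scale `b`,
#' shifted along the wavelength axis, captures that shape.  The location
#' shift `c` is chosen so the density's mode sits at the requested peak
#' wavelength: `c = peak - b * ((a - 1) / a)^(1 / a)`.
#'
#' @param peak desired emission-peak (mode) wavelength in nm.
#' @param a Weibull shape, must be `> 1` so an interior mode exists
#'   (default 1.7).
#' @param b Weibull scale in nm (default 100).
#' @return a `spectrum_model`: list with `a`, `b`, `c` (location shift, nm)
#'   and `peak`.
#' @examples
#' sp <- weibull_spectrum(500)
#' sp$c  # about 440.6 nm
#' @export
weibull_spectrum <- function(peak, a = 1.7, b = 100) {
  if (a <= 1) stop("'a' must be > 1 for the spectrum to have a peak")
  if (b <= 0) stop("'b' must be positive")
  structure(list(a = a, b = b, c = peak - b * ((a - 1) / a)^(1 / a),
                 peak = peak),
            class = "spectrum_model")
}

#' Emission density of a spectrum model
#'
#' Unit-area relative intensity at the given wavelengths; zero below the
#' location shift `c`.
#'
#' @param spectrum a `spectrum_model`.
#' @param lambda wavelengths in nm.
#' @export
spectrum_density <- function(spectrum, lambda) {
  dweibull(pmax(lambda - spectrum$c, 0), shape = spectrum$a, scale = spectrum$b)
}

#' Detection-channel bandpasses
#'
#' The default four-detector bank of a two-photon system: blue 420-460 nm,
#' green 495-540 nm, red 575-630 nm, far-red 645-685 nm.  Bands need not
#' tile the spectrum.
#'
#' @param low,high numeric vectors of band edges in nm (`low < high`).
#' @param names optional channel names.
#' @return a `detector_bank`: matrix with columns `low` and `high`, one row
#'   per channel.
#' @export
detector_bank <- function(low = c(420, 495, 575, 645),
                          high = c(460, 540, 630, 685),
                          names = c("blue", "green", "red", "far_red")) {
  if (length(low) != length(high) || any(low >= high))
    stop("each band needs low < high")
  bank <- cbind(low = low, high = high)
  rownames(bank) <- if (!is.null(names)) names else paste0("ch", seq_along(low))
  structure(bank, class = c("detector_bank", class(bank)))
}

#' Integrate a spectrum over each detector bandpass
#'
#' The per-channel response is the integral of the unit-area emission density
#' within each band, evaluated in closed form via the Weibull CDF:
#' `exp(-((max(l, c) - c)/b)^a) - exp(-((max(u, c) - c)/b)^a)` for a band
#' `(l, u)`.  This is the ideal spectral signature a fluorophore presents to
#' the detector bank.
#'
#' @param spectrum a `spectrum_model`.
#' @param bank a [detector_bank()].
#' @return nonnegative numeric vector, one response per channel.
#' @export
channel_response <- function(spectrum, bank = detector_bank()) {
  lo <- pmax(bank[, "low"] - spectrum$c, 0)
  hi <- pmax(bank[, "high"] - spectrum$c, 0)
  r <- pweibull(hi, shape = spectrum$a, scale = spectrum$b) -
       pweibull(lo, shape = spectrum$a, scale = spectrum$b)
  names(r) <- rownames(bank)
  r
}

#' Evenly spaced emission peaks across the detection range
#'
#' Peaks are spread uniformly over `[low, high]` (both endpoints included for
#' `n >= 2`); a single fluorophore sits at the midpoint.  The defaults span
#' the default detector bank, 420-685 nm.
#'
#' @param n number of fluorophores.
#' @param low,high range limits in nm.
#' @return numeric vector of `n` peak wavelengths.
#' @export
evenly_spaced_peaks <- function(n, low = 420, high = 685) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (n == 1L) (low + high) / 2 else seq(low, high, length.out = n)
}

#' Percent overlap of two ideal emission spectra
#'
#' Overlap is the integral of the pointwise minimum of the two unit-area
#' densities over a wavelength grid spanning both supports, times 100:
#' the grid divides the axis into bins of width `resolution`, each bin
#' contributes the smaller of the two spectra's probability masses there
#' (computed exactly from the Weibull CDF).  It is symmetric in the two
#' peaks and decreases monotonically with their separation; identical
#' spectra overlap 100%.
#'
#' @param peak1,peak2 emission-peak wavelengths in nm.
#' @param a,b Weibull shape and scale shared by both spectra.
#' @param resolution grid step in nm (default 1).
#' @return overlap in percent.
#' @examples
#' spectra_overlap(500, 537)  # peaks 37 nm apart: about 72%
#' @export
spectra_overlap <- function(peak1, peak2, a = 1.7, b = 100, resolution = 1) {
  s1 <- weibull_spectrum(peak1, a, b)
  s2 <- weibull_spectrum(peak2, a, b)
  lo <- min(s1$c, s2$c)
  hi <- max(s1$c, s2$c) + stats::qweibull(1 - 1e-12, shape = a, scale = b)
  edges <- seq(lo, hi + resolution, by = resolution)
  mass1 <- diff(pweibull(pmax(edges - s1$c, 0), shape = a, scale = b))
  mass2 <- diff(pweibull(pmax(edges - s2$c, 0), shape = a, scale = b))
  100 * sum(pmin(mass1, mass2))
}
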