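#' Spectrum container
#'
#' A spectrum is a strictly increasing wavelength grid (nm) with a
#' non-negative spectral photon flux density (photons s^-1 cm^-2 nm^-1)
#' at each grid point. All filtering, phasor and camera operations in the
#' package consume this container.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param intensity Numeric vector of non-negative spectral intensities,
#'   same length as `wavelength`.
#' @return An object of class `nir_spectrum` with fields `wavelength` and
#'   `intensity`.
#' @examples
#' s <- nir_spectrum(900:1200, rep(1, 301))
#' spectrum_integral(s)
#' @export
nir_spectrum <- function(wavelength, intensity) {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity)) {
    stop("wavelength and intensity must have the same length")
  }
  if (length(wavelength) < 2L) stop("a spectrum needs at least 2 grid points")
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensity must be finite and non-negative")
  }
  structure(list(wavelength = wavelength, intensity = intensity),
            class = "nir_spectrum")
}

#' @export
print.nir_spectrum <- function(x, ...) {
  cat(sprintf("<nir_spectrum: %d points, %.0f-%.0f nm, integral %.4g>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              spectrum_integral(x)))
  invisible(x)
}

#' Trapezoid integral of a spectrum
#'
#' @param spectrum A [nir_spectrum()].
#' @param window Optional [spectral_window()]; when given, integration is
#'   restricted to grid points inside the window.
#' @return Integrated flux (photons s^-1 cm^-2).
#' @export
spectrum_integral <- function(spectrum, window = NULL) {
  w <- spectrum$wavelength
  i <- spectrum$intensity
  if (!is.null(window)) {
    keep <- w >= window$lambda_min & w <= window$lambda_max
    if (sum(keep) < 2L) stop("fewer than 2 grid points inside the window")
    w <- w[keep]; i <- i[keep]
  }
  pracma::trapz(w, i)
}

#' Spectral window
#'
#' The wavelength interval onto which the phasor transform maps one full
#' turn of phase. Must lie inside the supported detection range
#' (InGaAs default 900-1600 nm).
#'
#' @param lambda_min,lambda_max Window edges in nm, `lambda_max > lambda_min`.
#' @param detection_range Length-2 numeric, the supported sensor range (nm).
#' @return An object of class `spectral_window`.
#' @export
spectral_window <- function(lambda_min, lambda_max,
                            detection_range = c(900, 1600)) {
  if (!is.numeric(lambda_min) || !is.numeric(lambda_max) ||
      lambda_max <= lambda_min) {
    stop("lambda_max must exceed lambda_min")
  }
  if (lambda_min < detection_range[1] || lambda_max > detection_range[2]) {
    stop(sprintf("window must lie within the detection range %g-%g nm",
                 detection_range[1], detection_range[2]))
  }
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max),
            class = "spectral_window")
}

#' @export
print.spectral_window <- function(x, ...) {
  cat(sprintf("<spectral_window: %g-%g nm>\n", x$lambda_min, x$lambda_max))
  invisible(x)
}

#' Default wavelength grid for a window
#'
#' 1 nm spacing, inclusive of both endpoints. Sub-resolution relative to the
#' narrowest (15 nm FWHM) lines the toolkit models.
#'
#' @param window A [spectral_window()] or length-2 numeric range.
#' @param step Grid spacing in nm.
#' @return Numeric wavelength vector.
#' @export
wavelength_grid <- function(window, step = 1) {
  if (inherits(window, "spectral_window")) {
    rng <- c(window$lambda_min, window$lambda_max)
  } else {
    rng <- as.numeric(window)
  }
  seq(rng[1], rng[2], by = step)
}

#' Window phase of a wavelength
#'
#' x(lambda) = 2*pi*(lambda - lambda_min) / (lambda_max - lambda_min):
#' the window is mapped onto one full turn, with phase 0 at the blue edge.
#'
#' @param wavelength Wavelengths in nm.
#' @param window A [spectral_window()].
#' @return Phase in radians.
#' @export
window_phase <- function(wavelength, window) {
  2 * pi * (wavelength - window$lambda_min) /
    (window$lambda_max - window$lambda_min)
}

#' Spectral cube
#'
#' An (x, y, lambda) scene: every pixel holds a spectrum on one shared
#' wavelength grid. Stored as an array with dimensions
#' (rows, cols, wavelengths).
#'
#' @param data Numeric array, dim = c(nrow, ncol, n_wavelength), non-negative.
#' @param wavelength Shared wavelength grid (nm), strictly increasing.
#' @param pixel_area Pixel area in cm^2 (metadata used by the camera model).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelength, pixel_area = 9e-6) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("cube data must be a 3D array")
  if (dim(data)[3] != length(wavelength)) {
    stop("third dimension must match the wavelength grid")
  }
  if (any(diff(wavelength) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(data < 0)) stop("cube intensities must be non-negative")
  structure(list(data = data, wavelength = as.numeric(wavelength),
                 pixel_area = pixel_area),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube: %d x %d pixels, %d wavelengths (%.0f-%.0f nm)>\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Total in-band flux image of a cube
#'
#' Trapezoid-integrates every pixel spectrum over the grid (optionally
#' restricted to a window), returning a matrix of photons s^-1 cm^-2.
#'
#' @inheritParams spectrum_integral
#' @param cube A [spectral_cube()].
#' @return Numeric matrix.
#' @export
cube_flux <- function(cube, window = NULL) {
  w <- cube$wavelength
  keep <- rep(TRUE, length(w))
  if (!is.null(window)) keep <- w >= window$lambda_min & w <= window$lambda_max
  wk <- w[keep]
  wt <- trapezoid_weights(wk)
  d <- dim(cube$data)
  m <- matrix(cube$data[, , keep, drop = FALSE], nrow = d[1] * d[2])
  matrix(m %*% wt, nrow = d[1], ncol = d[2])
}

# trapezoid quadrature weights for an arbitrary strictly increasing grid
trapezoid_weights <- function(wavelength) {
  n <- length(wavelength)
  dw <- diff(wavelength)
  c(dw[1], dw[-1] + dw[-(n - 1)], dw[n - 1]) / 2
}
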