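#' EMVA-1288 camera model
#'
#' Parameters of the linear camera model in which the variance of the
#' digitized signal is a linear function of the signal itself:
#' \deqn{\sigma_y^2 = K^2(\sigma_d^2 + \sigma_q^2) + K(\mu_y - \mu_{y,dark})}
#' Defaults describe a cooled InGaAs sensor in a low-gain (deep full well)
#' mode: system gain K = 1.1e-3 DN/e-, RMS read noise 1000 e-
#' (`read_noise_var` = 1e6 e-^2), 12-bit quantization (sigma_q^2 = 1/12 DN^2),
#' quantum efficiency 0.56, pixel area 9e-6 cm^2, 3 s exposure, dark offset
#' neglected (0 DN).
#'
#' @param gain System gain K in DN per photoelectron.
#' @param read_noise_var Read-noise variance sigma_d^2 in electrons^2.
#' @param quantization_var Quantization-noise variance sigma_q^2 in DN^2.
#' @param qe Quantum efficiency: a scalar in `[0, 1]` or a function of
#'   wavelength (nm) returning fractions.
#' @param pixel_area Pixel area A in cm^2.
#' @param exposure Exposure time t_exp in s.
#' @param bit_depth ADC bit depth (values clipped to `[0, 2^bit_depth - 1]`).
#' @param dark_offset Dark signal mu_y,dark in DN.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(gain = 1.1e-3, read_noise_var = 1e6,
                         quantization_var = 1 / 12, qe = 0.56,
                         pixel_area = 9e-6, exposure = 3, bit_depth = 12,
                         dark_offset = 0) {
  if (gain <= 0 || read_noise_var < 0 || quantization_var < 0 ||
      pixel_area <= 0 || exposure <= 0 || dark_offset < 0) {
    stop("camera parameters must be non-negative (gain, area, exposure > 0)")
  }
  if (is.numeric(qe) && (qe < 0 || qe > 1)) stop("qe must be in [0, 1]")
  structure(list(gain = gain, read_noise_var = read_noise_var,
                 quantization_var = quantization_var, qe = qe,
                 pixel_area = pixel_area, exposure = exposure,
                 bit_depth = bit_depth, dark_offset = dark_offset),
            class = "camera_model")
}

qe_at <- function(camera, wavelength) {
  if (is.function(camera$qe)) camera$qe(wavelength)
  else rep(camera$qe, length(wavelength))
}

#' Signal variance of the camera model
#'
#' Evaluates the linear noise model
#' `K^2 * (sigma_d^2 + sigma_q^2) + K * (mu_y - mu_y_dark)`: a
#' signal-independent floor of read and quantization noise plus a shot-noise
#' term proportional to the signal above dark.
#'
#' @param signal Mean signal(s) mu_y in DN; must be `>= dark_offset`.
#' @param camera A [camera_model()].
#' @return Variance(s) in DN^2.
#' @examples
#' cam <- camera_model()
#' noise_variance(c(10, 100, 600), cam)
#' @export
noise_variance <- function(signal, camera = camera_model()) {
  if (any(signal < camera$dark_offset)) {
    stop("signal must be at least the dark offset")
  }
  camera$gain^2 * (camera$read_noise_var + camera$quantization_var) +
    camera$gain * (signal - camera$dark_offset)
}

#' Photon flux from a camera signal
#'
#' Inverts the photoelectron chain: `Phi = mu_y / (K * QE * A * t_exp)`,
#' the photon flux (photons s^-1 cm^-2) on the pixel that produces a mean
#' signal mu_y.
#'
#' @param signal Mean signal(s) in DN (above dark).
#' @param camera A [camera_model()].
#' @param wavelength Wavelength in nm at which to evaluate the quantum
#'   efficiency (ignored for scalar QE; default 990 nm).
#' @return Photon flux(es) in photons s^-1 cm^-2.
#' @seealso [signal_from_flux()] for the exact inverse.
#' @export
photon_flux <- function(signal, camera = camera_model(), wavelength = 990) {
  qe <- qe_at(camera, wavelength)[1]
  denom <- camera$gain * qe * camera$pixel_area * camera$exposure
  if (denom == 0) stop("gain * QE * area * exposure must be positive")
  signal / denom
}

#' Camera signal from a photon flux
#'
#' Exact inverse of [photon_flux()]:
#' `mu_y = Phi * K * QE * A * t_exp` (DN, above dark).
#'
#' @param flux Photon flux(es) in photons s^-1 cm^-2.
#' @inheritParams photon_flux
#' @return Mean signal(s) in DN.
#' @export
signal_from_flux <- function(flux, camera = camera_model(), wavelength = 990) {
  qe <- qe_at(camera, wavelength)[1]
  flux * camera$gain * qe * camera$pixel_area * camera$exposure
}

#' Intensity image container
#'
#' A single filtered camera frame in digital numbers with its acquisition
#' metadata.
#'
#' @param data Numeric matrix of DN values.
#' @param filter_kind Which filter produced the frame
#'   (`"sine"`, `"cosine"`, `"total"`, or `"none"`).
#' @param exposure Exposure time in s.
#' @param clipped Number of pixels clipped at the ADC limits (metadata).
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(data, filter_kind = "none", exposure = NA_real_,
                            clipped = 0L) {
  structure(list(data = as.matrix(data), filter_kind = filter_kind,
                 exposure = exposure, clipped = clipped),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image: %d x %d DN, filter %s, mean %.2f%s>\n",
              nrow(x$data), ncol(x$data), x$filter_kind, mean(x$data),
              if (x$clipped > 0) sprintf(", %d clipped", x$clipped) else ""))
  invisible(x)
}

#' Acquire one filtered frame of a spectral cube
#'
#' Simulates the camera exposure of a scene through a transmission filter:
#' per pixel the expected photoelectron count is
#' `t_exp * A * integral(I(lambda) * T(lambda) * QE(lambda) dlambda)`
#' (trapezoid rule on the cube grid), the expected signal is
#' `K * electrons + dark_offset` DN, and the realized signal is drawn from a
#' normal distribution with the EMVA-1288 variance of [noise_variance()],
#' then clipped to the ADC range and quantized (round half to even).
#' Noise and quantization can be disabled for oracle comparisons.
#'
#' @param cube A [spectral_cube()].
#' @param filter A [filter_setting()] or [transmission_curve()]. A setting is
#'   realized on the cube grid via [realized_curve()]; a curve must share the
#'   cube's wavelength grid. The filter's `sign` is metadata for the phasor
#'   stage and does not alter the light.
#' @param camera A [camera_model()].
#' @param seed Optional integer seed making the draw reproducible.
#' @param noise Draw noise? (`FALSE` returns the expected signal.)
#' @param quantize Clip and round to ADC integers? (`FALSE` keeps real DN.)
#' @return An [intensity_image()].
#' @export
acquire_frame <- function(cube, filter, camera = camera_model(), seed = NULL,
                          noise = TRUE, quantize = noise) {
  grid <- cube$wavelength
  if (inherits(filter, "filter_setting")) {
    kind <- filter$kind
    curve <- realized_curve(filter, grid = grid)
  } else if (inherits(filter, "transmission_curve")) {
    kind <- "custom"
    curve <- filter
  } else stop("filter must be a filter_setting or transmission_curve")
  if (length(curve$wavelength) != length(grid) ||
      any(abs(curve$wavelength - grid) > 1e-9)) {
    stop("transmission curve grid does not match the cube grid")
  }

  wt <- trapezoid_weights(grid) * curve$transmission * qe_at(camera, grid)
  d <- dim(cube$data)
  flux <- matrix(cube$data, nrow = d[1] * d[2]) %*% wt   # photons s^-1 cm^-2
  electrons <- camera$exposure * camera$pixel_area * flux
  mu_y <- camera$gain * electrons + camera$dark_offset

  y <- mu_y
  if (noise) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    y <- stats::rnorm(length(mu_y), mean = mu_y, sd = sqrt(noise_variance(mu_y, camera)))
  }
  clipped <- 0L
  if (quantize) {
    top <- 2^camera$bit_depth - 1
    clipped <- sum(y < 0 | y > top)
    y <- round(pmin(pmax(y, 0), top))   # round() is half-to-even in R
  }
  intensity_image(matrix(y, d[1], d[2]), filter_kind = kind,
                  exposure = camera$exposure, clipped = as.integer(clipped))
}

#' Acquire the three-frame phasor stack
#'
#' Convenience wrapper acquiring the sine, cosine and total frames of one
#' hyperspectral measurement with independent noise per frame.
#'
#' @param cube A [spectral_cube()].
#' @param settings Named list with elements `sine`, `cosine`, `total`
#'   ([filter_setting()]s or [transmission_curve()]s).
#' @inheritParams acquire_frame
#' @return Named list of three [intensity_image()]s
#'   (`sine`, `cosine`, `total`).
#' @export
acquire_stack <- function(cube, settings, camera = camera_model(), seed = NULL,
                          noise = TRUE, quantize = noise) {
  stopifnot(all(c("sine", "cosine", "total") %in% names(settings)))
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else as.list(seed + 0:2)
  list(sine   = acquire_frame(cube, settings$sine,   camera, seeds[[1]], noise, quantize),
       cosine = acquire_frame(cube, settings$cosine, camera, seeds[[2]], noise, quantize),
       total  = acquire_frame(cube, settings$total,  camera, seeds[[3]], noise, quantize))
}

#' Phasor spread of a phasor image
#'
#' The scalar cluster-spread statistic used in the photon-limit study: the
#' sum of the standard deviations of the G and S coordinates over all valid
#' pixels.
#'
#' @param phasor A `phasor_image` (see [phasor_from_frames()]).
#' @return `sd(G) + sd(S)` over valid pixels (0 for a constant image).
#' @export
phasor_spread <- function(phasor) {
  g <- phasor$G[phasor$valid]
  s <- phasor$S[phasor$valid]
  if (length(g) < 2L) return(0)
  stats::sd(g) + stats::sd(s)
}

#' Predicted phasor spread from the noise model
#'
#' First-order error propagation of the EMVA-1288 frame variance through the
#' three-frame phasor transform: with independent sine/cosine/total frames of
#' means `mu_s`, `mu_g`, `mu_t` and variances from [noise_variance()], the
#' variance of `S = 2 I_s / I_t - 1` is
#' `4 * (var_s / mu_t^2 + mu_s^2 * var_t / mu_t^4)` (similarly for G), and
#' the predicted spread is `sd(G) + sd(S)`. This is the model curve against
#' which the simulated spread-versus-flux trend is compared.
#'
#' @param mu_sine,mu_cosine,mu_total Mean frame signals in DN (above dark).
#' @param camera A [camera_model()].
#' @return Predicted spread (dimensionless).
#' @export
predicted_phasor_spread <- function(mu_sine, mu_cosine, mu_total,
                                    camera = camera_model()) {
  vs <- noise_variance(mu_sine, camera)
  vg <- noise_variance(mu_cosine, camera)
  vt <- noise_variance(mu_total, camera)
  sd_s <- 2 * sqrt(vs / mu_total^2 + mu_sine^2 * vt / mu_total^4)
  sd_g <- 2 * sqrt(vg / mu_total^2 + mu_cosine^2 * vt / mu_total^4)
  sd_g + sd_s
}
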