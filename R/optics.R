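#' Transmission of the polarizer-retarder-polarizer stack
#'
#' For a variable retarder of retardance `R` (nm) between two parallel linear
#' polarizers, both at 45 degrees to the retarder fast axis, the transmission
#' relative to the light passing the first polarizer is
#' \deqn{T(R, \lambda) = \tfrac{1}{2}\left(1 + \cos(2\pi R / \lambda)\right).}
#' At `R = 0` the stack transmits fully at every wavelength, which provides
#' the "total" normalization filter of the three-frame phasor acquisition.
#'
#' @param retardance Retardance in nm (optical path difference), `>= 0`.
#'   The physical retardance is R = d * dn(lambda); with the package's default
#'   dispersionless retarder it is a single wavelength-independent number.
#' @param wavelength Wavelength(s) in nm, `> 0`. Vectorized over both
#'   arguments with the usual recycling.
#' @return Transmission fraction(s) in `[0, 1]`.
#' @seealso [jones_transmission()] for the general Jones-calculus stack,
#'   [calibrate_retardance()] for choosing `R` to approximate sine/cosine
#'   targets over a window.
#' @examples
#' transmission(0, 1000)        # 1: total-transmission setting
#' transmission(500, 1000)      # 0: half-wave retardance
#' transmission(250, 1000)      # 0.5: quarter-wave
#' @export
transmission <- function(retardance, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  if (any(retardance < 0)) stop("retardance must be non-negative")
  0.5 * (1 + cos(2 * pi * retardance / wavelength))
}

#' General Jones-calculus transmission of polarizer -> retarder -> polarizer
#'
#' Propagates light through a linear polarizer, a linear retarder with a given
#' fast-axis orientation and retardance, and a second linear polarizer, using
#' 2x2 Jones matrices. Intensity is reported relative to the light exiting the
#' first polarizer (unpolarized input loses 50% there; that loss is part of
#' the optical throughput, not of the spectral filter shape). With both
#' polarizers parallel at 45 degrees to the fast axis this reduces exactly to
#' [transmission()].
#'
#' @param polarizer_angles Length-2 numeric: angles of the first and second
#'   polarizer axes in degrees, measured from a common laboratory axis.
#' @param retarder_fast_axis Fast-axis angle of the retarder in degrees.
#' @param retardance Retardance in nm.
#' @param wavelength Wavelength in nm (vectorized).
#' @return Transmission fraction(s) in `[0, 1]`.
#' @examples
#' jones_transmission(c(45, 45), 0, 500, 1000)   # == transmission(500, 1000)
#' jones_transmission(c(0, 0), 0, 700, 1000)     # 1: light along the fast axis
#' @export
jones_transmission <- function(polarizer_angles, retarder_fast_axis,
                               retardance, wavelength) {
  if (length(polarizer_angles) != 2L) {
    stop("polarizer_angles must be a length-2 vector (first, second)")
  }
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  if (any(retardance < 0)) stop("retardance must be non-negative")
  th1 <- polarizer_angles[1] * pi / 180
  th2 <- polarizer_angles[2] * pi / 180
  phi <- retarder_fast_axis * pi / 180
  delta <- 2 * pi * retardance / wavelength   # phase retardation

  # Jones vector after the first polarizer: unit amplitude along its axis.
  v <- c(cos(th1), sin(th1))
  # Retarder in its own frame: diag(1, exp(i*delta)); rotate in and out.
  cphi <- cos(phi); sphi <- sin(phi)
  vr1 <- cphi * v[1] + sphi * v[2]    # component along fast axis
  vr2 <- -sphi * v[1] + cphi * v[2]   # component along slow axis
  e2 <- exp(1i * delta)
  out1 <- cphi * vr1 - sphi * (vr2 * e2)
  out2 <- sphi * vr1 + cphi * (vr2 * e2)
  # Project onto the second polarizer axis.
  amp <- out1 * cos(th2) + out2 * sin(th2)
  as.numeric(Mod(amp)^2)
}

#' Ideal sine/cosine/total filter targets over a window
#'
#' Generates the target transmission curve that retardance calibration tries
#' to approximate: with window phase `x(lambda) = 2*pi*(lambda - lambda_min) /
#' (lambda_max - lambda_min)`, the cosine target is
#' `0.5 * (1 + sign * cos(order * x))`, the sine target the same with `sin`,
#' and the total target is 1 everywhere. `order > 1` squeezes several full
#' periods into the window (multi-order filter).
#'
#' @param window A [spectral_window()].
#' @param kind One of `"sine"`, `"cosine"`, `"total"`.
#' @param sign `+1` or `-1` (negated targets are legitimate calibration fits).
#' @param order Positive integer number of periods across the window.
#' @param grid Wavelength grid (nm); defaults to [wavelength_grid()] at 1 nm.
#' @return A `transmission_curve`: list with `wavelength` and `transmission`.
#' @export
ideal_filter_curve <- function(window, kind = c("cosine", "sine", "total"),
                               sign = 1, order = 1,
                               grid = wavelength_grid(window)) {
  kind <- match.arg(kind)
  if (order < 1 || order != round(order)) stop("order must be a positive integer")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  x <- order * window_phase(grid, window)
  tr <- switch(kind,
               cosine = 0.5 * (1 + sign * cos(x)),
               sine   = 0.5 * (1 + sign * sin(x)),
               total  = rep(1, length(grid)))
  transmission_curve(grid, tr)
}

#' Transmission curve container
#'
#' @param wavelength Wavelength grid (nm).
#' @param transmission Transmission fractions in `[0, 1]`.
#' @return An object of class `transmission_curve`.
#' @export
transmission_curve <- function(wavelength, transmission) {
  if (length(wavelength) != length(transmission)) {
    stop("wavelength and transmission must have the same length")
  }
  if (any(transmission < -1e-12) || any(transmission > 1 + 1e-12)) {
    stop("transmission values must lie in [0, 1]")
  }
  structure(list(wavelength = as.numeric(wavelength),
                 transmission = pmin(pmax(transmission, 0), 1)),
            class = "transmission_curve")
}

#' Retarder model
#'
#' A variable retarder characterized by its maximum retardance. Optionally a
#' thickness `d` (nm) and birefringence function `dn(lambda)` may be given;
#' the default is dispersionless (constant birefringence), so the retardance
#' is a single wavelength-independent number and the stack transmission is
#' exactly [transmission()].
#'
#' @param max_retardance Maximum achievable retardance in nm (e.g. 10400 for
#'   a typical NIR liquid-crystal variable retarder).
#' @param thickness Optional cell thickness in nm.
#' @param birefringence Optional function of wavelength (nm) returning the
#'   birefringence dn; retardance is then `thickness * dn(lambda)` scaled so
#'   that its maximum over 900-1600 nm equals the commanded retardance.
#' @return An object of class `retarder_model`.
#' @export
retarder_model <- function(max_retardance, thickness = NULL,
                           birefringence = NULL) {
  if (max_retardance < 0) stop("max_retardance must be non-negative")
  structure(list(max_retardance = max_retardance, thickness = thickness,
                 birefringence = birefringence),
            class = "retarder_model")
}

# Effective retardance at each wavelength for a commanded retardance.
# Dispersionless default: constant. With a birefringence curve the commanded
# value sets the scale at the reference wavelength (grid maximum of dn).
retardance_profile <- function(retarder, commanded, wavelength) {
  if (is.null(retarder$birefringence)) return(rep(commanded, length(wavelength)))
  dn <- retarder$birefringence(wavelength)
  if (any(dn < 0)) stop("birefringence must be non-negative")
  commanded * dn / max(dn)
}

#' Filter setting
#'
#' A calibrated retardance that approximates an ideal sine, cosine or total
#' transmission filter over a spectral window, together with the sign of the
#' best-fitting target and the quality of the fit.
#'
#' @param kind `"sine"`, `"cosine"` or `"total"`.
#' @param retardance Calibrated retardance in nm (`0` for `"total"`).
#' @param sign `+1` or `-1`; a negated target fit is folded back into the
#'   phasor transform downstream.
#' @param order Periods across the window (default 1).
#' @param fit_r2 Squared Pearson correlation of the realized transmission
#'   against the ideal target, in `[0, 1]`; `NA` for the (trivially exact)
#'   total filter.
#' @param window The [spectral_window()] the setting was calibrated for.
#' @param degenerate Logical flag set when calibration could not move the
#'   retardance (e.g. `max_retardance = 0`) and the result collapses to the
#'   total filter.
#' @return An object of class `filter_setting`.
#' @export
filter_setting <- function(kind, retardance, sign = 1, order = 1,
                           fit_r2 = NA_real_, window = NULL,
                           degenerate = FALSE) {
  kind <- match.arg(kind, c("sine", "cosine", "total"))
  if (kind == "total" && (retardance != 0 || sign != 1)) {
    stop("the total filter has retardance 0 and sign +1")
  }
  if (!is.na(fit_r2) && (fit_r2 < 0 || fit_r2 > 1)) stop("fit_r2 must be in [0, 1]")
  structure(list(kind = kind, retardance = retardance, sign = sign,
                 order = order, fit_r2 = fit_r2, window = window,
                 degenerate = degenerate),
            class = "filter_setting")
}

#' @export
print.filter_setting <- function(x, ...) {
  cat(sprintf("<filter_setting: %s, R = %.1f nm, sign %+d, order %d, r2 = %s%s>\n",
              x$kind, x$retardance, x$sign, x$order,
              ifelse(is.na(x$fit_r2), "NA", sprintf("%.4f", x$fit_r2)),
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Realized transmission curve of a filter setting
#'
#' Evaluates the physical stack transmission at the setting's retardance on a
#' wavelength grid (the sign is *not* applied here: negation is an
#' interpretation applied in the phasor transform, not a property of light).
#'
#' @param setting A [filter_setting()].
#' @param grid Wavelength grid (nm); defaults to the setting's window at 1 nm.
#' @param retarder Optional [retarder_model()] supplying dispersion.
#' @return A [transmission_curve()].
#' @export
realized_curve <- function(setting, grid = wavelength_grid(setting$window),
                           retarder = NULL) {
  reff <- if (is.null(retarder)) rep(setting$retardance, length(grid))
          else retardance_profile(retarder, setting$retardance, grid)
  transmission_curve(grid, transmission(reff, grid))
}

#' Calibrate the retardance for a sine or cosine filter
#'
#' Grid-searches the retardance in `[0, max_retardance]` for the value whose
#' stack transmission best matches the ideal sine or cosine target over the
#' window, in the sense of the squared Pearson correlation, and refines the
#' best grid point by golden-section search. Both the positive and the
#' negated target are evaluated; because the negated target is an affine flip
#' of the positive one, the correlation only changes sign, so the reported
#' sign is the sign of the correlation at the optimum. Ties in r2 are broken
#' toward the smallest retardance.
#'
#' @param window A [spectral_window()].
#' @param kind `"sine"` or `"cosine"`.
#' @param retarder A [retarder_model()] (its `max_retardance` caps the search;
#'   `Inf` searches up to two full periods across the window).
#' @param order Periods across the window for the target (default 1).
#' @param grid_step Wavelength grid step in nm for the correlation (default 1).
#' @param search_step Retardance search step in nm (default 5).
#' @return A [filter_setting()] carrying the best retardance, sign and
#'   `fit_r2`. With `max_retardance = 0` the result is the degenerate total
#'   filter (`fit_r2 = NA`, `degenerate = TRUE`).
#' @examples
#' w <- spectral_window(900, 1200)
#' calibrate_retardance(w, "cosine", retarder_model(10400))
#' @export
calibrate_retardance <- function(window, kind = c("cosine", "sine"),
                                 retarder = retarder_model(10400),
                                 order = 1, grid_step = 1, search_step = 5) {
  kind <- match.arg(kind)
  grid <- wavelength_grid(window, grid_step)
  if (length(grid) < 3L) stop("degenerate window: fewer than 3 grid points")
  if (retarder$max_retardance == 0) {
    return(filter_setting("total", 0, 1, order = order, fit_r2 = NA_real_,
                          window = window, degenerate = TRUE))
  }
  target <- ideal_filter_curve(window, kind, sign = 1, order = order,
                               grid = grid)$transmission

  # One full period across the window needs R = order / (1/l_min - 1/l_max);
  # searching to twice that covers every distinct phase alignment.
  r_period <- order / (1 / window$lambda_min - 1 / window$lambda_max)
  r_max <- min(retarder$max_retardance, 2 * r_period)

  corr_at <- function(r) {
    tr <- transmission(retardance_profile(retarder, r, grid), grid)
    if (stats::sd(tr) == 0) return(0)
    stats::cor(tr, target)
  }
  rs <- seq(0, r_max, by = search_step)
  if (rs[length(rs)] < r_max) rs <- c(rs, r_max)
  cors <- vapply(rs, corr_at, numeric(1))
  best <- which.max(cors^2)   # which.max takes the first (smallest R) on ties

  lo <- max(0, rs[best] - search_step)
  hi <- min(r_max, rs[best] + search_step)
  opt <- stats::optimize(function(r) -corr_at(r)^2, c(lo, hi),
                         tol = .Machine$double.eps^0.5)
  r_best <- opt$minimum
  # keep the coarse point if refinement did not actually improve
  if (-opt$objective < cors[best]^2) r_best <- rs[best]
  r_final <- corr_at(r_best)
  filter_setting(kind, r_best, sign = ifelse(r_final >= 0, 1, -1),
                 order = order, fit_r2 = r_final^2, window = window)
}

#' Voltage-to-retardance lookup
#'
#' Monotone interpolation of a measured voltage-retardance table (the
#' tuning curve of a physical liquid-crystal retarder). Exact at the table
#' knots; queries outside the table range are refused rather than
#' extrapolated.
#'
#' @param voltage_table Data frame or list with numeric `voltage` (V) and
#'   `retardance` (nm), strictly monotone in voltage.
#' @param voltage Query voltage(s) in V.
#' @return Retardance(s) in nm.
#' @export
retardance_lookup <- function(voltage_table, voltage) {
  v <- voltage_table$voltage
  r <- voltage_table$retardance
  if (is.null(v) || is.null(r)) stop("table needs 'voltage' and 'retardance'")
  if (length(v) < 2L) stop("table needs at least 2 knots")
  dv <- diff(v)
  if (!(all(dv > 0) || all(dv < 0))) stop("voltages must be strictly monotone")
  if (dv[1] < 0) { v <- rev(v); r <- rev(r) }
  if (any(voltage < min(v)) || any(voltage > max(v))) {
    stop("voltage outside the table range; no extrapolation")
  }
  # monotone (Fritsch-Carlson) interpolation: exact at knots, no overshoot
  f <- stats::splinefun(v, r, method = "monoH.FC")
  f(voltage)
}

#' Write calibration settings to JSON
#'
#' @param settings A [filter_setting()] or list of them.
#' @param path Output file path.
#' @export
write_filter_settings <- function(settings, path) {
  if (inherits(settings, "filter_setting")) settings <- list(settings)
  rec <- lapply(settings, function(s) {
    list(kind = s$kind, retardance_nm = s$retardance, sign = s$sign,
         order = s$order, r2 = s$fit_r2,
         lambda_min = s$window$lambda_min, lambda_max = s$window$lambda_max)
  })
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read calibration settings from JSON
#'
#' @param path File written by [write_filter_settings()].
#' @return List of [filter_setting()] objects.
#' @export
read_filter_settings <- function(path) {
  rec <- jsonlite::read_json(path)
  lapply(rec, function(s) {
    filter_setting(s$kind, s$retardance_nm, s$sign, s$order,
                   fit_r2 = if (is.null(s$r2)) NA_real_ else s$r2,
                   window = spectral_window(s$lambda_min, s$lambda_max))
  })
}

#' Write a transmission curve as CSV
#'
#' Two columns: `wavelength_nm`, `transmission`.
#' @param curve A [transmission_curve()].
#' @param path Output file path.
#' @export
write_transmission_csv <- function(curve, path) {
  utils::write.csv(data.frame(wavelength_nm = curve$wavelength,
                              transmission = curve$transmission),
                   path, row.names = FALSE)
  invisible(path)
}
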