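#' Phasor point
#'
#' A single spectral phasor coordinate with its polar form.
#'
#' @param G,S Cartesian phasor coordinates (cosine and sine components).
#' @return Object of class `phasor_point` with `G`, `S`, modulus `M` and
#'   phase `theta = atan2(S, G)`.
#' @export
phasor_point <- function(G, S) {
  structure(list(G = G, S = S, M = sqrt(G^2 + S^2), theta = atan2(S, G)),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point: G = %.4f, S = %.4f (M = %.4f, theta = %.3f rad)>\n",
              x$G, x$S, x$M, x$theta))
  invisible(x)
}

#' Exact spectral phasor of a spectrum
#'
#' The first-harmonic Fourier coordinates of a spectrum over a window, with
#' the window phase `x(lambda) = 2*pi*(lambda - lambda_min) /
#' (lambda_max - lambda_min)`:
#' \deqn{G = \frac{\int I \cos x \, d\lambda}{\int I \, d\lambda}, \qquad
#'       S = \frac{\int I \sin x \, d\lambda}{\int I \, d\lambda}}
#' (trapezoid integration on the spectrum's grid restricted to the window).
#' This is the ideal quantity the three-frame optical acquisition estimates,
#' and serves as the oracle for the whole pipeline.
#'
#' @param spectrum A [nir_spectrum()].
#' @param window A [spectral_window()].
#' @return A [phasor_point()].
#' @examples
#' w <- spectral_window(900, 1200)
#' spectral_phasor(gaussian_line(1050, 15, 1), w)  # near (-1, 0): x = pi
#' @export
spectral_phasor <- function(spectrum, window) {
  keep <- spectrum$wavelength >= window$lambda_min &
          spectrum$wavelength <= window$lambda_max
  if (sum(keep) < 2L) stop("fewer than 2 grid points inside the window")
  wl <- spectrum$wavelength[keep]
  ii <- spectrum$intensity[keep]
  total <- pracma::trapz(wl, ii)
  if (total <= 0) stop("zero total intensity in the window")
  x <- window_phase(wl, window)
  phasor_point(G = pracma::trapz(wl, ii * cos(x)) / total,
               S = pracma::trapz(wl, ii * sin(x)) / total)
}

#' Phasor of a spectrum through (possibly imperfect) transmission curves
#'
#' Applies the three-frame phasor estimator using the supplied sine, cosine
#' and total transmission curves: `S = sign_s * (2 I_s / I_t - 1)`,
#' `G = sign_g * (2 I_g / I_t - 1)` with `I_f = integral(I * T_f dlambda)`.
#' With ideal single-order curves this equals [spectral_phasor()] exactly;
#' with retarder-calibrated curves the point is displaced because the stack
#' transmits a chirped cos(1/lambda), not a true cosine in lambda.
#'
#' @param spectrum A [nir_spectrum()].
#' @param curves Named list of [transmission_curve()]s
#'   (`sine`, `cosine`, `total`) sharing the spectrum's grid (or a subset
#'   window of it).
#' @param signs Named numeric c(sine = ±1, cosine = ±1) to undo negated
#'   calibration targets.
#' @return A [phasor_point()].
#' @export
phasor_through_filters <- function(spectrum, curves,
                                   signs = c(sine = 1, cosine = 1)) {
  stopifnot(all(c("sine", "cosine", "total") %in% names(curves)))
  wl0 <- curves$total$wavelength
  keep <- spectrum$wavelength >= min(wl0) - 1e-9 &
          spectrum$wavelength <= max(wl0) + 1e-9
  wl <- spectrum$wavelength[keep]
  ii <- spectrum$intensity[keep]
  tr <- function(cu) {
    if (length(cu$wavelength) != length(wl) ||
        any(abs(cu$wavelength - wl) > 1e-9)) {
      stop("transmission curves must share the spectrum grid on the window")
    }
    pracma::trapz(wl, ii * cu$transmission)
  }
  i_t <- tr(curves$total)
  if (i_t <= 0) stop("zero total filtered intensity")
  phasor_point(G = unname(signs["cosine"]) * (2 * tr(curves$cosine) / i_t - 1),
               S = unname(signs["sine"]) * (2 * tr(curves$sine) / i_t - 1))
}

#' Phasor image from three camera frames
#'
#' The per-pixel phasor transform of a sine/cosine/total frame triplet:
#' `S = sign_s * (2 I_s / I_t - 1)`, `G = sign_g * (2 I_g / I_t - 1)`.
#' Pixels with a total signal below `min_total`, and pixels landing outside
#' the unit circle by more than `circle_tol` (noise artifacts), are marked
#' invalid and excluded from every downstream statistic.
#'
#' @param sine,cosine,total [intensity_image()]s (or bare matrices) of equal
#'   shape, background-subtracted.
#' @param signs Named numeric `c(sine = ±1, cosine = ±1)` from the filter
#'   calibration.
#' @param min_total Validity threshold on the total frame in DN; default
#'   `max(10, 0.01 * max(total))`.
#' @param circle_tol Modulus tolerance beyond 1 before invalidation
#'   (default 0.05).
#' @return An object of class `phasor_image`: matrices `G`, `S`, logical
#'   `valid`, and a `provenance` list. A warning is raised when no pixel
#'   is valid.
#' @export
phasor_from_frames <- function(sine, cosine, total,
                               signs = c(sine = 1, cosine = 1),
                               min_total = NULL, circle_tol = 0.05) {
  m <- function(x) if (inherits(x, "intensity_image")) x$data else as.matrix(x)
  is_ <- m(sine); ig <- m(cosine); it <- m(total)
  if (!all(dim(is_) == dim(ig)) || !all(dim(is_) == dim(it))) {
    stop("the three frames must have identical shapes")
  }
  if (is.null(min_total)) min_total <- max(10, 0.01 * max(it))
  valid <- it >= min_total
  G <- matrix(NA_real_, nrow(it), ncol(it))
  S <- G
  G[valid] <- unname(signs["cosine"]) * (2 * ig[valid] / it[valid] - 1)
  S[valid] <- unname(signs["sine"]) * (2 * is_[valid] / it[valid] - 1)
  mod2 <- G^2 + S^2
  out <- valid & mod2 > (1 + circle_tol)^2
  valid[out] <- FALSE
  G[!valid] <- NA_real_
  S[!valid] <- NA_real_
  if (!any(valid)) warning("no valid pixels in phasor image")
  structure(list(G = G, S = S, valid = valid,
                 provenance = list(signs = signs, min_total = min_total,
                                   circle_tol = circle_tol)),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("<phasor_image: %d x %d, %d/%d valid>\n",
              nrow(x$G), ncol(x$G), sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Mean phasor of the valid pixels
#'
#' @param phasor A `phasor_image`.
#' @return A [phasor_point()] at the centroid of the valid pixels.
#' @export
phasor_centroid <- function(phasor) {
  phasor_point(mean(phasor$G[phasor$valid]), mean(phasor$S[phasor$valid]))
}

#' Ideal filter curve triplet for a window
#'
#' @param window A [spectral_window()].
#' @param grid Wavelength grid (default 1 nm over the window).
#' @param order Periods across the window.
#' @return Named list of [transmission_curve()]s (`sine`, `cosine`, `total`).
#' @export
ideal_filter_set <- function(window, grid = wavelength_grid(window), order = 1) {
  list(sine   = ideal_filter_curve(window, "sine", 1, order, grid),
       cosine = ideal_filter_curve(window, "cosine", 1, order, grid),
       total  = ideal_filter_curve(window, "total", 1, order, grid))
}

#' Calibrated filter setting triplet for a window
#'
#' Runs [calibrate_retardance()] for the sine and cosine targets and adds the
#' exact total setting (retardance 0).
#'
#' @inheritParams calibrate_retardance
#' @return Named list of [filter_setting()]s (`sine`, `cosine`, `total`).
#' @export
calibrated_filter_set <- function(window, retarder = retarder_model(10400),
                                  order = 1, grid_step = 1) {
  list(sine   = calibrate_retardance(window, "sine", retarder, order, grid_step),
       cosine = calibrate_retardance(window, "cosine", retarder, order, grid_step),
       total  = filter_setting("total", 0, 1, order = order, window = window))
}

#' Sign pair of a calibrated filter set
#'
#' @param settings Result of [calibrated_filter_set()].
#' @return Named numeric `c(sine = ±1, cosine = ±1)` for
#'   [phasor_from_frames()] / [phasor_through_filters()].
#' @export
signs_of <- function(settings) {
  c(sine = settings$sine$sign, cosine = settings$cosine$sign)
}

#' Phasor distortion of calibrated filters and its look-up correction
#'
#' Tabulates, for a set of narrow probe lines, the ideal phasor position
#' (exact Fourier), the position realized through the supplied calibrated
#' filter curves, and their displacement. Because the realized phase is
#' monotone in the line wavelength for single-order filters, interpolating
#' the displacement against the realized phase yields an invertible look-up
#' correction for narrowband signals ([correct_phasor()]).
#'
#' @param window A [spectral_window()].
#' @param settings Filter settings from [calibrated_filter_set()] (or ideal
#'   curves, in which case all displacements are 0).
#' @param probe_lines Center wavelengths (nm) of delta-like probe lines;
#'   default 21 lines spanning the inner 90% of the window.
#' @param fwhm Probe line FWHM in nm (default 2: effectively monochromatic).
#' @return Object of class `distortion_map`: data frame with columns
#'   `wavelength`, `G_ideal`, `S_ideal`, `G_real`, `S_real`, `dG`, `dS`,
#'   `displacement`, `theta_real`.
#' @export
distortion_map <- function(window, settings, probe_lines = NULL, fwhm = 2) {
  if (is.null(probe_lines)) {
    span <- window$lambda_max - window$lambda_min
    probe_lines <- seq(window$lambda_min + 0.05 * span,
                       window$lambda_max - 0.05 * span, length.out = 21)
  }
  grid <- wavelength_grid(window, 0.5)
  curves <- lapply(settings, function(s) {
    if (inherits(s, "filter_setting")) realized_curve(s, grid = grid) else s
  })
  signs <- if (inherits(settings$sine, "filter_setting")) signs_of(settings)
           else c(sine = 1, cosine = 1)
  rows <- lapply(probe_lines, function(l0) {
    sp <- gaussian_line(l0, fwhm, 1, grid = grid)
    pi_ <- spectral_phasor(sp, window)
    pr <- phasor_through_filters(sp, curves, signs)
    data.frame(wavelength = l0, G_ideal = pi_$G, S_ideal = pi_$S,
               G_real = pr$G, S_real = pr$S,
               dG = pr$G - pi_$G, dS = pr$S - pi_$S,
               displacement = sqrt((pr$G - pi_$G)^2 + (pr$S - pi_$S)^2),
               theta_real = atan2(pr$S, pr$G))
  })
  structure(do.call(rbind, rows), class = c("distortion_map", "data.frame"))
}

#' Look-up correction of narrowband phasor points
#'
#' Subtracts the filter-distortion displacement interpolated from a
#' [distortion_map()] at each point's realized phase. Exact (to interpolation
#' accuracy) at the map's probe lines; for narrowband signals between probes
#' the residual displacement shrinks by an order of magnitude.
#'
#' @param G,S Numeric vectors of realized phasor coordinates.
#' @param dmap A [distortion_map()].
#' @return List with corrected `G` and `S`.
#' @export
correct_phasor <- function(G, S, dmap) {
  th <- atan2(S, G)
  # unwrap the table phase so interpolation runs on a monotone axis
  tth <- unwrap_phase(dmap$theta_real)
  th_u <- th
  for (i in seq_along(th_u)) {
    k <- round((tth[which.min(abs(dmap$theta_real - th[i]))] - th[i]) / (2 * pi))
    th_u[i] <- th[i] + 2 * pi * k
  }
  dg <- stats::approx(tth, dmap$dG, xout = th_u, rule = 2)$y
  ds <- stats::approx(tth, dmap$dS, xout = th_u, rule = 2)$y
  list(G = G - dg, S = S - ds)
}

unwrap_phase <- function(theta) {
  out <- theta
  for (i in seq_along(theta)[-1]) {
    d <- theta[i] - theta[i - 1]
    out[i] <- out[i - 1] + (d - 2 * pi * round(d / (2 * pi)))
  }
  out
}

#' Spatial G/S correction field from a uniform reference
#'
#' Estimates per-pixel additive offsets of the phasor coordinates from
#' repeated three-frame acquisitions of a spectrally uniform reference (a
#' white diffuse reflectance standard): the offset field is the reference
#' phasor image minus its spatial mean, averaged over repeats. Subtracting
#' the field ([apply_correction()]) suppresses spatial non-uniformity of the
#' retarder and illumination.
#'
#' @param reference_phasors List of `phasor_image`s of the uniform reference.
#' @return Object of class `correction_field` with matrices `dG`, `dS` and
#'   logical `valid`.
#' @export
estimate_correction_field <- function(reference_phasors) {
  if (inherits(reference_phasors, "phasor_image")) {
    reference_phasors <- list(reference_phasors)
  }
  gs <- Reduce(`+`, lapply(reference_phasors, function(p) {
    g <- p$G; g[!p$valid] <- 0; g
  }))
  ss <- Reduce(`+`, lapply(reference_phasors, function(p) {
    s <- p$S; s[!p$valid] <- 0; s
  }))
  nv <- Reduce(`+`, lapply(reference_phasors, function(p) 0 + p$valid))
  if (mean(nv > 0) < 0.5) stop("more than 50% of reference pixels are invalid")
  valid <- nv > 0
  G <- gs / pmax(nv, 1)
  S <- ss / pmax(nv, 1)
  dG <- G - mean(G[valid])
  dS <- S - mean(S[valid])
  dG[!valid] <- 0
  dS[!valid] <- 0
  structure(list(dG = dG, dS = dS, valid = valid), class = "correction_field")
}

#' Apply a spatial correction field to a phasor image
#'
#' @param phasor A `phasor_image`.
#' @param field A [estimate_correction_field()] result of the same shape.
#' @return The corrected `phasor_image`.
#' @export
apply_correction <- function(phasor, field) {
  if (!all(dim(phasor$G) == dim(field$dG))) {
    stop("correction field shape does not match the phasor image")
  }
  phasor$G <- phasor$G - field$dG
  phasor$S <- phasor$S - field$dS
  phasor
}

#' Angular colour-coding of a phasor image
#'
#' Maps each valid pixel's phase angle linearly onto `n_colors` colour
#' indices over `angle_range`; the two ends of a full-turn range are the same
#' colour (wrap-around). Invalid pixels get the sentinel index 0.
#'
#' @param phasor A `phasor_image`.
#' @param angle_range Length-2 numeric radians (default `c(-pi, pi)`).
#' @param n_colors Number of colour bins.
#' @return Integer matrix of colour indices in `0:n_colors`.
#' @export
angular_color <- function(phasor, angle_range = c(-pi, pi), n_colors = 256L) {
  theta <- atan2(phasor$S, phasor$G)
  span <- angle_range[2] - angle_range[1]
  frac <- ((theta - angle_range[1]) %% (2 * pi)) / span
  idx <- pmin(floor(frac * n_colors), n_colors - 1L) + 1L
  idx[!phasor$valid] <- 0L
  mode(idx) <- "integer"
  matrix(idx, nrow(phasor$G), ncol(phasor$G))
}

#' Polygon gating in phasor space
#'
#' Labels every valid pixel by the first polygon of `(G, S)` space containing
#' its phasor point (boundary counts as inside); unmatched valid pixels get
#' label 0, invalid pixels NA.
#'
#' @param phasor A `phasor_image`.
#' @param polygons Named list of two-column matrices (G, S vertices of closed
#'   polygons).
#' @return Integer label matrix (values `0:length(polygons)`, NA invalid);
#'   polygon names attached as the `labels` attribute.
#' @export
polygon_gate <- function(phasor, polygons) {
  lab <- matrix(NA_integer_, nrow(phasor$G), ncol(phasor$G))
  lab[phasor$valid] <- 0L
  g <- phasor$G[phasor$valid]
  s <- phasor$S[phasor$valid]
  assigned <- rep(0L, length(g))
  for (k in seq_along(polygons)) {
    poly <- as.matrix(polygons[[k]])
    inside <- pracma::inpolygon(g, s, poly[, 1], poly[, 2], boundary = TRUE)
    assigned[assigned == 0L & inside] <- k
  }
  lab[phasor$valid] <- assigned
  attr(lab, "labels") <- names(polygons)
  lab
}

#' 2D histogram of a phasor image
#'
#' Counts valid pixels over a regular grid on `[-1, 1]^2` (the phasor unit
#' square). The total count equals the number of valid pixels; points
#' outside the square (within the circle tolerance) are counted in the edge
#' bins.
#'
#' @param phasor A `phasor_image`.
#' @param bins Number of bins per axis.
#' @return List with `counts` (bins x bins matrix, G along rows, S along
#'   columns), and bin edge vectors `g_edges`, `s_edges`.
#' @export
phasor_histogram <- function(phasor, bins = 64L) {
  edges <- seq(-1, 1, length.out = bins + 1L)
  g <- pmin(pmax(phasor$G[phasor$valid], -1), 1)
  s <- pmin(pmax(phasor$S[phasor$valid], -1), 1)
  gi <- pmin(pmax(findInterval(g, edges, rightmost.closed = TRUE), 1L), bins)
  si <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(tabulate((si - 1L) * bins + gi, nbins = bins * bins),
                   bins, bins)
  list(counts = counts, g_edges = edges, s_edges = edges)
}
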