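#' Gaussian emission line
#'
#' Models the output of a monochromator or a narrow-band emitter as a
#' Gaussian spectral line of given full width at half maximum, normalized so
#' that its trapezoid integral over the grid equals the requested total flux.
#'
#' @param center Line center in nm; must lie inside the grid.
#' @param fwhm Full width at half maximum in nm (monochromator lines in this
#'   toolkit default to 15 nm).
#' @param total_flux Integrated flux in photons s^-1 cm^-2.
#' @param grid Wavelength grid in nm (default 900-1600 at 1 nm).
#' @return A [nir_spectrum()].
#' @examples
#' s <- gaussian_line(1050, 15, 1e10)
#' spectrum_integral(s)  # 1e10 to within renormalization accuracy
#' @export
gaussian_line <- function(center, fwhm, total_flux,
                          grid = wavelength_grid(c(900, 1600))) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (total_flux < 0) stop("total_flux must be non-negative")
  if (center < min(grid) || center > max(grid)) {
    stop("center lies outside the wavelength grid")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  shape <- exp(-0.5 * ((grid - center) / sigma)^2)
  area <- pracma::trapz(grid, shape)
  nir_spectrum(grid, shape * total_flux / area)
}

#' Narrow-band NIR fluorophore spectrum
#'
#' Analytic stand-in for the emission of a narrow-band NIR fluorophore such
#' as a single-chirality semiconducting carbon nanotube: a Gaussian or
#' Lorentzian profile truncated to the grid and renormalized to the requested
#' total flux.
#'
#' @inheritParams gaussian_line
#' @param peak Emission peak in nm.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return A [nir_spectrum()].
#' @export
fluorophore_spectrum <- function(peak, fwhm, shape = c("gaussian", "lorentzian"),
                                 total_flux = 1e10,
                                 grid = wavelength_grid(c(900, 1600))) {
  shape <- match.arg(shape)
  if (shape == "gaussian") return(gaussian_line(peak, fwhm, total_flux, grid))
  if (fwhm <= 0) stop("fwhm must be positive")
  if (peak < min(grid) || peak > max(grid)) stop("peak lies outside the grid")
  gam <- fwhm / 2
  prof <- gam^2 / ((grid - peak)^2 + gam^2)
  area <- pracma::trapz(grid, prof)
  nir_spectrum(grid, prof * total_flux / area)
}

#' Named narrow-band emitter presets
#'
#' Five synthetic chirality-like emission presets with peaks spanning
#' 950-1120 nm, two of which sit only 5 nm apart (the pair used to probe the
#' spectral-zoom resolution limit), plus a red-shifted and broadened
#' "defect" variant of the 990 nm species. Peak positions and widths are
#' fixture choices of this package, not measured values.
#'
#' @return Data frame with columns `name`, `peak_nm`, `fwhm_nm`.
#' @export
emitter_presets <- function() {
  data.frame(
    name    = c("em950", "em990", "em1030", "em1115", "em1120", "em990_defect"),
    peak_nm = c(950,     990,     1030,     1115,     1120,     1040),
    fwhm_nm = c(28,      25,      32,       30,       30,       40),
    stringsAsFactors = FALSE
  )
}

#' Spectrum of a named emitter preset
#'
#' @param name One of `emitter_presets()$name`.
#' @inheritParams gaussian_line
#' @return A [nir_spectrum()].
#' @export
preset_spectrum <- function(name, total_flux = 1e10,
                            grid = wavelength_grid(c(900, 1600))) {
  p <- emitter_presets()
  i <- match(name, p$name)
  if (is.na(i)) stop("unknown preset: ", name)
  gaussian_line(p$peak_nm[i], p$fwhm_nm[i], total_flux, grid)
}

#' Synthetic NIR reflectance spectra
#'
#' Analytic reflectance stand-ins for the toolkit's label-free scenes:
#' \describe{
#'   \item{polymerA / polymerB}{Broadband plateaus that are identical below
#'     1400 nm and differ only by distinct absorption dips in 1400-1600 nm,
#'     mimicking two plastics that look alike in the visible and short NIR
#'     but separate in the overtone region.}
#'   \item{leaf}{A high scattering plateau over 900-1350 nm multiplied by a
#'     water absorption band centered at 1450 nm whose depth grows
#'     monotonically with `water_fraction`.}
#' }
#' Intensities are reflectance fractions scaled by `illumination` so the
#' result plugs directly into the camera model as a photon flux density.
#'
#' @param kind `"polymerA"`, `"polymerB"` or `"leaf"`.
#' @param water_fraction Water content in `[0, 1]` (leaf only).
#' @param illumination Scalar photon flux density of the illumination
#'   (photons s^-1 cm^-2 nm^-1); reflected intensity = reflectance times this.
#' @param grid Wavelength grid in nm.
#' @return A [nir_spectrum()].
#' @export
reflectance_spectrum <- function(kind = c("polymerA", "polymerB", "leaf"),
                                 water_fraction = 0.5, illumination = 1e11,
                                 grid = wavelength_grid(c(900, 1600))) {
  kind <- match.arg(kind)
  dip <- function(center, depth, width) depth * exp(-0.5 * ((grid - center) / width)^2)
  if (kind == "leaf") {
    if (water_fraction < 0 || water_fraction > 1) {
      stop("water_fraction must be in [0, 1]")
    }
    plateau <- 0.55 / (1 + exp((grid - 1620) / 60))   # gentle long-edge rolloff
    band <- exp(-0.5 * ((grid - 1450) / 60)^2)
    band[grid < 1350] <- 0    # water combination band only acts beyond 1350 nm
    refl <- plateau * exp(-2.5 * water_fraction * band)
  } else {
    plateau <- 0.80 - 1e-5 * (grid - 900)             # near-flat backbone
    refl <- if (kind == "polymerA") {
      plateau * (1 - dip(1460, 0.45, 20))
    } else {
      plateau * (1 - dip(1505, 0.50, 22) - dip(1565, 0.35, 18))
    }
  }
  nir_spectrum(grid, refl * illumination)
}

#' Scene specification
#'
#' Describes a synthetic 2D scene as a list of regions (disks or polygons),
#' each bound to a spectrum, a peak flux scale and an intensity profile, over
#' an optional spatially uniform background spectrum. Rendered to a
#' [spectral_cube()] by [render_scene()].
#'
#' @param dim Length-2 integer image shape `c(nrow, ncol)` in pixels.
#' @param regions List of regions from [region_disk()] / [region_polygon()].
#' @param background Optional [nir_spectrum()] added to every pixel.
#' @param pixel_area Pixel area in cm^2.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(dim, regions, background = NULL, pixel_area = 9e-6) {
  if (length(dim) != 2L || any(dim < 1)) stop("dim must be c(nrow, ncol)")
  structure(list(dim = as.integer(dim), regions = regions,
                 background = background, pixel_area = pixel_area),
            class = "scene_spec")
}

#' Disk region of a scene
#'
#' @param center Length-2 numeric `c(row, col)` center in pixel coordinates.
#' @param radius Radius in pixels.
#' @param spectrum The region's [nir_spectrum()] (unit shape; scaled by
#'   `peak_flux` relative to the spectrum's own integral).
#' @param peak_flux Multiplier applied to the spectrum at the profile peak.
#' @param profile `"uniform"` or `"gaussian"` (circular Gaussian with
#'   sigma = radius / 2, truncated at the disk edge).
#' @return A region descriptor for [scene_spec()].
#' @export
region_disk <- function(center, radius, spectrum, peak_flux = 1,
                        profile = c("uniform", "gaussian")) {
  profile <- match.arg(profile)
  structure(list(type = "disk", center = center, radius = radius,
                 spectrum = spectrum, peak_flux = peak_flux,
                 profile = profile), class = "scene_region")
}

#' Polygon region of a scene
#'
#' @param vertices Two-column matrix of `(row, col)` vertices of a closed
#'   polygon in pixel coordinates.
#' @inheritParams region_disk
#' @return A region descriptor for [scene_spec()].
#' @export
region_polygon <- function(vertices, spectrum, peak_flux = 1) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("vertices must be an n x 2 matrix with n >= 3")
  }
  structure(list(type = "polygon", vertices = vertices, spectrum = spectrum,
                 peak_flux = peak_flux, profile = "uniform"),
            class = "scene_region")
}

# per-pixel weight map of one region (0 outside, profile weight inside)
region_weights <- function(region, dim) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  if (region$type == "disk") {
    d2 <- (rows - region$center[1])^2 + (cols - region$center[2])^2
    inside <- d2 <= region$radius^2
    w <- matrix(0, dim[1], dim[2])
    if (region$profile == "uniform") {
      w[inside] <- 1
    } else {
      sig <- region$radius / 2
      w[inside] <- exp(-0.5 * d2[inside] / sig^2)
    }
  } else {
    inside <- pracma::inpolygon(as.vector(rows), as.vector(cols),
                                region$vertices[, 1], region$vertices[, 2],
                                boundary = TRUE)
    w <- matrix(as.numeric(inside), dim[1], dim[2])
  }
  w
}

#' Render a scene to a spectral cube
#'
#' Per pixel: `spectrum_of_region * profile_weight * peak_flux`, summed over
#' overlapping regions, plus the background spectrum. Deterministic; noise
#' enters only at camera acquisition.
#'
#' @param spec A [scene_spec()].
#' @param grid Shared wavelength grid; defaults to the first region's grid.
#' @return A [spectral_cube()].
#' @export
render_scene <- function(spec, grid = NULL) {
  if (length(spec$regions) == 0L && is.null(spec$background)) {
    stop("scene has no regions and no background")
  }
  if (is.null(grid)) {
    grid <- if (length(spec$regions)) spec$regions[[1]]$spectrum$wavelength
            else spec$background$wavelength
  }
  nl <- length(grid)
  cube <- array(0, c(spec$dim[1], spec$dim[2], nl))
  for (region in spec$regions) {
    s <- region$spectrum
    if (!isTRUE(all.equal(s$wavelength, grid))) {
      stop("all region spectra must share the scene wavelength grid")
    }
    w <- region_weights(region, spec$dim) * region$peak_flux
    cube <- cube + outer(w, s$intensity)
  }
  if (!is.null(spec$background)) {
    if (!isTRUE(all.equal(spec$background$wavelength, grid))) {
      stop("background spectrum must share the scene wavelength grid")
    }
    cube <- cube + rep(spec$background$intensity, each = prod(spec$dim))
  }
  spectral_cube(cube, grid, pixel_area = spec$pixel_area)
}

#' Leaf water-uptake time series
#'
#' Generates a sequence of spectral cubes in which every pixel's leaf
#' reflectance follows a clamped linear water ramp: water_fraction(t) = 0
#' before the pixel's onset time, then rises at the pixel's rate (per second)
#' and saturates at 1. Emulates water arriving in veins before the
#' surrounding lamina when the onset map says so. Frames are timestamped at a
#' fixed period (default 5 s, i.e. 0.2 hyperspectral cubes per second).
#'
#' @param dim Image shape `c(nrow, ncol)`.
#' @param onset Matrix (same shape) of per-pixel onset times in s.
#' @param rate Matrix of per-pixel uptake rates in water-fraction s^-1
#'   (non-negative).
#' @param frame_period Seconds between hyperspectral frames (default 5).
#' @param duration Total duration in s; frames at `0, frame_period, ...`.
#' @param leaf_mask Optional logical matrix: pixels outside the leaf render
#'   as zero flux.
#' @param illumination Illumination flux density passed to
#'   [reflectance_spectrum()].
#' @param grid Wavelength grid in nm (default 900-1600 at 5 nm; the water
#'   band is 60 nm wide, so 5 nm sampling is still sub-resolution).
#' @return List with `frames` (list of [spectral_cube()]), `time` (numeric
#'   timestamps in s) and `water` (function(t) returning the water map).
#' @export
water_uptake_series <- function(dim, onset, rate, frame_period = 5,
                                duration = 600, leaf_mask = NULL,
                                illumination = 1e11,
                                grid = wavelength_grid(c(900, 1600), 5)) {
  onset <- matrix(onset, dim[1], dim[2])
  rate <- matrix(rate, dim[1], dim[2])
  if (any(rate < 0)) stop("uptake rates must be non-negative")
  if (is.null(leaf_mask)) leaf_mask <- matrix(TRUE, dim[1], dim[2])

  # reflectance is linear-in-exp(water): precompute dry and band shapes once
  dry <- reflectance_spectrum("leaf", 0, illumination, grid)$intensity
  band <- exp(-0.5 * ((grid - 1450) / 60)^2)
  band[grid < 1350] <- 0

  water_at <- function(t) pmin(pmax((t - onset) * rate, 0), 1)
  times <- seq(0, duration, by = frame_period)
  frames <- lapply(times, function(t) {
    wf <- water_at(t)
    # cube[p, l] = dry[l] * exp(-2.5 * wf[p] * band[l]), masked
    m <- exp(outer(as.vector(wf), band, function(f, b) -2.5 * f * b))
    m <- m * rep(dry, each = length(wf)) * as.vector(leaf_mask)
    spectral_cube(array(m, c(dim[1], dim[2], length(grid))), grid)
  })
  list(frames = frames, time = times, water = water_at)
}
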