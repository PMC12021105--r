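#' Read a spectrum from a two-column CSV
#'
#' Accepts `wavelength_nm, intensity` with or without a header row.
#'
#' @param path CSV file path.
#' @return A [nir_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- suppressWarnings(any(is.na(as.numeric(unlist(first)))))
  df <- utils::read.csv(path, header = has_header)
  if (ncol(df) < 2L) stop("expected two columns (wavelength_nm, intensity)")
  nir_spectrum(df[[1]], df[[2]])
}

#' Write a spectrum to CSV
#'
#' @param spectrum A [nir_spectrum()].
#' @param path Output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a sine/cosine/total frame stack as TIFF + JSON sidecar
#'
#' Frames are stored as a 3-page 16-bit TIFF in the order sine, cosine,
#' total; the sidecar (`<path>.json`) records the filter settings (kind,
#' retardance, sign, window), the DN scale and the camera parameters, so a
#' stack round-trips losslessly and self-describes its acquisition.
#'
#' @param frames Named list of [intensity_image()]s (`sine`, `cosine`,
#'   `total`) with integer-valued DN data.
#' @param path Output TIFF path (sidecar written next to it).
#' @param settings Optional named list of [filter_setting()]s to record.
#' @param camera Optional [camera_model()] to record.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(frames, path, settings = NULL, camera = NULL,
                              seed = NULL) {
  stopifnot(all(c("sine", "cosine", "total") %in% names(frames)))
  mats <- lapply(frames[c("sine", "cosine", "total")], function(f) {
    if (inherits(f, "intensity_image")) f$data else as.matrix(f)
  })
  top <- max(1, max(unlist(lapply(mats, max))))
  scale <- 65535
  if (top > scale) stop("DN values exceed 16-bit storage")
  tiff::writeTIFF(lapply(mats, function(m) m / scale), path,
                  bits.per.sample = 16)
  meta <- list(
    order = c("sine", "cosine", "total"),
    dn_scale = scale,
    shape = dim(mats[[1]]),
    filters = if (is.null(settings)) NULL else lapply(
      settings[c("sine", "cosine", "total")], function(s) {
        list(kind = s$kind, retardance_nm = s$retardance, sign = s$sign,
             order = s$order, r2 = s$fit_r2,
             lambda_min = s$window$lambda_min,
             lambda_max = s$window$lambda_max)
      }),
    camera = if (is.null(camera)) NULL else camera[
      c("gain", "read_noise_var", "quantization_var", "pixel_area",
        "exposure", "bit_depth", "dark_offset")],
    seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' Refuses stacks whose sidecar does not declare exactly the sine, cosine
#' and total filter kinds.
#'
#' @param path TIFF path with a `<path>.json` sidecar next to it.
#' @return Named list with `sine`, `cosine`, `total` ([intensity_image()]s)
#'   and `meta` (the sidecar contents).
#' @export
read_frame_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(sort(meta$order), c("cosine", "sine", "total"))) {
    stop("sidecar must declare exactly the sine, cosine and total frames")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) stop("expected a 3-page TIFF")
  mats <- lapply(pages, function(p) round(p * meta$dn_scale))
  names(mats) <- meta$order
  out <- lapply(c(sine = "sine", cosine = "cosine", total = "total"),
                function(k) intensity_image(mats[[k]], filter_kind = k))
  out$meta <- meta
  out
}

#' Write a phasor image as a 3-plane TIFF + JSON provenance
#'
#' Planes G, S (affinely scaled into `[0, 1]`; the scale is recorded in the
#' sidecar) and the validity mask, stored as 32-bit float.
#'
#' @param phasor A `phasor_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phasor_tiff <- function(phasor, path) {
  lo <- -1.1; hi <- 1.1   # beyond the unit-circle rejection band
  enc <- function(m) {
    m[!phasor$valid] <- 0
    pmin(pmax((m - lo) / (hi - lo), 0), 1)
  }
  tiff::writeTIFF(list(enc(phasor$G), enc(phasor$S), 1 * phasor$valid),
                  path, bits.per.sample = 32)
  jsonlite::write_json(list(planes = c("G", "S", "valid"), lo = lo, hi = hi,
                            provenance = phasor$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a phasor image written by [write_phasor_tiff()]
#'
#' @param path TIFF path with sidecar.
#' @return A `phasor_image`.
#' @export
read_phasor_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  valid <- pages[[3]] > 0.5
  dec <- function(p) {
    m <- p * (meta$hi - meta$lo) + meta$lo
    m[!valid] <- NA_real_
    m
  }
  structure(list(G = dec(pages[[1]]), S = dec(pages[[2]]), valid = valid,
                 provenance = meta$provenance),
            class = "phasor_image")
}

#' Write a spectral cube as multi-page TIFF + JSON sidecar
#'
#' One page per wavelength, intensities scaled by the cube maximum (recorded
#' in the sidecar together with the wavelength grid and units).
#'
#' @param cube A [spectral_cube()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cube_tiff <- function(cube, path) {
  top <- max(cube$data, 1e-300)
  pages <- lapply(seq_along(cube$wavelength),
                  function(i) cube$data[, , i] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(wavelength_nm = cube$wavelength, scale = top,
                            pixel_area_cm2 = cube$pixel_area,
                            units = "photons s-1 cm-2 nm-1"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral cube written by [write_cube_tiff()]
#'
#' @param path TIFF path with sidecar.
#' @return A [spectral_cube()].
#' @export
read_cube_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  spectral_cube(arr * meta$scale, meta$wavelength_nm,
                pixel_area = meta$pixel_area_cm2)
}

#' Read and validate a pipeline run configuration
#'
#' A YAML file with the sections `window`, `camera`, `scene`/`input`,
#' `pipeline` and a mandatory `seed`. Unknown top-level keys are rejected so
#' typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("window", "camera", "scene", "input", "pipeline", "seed",
               "output")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}
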