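# shared fixtures: all built in code, nothing loaded from disk

win_900_1200 <- spectral_window(900, 1200)
grid_900_1200 <- wavelength_grid(win_900_1200)

# uniform single-spectrum cube: npix pixels of the same spectrum
uniform_cube <- function(spectrum, npix = 100) {
  nr <- floor(sqrt(npix)); nc <- ceiling(npix / nr)
  spectral_cube(array(rep(spectrum$intensity, each = nr * nc),
                      c(nr, nc, length(spectrum$wavelength))),
                spectrum$wavelength)
}

# two-disk scene used by several end-to-end tests
two_region_scene <- function(dim = c(16, 16), peaks = c(1000, 1120),
                             flux = 1e11, grid = grid_900_1200) {
  scene_spec(dim, list(
    region_disk(c(dim[1] / 2, dim[2] / 4), dim[2] / 6,
                gaussian_line(peaks[1], 20, flux, grid)),
    region_disk(c(dim[1] / 2, 3 * dim[2] / 4), dim[2] / 6,
                gaussian_line(peaks[2], 20, flux, grid))))
}

# exact spectral phasor by direct Riemann-sum integration on a dense grid;
# deliberately does not call spectral_phasor/trapz (independent oracle)
oracle_phasor <- function(spectrum, window, n = 20001) {
  wl <- seq(max(min(spectrum$wavelength), window$lambda_min),
            min(max(spectrum$wavelength), window$lambda_max),
            length.out = n)
  ii <- approx(spectrum$wavelength, spectrum$intensity, xout = wl)$y
  x <- 2 * pi * (wl - window$lambda_min) /
    (window$lambda_max - window$lambda_min)
  dl <- wl[2] - wl[1]
  tot <- sum(ii) * dl
  c(G = sum(ii * cos(x)) * dl / tot, S = sum(ii * sin(x)) * dl / tot)
}
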