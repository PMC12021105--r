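test_that("spectral phasor matches closed forms for deltas and Gaussians", {
  w <- win_900_1200
  # delta-like line at the window center sits at phase pi: (G, S) = (-1, 0)
  delta <- nir_spectrum(grid_900_1200,
                        as.numeric(grid_900_1200 == 1050))
  p <- spectral_phasor(delta, w)
  expect_equal(p$G, -1); expect_equal(p$S, 0)
  expect_equal(p$M, 1)
  # Gaussian at the center: G = -exp(-(2 pi sigma / dLambda)^2 / 2)
  # (characteristic function of a Gaussian, checked against the independent
  # Riemann-sum oracle as well)
  for (fwhm in c(15, 40, 80)) {
    sig <- fwhm / (2 * sqrt(2 * log(2)))
    s <- gaussian_line(1050, fwhm, 1, grid = wavelength_grid(w, 0.25))
    p <- spectral_phasor(s, w)
    # 1e-4: grid discretization and window truncation of the Gaussian tails
    expect_equal(p$G, -exp(-(2 * pi * sig / 300)^2 / 2), tolerance = 1e-4)
    expect_equal(p$S, 0, tolerance = 1e-6)
    o <- oracle_phasor(s, w)
    expect_equal(p$G, unname(o["G"]), tolerance = 1e-4)
  }
  expect_error(spectral_phasor(nir_spectrum(c(1, 2), c(1, 1)), w), "grid points")
})

test_that("mixtures lie on the segment between component phasors", {
  w <- win_900_1200
  s1 <- gaussian_line(980, 20, 1, grid = grid_900_1200)
  s2 <- gaussian_line(1130, 35, 1, grid = grid_900_1200)
  p1 <- spectral_phasor(s1, w); p2 <- spectral_phasor(s2, w)
  w1 <- spectrum_integral(s1, w); w2 <- spectrum_integral(s2, w)
  set.seed(1)
  for (i in 1:100) {
    a <- runif(1, 0.01, 5); b <- runif(1, 0.01, 5)
    mix <- nir_spectrum(grid_900_1200, a * s1$intensity + b * s2$intensity)
    pm <- spectral_phasor(mix, w)
    expect_equal(pm$G, (a * w1 * p1$G + b * w2 * p2$G) / (a * w1 + b * w2),
                 tolerance = 1e-9)
    expect_equal(pm$S, (a * w1 * p1$S + b * w2 * p2$S) / (a * w1 + b * w2),
                 tolerance = 1e-9)
  }
})

test_that("modulus is below 1 for broad spectra and 1 only for monochromatic", {
  w <- win_900_1200
  for (fwhm in c(5, 15, 60, 150)) {
    p <- spectral_phasor(gaussian_line(1020, fwhm, 1, grid = grid_900_1200), w)
    expect_lte(p$M, 1 + 1e-12)
    expect_lt(p$M, 1)   # strictly below for any finite width
  }
  on_grid_delta <- nir_spectrum(grid_900_1200,
                                as.numeric(grid_900_1200 == 1000))
  expect_equal(spectral_phasor(on_grid_delta, w)$M, 1, tolerance = 1e-12)
})

test_that("phasor through ideal curves equals the exact transform", {
  w <- win_900_1200
  curves <- ideal_filter_set(w, grid_900_1200)
  for (pk in c(950, 1050, 1150)) {
    s <- gaussian_line(pk, 25, 1, grid = grid_900_1200)
    a <- phasor_through_filters(s, curves)
    b <- spectral_phasor(s, w)
    expect_equal(a$G, b$G, tolerance = 1e-12)
    expect_equal(a$S, b$S, tolerance = 1e-12)
  }
})

test_that("calibrated (chirped) filters displace narrow lines, less so red-ward", {
  # a 100 nm window realized by real retardance curves displaces a probe
  # line from its ideal position; the displacement shrinks as the window
  # center moves red at fixed width (the chirp flattens)
  disp <- vapply(c(950, 1150, 1450), function(c0) {
    w <- spectral_window(c0 - 50, c0 + 50)
    st <- calibrated_filter_set(w, retarder_model(Inf))
    grid <- wavelength_grid(w, 0.5)
    curves <- lapply(st, realized_curve, grid = grid)
    s <- gaussian_line(c0 - 20, 5, 1, grid = grid)
    a <- phasor_through_filters(s, curves, signs_of(st))
    b <- spectral_phasor(s, w)
    sqrt((a$G - b$G)^2 + (a$S - b$S)^2)
  }, numeric(1))
  expect_true(all(disp > 0))
  expect_true(all(diff(disp) < 0))
})

test_that("frame transform handles flat, monochromatic and guarded pixels", {
  tot <- matrix(100, 4, 4)
  p <- phasor_from_frames(tot / 2, tot / 2, tot, min_total = 1)
  expect_true(all(abs(p$G[p$valid]) < 1e-12 & abs(p$S[p$valid]) < 1e-12))
  # zero-total pixel is invalid, not NaN-propagating
  tot2 <- tot; tot2[1, 1] <- 0
  p2 <- phasor_from_frames(tot2 / 2, tot2 / 2, tot2, min_total = 1)
  expect_false(p2$valid[1, 1])
  expect_true(is.na(p2$G[1, 1]))
  expect_equal(sum(p2$valid), 15)
  # monochromatic pixel through ideal filters: modulus 1
  w <- win_900_1200
  x0 <- window_phase(1000, w)
  is_ <- matrix(100 * 0.5 * (1 + sin(x0)), 2, 2)
  ig <- matrix(100 * 0.5 * (1 + cos(x0)), 2, 2)
  p3 <- phasor_from_frames(is_, ig, matrix(100, 2, 2), min_total = 1)
  expect_equal(sqrt(p3$G[1, 1]^2 + p3$S[1, 1]^2), 1, tolerance = 1e-12)
  expect_equal(p3$G[1, 1], cos(x0), tolerance = 1e-12)
  expect_error(phasor_from_frames(matrix(1, 2, 2), matrix(1, 3, 3),
                                  matrix(1, 2, 2)), "shape")
  expect_warning(phasor_from_frames(tot / 2, tot / 2, tot, min_total = 1e9),
                 "no valid")
})

test_that("negating the sine sign flips S exactly; double negation is identity", {
  is_ <- matrix(c(30, 70, 55, 20), 2, 2)
  ig <- matrix(c(60, 10, 45, 80), 2, 2)
  it <- matrix(100, 2, 2)
  p_pos <- phasor_from_frames(is_, ig, it, signs = c(sine = 1, cosine = 1),
                              min_total = 1)
  p_neg <- phasor_from_frames(is_, ig, it, signs = c(sine = -1, cosine = 1),
                              min_total = 1)
  expect_equal(p_neg$S, -p_pos$S)
  expect_equal(p_neg$G, p_pos$G)
  p_back <- phasor_from_frames(is_, ig, it, signs = c(sine = -1, cosine = 1),
                               min_total = 1)
  expect_equal(p_back$S, p_neg$S)
})

test_that("distortion map is zero for ideal filters and its lookup corrects", {
  w <- win_900_1200
  ideal <- ideal_filter_set(w, wavelength_grid(w, 0.5))
  d0 <- distortion_map(w, ideal)
  expect_lt(max(d0$displacement), 1e-9)

  st <- calibrated_filter_set(w, retarder_model(10400))
  dm <- distortion_map(w, st)
  expect_gt(max(dm$displacement), 1e-3)
  # correction at the probe lines recovers the ideal points
  cor_at <- correct_phasor(dm$G_real, dm$S_real, dm)
  expect_lt(max(abs(cor_at$G - dm$G_ideal)), 1e-3)
  expect_lt(max(abs(cor_at$S - dm$S_ideal)), 1e-3)
  # off-knot line: correction removes >= 90% of the displacement
  grid <- wavelength_grid(w, 0.5)
  curves <- lapply(st, realized_curve, grid = grid)
  s <- gaussian_line(1003.7, 2, 1, grid = grid)
  real <- phasor_through_filters(s, curves, signs_of(st))
  ideal_p <- spectral_phasor(s, w)
  cor <- correct_phasor(real$G, real$S, dm)
  d_raw <- sqrt((real$G - ideal_p$G)^2 + (real$S - ideal_p$S)^2)
  d_cor <- sqrt((cor$G - ideal_p$G)^2 + (cor$S - ideal_p$S)^2)
  expect_lt(d_cor, 0.1 * d_raw)
})

test_that("spatial correction field recovers an injected tilt and zeroes a flat", {
  flat <- structure(list(G = matrix(0.4, 8, 8), S = matrix(0.1, 8, 8),
                         valid = matrix(TRUE, 8, 8)), class = "phasor_image")
  f0 <- estimate_correction_field(list(flat))
  expect_lt(max(abs(f0$dG)), 1e-12)
  # planar tilt injected into G
  tilt <- outer(seq(-0.05, 0.05, length.out = 8), rep(1, 8))
  tilted <- flat; tilted$G <- flat$G + tilt
  f1 <- estimate_correction_field(list(tilted))
  expect_equal(f1$dG, tilt - mean(tilt), tolerance = 1e-9)
  corrected <- apply_correction(tilted, f1)
  expect_lt(phasor_spread(corrected), phasor_spread(tilted))
  # too many invalid reference pixels is an error
  bad <- flat; bad$valid[, 1:5] <- FALSE
  expect_error(estimate_correction_field(list(bad)), "50%")
})

test_that("angular colour coding wraps at +/- pi and separates clusters", {
  p <- structure(list(G = matrix(c(-1, -1, 1, 1), 2, 2),
                      S = matrix(c(0, -0, 0.5, 0.5), 2, 2),
                      valid = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)),
                 class = "phasor_image")
  # signed zeros give atan2 exactly +pi and -pi for the first two pixels
  idx <- angular_color(p, n_colors = 16)
  expect_identical(idx[1, 1], idx[2, 1])   # theta = pi and -pi: same colour
  expect_false(idx[1, 1] == idx[1, 2])     # distinct clusters differ
  expect_identical(idx[2, 2], 0L)          # invalid sentinel
})

test_that("polygon gating labels by even-odd membership with inclusive borders", {
  p <- structure(list(G = matrix(c(-0.5, 0.5, 0, 0.9), 2, 2),
                      S = matrix(c(0.5, 0.5, 0, 0.9), 2, 2),
                      valid = matrix(TRUE, 2, 2)), class = "phasor_image")
  all_poly <- list(everything = cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))
  lab <- polygon_gate(p, all_poly)
  expect_true(all(lab[p$valid] == 1))
  two <- list(left = cbind(c(-1, 0, 0, -1), c(-1, -1, 1, 1)),
              right = cbind(c(0.1, 1, 1, 0.1), c(-1, -1, 1, 1)))
  lab2 <- polygon_gate(p, two)
  expect_identical(as.vector(lab2), c(1L, 2L, 1L, 2L))  # boundary (0,0) inside left
})

test_that("phasor histogram conserves counts and localizes a point mass", {
  p <- structure(list(G = matrix(0.25, 3, 3), S = matrix(-0.25, 3, 3),
                      valid = matrix(c(rep(TRUE, 8), FALSE), 3, 3)),
                 class = "phasor_image")
  h <- phasor_histogram(p, bins = 8)
  expect_equal(sum(h$counts), 8)
  expect_equal(max(h$counts), 8)  # single point mass: one nonzero bin
})
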