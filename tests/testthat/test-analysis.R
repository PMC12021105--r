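test_that("two-endmember unmixing solves the segment geometry", {
  a <- phasor_point(-0.9, 0.1)
  b <- phasor_point(-0.5, 0.6)
  pair <- endmember_pair(a, b)
  expect_equal(unmix_two(a, pair)$fraction_b, 0)
  expect_equal(unmix_two(b, pair)$fraction_b, 1)
  mid <- phasor_point((a$G + b$G) / 2, (a$S + b$S) / 2)
  expect_equal(unmix_two(mid, pair)$fraction_b, 0.5)
  # off-segment point: clamped fraction, nonzero residual
  off <- phasor_point(mid$G + 0.1, mid$S - 0.08 * (b$G - a$G) / (b$S - a$S))
  expect_gt(unmix_two(off, pair)$residual, 0)
  expect_error(endmember_pair(a, a), "distinct")
  # brightness conversion: a dimmer b species is under-represented in
  # intensity, so its number fraction exceeds the intensity fraction
  pair_b <- endmember_pair(a, b, brightness_a = 1, brightness_b = 0.5)
  expect_gt(unmix_two(mid, pair_b)$number_fraction_b, 0.5)
  expect_equal(unmix_two(mid, pair_b)$number_fraction_b, 2 / 3)
})

test_that("noise-free mixtures unmix exactly across the fraction grid", {
  w <- win_900_1200
  s1 <- gaussian_line(990, 25, 1, grid = grid_900_1200)
  s2 <- gaussian_line(1040, 40, 1, grid = grid_900_1200)
  pair <- endmember_pair(spectral_phasor(s1, w), spectral_phasor(s2, w))
  for (fb in seq(0, 1, by = 0.05)) {
    mix <- nir_spectrum(grid_900_1200,
                        (1 - fb) * s1$intensity + fb * s2$intensity)
    expect_equal(unmix_two(spectral_phasor(mix, w), pair)$fraction_b, fb,
                 tolerance = 1e-6)
  }
})

test_that("median filter removes impulses and is exact against brute force", {
  const <- matrix(5, 6, 6)
  expect_equal(median_filter2d(const, c(3, 3)), const)
  imp <- const; imp[3, 3] <- 1000
  expect_equal(median_filter2d(imp, c(3, 3)), const)
  # brute-force oracle with edge replication on random images
  set.seed(7)
  for (rep in 1:5) {
    img <- matrix(rnorm(16 * 16), 16, 16)
    got <- median_filter2d(img, c(3, 3))
    want <- img
    for (i in 1:16) for (j in 1:16) {
      ri <- pmin(pmax((i - 1):(i + 1), 1), 16)
      cj <- pmin(pmax((j - 1):(j + 1), 1), 16)
      want[i, j] <- median(as.vector(img[ri, cj]))
    }
    expect_equal(got, want)
  }
  expect_error(median_filter2d(const, c(2, 2)), "odd")
})

test_that("background subtraction clamps at zero and order matters", {
  f <- list(sine = matrix(40, 2, 2), cosine = matrix(60, 2, 2),
            total = matrix(100, 2, 2))
  b <- list(sine = matrix(10, 2, 2), cosine = matrix(10, 2, 2),
            total = matrix(20, 2, 2))
  zero <- background_subtract(f, f)
  expect_true(all(zero$total == 0))
  ident <- background_subtract(f, lapply(b, function(x) x * 0))
  expect_identical(ident, f)
  sub <- background_subtract(f, b)
  expect_equal(sub$sine[1, 1], 30)
  # subtracting before the division differs from subtracting G/S afterwards
  p_before <- phasor_from_frames(sub$sine, sub$cosine, sub$total, min_total = 1)
  p_after <- phasor_from_frames(f$sine, f$cosine, f$total, min_total = 1)
  expect_false(isTRUE(all.equal(p_before$G[1, 1], p_after$G[1, 1])))
})

test_that("reference phasor averages the initial span and shrinks as 1/sqrt(n)", {
  mk <- function(g, s, valid = TRUE) {
    structure(list(G = matrix(g, 3, 3), S = matrix(s, 3, 3),
                   valid = matrix(valid, 3, 3)), class = "phasor_image")
  }
  series <- lapply(1:10, function(i) mk(0.2, -0.1))
  tme <- seq(0, 45, by = 5)
  ref <- reference_phasor(series, tme, t_ref = 25)
  expect_equal(ref$G, matrix(0.2, 3, 3))
  expect_equal(ref$provenance$n_frames, 5)
  # full-span reference is the global temporal mean
  drift <- lapply(1:10, function(i) mk(i / 10, 0))
  ref_all <- reference_phasor(drift, tme, t_ref = 50)  # span + one period
  expect_equal(ref_all$G[1, 1], mean((1:10) / 10))
  expect_error(reference_phasor(series, tme, t_ref = 100), "shorter")
  expect_error(reference_phasor(series, tme, t_ref = 60), "shorter")
  # noisy constant series: reference SD scales as 1/sqrt(n_frames)
  sd_of <- function(n) {
    set.seed(n)
    noisy <- lapply(1:n, function(i) mk(0.2 + rnorm(9, 0, 0.05), 0))
    r <- reference_phasor(noisy, seq(0, by = 5, length.out = n), t_ref = 5 * n)
    sd(r$G)
  }
  expect_equal(sd_of(64) / sd_of(4), sqrt(4 / 64), tolerance = 0.5)
})

test_that("displacement is the per-pixel Euclidean distance to the reference", {
  ref <- structure(list(G = matrix(0.3, 2, 2), S = matrix(0.3, 2, 2),
                        valid = matrix(TRUE, 2, 2)), class = "phasor_image")
  same <- phasor_displacement(list(ref), ref)
  expect_true(all(same == 0))
  shifted <- ref; shifted$G <- ref$G + 0.25
  expect_equal(as.vector(phasor_displacement(list(shifted), ref)),
               rep(0.25, 4), tolerance = 1e-12)
  # a point circling the reference at radius r keeps d = r
  r <- 0.4
  circle <- lapply(seq(0, 2 * pi, length.out = 7), function(a) {
    p <- ref; p$G <- ref$G + r * cos(a); p$S <- ref$S + r * sin(a); p
  })
  expect_equal(as.vector(phasor_displacement(circle, ref)),
               rep(r, 7 * 4), tolerance = 1e-12)
})

test_that("rate of change recovers exact and noisy slopes in trailing windows", {
  tme <- seq(0, 1200, by = 5)
  ramp <- array(rep(2e-4 * tme, each = 4), c(2, 2, length(tme)))
  rc <- rate_of_change(ramp, tme, window = 600)
  expect_equal(as.vector(rc$slope), rep(2e-4, length(rc$slope)),
               tolerance = 1e-12)
  flat <- array(0.3, c(2, 2, length(tme)))
  expect_true(all(rate_of_change(flat, tme, window = 600)$slope == 0))
  # invariance to a global time shift
  rc_shift <- rate_of_change(ramp, tme + 12345, window = 600)
  expect_equal(rc_shift$slope, rc$slope)
  expect_error(rate_of_change(ramp, tme, window = 1e9), "shorter")

  # noisy ramp: slope estimates distribute as OLS sampling theory predicts
  a_true <- 1e-3; sigma <- 0.02
  tt <- seq(0, 600, by = 5); n <- length(tt)
  se_theory <- sigma / sqrt(sum((tt - mean(tt))^2))
  est <- vapply(1:100, function(s) {
    set.seed(s)
    d <- array(a_true * tt + rnorm(n, 0, sigma), c(1, 1, n))
    rate_of_change(d, tt, window = 600)$slope[1, 1, 1]
  }, numeric(1))
  z <- abs(est - a_true) / se_theory
  expect_gte(sum(z < 3), 98)        # ~99.7% expected within 3 sigma
  expect_true(all(z < 5))
  expect_equal(mean(est), a_true, tolerance = 3 * se_theory / sqrt(100) / a_true)
  expect_equal(sd(est), se_theory, tolerance = 0.2)
})

test_that("rate normalization pools all frames at the 99th percentile", {
  tme <- seq(0, 1200, by = 5)
  ramp <- array(rep(5e-4 * tme, each = 4), c(2, 2, length(tme)))
  rc <- normalize_rates(rate_of_change(ramp, tme, window = 600))
  expect_equal(rc$normalization_constant, 5e-4)
  expect_true(all(abs(rc$normalized - 1) < 1e-9))
  # dominant-value mixture: constant equals the dominant slope
  slopes <- array(c(rep(1, 995), rep(2, 5)), c(1, 1, 1000))
  fake <- list(slope = slopes)
  expect_equal(normalize_rates(fake, probs = 0.99)$normalization_constant, 1)
  # pooled percentile invariant under frame permutation
  set.seed(3)
  perm <- list(slope = slopes[, , sample(1000), drop = FALSE])
  expect_equal(normalize_rates(perm)$normalization_constant, 1)
})

test_that("water uptake in veins shows up before the lamina end to end", {
  vein <- matrix(FALSE, 10, 10); vein[, 5] <- TRUE
  onset <- matrix(500, 10, 10); onset[vein] <- 250
  ser <- water_uptake_series(c(10, 10), onset, rate = matrix(1 / 300, 10, 10),
                             frame_period = 5, duration = 1500)
  w <- spectral_window(900, 1600)
  st <- ideal_filter_set(w, ser$frames[[1]]$wavelength)
  cam <- camera_model(exposure = 0.007)
  phs <- lapply(seq_along(ser$frames), function(i) {
    f <- acquire_stack(ser$frames[[i]], st, cam, seed = 100 + i)
    phasor_from_frames(f$sine, f$cosine, f$total)
  })
  ref <- reference_phasor(phs, ser$time, t_ref = 300)
  disp <- phasor_displacement(phs, ref)
  rc <- normalize_rates(rate_of_change(disp, ser$time, window = 600))
  peak_t <- apply(rc$normalized, c(1, 2), function(x) rc$time[which.max(x)])
  expect_lt(mean(peak_t[vein]), mean(peak_t[!vein]))
})
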