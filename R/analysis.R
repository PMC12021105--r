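#' Endmember pair for two-component unmixing
#'
#' @param phasor_a,phasor_b [phasor_point()]s of the two pure components;
#'   must be separated by more than 1e-6.
#' @param brightness_a,brightness_b Optional relative in-window intensities
#'   per unit amount of each component (equal by default); used to convert
#'   intensity fractions into number fractions.
#' @return Object of class `endmember_pair`.
#' @export
endmember_pair <- function(phasor_a, phasor_b,
                           brightness_a = 1, brightness_b = 1) {
  sep <- sqrt((phasor_a$G - phasor_b$G)^2 + (phasor_a$S - phasor_b$S)^2)
  if (!is.finite(sep) || sep <= 1e-6) stop("endmembers must be distinct")
  if (brightness_a <= 0 || brightness_b <= 0) stop("brightnesses must be positive")
  structure(list(a = phasor_a, b = phasor_b,
                 brightness_a = brightness_a, brightness_b = brightness_b),
            class = "endmember_pair")
}

#' Two-endmember phasor unmixing
#'
#' Because the phasor of a mixture is the intensity-weighted mean of the
#' component phasors, a two-component mixture lies on the segment between
#' the endmember points, at a position equal to the in-window intensity
#' fraction of component b. The estimator projects each phasor point
#' orthogonally onto that segment: the projection parameter (clamped to
#' `[0, 1]`) is the intensity fraction of b, and the off-segment residual
#' distance is reported as a quality metric. With endmember brightnesses
#' supplied, the intensity fraction `t` converts to the number fraction
#' `f_b = (t / brightness_b) / (t / brightness_b + (1 - t) / brightness_a)`.
#'
#' @param phasor A [phasor_point()] or `phasor_image`.
#' @param pair An [endmember_pair()].
#' @return For a point: list with `fraction_b` (intensity fraction),
#'   `number_fraction_b` and `residual`. For an image: the same as matrices
#'   (NA at invalid pixels).
#' @examples
#' a <- phasor_point(-0.9, 0.1); b <- phasor_point(-0.5, 0.6)
#' unmix_two(phasor_point(-0.7, 0.35), endmember_pair(a, b))$fraction_b  # 0.5
#' @export
unmix_two <- function(phasor, pair) {
  ab_g <- pair$b$G - pair$a$G
  ab_s <- pair$b$S - pair$a$S
  len2 <- ab_g^2 + ab_s^2
  solve_pt <- function(G, S) {
    t_raw <- ((G - pair$a$G) * ab_g + (S - pair$a$S) * ab_s) / len2
    t <- pmin(pmax(t_raw, 0), 1)
    proj_g <- pair$a$G + t_raw * ab_g
    proj_s <- pair$a$S + t_raw * ab_s
    res <- sqrt((G - proj_g)^2 + (S - proj_s)^2)
    fb <- (t / pair$brightness_b) /
      (t / pair$brightness_b + (1 - t) / pair$brightness_a)
    list(fraction_b = t, number_fraction_b = fb, residual = res)
  }
  if (inherits(phasor, "phasor_point")) {
    return(solve_pt(phasor$G, phasor$S))
  }
  out <- solve_pt(phasor$G, phasor$S)
  lapply(out, function(m) {
    m[!phasor$valid] <- NA_real_
    matrix(m, nrow(phasor$G), ncol(phasor$G))
  })
}

#' 2D median filter with edge replication
#'
#' Standard sliding-window median used to suppress single-pixel outliers in
#' intensity and phasor images (typical windows: 3x3, or 9x9 for rough
#' samples). Edges are handled by replicating the border pixels.
#'
#' @param image Numeric matrix (or [intensity_image()]).
#' @param window Odd integer window size, scalar or length-2 `c(rows, cols)`.
#' @return Filtered matrix (or [intensity_image()], matching the input).
#' @export
median_filter2d <- function(image, window = c(3, 3)) {
  img <- if (inherits(image, "intensity_image")) image$data else as.matrix(image)
  if (length(window) == 1L) window <- c(window, window)
  if (any(window %% 2 == 0) || any(window < 1)) {
    stop("window sizes must be odd and positive")
  }
  hr <- (window[1] - 1) / 2
  hc <- (window[2] - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[pmin(pmax(seq(1 - hr, nr + hr), 1), nr),
             pmin(pmax(seq(1 - hc, nc + hc), 1), nc), drop = FALSE]
  stack <- matrix(NA_real_, nr * nc, window[1] * window[2])
  k <- 0L
  for (dc in 0:(window[2] - 1)) {
    for (dr in 0:(window[1] - 1)) {
      k <- k + 1L
      stack[, k] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
    }
  }
  med <- apply(stack, 1, stats::median)
  out <- matrix(med, nr, nc)
  if (inherits(image, "intensity_image")) { image$data <- out; return(image) }
  out
}

#' Background subtraction of a frame triplet
#'
#' Subtracts per-filter background frames (excitation bleed-through and dark
#' signal) from the sine/cosine/total frames, clamping at zero. Subtraction
#' happens on the frames, before the phasor division, so the background does
#' not bias the ratio.
#'
#' @param frames Named list of [intensity_image()]s or matrices
#'   (`sine`, `cosine`, `total`).
#' @param background Same structure, same shapes.
#' @return The background-subtracted frames (same structure as `frames`).
#' @export
background_subtract <- function(frames, background) {
  stopifnot(all(c("sine", "cosine", "total") %in% names(frames)),
            all(c("sine", "cosine", "total") %in% names(background)))
  out <- frames
  for (k in c("sine", "cosine", "total")) {
    f <- frames[[k]]; b <- background[[k]]
    fm <- if (inherits(f, "intensity_image")) f$data else as.matrix(f)
    bm <- if (inherits(b, "intensity_image")) b$data else as.matrix(b)
    if (!all(dim(fm) == dim(bm))) stop("background shape mismatch for ", k)
    sub <- pmax(fm - bm, 0)
    if (inherits(f, "intensity_image")) out[[k]]$data <- sub else out[[k]] <- sub
  }
  out
}

#' Per-pixel reference phasor over an initial time span
#'
#' Averages G and S per pixel over the frames whose timestamp is below
#' `t_ref` (default 300 s: the first 5 minutes of a dry-state recording),
#' producing the reference position against which later displacement is
#' measured. A pixel invalid in more than half of the reference frames is
#' invalid throughout.
#'
#' @param series List of `phasor_image`s.
#' @param time Numeric timestamps (s), same length as `series`.
#' @param t_ref Reference span in s.
#' @return A `phasor_image` holding the per-pixel reference (G0, S0).
#' @export
reference_phasor <- function(series, time, t_ref = 300) {
  if (length(series) != length(time)) stop("series and time lengths differ")
  period <- if (length(time) > 1L) stats::median(diff(time)) else 0
  if (max(time) - min(time) + period < t_ref) {
    stop("series is shorter than t_ref")
  }
  sel <- which(time - min(time) < t_ref)
  if (length(sel) == 0L) stop("no frames inside the reference span")
  g <- s <- nv <- 0
  for (i in sel) {
    p <- series[[i]]
    gi <- p$G; gi[!p$valid] <- 0
    si <- p$S; si[!p$valid] <- 0
    g <- g + gi; s <- s + si; nv <- nv + p$valid
  }
  valid <- nv > length(sel) / 2
  G <- g / pmax(nv, 1); G[!valid] <- NA_real_
  S <- s / pmax(nv, 1); S[!valid] <- NA_real_
  structure(list(G = G, S = S, valid = valid,
                 provenance = list(t_ref = t_ref, n_frames = length(sel))),
            class = "phasor_image")
}

#' Per-pixel phasor displacement from a reference
#'
#' Euclidean distance in phasor space between each frame's per-pixel phasor
#' and the per-pixel reference position.
#'
#' @param series List of `phasor_image`s.
#' @param reference A `phasor_image` from [reference_phasor()].
#' @return 3D array (rows, cols, frames) of distances (NA where either the
#'   frame pixel or the reference is invalid).
#' @export
phasor_displacement <- function(series, reference) {
  d <- dim(reference$G)
  out <- array(NA_real_, c(d[1], d[2], length(series)))
  for (i in seq_along(series)) {
    p <- series[[i]]
    ok <- p$valid & reference$valid
    di <- matrix(NA_real_, d[1], d[2])
    di[ok] <- sqrt((p$G[ok] - reference$G[ok])^2 +
                   (p$S[ok] - reference$S[ok])^2)
    out[, , i] <- di
  }
  out
}

#' Sliding-window rate of change of the phasor displacement
#'
#' Per pixel and per frame, the ordinary least-squares slope of displacement
#' versus time over the trailing window ending at that frame (default
#' 600 s = 10 min). Outputs begin once a full window of data exists; at
#' least 3 frames per window are required. Negative slopes are permitted.
#' Invariant to a global shift of the timestamps.
#'
#' @param displacement 3D array from [phasor_displacement()].
#' @param time Frame timestamps in s.
#' @param window Trailing window length in s (default 600).
#' @return List with `slope` (3D array, rows x cols x n_out, in phasor
#'   units per second), `time` (timestamp of each output frame).
#' @export
rate_of_change <- function(displacement, time, window = 600) {
  nt <- dim(displacement)[3]
  if (length(time) != nt) stop("time length must match frames")
  d <- dim(displacement)
  flat <- matrix(displacement, nrow = d[1] * d[2])
  out_idx <- which(time - min(time) >= window)
  if (length(out_idx) == 0L) stop("series shorter than the regression window")
  slopes <- array(NA_real_, c(d[1], d[2], length(out_idx)))
  for (j in seq_along(out_idx)) {
    i2 <- out_idx[j]
    sel <- which(time > time[i2] - window & time <= time[i2])
    if (length(sel) < 3L) stop("fewer than 3 frames inside a window")
    tt <- time[sel] - mean(time[sel])
    y <- flat[, sel, drop = FALSE]
    n_ok <- rowSums(!is.na(y))
    y0 <- y; y0[is.na(y0)] <- 0
    ok <- !is.na(y)
    # per-pixel OLS slope allowing for scattered NAs:
    # slope = sum((t - tbar_i) * y) / sum((t - tbar_i)^2) with pixel-wise tbar
    tmat <- matrix(tt, nrow = nrow(y), ncol = length(sel), byrow = TRUE)
    tmat[!ok] <- NA
    tbar <- rowMeans(tmat, na.rm = TRUE)
    tc <- tmat - tbar
    num <- rowSums(tc * y, na.rm = TRUE)
    den <- rowSums(tc^2, na.rm = TRUE)
    sl <- num / den
    sl[n_ok < 3L | den == 0] <- NA_real_
    slopes[, , j] <- matrix(sl, d[1], d[2])
  }
  list(slope = slopes, time = time[out_idx], window = window)
}

#' Normalize rate maps by the pooled 99th percentile
#'
#' Divides all slopes by the normalization constant defined as the 99th
#' percentile (linear interpolation between order statistics) of the valid
#' slopes pooled over all frames and pixels.
#'
#' @param rates Result of [rate_of_change()].
#' @param probs Percentile used for normalization (default 0.99).
#' @return `rates` with an added `normalized` array and
#'   `normalization_constant`.
#' @export
normalize_rates <- function(rates, probs = 0.99) {
  pool <- rates$slope[!is.na(rates$slope)]
  if (length(pool) == 0L) stop("no valid slopes to normalize")
  const <- unname(stats::quantile(pool, probs, type = 7))
  if (const <= 0) stop("normalization constant must be positive")
  rates$normalized <- rates$slope / const
  rates$normalization_constant <- const
  rates
}
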