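---
title: "Spectral-phasor NIR imaging: model, noise and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-phasor NIR imaging: model, noise and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirphasor)
```

# The measurement model

A spectrum $I(\lambda)$ observed over a window $[\lambda_\min, \lambda_\max]$
is summarized by its first-harmonic Fourier coordinates with the window
phase $x(\lambda) = 2\pi(\lambda - \lambda_\min)/(\lambda_\max - \lambda_\min)$:

$$G = \frac{\int I \cos x \, d\lambda}{\int I \, d\lambda}, \qquad
  S = \frac{\int I \sin x \, d\lambda}{\int I \, d\lambda}.$$

`spectral_phasor()` computes this directly (trapezoid rule on the spectrum's
grid) and serves as the oracle for everything else. The optical route
estimates the same coordinates from three filtered camera frames,
$S = 2 I_S / I_{\mathrm{total}} - 1$ and $G = 2 I_G/I_{\mathrm{total}} - 1$,
because a filter $T = \tfrac12(1 + \cos x)$ turns the ratio of filtered to
total intensity into $\tfrac12(1 + G)$. Useful consequences, all enforced by
tests:

* $M = \sqrt{G^2 + S^2} \le 1$ for ideal single-order filters, with equality
  exactly for monochromatic input;
* the phasor of a mixture is the intensity-weighted mean of the component
  phasors (the geometric basis of `unmix_two()`);
* narrowing the window magnifies the separation of nearby peaks
  ("spectral zoom").

## The filter stack and its chirp

The physical filter is a retarder between parallel polarizers at 45° to the
fast axis: $T(R,\lambda) = \tfrac12(1 + \cos(2\pi R/\lambda))$
(`transmission()`, derived as a special case of the general Jones product in
`jones_transmission()`; light polarized along the fast axis only acquires a
global phase, so that configuration transmits fully). Setting $R = 0$ gives
the flat total-transmission frame used for normalization.

$\cos(2\pi R/\lambda)$ is a cosine in $1/\lambda$, not in $\lambda$: across a
window it is a chirped wave. `calibrate_retardance()` therefore searches
$R \in [0, R_\max]$ for the best Pearson correlation against the ideal
target, evaluating both the positive and the negated target. Because the
negated target is an affine flip, the correlation only changes sign, so the
search reduces to recording the sign of $r$ at the optimum; the sign is
folded back in the phasor transform, mirroring how a physically "negated"
filter would be handled in an acquisition pipeline. The search uses 5 nm
steps refined by golden-section search around the best coarse point, with
ties broken toward the smallest retardance; it is fully deterministic. One
full period across $[\lambda_\min, \lambda_\max]$ needs
$R = 1/(1/\lambda_\min - 1/\lambda_\max)$, so searching to twice that value
covers every distinct phase alignment when the retarder allows it.

Two regimes matter:

* **Wide windows, unbounded retarder.** The chirp is the only error. The fit
  improves as the window's *relative* width $\Delta\lambda/\lambda_c$
  shrinks, which is why the cosine $r^2$ rises monotonically as a fixed
  100 nm window slides red-ward (a property test asserts this over centers
  950–1450 nm).
* **Narrow windows, capped retarder.** A 50 nm window near 1050 nm needs
  $R \approx 22\,\mu$m for a full period; a 10.4 µm device reaches barely
  half a period, so the fit quality drops and the sine target (which needs a
  quarter-period offset) suffers more than the cosine. With the package's
  dispersionless retarder the best fits at 1025–1075 nm are
  $r^2 \approx 0.94$ (cosine) and $\approx 0.67$ (sine). Published values
  for a real device at this window are 0.96 and 0.82: the cosine agrees
  closely, while the sine gap is attributable to birefringence dispersion
  $\Delta n(\lambda)$, which steepens the phase sweep across a narrow window
  and which real devices have but this model deliberately omits (no public
  dispersion curve exists for the device class; a user can supply one via
  `retarder_model(birefringence = ...)`).

The residual chirp displaces phasor points ("the realized point is not the
ideal point"). `distortion_map()` tabulates ideal vs realized positions for
narrow probe lines; since the realized phase is monotone in wavelength for
single-order filters, interpolating displacement against realized phase
gives an invertible look-up correction (`correct_phasor()`) that removes
$\ge 90\%$ of the displacement between probe lines. The correction is
optional and off by default, since gating and unmixing work in realized
coordinates as long as endmembers and samples share the same filters.

# Camera noise model

`camera_model()` implements the standard linear (EMVA-1288 style) model: the
variance of the digitized signal is

$$\sigma_y^2 = K^2(\sigma_d^2 + \sigma_q^2) + K(\mu_y - \mu_{y,\mathrm{dark}}),$$

a signal-independent floor (read + quantization noise) plus a shot-noise
term linear in the signal. Defaults describe a cooled InGaAs sensor in a
deep-full-well mode: $K = 1.1\times10^{-3}$ DN/e⁻, RMS read noise 1000 e⁻
(`read_noise_var` $= 10^6$ e⁻²), $\sigma_q^2 = 1/12$ DN², QE 0.56, pixel
area $9\times10^{-6}$ cm², 3 s exposure, 12-bit ADC, dark offset 0 (dark and
background are assumed subtracted upstream, which is also why
`background_subtract()` operates on frames *before* the phasor division).
A note on units: sensor datasheets quote read noise as an RMS electron
count; with $K \approx 10^{-3}$ DN/e⁻ a floor of $10^6$ e⁻² (≈1.1 DN) is
what makes read noise matter at all at low signal, and it is the value that
reproduces the observed photon-flux limit of the method (below). Quoting
the same number as a variance of $10^3$ e⁻² would make the floor physically
negligible ($10^{-3}$ DN²) and move the photon limit down by two decades.

`acquire_frame()` integrates each pixel spectrum against
transmission × QE (trapezoid), converts to expected DN, draws a Gaussian
with the model variance, clips to the ADC range and rounds half-to-even.
The noise is Gaussian by construction, not compound Poisson — shot noise
enters only through the linear variance term — which is exactly the model
regime the variance law describes and keeps the simulated spread analyzable
in closed form. `predicted_phasor_spread()` propagates the three frame
variances to first order through the phasor ratio,

$$\mathrm{Var}(S) \approx 4\left(\frac{\sigma_S^2}{\mu_T^2}
  + \frac{\mu_S^2 \sigma_T^2}{\mu_T^4}\right),$$

and a Monte-Carlo test at $10^5$ pixels confirms agreement within 10%
(with the unit-circle rejection disabled — the rejection truncates noise
tails and would bias the comparison). The cluster-spread statistic itself
(`phasor_spread()`) is the sum of the G and S standard deviations over
valid pixels. Under the default camera it crosses 0.5 — the operational
"no identifiable cluster" criterion adopted here, since no quantitative
criterion is standard — at a photon flux of order $10^9$
photons s⁻¹ cm⁻², and the acceptance test verifies both the decade and its
insensitivity (within one decade) to criterion choices 0.3–0.7.

# Synthetic data

All generators are deterministic given their arguments; randomness enters
only at camera acquisition, always under an explicit seed.

* `gaussian_line()` — monochromator-like lines (default use: 15 nm FWHM),
  renormalized to a requested total flux on the grid.
* `fluorophore_spectrum()` / `emitter_presets()` — five narrow-band
  chirality-like emitters spanning 950–1120 nm with one 5 nm-apart pair,
  plus a red-shifted, broadened "defect" variant (990 → 1040 nm, wider).
  These are analytic fixtures — parameterized stand-ins with realistic
  positions and widths, not digitized measurements.
* `reflectance_spectrum()` — two polymers identical below 1400 nm but with
  distinct overtone dips in 1400–1600 nm, and a leaf model: a scattering
  plateau multiplied by $\exp(-2.5\,f_w\,B(\lambda))$ with a Gaussian water
  band $B$ centered at 1450 nm (σ = 60 nm, zeroed below 1350 nm so the
  short-NIR plateau is exactly water-independent). The factor 2.5 makes a
  fully hydrated leaf absorb strongly but not totally at 1450 nm.
  Reflectance illumination defaults to $10^{11}$
  photons s⁻¹ cm⁻² nm⁻¹ — a bright halogen-lamp regime where millisecond
  exposures give thousands of DN, as in label-free imaging practice.
* `render_scene()` / `water_uptake_series()` — disk/polygon regions bound to
  spectra; the time series ramps each pixel's water fraction linearly from a
  per-pixel onset at a per-pixel rate, clamped to [0, 1], at 0.2 cubes/s
  (5 s frame period) by default.

What the generators do **not** emulate: radiative-transfer leaf optics,
fluorescence excitation and quantum-yield physics, calibrated polymer
spectra, spatial drift, or fixed-pattern sensor artifacts. Passing tests
therefore demonstrate the *pipeline's* correctness and noise behaviour
under controlled spectra, not quantitative agreement with any particular
real sample.

# Downstream analyses

**Unmixing.** With endmember phasors $a, b$, `unmix_two()` projects each
point orthogonally onto the segment $a \to b$; the clamped projection
parameter is the in-window intensity fraction of $b$ (exact for noise-free
mixtures, by phasor linearity), and the off-segment residual is a quality
metric. An optional brightness pair converts intensity fractions to number
fractions via $f_b = (t/\beta_b) / (t/\beta_b + (1-t)/\beta_a)$; the
default reports intensity fractions, the convention being documented rather
than guessed since different communities normalize differently.

**Validity and gating.** `phasor_from_frames()` invalidates pixels whose
total signal falls below `min_total` (default `max(10 DN, 1%` of the image
maximum) — a threshold is needed because the ratio diverges at zero signal,
and 10 DN ≈ 9× the read-noise floor in DN) and pixels beyond the unit
circle by more than 0.05 (noise can push slightly past $M = 1$; anything
further is an artifact). Gates are closed polygons in (G, S) with
boundary-inclusive even–odd membership (`pracma::inpolygon`), so gate
definitions are portable. Angular colour coding wraps at $\pm\pi$.

**Spatial correction.** Retarders are spatially inhomogeneous; repeated
acquisitions of a spectrally uniform reference yield per-pixel offsets
$\Delta G = G_{\mathrm{ref}} - \overline{G_{\mathrm{ref}}}$ (likewise S)
that `apply_correction()` subtracts. Offsets are *additive*: additive
fields preserve cluster shapes and are exactly invertible, which is the
conservative choice when the true device behaviour is unknown.

**Time series.** `reference_phasor()` averages the first 5 min (default)
per pixel; displacement is the per-pixel Euclidean distance to that
reference; `rate_of_change()` fits an OLS slope over a trailing 600 s
window (trailing, because it matches causal monitoring — outputs exist once
a full window of history does; a minimum of 3 frames per window is
enforced); `normalize_rates()` divides by the 99th percentile (linear
interpolation between order statistics, `quantile(type = 7)`) of all valid
slopes pooled over frames and pixels. All operators are invariant to a
global time shift.

# Numerical choices and problem sizes

* Wavelength grids default to 1 nm spacing (5 nm for the leaf series, whose
  narrowest feature is the 60 nm water band); integration is trapezoid
  throughout. Closed-form checks agree to ~$10^{-4}$, limited by grid
  discretization and window truncation of Gaussian tails, and the noise-free
  pipeline agrees with the exact transform to $10^{-9}$.
* Quantization is round-half-to-even to $[0, 2^{\mathrm{bits}}-1]$; clipped
  pixel counts are reported on the frame object.
* Degenerate inputs fail loudly: windows with < 3 grid points, zero
  in-window intensity, coincident endmembers, non-monotone lookup tables,
  out-of-range voltages (no extrapolation). A zero-range retarder collapses
  calibration to the total filter, flagged `degenerate`.
* Test and acceptance workloads are sized for interactive runs: Monte-Carlo
  noise checks use $10^5$ pixels, scene-level oracle equivalence 64×64
  pixels, the separability sweep 100 pixels per species, and the leaf series
  10×10 pixels × 300 frames; the full suite runs in well under a minute.

# Known limitations

* The retarder is dispersionless by default; narrow-window sine fits for
  real devices are better than the model predicts (see above).
* Multi-order filters are supported at acquisition and calibration, but the
  phasor is always computed from one sine/cosine pair, so multi-order
  phasors are non-injective by construction.
* The look-up distortion correction is derived from narrowband probes and
  is only approximate for broadband spectra.
* Gaussian (not compound-Poisson) noise; no fixed-pattern noise,
  nonlinearity, or dark drift.
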