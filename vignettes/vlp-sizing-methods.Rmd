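---
title: "Methods: sizing virus-like particles from mobility spectra and cryo-TEM averages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sizing virus-like particles from mobility spectra and cryo-TEM averages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlpsizer)
```

`vlpsizer` implements two independent sizing chains for quasi-spherical
virus-like particles (VLPs) of the adeno-associated-virus class (~25 nm
capsids), plus the seeded synthetic generators that make both chains testable
without instrument data. This vignette explains the models, the tunable
parameters, the numerical choices, and what the tests do and do not establish.

## 1. DMA physics: from classifier voltage to EM diameter

A nano differential mobility analyzer (DMA) is a coaxial-cylinder capacitor:
a sheath flow $Q_{sh}$ carries charged particles axially while a radial field
set by the classifier voltage $V$ deflects them. For electrode radii $r_1 <
r_2$ and effective length $L$, the transfer-function centroid transmits the
electrical mobility

$$Z^*(V) = \frac{Q_{sh}\,\ln(r_2/r_1)}{2 \pi L V}.$$

The electrophoretic-mobility (EM) diameter of a singly charged sphere follows
from the Stokes–Millikan relation

$$Z(d) = \frac{n e\, C(d)}{3 \pi \mu d}, \qquad
C(d) = 1 + \mathrm{Kn}\left(A_1 + A_2 e^{-A_3/\mathrm{Kn}}\right),
\quad \mathrm{Kn} = 2\lambda/d,$$

with $C$ the Cunningham slip correction. `diameter_from_mobility()` inverts
$Z(d)$ by bisection on the fixed bracket $[0.1\,\mathrm{nm}, 10\,\mu\mathrm{m}]$
to relative tolerance $10^{-12}$ — derivative-free and deterministic, and
$Z(d)$ is strictly monotone on the bracket so the root is unique.

Defaults (all overridable): nano-DMA geometry $r_1 = 0.937$ cm, $r_2 = 1.905$
cm, $L = 4.987$ cm (published constants of the named classifier column); air
at 296.15 K and 101.325 kPa with $\mu = 1.83245\times10^{-5}$ Pa s,
$\lambda = 67.3$ nm, $(A_1, A_2, A_3) = (1.165, 0.483, 0.997)$ (the modern
slip parameterization used by aerosol instrumentation); scan endpoints
10 V–10 kV. With a sheath flow of $2.5\times10^{-4}$ m$^3$/s these choices
map the scan to a measurable EM-diameter range of about 1.91–65.6 nm,
reproducing the instrument's nominal 1.95–64.9 nm range within 2%. The
voltage endpoints and the vendor's exact slip constants are not public; the
defaults reproduce the nominal range but are not asserted to be the vendor's.

## 2. Mobility spectra: median, peak fit, counts, statistics

Repeated up-scans of one sample are combined channel-wise by the **median**
(`assemble_median_spectrum()`), the convention for suppressing electrospray
artifacts: up to $\lfloor (n-1)/2 \rfloor$ corrupted scans of $n$ cannot move
any channel outside the clean scans' range. Channel grids must agree exactly
(after rounding to 0.01 nm); mismatches are an error, never silently
interpolated.

The monomer peak is fit by least squares as Gaussian plus constant baseline
(`fit_gaussian_peak()`), restricted to a window (default 20–32 nm around the
~25 nm monomer). Starting values are robust heuristics: mean at the argmax
channel, sigma from FWHM/2.355, baseline from the window-edge median; the
`port` algorithm with box constraints keeps the mean inside the window and
sigma positive, with a Nelder–Mead fallback.

The **peak count metric** defaults to the baseline-subtracted height (the
fitted amplitude), matching the working practice of quoting "counts at 25 nm";
the area $A\sigma\sqrt{2\pi}$ is available by flag. Whether published figures
normalize heights or areas is not decidable from the text, so both are
exposed. **Normalization** divides each condition's metric by the metric at
the preparation's reference pH — pH 4 for empty, pH 9 for filled particles,
each preparation's count-richest condition — so the reference is exactly 1
and the operation is idempotent.

**Statistics.** Group comparison uses the two-sided Welch two-sample t-test
(small $n$, unknown variance ratio; the underlying publication names no
test), reporting the mean difference with CI. The pH trend is the ordinary
least-squares slope of EM diameter versus pH (negative = shrinking toward
alkaline). One calibration caveat found while testing: with a 1.0 nm
separation, 0.2 nm replicate SD and $n = 6$, the Welch test yields
$p < 10^{-4}$ in only ~85% of runs (noncentral-$t$, ncp ≈ 8.7, df ≈ 10) —
claims of near-certain $p < 10^{-4}$ at that design are optimistic, and the
unit tests assert the Monte-Carlo-verified rates instead. Pooled comparisons
across the six pH levels ($n = 36$ per preparation) are far better powered.

## 3. Cryo-TEM 2D averaging

Raw cryo-TEM images of unstained particles have very low contrast, so boxed
particles are aligned and averaged (`align_and_average()`). The scheme is
reference-based: the initial reference is the unaligned mean; each iteration
registers every particle to the current reference by maximizing
cross-correlation (via FFT) over integer shifts within `max_shift`, refined
to subpixel by quadratic interpolation of the correlation peak, optionally
over a coarse rotation grid (default off — quasi-spherical particles are
rotation-insensitive; when enabled, rotated candidates are re-normalized
because interpolation losses would otherwise bias the score toward
0/90/180/270 degrees). Boxes are normalized to zero mean, unit variance
before correlation; blank boxes are excluded with a warning.

Two refinements proved necessary at realistic SNR (~0.1 per particle):

* **Leave-one-out reference.** A particle's own white noise enters the plain
  reference as a delta spike at its current shift and locks misalignments in
  place; registering each particle against the mean of the *others* removes
  the spike. Updates are simultaneous within an iteration (Jacobi), keeping
  the result independent of particle order.
* **Correlation band-limit** (`cc_smooth`, default sigma 1.5 px). White noise
  is flat in frequency while the PSF-blurred particle lives at low frequency;
  a mild Gaussian low-pass of the correlation surface approximates the
  matched filter and sharpens peak localization without biasing its position.
  With both refinements, all shifts of a 100-particle stack at SNR 0.1 are
  recovered within 1 px (rms ≈ 0.2 px); with neither, only about half are.

Alignment is defined up to a global offset (and rotation, when searched):
translating every particle identically moves the average, not the recovered
relative shifts. Tests therefore compare shifts after removing the consensus
offset.

**SNR estimation** (`estimate_snr()`): noise variance per particle from the
particle-minus-average residuals (scaled $N/(N-1)$), signal variance from the
average inside a central disk (default radius $0.35\,\times$ box, sized to
cover a default-geometry particle) minus the noise left in the average
($\sigma^2/N$). The SNR of the average then grows linearly in $N$ — the
averaging law the tests check at $N = 16/64/256$ — and dividing by $N$ gives
the per-particle SNR, comparable to the generator's requested value.

## 4. Diameter from iso-height sections and robust circles

The average is treated as a grey-value surface $z(x, y)$
(`build_intensity_surface()`). Polarity is normalized so the particle is the
high region (auto mode compares the central-disk median with the border-ring
median and flips if the center is lower), letting the same code serve
dark-particle cryo-TEM images and high-particle AFM topographs. The
background is the border-ring median; the extreme is the surface maximum.
On a *noisy* average the raw maximum is inflated by the largest noise
excursion, which raises every fractional level and shrinks all contour radii
by 10–25%; the `extreme_smooth` option (sigma 2 px in the sizing pipeline)
takes the maximum of a lightly smoothed copy instead. Contours themselves are
always traced on the raw surface — no smoothing bias enters the boundary.

Sections are cut at `level = background + f (extreme − background)` for
fractions $f$ (default 0.35/0.50/0.65 — scale-free, reproducible substitutes
for the unspecified "three sections at different levels") and traced with
subpixel edge interpolation (marching squares via `grDevices::contourLines`).
When several closed contours exist, the smallest one enclosing the surface
maximum is kept: that is the particle boundary, not a background loop, and
not the inner hole of the projected shell's ring.

`fit_circle()` formalizes the visual red-point exclusion of off-circle
section points: Kasa algebraic least squares initializes a geometric
(orthogonal-distance) Gauss–Newton refinement; points with $|r_i - R| >
k \cdot \mathrm{MAD}$ (default $k = 3$, MAD with the 1.4826 consistency
factor) are excluded and the fit repeated, up to 5 rounds. Entirely
deterministic; collinear input and over-trimming are errors.

**Calibration.** For a shell-shaped density the iso-contour at any fractional
level lies *inside* the outer envelope (the half-height contour of a 25 nm,
3 nm-wall shell sits at ~23.7 nm), so the raw contour diameter — what
`estimate_diameter()` reports by default, and what one reports for real data
— systematically underestimates the geometric outer diameter.
`shell_contour_calibration()` computes, via an exact 1D Hankel/Bessel
quadrature of the analytic projection profile blurred by the PSF (a
computation independent of the 2D image pipeline), the expected contour
radius as a function of outer diameter, and inverts it. With this forward
model the synthetic end-to-end chain recovers the generator truth to better
than 0.1 nm on average (criterion: 0.5 nm). For real data the calibration is
only as good as the assumed shell geometry; the per-level consistency of
calibrated diameters is itself a check of that assumption.

## 5. Synthetic data: the stated world

The generators are pure functions of (spec, seed): the RNG state is saved and
restored around every draw, and identical inputs give bit-identical outputs.

* **Shell phantom**: 3D spherical shell, outer diameter 25 nm, wall 3 nm
  (an AAV-like capsid wall; chosen once, the text gives no value), optional
  uniform interior at 0.5 relative density for "filled" particles (packaged
  ssDNA is less dense in projection than the protein wall; value chosen once
  and documented), projected analytically (chord-length integral, so
  subpixel positions are exact), blurred by a Gaussian PSF (sigma 1 px), at
  4.124 Å/px. SNR is the variance ratio of signal to noise inside the
  particle support disk, making the $\sqrt{N}$ averaging law directly
  checkable. Spherical, not icosahedral: the sizing chain treats particles
  as circles, so sphericity suffices; faceting is a non-goal. No CTF is
  simulated because the pipeline performs no CTF correction.
* **Mobility scans**: counts per channel are independent Poisson draws with
  mean `baseline + depletion x amplitude x gauss(channel)`; defaults peak
  25 nm, sigma 1.2 nm, amplitude 275 (the 250–300-count working point),
  baseline 2, 10 scans, on a log-spaced grid (64 channels/decade) spanning
  the measurable 1.95–64.9 nm range.
* **pH study** (the stated world of the qualitative-pattern test): 6 pH
  levels (4–9) x 2 preparations x 6 replicates x 10 scans. Empty particles:
  24.3 nm at pH 7, slope −0.2 nm/pH, full counts everywhere. Filled: +1.0 nm
  offset, slope −0.05 nm/pH, counts depleted toward acid with retention
  (0.2, 0.3, 0.45, 0.7, 0.85, 1.0) for pH 4–9 — a monotone interpolation of
  the 4-level depletion pattern used in the module examples, emulating
  aggregation that removes monomers from the measurable range. Replicate
  peak positions jitter with SD 0.2 nm.
* **AFM topographs**: upper envelope of spheres on a plane, morphologically
  dilated by a spherical tip (apex heights unchanged, lateral widths
  broadened), plus Gaussian height noise; the analytic dilated profile
  $\max(0,\; R - r_t + \sqrt{(R + r_t)^2 - r^2})$ is returned as truth.

What a green test does **not** establish: the generators have white noise,
a single-Gaussian PSF, no ice-thickness gradients, no beam damage, no
electrospray droplet chemistry, and perfectly spherical particles. Green
tests certify the *algorithms* against a controlled forward model, not the
instruments.

## 6. Numerical choices and degenerate inputs

* Bisection bracket 0.1 nm–10 µm; mobilities outside its image raise a range
  error naming the bracket.
* Subpixel correlation peaks: 3-point parabola per axis, offsets clamped to
  ±0.5 px, ties broken toward the smallest shift magnitude; peaks on the
  search boundary are not refined.
* Fourier (phase-ramp) shifts for accumulating the aligned average: exact,
  no interpolation low-pass; the cyclic wrap only touches box-edge noise.
* Zero-variance particles, zero-variance images, collinear circle points,
  empty fit windows, missing normalization references, and out-of-grid AFM
  centers are all explicit errors, not silent results.
* MAD = 0 in circle trimming (exact circles) falls back to a tiny
  radius-relative threshold so gross outliers are still excluded.
* `estimate_diameter()` skips levels whose contour or fit fails (with a
  warning); at least one level must succeed.

## 7. Known limitations

* The contour calibration assumes the shell forward model; for particles
  deviating from it (strong faceting, asymmetric cargo) the mapping is
  approximate and the raw contour diameter should be reported alongside.
* The DMA module covers singly charged particles and the transfer-function
  centroid only — no diffusion broadening, no multiple-charge inversion.
* Rotation search is a coarse grid with bilinear interpolation, adequate for
  near-spherical particles, not for strongly asymmetric ones.
* MRC I/O covers the MRC2014 subset used here (modes 0/1/2/6, no extended
  header); TIFF is not supported (no TIFF-capable R package available),
  plain-text CSV matrices are the portable alternative.
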