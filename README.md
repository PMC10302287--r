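# vlpsizer

Sizing quasi-spherical virus-like particles (VLPs) — AAV-class, ~25 nm
capsids — from two complementary measurements:

1. **Gas-phase electrophoresis (nES-GEMMA / nES-DMA).** A charge-equilibrated,
   predominantly singly charged aerosol is size-classified in a cylindrical
   differential mobility analyzer and counted. The package maps classifier
   voltage to electrophoretic-mobility (EM) diameter via the transfer-function
   centroid `Z* = Q_sh ln(r2/r1) / (2 pi L V)` and the Stokes–Millikan
   relation `Z = n e C(d) / (3 pi mu d)` with Cunningham slip correction
   `C = 1 + Kn (A1 + A2 exp(-A3/Kn))`, assembles median spectra from repeated
   scans, fits Gaussian monomer peaks, normalizes particle counts across a pH
   series, and runs the empty-vs-filled statistics (Welch t-test, OLS pH
   trends).
2. **Cryo-TEM 2D averaging and circle-fit sizing.** Boxed particles are
   aligned (FFT cross-correlation, leave-one-out reference, subpixel peaks)
   and averaged; the average's grey-value surface is cut at fractional
   iso-height levels, and circles are fit to the section boundaries with
   MAD-based outlier trimming — an unbiased, reproducible particle diameter.

Seeded synthetic generators (projected spherical shells, Poisson mobility
scans, tip-convolved AFM topographs) stand in for instrument data, so the
whole pipeline is testable end to end. Audience: anyone characterizing
capsid-sized nanoparticles with SMPS-class mobility analyzers or desk-scale
cryo-EM averaging, and anyone needing a tested reference implementation of
these widely used but rarely packaged steps.

## Worked example

```r
library(vlpsizer)

## 1. What diameter range does a 10 V - 10 kV scan cover?
scan_diameter_range()
#>  d_min  d_max
#>  1.911 65.572        # nm; the instrument's nominal range is 1.95-64.9

## 2. Simulate and analyze a full pH study (6 pH x 2 preparations x 6 replicates)
study <- simulate_ph_study(ph_study_spec(seed = 42))
rep <- run_gemma_study(study)
rep$summaries[rep$summaries$pH %in% c(4, 7, 9),
              c("pH", "preparation", "mean_em_diameter", "normalized_counts")]
#>    pH preparation mean_em_diameter normalized_counts
#> 1   4       empty            24.82            1.0000
#> 4   7       empty            24.39            1.0192
#> 6   9       empty            23.79            1.0229
#> 7   4      filled            25.59            0.1987
#> 10  7      filled            25.29            0.6929
#> 12  9      filled            25.18            1.0000
```

Filled particles run ~1 nm larger than empty ones
(`rep$comparison`: difference 1.02 nm, Welch p = 4.4e-19), empty particles
shrink faster toward alkaline pH (slopes −0.208 vs −0.074 nm per pH unit),
and filled-particle counts collapse toward acidic pH (normalized to each
preparation's reference: pH 4 for empty, pH 9 for filled) — monomers lost to
aggregation leave the measurable range.

```r
## 3. Cryo-TEM chain: 100 noisy particles (SNR 0.1) -> average -> diameter
spec <- shell_phantom_spec(outer_diameter = 25, snr = 0.1, seed = 7)
sim  <- simulate_micrograph_stack(spec, n_particles = 100, shift_max = 5)
avg  <- align_and_average(sim$stack, max_shift = 8)
cal  <- shell_contour_calibration(spec, extreme_smooth = 2)
estimate_diameter(avg, extreme_smooth = 2, calibration = cal)
#> <diameter_estimate> 24.951 +/- 0.028 nm over 3 level(s) at 4.124 A/px
```

The three iso-height sections (0.35/0.50/0.65 of the background-to-extreme
span) give contour radii of 29.6/29.0/28.3 px; mapped through the shell
forward model they agree on 24.95 ± 0.03 nm against a generator truth of
25.0 nm. Without the calibration the raw contour diameters (what one reports
for real data) sit 1–2 nm lower — the iso-contour of a shell density lies
inside its outer envelope. See the methods vignette
(`vignettes/vlp-sizing-methods.Rmd`) for the model details.

## Command line

```sh
inst/cli/vlpsizer dma                      # print the scan diameter range
inst/cli/vlpsizer simulate stack --out d   # write stack.mrc + truths
inst/cli/vlpsizer gemma --out d --seed 1   # simulate + analyze a pH study
inst/cli/vlpsizer cryoem --stack d/stack.mrc --max-shift 8
```

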