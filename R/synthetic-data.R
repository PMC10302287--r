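# Seeded generators emulating the three instrument data streams: projected
# spherical-shell particles for cryo-TEM averaging, channelized mobility scans
# with Poisson counting noise for nES-GEMMA, and tip-convolved AFM topographs.
# All generators are pure functions of (spec, seed): the global RNG state is
# saved and restored around every draw.

#' Spherical-shell phantom specification
#'
#' The forward model for a quasi-spherical VLP: a 3D spherical shell (protein
#' capsid) of given outer diameter and wall thickness, optionally with a
#' uniform interior density (the packaged genome of a "filled" particle),
#' projected along the beam, blurred by a Gaussian PSF and, in stacks, read
#' out at a given signal-to-noise ratio. Defaults match the imaging scale of
#' an AAV-sized capsid: 25 nm outer diameter, 3 nm wall, 4.124 Angstrom
#' pixels.
#'
#' @param outer_diameter outer shell diameter, nm
#' @param shell_thickness shell wall thickness, nm; `0 < t < outer/2`
#' @param filled logical; add a uniform interior density
#' @param density_contrast overall signal scale (arbitrary units; negative for
#'   dark-on-bright cryo-TEM contrast)
#' @param core_density interior density relative to the shell (filled only)
#' @param pixel_size pixel size in Angstrom
#' @param psf_sigma Gaussian PSF sigma in px
#' @param snr per-particle signal-to-noise ratio (signal variance inside the
#'   particle support disk / noise variance)
#' @param seed integer seed used by the stochastic generators
#' @return Object of class `shell_phantom_spec`.
#' @export
shell_phantom_spec <- function(outer_diameter = 25, shell_thickness = 3,
                               filled = FALSE, density_contrast = 1,
                               core_density = 0.5, pixel_size = 4.124,
                               psf_sigma = 1, snr = 0.1, seed = 1) {
  check_scalar_pos(outer_diameter, "outer_diameter")
  check_scalar_pos(shell_thickness, "shell_thickness")
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(snr, "snr")
  if (psf_sigma < 0) stop_domain("`psf_sigma` must be >= 0")
  if (shell_thickness >= outer_diameter / 2) {
    stop_domain("`shell_thickness` must be < outer_diameter / 2")
  }
  if (density_contrast == 0) stop_domain("`density_contrast` must be non-zero")
  structure(list(outer_diameter = outer_diameter,
                 shell_thickness = shell_thickness, filled = filled,
                 density_contrast = density_contrast,
                 core_density = core_density, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, snr = snr, seed = seed),
            class = "shell_phantom_spec")
}

# Analytic (pre-PSF) radial projection profile of the shell, nm units:
# line integral through a shell of outer radius R, inner radius Ri, unit
# density, plus core_density inside Ri when filled.
shell_profile_fun <- function(spec) {
  R <- spec$outer_diameter / 2
  Ri <- R - spec$shell_thickness
  core <- if (isTRUE(spec$filled)) spec$core_density else 0
  function(r_nm) {
    outer <- 2 * sqrt(pmax(R^2 - r_nm^2, 0))
    inner <- 2 * sqrt(pmax(Ri^2 - r_nm^2, 0))
    spec$density_contrast * (outer - inner + core * inner)
  }
}

# Cyclic Gaussian blur; the phantom support stays well inside the box so the
# periodic wrap is inert.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  n <- nrow(img); m <- ncol(img)
  dx <- pmin(0:(m - 1), m - (0:(m - 1)))
  dy <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(img) * stats::fft(k), inverse = TRUE)) / (n * m)
}

# Evaluate the blurred projection on a box with the particle center at
# 0-based pixel coordinates (cx, cy).
project_shell <- function(spec, box_size, cx, cy) {
  px_nm <- spec$pixel_size / 10
  xg <- matrix(rep(0:(box_size - 1), each = box_size), box_size, box_size)
  yg <- matrix(rep(0:(box_size - 1), box_size), box_size, box_size)
  r_nm <- sqrt((xg - cx)^2 + (yg - cy)^2) * px_nm
  gaussian_blur(matrix(shell_profile_fun(spec)(r_nm), box_size, box_size),
                spec$psf_sigma)
}

#' Project a spherical-shell phantom into a noiseless image
#'
#' Line-integral projection of the 3D shell (plus uniform core when filled),
#' blurred by the Gaussian PSF, centered in the box. The analytic pre-PSF
#' radial profile is returned as a function of radius in nm for use as an
#' independent oracle.
#'
#' @param spec a [shell_phantom_spec()]
#' @param box_size box side in px (even)
#' @return List with `image` (box_size x box_size matrix), `profile`
#'   (function of radius in nm), `center` (0-based box center coordinate),
#'   `spec`.
#' @export
simulate_shell_projection <- function(spec, box_size = 96) {
  stopifnot(inherits(spec, "shell_phantom_spec"))
  if (box_size %% 2L != 0L || box_size < 8L) {
    stop_domain("`box_size` must be an even integer >= 8")
  }
  if (spec$outer_diameter * 10 / spec$pixel_size >= box_size - 4) {
    stop_domain("particle larger than the box")
  }
  ctr <- (box_size - 1) / 2
  list(image = project_shell(spec, box_size, ctr, ctr),
       profile = shell_profile_fun(spec),
       center = ctr,
       spec = spec)
}

# Noise SD that realizes spec$snr for this phantom: signal variance inside
# the particle support disk (outer radius + 3 psf sigma) over snr.
phantom_noise_sd <- function(spec, box_size) {
  proj <- simulate_shell_projection(spec, box_size)
  b <- box_size; ctr <- proj$center
  xg <- matrix(rep(0:(b - 1), each = b), b, b)
  yg <- matrix(rep(0:(b - 1), b), b, b)
  r_px <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  support <- r_px <= spec$outer_diameter / 2 * 10 / spec$pixel_size +
    3 * spec$psf_sigma
  sqrt(stats::var(proj$image[support]) / spec$snr)
}

#' Simulate a stack of noisy, randomly shifted particle images
#'
#' Each particle is the shell phantom displaced by a uniform random subpixel
#' offset within `shift_max` px (evaluated analytically at the shifted center,
#' so no interpolation error enters the truth) plus white Gaussian noise
#' scaled to the spec's SNR. The true offsets are returned for oracle use.
#'
#' @param spec a [shell_phantom_spec()]
#' @param n_particles number of particles (>= 1)
#' @param shift_max maximum |offset| per axis in px
#' @param box_size box side in px
#' @return List with `stack` (a [particle_stack()]), `truth` (data frame
#'   `dx`, `dy` in px), `phantom` (centered noiseless image), `noise_sd`.
#' @export
simulate_micrograph_stack <- function(spec, n_particles = 100, shift_max = 5,
                                      box_size = 96) {
  stopifnot(inherits(spec, "shell_phantom_spec"))
  if (n_particles < 1L) stop_domain("`n_particles` must be >= 1")
  if (shift_max < 0 || shift_max >= box_size / 4) {
    stop_domain("`shift_max` must satisfy 0 <= shift_max < box_size / 4")
  }
  noise_sd <- phantom_noise_sd(spec, box_size)
  phantom <- simulate_shell_projection(spec, box_size)
  ctr <- phantom$center
  with_seed(spec$seed, {
    dx <- stats::runif(n_particles, -shift_max, shift_max)
    dy <- stats::runif(n_particles, -shift_max, shift_max)
    arr <- array(0, dim = c(box_size, box_size, n_particles))
    for (i in seq_len(n_particles)) {
      arr[, , i] <- project_shell(spec, box_size, ctr + dx[i], ctr + dy[i]) +
        stats::rnorm(box_size^2, sd = noise_sd)
    }
    list(stack = particle_stack(arr, spec$pixel_size),
         truth = data.frame(dx = dx, dy = dy),
         phantom = phantom$image,
         noise_sd = noise_sd)
  })
}

#' Simulate a full micrograph with picked-particle coordinates
#'
#' Places `n_particles` phantoms at random non-overlapping positions on a
#' large noisy field and returns the micrograph together with the exact
#' integer pick coordinates, mimicking manual picking saved as model points.
#'
#' @param spec a [shell_phantom_spec()]
#' @param n_particles number of particles to place
#' @param size micrograph side in px
#' @param margin minimum distance of a center from the border, px
#' @return List with `micrograph` (a [micrograph()]), `coords` (0-based
#'   integer `(x, y)` matrix), `noise_sd`.
#' @export
simulate_micrograph <- function(spec, n_particles = 50, size = 512,
                                margin = 64) {
  stopifnot(inherits(spec, "shell_phantom_spec"))
  d_px <- spec$outer_diameter * 10 / spec$pixel_size
  # keep a boxed neighbor's density out of a ~1.5 d extraction box
  min_sep <- 1.6 * (d_px + 4 * spec$psf_sigma)
  noise_sd <- phantom_noise_sd(spec, box_size = 2L * (ceiling(d_px) %/% 2L * 2L + 8L))
  with_seed(spec$seed, {
    pts <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(pts) < n_particles && tries < 20000L) {
      tries <- tries + 1L
      cand <- round(stats::runif(2, margin, size - 1 - margin))
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))) > min_sep) {
        pts <- rbind(pts, cand)
      }
    }
    if (nrow(pts) < n_particles) {
      stop_domain("could not place ", n_particles, " non-overlapping particles")
    }
    img <- matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
    prof <- shell_profile_fun(spec)
    px_nm <- spec$pixel_size / 10
    r_sup <- ceiling(d_px / 2 + 4 * spec$psf_sigma + 2)
    patch <- 2L * r_sup + 1L
    offs <- -r_sup:r_sup
    for (i in seq_len(n_particles)) {
      rg <- matrix(sqrt(outer(offs^2, offs^2, "+")), patch, patch) * px_nm
      p <- gaussian_blur(matrix(prof(rg), patch, patch), spec$psf_sigma)
      rows <- pts[i, 2] + offs + 1L
      cols <- pts[i, 1] + offs + 1L
      img[rows, cols] <- img[rows, cols] + p
    }
    colnames(pts) <- c("x", "y")
    list(micrograph = micrograph(img, spec$pixel_size),
         coords = pts, noise_sd = noise_sd)
  })
}

#' Mobility-scan simulation specification
#'
#' Emulates repeated nES-GEMMA up-scans of a monomer peak: expected counts per
#' channel are `baseline + depletion_factor * peak * gauss(channel)`, realized
#' with independent Poisson noise per channel and scan. Defaults follow the
#' instrument's working point for a VLP monomer: peak at 25 nm, width sigma
#' 1.2 nm, 275 expected peak counts (samples are diluted to 250-300 counts at
#' the 25 nm signal), 10 scans per sample on a log-spaced channel grid
#' spanning the measurable 1.95-64.9 nm range.
#'
#' @param true_peak_diameter monomer peak position, nm
#' @param peak_sigma Gaussian peak sigma, nm
#' @param expected_peak_counts expected counts at the peak maximum
#' @param baseline_counts expected flat background counts per channel
#' @param channels channel grid in nm (strictly increasing)
#' @param depletion_factor multiplicative count loss in [0, 1] (aggregation
#'   removes monomers from the measurable range)
#' @param n_scans scans per sample
#' @param seed integer seed
#' @return Object of class `gemma_sim_spec`.
#' @export
gemma_sim_spec <- function(true_peak_diameter = 25, peak_sigma = 1.2,
                           expected_peak_counts = 275, baseline_counts = 2,
                           channels = gemma_channel_grid(),
                           depletion_factor = 1, n_scans = 10, seed = 1) {
  check_scalar_pos(true_peak_diameter, "true_peak_diameter")
  check_scalar_pos(peak_sigma, "peak_sigma")
  if (expected_peak_counts < 0 || baseline_counts < 0) {
    stop_domain("expected counts must be non-negative")
  }
  if (depletion_factor < 0 || depletion_factor > 1) {
    stop_domain("`depletion_factor` must lie in [0, 1]")
  }
  if (any(diff(channels) <= 0)) stop_domain("`channels` must be strictly increasing")
  if (n_scans < 1L) stop_domain("`n_scans` must be >= 1")
  structure(list(true_peak_diameter = true_peak_diameter,
                 peak_sigma = peak_sigma,
                 expected_peak_counts = expected_peak_counts,
                 baseline_counts = baseline_counts,
                 channels = as.numeric(channels),
                 depletion_factor = depletion_factor,
                 n_scans = as.integer(n_scans), seed = seed),
            class = "gemma_sim_spec")
}

#' Default log-spaced channel grid of the mobility scan
#'
#' @param d_min,d_max grid endpoints in nm (instrument range defaults)
#' @param channels_per_decade channel density (64, the SMPS convention)
#' @return Strictly increasing diameters in nm.
#' @export
gemma_channel_grid <- function(d_min = 1.95, d_max = 64.9,
                               channels_per_decade = 64) {
  n <- ceiling(log10(d_max / d_min) * channels_per_decade) + 1L
  10^seq(log10(d_min), log10(d_max), length.out = n)
}

# Unseeded core so composite generators can draw from one stream.
sim_gemma_scans_raw <- function(spec, ...) {
  mu <- spec$baseline_counts + spec$depletion_factor * spec$expected_peak_counts *
    exp(-(spec$channels - spec$true_peak_diameter)^2 / (2 * spec$peak_sigma^2))
  lapply(seq_len(spec$n_scans), function(k) {
    spectrum_scan(spec$channels, stats::rpois(length(mu), mu),
                  scan_index = k, ...)
  })
}

#' Simulate repeated mobility scans
#'
#' @param spec a [gemma_sim_spec()]
#' @param ... metadata passed to each [spectrum_scan()]
#' @return List of `n_scans` [spectrum_scan()] objects.
#' @export
simulate_gemma_scans <- function(spec, ...) {
  stopifnot(inherits(spec, "gemma_sim_spec"))
  with_seed(spec$seed, sim_gemma_scans_raw(spec, ...))
}

#' AFM topograph simulation specification
#'
#' @param sphere_diameter particle diameter, nm
#' @param tip_radius spherical probe-tip radius, nm (0 = ideal tip)
#' @param grid_spacing lateral sample spacing, nm
#' @param grid_size samples per side
#' @param noise_sd Gaussian height noise SD, nm
#' @param seed integer seed
#' @return Object of class `afm_sim_spec`.
#' @export
afm_sim_spec <- function(sphere_diameter = 25, tip_radius = 5,
                         grid_spacing = 1, grid_size = 64, noise_sd = 0.1,
                         seed = 1) {
  check_scalar_pos(sphere_diameter, "sphere_diameter")
  check_scalar_pos(grid_spacing, "grid_spacing")
  if (tip_radius < 0 || noise_sd < 0) stop_domain("`tip_radius` and `noise_sd` must be >= 0")
  if (grid_size < 8L) stop_domain("`grid_size` must be >= 8")
  structure(list(sphere_diameter = sphere_diameter, tip_radius = tip_radius,
                 grid_spacing = grid_spacing, grid_size = as.integer(grid_size),
                 noise_sd = noise_sd, seed = seed),
            class = "afm_sim_spec")
}

#' Simulate an AFM topograph of spheres with tip convolution
#'
#' The sample surface is the upper envelope of spheres resting on a flat
#' substrate. The measured topograph is that surface morphologically dilated
#' by a spherical tip of radius `tip_radius` (the tip apex rides the highest
#' admissible contact), plus Gaussian height noise. Dilation broadens features
#' laterally but leaves apex heights unchanged. The analytic apparent profile
#' of an isolated sphere, `max(0, R - r_t + sqrt((R + r_t)^2 - r^2))`, is
#' returned as the truth for oracle checks.
#'
#' @param spec an [afm_sim_spec()]
#' @param centers matrix of sphere center `(x, y)` positions in nm; all must
#'   lie on the grid
#' @return List with `height` (matrix, nm; rows = y), `x`, `y` (axis
#'   coordinates in nm), `truth` (list: `apex`, `apparent_base_radius`,
#'   `profile` function of radius in nm).
#' @export
simulate_afm_topography <- function(spec, centers = NULL) {
  stopifnot(inherits(spec, "afm_sim_spec"))
  n <- spec$grid_size; h <- spec$grid_spacing
  extent <- (n - 1) * h
  if (is.null(centers)) centers <- matrix(extent / 2, 1, 2)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (any(centers < 0) || any(centers > extent)) {
    stop_domain("sphere centers must lie inside the grid [0, ", extent, "] nm")
  }
  R <- spec$sphere_diameter / 2
  ax <- (0:(n - 1)) * h
  xg <- matrix(rep(ax, each = n), n, n)
  yg <- matrix(rep(ax, n), n, n)
  z <- matrix(0, n, n)
  for (i in seq_len(nrow(centers))) {
    r2 <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2
    cap <- ifelse(r2 <= R^2, R + sqrt(pmax(R^2 - r2, 0)), 0)
    z <- pmax(z, cap)
  }
  rt <- spec$tip_radius
  if (rt > 0) {
    kpx <- floor(rt / h)
    dil <- z
    for (di in -kpx:kpx) for (dj in -kpx:kpx) {
      u2 <- (di^2 + dj^2) * h^2
      if (u2 > rt^2) next
      hp <- rt - sqrt(rt^2 - u2)
      sh <- matrix(0, n, n)
      src_r <- max(1, 1 - di):min(n, n - di)
      src_c <- max(1, 1 - dj):min(n, n - dj)
      sh[src_r + di, src_c + dj] <- z[src_r, src_c]
      dil <- pmax(dil, sh - hp)
    }
    z <- dil
  }
  if (spec$noise_sd > 0) {
    z <- with_seed(spec$seed, z + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n))
  }
  profile <- function(r_nm) {
    pmax(0, ifelse(r_nm <= R + rt,
                   R - rt + sqrt(pmax((R + rt)^2 - r_nm^2, 0)), 0))
  }
  list(height = z, x = ax, y = ax,
       truth = list(apex = 2 * R,
                    apparent_base_radius = R + rt,
                    profile = profile))
}

#' pH-series study specification
#'
#' The stated world for the full synthetic pH study: 6 pH levels (4-9) x 2
#' preparations x 6 replicate analyses, each replicate a median of 10 Poisson
#' scans. Filled particles run 1 nm larger than empty ones and lose counts
#' toward acidic pH (aggregates leave the measurable range); empty particles
#' keep their counts but shrink more steeply toward alkaline pH. Replicate
#' peak positions jitter with SD `replicate_sd` around the condition mean.
#'
#' @param ph_levels numeric pH levels
#' @param empty_base empty-preparation mean EM diameter at pH 7, nm
#' @param filled_offset filled-minus-empty diameter offset, nm
#' @param slope_empty,slope_filled diameter trend in nm per pH unit
#'   (negative = shrinking toward alkaline)
#' @param replicate_sd between-replicate SD of the peak position, nm
#' @param depletion_filled,depletion_empty count-retention factors in [0, 1],
#'   one per pH level (aligned with `ph_levels`)
#' @param n_replicates replicate analyses per condition
#' @param n_scans scans per replicate
#' @param expected_peak_counts,baseline_counts,peak_sigma scan-shape
#'   parameters, see [gemma_sim_spec()]
#' @param seed integer seed
#' @return Object of class `ph_study_spec`.
#' @export
ph_study_spec <- function(ph_levels = 4:9,
                          empty_base = 24.3, filled_offset = 1.0,
                          slope_empty = -0.2, slope_filled = -0.05,
                          replicate_sd = 0.2,
                          depletion_filled = c(0.2, 0.3, 0.45, 0.7, 0.85, 1.0),
                          depletion_empty = rep(1, length(ph_levels)),
                          n_replicates = 6, n_scans = 10,
                          expected_peak_counts = 275, baseline_counts = 2,
                          peak_sigma = 1.2, seed = 1) {
  if (length(depletion_filled) != length(ph_levels) ||
      length(depletion_empty) != length(ph_levels)) {
    stop_domain("depletion factors must align with `ph_levels`")
  }
  structure(list(ph_levels = as.numeric(ph_levels), empty_base = empty_base,
                 filled_offset = filled_offset, slope_empty = slope_empty,
                 slope_filled = slope_filled, replicate_sd = replicate_sd,
                 depletion_filled = depletion_filled,
                 depletion_empty = depletion_empty,
                 n_replicates = as.integer(n_replicates),
                 n_scans = as.integer(n_scans),
                 expected_peak_counts = expected_peak_counts,
                 baseline_counts = baseline_counts, peak_sigma = peak_sigma,
                 seed = seed),
            class = "ph_study_spec")
}

#' Simulate the full pH-series study
#'
#' @param spec a [ph_study_spec()]
#' @return Object of class `gemma_study`: `scans` (flat list of
#'   [spectrum_scan()]s with preparation/pH/replicate metadata in
#'   `sample_id`), `truth` (data frame of true replicate peak diameters and
#'   depletion factors), `spec`.
#' @export
simulate_ph_study <- function(spec) {
  stopifnot(inherits(spec, "ph_study_spec"))
  with_seed(spec$seed, {
    scans <- list()
    truth <- list()
    for (prep in c("empty", "filled")) {
      for (k in seq_along(spec$ph_levels)) {
        ph <- spec$ph_levels[k]
        base <- if (prep == "empty") spec$empty_base
                else spec$empty_base + spec$filled_offset
        slope <- if (prep == "empty") spec$slope_empty else spec$slope_filled
        depl <- if (prep == "empty") spec$depletion_empty[k]
                else spec$depletion_filled[k]
        cond_mean <- base + slope * (ph - 7)
        for (r in seq_len(spec$n_replicates)) {
          mu <- cond_mean + stats::rnorm(1, 0, spec$replicate_sd)
          gs <- gemma_sim_spec(true_peak_diameter = mu,
                               peak_sigma = spec$peak_sigma,
                               expected_peak_counts = spec$expected_peak_counts,
                               baseline_counts = spec$baseline_counts,
                               depletion_factor = depl,
                               n_scans = spec$n_scans, seed = spec$seed)
          id <- sprintf("%s_pH%g_rep%d", prep, ph, r)
          scans <- c(scans, sim_gemma_scans_raw(gs, sample_id = id, ph = ph,
                                                preparation = prep))
          truth[[length(truth) + 1L]] <-
            data.frame(preparation = prep, pH = ph, replicate = r,
                       true_diameter = mu, depletion = depl)
        }
      }
    }
    structure(list(scans = scans, truth = do.call(rbind, truth), spec = spec),
              class = "gemma_study")
  })
}
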