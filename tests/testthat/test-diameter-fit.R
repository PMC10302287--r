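# Intensity surface, iso-height sections, robust circle fit, line profiles.

test_that("polarity normalization makes the particle the high region", {
  dome <- make_dome(64, 20)
  s_bright <- build_intensity_surface(dome, "auto")
  expect_false(s_bright$flipped)
  s_dark <- build_intensity_surface(-dome, "auto")
  expect_true(s_dark$flipped)
  ctr <- c(32, 32)
  for (s in list(s_bright, s_dark)) {
    expect_gt(s$z[ctr[1], ctr[2]], median(s$z[1, ]))
  }
  # constant offset shifts the background, not the shape
  s_off <- build_intensity_surface(dome + 5, "auto")
  expect_equal(s_off$background, s_bright$background + 5)
  expect_equal(s_off$z - 5, s_bright$z)
  expect_error(build_intensity_surface(matrix(1, 32, 32)), "zero variance")
  expect_error(build_intensity_surface(matrix(1, 8, 8)), "16 x 16")
})

test_that("surface extreme matches the blurred-profile oracle on a phantom", {
  spec <- shell_phantom_spec(psf_sigma = 1.5)
  proj <- simulate_shell_projection(spec, 96)
  s <- build_intensity_surface(proj$image)
  px_nm <- spec$pixel_size / 10
  prof_px <- function(r) proj$profile(r * px_nm)
  r <- seq(0, 40, by = 0.05)
  oracle <- max(vlpsizer:::blurred_radial_profile(prof_px, spec$psf_sigma,
                                                  r, 35))
  expect_equal(s$extreme, oracle, tolerance = 0.01)
})

test_that("iso-sections of a dome are circular at the analytic radius", {
  dome <- make_dome(96, 30)
  s <- build_intensity_surface(dome)
  sec <- extract_section(s, 0.5)
  r <- sqrt((sec$points[, 1] - 47.5)^2 + (sec$points[, 2] - 47.5)^2)
  expect_lt(max(abs(r - mean(r))), 0.1)
  expect_equal(mean(r), 30, tolerance = 0.01)  # half-height crossing by design

  # raising the level strictly shrinks the section
  radii <- vapply(c(0.3, 0.5, 0.7), function(f)
    mean(sqrt(rowSums(sweep(extract_section(s, f)$points, 2, c(47.5, 47.5))^2))),
    numeric(1))
  expect_true(all(diff(radii) < 0))

  expect_error(extract_section(s, 0), "between 0 and 1")
  expect_error(extract_section(s, 1.2), "between 0 and 1")
  # a pure gradient has only open contours
  ramp <- outer(1:64, 1:64, "+") * 1.0
  expect_error(extract_section(build_intensity_surface(ramp), 0.5),
               "contour")
})

test_that("shell-projection contour radius matches the analytic-profile oracle", {
  spec <- shell_phantom_spec(psf_sigma = 1)
  proj <- simulate_shell_projection(spec, 96)
  s <- build_intensity_surface(proj$image)
  sec <- extract_section(s, 0.5)
  r_meas <- mean(sqrt(rowSums(sweep(sec$points, 2, c(47.5, 47.5))^2)))
  # oracle: outermost level crossing of the 1D blurred analytic profile
  px_nm <- spec$pixel_size / 10
  prof_px <- function(r) proj$profile(r * px_nm)
  r <- seq(0, 40, by = 0.01)
  ip <- vlpsizer:::blurred_radial_profile(prof_px, spec$psf_sigma, r, 35)
  lev <- 0.5 * max(ip)
  r_oracle <- r[max(which(ip >= lev))]
  expect_equal(r_meas, r_oracle, tolerance = 0.01)
})

test_that("circle fit is exact on exact data and rejects degenerate input", {
  cf <- fit_circle(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(unname(cf$center), c(0, 0), tolerance = 1e-9)
  expect_equal(cf$radius, 1, tolerance = 1e-9)
  expect_lt(cf$rms_residual, 1e-9)

  th <- seq(0, 2 * pi, length.out = 21)[-21]
  pts <- rbind(cbind(cos(th), sin(th)), c(3, 0))
  cf2 <- fit_circle(pts)
  expect_equal(cf2$excluded, 21L)
  expect_equal(cf2$radius, 1, tolerance = 1e-6)

  expect_error(fit_circle(cbind(1:5, 2 * (1:5) + 1)), "collinear")
  expect_error(fit_circle(cbind(1, 2)), "3 points")
})

test_that("geometric circle fit agrees with the brute-force oracle", {
  set.seed(7)
  for (i in 1:10) {
    pts <- make_circle_points(200, r = 30, sd = 0.3)
    cf <- fit_circle(pts, trim_k = Inf)
    oracle <- grid_circle_oracle(pts)
    expect_lt(abs(cf$radius - oracle$radius), 0.05)
  }
})

test_that("MAD trimming resists gross contour outliers", {
  set.seed(13)
  pts <- make_circle_points(200, r = 30, sd = 0.3)
  clean_r <- fit_circle(pts, trim_k = Inf)$radius
  # 10% gross outliers, all well off the radius-30 ring
  th <- runif(20, 0, 2 * pi)
  rr <- sample(c(runif(10, 5, 22), runif(10, 38, 55)))
  out <- cbind(50 + rr * cos(th), 50 + rr * sin(th))
  cf <- fit_circle(rbind(pts, out))
  expect_lt(abs(cf$radius - clean_r), 0.1)
  expect_gte(length(cf$excluded), 15)
})

test_that("estimate_diameter does exact arithmetic on an ideal dome", {
  dome <- make_dome(96, 30)
  est <- estimate_diameter(dome, levels = 0.5, pixel_size = 4.124)
  expect_equal(est$mean_diameter, 2 * 30 * 4.124 / 10, tolerance = 1e-3)
  est2 <- estimate_diameter(dome, levels = 0.5, pixel_size = 8.248)
  expect_equal(est2$mean_diameter, 2 * est$mean_diameter, tolerance = 1e-6)
})

test_that("diameter estimation is rotation- and translation-invariant", {
  spec <- shell_phantom_spec(psf_sigma = 1)
  proj <- simulate_shell_projection(spec, 96)
  base <- estimate_diameter(proj$image)$mean_diameter
  rot <- estimate_diameter(t(proj$image)[, 96:1])$mean_diameter  # 90 degrees
  expect_lt(abs(rot - base) / base, 0.002)
  ctr <- proj$center
  shifted <- vlpsizer:::project_shell(spec, 96, ctr + 5.3, ctr - 4.1)
  tra <- estimate_diameter(shifted)$mean_diameter
  expect_lt(abs(tra - base) / base, 0.002)
})

test_that("calibrated per-level diameters agree on a single phantom radius", {
  spec <- shell_phantom_spec()
  proj <- simulate_shell_projection(spec, 96)
  cal <- shell_contour_calibration(spec)
  est <- estimate_diameter(proj$image, calibration = cal)
  expect_true(all(abs(est$per_level$diameter_nm - 25) < 0.05))
  expect_lt(est$sd, 0.05)
  # uncalibrated level diameters differ strongly across levels by contrast
  raw <- estimate_diameter(proj$image)
  expect_gt(diff(range(raw$per_level$diameter_nm)), 0.5)
})

test_that("line profiles interpolate correctly", {
  const <- matrix(4, 32, 32)
  lp <- extract_line_profile(const, c(2, 10), c(29, 10))
  expect_true(all(lp$values == 4))
  expect_true(all(diff(lp$positions) > 0))

  # hemispherical cap of radius 12.5 nm sampled at 1 nm spacing
  spec <- afm_sim_spec(sphere_diameter = 25, tip_radius = 0, noise_sd = 0,
                       grid_size = 65)
  topo <- simulate_afm_topography(spec, centers = cbind(32, 32))
  lp2 <- extract_line_profile(topo$height, c(0, 32), c(64, 32), scale = 1)
  expect_equal(max(lp2$values), 25, tolerance = 1)

  expect_error(extract_line_profile(const, c(5, 5), c(5, 5)), "coincide")
  expect_error(extract_line_profile(const, c(-2, 5), c(10, 5)), "inside")
})
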