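# Particle extraction, reference-based alignment, SNR estimation.

test_that("extract_particles centers boxes and rejects out-of-bounds picks", {
  spec <- shell_phantom_spec(outer_diameter = 12, shell_thickness = 2,
                             psf_sigma = 0.5)
  proj <- simulate_shell_projection(spec, 64)
  big <- matrix(0, 256, 256)
  big[97:160, 65:128] <- proj$image   # particle center at (x, y) = (96, 128)
  m <- micrograph(big, spec$pixel_size)
  st <- extract_particles(m, cbind(96, 128), 64)
  expect_equal(st$n, 1)
  # center of mass of the boxed particle is within 1 px of the box center
  w <- st$data[, , 1]
  xg <- outer(rep(1, 64), 0:63); yg <- t(xg)
  com <- c(sum(xg * w), sum(yg * w)) / sum(w)
  expect_lt(max(abs(com - 31.5)), 1)

  st2 <- extract_particles(m, rbind(c(96, 128), c(96, 128)), 64)
  expect_identical(st2$data[, , 1], st2$data[, , 2])

  expect_warning(st3 <- extract_particles(m, rbind(c(96, 128), c(5, 5)), 64),
                 "rejected.*2")
  expect_equal(st3$n, 1)
  expect_equal(attr(st3, "rejected"), 2L)
  expect_error(extract_particles(m, cbind(96, 128), 512), "larger")
})

test_that("generator-placed particles are all recovered by picking coordinates", {
  spec <- shell_phantom_spec(snr = 10, seed = 17)
  sim <- simulate_micrograph(spec, n_particles = 50, size = 1024, margin = 70)
  st <- extract_particles(sim$micrograph, sim$coords, 96)
  expect_equal(st$n, 50)
  ph <- simulate_shell_projection(spec, 96)$image
  cors <- vapply(seq_len(st$n), function(i)
    cor(as.vector(st$data[, , i]), as.vector(ph)), numeric(1))
  expect_true(all(cors > 0.9))
})

test_that("identical centered stacks align with zero shifts", {
  p <- simulate_shell_projection(shell_phantom_spec(), 96)$image
  st <- particle_stack(array(rep(p, 4), c(96, 96, 4)))
  avg <- align_and_average(st, max_shift = 8)
  expect_equal(max(abs(avg$shifts)), 0)
  # the average is the (normalized) input image to machine precision
  pn <- (p - mean(p)) / sd(p)
  expect_lt(max(abs(avg$average - pn)), 1e-8)
})

test_that("a known relative shift is recovered within 0.5 px", {
  p <- simulate_shell_projection(shell_phantom_spec(), 96)$image
  sh <- vlpsizer:::shift_image(p, 3, -2)
  st <- particle_stack(array(c(p, sh), c(96, 96, 2)))
  avg <- align_and_average(st, max_shift = 8)
  rel <- avg$shifts[2, ] - avg$shifts[1, ]
  expect_lt(max(abs(rel - c(-3, 2))), 0.5)
})

test_that("a known relative rotation is recovered on an asymmetric pattern", {
  set.seed(9)
  img <- vlpsizer:::gaussian_blur(matrix(rnorm(96^2), 96, 96), 4)
  xg <- outer(rep(1, 96), 0:95); yg <- t(xg)
  img <- img * exp(-((xg - 47.5)^2 + (yg - 47.5)^2) / (2 * 18^2))
  pr <- vlpsizer:::rotate_image(img, 60)
  st <- particle_stack(array(c(img, pr, img), c(96, 96, 3)))
  avg <- align_and_average(st, max_shift = 4, rotation_step = 10, n_iter = 3)
  rel <- (avg$rotations[2] - avg$rotations[1]) %% 360
  expect_equal(rel, 300)
})

test_that("shifts of a low-SNR stack are recovered within 1 px", {
  spec <- shell_phantom_spec(snr = 0.1, seed = 11)
  sim <- simulate_micrograph_stack(spec, n_particles = 100, shift_max = 5)
  avg <- align_and_average(sim$stack, max_shift = 8)
  # alignment is defined up to a global offset: compare after centering
  res <- avg$shifts + as.matrix(sim$truth)
  res <- sweep(res, 2, colMeans(res))
  expect_gte(mean(sqrt(rowSums(res^2)) < 1), 0.9)
  # the average is closer to the phantom than any single particle
  ph <- as.vector(sim$phantom)
  avg_cor <- cor(as.vector(avg$average), ph)
  single_cor <- max(vapply(1:10, function(i)
    cor(as.vector(sim$stack$data[, , i]), ph), numeric(1)))
  expect_gt(avg_cor, single_cor)
})

test_that("averaging is order-invariant and consistent under a global shift", {
  spec <- shell_phantom_spec(snr = 2, seed = 23)
  sim <- simulate_micrograph_stack(spec, n_particles = 8, shift_max = 3)
  avg <- align_and_average(sim$stack, max_shift = 6)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  st2 <- particle_stack(sim$stack$data[, , perm], spec$pixel_size)
  avg2 <- align_and_average(st2, max_shift = 6)
  expect_equal(avg2$shifts, avg$shifts[perm, ], tolerance = 1e-9)
  expect_equal(avg2$average, avg$average, tolerance = 1e-9)

  # shifting every particle by the same vector: alignment is defined relative
  # to the stack's own consensus, so the relative (gauge-invariant) shifts
  # are unchanged and the average itself moves by the applied vector
  moved <- array(0, dim(sim$stack$data))
  for (i in 1:8) moved[, , i] <- vlpsizer:::shift_image(sim$stack$data[, , i], 2, 1)
  avg3 <- align_and_average(particle_stack(moved, spec$pixel_size), max_shift = 6)
  delta <- avg3$shifts - avg$shifts
  expect_lt(max(abs(sweep(delta, 2, colMeans(delta)))), 0.3)
  cc <- vlpsizer:::corr_surface(avg3$average, avg$average)
  pk <- vlpsizer:::find_peak_shift(cc, 6)
  expect_lt(max(abs(c(pk$dx - 2, pk$dy - 1))), 0.5)
})

test_that("blank particles are excluded with a warning", {
  p <- simulate_shell_projection(shell_phantom_spec(), 96)$image
  arr <- array(c(p, matrix(0, 96, 96), p), c(96, 96, 3))
  expect_warning(avg <- align_and_average(particle_stack(arr), max_shift = 4),
                 "blank")
  expect_equal(avg$excluded, 2L)
  expect_equal(avg$n_particles, 2)
})

test_that("SNR estimator behaves at both extremes", {
  p <- simulate_shell_projection(shell_phantom_spec(), 96)$image
  ident <- particle_stack(array(rep(p, 8), c(96, 96, 8)))
  avg <- align_and_average(ident, max_shift = 4)
  expect_gt(estimate_snr(avg)$snr_average, 1e6)

  set.seed(3)
  noise <- array(rnorm(96 * 96 * 64), c(96, 96, 64))
  avgn <- align_and_average(particle_stack(noise), max_shift = 0)
  expect_lt(estimate_snr(avgn)$snr_average, 0.05)
  expect_error(estimate_snr(structure(list(n_particles = 1), class = "class_average")),
               "2 particles")
})

test_that("estimated per-particle SNR matches the generator's request", {
  spec <- shell_phantom_spec(snr = 0.1, seed = 5)
  sim <- simulate_micrograph_stack(spec, n_particles = 256, shift_max = 5)
  avg <- align_and_average(sim$stack, max_shift = 8)
  est <- estimate_snr(avg)$snr_particle
  expect_lt(abs(est - spec$snr) / spec$snr, 0.25)
})

test_that("average-to-phantom correlation is non-decreasing in stack size", {
  spec <- shell_phantom_spec(snr = 0.1, seed = 29)
  sim <- simulate_micrograph_stack(spec, n_particles = 256, shift_max = 4)
  ph <- as.vector(sim$phantom)
  cors <- vapply(c(4, 16, 64, 256), function(N) {
    st <- particle_stack(sim$stack$data[, , 1:N], spec$pixel_size)
    cor(as.vector(align_and_average(st, max_shift = 6)$average), ph)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})
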