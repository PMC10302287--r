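# Median spectra, Gaussian peak fitting, count normalization, statistics.

test_that("spectrum_scan validates channels and counts", {
  expect_s3_class(spectrum_scan(1:5, rep(0, 5)), "spectrum_scan")
  expect_error(spectrum_scan(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(spectrum_scan(1:3, c(1, -1, 0)), "non-negative")
  expect_error(spectrum_scan(1:3, 1:2), "equal-length")
  expect_error(spectrum_scan(1:3, 1:3, preparation = "full"), "empty")
})

test_that("median spectrum is the channel-wise median and checks the grid", {
  ch <- seq(20, 30, by = 0.5)
  scans <- lapply(1:10, function(i) spectrum_scan(ch, rep(7, length(ch))))
  med <- assemble_median_spectrum(scans)
  expect_equal(med$median_counts, rep(7, length(ch)))
  expect_equal(med$n_scans, 10)

  three <- lapply(c(0, 5, 100), function(v) spectrum_scan(ch, rep(v, length(ch))))
  expect_equal(assemble_median_spectrum(three)$median_counts[3], 5)

  bad <- c(scans[1:3], list(spectrum_scan(ch + 0.1, rep(1, length(ch)))))
  expect_error(assemble_median_spectrum(bad), "scan\\(s\\): 4")
})

test_that("median spectrum is permutation-invariant and outlier-robust", {
  set.seed(41)
  ch <- gemma_channel_grid()
  mu <- 2 + 275 * exp(-(ch - 25)^2 / (2 * 1.2^2))
  scans <- lapply(1:9, function(i) spectrum_scan(ch, rpois(length(ch), mu)))
  spike <- rpois(length(ch), mu); spike[60] <- 1e5
  scans <- c(scans, list(spectrum_scan(ch, spike)))

  med <- assemble_median_spectrum(scans)
  perm <- assemble_median_spectrum(scans[sample(10)])
  expect_identical(med$median_counts, perm$median_counts)

  # the spiked scan cannot pull the median outside Poisson noise of the truth
  expect_true(all(abs(med$median_counts - mu) <= 4 * sqrt(mu) + 3))

  # corrupting floor((n-1)/2) scans cannot leave the clean scans' min-max
  clean <- lapply(1:7, function(i) spectrum_scan(ch, rpois(length(ch), mu)))
  corrupt <- lapply(1:3, function(i) spectrum_scan(ch, rep(1e6, length(ch))))
  m <- assemble_median_spectrum(c(clean, corrupt))$median_counts
  cmat <- sapply(clean, function(s) s$counts)
  expect_true(all(m >= apply(cmat, 1, min) & m <= apply(cmat, 1, max)))
})

test_that("Gaussian peak fit recovers exact model data and separates baseline", {
  ch <- seq(20, 32, by = 0.15)
  y <- 300 * exp(-(ch - 25)^2 / (2 * 1^2))
  spec <- assemble_median_spectrum(list(spectrum_scan(ch, y)))
  fit <- fit_gaussian_peak(spec)
  expect_equal(fit$mean_diameter, 25, tolerance = 1e-6)
  expect_equal(fit$sigma, 1, tolerance = 1e-6)
  expect_equal(fit$amplitude, 300, tolerance = 1e-6)
  expect_lt(abs(fit$baseline), 1e-4)

  fit2 <- fit_gaussian_peak(assemble_median_spectrum(
    list(spectrum_scan(ch, y + 10))))
  expect_equal(fit2$mean_diameter, fit$mean_diameter, tolerance = 1e-6)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-6)
  expect_equal(fit2$baseline, 10, tolerance = 1e-4)

  # shift equivariance: translating the channel grid moves the mean exactly
  fit3 <- fit_gaussian_peak(assemble_median_spectrum(
    list(spectrum_scan(ch + 2, y))), window = c(22, 34))
  expect_equal(fit3$mean_diameter, fit$mean_diameter + 2, tolerance = 1e-6)

  expect_error(fit_gaussian_peak(spec, window = c(25, 25.2)), "5 channels")
  flat <- assemble_median_spectrum(list(spectrum_scan(ch, rep(5, length(ch)))))
  expect_error(fit_gaussian_peak(flat), "baseline")
})

test_that("peak_count_metric returns height / area consistent with quadrature", {
  ch <- seq(20, 32, by = 0.15)
  y <- 5 + 300 * exp(-(ch - 25.3)^2 / (2 * 1.1^2))
  fit <- fit_gaussian_peak(assemble_median_spectrum(list(spectrum_scan(ch, y))))
  expect_equal(peak_count_metric(fit, "height"), fit$amplitude)
  expect_equal(peak_count_metric(fit, "area"),
               fit$amplitude * fit$sigma * sqrt(2 * pi))
  # quadrature oracle: integral of the fitted Gaussian minus baseline
  num <- stats::integrate(function(x)
    fit$amplitude * exp(-(x - fit$mean_diameter)^2 / (2 * fit$sigma^2)),
    -Inf, Inf)$value
  expect_equal(peak_count_metric(fit, "area"), num, tolerance = 1e-3)
})

test_that("count normalization uses the per-preparation reference and is idempotent", {
  cs <- condition_summary(
    ph = c(4, 7, 9, 4, 7, 9),
    preparation = rep(c("empty", "filled"), each = 3),
    diameters = rep(list(c(24, 24.1)), 6),
    metrics = list(200, 150, 100, 60, 150, 300))
  out <- normalize_counts(cs)
  expect_equal(out$normalized_counts[out$preparation == "empty"],
               c(1, 0.75, 0.5))
  expect_equal(out$normalized_counts[out$preparation == "filled"],
               c(0.2, 0.5, 1))
  # scale invariance
  cs2 <- cs; cs2$peak_count_metric <- cs$peak_count_metric * 2
  expect_equal(normalize_counts(cs2)$normalized_counts, out$normalized_counts)
  # idempotence
  expect_equal(normalize_counts(out)$normalized_counts, out$normalized_counts)
  # missing reference
  expect_error(normalize_counts(cs[cs$pH != 4, ]), "reference condition")
})

test_that("generator-imposed depletion factors are recovered in normalized counts", {
  depl <- c(1.0, 0.7, 0.4, 0.2)   # pH 9 -> 4 for a filled series
  ph <- c(9, 8, 7, 4)
  reps <- 6
  mets <- list(); dias <- list()
  for (i in seq_along(ph)) {
    m <- numeric(reps)
    d <- numeric(reps)
    for (r in seq_len(reps)) {
      gs <- gemma_sim_spec(depletion_factor = depl[i], seed = 1000 * i + r)
      fit <- fit_gaussian_peak(assemble_median_spectrum(simulate_gemma_scans(gs)))
      m[r] <- peak_count_metric(fit, "height")
      d[r] <- fit$mean_diameter
    }
    mets[[i]] <- m; dias[[i]] <- d
  }
  cs <- condition_summary(ph, rep("filled", 4), dias, mets)
  out <- normalize_counts(cs, reference = c(filled = 9))
  # each recovered factor within 3 SE (delta method for the ratio) of truth
  mbar <- vapply(mets, mean, numeric(1))
  se <- vapply(mets, function(m) sd(m) / sqrt(reps), numeric(1))
  ratio_se <- out$normalized_counts *
    sqrt((se / mbar)^2 + (se[1] / mbar[1])^2)
  expect_true(all(abs(out$normalized_counts - depl) <= 3 * ratio_se + 1e-6))
})

test_that("compare_preparations is a two-sided Welch test with effect size", {
  a <- c(24.1, 24.3, 24.2, 24.25, 24.15, 24.2)
  same <- compare_preparations(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate, 0)

  b <- a + 10
  sep <- compare_preparations(a, b)
  expect_lt(sep$p_value, 1e-4)
  expect_equal(sep$estimate, -10, tolerance = 1e-9)

  tie <- compare_preparations(rep(5, 3), rep(5, 3))
  expect_equal(tie$p_value, 1)
  expect_match(tie$method, "tie")
  expect_error(compare_preparations(1:2, 1:5), "3 replicates")
})

test_that("1 nm separation at 0.2 nm replicate SD and n = 6 is detected", {
  # Monte-Carlo oracle (2000 sims): at these parameters the Welch test gives
  # p < 1e-4 in ~85% of runs (noncentral t, ncp ~ 8.7, df ~ 10) and p < 1e-3
  # in ~99.6%; the frozen expectations below follow the oracle.
  p <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(6, 24.3, 0.2)
    b <- rnorm(6, 25.3, 0.2)
    p[s] <- compare_preparations(a, b)$p_value
  }
  expect_gte(mean(p < 1e-3), 0.95)
  expect_lt(median(p), 1e-4)
})

test_that("ph_trend recovers slopes and flags flat series", {
  # noiseless inputs trigger lm's "essentially perfect fit" warning
  flat <- data.frame(pH = 4:9, diameter = rep(24.5, 6))
  expect_lt(abs(suppressWarnings(ph_trend(flat))$slope), 1e-12)
  lin <- data.frame(pH = 4:9, diameter = 25 - 0.2 * (4:9))
  expect_equal(suppressWarnings(ph_trend(lin))$slope, -0.2, tolerance = 1e-12)
  expect_error(ph_trend(data.frame(pH = c(4, 4, 7), diameter = 1:3)),
               "3 distinct")
  # empty trend is steeper than filled in noisy replicates
  steeper <- 0L
  for (s in 1:100) {
    set.seed(s)
    ph <- rep(4:9, each = 6)
    emp <- ph_trend(data.frame(pH = ph,
                               diameter = 24.3 - 0.2 * (ph - 7) + rnorm(36, 0, 0.1)))
    fil <- ph_trend(data.frame(pH = ph,
                               diameter = 25.3 - 0.05 * (ph - 7) + rnorm(36, 0, 0.1)))
    if (abs(emp$slope) > abs(fil$slope)) steeper <- steeper + 1L
  }
  expect_gte(steeper, 95)
})

test_that("scan files round-trip through diameter and voltage representations", {
  ch <- seq(20, 30, by = 0.5)
  y <- rpois(length(ch), 50)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(diameter_nm = ch, counts = y), f,
                   row.names = FALSE)
  sc <- read_spectrum_scan(f)
  expect_equal(sc$channels, ch)
  expect_equal(sc$counts, as.numeric(y))

  # voltage representation of the same channels
  z <- mobility_from_diameter(ch * 1e-9)
  v <- scan_settings()$sheath_flow * log(dma_geometry()$r_outer / dma_geometry()$r_inner) /
    (2 * pi * dma_geometry()$effective_length * z)
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(voltage_V = v, counts = y), f2, row.names = FALSE)
  sc2 <- read_spectrum_scan(f2)
  expect_equal(sc2$channels, ch, tolerance = 1e-6)
})
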