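# Unbiased particle-diameter determination from a 2D average: treat the image
# as a grey-value surface, cut iso-height sections at fractional levels between
# background and particle extreme, and fit circles to the section boundaries
# with iterative outlier trimming. Also provides line profiles for AFM
# topograph analysis.

#' Build a polarity-normalized intensity surface
#'
#' Treats an image as a 3D grey-value surface z(x, y). Polarity is normalized
#' so that the particle is the high region: with `polarity = "auto"` the
#' central-disk median is compared with the border-ring median and the image is
#' negated if the center is lower (cryo-TEM particles are dark, AFM particles
#' high; both map onto the same downstream code). The background level is the
#' border-ring median and the extreme is the maximum after normalization.
#'
#' @param img numeric matrix, at least 16 x 16
#' @param polarity `"auto"`, `"bright"` (no flip) or `"dark"` (always flip)
#' @param extreme_smooth sigma (px) of a Gaussian applied to the surface only
#'   for determining the extreme level. On a noisy average the raw maximum is
#'   inflated by the largest noise excursion, which silently raises every
#'   fractional section level; a smoothed maximum is robust. `0` (default)
#'   uses the raw maximum. Contours are always traced on the raw surface.
#' @return An object of class `intensity_surface` with fields `z`,
#'   `background`, `extreme`, `flipped`.
#' @export
build_intensity_surface <- function(img, polarity = c("auto", "bright", "dark"),
                                    extreme_smooth = 0) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(img))
  if (nrow(img) < 16L || ncol(img) < 16L) stop_domain("image must be at least 16 x 16 px")
  if (any(!is.finite(img))) stop_domain("image values must be finite")
  if (stats::sd(as.numeric(img)) == 0) stop_domain("image has zero variance")
  nr <- nrow(img); nc <- ncol(img)
  ring <- max(2L, round(0.05 * min(nr, nc)))
  border <- img[c(seq_len(ring), nr - seq_len(ring) + 1L), ]
  border <- c(border, img[, c(seq_len(ring), nc - seq_len(ring) + 1L)])
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  rad <- min(nr, nc) / 4
  xg <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  yg <- matrix(rep(0:(nr - 1), nc), nr, nc)
  center <- img[(xg - cx)^2 + (yg - cy)^2 <= rad^2]
  flip <- switch(polarity,
                 bright = FALSE,
                 dark = TRUE,
                 auto = stats::median(center) < stats::median(border))
  z <- if (flip) -img else img
  bg <- stats::median(if (flip) -border else border)
  extreme <- if (extreme_smooth > 0) max(gaussian_blur(z, extreme_smooth))
             else max(z)
  structure(list(z = z, background = bg, extreme = extreme, flipped = flip),
            class = "intensity_surface")
}

# Shoelace area of a closed polygon (0-based pixel coordinates).
polygon_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Ray-casting point-in-polygon.
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Extract an iso-height contour section of the surface
#'
#' Cuts the grey-value surface at
#' `level = background + level_fraction * (extreme - background)` and traces
#' the iso-contour with subpixel linear interpolation along grid edges
#' (marching-squares as implemented by [grDevices::contourLines()]). If
#' several closed contours exist at the level, the smallest one enclosing the
#' surface maximum (the particle boundary, not a surrounding background loop)
#' is kept.
#'
#' @param surface a [build_intensity_surface()] result
#' @param level_fraction fraction in (0, 1) of the background-to-extreme span
#' @return An object of class `contour_section` with `level`,
#'   `level_fraction`, and `points` (two-column matrix of subpixel 0-based
#'   `(x, y)` boundary points).
#' @export
extract_section <- function(surface, level_fraction) {
  stopifnot(inherits(surface, "intensity_surface"))
  if (!is.numeric(level_fraction) || length(level_fraction) != 1L ||
      level_fraction <= 0 || level_fraction >= 1) {
    stop_domain("`level_fraction` must lie strictly between 0 and 1")
  }
  z <- surface$z
  level <- surface$background + level_fraction * (surface$extreme - surface$background)
  nr <- nrow(z); nc <- ncol(z)
  # contourLines wants z[i, j] at (x[i], y[j]); transpose so x = columns
  cl <- grDevices::contourLines(x = 0:(nc - 1), y = 0:(nr - 1), z = t(z),
                                levels = level)
  if (!length(cl)) {
    stop("no contour found at level fraction ", level_fraction, call. = FALSE)
  }
  mx <- which(z == max(z), arr.ind = TRUE)[1, ]
  mx_x <- mx[2] - 1; mx_y <- mx[1] - 1
  best <- NULL; best_area <- Inf
  for (co in cl) {
    closed <- sqrt((co$x[1] - co$x[length(co$x)])^2 +
                     (co$y[1] - co$y[length(co$y)])^2) < 1e-8
    if (!closed) next
    if (!point_in_polygon(mx_x, mx_y, co$x, co$y)) next
    a <- polygon_area(co$x, co$y)
    if (a < best_area) { best <- co; best_area <- a }
  }
  if (is.null(best)) {
    stop("no closed contour enclosing the surface maximum at level fraction ",
         level_fraction, call. = FALSE)
  }
  pts <- cbind(x = best$x, y = best$y)
  # drop the duplicated closing point
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), ]
  structure(list(level = level, level_fraction = level_fraction, points = pts),
            class = "contour_section")
}

# Kasa algebraic circle fit: linear least squares of x^2 + y^2 on (2x, 2y, 1).
kasa_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  if (qr(A)$rank < 3L) stop_domain("degenerate geometry: points are collinear")
  sol <- qr.solve(A, x^2 + y^2)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) stop_domain("degenerate geometry: no real circle through the points")
  c(cx = sol[1], cy = sol[2], r = sqrt(r2))
}

# Geometric (orthogonal-distance) refinement by Gauss-Newton.
geometric_refine <- function(x, y, init, max_iter = 100, tol = 1e-12) {
  p <- init
  for (i in seq_len(max_iter)) {
    dx <- x - p[1]; dy <- y - p[2]
    r <- sqrt(dx^2 + dy^2)
    r[r < 1e-12] <- 1e-12
    f <- r - p[3]
    J <- cbind(-dx / r, -dy / r, -1)
    step <- tryCatch(qr.solve(J, -f), error = function(e) rep(0, 3))
    p <- p + step
    if (max(abs(step)) < tol * max(1, p[3])) break
  }
  names(p) <- c("cx", "cy", "r")
  p
}

#' Robust circle fit with iterative outlier trimming
#'
#' Fits a circle to 2D points: Kasa algebraic least squares for
#' initialization, refined by geometric (orthogonal-distance) least squares,
#' then iteratively trims points whose absolute radial residual exceeds
#' `trim_k` times the MAD of the residuals (MAD with the usual 1.4826
#' consistency scaling) and refits, up to `max_iter` trimming rounds. This
#' formalizes the visual exclusion of off-circle section points. Entirely
#' deterministic. `trim_k = Inf` disables trimming.
#'
#' @param points two-column matrix of `(x, y)` points (or a `contour_section`)
#' @param trim_k trimming threshold in MAD units (default 3)
#' @param max_iter maximum trimming rounds (default 5)
#' @return An object of class `circle_fit` with `center`, `radius`,
#'   `rms_residual` (over included points), `included`, `excluded`
#'   (index vectors), `n_iterations`.
#' @export
fit_circle <- function(points, trim_k = 3, max_iter = 5) {
  if (inherits(points, "contour_section")) points <- points$points
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 3L) stop_domain("need at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  included <- seq_len(nrow(points))
  n_iter <- 0L
  p <- NULL
  repeat {
    n_iter <- n_iter + 1L
    p <- geometric_refine(x[included], y[included],
                          kasa_fit(x[included], y[included]))
    res <- sqrt((x[included] - p[1])^2 + (y[included] - p[2])^2) - p[3]
    if (!is.finite(trim_k) || n_iter > max_iter) break
    thr <- trim_k * max(stats::mad(res), 1e-9 * p[3])
    out <- abs(res) > thr
    if (!any(out)) break
    if (sum(!out) < 3L) stop("trimming removed too many points", call. = FALSE)
    included <- included[!out]
  }
  res <- sqrt((x[included] - p[1])^2 + (y[included] - p[2])^2) - p[3]
  structure(list(center = c(x = unname(p[1]), y = unname(p[2])),
                 radius = unname(p[3]),
                 rms_residual = sqrt(mean(res^2)),
                 included = included,
                 excluded = setdiff(seq_len(nrow(points)), included),
                 n_iterations = n_iter),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.3f, %.3f), radius %.4f px, rms %.4f px, %d excluded\n",
              x$center[1], x$center[2], x$radius, x$rms_residual,
              length(x$excluded)))
  invisible(x)
}

#' Estimate a particle diameter from a 2D average
#'
#' The full sizing workflow: build the polarity-normalized intensity surface,
#' extract iso-height sections at the requested fractional levels (default
#' three levels 0.35 / 0.50 / 0.65 of the background-to-extreme span), fit a
#' trimmed circle to each section, and convert radii to diameters with the
#' pixel size. Levels whose contour extraction or fit fails are skipped with a
#' warning; at least one level must succeed.
#'
#' @param img numeric matrix, or a `class_average` (its pixel size is used)
#' @param levels fractional section levels in (0, 1)
#' @param pixel_size pixel size in Angstrom (ignored if `img` carries one)
#' @param polarity passed to [build_intensity_surface()]
#' @param trim_k,max_iter passed to [fit_circle()]
#' @param extreme_smooth passed to [build_intensity_surface()]
#' @param calibration optional [shell_contour_calibration()]: maps each
#'   level's fitted contour radius back to the outer particle diameter through
#'   the forward model of the shell projection. Without it the reported
#'   diameter is that of the iso-density contour itself, which for a
#'   shell-shaped density lies inside the outer envelope.
#' @return An object of class `diameter_estimate`: `per_level` data frame
#'   (`level_fraction`, `radius_px`, `diameter_nm`, `rms_px`, `n_excluded`),
#'   `mean_diameter` and `sd` in nm, `pixel_size`.
#' @export
estimate_diameter <- function(img, levels = c(0.35, 0.5, 0.65),
                              pixel_size = 4.124, polarity = "auto",
                              trim_k = 3, max_iter = 5, extreme_smooth = 0,
                              calibration = NULL) {
  if (inherits(img, "class_average")) {
    pixel_size <- img$pixel_size
    img <- img$average
  }
  check_scalar_pos(pixel_size, "pixel_size")
  if (length(levels) < 1L) stop_domain("need at least one level")
  surface <- build_intensity_surface(img, polarity,
                                     extreme_smooth = extreme_smooth)
  rows <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    fit <- tryCatch({
      sec <- extract_section(surface, levels[i])
      fit_circle(sec, trim_k = trim_k, max_iter = max_iter)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("level %.2f skipped: %s", levels[i], conditionMessage(fit)))
      next
    }
    dia <- if (is.null(calibration)) 2 * fit$radius * pixel_size / 10
           else calibration$diameter(levels[i], fit$radius)
    rows[[i]] <- data.frame(level_fraction = levels[i],
                            radius_px = fit$radius,
                            diameter_nm = dia,
                            rms_px = fit$rms_residual,
                            n_excluded = length(fit$excluded))
  }
  per_level <- do.call(rbind, rows)
  if (is.null(per_level) || nrow(per_level) < 1L) {
    stop("diameter estimation failed at every level", call. = FALSE)
  }
  structure(list(per_level = per_level,
                 mean_diameter = mean(per_level$diameter_nm),
                 sd = if (nrow(per_level) > 1L) stats::sd(per_level$diameter_nm) else 0,
                 levels = per_level$level_fraction,
                 pixel_size = pixel_size),
            class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat(sprintf("<diameter_estimate> %.3f +/- %.3f nm over %d level(s) at %.3f A/px\n",
              x$mean_diameter, x$sd, nrow(x$per_level), x$pixel_size))
  invisible(x)
}

# Radial profile of a circularly symmetric image blurred by an isotropic 2D
# Gaussian, computed by the exact Hankel-type quadrature
#   I(r) = int p(s) (s / sigma^2) exp(-(r - s)^2 / (2 sigma^2))
#              I0s(r s / sigma^2) ds,
# I0s the exponentially scaled modified Bessel function. This is a 1D
# computation independent of the 2D image pipeline, usable as an oracle.
blurred_radial_profile <- function(profile_px, sigma, r, s_max, ds = 0.05) {
  if (sigma <= 0) return(profile_px(r))
  s <- seq(ds / 2, s_max, by = ds)
  p <- profile_px(s)
  keep <- p != 0
  s <- s[keep]; p <- p[keep]
  if (!length(s)) return(numeric(length(r)))
  g <- exp(-(outer(r, s, "-"))^2 / (2 * sigma^2))
  nz <- which(g > 1e-12)            # Bessel only where the Gaussian survives
  w <- matrix(0, length(r), length(s))
  x <- (outer(r, s) / sigma^2)[nz]
  w[nz] <- g[nz] * besselI(x, 0, expon.scaled = TRUE)
  as.numeric(w %*% (p * s / sigma^2)) * ds
}

#' Forward-model calibration of level-contour radii for shell projections
#'
#' For a spherical-shell density, the iso-contour at a fraction of the
#' background-to-extreme span lies inside the outer envelope, so the raw
#' contour diameter underestimates the particle diameter. This calibration
#' computes, from the analytic projection profile blurred by the PSF (a 1D
#' Bessel quadrature independent of the image pipeline), the expected contour
#' radius at each level for a grid of candidate outer diameters, and returns
#' the inverse map from a measured contour radius back to the outer diameter.
#'
#' @param spec a [shell_phantom_spec()] describing the particle model (its
#'   `outer_diameter` only centers the calibration grid)
#' @param levels level fractions to calibrate
#' @param extreme_smooth must match the `extreme_smooth` used in
#'   [estimate_diameter()]: the predicted extreme is taken from the profile
#'   blurred by `sqrt(psf_sigma^2 + extreme_smooth^2)`
#' @param d_rel relative span of the calibration grid around
#'   `spec$outer_diameter`
#' @param n_grid number of grid diameters
#' @return Object of class `contour_calibration` with a `diameter(level,
#'   radius_px)` function and the underlying `table`.
#' @export
shell_contour_calibration <- function(spec, levels = c(0.35, 0.5, 0.65),
                                      extreme_smooth = 0,
                                      d_rel = c(0.7, 1.3), n_grid = 19) {
  stopifnot(inherits(spec, "shell_phantom_spec"))
  px_nm <- spec$pixel_size / 10
  sig_e <- sqrt(spec$psf_sigma^2 + extreme_smooth^2)
  d_grid <- seq(d_rel[1], d_rel[2], length.out = n_grid) * spec$outer_diameter
  tab <- list()
  for (D in d_grid) {
    sp <- spec
    sp$outer_diameter <- D
    sp$shell_thickness <- min(spec$shell_thickness, D / 2 * 0.999)
    prof_nm <- shell_profile_fun(sp)
    prof_px <- function(r_px) prof_nm(r_px * px_nm)
    r_max <- D / 2 / px_nm + 5 * sig_e + 2
    r <- seq(0, r_max, by = 0.05)
    s_hi <- D / 2 / px_nm + 0.1
    i_psf <- blurred_radial_profile(prof_px, spec$psf_sigma, r, s_hi)
    i_ext <- if (sig_e > spec$psf_sigma)
      blurred_radial_profile(prof_px, sig_e, r, s_hi) else i_psf
    extreme <- max(i_ext)
    for (f in levels) {
      lev <- f * extreme   # background of the noiseless model is 0
      # outermost downward crossing
      idx <- which(i_psf >= lev)
      if (!length(idx)) next
      k <- max(idx)
      r_cross <- if (k < length(r)) {
        r[k] + (i_psf[k] - lev) / (i_psf[k] - i_psf[k + 1]) * 0.05
      } else r[k]
      tab[[length(tab) + 1L]] <-
        data.frame(level = f, diameter = D, radius_px = r_cross)
    }
  }
  tab <- do.call(rbind, tab)
  structure(list(
    table = tab,
    levels = levels,
    diameter = function(level, radius_px) {
      sub <- tab[abs(tab$level - level) < 1e-9, ]
      if (nrow(sub) < 2L) stop_domain("level ", level, " not calibrated")
      stats::approx(sub$radius_px, sub$diameter, xout = radius_px,
                    rule = 2)$y
    }), class = "contour_calibration")
}

#' Sample a line profile through an image
#'
#' Bilinear interpolation at uniform spacing along a segment, e.g. a
#' longitudinal or medial plane section through an AFM topograph or a 2D
#' average. Positions are reported in physical units (`scale` units per
#' pixel); for AFM height maps the values themselves are heights in nm.
#'
#' @param img numeric matrix (rows = y, cols = x)
#' @param from,to segment endpoints as `(x, y)` in 0-based pixel coordinates
#' @param spacing sample spacing in physical units (default one pixel)
#' @param scale physical length of one pixel (e.g. nm per px), default 1
#' @return An object of class `line_profile` with `positions` (strictly
#'   increasing, physical units) and `values`.
#' @export
extract_line_profile <- function(img, from, to, spacing = NULL, scale = 1) {
  stopifnot(is.matrix(img), length(from) == 2L, length(to) == 2L)
  check_scalar_pos(scale, "scale")
  len_px <- sqrt(sum((to - from)^2))
  if (len_px == 0) stop_domain("line endpoints coincide")
  if (any(c(from, to) < 0) || from[1] > ncol(img) - 1 || to[1] > ncol(img) - 1 ||
      from[2] > nrow(img) - 1 || to[2] > nrow(img) - 1) {
    stop_domain("line endpoints must lie inside the image")
  }
  spacing <- spacing %||% scale
  n <- max(2L, floor(len_px * scale / spacing) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- from[1] + t * (to[1] - from[1])
  ys <- from[2] + t * (to[2] - from[2])
  structure(list(positions = t * len_px * scale,
                 values = bilinear_at(img, xs, ys),
                 from = from, to = to, scale = scale),
            class = "line_profile")
}
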