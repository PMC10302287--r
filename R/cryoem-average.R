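# Reference-based 2D alignment and averaging of boxed particle images, the
# desk-scale stand-in for subtomogram-averaging software used in 2D mode.
# Registration maximizes cross-correlation (computed by FFT) over integer
# shifts, refined to subpixel by quadratic interpolation of the correlation
# peak, optionally over a coarse rotation grid. Coordinates are 0-based,
# (x right, y down), with pixel centers at integer positions.

#' A micrograph
#' @param data numeric matrix of grey values, rows = y, cols = x
#' @param pixel_size pixel size in Angstrom
#' @return Object of class `micrograph`.
#' @export
micrograph <- function(data, pixel_size = 4.124) {
  stopifnot(is.matrix(data))
  if (any(!is.finite(data))) stop_domain("micrograph values must be finite")
  check_scalar_pos(pixel_size, "pixel_size")
  structure(list(data = data, pixel_size = pixel_size), class = "micrograph")
}

#' A stack of boxed particle images
#' @param data y-by-x-by-N numeric array of square boxes (even box size)
#' @param pixel_size pixel size in Angstrom
#' @return Object of class `particle_stack`.
#' @export
particle_stack <- function(data, pixel_size = 4.124) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[1] != dim(data)[2]) stop_domain("boxes must be square")
  if (dim(data)[1] %% 2L != 0L) stop_domain("box size must be even")
  check_scalar_pos(pixel_size, "pixel_size")
  structure(list(data = data, box_size = dim(data)[1],
                 n = dim(data)[3], pixel_size = pixel_size),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat(sprintf("<particle_stack> %d particle(s), box %d px, %.3f A/px\n",
              x$n, x$box_size, x$pixel_size))
  invisible(x)
}

#' Extract boxed particles from a micrograph
#'
#' Cuts a square `box_size` sub-image around each picked coordinate. A
#' coordinate `(cx, cy)` (0-based) sits at box position `box_size / 2` in both
#' axes. Coordinates whose box would leave the micrograph are rejected and
#' reported by index.
#'
#' @param m a [micrograph()]
#' @param coords two-column matrix of 0-based `(x, y)` particle centers
#' @param box_size even box size in pixels
#' @return A [particle_stack()]; rejected picks are in `attr(, "rejected")`.
#' @export
extract_particles <- function(m, coords, box_size) {
  stopifnot(inherits(m, "micrograph"))
  coords <- matrix(as.numeric(coords), ncol = 2)
  if (box_size %% 2L != 0L || box_size < 4L) {
    stop_domain("`box_size` must be an even integer >= 4")
  }
  nr <- nrow(m$data); nc <- ncol(m$data)
  if (box_size > min(nr, nc)) stop_domain("box larger than the micrograph")
  half <- box_size %/% 2L
  cx <- round(coords[, 1]); cy <- round(coords[, 2])
  # 0-based extents [c - half, c + half - 1]
  ok <- cx - half >= 0 & cx + half - 1 <= nc - 1 &
    cy - half >= 0 & cy + half - 1 <= nr - 1
  if (!any(ok)) stop_domain("all coordinates out of bounds for this box size")
  if (any(!ok)) {
    warning(sprintf("rejected %d out-of-bounds coordinate(s): %s",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  }
  keep <- which(ok)
  out <- array(0, dim = c(box_size, box_size, length(keep)))
  for (i in seq_along(keep)) {
    k <- keep[i]
    rows <- (cy[k] - half):(cy[k] + half - 1) + 1L
    cols <- (cx[k] - half):(cx[k] + half - 1) + 1L
    out[, , i] <- m$data[rows, cols]
  }
  st <- particle_stack(out, m$pixel_size)
  attr(st, "rejected") <- which(!ok)
  st
}

# ---- registration internals -------------------------------------------------

normalize_box <- function(img) {
  s <- stats::sd(as.numeric(img))
  if (!is.finite(s) || s == 0) return(NULL)
  (img - mean(img)) / s
}

# Shift image content by (dx, dy) pixels: out(x, y) = img(x - dx, y - dy),
# bilinear, zero fill outside.
shift_image <- function(img, dx, dy) {
  n <- nrow(img); m <- ncol(img)
  xg <- matrix(rep(0:(m - 1), each = n), n, m)
  yg <- matrix(rep(0:(n - 1), m), n, m)
  sx <- xg - dx; sy <- yg - dy
  out <- bilinear_at(img, sx, sy)
  out[sx < 0 | sx > m - 1 | sy < 0 | sy > n - 1] <- 0
  matrix(out, n, m)
}

# Subpixel shift by a Fourier phase ramp: exact (no interpolation low-pass),
# cyclic wrap at the box edge. out(x, y) = img(x - dx, y - dy).
fourier_shift <- function(img, dx, dy) {
  if (dx == 0 && dy == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  fy <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fx <- c(0:(m %/% 2), -((m - m %/% 2 - 1):1)) / m
  ph <- exp(-2i * pi * (outer(fy * dy, fx * dx, "+")))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n * m)
}

# Rotate image by `angle` degrees (counter-clockwise in (x right, y down)
# coordinates) about the box center, bilinear, zero fill.
rotate_image <- function(img, angle) {
  if (angle %% 360 == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  cx <- (m - 1) / 2; cy <- (n - 1) / 2
  th <- -angle * pi / 180
  xg <- matrix(rep(0:(m - 1), each = n), n, m) - cx
  yg <- matrix(rep(0:(n - 1), m), n, m) - cy
  sx <- cos(th) * xg - sin(th) * yg + cx
  sy <- sin(th) * xg + cos(th) * yg + cy
  out <- bilinear_at(img, sx, sy)
  out[sx < 0 | sx > m - 1 | sy < 0 | sy > n - 1] <- 0
  matrix(out, n, m)
}

# Cyclic cross-correlation surface between two same-size images via FFT.
# corr_surface(img, ref)[s] = sum_x img(x) * ref(x - s): if img equals ref
# displaced by t, the peak sits at s = t.
corr_surface <- function(img, ref) {
  Re(stats::fft(stats::fft(img) * Conj(stats::fft(ref)), inverse = TRUE)) /
    length(img)
}

# Locate the correlation peak within |shift| <= max_shift; returns the
# subpixel displacement of `img` relative to `ref` and the peak value.
# Ties broken toward the smallest shift magnitude.
find_peak_shift <- function(cc, max_shift) {
  n <- nrow(cc)
  if (max_shift == 0) {
    return(list(dx = 0, dy = 0, value = cc[1, 1]))
  }
  sv <- c(0:max_shift, -(max_shift:1))          # shift values searched
  idx <- c(1:(max_shift + 1), n - (max_shift:1) + 1)  # their cyclic indices
  sub <- cc[idx, idx]
  mag <- outer(sv^2, sv^2, "+")
  o <- order(mag)                                # smallest |shift| first
  best <- o[which.max(sub[o])]
  iy <- (best - 1) %% length(idx) + 1
  ix <- (best - 1) %/% length(idx) + 1
  dy <- sv[iy]; dx <- sv[ix]
  at <- function(y, x) cc[(y %% n) + 1, (x %% n) + 1]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) return(0)
    max(min((cm - cp) / (2 * den), 0.5), -0.5)
  }
  ddy <- if (abs(dy) < max_shift)
    refine(at(dy - 1, dx), at(dy, dx), at(dy + 1, dx)) else 0
  ddx <- if (abs(dx) < max_shift)
    refine(at(dy, dx - 1), at(dy, dx), at(dy, dx + 1)) else 0
  list(dx = dx + ddx, dy = dy + ddy, value = at(dy, dx))
}

#' Align a particle stack and compute its 2D class average
#'
#' Iterative reference-based registration: the initial reference is the
#' unaligned mean; each iteration registers every particle to the current
#' reference by maximizing cross-correlation over integer shifts within
#' `max_shift` (refined to subpixel by quadratic interpolation of the
#' correlation peak) and, optionally, a coarse rotation grid, then rebuilds the
#' reference as the mean of the aligned particles. Every box is normalized to
#' zero mean and unit variance before correlation; blank (zero-variance)
#' particles are excluded with a warning.
#'
#' @param stack a [particle_stack()] with at least 2 usable particles
#' @param max_shift maximum shift searched, in px; must be `< box_size / 4`.
#'   `0` disables the translation search.
#' @param rotation_step rotation grid step in degrees over `[0, 360)`; `0` or
#'   `NULL` disables the rotation search (appropriate for quasi-spherical
#'   particles, which are rotation-insensitive)
#' @param n_iter maximum refinement iterations
#' @param tol convergence threshold on the largest shift update, px
#' @param cc_smooth Gaussian band-limit applied to the correlation surface,
#'   expressed as a real-space sigma in px. White noise is flat in frequency
#'   while the blurred particle signal lives at low frequency, so a mild
#'   low-pass of the correlation (default 1.5 px) sharpens peak localization
#'   at low SNR without biasing the peak position; `0` disables it.
#' @return An object of class `class_average` with the averaged image, the
#'   per-particle `shifts` (px; the correction applied to register each
#'   particle, so a particle displaced by `+t` receives shift `-t`) and
#'   `rotations` (deg), excluded particle indices, and the aligned stack.
#' @export
align_and_average <- function(stack, max_shift = 8, rotation_step = 0,
                              n_iter = 5, tol = 0.1, cc_smooth = 1.5) {
  stopifnot(inherits(stack, "particle_stack"))
  b <- stack$box_size
  if (max_shift < 0 || max_shift >= b / 4) {
    stop_domain("`max_shift` must satisfy 0 <= max_shift < box_size / 4")
  }
  max_shift <- as.integer(max_shift)
  angles <- if (is.null(rotation_step) || rotation_step <= 0) 0
            else seq(0, 360 - rotation_step, by = rotation_step)

  norm <- vector("list", stack$n)
  for (i in seq_len(stack$n)) norm[[i]] <- normalize_box(stack$data[, , i])
  excluded <- which(vapply(norm, is.null, logical(1)))
  if (length(excluded)) {
    warning("excluded blank (zero-variance) particle(s): ",
            paste(excluded, collapse = ", "))
  }
  use <- setdiff(seq_len(stack$n), excluded)
  if (length(use) < 2L) stop_domain("need at least 2 non-blank particles")

  shifts <- matrix(0, stack$n, 2, dimnames = list(NULL, c("dx", "dy")))
  rots <- numeric(stack$n)
  nu <- length(use)
  iterations <- 0L

  # everything lives in the Fourier domain: shifting a particle is a phase
  # ramp, the running reference is the sum of aligned transforms, and each
  # particle is matched against the leave-one-out reference so its own noise
  # (a delta spike at the current shift) cannot lock a misalignment in place
  fy <- c(0:(b %/% 2), -((b - b %/% 2 - 1):1)) / b
  phase_ramp <- function(dx, dy) exp(-2i * pi * outer(fy * dy, fy * dx, "+"))
  cc_filter <- if (cc_smooth > 0) {
    exp(-2 * pi^2 * cc_smooth^2 * outer(fy^2, fy^2, "+"))
  } else 1
  fts <- lapply(use, function(i) stats::fft(norm[[i]]))
  aligned_ft <- fts
  f_sum <- Reduce(`+`, aligned_ft)

  for (it in seq_len(n_iter)) {
    iterations <- it
    max_update <- 0
    new_aligned <- aligned_ft
    for (j in seq_len(nu)) {
      i <- use[j]
      # leave-one-out against the reference frozen at the iteration start:
      # updates are simultaneous (Jacobi), keeping the result independent of
      # particle order
      f_ref <- if (nu > 2L) (f_sum - aligned_ft[[j]]) / (nu - 1) else
        f_sum / nu
      best <- NULL
      for (a in angles) {
        # re-normalize after rotation: interpolation attenuates high
        # frequencies and would otherwise bias the score toward 0/90/180/270
        ft <- if (a == 0) fts[[j]] else
          stats::fft(normalize_box(rotate_image(norm[[i]], a)))
        cc <- Re(stats::fft(ft * Conj(f_ref) * cc_filter,
                            inverse = TRUE)) / (b * b)
        pk <- find_peak_shift(cc, max_shift)
        if (is.null(best) || pk$value > best$value) {
          best <- pk; best$angle <- a; best$ft <- ft
        }
      }
      new_shift <- c(-best$dx, -best$dy)
      max_update <- max(max_update, max(abs(new_shift - shifts[i, ])))
      shifts[i, ] <- new_shift
      rots[i] <- best$angle
      new_aligned[[j]] <- best$ft * phase_ramp(new_shift[1], new_shift[2])
    }
    aligned_ft <- new_aligned
    f_sum <- Reduce(`+`, aligned_ft)
    if (max_update < tol) break
  }

  aligned <- array(0, dim = c(b, b, nu))
  for (j in seq_len(nu)) {
    aligned[, , j] <- Re(stats::fft(aligned_ft[[j]], inverse = TRUE)) / (b * b)
  }
  ref <- apply(aligned, c(1, 2), mean)

  structure(list(average = ref,
                 shifts = shifts, rotations = rots,
                 n_particles = length(use),
                 iterations_run = iterations,
                 excluded = excluded,
                 aligned = aligned,
                 box_size = b, pixel_size = stack$pixel_size,
                 max_shift = max_shift),
            class = "class_average")
}

#' @export
print.class_average <- function(x, ...) {
  cat(sprintf("<class_average> %d particle(s), box %d px, %d iteration(s), %d excluded\n",
              x$n_particles, x$box_size, x$iterations_run, length(x$excluded)))
  invisible(x)
}

#' Estimate the signal-to-noise ratio of a class average
#'
#' The noise variance per particle is estimated from the particle-minus-average
#' residuals of the aligned stack (scaled by `N / (N - 1)` to undo the shared
#' mean); the signal variance is the variance of the average inside a central
#' disk mask minus the noise left in the average (`sigma^2 / N`). Reported are
#' the SNR of the average (`signal / (sigma^2 / N)`, which grows linearly with
#' N for fixed per-particle SNR) and the implied per-particle SNR
#' (`snr_average / N`).
#'
#' @param avg a [align_and_average()] result carrying the aligned stack
#' @param mask_radius radius of the central disk mask in px; default
#'   `0.35 * box_size`, sized to cover a default-geometry particle
#' @return List with `snr_average`, `snr_particle`, `signal_variance`,
#'   `noise_variance`, `n`.
#' @export
estimate_snr <- function(avg, mask_radius = NULL) {
  stopifnot(inherits(avg, "class_average"))
  n <- avg$n_particles
  if (n < 2L) stop_domain("SNR estimation needs at least 2 particles")
  b <- avg$box_size
  mask_radius <- mask_radius %||% (0.35 * b)
  cx <- (b - 1) / 2
  xg <- matrix(rep(0:(b - 1), each = b), b, b)
  yg <- matrix(rep(0:(b - 1), b), b, b)
  mask <- (xg - cx)^2 + (yg - cx)^2 <= mask_radius^2

  resid_var <- mean(vapply(seq_len(n), function(j) {
    r <- avg$aligned[, , j] - avg$average
    mean(r^2)
  }, numeric(1)))
  noise_var <- resid_var * n / (n - 1)
  avg_vals <- avg$average[mask]
  sig_var <- max(stats::var(avg_vals) - noise_var / n, 0)
  noise_in_avg <- max(noise_var / n, .Machine$double.eps)
  list(snr_average = sig_var / noise_in_avg,
       snr_particle = sig_var / noise_in_avg / n,
       signal_variance = sig_var,
       noise_variance = noise_var,
       n = n)
}
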