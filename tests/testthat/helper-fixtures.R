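# Shared fixtures, all built in code.

# Smooth dome with value 1 at the center and a half-height crossing at
# exactly `r_half` px from the center; clipped to 0 well inside the box.
make_dome <- function(box = 96, r_half = 30) {
  ctr <- (box - 1) / 2
  xg <- outer(rep(1, box), 0:(box - 1))
  yg <- t(xg)
  r2 <- (xg - ctr)^2 + (yg - ctr)^2
  pmax(1 - r2 / (2 * r_half^2), 0)
}

# Noisy circle points: radius-r circle with Gaussian radial noise.
make_circle_points <- function(n = 200, r = 30, center = c(50, 50), sd = 0.3) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rr <- r + stats::rnorm(n, 0, sd)
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

# Independent brute-force circle-fit oracle: coarse-to-fine grid search over
# the center; for each candidate center the least-squares radius is the mean
# point distance. Refined down to a 0.002 px center grid.
grid_circle_oracle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  cx <- mean(x); cy <- mean(y)
  span <- 2
  for (step in c(0.2, 0.02, 0.002)) {
    gx <- seq(cx - span, cx + span, by = step)
    gy <- seq(cy - span, cy + span, by = step)
    best <- c(Inf, cx, cy)
    for (ax in gx) {
      dx2 <- (x - ax)^2
      for (ay in gy) {
        d <- sqrt(dx2 + (y - ay)^2)
        ss <- sum((d - mean(d))^2)
        if (ss < best[1]) best <- c(ss, ax, ay)
      }
    }
    cx <- best[2]; cy <- best[3]
    span <- step * 2
  }
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  list(center = c(cx, cy), radius = mean(d))
}
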