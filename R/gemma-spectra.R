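# Analysis of nES-GEMMA mobility spectra: median spectra from repeated scans,
# Gaussian monomer-peak fitting, count normalization across a pH series, and
# the group statistics for empty-vs-filled VLP preparations.

#' A single mobility-spectrum scan
#'
#' Channelized particle counts versus EM diameter from one classifier up-scan.
#'
#' @param channels strictly increasing EM diameters in nm
#' @param counts non-negative particle counts, one per channel
#' @param sample_id,ph,preparation,scan_index optional metadata; `preparation`
#'   must be `"empty"` or `"filled"` when given
#' @return An object of class `spectrum_scan`.
#' @export
spectrum_scan <- function(channels, counts, sample_id = NA_character_,
                          ph = NA_real_, preparation = NA_character_,
                          scan_index = NA_integer_) {
  channels <- as.numeric(channels); counts <- as.numeric(counts)
  if (length(channels) != length(counts) || length(channels) < 1L) {
    stop_domain("`channels` and `counts` must be equal-length, non-empty")
  }
  if (any(diff(channels) <= 0)) stop_domain("`channels` must be strictly increasing")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_domain("`counts` must be finite and non-negative")
  }
  if (!is.na(preparation) && !preparation %in% c("empty", "filled")) {
    stop_domain('`preparation` must be "empty" or "filled"')
  }
  structure(list(channels = channels, counts = counts,
                 sample_id = sample_id, ph = ph, preparation = preparation,
                 scan_index = scan_index),
            class = "spectrum_scan")
}

#' @export
print.spectrum_scan <- function(x, ...) {
  cat(sprintf("<spectrum_scan> %d channels, %.2f-%.2f nm, total counts %g\n",
              length(x$channels), min(x$channels), max(x$channels),
              sum(x$counts)))
  invisible(x)
}

# Channel grids must agree exactly after rounding to 0.01 nm; silent
# interpolation across grids is never attempted.
same_grid <- function(a, b) {
  length(a) == length(b) && all(round(a, 2) == round(b, 2))
}

#' Median spectrum of repeated scans
#'
#' Per-channel median of the counts across scans, the instrument-software
#' convention for combining repeated up-scans of one sample (typically 10).
#' The median makes single-scan artifacts (electrospray spikes, dropouts)
#' innocuous: up to `floor((n - 1) / 2)` corrupted scans cannot move any
#' channel's value outside the range of the clean scans.
#'
#' @param scans list of [spectrum_scan()] objects on identical channel grids
#' @return An object of class `mobility_spectrum` with fields `channels`,
#'   `median_counts`, `n_scans`.
#' @export
assemble_median_spectrum <- function(scans) {
  if (!is.list(scans) || length(scans) < 1L ||
      !all(vapply(scans, inherits, logical(1), "spectrum_scan"))) {
    stop_domain("`scans` must be a non-empty list of spectrum_scan objects")
  }
  ref <- scans[[1]]$channels
  bad <- which(!vapply(scans, function(s) same_grid(s$channels, ref), logical(1)))
  if (length(bad)) {
    stop_domain("channel grids differ from scan 1 for scan(s): ",
                paste(bad, collapse = ", "))
  }
  counts <- vapply(scans, function(s) s$counts, numeric(length(ref)))
  counts <- matrix(counts, nrow = length(ref))
  structure(list(channels = ref,
                 median_counts = apply(counts, 1, stats::median),
                 n_scans = length(scans)),
            class = "mobility_spectrum")
}

#' @export
print.mobility_spectrum <- function(x, ...) {
  cat(sprintf("<mobility_spectrum> median of %d scan(s), %d channels, peak %g counts at %.2f nm\n",
              x$n_scans, length(x$channels), max(x$median_counts),
              x$channels[which.max(x$median_counts)]))
  invisible(x)
}

#' Fit a Gaussian monomer peak to a mobility spectrum
#'
#' Least-squares fit of `baseline + amplitude * exp(-(d - mean)^2 / (2 sigma^2))`
#' restricted to a diameter window around the monomer peak. Starting values use
#' robust heuristics: mean at the argmax channel, sigma from the full width at
#' half maximum divided by 2.355, baseline from the window-edge median. The
#' default window 20-32 nm brackets the ~25 nm VLP monomer.
#'
#' @param spec a [mobility_spectrum()] (or a `spectrum_scan`)
#' @param window numeric length-2, diameter window in nm
#' @return An object of class `gaussian_peak_fit` with fields `mean_diameter`,
#'   `sigma`, `amplitude`, `baseline`, `rms_residual`, `window`, `converged`,
#'   `n_channels`.
#' @export
fit_gaussian_peak <- function(spec, window = c(20, 32)) {
  if (inherits(spec, "spectrum_scan")) {
    spec <- structure(list(channels = spec$channels,
                           median_counts = spec$counts, n_scans = 1L),
                      class = "mobility_spectrum")
  }
  stopifnot(inherits(spec, "mobility_spectrum"))
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_domain("`window` must be c(lo, hi) with lo < hi")
  }
  sel <- spec$channels >= window[1] & spec$channels <= window[2]
  d <- spec$channels[sel]; y <- spec$median_counts[sel]
  if (length(d) < 5L) stop_domain("window must contain at least 5 channels")

  edge_k <- max(2L, length(y) %/% 10L)
  b0 <- stats::median(c(utils::head(y, edge_k), utils::tail(y, edge_k)))
  a0 <- max(y) - b0
  if (a0 <= 0) stop_domain("no peak above the baseline estimate inside the window")
  mu0 <- d[which.max(y)]
  half <- b0 + a0 / 2
  above <- which(y >= half)
  fwhm <- if (length(above) >= 2L) d[max(above)] - d[min(above)] else diff(window) / 4
  s0 <- max(fwhm / 2.355, diff(range(d)) / length(d))

  fit <- tryCatch(
    stats::nls(y ~ b + a * exp(-(d - mu)^2 / (2 * s^2)),
               start = list(a = a0, mu = mu0, s = s0, b = b0),
               lower = c(a = 1e-12, mu = window[1], s = 1e-6, b = -Inf),
               upper = c(a = Inf, mu = window[2], s = diff(window), b = Inf),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # fall back to direct minimization of the same sum of squares
    obj <- function(p) {
      mu <- p[2]; s <- exp(p[3])
      sum((y - p[4] - p[1] * exp(-(d - mu)^2 / (2 * s^2)))^2)
    }
    op <- stats::optim(c(a0, mu0, log(s0), b0), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    pars <- c(a = op$par[1], mu = op$par[2], s = exp(op$par[3]), b = op$par[4])
    resid <- y - pars["b"] - pars["a"] * exp(-(d - pars["mu"])^2 / (2 * pars["s"]^2))
    converged <- op$convergence == 0
  } else {
    pars <- stats::coef(fit)
    resid <- stats::residuals(fit)
    converged <- fit$convInfo$isConv %||% TRUE
  }
  if (!converged || !is.finite(pars["a"]) || pars["a"] <= 0 || pars["s"] <= 0) {
    stop(sprintf(
      "Gaussian peak fit did not converge (rms residual %.3g over %d channels)",
      sqrt(mean(resid^2)), length(d)), call. = FALSE)
  }
  structure(list(mean_diameter = unname(pars["mu"]),
                 sigma = unname(pars["s"]),
                 amplitude = unname(pars["a"]),
                 baseline = unname(pars["b"]),
                 rms_residual = sqrt(mean(resid^2)),
                 window = as.numeric(window),
                 converged = converged,
                 n_channels = length(d)),
            class = "gaussian_peak_fit")
}

#' @export
print.gaussian_peak_fit <- function(x, ...) {
  cat(sprintf("<gaussian_peak_fit> mean %.3f nm, sigma %.3f nm, amplitude %.1f, baseline %.1f (rms %.2f)\n",
              x$mean_diameter, x$sigma, x$amplitude, x$baseline, x$rms_residual))
  invisible(x)
}

#' Peak count metric from a fitted Gaussian
#'
#' Either the baseline-subtracted peak height (the fitted amplitude, the
#' default, matching "particle counts for the signal at 25 nm") or the
#' baseline-excluded peak area `amplitude * sigma * sqrt(2 * pi)`.
#'
#' @param fit a [fit_gaussian_peak()] result
#' @param mode `"height"` or `"area"`
#' @return Counts (height) or counts x nm (area).
#' @export
peak_count_metric <- function(fit, mode = c("height", "area")) {
  stopifnot(inherits(fit, "gaussian_peak_fit"))
  mode <- match.arg(mode)
  switch(mode,
         height = fit$amplitude,
         area = fit$amplitude * fit$sigma * sqrt(2 * pi))
}

#' Build a per-condition summary table
#'
#' One row per (preparation, pH) condition with the mean and SD of the
#' replicate EM diameters and the mean peak-count metric.
#'
#' @param ph numeric pH per condition
#' @param preparation `"empty"` / `"filled"` per condition
#' @param diameters list of numeric replicate diameters (nm) per condition
#' @param metrics list of numeric replicate peak-count metrics per condition
#' @param metric_mode `"height"` or `"area"`, recorded in the table
#' @return A `condition_summary` data frame.
#' @export
condition_summary <- function(ph, preparation, diameters, metrics,
                              metric_mode = "height") {
  stopifnot(length(ph) == length(preparation),
            length(ph) == length(diameters), length(ph) == length(metrics))
  n <- vapply(diameters, length, integer(1))
  if (any(n < 1L)) stop_domain("each condition needs >= 1 replicate")
  out <- data.frame(
    pH = as.numeric(ph),
    preparation = as.character(preparation),
    mean_em_diameter = vapply(diameters, mean, numeric(1)),
    sd_em_diameter = vapply(diameters, function(x)
      if (length(x) > 1L) stats::sd(x) else 0, numeric(1)),
    n = n,
    peak_count_metric = vapply(metrics, mean, numeric(1)),
    metric_mode = metric_mode,
    normalized_counts = NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Normalize particle counts within each preparation
#'
#' Divides every condition's peak-count metric by the metric at that
#' preparation's reference pH: pH 4 for empty VLPs and pH 9 for filled VLPs
#' (the condition where each preparation's counts are highest). The reference
#' condition itself gets 1. The operation recomputes from the raw metric, so
#' it is idempotent.
#'
#' @param summaries a [condition_summary()] data frame
#' @param reference named numeric, reference pH per preparation
#' @return The same table with `normalized_counts` filled in.
#' @export
normalize_counts <- function(summaries, reference = c(empty = 4, filled = 9)) {
  stopifnot(inherits(summaries, "data.frame"))
  for (prep in unique(summaries$preparation)) {
    if (!prep %in% names(reference)) {
      stop_domain("no reference pH configured for preparation '", prep, "'")
    }
    rows <- summaries$preparation == prep
    ref_row <- rows & abs(summaries$pH - reference[[prep]]) < 1e-9
    if (!any(ref_row)) {
      stop_domain(sprintf(
        "reference condition (pH %g) missing for preparation '%s'",
        reference[[prep]], prep))
    }
    ref_metric <- summaries$peak_count_metric[ref_row][1]
    if (!is.finite(ref_metric) || ref_metric <= 0) {
      stop_domain("reference peak count metric must be positive")
    }
    summaries$normalized_counts[rows] <-
      summaries$peak_count_metric[rows] / ref_metric
  }
  summaries
}

#' Compare replicate diameters of two preparations
#'
#' Two-sided Welch two-sample t-test (unequal variances) on the replicate EM
#' diameters, with the difference of means and its confidence interval as the
#' effect size. Welch's test is used because replicate counts are small
#' (typically n = 6) and the variance ratio is unknown.
#'
#' @param a,b numeric vectors of replicate diameters (nm), each of length >= 3
#' @param conf_level confidence level for the difference-of-means CI
#' @return List with `statistic`, `df`, `p_value`, `estimate` (mean difference
#'   a - b), `conf_int`, `method`.
#' @export
compare_preparations <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L) {
    stop_domain("each group needs at least 3 replicates")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: no within-group variability, decide by exact tie
    tie <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (tie) 0 else Inf, df = NA_real_,
                p_value = if (tie) 1 else 0,
                estimate = mean(a) - mean(b),
                conf_int = c(NA_real_, NA_real_),
                method = "exact tie (zero-variance groups)"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, estimate = unname(diff(rev(tt$estimate))),
       conf_int = as.numeric(tt$conf.int),
       method = "Welch two-sample t-test, two-sided")
}

#' pH trend of the EM diameter
#'
#' Ordinary least-squares slope of EM diameter versus pH. A negative slope
#' means particles shrink toward alkaline pH. Accepts either a
#' [condition_summary()] table (one point per condition mean) or a data frame
#' with columns `pH` and `diameter` (replicate level).
#'
#' @param summaries condition summary or data frame with `pH` and `diameter`
#' @param preparation optional filter when `summaries` covers both preparations
#' @param conf_level confidence level of the slope CI
#' @return List with `slope` (nm per pH unit), `se`, `conf_int`, `p_value`,
#'   `n_levels`.
#' @export
ph_trend <- function(summaries, preparation = NULL, conf_level = 0.95) {
  stopifnot(inherits(summaries, "data.frame"))
  df <- summaries
  if (!is.null(preparation) && "preparation" %in% names(df)) {
    df <- df[df$preparation == preparation, , drop = FALSE]
  }
  y <- if ("diameter" %in% names(df)) df$diameter else df$mean_em_diameter
  x <- df$pH
  if (length(unique(x)) < 3L) stop_domain("need >= 3 distinct pH levels")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  ci <- stats::confint(fit, "x", level = conf_level)
  list(slope = unname(co["x", "Estimate"]),
       se = unname(co["x", "Std. Error"]),
       conf_int = as.numeric(ci),
       p_value = unname(co["x", "Pr(>|t|)"]),
       n_levels = length(unique(x)))
}

#' Read a mobility scan from a delimited text file
#'
#' Accepts either a `diameter_nm,counts` table or a `voltage_V,counts` table;
#' voltages are converted to EM diameters through the DMA physics of the given
#' geometry, scan settings and gas conditions. Delimiter is sniffed from the
#' extension (`.tsv` = tab, otherwise comma).
#'
#' @param file path to a CSV/TSV file with a header
#' @param geom,scan,gas DMA configuration used only for voltage input
#' @param ... metadata passed to [spectrum_scan()]
#' @return A [spectrum_scan()].
#' @export
read_spectrum_scan <- function(file, geom = dma_geometry(),
                               scan = scan_settings(), gas = gas_conditions(),
                               ...) {
  sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if ("diameter_nm" %in% names(df)) {
    d <- df$diameter_nm
  } else if ("voltage_V" %in% names(df)) {
    z <- centroid_mobility(df$voltage_V, geom, scan)
    d <- diameter_from_mobility(z, gas = gas) * 1e9
  } else {
    stop_domain("file must have a 'diameter_nm' or 'voltage_V' column")
  }
  o <- order(d)
  spectrum_scan(d[o], df$counts[o], ...)
}
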