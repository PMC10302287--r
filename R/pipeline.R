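# Orchestration of the two analysis chains: (i) the GEMMA pH series from raw
# scans to condition summaries, normalized counts and statistics; (ii) the
# cryo-TEM chain from a particle stack to an aligned average and a circle-fit
# diameter. Reports are plain lists, optionally flushed to JSON/CSV.

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the GEMMA pH-series analysis
#'
#' Groups scans by (preparation, pH, replicate), assembles a median spectrum
#' per replicate, fits the Gaussian monomer peak in the window, summarizes per
#' condition, normalizes counts to each preparation's reference pH, and runs
#' the empty-vs-filled comparison (Welch t-test on pooled replicate diameters)
#' and the per-preparation pH trends.
#'
#' @param study a `gemma_study` from [simulate_ph_study()], or a flat list of
#'   [spectrum_scan()]s carrying `preparation`, `ph` and `sample_id` metadata
#' @param window Gaussian fit window in nm
#' @param metric `"height"` or `"area"` peak-count metric
#' @param reference named reference pH per preparation for normalization
#' @param outdir optional output directory for `report.json` and
#'   `summaries.csv`
#' @return A report list: `summaries` (condition table), `replicates`
#'   (per-replicate fits), `comparison`, `trends`, `n_conditions`,
#'   `config_hash`, `seed`.
#' @export
run_gemma_study <- function(study, window = c(20, 32),
                            metric = c("height", "area"),
                            reference = c(empty = 4, filled = 9),
                            outdir = NULL) {
  metric <- match.arg(metric)
  scans <- if (inherits(study, "gemma_study")) study$scans else study
  if (!length(scans)) stop_domain("no scans supplied")
  seed <- if (inherits(study, "gemma_study")) study$spec$seed else NA
  key <- vapply(scans, function(s)
    paste(s$preparation, s$ph, s$sample_id, sep = "\r"), character(1))
  groups <- split(scans, key)

  reps <- lapply(groups, function(g) {
    fit <- fit_gaussian_peak(assemble_median_spectrum(g), window)
    data.frame(preparation = g[[1]]$preparation, pH = g[[1]]$ph,
               sample_id = g[[1]]$sample_id,
               diameter = fit$mean_diameter, sigma = fit$sigma,
               metric = peak_count_metric(fit, metric),
               rms = fit$rms_residual, n_scans = length(g),
               stringsAsFactors = FALSE)
  })
  reps <- do.call(rbind, c(reps, list(make.row.names = FALSE)))

  cond_key <- interaction(reps$preparation, reps$pH, drop = TRUE)
  conds <- split(reps, cond_key)
  summaries <- condition_summary(
    ph = vapply(conds, function(d) d$pH[1], numeric(1)),
    preparation = vapply(conds, function(d) d$preparation[1], character(1)),
    diameters = lapply(conds, function(d) d$diameter),
    metrics = lapply(conds, function(d) d$metric),
    metric_mode = metric)
  summaries <- summaries[order(summaries$preparation, summaries$pH), ]
  rownames(summaries) <- NULL
  have_both <- all(c("empty", "filled") %in% summaries$preparation)
  if (have_both) summaries <- normalize_counts(summaries, reference)

  comparison <- if (have_both) {
    compare_preparations(reps$diameter[reps$preparation == "empty"],
                         reps$diameter[reps$preparation == "filled"])
  } else NULL
  trends <- lapply(stats::setNames(nm = unique(reps$preparation)), function(p) {
    d <- reps[reps$preparation == p, ]
    if (length(unique(d$pH)) >= 3L) {
      ph_trend(data.frame(pH = d$pH, diameter = d$diameter))
    } else NULL
  })

  report <- list(summaries = summaries, replicates = reps,
                 comparison = comparison, trends = trends,
                 n_conditions = nrow(summaries),
                 window = window, metric = metric,
                 seed = seed,
                 config_hash = config_hash(list(window, metric, reference, seed)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summaries, file.path(outdir, "summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report[c("summaries", "comparison", "trends",
                                  "n_conditions", "window", "metric",
                                  "seed", "config_hash")],
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Run the cryo-TEM sizing chain on one or more samples
#'
#' For each sample: align and average the particle stack, then estimate the
#' diameter from iso-height sections of the average. When both an empty and a
#' filled preparation are present, their per-level diameters are compared
#' (Welch t-test across section levels).
#'
#' @param samples named list; each element either a [particle_stack()] or a
#'   list with fields `stack`, optional `preparation` (`"empty"` /
#'   `"filled"`) and optional `calibration` (a
#'   [shell_contour_calibration()]; without one the raw iso-contour diameter
#'   is reported, which for shell-shaped densities underestimates the outer
#'   diameter)
#' @param max_shift,rotation_step,n_iter alignment parameters, see
#'   [align_and_average()]
#' @param levels,trim_k,extreme_smooth sizing parameters, see
#'   [estimate_diameter()]; the robust extreme (default sigma 2 px) is
#'   appropriate for the noisy averages this chain operates on
#' @param outdir optional output directory: writes `average_<sample>.mrc`,
#'   `diameters.csv`, `report.json`
#' @return A report list: `samples` (per-sample average + estimate),
#'   `diameters` (data frame), `comparison` (or NULL), `config_hash`.
#' @export
run_cryoem_sizing <- function(samples, max_shift = 8, rotation_step = 0,
                              n_iter = 5, levels = c(0.35, 0.5, 0.65),
                              trim_k = 3, extreme_smooth = 2, outdir = NULL) {
  if (inherits(samples, "particle_stack")) samples <- list(sample = samples)
  if (!length(samples)) stop_domain("no samples supplied")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  out <- list(); rows <- list()
  for (nm in names(samples)) {
    s <- samples[[nm]]
    stack <- if (inherits(s, "particle_stack")) s else s$stack
    prep <- if (inherits(s, "particle_stack")) NA_character_
            else s$preparation %||% NA_character_
    cal <- if (inherits(s, "particle_stack")) NULL else s$calibration
    res <- tryCatch({
      avg <- align_and_average(stack, max_shift = max_shift,
                               rotation_step = rotation_step, n_iter = n_iter)
      est <- estimate_diameter(avg, levels = levels, trim_k = trim_k,
                               extreme_smooth = extreme_smooth,
                               calibration = cal)
      list(average = avg, estimate = est, preparation = prep)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("sample '%s' failed: %s", nm, conditionMessage(res)))
      next
    }
    out[[nm]] <- res
    rows[[nm]] <- data.frame(sample = nm, preparation = prep,
                             res$estimate$per_level,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("every sample failed", call. = FALSE)
  diam <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  preps <- vapply(out, function(s) s$preparation, character(1))
  comparison <- NULL
  if (all(c("empty", "filled") %in% preps)) {
    d_e <- diam$diameter_nm[diam$preparation == "empty"]
    d_f <- diam$diameter_nm[diam$preparation == "filled"]
    comparison <- c(compare_preparations(d_f, d_e),
                    list(mean_filled = mean(d_f), mean_empty = mean(d_e),
                         filled_larger = mean(d_f) > mean(d_e)))
  }
  report <- list(samples = out, diameters = diam, comparison = comparison,
                 levels = levels,
                 config_hash = config_hash(list(max_shift, rotation_step,
                                                n_iter, levels, trim_k)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write_mrc(out[[nm]]$average$average,
                file.path(outdir, paste0("average_", nm, ".mrc")),
                pixel_size = out[[nm]]$average$pixel_size)
    }
    utils::write.csv(diam, file.path(outdir, "diameters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(diameters = diam,
           comparison = comparison[setdiff(names(comparison), "conf_int")],
           levels = levels, config_hash = report$config_hash),
      file.path(outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}
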