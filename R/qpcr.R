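# RT-qPCR relative quantification: calibrator standard curves, Cq
# inversion, inter-run adjustment, and ln gene/actin expression ratios.

#' Fit a gene-specific standard curve
#'
#' Least-squares line of quantification cycle (Cq) on log10 calibrator
#' volume. The amplification efficiency is derived from the slope as
#' `E = 10^(-1/slope) - 1` (E = 1 for perfect doubling each cycle).
#'
#' @param calibrator data frame with columns `volume` (positive) and `cq`,
#'   one row per calibrator point; at least 3 distinct volumes.
#' @return object of class `standard_curve` with `intercept`, `slope`,
#'   `efficiency`, `n_points`, `r_squared`.
#' @export
fit_standard_curve <- function(calibrator) {
  d <- as.data.frame(calibrator)
  stopifnot(all(c("volume", "cq") %in% names(d)))
  if (any(d$volume <= 0)) stop("calibrator volumes must be positive")
  if (length(unique(d$volume)) < 3) {
    stop("need at least 3 distinct calibrator volumes, got ",
         length(unique(d$volume)))
  }
  fit <- stats::lm(cq ~ log10(volume), data = d)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("quality error: standard-curve slope is non-negative (",
         signif(slope, 3), "); Cq must decrease with template amount")
  }
  # R^2 computed directly: summary.lm warns on noiseless calibrators
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((d$cq - mean(d$cq))^2)
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = slope,
    efficiency = 10^(-1 / slope) - 1,
    n_points = nrow(d),
    r_squared = r2
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Cq = %.3f %+.4f * log10(volume)  (E = %.3f, n = %d)\n",
              x$intercept, x$slope, x$efficiency, x$n_points))
  invisible(x)
}

#' Invert a standard curve: Cq to expression
#'
#' @param curve a [fit_standard_curve()] result.
#' @param cq quantification cycle(s).
#' @return expression in log10-calibrator-volume ("arbitrary") units:
#'   `10^((cq - intercept) / slope)`.
#' @export
quantify <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Relative pituitary expression as ln gene/actin ratios
#'
#' Converts per-fish Cq measurements into natural-log ratios of gene
#' expression over actin-beta expression. Duplicate technical measurements
#' (multiple rows per fish) are averaged on the Cq scale. When a
#' run-calibrator table is supplied, each run's Cq values are first shifted
#' additively so that its calibrator matches the reference run (inter-run
#' adjustment); a run blank amplifying below the threshold raises a
#' contamination warning.
#'
#' @param samples data frame with columns `fish_id`, `cq_lhb`, `cq_fshb`,
#'   `cq_gh`, `cq_actb`, and optionally `run_id`.
#' @param curves named list of standard curves for `lhb`, `fshb`, `gh`,
#'   `actb`.
#' @param run_calibrator optional data frame `run_id`, `gene`, `cq`
#'   (and optionally `blank_cq`) with the per-run calibrator measurements.
#' @param reference_run run whose calibrator defines the reference level
#'   (default: first run in `run_calibrator`).
#' @param blank_threshold Cq below which a blank is considered
#'   contaminated (default 35).
#' @return data frame with `fish_id`, `ln_ratio_lhb`, `ln_ratio_fshb`,
#'   `ln_ratio_gh`.
#' @export
relative_expression <- function(samples, curves, run_calibrator = NULL,
                                reference_run = NULL,
                                blank_threshold = 35) {
  d <- as.data.frame(samples)
  genes <- c("lhb", "fshb", "gh", "actb")
  cols <- paste0("cq_", genes)
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols) > 0) {
    stop("samples are missing Cq column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(genes %in% names(curves))) {
    stop("need standard curves for all of: ", paste(genes, collapse = ", "))
  }
  if (anyNA(d$cq_actb)) {
    stop("unusable sample(s) without an actin measurement: ",
         paste(unique(d$fish_id[is.na(d$cq_actb)]), collapse = ", "))
  }
  # duplicate technical measurements: average on the Cq scale
  if (!"run_id" %in% names(d)) d$run_id <- "run1"
  agg <- stats::aggregate(d[cols],
                          by = list(fish_id = d$fish_id, run_id = d$run_id),
                          FUN = mean)
  # keep the samples' first-occurrence order, not aggregate's sort order
  agg <- agg[order(match(agg$fish_id, d$fish_id)), , drop = FALSE]
  # inter-run adjustment: additive Cq shift equalizing each run's
  # calibrator with the reference run
  if (!is.null(run_calibrator)) {
    rc <- as.data.frame(run_calibrator)
    if (is.null(reference_run)) reference_run <- rc$run_id[1]
    if ("blank_cq" %in% names(rc)) {
      bad <- rc$run_id[!is.na(rc$blank_cq) & rc$blank_cq < blank_threshold]
      if (length(bad) > 0) {
        warning("blank amplification below Cq ", blank_threshold,
                " in run(s): ", paste(unique(bad), collapse = ", "))
      }
    }
    for (g in genes) {
      ref_cq <- rc$cq[rc$gene == g & rc$run_id == reference_run]
      if (length(ref_cq) != 1) next
      for (run in unique(agg$run_id)) {
        run_cq <- rc$cq[rc$gene == g & rc$run_id == run]
        if (length(run_cq) != 1) next
        sel <- agg$run_id == run
        agg[sel, paste0("cq_", g)] <- agg[sel, paste0("cq_", g)] -
          (run_cq - ref_cq)
      }
    }
  }
  expr <- lapply(genes, function(g) quantify(curves[[g]],
                                             agg[[paste0("cq_", g)]]))
  names(expr) <- genes
  data.frame(
    fish_id = agg$fish_id,
    ln_ratio_lhb = log(expr$lhb / expr$actb),
    ln_ratio_fshb = log(expr$fshb / expr$actb),
    ln_ratio_gh = log(expr$gh / expr$actb),
    stringsAsFactors = FALSE
  )
}

#' Generate Cq measurements from simulated ln hormone ratios
#'
#' Inverse of the quantification pipeline, used to emit raw qPCR data from
#' the hormone simulator: each fish receives an actin-beta expression level
#' (log-normal across fish), gene expressions follow from the configured
#' ln ratios, and Cq values are produced through the standard curves with
#' optional technical noise.
#'
#' @param hormones hormone table from [simulate_hormones()] (columns
#'   `fish_id`, `ln_ratio_*`).
#' @param curves named list of standard curves (`lhb`, `fshb`, `gh`,
#'   `actb`).
#' @param actb_expression mean actin expression in calibrator-volume
#'   units.
#' @param actb_sd log-scale sd of actin expression across fish.
#' @param cq_noise_sd technical Cq noise (0 gives an exact round trip).
#' @param run_id run label attached to the output.
#' @param seed optional integer seed.
#' @return data frame with `fish_id`, `run_id`, `cq_lhb`, `cq_fshb`,
#'   `cq_gh`, `cq_actb`.
#' @export
hormones_to_cq <- function(hormones, curves, actb_expression = 1,
                           actb_sd = 0.3, cq_noise_sd = 0,
                           run_id = "run1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(hormones)
  act <- actb_expression * exp(stats::rnorm(n, 0, actb_sd))
  to_cq <- function(curve, expr) {
    curve$intercept + curve$slope * log10(expr) +
      stats::rnorm(n, 0, cq_noise_sd)
  }
  data.frame(
    fish_id = hormones$fish_id,
    run_id = run_id,
    cq_lhb = to_cq(curves$lhb, act * exp(hormones$ln_ratio_lhb)),
    cq_fshb = to_cq(curves$fshb, act * exp(hormones$ln_ratio_fshb)),
    cq_gh = to_cq(curves$gh, act * exp(hormones$ln_ratio_gh)),
    cq_actb = to_cq(curves$actb, act),
    stringsAsFactors = FALSE
  )
}
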