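#' Normalize well ODs to the medium control
#'
#' @param od_wells Numeric vector of OD490 values.
#' @param medium_control_wells Numeric vector of medium control ODs (>= 1,
#'   positive mean).
#' @return `od_wells` divided by the mean control OD.
#' @export
normalize_viability <- function(od_wells, medium_control_wells) {
  if (length(medium_control_wells) == 0L) {
    stop("no medium control wells", call. = FALSE)
  }
  ctrl <- mean(medium_control_wells)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("mean medium-control OD must be positive", call. = FALSE)
  }
  od_wells / ctrl
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Normalizes well ODs to the medium control, then least-squares fits
#' `v = bottom + (top - bottom) / (1 + 10^(hill * (log10(c) - log10(ic50))))`
#' on log10 concentration. The IC50 is the fitted midpoint. A flat response
#' (dynamic range below `flat_epsilon`) is flagged indeterminate without
#' fitting — the phenotype of a fully inhibitor-resistant line. An IC50
#' outside the tested concentration range is flagged `extrapolated`.
#'
#' @param plate Data frame with columns `concentration_um`, `od490`,
#'   `is_medium_control` (see [simulate_dose_response()]).
#' @param flat_epsilon Minimal dynamic range (difference between the largest
#'   and smallest per-concentration mean normalized viability) required to
#'   attempt a fit.
#' @return An object of class `dose_response` with fields `ic50`, `hill`,
#'   `top`, `bottom`, `converged`, `indeterminate`, `extrapolated`,
#'   `residual_ss`, `concentrations`, `normalized`.
#' @export
fit_dose_response <- function(plate, flat_epsilon = 0.2) {
  req <- c("concentration_um", "od490", "is_medium_control")
  missing_cols <- setdiff(req, names(plate))
  if (length(missing_cols) > 0L) {
    stop("plate is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- plate$od490[plate$is_medium_control]
  wells <- plate[!plate$is_medium_control, , drop = FALSE]
  conc <- wells$concentration_um
  if (length(unique(conc)) < 4L) {
    stop("need >= 4 distinct concentrations to fit", call. = FALSE)
  }
  v <- normalize_viability(wells$od490, ctrl)
  per_conc <- tapply(v, conc, mean)
  out <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
              bottom = NA_real_, converged = FALSE, indeterminate = FALSE,
              extrapolated = FALSE, residual_ss = NA_real_,
              concentrations = sort(unique(conc)), normalized = v)
  if (max(per_conc) - min(per_conc) < flat_epsilon) {
    out$indeterminate <- TRUE
    return(structure(out, class = "dose_response"))
  }
  lx <- log10(conc)
  start <- list(top = max(per_conc), bottom = min(per_conc),
                l50 = stats::median(lx), hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - l50))),
      start = start,
      lower = c(top = -Inf, bottom = -Inf, l50 = -Inf, hill = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(out, class = "dose_response"))
  cf <- stats::coef(fit)
  out$ic50 <- unname(10^cf["l50"])
  out$hill <- unname(cf["hill"])
  out$top <- unname(cf["top"])
  out$bottom <- unname(cf["bottom"])
  out$converged <- TRUE
  out$residual_ss <- sum(stats::residuals(fit)^2)
  out$extrapolated <- out$ic50 < min(conc) || out$ic50 > max(conc)
  structure(out, class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  if (x$indeterminate) {
    cat("<dose_response> flat response; IC50 indeterminate (resistant phenotype)\n")
  } else if (!x$converged) {
    cat("<dose_response> fit did not converge; no IC50\n")
  } else {
    cat(sprintf("<dose_response> IC50 %.4g uM (hill %.2f, top %.2f, bottom %.2f)%s\n",
                x$ic50, x$hill, x$top, x$bottom,
                if (x$extrapolated) " [extrapolated]" else ""))
  }
  invisible(x)
}

#' Doubling time from bead-calibrated growth counts
#'
#' Cell counts are bead-normalized (`cells * beads_expected /
#' beads_observed`, cancelling per-acquisition volume fluctuations), then
#' log2-transformed and regressed on time. The doubling time is the
#' reciprocal slope, with a confidence interval from the slope standard
#' error. A non-positive slope is reported as non-growing.
#'
#' @param series Data frame with columns `time_h`, `cell_count`,
#'   `bead_count` (see [simulate_growth()]).
#' @param beads_expected Beads spiked per acquisition; defaults to the
#'   series' `beads_spiked` attribute, else the median observed bead count.
#' @param conf_level Confidence level for the doubling-time interval.
#' @return List of class `doubling_time_fit` with `doubling_time_h`, `ci`,
#'   `slope`, `non_growing`, `n_timepoints`.
#' @export
fit_doubling_time <- function(series, beads_expected = NULL,
                              conf_level = 0.95) {
  req <- c("time_h", "cell_count", "bead_count")
  missing_cols <- setdiff(req, names(series))
  if (length(missing_cols) > 0L) {
    stop("growth series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (all(series$cell_count == 0)) {
    stop("all cell counts are zero", call. = FALSE)
  }
  if (is.null(beads_expected)) {
    beads_expected <- attr(series, "beads_spiked")
    if (is.null(beads_expected)) {
      beads_expected <- stats::median(series$bead_count)
    }
  }
  norm <- series$cell_count * beads_expected / series$bead_count
  ok <- is.finite(norm) & norm > 0
  if (sum(ok) < 3L) {
    stop("need >= 3 timepoints with positive normalized counts",
         call. = FALSE)
  }
  if (length(unique(norm[ok])) < 2L) {
    stop("need >= 2 distinct positive normalized counts", call. = FALSE)
  }
  fit <- stats::lm(log2(norm[ok]) ~ series$time_h[ok])
  slope <- unname(stats::coef(fit)[2])
  ci_slope <- suppressWarnings(stats::confint(fit, level = conf_level)[2, ])
  if (slope <= 0) {
    out <- list(doubling_time_h = NA_real_, ci = c(NA_real_, NA_real_),
                slope = slope, non_growing = TRUE, n_timepoints = sum(ok))
  } else {
    # reciprocal of the slope interval; an interval crossing zero has an
    # unbounded upper doubling time
    upper <- if (ci_slope[1] > 0) 1 / ci_slope[1] else Inf
    out <- list(doubling_time_h = 1 / slope,
                ci = c(1 / ci_slope[2], upper), slope = slope,
                non_growing = FALSE, n_timepoints = sum(ok))
  }
  structure(out, class = "doubling_time_fit")
}

#' @export
print.doubling_time_fit <- function(x, ...) {
  if (x$non_growing) {
    cat("<doubling_time_fit> non-growing (slope <= 0)\n")
  } else {
    cat(sprintf("<doubling_time_fit> %.2f h (%.0f%% CI %.2f-%.2f h, %d timepoints)\n",
                x$doubling_time_h, 95, x$ci[1], x$ci[2], x$n_timepoints))
  }
  invisible(x)
}

#' Significance stars for a P value
#'
#' Standard figure-legend thresholds: `***` P < 0.001, `**` P < 0.01,
#' `*` P < 0.05, else `ns`.
#' @param p P value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare replicate doubling times between two experimental groups
#'
#' Two-sided (by default) unpaired t test on replicate doubling times, with
#' the usual star annotation.
#'
#' @param group_a,group_b Numeric vectors of replicate doubling times (>= 2
#'   each; assays typically run triplicates).
#' @param sided `"two.sided"`, `"less"` or `"greater"`.
#' @return List with `statistic`, `p_value`, `df`, `stars`.
#' @export
compare_doubling_times <- function(group_a, group_b, sided = "two.sided") {
  res <- two_sample_t(group_a, group_b, sided = sided, var_equal = TRUE)
  res$stars <- significance_stars(res$p_value)
  res
}
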