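#' Simulate a paired phospho-flow sample
#'
#' Generates per-cell fluorescence for an unstimulated and an anti-Ig
#' crosslinked aliquot of the same transductant. Fluorescence is lognormal
#' around the target MFIs (geometric-mean parameterization, so the two
#' conditions share the same multiplicative dispersion and their ratio is
#' noise-invariant). A `1 - live_fraction` share of cells is marked dead by
#' the viability dye.
#'
#' @param n_cells Cells per condition.
#' @param mfi_unstim,mfi_stim Target fluorescence of the unstimulated and
#'   crosslinked condition (> 0).
#' @param noise_cv Multiplicative coefficient of variation of per-cell
#'   fluorescence.
#' @param live_fraction Fraction of live cells, in (0, 1].
#' @param seed Integer seed.
#' @param target Phospho-target label (e.g. "pBLNK Y84").
#' @return List of class `phospho_pair` with elements `unstim` and `stim`,
#'   each a data frame of class `phospho_sample` with columns `fluor`, `gfp`,
#'   `dtomato`, `viability`, `condition` and attribute `target`.
#' @export
simulate_phospho <- function(n_cells = 2000, mfi_unstim, mfi_stim,
                             noise_cv = 0.3, live_fraction = 0.95, seed = 1L,
                             target = "pBLNK") {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(mfi_unstim, "mfi_unstim", lower = 1e-12)
  check_number(mfi_stim, "mfi_stim", lower = 1e-12)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(live_fraction, "live_fraction", lower = 1e-9, upper = 1)
  seed <- check_count(seed, "seed", lower = 0L)
  set.seed(seed)
  one_condition <- function(mfi, condition) {
    fluor <- mfi * rlnorm_cv(n_cells, noise_cv) /
      exp(-log1p(noise_cv^2) / 2)  # undo unit-mean shift: geometric mean = mfi
    dead <- stats::runif(n_cells) > live_fraction
    viability <- exp(ifelse(dead, log(5000), log(100)) +
                       stats::rnorm(n_cells, 0, SIM_MARKER_SDLOG))
    out <- data.frame(fluor = fluor,
                      gfp = exp(SIM_GFP_POS_MEANLOG +
                                  stats::rnorm(n_cells, 0, SIM_MARKER_SDLOG)),
                      dtomato = exp(SIM_DTOMATO_MEANLOG +
                                      stats::rnorm(n_cells, 0,
                                                   SIM_MARKER_SDLOG)),
                      viability = viability,
                      condition = condition)
    structure(out, target = target,
              class = c("phospho_sample", "data.frame"))
  }
  structure(list(unstim = one_condition(mfi_unstim, "unstimulated"),
                 stim = one_condition(mfi_stim, "crosslinked")),
            class = "phospho_pair")
}

#' Default two-fold inhibitor dilution series
#'
#' Ten concentrations from 96 uM down to 0.1875 uM in two-fold steps, the
#' standard titration used for the BTK-inhibitor viability assay.
#' @return Numeric vector of concentrations (uM), descending.
#' @export
dose_series_um <- function() 96 / 2^(0:9)

#' Simulate a viability plate for dose-response fitting
#'
#' Well OD values follow a four-parameter logistic of concentration plus
#' additive Gaussian noise, scaled to an OD490 range by `od_scale`. Medium
#' control wells (no inhibitor) sit at the top plateau and anchor the
#' normalization.
#'
#' @param ic50 True IC50 (uM, > 0).
#' @param hill Hill slope (> 0; response decreases with concentration).
#' @param top,bottom Upper and lower viability plateaus as fractions of the
#'   medium control.
#' @param concentrations Tested concentrations (uM), strictly positive;
#'   defaults to [dose_series_um()].
#' @param noise_sd Additive Gaussian noise SD on the viability scale.
#' @param n_replicates Wells per concentration (assay uses duplicates).
#' @param od_scale OD490 of a fully viable well.
#' @param n_controls Number of medium control wells.
#' @param seed Integer seed.
#' @return Data frame of class `viability_plate` with columns
#'   `concentration_um` (NA for controls), `od490`, `is_medium_control`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, top = 1, bottom = 0.05,
                                   concentrations = dose_series_um(),
                                   noise_sd = 0.05, n_replicates = 2L,
                                   od_scale = 1.5, n_controls = 4L,
                                   seed = 1L) {
  check_number(ic50, "ic50", lower = 1e-12)
  check_number(hill, "hill", lower = 1e-9)
  check_number(top, "top"); check_number(bottom, "bottom")
  check_number(noise_sd, "noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  n_controls <- check_count(n_controls, "n_controls")
  seed <- check_count(seed, "seed", lower = 0L)
  if (any(concentrations <= 0)) {
    abort_field("concentrations", "must be strictly positive")
  }
  set.seed(seed)
  conc <- rep(concentrations, each = n_replicates)
  viability <- bottom + (top - bottom) / (1 + (conc / ic50)^hill)
  od <- od_scale * (viability + stats::rnorm(length(conc), 0, noise_sd))
  ctrl_od <- od_scale * (top + stats::rnorm(n_controls, 0, noise_sd))
  out <- data.frame(
    concentration_um = c(conc, rep(NA_real_, n_controls)),
    od490 = c(od, ctrl_od),
    is_medium_control = c(rep(FALSE, length(conc)), rep(TRUE, n_controls)))
  structure(out, truth = list(ic50 = ic50, hill = hill, top = top,
                              bottom = bottom),
            class = c("viability_plate", "data.frame"))
}

#' Simulate bead-calibrated exponential growth
#'
#' Cell counts grow as `n0 * 2^(t / doubling_time_h)`. Each acquisition
#' carries a shared multiplicative volume fluctuation that affects cell and
#' bead counts alike (this is what bead normalization removes), plus smaller
#' independent counting noise on each channel.
#'
#' @param doubling_time_h True doubling time in hours (> 0, finite).
#' @param n_timepoints Number of sampled timepoints (>= 3 for fitting).
#' @param interval_h Hours between timepoints.
#' @param n0 Initial cell count.
#' @param bead_count Beads spiked into every acquisition.
#' @param noise_cv Coefficient of variation of the shared volume
#'   fluctuation; channel counting noise uses half this CV.
#' @param seed Integer seed.
#' @return Data frame of class `growth_series` with columns `time_h`,
#'   `cell_count`, `bead_count` and attributes `beads_spiked` and `truth`.
#' @export
simulate_growth <- function(doubling_time_h, n_timepoints = 5L,
                            interval_h = 24, n0 = 1e4, bead_count = 5000,
                            noise_cv = 0.1, seed = 1L) {
  check_number(doubling_time_h, "doubling_time_h", lower = 1e-9)
  if (!is.finite(doubling_time_h)) {
    abort_field("doubling_time_h", "must be finite")
  }
  n_timepoints <- check_count(n_timepoints, "n_timepoints", lower = 2L)
  check_number(interval_h, "interval_h", lower = 1e-9)
  check_number(n0, "n0", lower = 1e-9)
  check_number(bead_count, "bead_count", lower = 1e-9)
  check_number(noise_cv, "noise_cv", lower = 0)
  seed <- check_count(seed, "seed", lower = 0L)
  set.seed(seed)
  time_h <- (seq_len(n_timepoints) - 1L) * interval_h
  true_cells <- n0 * 2^(time_h / doubling_time_h)
  volume <- rlnorm_cv(n_timepoints, noise_cv)
  cells_obs <- true_cells * volume * rlnorm_cv(n_timepoints, noise_cv / 2)
  beads_obs <- bead_count * volume * rlnorm_cv(n_timepoints, noise_cv / 2)
  out <- data.frame(time_h = time_h, cell_count = cells_obs,
                    bead_count = beads_obs)
  structure(out, beads_spiked = bead_count,
            truth = list(doubling_time_h = doubling_time_h, n0 = n0),
            class = c("growth_series", "data.frame"))
}

#' Simulate binary aberration vectors from a cluster model
#'
#' Draws `n_cases_per_cluster` cases from every cluster of a
#' [cluster_model()]: each cluster-defining locus is independently aberrant
#' with the cluster's (unsmoothed) conditional frequency.
#'
#' @param model A [cluster_model()].
#' @param n_cases_per_cluster Cases to draw per cluster (> 0).
#' @param seed Integer seed.
#' @return List of class `aberration_sim` with `states` (cases x loci 0/1
#'   matrix) and `truth` (character vector of generating clusters).
#' @export
simulate_aberrations <- function(model, n_cases_per_cluster, seed = 1L) {
  stopifnot(inherits(model, "cluster_model"))
  n_cases_per_cluster <- check_count(n_cases_per_cluster,
                                     "n_cases_per_cluster")
  seed <- check_count(seed, "seed", lower = 0L)
  set.seed(seed)
  n_total <- n_cases_per_cluster * length(model$clusters)
  states <- matrix(0L, nrow = n_total, ncol = length(model$loci),
                   dimnames = list(NULL, model$loci))
  truth <- character(n_total)
  row <- 1L
  for (cl in model$clusters) {
    p <- model$freq[, cl]
    for (i in seq_len(n_cases_per_cluster)) {
      states[row, ] <- as.integer(stats::runif(length(p)) < p)
      truth[row] <- cl
      row <- row + 1L
    }
  }
  rownames(states) <- sprintf("case_%03d", seq_len(n_total))
  structure(list(states = states, truth = truth), class = "aberration_sim")
}
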