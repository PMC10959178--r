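#' Parameters for a simulated calcium-flux experiment
#'
#' Encodes the biological and instrumental conditions of one transduced
#' sample: how many cells are acquired, which fraction carries the BCR
#' (transduced, GFP-positive), which fraction of transduced cells responds
#' autonomously after 4-OHT, which fraction is totally unresponsive even to
#' crosslinking, and the amplitudes of the autonomous and maximal (crosslink)
#' SIR responses relative to baseline.
#'
#' @param n_cells Number of acquired cells (one event per cell).
#' @param event_rate Nominal instrument acquisition rate (events/second);
#'   recorded as metadata. With a constant flow rate, arrival times are
#'   uniform over the protocol window regardless of the nominal rate.
#' @param transduced_fraction Fraction of cells expressing the BCR (GFP+).
#' @param p_aut Fraction of transduced cells that respond autonomously after
#'   4-OHT (before any crosslinking).
#' @param u_true Fraction of transduced cells that are totally unresponsive,
#'   even to anti-Ig crosslinking.
#' @param mu0 Baseline SIR (405/485 ratio) of resting cells.
#' @param a_aut Multiplicative SIR fold-change of autonomous responders
#'   (>= 1).
#' @param a_max Multiplicative SIR fold-change at the maximal crosslink
#'   response (>= `a_aut`).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise applied independently to each Indo-1 channel.
#' @param response_lag_s Lag (seconds) between 4-OHT addition and the onset
#'   of the autonomous response.
#' @param seed Integer seed making the simulated sample reproducible.
#' @return An object of class `flux_sim_params`.
#' @export
flux_sim_params <- function(n_cells = 5000, event_rate = 100,
                            transduced_fraction = 0.6, p_aut = 0,
                            u_true = 0.05, mu0 = 1, a_aut = 2, a_max = 3,
                            noise_cv = 0.15, response_lag_s = 10, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  check_number(event_rate, "event_rate", lower = 1e-9)
  check_number(transduced_fraction, "transduced_fraction", 0, 1)
  check_number(p_aut, "p_aut", 0, 1)
  check_number(u_true, "u_true", 0, 1)
  if (p_aut + u_true > 1) {
    abort_field("p_aut",
                "p_aut + u_true must be <= 1 (a cell cannot be both an autonomous responder and totally unresponsive)")
  }
  check_number(mu0, "mu0", lower = 1e-12)
  check_number(a_aut, "a_aut", lower = 1)
  check_number(a_max, "a_max", lower = 1)
  if (a_max < a_aut) {
    abort_field("a_max", "must be >= a_aut (crosslink response is maximal)")
  }
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(response_lag_s, "response_lag_s", lower = 0)
  seed <- check_count(seed, "seed", lower = 0L)
  structure(list(n_cells = n_cells, event_rate = event_rate,
                 transduced_fraction = transduced_fraction, p_aut = p_aut,
                 u_true = u_true, mu0 = mu0, a_aut = a_aut, a_max = a_max,
                 noise_cv = noise_cv, response_lag_s = response_lag_s,
                 seed = seed),
            class = "flux_sim_params")
}

# detector scale constants for the simulated instrument
SIM_CH485_BASE <- 1000
SIM_GFP_POS_MEANLOG <- log(5000)
SIM_GFP_NEG_MEANLOG <- log(50)
SIM_MARKER_SDLOG <- 0.4
SIM_DTOMATO_MEANLOG <- log(3000)

#' Simulate one calcium-flux experiment with ground truth
#'
#' Generates a per-cell event stream spanning the three protocol phases.
#' Each cell contributes one event at a uniformly distributed acquisition
#' time (constant flow rate). The true SIR of a cell is a step function:
#' baseline `mu0`; autonomous responders step to `mu0 * a_aut` after
#' `t_4oht_s + response_lag_s`; every transduced, non-unresponsive cell steps
#' to `mu0 * a_max` after crosslinking. Untransduced (GFP-negative) cells
#' carry no BCR and never respond. Both Indo-1 channels receive independent
#' multiplicative lognormal noise.
#'
#' @param params A [flux_sim_params()].
#' @param protocol A [flux_protocol()].
#' @param sample_id,replicate Metadata for the generated series.
#' @return A list of class `flux_simulation` with elements `series` (a
#'   [flux_series()]) and `truth` (per-cell labels: `transduced`,
#'   `autonomous`, `crosslink_responder`, plus the generating parameters).
#' @examples
#' sim <- simulate_flux_experiment(flux_sim_params(p_aut = 0.6, seed = 7))
#' mean(sim$truth$autonomous[sim$truth$transduced])
#' @export
simulate_flux_experiment <- function(params, protocol = flux_protocol(),
                                     sample_id = "sim", replicate = 1L) {
  stopifnot(inherits(params, "flux_sim_params"),
            inherits(protocol, "flux_protocol"))
  set.seed(params$seed)
  n <- params$n_cells
  time_s <- sort(stats::runif(n, 0, protocol$crosslink_end_s))
  transduced <- stats::runif(n) < params$transduced_fraction
  class_draw <- stats::runif(n)
  autonomous <- transduced & class_draw < params$p_aut
  unresponsive <- transduced & !autonomous &
    class_draw < params$p_aut + params$u_true
  crosslink_responder <- transduced & !unresponsive

  s_true <- rep(params$mu0, n)
  in_aut <- time_s >= protocol$t_4oht_s + params$response_lag_s &
    time_s < protocol$autonomous_end_s
  in_xl <- time_s >= protocol$autonomous_end_s
  s_true[autonomous & in_aut] <- params$mu0 * params$a_aut
  s_true[crosslink_responder & in_xl] <- params$mu0 * params$a_max

  ch485 <- SIM_CH485_BASE * rlnorm_cv(n, params$noise_cv)
  ch405 <- s_true * SIM_CH485_BASE * rlnorm_cv(n, params$noise_cv)
  gfp <- exp(ifelse(transduced, SIM_GFP_POS_MEANLOG, SIM_GFP_NEG_MEANLOG) +
               stats::rnorm(n, 0, SIM_MARKER_SDLOG))
  dtomato <- exp(SIM_DTOMATO_MEANLOG + stats::rnorm(n, 0, SIM_MARKER_SDLOG))

  series <- flux_series(data.frame(time_s = time_s, ch405 = ch405,
                                   ch485 = ch485, gfp = gfp,
                                   dtomato = dtomato),
                        sample_id = sample_id, replicate = replicate)
  truth <- list(transduced = transduced, autonomous = autonomous,
                crosslink_responder = crosslink_responder,
                params = params)
  structure(list(series = series, truth = truth), class = "flux_simulation")
}

#' Default GFP gate separating transduced from untransduced simulated cells
#'
#' The simulated GFP intensities are lognormal around 5000 (transduced) and
#' 50 (untransduced); 500 is the geometric midpoint.
#' @return A numeric threshold for [gate_events()].
#' @export
sim_gfp_gate <- function() exp((SIM_GFP_POS_MEANLOG + SIM_GFP_NEG_MEANLOG) / 2)

#' Specification of one cohort case
#'
#' @param case_id Unique case identifier.
#' @param isotype BCR isotype label (e.g. "IgM", "IgG1", "IgG2", "IgG4").
#' @param signaling Logical ground-truth label: does this case's BCR signal
#'   autonomously?
#' @param params A [flux_sim_params()] describing the case's flux behaviour.
#' @return A list of class `cohort_case_spec`.
#' @export
cohort_case <- function(case_id, isotype, signaling, params) {
  stopifnot(is.character(case_id), length(case_id) == 1L,
            is.logical(signaling), length(signaling) == 1L,
            inherits(params, "flux_sim_params"))
  structure(list(case_id = case_id, isotype = isotype,
                 signaling = signaling, params = params),
            class = "cohort_case_spec")
}

#' Simulate a cohort of replicated calcium-flux measurements
#'
#' Every case is measured `n_replicates` times (the assay protocol measures
#' each BCR twice); replicates share the case's ground truth parameters but
#' have independent noise. Per-case seeds are derived deterministically from
#' the global seed and the case/replicate index, so a cohort is reproducible
#' case by case.
#'
#' @param case_specs List of [cohort_case()] specifications (>= 1, unique
#'   `case_id`s).
#' @param protocol A [flux_protocol()].
#' @param seed Global integer seed.
#' @param n_replicates Measurements per case.
#' @return A list of class `flux_cohort`: one element per case, each a list
#'   with `case_id`, `isotype`, `signaling` (ground truth) and `replicates`
#'   (a list of `flux_simulation` objects).
#' @export
simulate_cohort <- function(case_specs, protocol = flux_protocol(), seed = 1L,
                            n_replicates = 2L) {
  if (length(case_specs) == 0L) stop("case_specs is empty", call. = FALSE)
  stopifnot(all(vapply(case_specs, inherits, TRUE, "cohort_case_spec")))
  seed <- check_count(seed, "seed", lower = 0L)
  n_replicates <- check_count(n_replicates, "n_replicates")
  ids <- vapply(case_specs, `[[`, "", "case_id")
  if (anyDuplicated(ids)) {
    stop("duplicate case_id: ", paste(unique(ids[duplicated(ids)]),
                                      collapse = ", "), call. = FALSE)
  }
  cases <- lapply(seq_along(case_specs), function(i) {
    spec <- case_specs[[i]]
    reps <- lapply(seq_len(n_replicates), function(r) {
      p <- spec$params
      # mix case and replicate indices into the derived stream seed; double
      # arithmetic is exact here and the modulus keeps it a valid integer
      p$seed <- as.integer((as.numeric(seed) * 1009 + i * 131 + r) %%
                             2147483647)
      simulate_flux_experiment(p, protocol, sample_id = spec$case_id,
                               replicate = r)
    })
    list(case_id = spec$case_id, isotype = spec$isotype,
         signaling = spec$signaling, replicates = reps)
  })
  names(cases) <- ids
  structure(cases, class = "flux_cohort", seed = seed)
}
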