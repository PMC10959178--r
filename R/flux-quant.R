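#' Baseline SIR responder threshold
#'
#' The responder threshold is a high quantile (default 95th percentile,
#' linear interpolation between order statistics) of the per-event 405/485
#' signal intensity ratio in the baseline window, i.e. prior to 4-OHT
#' addition.
#'
#' @param series A gated [flux_series()].
#' @param protocol A [flux_protocol()].
#' @param min_events Minimum baseline events required for a usable estimate.
#' @return The threshold SIR value.
#' @export
baseline_threshold <- function(series, protocol = flux_protocol(),
                               min_events = 20L) {
  stopifnot(inherits(series, "flux_series"),
            inherits(protocol, "flux_protocol"))
  base <- sir(series)[series$time_s < protocol$t_4oht_s]
  if (length(base) < min_events) {
    stop(sprintf("only %d baseline events (< %d); sample unusable",
                 length(base), min_events), call. = FALSE)
  }
  unname(stats::quantile(base, protocol$baseline_quantile, type = 7))
}

# consecutive full bins partitioning the crosslink window; a trailing
# partial bin is dropped
crosslink_bins <- function(protocol) {
  n_bins <- floor((protocol$crosslink_end_s - protocol$autonomous_end_s) /
                    protocol$bin_width_s)
  starts <- protocol$autonomous_end_s +
    (seq_len(n_bins) - 1L) * protocol$bin_width_s
  cbind(start = starts, end = starts + protocol$bin_width_s)
}

# index of the peak-response bin (maximal median SIR; ties -> earliest)
# and per-event bin membership
peak_crosslink_bin <- function(series, protocol) {
  bins <- crosslink_bins(protocol)
  s <- sir(series)
  medians <- rep(-Inf, nrow(bins))
  members <- vector("list", nrow(bins))
  for (i in seq_len(nrow(bins))) {
    inside <- series$time_s >= bins[i, "start"] &
      series$time_s < bins[i, "end"]
    members[[i]] <- inside
    if (any(inside)) medians[i] <- stats::median(s[inside])
  }
  if (all(!is.finite(medians))) {
    stop("no events in any full crosslink bin", call. = FALSE)
  }
  peak <- which.max(medians)
  list(peak_bin = bins[peak, ], in_peak = members[[peak]])
}

#' Fraction of totally unresponsive cells at the crosslink peak
#'
#' Partitions the crosslink window into consecutive 20-s bins (protocol bin
#' width), selects the bin with the maximal median SIR — the peak of the
#' maximum response to anti-Ig crosslinking — and reports the fraction of
#' events in that bin whose SIR stays at or below the baseline threshold.
#' These cells fail to respond even to crosslinking and are removed from the
#' denominator of the responder fraction.
#'
#' @param series A gated [flux_series()].
#' @param protocol A [flux_protocol()].
#' @param threshold Baseline SIR threshold from [baseline_threshold()].
#' @return List with `u` (fraction in `[0, 1]`), `peak_bin` (start/end
#'   seconds) and `n_events` in the peak bin.
#' @export
unresponsive_fraction <- function(series, protocol = flux_protocol(),
                                  threshold) {
  stopifnot(inherits(series, "flux_series"),
            inherits(protocol, "flux_protocol"))
  check_number(threshold, "threshold", lower = 0)
  peak <- peak_crosslink_bin(series, protocol)
  s <- sir(series)[peak$in_peak]
  list(u = mean(s <= threshold), peak_bin = peak$peak_bin,
       n_events = length(s))
}

#' Corrected autonomous responder fraction (Q^aut)
#'
#' Raw responder fraction = share of autonomous-window events (4-OHT to
#' crosslink) with SIR above the baseline threshold. The raw fraction is
#' divided by `1 - u` to remove totally unresponsive cells from the
#' denominator, and capped at 1.
#'
#' @param series A gated [flux_series()].
#' @param protocol A [flux_protocol()].
#' @param threshold Baseline SIR threshold.
#' @param u Unresponsive fraction from [unresponsive_fraction()]; must be
#'   < 1.
#' @return The corrected responder fraction in `[0, 1]`.
#' @export
q_aut <- function(series, protocol = flux_protocol(), threshold, u) {
  stopifnot(inherits(series, "flux_series"),
            inherits(protocol, "flux_protocol"))
  check_number(threshold, "threshold", lower = 0)
  check_number(u, "u", lower = 0, upper = 1)
  if (u >= 1) {
    stop("every cell in the peak crosslink bin is unresponsive (u >= 1); ",
         "responder correction impossible", call. = FALSE)
  }
  in_aut <- series$time_s >= protocol$t_4oht_s &
    series$time_s < protocol$autonomous_end_s
  if (!any(in_aut)) stop("no events in the autonomous window", call. = FALSE)
  raw <- mean(sir(series)[in_aut] > threshold)
  min(raw / (1 - u), 1)
}

#' Calibrated median responder SIR (calSIR^aut)
#'
#' Median SIR over autonomous-window events above the baseline threshold,
#' calibrated to (divided by) the median SIR in the peak crosslink bin, i.e.
#' the maximum response the sample can mount. A sample with no
#' above-threshold autonomous events has no autonomous signal and returns 0
#' by convention.
#'
#' @param series A gated [flux_series()].
#' @param protocol A [flux_protocol()].
#' @param threshold Baseline SIR threshold.
#' @return Dimensionless calibrated ratio (>= 0).
#' @export
cal_sir_aut <- function(series, protocol = flux_protocol(), threshold) {
  stopifnot(inherits(series, "flux_series"),
            inherits(protocol, "flux_protocol"))
  check_number(threshold, "threshold", lower = 0)
  s <- sir(series)
  in_aut <- series$time_s >= protocol$t_4oht_s &
    series$time_s < protocol$autonomous_end_s
  responders <- s[in_aut & s > threshold]
  if (length(responders) == 0L) return(0)
  peak <- peak_crosslink_bin(series, protocol)
  if (!any(peak$in_peak)) stop("empty peak crosslink bin", call. = FALSE)
  stats::median(responders) / stats::median(s[peak$in_peak])
}

#' Autonomous BCR signaling strength of one measurement
#'
#' Composes the full statistic: baseline threshold, unresponsive-cell
#' correction at the crosslink peak, corrected responder fraction Q^aut, and
#' calibrated median responder SIR calSIR^aut. Signaling strength is the
#' arithmetic product `q_aut * cal_sir_aut`.
#'
#' @param series A gated [flux_series()].
#' @param protocol A [flux_protocol()].
#' @return An object of class `signaling_result` with fields
#'   `baseline_threshold`, `u`, `peak_bin`, `q_aut`, `cal_sir_aut`,
#'   `strength`, `n_events` (per phase) and `sample_id`/`replicate`.
#' @examples
#' sim <- simulate_flux_experiment(flux_sim_params(p_aut = 0.7, seed = 3))
#' gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())
#' signaling_strength(gated)
#' @export
signaling_strength <- function(series, protocol = flux_protocol()) {
  stopifnot(inherits(series, "flux_series"),
            inherits(protocol, "flux_protocol"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  thr <- stage("baseline_threshold", baseline_threshold(series, protocol))
  un <- stage("unresponsive_fraction",
              unresponsive_fraction(series, protocol, thr))
  q <- stage("q_aut", q_aut(series, protocol, thr, un$u))
  cal <- stage("cal_sir_aut", cal_sir_aut(series, protocol, thr))
  n_events <- c(
    baseline = sum(series$time_s < protocol$t_4oht_s),
    autonomous = sum(series$time_s >= protocol$t_4oht_s &
                       series$time_s < protocol$autonomous_end_s),
    crosslink = sum(series$time_s >= protocol$autonomous_end_s))
  structure(list(baseline_threshold = thr, u = un$u,
                 peak_bin = un$peak_bin, q_aut = q, cal_sir_aut = cal,
                 strength = q * cal, n_events = n_events,
                 sample_id = attr(series, "sample_id"),
                 replicate = attr(series, "replicate")),
            class = "signaling_result")
}

#' @export
print.signaling_result <- function(x, ...) {
  cat(sprintf(paste0("<signaling_result> '%s' rep %s: strength %.4f ",
                     "(Q_aut %.4f x calSIR_aut %.4f), u %.3f, ",
                     "threshold %.4f\n"),
              x$sample_id, x$replicate, x$strength, x$q_aut, x$cal_sir_aut,
              x$u, x$baseline_threshold))
  invisible(x)
}

#' Average signaling strength over replicate measurements
#'
#' Each BCR is measured repeatedly (typically twice); the reported signaling
#' strength is the arithmetic mean of the replicate strengths.
#'
#' @param results List of `signaling_result` objects (or bare strengths).
#' @return List with `mean_strength`, `n_replicates` and the individual
#'   `strengths`.
#' @export
average_replicates <- function(results) {
  if (length(results) == 0L) stop("no replicate results", call. = FALSE)
  strengths <- vapply(results, function(r) {
    if (inherits(r, "signaling_result")) r$strength else as.numeric(r)
  }, numeric(1))
  list(mean_strength = mean(strengths), n_replicates = length(strengths),
       strengths = strengths)
}

#' Classify a BCR as autonomously signaling or not
#'
#' The decision threshold is the upper limit of signaling strength observed
#' for non-signaling control BCRs: `max(null_strengths)`. A BCR is called
#' signaling iff its replicate-averaged strength strictly exceeds the
#' threshold; equality is conservatively called non-signaling.
#'
#' @param mean_strength Replicate-averaged strength (scalar or vector).
#' @param null_strengths Strengths of non-signaling control measurements
#'   (>= 1 value).
#' @return Character vector, `"signaling"` or `"non_signaling"`, with the
#'   threshold attached as attribute `threshold`.
#' @export
classify_signaling <- function(mean_strength, null_strengths) {
  if (length(null_strengths) == 0L) {
    stop("no non-signaling control strengths supplied", call. = FALSE)
  }
  threshold <- max(null_strengths)
  out <- ifelse(mean_strength > threshold, "signaling", "non_signaling")
  attr(out, "threshold") <- threshold
  out
}

#' Score and classify a simulated cohort end to end
#'
#' Convenience pipeline over a [simulate_cohort()] object: gates every
#' replicate on GFP, computes per-replicate signaling strength, averages
#' replicates per case and, when control strengths are supplied, classifies
#' each case against the upper limit of the controls.
#'
#' @param cohort A `flux_cohort`.
#' @param protocol A [flux_protocol()].
#' @param gfp_min GFP gate threshold (default [sim_gfp_gate()]).
#' @param null_strengths Optional non-signaling control strengths; when
#'   given, a `classification` column is added.
#' @return Data frame with one row per case: `case_id`, `isotype`,
#'   `signaling_true`, `strength` and optionally `classification`.
#' @export
score_cohort <- function(cohort, protocol = flux_protocol(),
                         gfp_min = sim_gfp_gate(), null_strengths = NULL) {
  stopifnot(inherits(cohort, "flux_cohort"))
  rows <- lapply(cohort, function(case) {
    res <- lapply(case$replicates, function(rep) {
      gated <- gate_events(rep$series, gfp_min = gfp_min)
      signaling_strength(gated, protocol)
    })
    data.frame(case_id = case$case_id, isotype = case$isotype,
               signaling_true = case$signaling,
               strength = average_replicates(res)$mean_strength)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(null_strengths)) {
    cls <- classify_signaling(out$strength, null_strengths)
    out$classification <- as.character(cls)
    attr(out, "threshold") <- attr(cls, "threshold")
  }
  out
}
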