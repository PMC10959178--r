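#' Acquisition protocol for a ratiometric calcium-flux measurement
#'
#' Defines the three phases of the kinetic assay: a baseline window before
#' the 4-OHT stimulus, an autonomous-response window between stimulus and
#' anti-Ig crosslinking, and a terminal crosslink window in which the maximal
#' BCR response is recorded. The defaults follow the standard protocol
#' (baseline 0-90 s, autonomous response measured for 450 s, maximum response
#' for 90 s, 20-s kinetic bins, 95th-percentile baseline threshold).
#'
#' @param t_4oht_s Time (seconds) at which 4-OHT is added; end of baseline.
#' @param autonomous_end_s End (seconds) of the autonomous window; time of
#'   anti-Ig crosslinking.
#' @param crosslink_end_s End (seconds) of acquisition.
#' @param bin_width_s Width (seconds) of the kinetic bins used to locate the
#'   peak crosslink response. A trailing partial bin is dropped.
#' @param baseline_quantile Quantile of the baseline SIR distribution used as
#'   responder threshold.
#' @return An object of class `flux_protocol`.
#' @examples
#' flux_protocol()
#' @export
flux_protocol <- function(t_4oht_s = 90, autonomous_end_s = 540,
                          crosslink_end_s = 630, bin_width_s = 20,
                          baseline_quantile = 0.95) {
  check_number(t_4oht_s, "t_4oht_s", lower = 1e-9)
  check_number(autonomous_end_s, "autonomous_end_s")
  check_number(crosslink_end_s, "crosslink_end_s")
  check_number(bin_width_s, "bin_width_s", lower = 1e-9)
  check_number(baseline_quantile, "baseline_quantile")
  if (!(t_4oht_s < autonomous_end_s && autonomous_end_s < crosslink_end_s)) {
    abort_field("flux_protocol",
                "windows must satisfy 0 < t_4oht_s < autonomous_end_s < crosslink_end_s")
  }
  if (baseline_quantile <= 0 || baseline_quantile >= 1) {
    abort_field("baseline_quantile", "must be strictly inside (0, 1)")
  }
  if (crosslink_end_s - autonomous_end_s < bin_width_s) {
    abort_field("bin_width_s", "crosslink window holds no full bin")
  }
  structure(list(t_4oht_s = t_4oht_s,
                 autonomous_end_s = autonomous_end_s,
                 crosslink_end_s = crosslink_end_s,
                 bin_width_s = bin_width_s,
                 baseline_quantile = baseline_quantile),
            class = "flux_protocol")
}

#' @export
print.flux_protocol <- function(x, ...) {
  cat(sprintf(paste0("<flux_protocol> baseline [0, %g) s | autonomous [%g, %g) s | ",
                     "crosslink [%g, %g] s | %g-s bins | q = %g\n"),
              x$t_4oht_s, x$t_4oht_s, x$autonomous_end_s, x$autonomous_end_s,
              x$crosslink_end_s, x$bin_width_s, x$baseline_quantile))
  invisible(x)
}

FLUX_REQUIRED_COLS <- c("time_s", "ch405", "ch485", "gfp")
FLUX_OPTIONAL_COLS <- c("dtomato", "viability")

#' Per-cell calcium-flux event table
#'
#' Wraps a data frame of flow-cytometry events in a validated container.
#' Events are sorted by acquisition time; rows with a non-positive Indo-1
#' channel are dropped (their 405/485 signal intensity ratio is undefined)
#' and counted in the attached QC report.
#'
#' @param data Data frame with columns `time_s`, `ch405` (calcium-bound
#'   Indo-1), `ch485` (calcium-free Indo-1), `gfp` (BCR-expression marker),
#'   and optionally `dtomato` (SLP65-ERT2 marker) and `viability`
#'   (dead-cell dye).
#' @param sample_id Sample identifier stored as an attribute.
#' @param replicate Replicate index (measurements are typically taken twice).
#' @return A data frame of class `flux_series` with attributes `sample_id`,
#'   `replicate` and `qc` (a list with `n_input` and `n_dropped_nonpositive`).
#' @export
flux_series <- function(data, sample_id = "sample", replicate = 1L) {
  if (!is.data.frame(data)) abort_field("data", "must be a data frame")
  missing_cols <- setdiff(FLUX_REQUIRED_COLS, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0L) stop("event table is empty", call. = FALSE)
  keep <- intersect(c(FLUX_REQUIRED_COLS, FLUX_OPTIONAL_COLS), names(data))
  data <- data[, keep, drop = FALSE]
  n_input <- nrow(data)
  ok <- is.finite(data$ch405) & is.finite(data$ch485) &
    data$ch405 > 0 & data$ch485 > 0
  data <- data[ok, , drop = FALSE]
  if (nrow(data) == 0L) {
    stop("no events with positive Indo-1 channels remain", call. = FALSE)
  }
  data <- data[order(data$time_s), , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            sample_id = sample_id,
            replicate = as.integer(replicate),
            qc = list(n_input = n_input,
                      n_dropped_nonpositive = n_input - nrow(data)),
            class = c("flux_series", "data.frame"))
}

#' @export
print.flux_series <- function(x, ...) {
  qc <- attr(x, "qc")
  cat(sprintf("<flux_series> sample '%s' replicate %d: %d events (%d dropped at read)\n",
              attr(x, "sample_id"), attr(x, "replicate"), nrow(x),
              qc$n_dropped_nonpositive))
  invisible(x)
}

#' Per-event 405/485 signal intensity ratio (SIR)
#'
#' @param series A [flux_series()].
#' @return Numeric vector of per-event SIR values.
#' @export
sir <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  series$ch405 / series$ch485
}

#' QC report attached to a flux series
#'
#' @param series A [flux_series()].
#' @return List with `n_input` and `n_dropped_nonpositive`, plus the gate
#'   report when the series has been gated.
#' @export
qc_report <- function(series) {
  stopifnot(inherits(series, "flux_series"))
  c(attr(series, "qc"), list(gate = attr(series, "gate")))
}

#' Read a calcium-flux event table from CSV
#'
#' The dialect is UTF-8, comma-separated, header row required, `.` decimal.
#' Rows with non-positive Indo-1 channels are dropped and counted in the QC
#' report.
#'
#' @param path Path to the CSV file.
#' @param sample_id,replicate Metadata attached to the series; `sample_id`
#'   defaults to the file name.
#' @return A [flux_series()].
#' @export
read_flux_csv <- function(path, sample_id = NULL, replicate = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  }
  flux_series(data, sample_id = sample_id, replicate = replicate)
}

#' Write a calcium-flux event table to CSV
#'
#' @param series A [flux_series()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_flux_csv <- function(series, path) {
  stopifnot(inherits(series, "flux_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Gate events on expression markers and viability
#'
#' Subsets a series to events passing all supplied gates: GFP above a fixed
#' threshold (BCR-expressing cells), dTomato above a threshold (SLP65-ERT2
#' expression) and viability dye below a threshold (live cells). Instead of a
#' fixed GFP threshold, an untransduced control series may be supplied, in
#' which case the threshold is learned as a high quantile (default 99th) of
#' the control's GFP distribution.
#'
#' @param series A [flux_series()].
#' @param gfp_min Fixed GFP threshold (events with `gfp > gfp_min` retained).
#' @param dtomato_min dTomato threshold (requires a `dtomato` column).
#' @param viability_max Viability-dye threshold (requires `viability`).
#' @param gfp_control Optional untransduced control [flux_series()] from
#'   which the GFP threshold is learned; overrides `gfp_min`.
#' @param gfp_control_quantile Quantile of the control GFP used as threshold.
#' @return The gated [flux_series()] with a `gate` attribute recording input
#'   and output counts, the fraction retained and thresholds used. Gating is
#'   idempotent: regating with identical thresholds returns the same events.
#' @export
gate_events <- function(series, gfp_min = NULL, dtomato_min = NULL,
                        viability_max = NULL, gfp_control = NULL,
                        gfp_control_quantile = 0.99) {
  stopifnot(inherits(series, "flux_series"))
  if (!is.null(gfp_control)) {
    stopifnot(inherits(gfp_control, "flux_series"))
    check_number(gfp_control_quantile, "gfp_control_quantile",
                 lower = 1e-9, upper = 1 - 1e-9)
    gfp_min <- unname(stats::quantile(gfp_control$gfp, gfp_control_quantile,
                                      type = 7))
  }
  if (is.null(gfp_min) && is.null(dtomato_min) && is.null(viability_max)) {
    stop("at least one gate must be specified", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(series))
  if (!is.null(gfp_min)) {
    check_number(gfp_min, "gfp_min")
    keep <- keep & series$gfp > gfp_min
  }
  if (!is.null(dtomato_min)) {
    check_number(dtomato_min, "dtomato_min")
    if (is.null(series$dtomato)) {
      stop("series has no `dtomato` column to gate on", call. = FALSE)
    }
    keep <- keep & series$dtomato > dtomato_min
  }
  if (!is.null(viability_max)) {
    check_number(viability_max, "viability_max")
    if (is.null(series$viability)) {
      stop("series has no `viability` column to gate on", call. = FALSE)
    }
    keep <- keep & series$viability < viability_max
  }
  n_in <- nrow(series)
  out <- series[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("gate retains zero events; sample unusable", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(series, "sample_id")
  attr(out, "replicate") <- attr(series, "replicate")
  attr(out, "qc") <- attr(series, "qc")
  attr(out, "gate") <- list(n_input = n_in, n_output = nrow(out),
                            fraction_retained = nrow(out) / n_in,
                            gfp_min = gfp_min, dtomato_min = dtomato_min,
                            viability_max = viability_max)
  class(out) <- c("flux_series", "data.frame")
  out
}
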