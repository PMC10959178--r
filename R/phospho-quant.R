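#' Gates for phospho-flow samples
#'
#' Live, SLP65-ERT2 (dTomato) and BCR (GFP) double-positive cells are
#' retained. Defaults match the synthetic-data detector scales.
#'
#' @param gfp_min,dtomato_min Lower thresholds on the expression markers.
#' @param viability_max Upper threshold on the dead-cell dye.
#' @return Named list of thresholds.
#' @export
phospho_gates <- function(gfp_min = 500, dtomato_min = 500,
                          viability_max = 1000) {
  list(gfp_min = gfp_min, dtomato_min = dtomato_min,
       viability_max = viability_max)
}

gate_phospho <- function(sample, gates) {
  stopifnot(inherits(sample, "phospho_sample"))
  keep <- sample$gfp > gates$gfp_min &
    sample$dtomato > gates$dtomato_min &
    sample$viability < gates$viability_max
  out <- sample[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no cells remain after phospho gating", call. = FALSE)
  }
  out
}

#' Mean fluorescence intensity of a gated phospho sample
#'
#' @param sample A `phospho_sample` (see [simulate_phospho()]).
#' @param gates Thresholds from [phospho_gates()].
#' @param type `"arithmetic"` (MFI, default) or `"geometric"`.
#' @return List with `mfi`, `sd` (per-cell dispersion) and `n` cells after
#'   gating.
#' @export
compute_mfi <- function(sample, gates = phospho_gates(),
                        type = c("arithmetic", "geometric")) {
  type <- match.arg(type)
  gated <- gate_phospho(sample, gates)
  x <- gated$fluor
  mfi <- if (type == "arithmetic") mean(x) else exp(mean(log(x)))
  list(mfi = mfi, sd = stats::sd(x), n = length(x))
}

#' Crosslink-normalized phospho-flow MFI
#'
#' The MFI of the unstimulated sample is divided by the MFI measured after
#' anti-Ig crosslinking of the same transductant. A value of 1 means
#' autonomous phosphorylation reaches the crosslink-induced level.
#'
#' @param unstim,stim `phospho_sample` objects for the unstimulated and
#'   crosslinked condition of the same target.
#' @param gates Thresholds from [phospho_gates()].
#' @param type MFI type passed to [compute_mfi()].
#' @return An object of class `phospho_result` with fields `target`,
#'   `mfi_unstim`, `mfi_stim`, `normalized_mfi`, `sd_unstim`, `sd_stim`,
#'   `n_unstim`, `n_stim`.
#' @export
normalized_mfi <- function(unstim, stim, gates = phospho_gates(),
                           type = "arithmetic") {
  t_u <- attr(unstim, "target"); t_s <- attr(stim, "target")
  if (!is.null(t_u) && !is.null(t_s) && !identical(t_u, t_s)) {
    stop(sprintf("samples target different proteins: '%s' vs '%s'", t_u, t_s),
         call. = FALSE)
  }
  mu <- compute_mfi(unstim, gates, type)
  ms <- compute_mfi(stim, gates, type)
  if (ms$mfi <= 0) stop("crosslinked MFI is non-positive", call. = FALSE)
  structure(list(target = t_u, mfi_unstim = mu$mfi, mfi_stim = ms$mfi,
                 normalized_mfi = mu$mfi / ms$mfi,
                 sd_unstim = mu$sd, sd_stim = ms$sd,
                 n_unstim = mu$n, n_stim = ms$n),
            class = "phospho_result")
}

#' @export
print.phospho_result <- function(x, ...) {
  cat(sprintf("<phospho_result> %s: normalized MFI %.4f (unstim %.1f / crosslinked %.1f)\n",
              if (is.null(x$target)) "?" else x$target,
              x$normalized_mfi, x$mfi_unstim, x$mfi_stim))
  invisible(x)
}

#' Compare phosphorylation levels between two groups
#'
#' Two-sample t test (equal-variance Student by default) on per-group
#' values, one- or two-sided. Degenerate input (both groups constant and
#' equal) returns P = 1 by convention.
#'
#' @param group_a,group_b Numeric vectors (>= 2 values each).
#' @param sided `"two.sided"`, `"less"` or `"greater"`.
#' @param var_equal Use the pooled-variance Student t test (default) rather
#'   than Welch.
#' @return List with `statistic`, `p_value`, `df`, `sided`.
#' @export
compare_phospho <- function(group_a, group_b, sided = "two.sided",
                            var_equal = TRUE) {
  two_sample_t(group_a, group_b, sided = sided, var_equal = var_equal)
}
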