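#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test; the two-sided P value sums the probabilities
#' of all tables (with the observed margins) no more probable than the
#' observed one, the standard convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param sided `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `p_value`, `odds_ratio` (conditional MLE) and `sided`.
#' @examples
#' # isotype x signaling association in an 18-case cohort
#' fisher_exact(matrix(c(13, 0, 1, 4), nrow = 2,
#'                     dimnames = list(signaling = c("yes", "no"),
#'                                     isotype = c("IgM", "IgG"))))
#' @export
fisher_exact <- function(table, sided = "two.sided") {
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    abort_field("table", "must be 2x2")
  }
  if (any(!is.finite(table)) || any(table < 0) ||
      any(table != round(table))) {
    abort_field("table", "counts must be non-negative integers")
  }
  if (sum(table) == 0) abort_field("table", "total count must be > 0")
  fit <- stats::fisher.test(table, alternative = sided)
  list(p_value = min(fit$p.value, 1), odds_ratio = unname(fit$estimate),
       sided = sided)
}

#' Rank-based comparison of two groups
#'
#' `variant = "signed_rank"` runs Wilcoxon's signed rank test on paired,
#' equal-length samples; `variant = "rank_sum"` runs the rank-sum
#' (Mann-Whitney) test on independent samples. P values are exact for small
#' samples without ties (n <= 25), and use the normal approximation with
#' continuity correction otherwise. All paired differences zero returns
#' P = 1 by convention.
#'
#' @param group_a,group_b Numeric vectors; equal length for the signed-rank
#'   variant.
#' @param variant `"signed_rank"` or `"rank_sum"`.
#' @param sided `"two.sided"`, `"less"` or `"greater"`.
#' @return List with `statistic`, `p_value`, `variant`, `sided`, `exact`.
#' @export
rank_test <- function(group_a, group_b,
                      variant = c("signed_rank", "rank_sum"),
                      sided = "two.sided") {
  variant <- match.arg(variant)
  sided <- match.arg(sided, c("two.sided", "less", "greater"))
  if (variant == "signed_rank") {
    if (length(group_a) != length(group_b)) {
      stop("signed-rank variant requires equal-length paired samples",
           call. = FALSE)
    }
    d <- group_a - group_b
    if (all(d == 0)) {
      return(list(statistic = NA_real_, p_value = 1, variant = variant,
                  sided = sided, exact = TRUE))
    }
    d <- d[d != 0]
    use_exact <- length(d) <= 25L && !anyDuplicated(abs(d))
    fit <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, paired = TRUE,
                         alternative = sided, exact = use_exact,
                         correct = TRUE))
  } else {
    n <- length(group_a) + length(group_b)
    use_exact <- n <= 50L && !anyDuplicated(c(group_a, group_b))
    fit <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, paired = FALSE,
                         alternative = sided, exact = use_exact,
                         correct = TRUE))
  }
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       variant = variant, sided = sided, exact = use_exact)
}

#' Percent identity of an IGHV sequence to its germline allele
#'
#' Position-by-position identity of two pre-aligned nucleotide sequences
#' (e.g. IMGT-gapped). Positions where either sequence carries a gap
#' (`-` or `.`) or an `N` are excluded from the comparison. The result is
#' `100 * matches / compared positions`, reported to 0.1%.
#'
#' @param sequence,germline_reference Equal-length character strings (or
#'   objects coercible via `as.character`, e.g. `Biostrings::DNAString`).
#' @return Percent identity in `[0, 100]`, rounded to 1 decimal.
#' @examples
#' ighv_homology("ACGTACGTAC", "ACGTACGTAT")  # 90.0
#' @export
ighv_homology <- function(sequence, germline_reference) {
  a <- toupper(as.character(sequence))
  b <- toupper(as.character(germline_reference))
  if (length(a) != 1L || length(b) != 1L) {
    stop("supply one sequence and one germline reference", call. = FALSE)
  }
  if (nchar(a) != nchar(b)) {
    stop("sequences must be pre-aligned to equal length", call. = FALSE)
  }
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  vb <- strsplit(b, "", fixed = TRUE)[[1]]
  skip <- c("-", ".", "N")
  comparable <- !(va %in% skip) & !(vb %in% skip)
  n <- sum(comparable)
  if (n == 0L) stop("no comparable positions", call. = FALSE)
  round(100 * sum(va[comparable] == vb[comparable]) / n, 1)
}

#' Read pre-aligned case/germline FASTA pairs and compute homologies
#'
#' Expects a FASTA file with an even number of records ordered as
#' case sequence followed by its germline reference. Requires the
#' `Biostrings` package.
#'
#' @param path FASTA file path.
#' @return Data frame with `case_id` (case record names) and
#'   `ighv_homology`.
#' @export
read_homology_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) %% 2L != 0L) {
    stop("expected case/germline record pairs", call. = FALSE)
  }
  idx <- seq(1L, length(seqs), by = 2L)
  data.frame(
    case_id = names(seqs)[idx],
    ighv_homology = vapply(idx, function(i) {
      ighv_homology(as.character(seqs[[i]]), as.character(seqs[[i + 1L]]))
    }, numeric(1)))
}

is_signaling_label <- function(x) {
  if (is.logical(x)) return(x)
  normalize_label(x) %in% c("signaling", "yes", "true", "1")
}

#' Cohort-level summary of autonomous signaling associations
#'
#' Counts signaling cases by isotype and by cell-of-origin class, tests both
#' associations with Fisher's exact test (IgM vs class-switched isotypes;
#' ABC/non-GCB vs GCB, unclassified cases excluded), and summarizes IGHV
#' germline homology as median and range.
#'
#' @param table Data frame with one row per case and columns `case_id`,
#'   `signaling` (logical or "signaling"/"non_signaling"), and optionally
#'   `isotype`, `coo`, `cluster`, `ighv_homology`.
#' @return List of class `cohort_summary` with counts, per-association
#'   Fisher results and the homology summary.
#' @export
cohort_summary <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("cohort table must have >= 1 case", call. = FALSE)
  }
  if (anyDuplicated(table$case_id)) {
    stop("case_ids must be unique", call. = FALSE)
  }
  signaling <- is_signaling_label(table$signaling)
  out <- list(n_cases = nrow(table), n_signaling = sum(signaling))

  if (!is.null(table$isotype)) {
    igm <- toupper(table$isotype) == "IGM"
    out$signaling_by_isotype <- stats::setNames(
      as.data.frame(table(isotype = table$isotype, signaling = signaling)),
      c("isotype", "signaling", "n"))
    tab <- matrix(c(sum(igm & signaling), sum(igm & !signaling),
                    sum(!igm & signaling), sum(!igm & !signaling)),
                  nrow = 2,
                  dimnames = list(signaling = c("yes", "no"),
                                  isotype = c("IgM", "other")))
    out$fisher_isotype <- fisher_exact(tab)
    out$isotype_table <- tab
  }

  if (!is.null(table$coo)) {
    coo <- normalize_label(table$coo)
    informative <- coo %in% c("abc", "non_gcb", "gcb")
    abc_like <- coo %in% c("abc", "non_gcb")
    if (sum(informative) > 0L) {
      tab <- matrix(c(sum(informative & abc_like & signaling),
                      sum(informative & abc_like & !signaling),
                      sum(informative & !abc_like & signaling),
                      sum(informative & !abc_like & !signaling)),
                    nrow = 2,
                    dimnames = list(signaling = c("yes", "no"),
                                    coo = c("ABC/non-GCB", "GCB")))
      out$fisher_coo <- fisher_exact(tab)
      out$coo_table <- tab
    }
  }

  if (!is.null(table$ighv_homology)) {
    h <- table$ighv_homology[!is.na(table$ighv_homology)]
    if (any(h < 0 | h > 100)) {
      abort_field("ighv_homology", "must be in [0, 100]")
    }
    if (length(h) > 0L) {
      out$homology <- list(median = stats::median(h), range = range(h),
                           n = length(h))
    }
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d/%d cases autonomously signaling\n",
              x$n_signaling, x$n_cases))
  if (!is.null(x$fisher_isotype)) {
    cat(sprintf("  isotype association (IgM vs other): Fisher P = %.4g\n",
                x$fisher_isotype$p_value))
  }
  if (!is.null(x$fisher_coo)) {
    cat(sprintf("  COO association (ABC/non-GCB vs GCB): Fisher P = %.4g\n",
                x$fisher_coo$p_value))
  }
  if (!is.null(x$homology)) {
    cat(sprintf("  IGHV germline homology: median %g%% (range: %g-%g%%)\n",
                x$homology$median, x$homology$range[1], x$homology$range[2]))
  }
  invisible(x)
}

#' Write a cohort summary as TSV and JSON
#'
#' @param summary A [cohort_summary()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "cohort_summary.json")
  payload <- list(n_cases = summary$n_cases,
                  n_signaling = summary$n_signaling)
  if (!is.null(summary$fisher_isotype)) {
    payload$fisher_isotype_p <- summary$fisher_isotype$p_value
  }
  if (!is.null(summary$fisher_coo)) {
    payload$fisher_coo_p <- summary$fisher_coo$p_value
  }
  if (!is.null(summary$homology)) {
    payload$homology_median <- summary$homology$median
    payload$homology_min <- summary$homology$range[1]
    payload$homology_max <- summary$homology$range[2]
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  tsv_path <- file.path(dir, "signaling_by_isotype.tsv")
  if (!is.null(summary$signaling_by_isotype)) {
    utils::write.table(summary$signaling_by_isotype, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(json = json_path, tsv = tsv_path))
}
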