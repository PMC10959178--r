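#' Consequence whitelist for DLBCL variant filtering
#'
#' VEP-style consequence terms retained by the variant filter: coding
#' changes and splice-region variants in the classes used to annotate
#' NF-kB-pathway and recurrently mutated DLBCL genes.
#'
#' @return Character vector of consequence terms.
#' @export
dlbcl_consequences <- function() {
  c("frameshift_variant", "inframe_deletion", "inframe_insertion",
    "missense_variant", "missense_variant&splice_region_variant",
    "splice_region_variant&synonymous_variant", "synonymous_variant",
    "stop_gained", "stop_lost", "frameshift_variant&stop_lost",
    "coding_sequence_variant")
}

DAMAGING_POLYPHEN <- c("possibly_damaging", "probably_damaging")
PATHOGENIC_CLINSIG <- c("likely_pathogenic", "pathogenic")

normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[ /]+", "_", x)
}

#' Filter annotated variants by pathogenicity rules
#'
#' A variant is retained iff its gene is whitelisted, its consequence is
#' whitelisted, it carries at least one damaging annotation (SIFT
#' "deleterious", PolyPhen "possibly damaging"/"probably damaging", or
#' clinical significance "likely pathogenic"/"pathogenic"), and it is not
#' annotated benign — variants with benign clinical significance are always
#' discarded, regardless of other annotations. Missing annotations count as
#' not damaging. Label matching is case-insensitive and tolerant of
#' space/underscore variants. The filter is idempotent and order-independent.
#'
#' @param records Data frame with columns `case_id`, `gene`, `consequence`
#'   and optionally `sift`, `polyphen`, `clinical_significance`.
#' @param gene_whitelist Non-empty character vector of gene symbols.
#' @param consequence_whitelist Non-empty character vector of consequence
#'   terms; defaults to [dlbcl_consequences()].
#' @return The retained rows of `records`.
#' @export
filter_variants <- function(records, gene_whitelist,
                            consequence_whitelist = dlbcl_consequences()) {
  if (length(gene_whitelist) == 0L) {
    abort_field("gene_whitelist", "must be non-empty")
  }
  if (length(consequence_whitelist) == 0L) {
    abort_field("consequence_whitelist", "must be non-empty")
  }
  req <- c("gene", "consequence")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) return(records)
  get_label <- function(col) {
    if (col %in% names(records)) normalize_label(records[[col]])
    else rep(NA_character_, nrow(records))
  }
  sift <- get_label("sift")
  polyphen <- get_label("polyphen")
  clinsig <- get_label("clinical_significance")
  damaging <- (!is.na(sift) & sift == "deleterious") |
    (!is.na(polyphen) & polyphen %in% DAMAGING_POLYPHEN) |
    (!is.na(clinsig) & clinsig %in% PATHOGENIC_CLINSIG)
  benign <- !is.na(clinsig) & clinsig == "benign"
  keep <- records$gene %in% gene_whitelist &
    normalize_label(records$consequence) %in%
      normalize_label(consequence_whitelist) &
    damaging & !benign
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive-Bayes model of DLBCL consensus clusters
#'
#' Defines the probabilistic classifier over binary aberration states
#' (wild-type vs aberrant) of cluster-defining loci: a prior per cluster and,
#' per locus, the conditional frequency of the aberrant state in each
#' cluster. Frequencies of exactly 0 or 1 are smoothed to `epsilon` /
#' `1 - epsilon` for classification so that a single discordant locus cannot
#' zero out a posterior; the raw frequencies are kept for data generation.
#'
#' @param clusters Character vector of cluster names (declared order breaks
#'   posterior ties).
#' @param loci Character vector of locus names.
#' @param freq Numeric matrix (loci x clusters) of aberration frequencies in
#'   `[0, 1]`.
#' @param priors Cluster prior probabilities (default uniform); must sum
#'   to 1.
#' @param epsilon Smoothing pseudo-probability in (0, 0.5).
#' @return An object of class `cluster_model`.
#' @export
cluster_model <- function(clusters, loci, freq, priors = NULL,
                          epsilon = 0.01) {
  stopifnot(is.character(clusters), is.character(loci))
  if (length(clusters) < 2L) abort_field("clusters", "need >= 2 clusters")
  freq <- as.matrix(freq)
  if (!all(dim(freq) == c(length(loci), length(clusters)))) {
    abort_field("freq", "must be a loci x clusters matrix")
  }
  if (any(!is.finite(freq)) || any(freq < 0) || any(freq > 1)) {
    abort_field("freq", "frequencies must be in [0, 1]")
  }
  dimnames(freq) <- list(loci, clusters)
  if (is.null(priors)) priors <- rep(1 / length(clusters), length(clusters))
  if (length(priors) != length(clusters) || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-9) {
    abort_field("priors", "must be non-negative and sum to 1")
  }
  names(priors) <- clusters
  check_number(epsilon, "epsilon", lower = 1e-12, upper = 0.5 - 1e-12)
  freq_smoothed <- pmin(pmax(freq, epsilon), 1 - epsilon)
  structure(list(clusters = clusters, loci = loci, freq = freq,
                 freq_smoothed = freq_smoothed, priors = priors,
                 epsilon = epsilon),
            class = "cluster_model")
}

#' Read or write a cluster model as JSON
#'
#' The schema holds `clusters`, `priors`, `loci`, `frequencies` (an object
#' mapping each locus to its per-cluster aberration frequencies) and
#' `epsilon`.
#'
#' @param path JSON file path.
#' @return For `read_cluster_model`, a [cluster_model()]; for
#'   `write_cluster_model`, invisibly `path`.
#' @export
read_cluster_model <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  freq <- do.call(rbind, spec$frequencies[spec$loci])
  cluster_model(clusters = spec$clusters, loci = spec$loci, freq = freq,
                priors = spec$priors,
                epsilon = if (is.null(spec$epsilon)) 0.01 else spec$epsilon)
}

#' @rdname read_cluster_model
#' @param model A [cluster_model()].
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  freq_list <- stats::setNames(
    lapply(seq_along(model$loci), function(i) unname(model$freq[i, ])),
    model$loci)
  jsonlite::write_json(list(clusters = model$clusters,
                            priors = unname(model$priors),
                            loci = model$loci, frequencies = freq_list,
                            epsilon = model$epsilon),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Assign a case to a consensus cluster by conditional probabilities
#'
#' Computes, in log space, `posterior(c) proportional to prior(c) * product
#' over observed loci of [p_lc if aberrant else 1 - p_lc]` with smoothed
#' frequencies, then normalizes. Loci in the model but missing (NA) from the
#' vector are skipped. A vector with zero observed loci returns the priors,
#' flagged uninformative. Posterior ties are broken by declared cluster
#' order and flagged ambiguous.
#'
#' @param aberration_vector Named vector of 0/1 (or logical) states; names
#'   must be model loci. NA marks a missing locus.
#' @param model A [cluster_model()].
#' @return An object of class `cluster_assignment` with `posterior` (named,
#'   sums to 1), `cluster` (argmax), `max_posterior`, `uninformative`,
#'   `ambiguous` and `n_observed_loci`.
#' @export
assign_consensus_cluster <- function(aberration_vector, model) {
  stopifnot(inherits(model, "cluster_model"))
  x <- aberration_vector
  if (is.logical(x)) x <- as.integer(x)
  if (is.null(names(x)) && length(x) > 0L) {
    abort_field("aberration_vector", "must be named by locus")
  }
  unknown <- setdiff(names(x), model$loci)
  if (length(unknown) > 0L) {
    stop("loci absent from the model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x <- x[!is.na(x)]
  if (any(!x %in% c(0L, 1L))) {
    abort_field("aberration_vector", "states must be 0/1 (or NA)")
  }
  if (length(x) == 0L) {
    post <- model$priors
    return(structure(list(posterior = post,
                          cluster = model$clusters[which.max(post)],
                          max_posterior = max(post), uninformative = TRUE,
                          ambiguous = FALSE, n_observed_loci = 0L),
                     class = "cluster_assignment"))
  }
  p <- model$freq_smoothed[names(x), , drop = FALSE]
  # x recycles down the rows of the loci x clusters matrix
  loglik <- colSums(log(p) * x + log1p(-p) * (1 - x))
  logpost <- log(model$priors) + loglik
  post <- exp(logpost - logsumexp(logpost))
  post <- post / sum(post)
  best <- which.max(post)  # first maximum = declared cluster order
  ambiguous <- sum(abs(post - post[best]) < 1e-12) > 1L
  structure(list(posterior = post, cluster = model$clusters[best],
                 max_posterior = unname(post[best]),
                 uninformative = FALSE, ambiguous = ambiguous,
                 n_observed_loci = length(x)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s (posterior %.3f%s%s)\n", x$cluster,
              x$max_posterior,
              if (x$uninformative) ", uninformative" else "",
              if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}

#' High-confidence call on a cluster assignment
#'
#' A case is `"assigned"` iff its maximum posterior strictly exceeds the
#' confidence threshold (default 0.9), else `"unclassified"`.
#'
#' @param assignment A `cluster_assignment`.
#' @param threshold Confidence threshold (strict inequality).
#' @return `"assigned"` or `"unclassified"`.
#' @export
confidence_call <- function(assignment, threshold = 0.9) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  check_number(threshold, "threshold", lower = 0, upper = 1)
  if (assignment$max_posterior > threshold) "assigned" else "unclassified"
}

#' Hans-algorithm cell-of-origin call from immunohistochemistry
#'
#' Decision tree over CD10, BCL6 and MUM1 staining: CD10+ is GCB; CD10-
#' BCL6- is non-GCB; CD10- BCL6+ follows MUM1 (MUM1+ non-GCB, MUM1- GCB).
#'
#' @param cd10,bcl6,mum1 Logical marker calls (TRUE = positive staining).
#' @return `"GCB"` or `"non_GCB"`.
#' @export
hans_coo <- function(cd10, bcl6, mum1) {
  markers <- list(cd10 = cd10, bcl6 = bcl6, mum1 = mum1)
  for (m in names(markers)) {
    v <- markers[[m]]
    if (length(v) != 1L || !is.logical(v) || is.na(v)) {
      abort_field(m, "must be a single TRUE/FALSE marker call")
    }
  }
  if (cd10) return("GCB")
  if (!bcl6) return("non_GCB")
  if (mum1) "non_GCB" else "GCB"
}
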