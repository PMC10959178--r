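# Independent oracle implementations. These deliberately avoid the package's
# code paths (and stats::quantile/median where the package uses them): sorted
# order statistics, explicit loops and direct products only.

sort_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

sort_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# brute-force per-event recomputation of the signaling-strength statistic
brute_force_strength <- function(df, t_4oht = 90, aut_end = 540,
                                 xl_end = 630, bin_w = 20, q = 0.95) {
  ratio <- df$ch405 / df$ch485
  thr <- sort_quantile7(ratio[df$time_s < t_4oht], q)

  n_bins <- floor((xl_end - aut_end) / bin_w)
  best_med <- -Inf
  peak_members <- NULL
  for (b in seq_len(n_bins)) {
    lo <- aut_end + (b - 1) * bin_w
    inside <- df$time_s >= lo & df$time_s < lo + bin_w
    if (any(inside)) {
      m <- sort_median(ratio[inside])
      if (m > best_med) {  # strict: ties keep the earliest bin
        best_med <- m
        peak_members <- inside
      }
    }
  }
  peak_ratio <- ratio[peak_members]
  u <- sum(peak_ratio <= thr) / length(peak_ratio)

  in_aut <- df$time_s >= t_4oht & df$time_s < aut_end
  raw <- sum(ratio[in_aut] > thr) / sum(in_aut)
  q_corr <- min(raw / (1 - u), 1)

  responders <- ratio[in_aut & ratio > thr]
  cal <- if (length(responders) == 0) 0 else sort_median(responders) / best_med
  list(threshold = thr, u = u, q_aut = q_corr, cal_sir_aut = cal,
       strength = q_corr * cal)
}

# direct-product naive-Bayes posterior (no logs)
nb_posterior_oracle <- function(x, priors, freq_smoothed) {
  x <- x[!is.na(x)]
  num <- priors
  for (cl in seq_along(priors)) {
    for (locus in names(x)) {
      p <- freq_smoothed[locus, cl]
      num[cl] <- num[cl] * (if (x[[locus]] == 1) p else 1 - p)
    }
  }
  num / sum(num)
}

# boolean restatement of the variant retention rule
variant_rule_oracle <- function(rec, genes, consequences) {
  norm <- function(z) gsub("[ /]+", "_", tolower(trimws(as.character(z))))
  sift_del <- !is.na(rec$sift) && norm(rec$sift) == "deleterious"
  pp_dam <- !is.na(rec$polyphen) &&
    norm(rec$polyphen) %in% c("possibly_damaging", "probably_damaging")
  cs <- if (is.na(rec$clinical_significance)) "" else
    norm(rec$clinical_significance)
  cs_path <- cs %in% c("likely_pathogenic", "pathogenic")
  if (cs == "benign") return(FALSE)
  rec$gene %in% genes && norm(rec$consequence) %in% norm(consequences) &&
    (sift_del || pp_dam || cs_path)
}

# full enumeration of 2x2 tables with fixed margins via choose()
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- choose(c1, ks) * choose(n - c1, r1 - ks) / choose(n, r1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact one-sided signed-rank P by enumeration of all sign patterns
signed_rank_enum_oracle <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  v_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% ranks
  if (alternative == "greater") mean(v_all >= v_obs) else mean(v_all <= v_obs)
}

# random annotated variant table exercising every branch of the filter rule
random_variant_records <- function(n, seed) {
  set.seed(seed)
  lab <- function(x) sample(x, n, replace = TRUE)
  data.frame(
    case_id = lab(sprintf("case%02d", 1:10)),
    gene = lab(c("MYD88", "CD79B", "CARD11", "PIM1", "TP53", "ACTB", "GAPDH")),
    consequence = lab(c("missense_variant", "stop_gained",
                        "synonymous_variant", "intron_variant",
                        "frameshift_variant", "inframe_deletion")),
    sift = lab(c("deleterious", "tolerated", NA)),
    polyphen = lab(c("probably_damaging", "possibly_damaging", "benign", NA)),
    clinical_significance = lab(c("pathogenic", "likely_pathogenic", "benign",
                                  "uncertain_significance", NA)),
    stringsAsFactors = FALSE)
}

# standard two-cluster model with well-separated aberration frequencies
well_separated_model <- function(n_loci = 8, epsilon = 0.01) {
  freq <- cbind(A = rep(c(0.9, 0.1), length.out = n_loci),
                B = rep(c(0.1, 0.9), length.out = n_loci))
  cluster_model(clusters = c("A", "B"),
                loci = sprintf("locus%02d", seq_len(n_loci)),
                freq = freq, epsilon = epsilon)
}
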