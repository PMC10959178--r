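test_that("variant filter applies the pathogenicity retention rule", {
  genes <- c("MYD88", "CD79B", "CARD11", "PIM1", "TP53")
  keep_one <- data.frame(case_id = "c1", gene = "MYD88",
                         consequence = "missense_variant",
                         sift = "deleterious", polyphen = NA,
                         clinical_significance = NA)
  expect_identical(nrow(filter_variants(keep_one, genes)), 1L)

  # benign clinical significance dominates any damaging annotation
  benign <- keep_one
  benign$clinical_significance <- "benign"
  expect_identical(nrow(filter_variants(benign, genes)), 0L)

  # non-whitelisted gene or consequence is discarded
  off_gene <- keep_one; off_gene$gene <- "ACTB"
  expect_identical(nrow(filter_variants(off_gene, genes)), 0L)
  off_cons <- keep_one; off_cons$consequence <- "intron_variant"
  expect_identical(nrow(filter_variants(off_cons, genes)), 0L)

  expect_error(filter_variants(keep_one, character(0)), "gene_whitelist")
})

test_that("variant filter matches the boolean-rule oracle on random records", {
  genes <- c("MYD88", "CD79B", "CARD11", "PIM1", "TP53")
  records <- random_variant_records(500, seed = 17)
  got <- filter_variants(records, genes)
  want <- records[vapply(seq_len(nrow(records)), function(i) {
    variant_rule_oracle(records[i, ], genes, dlbcl_consequences())
  }, logical(1)), , drop = FALSE]
  rownames(want) <- NULL
  expect_identical(got, want)
  expect_gt(nrow(got), 0L)

  # idempotent and order-independent (same retained set, any input order)
  expect_identical(filter_variants(got, genes), got)
  shuffled <- records[sample(nrow(records)), , drop = FALSE]
  resorted <- filter_variants(shuffled, genes)
  key <- function(df) sort(do.call(paste, df))
  expect_identical(key(resorted), key(got))
})

test_that("naive-Bayes posteriors equal direct-product enumeration", {
  set.seed(23)
  loci <- sprintf("L%02d", 1:12)
  clusters <- sprintf("C%d", 1:5)
  freq <- matrix(runif(60), nrow = 12, dimnames = list(loci, clusters))
  priors <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  model <- cluster_model(clusters, loci, freq, priors = priors)
  for (i in 1:100) {
    x <- setNames(sample(c(0L, 1L, NA), 12, replace = TRUE,
                         prob = c(0.4, 0.4, 0.2)), loci)
    got <- assign_consensus_cluster(x, model)
    want <- nb_posterior_oracle(x, model$priors, model$freq_smoothed)
    expect_equal(got$posterior, want, tolerance = 1e-12)
    expect_equal(sum(got$posterior), 1, tolerance = 1e-9)
    expect_identical(got$cluster, clusters[which.max(want)])
  }
})

test_that("single-locus and empty aberration vectors follow Bayes exactly", {
  model <- cluster_model(c("A", "B"), "locus1", matrix(c(1, 0), nrow = 1),
                         epsilon = 0.01)
  one <- assign_consensus_cluster(c(locus1 = 1L), model)
  expect_equal(unname(one$posterior), c(0.99, 0.01), tolerance = 1e-12)

  empty <- assign_consensus_cluster(setNames(integer(0), character(0)), model)
  expect_equal(empty$posterior, model$priors)
  expect_true(empty$uninformative)

  # uniform frequencies are uninformative: posterior equals the priors
  flat <- cluster_model(c("A", "B"), c("l1", "l2"),
                        matrix(0.4, nrow = 2, ncol = 2),
                        priors = c(0.7, 0.3))
  res <- assign_consensus_cluster(c(l1 = 1L, l2 = 0L), flat)
  expect_equal(unname(res$posterior), c(0.7, 0.3), tolerance = 1e-12)

  expect_error(assign_consensus_cluster(c(nope = 1L), model), "nope")
})

test_that("classifier recovers labels on well-separated synthetic models", {
  model <- well_separated_model(n_loci = 10)
  sim <- simulate_aberrations(model, n_cases_per_cluster = 100, seed = 41)
  calls <- vapply(seq_len(nrow(sim$states)), function(i) {
    assign_consensus_cluster(sim$states[i, ], model)$cluster
  }, character(1))
  expect_gte(mean(calls == sim$truth), 0.95)

  # deterministic loci (frequencies all 0/1) recover every label
  det <- cluster_model(c("A", "B"), sprintf("l%d", 1:4),
                       matrix(c(1, 1, 0, 0, 0, 0, 1, 1), nrow = 4))
  dsim <- simulate_aberrations(det, n_cases_per_cluster = 50, seed = 2)
  dcalls <- vapply(seq_len(nrow(dsim$states)), function(i) {
    assign_consensus_cluster(dsim$states[i, ], det)$cluster
  }, character(1))
  expect_identical(dcalls, dsim$truth)
})

test_that("confidence calls use a strict 0.9 threshold and are monotone", {
  model <- well_separated_model()
  mk <- function(p) {
    structure(list(posterior = c(A = p, B = 1 - p), cluster = "A",
                   max_posterior = p, uninformative = FALSE,
                   ambiguous = FALSE, n_observed_loci = 8L),
              class = "cluster_assignment")
  }
  expect_identical(confidence_call(mk(0.95)), "assigned")
  expect_identical(confidence_call(mk(0.9)), "unclassified")  # strict
  # raising the threshold never converts unclassified to assigned
  thresholds <- seq(0.5, 0.99, by = 0.07)
  for (p in c(0.55, 0.8, 0.93)) {
    calls <- vapply(thresholds, function(th) confidence_call(mk(p), th), "")
    assigned <- calls == "assigned"
    expect_true(all(diff(as.integer(assigned)) <= 0))
  }
})

test_that("cluster models validate, smooth and round-trip through JSON", {
  expect_error(cluster_model("A", "l1", matrix(0.5)), "clusters")
  expect_error(cluster_model(c("A", "B"), "l1", matrix(c(0.5, 1.2), 1)),
               "freq")
  expect_error(cluster_model(c("A", "B"), "l1", matrix(c(0.5, 0.5), 1),
                             priors = c(0.5, 0.6)), "priors")
  model <- well_separated_model()
  expect_true(all(model$freq_smoothed > 0 & model$freq_smoothed < 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(model, path)
  back <- read_cluster_model(path)
  expect_equal(back$freq, model$freq)
  expect_equal(back$priors, model$priors)
  expect_identical(back$clusters, model$clusters)
})

test_that("the Hans decision tree matches the enumerated truth table", {
  truth <- list(
    list(c(TRUE, FALSE, FALSE), "GCB"),
    list(c(TRUE, TRUE, FALSE), "GCB"),
    list(c(TRUE, FALSE, TRUE), "GCB"),
    list(c(TRUE, TRUE, TRUE), "GCB"),
    list(c(FALSE, FALSE, FALSE), "non_GCB"),
    list(c(FALSE, FALSE, TRUE), "non_GCB"),
    list(c(FALSE, TRUE, TRUE), "non_GCB"),
    list(c(FALSE, TRUE, FALSE), "GCB"))
  for (case in truth) {
    m <- case[[1]]
    expect_identical(hans_coo(m[1], m[2], m[3]), case[[2]])
  }
  expect_error(hans_coo(NA, TRUE, FALSE), "cd10")
})
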