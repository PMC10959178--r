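# Cohort layout mirroring the tested 18-case study: 13 autonomously
# signaling IgM BCRs; non-signaling = four class-switched cases plus one IgM
# case. Signaling cases get a strong autonomous response (a_aut = 0.6 *
# a_max, 80% responders); non-signaling cases have no autonomous responders.
paper_cohort_specs <- function(n_cells = 5000) {
  non_signaling <- data.frame(
    case_id = c("3882", "4391", "3567", "3850", "4328"),
    isotype = c("IgG1", "IgG2", "IgG2", "IgG4", "IgM"))
  specs <- lapply(sprintf("sig%02d", 1:13), function(id) {
    cohort_case(id, "IgM", TRUE,
                flux_sim_params(n_cells = n_cells, p_aut = 0.8, a_aut = 1.8,
                                a_max = 3))
  })
  for (i in seq_len(nrow(non_signaling))) {
    specs[[13 + i]] <- cohort_case(
      non_signaling$case_id[i], non_signaling$isotype[i], FALSE,
      flux_sim_params(n_cells = n_cells, p_aut = 0, a_aut = 1, a_max = 3))
  }
  specs
}

# strengths of k independent non-signaling control measurements
null_control_strengths <- function(seed, k = 3, n_cells = 5000,
                                   protocol = flux_protocol()) {
  vapply(seq_len(k), function(j) {
    sim <- simulate_flux_experiment(
      flux_sim_params(n_cells = n_cells, p_aut = 0, a_aut = 1, a_max = 3,
                      seed = as.integer((as.numeric(seed) * 7919 + j) %%
                                          2147483647)),
      protocol)
    gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())
    signaling_strength(gated, protocol)$strength
  }, numeric(1))
}

# number of cases called signaling in one seeded end-to-end run
signaling_count_one_run <- function(seed, n_cells = 5000,
                                    protocol = flux_protocol()) {
  cohort <- simulate_cohort(paper_cohort_specs(n_cells), protocol,
                            seed = seed)
  nulls <- null_control_strengths(seed, n_cells = n_cells,
                                  protocol = protocol)
  tab <- score_cohort(cohort, protocol, null_strengths = nulls)
  sum(tab$classification == "signaling")
}
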