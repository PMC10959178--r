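# handcrafted series with fully controlled SIR values (ch485 = 1)
make_sir_series <- function(time_s, sir_values) {
  flux_series(data.frame(time_s = time_s, ch405 = sir_values,
                         ch485 = rep(1, length(time_s)),
                         gfp = rep(1e4, length(time_s))))
}

test_that("baseline threshold is the declared order-statistic quantile", {
  proto <- flux_protocol()
  flat <- make_sir_series(seq(0.5, 89.5, length.out = 40), rep(2.5, 40))
  expect_equal(baseline_threshold(flat, proto), 2.5)

  # 1..100 uniformly: 95th percentile under linear interpolation
  s <- make_sir_series(seq(0.5, 89.5, length.out = 100), sample(1:100))
  expect_equal(baseline_threshold(s, proto), sort_quantile7(1:100, 0.95))
  expect_equal(baseline_threshold(s, proto), 95.05)

  few <- make_sir_series(seq(0.5, 89.5, length.out = 10), rep(1, 10))
  expect_error(baseline_threshold(few, proto), "baseline")
})

test_that("unresponsive fraction finds the peak crosslink bin", {
  proto <- flux_protocol()
  # two bins: first low, second high; unresponsive events sit in the peak bin
  t_xl <- c(seq(541, 559, length.out = 10), seq(561, 579, length.out = 10))
  s_xl <- c(rep(1, 10), c(rep(5, 8), rep(0.5, 2)))
  series <- make_sir_series(c(seq(1, 89, length.out = 30), t_xl),
                            c(rep(1, 30), s_xl))
  res <- unresponsive_fraction(series, proto, threshold = 1.5)
  expect_equal(unname(res$peak_bin["start"]), 560)
  expect_equal(res$u, 0.2)

  # everyone responds at crosslinking
  all_up <- make_sir_series(c(seq(1, 89, length.out = 30),
                              seq(541, 629, length.out = 30)),
                            c(rep(1, 30), rep(4, 30)))
  expect_equal(unresponsive_fraction(all_up, proto, threshold = 1.5)$u, 0)

  # nobody responds: u = 1 and the downstream correction refuses
  none <- make_sir_series(c(seq(1, 89, length.out = 30),
                            seq(91, 539, length.out = 30),
                            seq(541, 629, length.out = 30)), rep(1, 90))
  expect_equal(unresponsive_fraction(none, proto, threshold = 1.5)$u, 1)
  expect_error(q_aut(none, proto, threshold = 1.5, u = 1), "u >= 1")

  # generator ground truth: u_true recovered at the crosslink peak
  sim <- simulate_flux_experiment(
    flux_sim_params(n_cells = 8000, p_aut = 0.3, u_true = 0.2, seed = 31))
  gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())
  thr <- baseline_threshold(gated, proto)
  res <- unresponsive_fraction(gated, proto, thr)
  expect_lt(abs(res$u - 0.2), 3 * sqrt(0.2 * 0.8 / res$n_events) + 0.05)
})

test_that("responder fraction correction divides by 1 - u and caps at 1", {
  proto <- flux_protocol()
  # 20 autonomous events: 9 above threshold -> raw 0.45
  t_aut <- seq(100, 530, length.out = 20)
  series <- make_sir_series(
    c(seq(1, 89, length.out = 30), t_aut, seq(541, 629, length.out = 10)),
    c(rep(1, 30), rep(3, 9), rep(1, 11), rep(4, 10)))
  expect_equal(q_aut(series, proto, threshold = 2, u = 0), 0.45)
  expect_equal(q_aut(series, proto, threshold = 2, u = 0.1), 0.45 / 0.9)
  expect_equal(q_aut(series, proto, threshold = 2, u = 0.5), 0.9)
  expect_equal(q_aut(series, proto, threshold = 2, u = 0.6), 1)  # capped
  expect_equal(q_aut(series, proto, threshold = 10, u = 0.3), 0)
})

test_that("calibrated responder SIR is the ratio of medians", {
  proto <- flux_protocol()
  # responders at SIR 2, crosslink peak at SIR 4 -> ratio 0.5 exactly
  series <- make_sir_series(
    c(seq(1, 89, length.out = 30), seq(100, 530, length.out = 20),
      seq(541, 629, length.out = 10)),
    c(rep(1, 30), rep(2, 20), rep(4, 10)))
  expect_equal(cal_sir_aut(series, proto, threshold = 1.5), 0.5)
  # no above-threshold autonomous events: 0 by convention
  expect_equal(cal_sir_aut(series, proto, threshold = 5), 0)
  # identical autonomous and crosslink distributions: exactly 1
  same <- make_sir_series(
    c(seq(1, 89, length.out = 30), seq(100, 530, length.out = 20),
      seq(541, 629, length.out = 10)),
    c(rep(1, 30), rep(3, 20), rep(3, 10)))
  expect_equal(cal_sir_aut(same, proto, threshold = 2), 1)

  # noise-free generator with a_aut = a_max / 2 gives exactly 0.5
  sim <- simulate_flux_experiment(
    flux_sim_params(n_cells = 3000, p_aut = 1, u_true = 0, a_aut = 1.5,
                    a_max = 3, noise_cv = 0, transduced_fraction = 1,
                    seed = 5))
  thr <- baseline_threshold(sim$series, proto)
  expect_equal(cal_sir_aut(sim$series, proto, thr), 0.5)
})

test_that("full statistic matches the brute-force per-event oracle", {
  proto <- flux_protocol()
  for (seed in c(101, 202, 303)) {
    sim <- simulate_flux_experiment(
      flux_sim_params(n_cells = 500, p_aut = 0.5, u_true = 0.1, seed = seed))
    gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())
    res <- signaling_strength(gated, proto)
    oracle <- brute_force_strength(as.data.frame(gated))
    expect_equal(res$baseline_threshold, oracle$threshold,
                 tolerance = 1e-12)
    expect_equal(res$u, oracle$u, tolerance = 1e-12)
    expect_equal(res$q_aut, oracle$q_aut, tolerance = 1e-12)
    expect_equal(res$cal_sir_aut, oracle$cal_sir_aut, tolerance = 1e-12)
    expect_equal(res$strength, oracle$strength, tolerance = 1e-12)
    expect_equal(res$strength, res$q_aut * res$cal_sir_aut)  # exact identity
  }
})

test_that("the statistic is invariant to global rescaling of both channels", {
  proto <- flux_protocol()
  sim <- simulate_flux_experiment(
    flux_sim_params(n_cells = 1000, p_aut = 0.4, seed = 77))
  gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())
  scaled_df <- as.data.frame(gated)
  scaled_df$ch405 <- scaled_df$ch405 * 37.5
  scaled_df$ch485 <- scaled_df$ch485 * 37.5
  scaled <- flux_series(scaled_df)
  a <- signaling_strength(gated, proto)
  b <- signaling_strength(scaled, proto)
  for (f in c("baseline_threshold", "u", "q_aut", "cal_sir_aut", "strength")) {
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  }
})

test_that("expected strength increases with the responder fraction", {
  proto <- flux_protocol()
  mean_strength <- vapply(c(0.2, 0.5, 0.8), function(p) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_flux_experiment(
        flux_sim_params(n_cells = 2000, p_aut = p, a_aut = 2, a_max = 3,
                        seed = 1000L + round(1000 * p) + s))
      gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())
      signaling_strength(gated, proto)$strength
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_strength) > 0))
})

test_that("replicate averaging and threshold classification follow the rules", {
  expect_equal(average_replicates(list(0.4, 0.6))$mean_strength, 0.5)
  expect_equal(average_replicates(list(0.7))$mean_strength, 0.7)
  xs <- c(0.1, 0.25, 0.4, 0.55)
  expect_equal(average_replicates(as.list(xs))$mean_strength, sum(xs) / 4)
  expect_error(average_replicates(list()), "no replicate")

  expect_identical(as.character(classify_signaling(0.9, c(0.05, 0.1))),
                   "signaling")
  expect_identical(as.character(classify_signaling(0.1, c(0.05, 0.1))),
                   "non_signaling")  # tie with max null
  expect_identical(as.character(classify_signaling(0.02, c(0.05, 0.1))),
                   "non_signaling")
  expect_error(classify_signaling(0.5, numeric(0)), "control")
})

test_that("saturated and null samples bracket the statistic's range", {
  proto <- flux_protocol()
  sat <- simulate_flux_experiment(
    flux_sim_params(n_cells = 5000, p_aut = 1, u_true = 0, a_aut = 3,
                    a_max = 3, seed = 11))
  g <- gate_events(sat$series, gfp_min = sim_gfp_gate())
  s_sat <- signaling_strength(g, proto)
  expect_gt(s_sat$strength, 0.9)
  expect_lt(s_sat$strength, 1.05)
  expect_true(s_sat$q_aut >= 0 && s_sat$q_aut <= 1)

  null <- simulate_flux_experiment(
    flux_sim_params(n_cells = 5000, p_aut = 0, u_true = 0, seed = 12))
  g0 <- gate_events(null$series, gfp_min = sim_gfp_gate())
  s_null <- signaling_strength(g0, proto)
  expect_lt(s_null$strength, 0.05)
  expect_gte(s_null$strength, 0)
})
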