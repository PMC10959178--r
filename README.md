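# autobcr

Quantification of antigen-independent ("autonomous") B cell receptor (BCR)
signaling from flow-cytometry assays, as used to characterize diffuse large
B cell lymphoma (DLBCL).

Some lymphoma BCRs activate their own signaling cascade without antigen.
The functional test expresses a candidate BCR in reconstituted pre-B cells
carrying a 4-OHT-inducible SLP65 adaptor, loads them with the ratiometric
calcium dye Indo-1, and records the per-cell 405/485 signal intensity ratio
(SIR) over three phases: baseline (0–90 s), autonomous response after 4-OHT
(90–540 s), and maximal response after anti-Ig crosslinking (540–630 s).
`autobcr` scores such measurements with the statistic

```
strength = Q_aut x calSIR_aut
```

where `Q_aut` is the fraction of autonomous-window cells with SIR above the
95th percentile of baseline, corrected for totally unresponsive cells
(divided by `1 - u`, with `u` measured in the peak 20-s bin of the
crosslink response), and `calSIR_aut` is the median SIR of those responders
calibrated to the median SIR of the crosslink peak. A saturating BCR scores
~1, a silent one ~0. Replicate measurements are averaged, and a BCR is
called signaling when its mean strength exceeds the upper limit observed
for non-signaling control BCRs.

Around the core statistic the package provides:

- **cytometry I/O** — CSV event tables, a minimal FCS 3.0/3.1 reader with
  channel mapping and time-tick conversion, marker/viability gating with QC
  reports;
- **phospho-flow** — crosslink-normalized MFI of BCR-pathway phospho-targets
  and group comparisons;
- **functional readouts** — four-parameter logistic IC50 fitting for
  inhibitor viability plates; bead-calibrated doubling times from
  exponential growth series;
- **genomic classification** — pathogenicity-based variant filtering
  (SIFT/PolyPhen/clinical significance), naive-Bayes assignment of cases to
  DLBCL consensus clusters with a strict 0.9 confidence call, Hans
  CD10/BCL6/MUM1 cell-of-origin calls;
- **cohort statistics** — Fisher exact tests, signed-rank/rank-sum tests,
  IGHV germline homology summaries, cohort reports;
- **synthetic data** — seeded generators for every input above with
  ground-truth labels, so the full pipeline is testable end to end.

## Worked example

Simulate a strongly autonomously signaling case (80% responders at 60% of
the crosslink amplitude), gate it on GFP, and score it:

```r
library(autobcr)

protocol <- flux_protocol()        # 90/540/630 s windows, 20-s bins, q95
params <- flux_sim_params(n_cells = 5000, p_aut = 0.8, a_aut = 1.8,
                          a_max = 3, seed = 42)
sim <- simulate_flux_experiment(params, protocol, sample_id = "case3267")
gated <- gate_events(sim$series, gfp_min = sim_gfp_gate())

signaling_strength(gated, protocol)
#> <signaling_result> 'case3267' rep 1: strength 0.4577 (Q_aut 0.7451 x calSIR_aut 0.6143), u 0.048, threshold 1.3947
```

74.5% of autonomous-window cells exceeded the baseline threshold (SIR
1.39) after correcting for the 4.8% of cells that ignored even
crosslinking, and those responders reached 61% of the maximal crosslink
SIR — a strength of 0.46, far above a typical non-signaling floor of ~0.02.
Classified against non-signaling controls:

```r
classify_signaling(0.4577, c(0.021, 0.018, 0.026))
#> [1] "signaling"
```

Cohort-level association of signaling with the IgM isotype (18 cases, 13
signaling, all IgM; four IgG cases, all non-signaling):

```r
tab <- matrix(c(13, 1, 0, 4), nrow = 2, byrow = TRUE,
              dimnames = list(signaling = c("yes", "no"),
                              isotype = c("IgM", "IgG")))
fisher_exact(tab)$p_value
#> [1] 0.001633987
```

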