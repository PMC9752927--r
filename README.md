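# pligraph

Functional brain-network analysis of interictal resting-state scalp EEG,
built around the phase lag index (PLI). The package targets the question a
clinical EEG network study asks: does frontotemporal phase coupling —
especially in the theta band (4–7 Hz) — track seizure severity in temporal
lobe epilepsy, when measured non-invasively on the 25-channel IFCN montage?

For two channels with instantaneous phase difference Δφ (Hilbert phases of
the band-filtered signal),

```
PLI = | < sign(Δφ) > |
```

the absolute time-average of the sign of the wrapped phase difference.
PLI is 0 for symmetric phase differences — including exactly zero lag, so
volume-conducted common activity is discounted — and 1 for a fixed nonzero
lag. Electrodes are network nodes, PLI values edge weights, and 1/PLI edge
distances. From there the package computes:

* **weighted network metrics** — mean PLI, weighted clustering coefficient
  (CC, local segregation), characteristic path length (PL, global
  integration), for the whole 25-node network and the 16-electrode
  frontotemporal subnetwork;
* **minimum spanning tree metrics** (Kruskal on 1/PLI distances) —
  diameter, leaf number/fraction, betweenness centrality, tree hierarchy
  TH = LN/(2·m·BC_max), kappa = ⟨k²⟩/⟨k⟩;
* **community structure** — weighted Newman modularity Q (exact
  enumeration ≤ 8 nodes, multi-start Louvain above), participation
  coefficient P_i = 1 − Σ_s(κ_is/k_i)²;
* **spectral indices** — Welch PSD, mean frequency, frontal laterality
  index (P_left − P_right)/(P_left + P_right);
* **cohort statistics** — ANOVA with Tukey post-hoc, Spearman severity
  correlations, SPSS-style stepwise regression with standardized βs;
* **a seeded synthetic cohort generator** — coupled band-limited
  oscillators with controllable region pair, band, phase lag and
  severity-linked coupling strength, emulating a TLE/control study design
  for end-to-end validation.

## Worked example

```r
library(pligraph)

# a 90-s recording with left frontotemporal theta coupling at lag pi/4
cp  <- sim_coupling(ft_a <- c("Fp1","F3","F7","F9"), c("T7","T9","P7","P9"),
                    band = "theta", phase_lag = pi/4, strength = 0.8)
rec <- simulate_recording(90, 500, couplings = list(cp), seed = 42,
                          subject_id = "demo")

res <- run_subject(rec, default_config())
subset(res$network, band == "theta")
#>   subject_id  band       node_set  mean_pli        cc       pl
#> 3       demo theta          whole 0.3750821 0.3245926 2.466619
#> 4       demo theta frontotemporal 0.4787132 0.4133458 2.070181
subset(res$mst, band == "theta" & node_set == "frontotemporal",
       select = c(band, diameter, leaf_fraction, tree_hierarchy, kappa))
#>    band diameter leaf_fraction tree_hierarchy    kappa
#> 4 theta        5         0.625       0.472973 2.933333
```

The frontotemporal theta mean PLI (0.479) exceeds the whole-network value
(0.375): the 16 cross pairs between the coupled frontal and temporal sets
carry the planted constant-lag oscillation at PLI ≈ 1, while uncoupled
pairs sit near the finite-sample chance level (≈ 0.05). The coupled
subnetwork's MST is correspondingly compact and leafy (diameter 5 of a
possible 15, leaf fraction 0.625).

At cohort scale, `simulate_cohort()` draws log-normal severity scores
(median 40, IQR 182), ties each patient's frontotemporal theta coupling
strength linearly to severity, and `run_cohort()` recovers the link: the
group contrast, a positive Spearman correlation of frontotemporal theta
PLI with severity, selection of that term by the stepwise model, and the
expected metric directions (CC up, PL down, MST diameter down with
severity) are all checked in `tests/testthat/test-acceptance.R`.

## Documentation

The methods vignette (`vignettes/pli-network-analysis.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, the numerical choices (filter design, phase trimming, tie
breaking, distance caps), what the synthetic generator does and does not
emulate, and known limitations.
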