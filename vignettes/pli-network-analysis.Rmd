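---
title: "Phase-lag-index brain networks from interictal scalp EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index brain networks from interictal scalp EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pligraph)
```

## The problem

Temporal lobe epilepsy reorganizes large-scale brain networks even between
seizures. Resting scalp EEG on the 25-channel IFCN montage (the 10–20
system plus the inferior temporal chain F9/F10, T9/T10, P9/P10) samples
frontotemporal cortex well enough to quantify that reorganization
non-invasively. `pligraph` implements the full analysis chain: phase lag
index (PLI) connectivity per frequency band, weighted-network and
minimum-spanning-tree (MST) summaries, community structure, spectral
indices, and a cohort-level statistical stage relating frontotemporal
theta-band coupling to seizure severity. A seeded synthetic cohort
generator provides ground-truth data for validating every stage.

## Preprocessing

Recordings (channels × samples, µV, 500 Hz by default) are re-referenced
to the common average, which removes the recording reference and
common-mode activity; at every sample the montage mean is zero afterwards.

Filtering uses windowed-sinc (Hamming) linear-phase FIR filters. The
transition width is `max(1, 0.25 · f_lo)` Hz and the tap count follows the
Hamming rule `3.3 · fs / transition`, giving ≈ 53 dB of stop-band
attenuation one transition width beyond the band edges. Filters are
applied as a single delay-compensated pass (FFT convolution with the group
delay removed, odd-reflection padding at the ends), so the net phase shift
is zero — essential, since PLI is a pure phase statistic and any filter
delay would bias it.

The broadband filter (0.1–45 Hz) is applied first, then each analysis
band: delta 1–4, theta 4–7, alpha 8–13, beta 14–30, gamma 30–45 Hz, plus a
full 1–45 Hz band in the pipeline. The printed band edges do not partition
the spectrum (7→8 Hz gap, shared 4 Hz edge); adjacent filters simply
overlap through their transition bands.

**Filter-then-epoch.** Band filtering is applied to the continuous
recording *before* cutting epochs. For a linear time-invariant filter the
two orders are equivalent away from boundaries, but filtering 10-s epochs
individually would place a transient longer than the 0.5-s phase trim at
both ends of every epoch; filtering first confines transients to the
recording boundaries.

The default epoch scheme cuts the first 90 s into nine 10-s epochs.
Functional connectivity stabilizes for continuous epochs longer than about
10 s, and 90 s of artifact-free eyes-closed EEG is a realistic clinical
yield; a single 90-s epoch is one configuration switch away
(`default_config(epoch_length_s = 90)`). Artifact handling is deliberately
out of scope: `remove_components()` accepts an externally supplied
unmixing (e.g. from a manually curated ICA) and zeroes chosen components,
but the package performs no automatic artifact detection.

## Phase lag index

Instantaneous phases come from the analytic signal (frequency-domain
Hilbert method) of each band-filtered epoch. The first and last 0.5 s of
each epoch are discarded to remove edge effects of the transform. No taper
is applied before the analytic transform: tapering distorts phase near the
epoch edges, which is precisely where the trim already operates, and
amplitude weighting is irrelevant to a sign statistic. (The Hann taper is
used where it belongs, in the Welch spectral estimator.)

For channels *i*, *j*,

PLI = | ⟨ sign(Δφ) ⟩ |,

the absolute time-average of the sign of the phase difference, with Δφ
wrapped to (−π, π] before the sign — the sign of an unwrapped difference
is meaningless. Two conventions are fixed deliberately:

* `sign(0) = 0` exactly (the mathematical convention; some implementations
  map 0 → +1, which inflates PLI for identical channels);
* zero lag ⇒ PLI = 0, which is the point of the statistic: coupling that
  is instantaneous on the scalp (volume conduction, a shared reference)
  produces symmetric phase differences around zero and is discounted.

Per-epoch matrices are averaged element-wise; averaging preserves symmetry
and the [0, 1] range. The estimator is validated against a literal
sign-mean double loop at 1e−12 on random phase matrices.

## Weighted network metrics

Electrodes are nodes, PLI values edge weights, and 1/PLI the edge
distance, so stronger coupling means shorter distance. Zero-PLI pairs are
capped at distance 1/ε with ε = 1e−6; the cap keeps the graph formally
connected while guaranteeing such edges never win a shortest path. Metrics
are computed for the whole 25-node network and the 16-electrode
frontotemporal subnetwork (Fp1, Fp2, F3, F4, F9, F10, T9, T10, P9, P10,
F7, F8, T7, T8, P7, P8).

* **Mean PLI** — upper-triangle average of the weights.
* **Clustering coefficient (CC)** — Onnela geometric-mean triangle
  formula, node-averaged; local segregation.
* **Characteristic path length (PL)** — mean shortest-path distance
  (Dijkstra) over all pairs; global integration, lower = more integrated.

**CC normalization.** The classical Onnela formula rescales weights by the
graph's maximum weight. For PLI networks that choice is actively harmful:
as a subset of edges strengthens, the rising maximum *deflates* every
normalized triangle, so CC would decrease with increasing coupling —
the opposite of the expected and empirically observed direction. Since PLI
is already bounded in [0, 1], the natural ceiling is 1, and that is the
default (`normalization = "unit"`); the graph-max variant remains
available (`"max"`) for comparison with literature using it. Under the
unit ceiling a homogeneous complete graph with weight *w* has CC = *w*,
and CC increases monotonically with simulated coupling strength (verified
by test).

## Minimum spanning tree

Kruskal's algorithm on the 1/PLI distances extracts the acyclic backbone
without any threshold choice. Ties are broken by sorting edges on
(distance, lexicographic label pair), so trees are reproducible across
runs and platforms. Summaries:

* **Diameter (D)** — largest hop distance in the tree (the dominant
  convention; a summed-distance variant would follow immediately from the
  stored edge distances, and the normalized D/(n−1) is also emitted).
* **Leaf number / fraction (LN, LF)** — degree-1 nodes, and LN/n.
* **Betweenness centrality (BC)** — on a tree each pair has exactly one
  path, so BC(v) counts pairs whose path crosses v; computed by the
  component-split identity and normalized by (n−1)(n−2)/2 so the maximum
  attainable value (a star centre) is 1. Raw counts are also returned.
* **Tree hierarchy (TH)** — LN / (2·m·BC_max) with m = n−1 edges and
  normalized BC_max. With this normalization TH(star) = 0.5 exactly for
  every size, the reference value of the MST-EEG literature, and TH(path)
  → 0 as the path grows.
* **Kappa** — ⟨k²⟩/⟨k⟩ of the tree degrees, the standard broadness measure
  of the degree distribution (no formula is fixed by convention elsewhere;
  this is the usual MST-EEG choice and is isolated in `degree_kappa()` so
  an alternative is a one-line swap).

A more star-like tree (higher LF and kappa, smaller D) reflects a more
integrated network backbone.

## Community structure

Weighted Newman modularity

Q = 1/(2M) Σᵢⱼ (aᵢⱼ − kᵢkⱼ/2M) δ(Cᵢ, Cⱼ)

with aᵢⱼ the PLI weight, kᵢ the node strength, 2M twice the total edge
weight, and δ = 1 for nodes sharing a module — the standard convention,
under which Q = 0 for the trivial one-module partition and larger Q means
a clearer division. (Printed statements of this formula sometimes invert
the δ convention or conflate M with the node count; only the standard
reading is consistent with "larger Q = clearer structure", so that is what
is implemented.)

Partitions are found exactly for networks of ≤ 8 nodes by enumerating all
set partitions (Bell(8) = 4140) and by multi-start Louvain (20 seeded
restarts, best Q kept) above that; detection is deterministic given the
seed. The participation coefficient

Pᵢ = 1 − Σₛ (κᵢₛ/kᵢ)²

(κᵢₛ = weight from node i into module s) is 0 for purely intra-modular
nodes and approaches 1 − 1/N_M for weight spread evenly over N_M modules;
isolated nodes yield NA with a warning.

## Spectral indices

Welch PSD: 2-s segments, 50% overlap, Hann taper, window-power corrected,
interpolated onto a 1-Hz grid from 1 to 45 Hz. The grid stops at the
45-Hz filter edge — evaluating a wider range would only sum zeros of the
filtered signal, so the honest range is reported. From the PSD:

* **Mean frequency** — the spectral centroid Σ P(f)·f / Σ P(f).
* **Laterality index** — LI = (P_left − P_right)/(P_left + P_right) over
  the frontal triples Fp1/F3/F7 and Fp2/F4/F8; LI ∈ [−1, 1], 0 for
  symmetric power, negated by a left-right swap. It is emitted broadband
  *and* per band, since a frontal asymmetry can be band-specific and the
  broadband value alone would hide that.

## The synthetic cohort generator

The generator is a first-class, tested module, and its defaults define the
validation conditions. Each channel carries band-limited Gaussian
components (white noise band-passed at the component band — *not* pure
sinusoids, which would make PLI trivially 1) plus 1/f noise, all scaled so
channel variance equals the sum of squared component amplitudes. The
default background is a 10-Hz alpha component (amplitude 1) over 1/f noise
(amplitude 1).

Coupling injects a shared band-limited oscillator into two electrode sets;
the second set's copy is delayed by τ = lag/(2π·f_center) via an exact
FFT fractional delay, so the sets hold a constant phase lag (instantaneous
lag jitters slightly with instantaneous frequency across the band).
`strength` is the fraction of channel variance contributed by the shared
oscillator. Two consequences worth stating plainly:

* within a coupled set, channels share the oscillator at **zero** lag, so
  within-set PLI stays near 0 — by design, this mimics volume-conducted
  common activity that PLI should discount;
* only cross-set pairs acquire high PLI, so a unilateral frontotemporal
  coupling raises the mean over the 16-node frontotemporal network only
  partially (16 of 120 pairs), as in real focal disease.

Cohorts: patient severity scores are log-normal with meanlog = log(40),
sdlog = 2.31, which reproduces a median of 40 and an interquartile range
of 182 — a deliberately heavy right tail. Coupling strength is linear in
severity (`0.15 + 0.002·severity + N(0, 0.03)`, clamped to [0.02, 0.92]),
patients split into left / right / bilateral subgroups at 56/55/40
weights, and controls receive a bilateral occipito-parietal alpha coupling
(strength 0.4) emulating the posterior-dominant resting rhythm. Seizure
frequency class and drug-resistance are deterministic functions of
severity (cut points 20/60/365 and > 365); histories are independent
Bernoulli draws. Everything flows from one root seed; identical specs are
byte-identical.

What the generator does **not** emulate: artifacts, interictal spikes,
true volume-conduction forward models, nonstationarity, and spatially
correlated background. Passing the recovery tests therefore demonstrates
that the pipeline measures what the generator plants — not that real TLE
cohorts will show effects of the same size.

**Chance-level PLI is not zero at finite duration.** Band-filtered noise
phases decorrelate over roughly 1/bandwidth seconds, so a 60-s theta-band
epoch yields only a few hundred effective sign samples; the null mean PLI
across pairs sits near 0.05 and the null *maximum* over the 300 montage
pairs near 0.2. Tests and users should compare against these finite-sample
levels, not against zero.

## Cohort statistics

* Group comparisons: one-way ANOVA with Tukey HSD post-hoc.
* Severity correlations: Spearman rank correlation (tie-corrected,
  asymptotic p) among subjects with a severity score.
* Stepwise multiple linear regression of the severity score on network and
  clinical candidates: forward entry at p < 0.05 with backward removal at
  p > 0.10 — the classical SPSS-style defaults, the most plausible
  convention where none is stated. Response and predictors are z-scored,
  so coefficients are standardized βs (severity scales span orders of
  magnitude). Complete cases per model; exact duplicates and zero-variance
  candidates are excluded by rank check with a warning. No multiplicity
  correction is applied to the metric-wise tests by default, matching
  common practice of reporting raw p values; `p.adjust` can be applied to
  the returned tables by the user.

## Validation design and problem sizes

Every estimator is tested against an independent oracle: literal
double-loop sign means for PLI (100 random phase matrices at 1e−12);
triangle enumeration for CC; Floyd–Warshall for PL; exhaustive
Prüfer-sequence enumeration of all spanning trees (n ≤ 7, 50 random
graphs) for MST minimality; brute-force path walks on 50 random trees for
D/LN/BC; Bell-number partition enumeration plus igraph's modularity for
community detection (n ≤ 8); and 1000-replicate calibration simulations
for the statistical stage. The end-to-end study simulates 60 patients and
20 controls at 90 s / 500 Hz (the full acquisition conditions) and checks
direction and rank-correlation recovery of the planted severity link; it
completes in minutes on one core.

## Known limitations

* EDF reading/writing is not included; recordings enter as numeric
  matrices or the package's TSV + JSON sidecar format.
* PLI discards zero-lag coupling by construction; genuinely instantaneous
  cortical coupling is invisible to the whole pipeline.
* The weighted CC and kappa formulas are conventions, not identities;
  alternatives are isolated behind single functions.
* Stepwise selection inherits the known liabilities of stepwise methods
  (selection bias, unstable term sets near the threshold); it is provided
  as the field-standard reproduction, not an endorsement.
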