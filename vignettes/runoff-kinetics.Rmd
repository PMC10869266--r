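---
title: "Polysome runoff kinetics: models, simulator and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polysome runoff kinetics: models, simulator and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riborunoff)
```

## The assay and the model

Timed ribosome runoff measures how fast ribosomes elongate, without
transcript-level information. Cells are treated with harringtonine (HRN),
which immobilises initiating ribosomes at start codons while elongating
ribosomes continue to the stop codon and dissociate; after `t` minutes
cycloheximide freezes everything and a sucrose-gradient polysome profile is
recorded as UV absorbance at 254 nm. As runoff proceeds, the polysome peaks
(mRNAs carrying two or more ribosomes) decay and the monosome (80S) peak
grows. The area under the polysome region of the profile approximates the
number of polysomal ribosomes, so the fold change of that area relative to
the cycloheximide-only control (`t = 0`) is a per-time-point readout of how
many ribosomes are still elongating.

`riborunoff` fits this decline with an exponential decay with plateau,

$$P(t) = C + (1 - C)\,e^{-k_P t},$$

by least squares. The rate constant $k_P$ (per minute) is the ribosome-speed
proxy, and the plateau $C \in [0, 1]$ is the fraction of the initial
polysomal signal that never runs off — translationally inactive ribosomes.
The intercept is pinned at 1 because the series is constructed as fold
change against its own `t = 0` control; a 3-parameter variant with a free
intercept is available (`constrain_t0 = FALSE`) since either convention is
defensible for noisy data. The monosome rise is fitted with the mirrored
form $M(t) = M_\infty - (M_\infty - 1)e^{-kt}$, $M_\infty \ge 1$.

The complementary puromycin (PMY) readout — decay of nascent-chain
labelling during runoff — is a declining normalised signal of the same
shape and is fitted with the same routine (`kind = "pmy_decline"`); input
signals are expected pre-normalised per lane, as blot quantification
conventions vary.

### Numerical strategy and its limits

For fixed $k$ the model is linear in the plateau, so the fit profiles $C$
out in closed form (clipped to its bounds) and minimises over $k$ alone on a
dense log-spaced grid ($160$ points over $[10^{-4}, 20]$ per minute plus
$k = 0$) refined by golden-section search. The objective is non-convex in
$k$; the test suite verifies the optimum against an exhaustive
two-dimensional grid search at $10^{-3}$ resolution. Noiseless model points
are recovered to better than $10^{-6}$, and a constant series returns
`k = 0` with a degeneracy flag rather than an error.

One identifiability caveat is worth stating explicitly. With the standard
sampling grid `t = 0, 1, 5, 10` min and measurement noise of a few percent,
rates around $k \approx 0.1$/min are poorly determined whenever the plateau
is also free: by 10 minutes such a curve has completed only ~63 % of its
decay, and $k$ and $C$ trade off along a ridge. Monte-Carlo recovery at
$k = 0.1$, $C = 0.25\text{–}0.5$, $\sigma = 0.02$ shows median relative
errors of 25–45 % in $\hat k$ for the *exact global* least-squares optimum
(verified by grid search), so this is a property of the design, not of the
optimiser. Slow-decay experiments need later time points (the 20 min
control point helps considerably). At $k \ge 0.3$/min median errors are
well under 10 %.

## Profile quantification

Quantification follows the manual procedure the assay community uses, made
reproducible:

* **Baseline.** Default `linear_endpoints`: a straight line through the
  mean of the first and last 2 % of samples — the simplest defensible model
  for a UV trace whose ends are signal-free. `rolling_minimum` (a
  morphological opening: rolling minimum, then rolling maximum, then a
  rolling mean; window default 25 mm, which must exceed the widest peak
  structure) is offered for non-linearly drifting baselines. After
  subtraction, residual negative values are clipped to zero so corrected
  traces are non-negative. Note that clipping rectifies zero-mean noise
  into a small positive area bias ($\approx \sigma \cdot
  \mathrm{span}/\sqrt{2\pi}$); the integration oracle in the tests is
  therefore run on noiseless mixtures, while noisy inputs are covered by
  the end-to-end simulator checks at a 3 % band.
* **Peaks.** Within each user-supplied search window the local maximum of
  greatest prominence is taken and its centre refined by a 3-point
  parabolic fit, giving sub-sample accuracy (verified to half a sampling
  step on planted peaks). Only the 80S peak is required by default;
  subunit or disome windows that contain no peak are dropped silently
  because those species are absent in many conditions.
* **Segmentation.** The polysome region starts a constant offset
  downstream of the 80S peak centre — 8.9 mm by default, matching the
  fixed monosome-to-polysome distance used for this fractionator geometry.
  The offset is configurable because other instruments differ; we
  interpret the distance as peak-centre-to-region-start. The monosome
  region runs from the 80S window start to that boundary; everything
  lighter is the subunit region; everything past `gradient_end` (pellet)
  is excluded.
* **Integration.** Plain trapezoids on the raw sampling grid, no
  smoothing — any smoothing would trade a visible error bound for a
  method-dependent bias. Region AUCs are additive to the total AUC to
  1e-9, and `P/M = polysome AUC / monosome AUC`. A zero monosome AUC
  yields `NaN` with a warning instead of an error so batch runs survive
  degenerate inputs.

`rnase_units()` implements the calibrated dosing rule for converting
polysomes to monosomes by RNase1 digestion: 0.19 U per microlitre of lysate
per A260 unit.

## The mechanistic simulator

`sim_config()` / `simulate_timecourse()` generate ground-truth data for
every pipeline stage. The design goal is the smallest mechanistic model
that reproduces the assay's observables, not a full elongation simulator:

* mRNA coding lengths are lognormal (default mean ≈ 500 codons, typical of
  mammalian coding sequences); each mRNA carries Poisson(L/spacing)
  ribosomes placed uniformly subject to a hard exclusion footprint
  (10 codons). Placement uses the exact order-statistics construction
  (sorted uniforms on the footprint-reduced interval plus cumulative
  offsets), which samples the uniform-with-exclusion distribution directly.
* Runoff is a deterministic transit-time model: a ribosome at codon `x` on
  an active mRNA of length `L` terminates iff `(L - x)/v <= 60 t`; the
  rest advance by `60 t v`. There is no per-codon stochasticity — the
  ensemble decay shape comes from the length and position distributions,
  which is what the profile-level readout can see. Sequential application
  composes additively in `t`, and ribosome counts are conserved exactly
  (an integer invariant the tests check through every treatment chain).
* A fraction `f_inactive` of loaded mRNAs is frozen as inactive granules:
  runoff and puromycin leave them untouched, EDTA dissociates them, RNase1
  destroys them without producing protected monosomes. Because the assay
  cannot distinguish stalled from vacant dormant ribosomes, the simulator
  exposes only this single fraction.
* Harringtonine leaves one immobilised 80S at each active mRNA's start
  codon (drawn from the free 80S pool, which defaults to 40 % of the
  loaded count), so the post-runoff monosome peak contains both released
  and newly stalled ribosomes.
* In-silico treatments mirror their biochemistry: EDTA converts every 80S
  equivalent to two subunits; PMY releases elongating ribosomes only;
  RNase1 converts each active n-some to n monosomes with an over-digestion
  law `p_over(u) = 1 - exp(-lambda * max(0, u - u_opt))`
  (`lambda = 0.5/u_opt`), the simplest monotone dose-response that
  reproduces the observed decline of monosome yield past the optimal dose;
  NMDA recruits additional active mRNAs into granules (`nmda_delta_f`),
  a no-op for the immature-neuron preset.
* Trace synthesis places one Gaussian per species with geometrically
  compressing centres (`mu_n = mu_1 + d_1 (1 - r^{n-1})/(1 - r)`, standard
  gradient: `mu_1 = 20` mm, `d_1 = 11` mm, `r = 0.6`, so the default
  8.9 mm offset separates the disome cleanly from the 80S peak), amplitude
  proportional to RNA content (`n + 1` mRNA-equivalents per n-some, 0.5
  per subunit), granules at the same heavy-region positions (the
  deoxycholate-treated lysate brings them into the gradient), plus a
  linear baseline and Gaussian noise.

Cell-type presets (`hek`, `hnsc`, `rcn_immature`, `rcn_mature`,
`rcn_mature_nmda`) span the regimes the assay distinguishes — fast/low-
inactive, slow stem-cell-like, and fast-but-high-inactive mature neurons.
The speeds (1–3 codons/s) are chosen so the decline resolves on the
0–20 min grid, and the inactive fractions (0.02–0.35, +0.15 under NMDA)
are illustrative: the assay's own estimate of that quantity is the fitted
plateau, and no published per-cell-type values exist to copy. The default
time grid `0, 1, 5, 10, 20` min is the full experimental design including
the completeness-control point, which is also what pins the plateau
numerically.

What the simulator does *not* emulate — and what passing tests therefore do
not establish for real data: codon-specific dwell times and tRNA limitation,
re-initiation, elongating monosomes, detector drift beyond a linear
baseline, peak-shape asymmetries, and fractionator-to-fractionator geometry
differences (the mm positions are one instrument's convention).

With 10,000 mRNAs the full loop (simulate → synthesise traces → quantify →
build series → fit) recovers the configured inactive fraction to better
than ±0.05 at `f_inactive` of 0–0.4; the residual underestimate of the
plateau (~0.03) comes from the early-time flattening that the stalled
start-codon 80S adds to the polysome signal, which the pure exponential
absorbs by lowering `C` slightly.

## Fraction-resolved proteomics

The proteomics module re-implements the fraction-shift analysis applied to
monosome/polysome iBAQ matrices under CHX vs HRN:

* **Normalisation** (`vsn_normalize`): per-sample scale calibration by the
  median ratio to a per-protein geometric reference, then a generalised-log
  transform `glog2(x, c) = log2((x + sqrt(x^2 + c^2))/2)`. The offset `c`
  is estimated from the error model `Var = s_add^2 + (sigma_m * mean)^2`
  by regressing per-protein within-condition variances on squared means
  over mean-deciles (decile medians, so the heavy-tailed variance
  distribution cannot dominate); `c = s_add/sigma_m` is exactly the offset
  that makes the transform's derivative proportional to `1/sd`. Data with
  no additive floor yield `c ≈ 0`, i.e. a plain log — important, because a
  forced offset would *create* heteroscedasticity.
* **Imputation** (`impute_mixed`): a protein missing in *all* replicates of
  at least one condition is classed MNAR (left-censored) and its holes are
  set to the minimum of the transformed scale; all other holes are MAR and
  filled by k-nearest-neighbour averaging over proteins (k = 10, Euclidean
  on co-observed entries, ties broken by protein order) — deterministic,
  and the MNAR rule is the simplest condition-wise classifier consistent
  with the "mixed" strategy.
* **Testing** (`moderated_test`): empirical-Bayes moderated t. The prior
  `(d0, s0^2)` is estimated in closed form by matching the mean and
  variance of `log s_g^2` under the scaled-F model
  (`Var(log s^2) = trigamma(d_g/2) + trigamma(d0/2)`, inverted with a
  Newton solver for the trigamma inverse); the posterior variance is the
  usual precision-weighted blend and the statistic has `d0 + d_g` degrees
  of freedom. `d0 = 0` reproduces the classic equal-variance t exactly and
  `d0 = Inf` the fully pooled z — both asserted in the tests, along with
  agreement with the installed reference empirical-Bayes implementation on
  shared input.
* **Rejections and shift classes**: `significant ⇔ adj_p < 0.05` and
  `|log2FC| > log2(1.5)`. Adjustment defaults to Benjamini–Hochberg; a
  Storey-type q-value mode (`adjust = "qvalue"`, BH scaled by
  `pi0 = min(1, 2 mean(p > 0.5))`) is exposed because FDR-adjustment
  flavours differ between toolchains and the choice moves borderline set
  counts. The three reported sets are: proteins enriched in CHX polysomes
  vs CHX monosomes; the subset of those that drop in HRN polysomes
  (shifted to monosomes on runoff); and proteins elevated in HRN polysomes
  (retained on the inactive complexes).

The iBAQ simulator plants these effects directly (log-normal baselines,
multiplicative plus additive noise, threshold-censored MNAR and random MAR
missingness) and provides the ground truth for the calibration (uniform
null p-values, ≤ 7 % false positives at the stated thresholds) and power
(≥ 90 % recovery of 2-log2 effects at n = 3) checks. The published
protein-set counts from the original study's deposited tables are not
recomputable without that external download; the pipeline accepts any
proteinGroups-style wide TSV plus design CSV via `read_abundance_table()`.

## Problem sizes and reproducibility

The test suite and the acceptance script run the studies at: 10,000 mRNAs
for end-to-end plateau recovery and the closed-form runoff check; 2,000
mRNAs × 100 seeds for the preset P/M comparison; 200 Monte-Carlo replicates
per (k, C) grid point for noisy recovery; 100 Gaussian-mixture fixtures for
the integration oracle; 500–1,000 random chains for conservation; 2,000
proteins for the null calibration and 200 × 100 seeds for power. These
sizes give stable ensemble statistics while keeping a full run in tens of
seconds. Every stochastic step is seeded; `run_pipeline()` reruns are
byte-identical.

## Known limitations

* $k_P$ is a profile-level proxy: converting it to codons/s needs the
  transcript length distribution, which polysome profiling does not give.
* The plateau conflates everything that does not run off (granules, very
  slow ribosomes, incompletely dissolved aggregates).
* Replicate means are fitted (matching mean ± SEM presentation);
  per-replicate fits are available but no profile-likelihood intervals.
* The knn imputer is O(proteins² · samples) per missing row; fine for
  thousands of proteins, not for much larger matrices.
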