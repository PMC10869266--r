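# riborunoff

Quantitative analysis of **timed ribosome runoff** experiments: polysome
profile quantification, exponential runoff-decay kinetics, a mechanistic
runoff simulator, and a fraction-resolved proteomics differential-abundance
pipeline.

## The problem

How fast do ribosomes elongate in a given cell type, and how many of its
ribosomes are translationally inactive? Timed runoff answers both with
nothing more than polysome profiles: harringtonine (HRN) immobilises
initiating ribosomes at start codons while elongating ribosomes run off
their mRNAs; freezing the cells with cycloheximide (CHX) after t minutes and
recording the sucrose-gradient A254 profile shows polysome peaks decaying
and the monosome (80S) peak growing. The polysome-region area, as a proxy
for polysomal ribosome number, declines as

**P(t) = C + (1 − C)·e^(−k_P·t)**

where **k_P** (per minute) tracks ribosome speed and the plateau **C** is
the fraction of polysomal signal that never runs off — translationally
inactive ribosomes, a hallmark of neurons. The package is written for
groups running such experiments (polysome profiling ± HRN/EDTA/puromycin/
RNase1/NMDA treatments) and for anyone who wants a fully simulated,
ground-truthed version of the assay.

It provides, as tidyverse-style functions over tibbles:

* **Trace I/O** — `read_trace()` / `write_trace()` for two-column
  position-vs-A254 text files with `# key: value` metadata headers, plus
  sample sheets.
* **Quantification** — `correct_baseline()`, `detect_peaks()`,
  `segment_regions()` (polysome region starts a fixed 8.9 mm past the 80S
  peak centre, configurable), `integrate_regions()`, `quantify_trace()`;
  fold changes, P/M ratios, disome/80S ratios, RNase1 dosing
  (`rnase_units()`, 0.19 U/µl·A260).
* **Kinetics** — `build_series()`, `fit_decay()`, `fit_rise()`,
  `compare_conditions()`; fits are S3 objects with `tidy()`, `glance()`,
  `predict()` and `autoplot()` methods.
* **Simulator** — `sim_config()`/`sim_preset()`, `init_steady_state()`,
  `apply_runoff()`, `apply_treatment()` (EDTA, PMY, RNase1, NMDA),
  `census()`, `synthesize_trace()`, `simulate_timecourse()`,
  `simulate_proteomics()`: a mechanistic mRNA/ribosome population model
  with an inactive-granule fraction, providing exact ground truth for
  every pipeline stage.
* **Proteomics** — `vsn_normalize()`, `impute_mixed()` (knn for MAR,
  scale-minimum for MNAR), `moderated_test()` (empirical-Bayes variance
  shrinkage), `apply_rejections()` (alpha = 0.05, |log2FC| > log2 1.5),
  `classify_fraction_shifts()`, `analyze_fraction_shifts()`.
* **Orchestration** — `run_pipeline()` runs simulate → quantify → fit and
  writes a versioned, byte-reproducible artifact directory from a YAML or
  list config.

## Worked example

Simulate a mature-neuron-like runoff time course (fast ribosomes, 35 %
inactive granules), quantify the traces, and fit the decay:

```r
library(riborunoff)

cfg    <- sim_preset("rcn_mature", n_mrnas = 5000, seed = 42)
sim    <- simulate_timecourse(cfg)            # t = 0, 1, 5, 10, 20 min
quant  <- quantify_traces(sim$traces)
quant[, c("runoff_time_min", "monosome_auc", "polysome_auc", "pm_ratio")]
#> # A tibble: 5 × 4
#>   runoff_time_min monosome_auc polysome_auc pm_ratio
#> 1               0         11.7         31.5    2.70
#> 2               1         15.6         27.7    1.78
#> 3               5         31.5         11.7    0.371
#> 4              10         32.2         11.0    0.343
#> 5              20         32.2         11.0    0.341

fit <- fit_decay(build_series(quant, region = "polysome"))
fit
#> <decay_fit> polysome_decline
#>   k = 0.3511 /min, plateau = 0.3226, amplitude = 0.6774, R^2 = 0.9720, n = 5
```

Read-out: the CHX control's P/M(0) of 2.7 reflects steady-state translation
activity; during runoff the polysome area collapses to a plateau while the
monosome area roughly triples (released + start-codon-stalled 80S). The
fitted rate constant `k = 0.35/min` is the ribosome-speed proxy and the
plateau `0.32` estimates the configured inactive fraction (0.35). `tidy()`,
`glance()` and `autoplot()` work on the fit; `autoplot()` on traces and
series gives the standard QC figures, and `plot_volcano()` displays
proteomics contrasts.

The proteomics side runs the same way from a raw iBAQ matrix:

```r
tab <- simulate_proteomics(n_proteins = 1200, n_rep = 3, seed = 1)  # or read_abundance_table()
res <- analyze_fraction_shifts(tab, alpha = 0.05, lfc = log2(1.5), adjust = "BH")
res$summary   # set sizes + mean log2FC of the polysome-enriched set
```

See `vignette("runoff-kinetics")` for the models, parameter meanings,
simulator assumptions and numerical choices.

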