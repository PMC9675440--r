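---
title: "Methods: responder classification, RNAscope quantification, and coexpression counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: responder classification, RNAscope quantification, and coexpression counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcquant)
```

arcquant packages three quantitative procedures used in studies of
dopaminergic control of arcuate (ARC) feeding-circuit neurons — POMC and
AgRP/NPY cells and the Drd2-expressing POMC subpopulation — together with
synthetic-data generators that emit ground truth. This vignette documents
the models, the tunable parameters, and the design decisions taken where
the procedures were genuinely underspecified.

## The 3σ responder criterion

A perforated-patch recording yields spontaneous action-potential times on a
recording clock shared with the bath-application protocol. Firing is
discretised into uniform bins of `bin_width_s = 10` s. Baseline statistics
come from a 5-minute window (30 bins): the mean `m` and the *sample*
standard deviation `s` (n − 1 denominator; n = 30 is small enough that the
distinction matters) of the per-bin rates. For every drug epoch the mean
binned rate `f` over the epoch's analysis window gives `Δf = f − m`, and

* excited: `Δf > 3·s_eff`,
* inhibited: `Δf < −3·s_eff`,
* otherwise not responsive (strict inequalities; a tie is not a response).

with `s_eff = max(s, s_floor)`. Per-bin z-scores `(f_i − m)/s_eff` are the
visualisation companion (`zscore_trace()`, `response_heatmap_table()`).

Decisions behind this implementation:

* **Windows.** Baseline = the last 5 minutes of the baseline epoch; drug
  window = the last 5 minutes of each epoch ("end of the application",
  when the bath concentration has equilibrated), clipped to the epoch
  length so a 5-minute somatostatin epoch is used whole. Windows that are
  not multiples of the bin width are truncated backwards from the window
  end, keeping the bins flush with the epoch end.
* **One baseline for all concentrations.** Concentrations are applied
  sequentially without intervening washout, so every epoch is compared
  against the single pre-application baseline. Re-referencing each epoch to
  the previous one would compound drug effects and is not what
  "baseline conditions" means for these recordings.
* **Epoch membership is half-open.** `[t_start, t_end)` everywhere; a
  spike exactly on a boundary belongs to the later epoch. This makes
  binning unambiguous and translation-invariant.
* **SD floor.** A nearly silent baseline has an empirical SD close to 0,
  which would make the 3σ test infinitely sensitive. The floor
  `(1/bin_width)/sqrt(n_bins)` (≈ 0.018 Hz at the defaults) is the rate
  resolution of one spike in one bin propagated to a window mean: effects
  smaller than one spike per bin cannot be certified. It only binds for
  baselines quieter than ~1 spike per bin.
* **Silent neurons.** A baseline with zero spikes carries no rate
  information at all; such neurons are classified on per-bin mean membrane
  potential with the same 3σ logic (depolarisation ⇒ excited), flagged
  `modality = "membrane_potential"`. The Vm SD floor is 0.01 mV — far
  below instrument noise; it exists only to keep flat synthetic traces
  from dividing by zero. Without a Vm trace the call is `indeterminate`
  and excluded from population percentages (reported separately).
* **Washout.** Washout bins appear in heatmap tables (rebound firing is a
  real phenomenon worth displaying) but are never classified.

The false-positive behaviour of the criterion is strongly conservative:
`Δf` is a difference of two 30-bin means, so its standard error is
`s·sqrt(2/30) ≈ 0.26·s`, and the 3σ cut sits ≈ 11.6 standard errors out.
On stationary Poisson trains the test suite measures a responsive rate of
0% over 10,000 neurons (the 2% bound it asserts is generous); genuinely
drifting baselines in real recordings will produce more false calls than
this stationary bound suggests.

## What the spike-train generator emulates

`simulate_spike_trains()` produces, per neuron, a point process with rate
`r(t) = r0·(1 + E(c(t)))` where `E(c) = emax·c^h/(ec50^h + c^h)` is a Hill
dose-response in the bath concentration (instantaneous bath exchange at
epoch boundaries) and `emax ∈ [−1, ∞)` carries the response direction.
Inhibited neurons may receive an additive rebound bump
`r0·A·exp(−t′/τ)` from the final drug offset, emulating post-washout
rebound firing; rebound segments are drawn by thinning against the rate
envelope. Spiking is homogeneous Poisson within an epoch, or a
gamma-renewal process (`shape > 1`, more regular than Poisson) restarted at
each epoch boundary — the restart introduces a negligible boundary artifact
(one interval per epoch) and keeps epochs independent.

Ground truth classes are defined on the *programmed* rate change against
the *expected* baseline SD of binned rates, `sqrt(r0/(shape·bin_width))`,
with the same 3σ rule. The `effect_sd_mult` interface of
`neuron_sim_specs()` programs effect sizes directly on this scale, which is
the natural scale of the criterion.

Defaults were chosen once to mirror the recorded populations: baseline
rates uniform on 1–10 Hz (4–10 Hz in the strong-effect recovery runs, since
a 6σ inhibition is arithmetically impossible below ~3.6 Hz — rates cannot
go negative), EC50 3 µM with Hill coefficient 1.5 (mid-range of the applied
0.3–30 µM ladder), rebound amplitude 0.5 with τ = 60 s. What the generator
does *not* emulate: slow baseline drift, bath-exchange kinetics, synaptic
noise correlations, and bursting. Passing tests therefore certify the
arithmetic and the stationary error rates, not robustness to
non-stationary recordings.

## RNAscope quantification

Segmentation reproduces a standard particle-analysis chain on the
cell-body marker channel: median filter (radius 2 px; EBImage's
square-window median — ImageJ's circular kernel differs at corners, which
moves ROI boundaries by at most a pixel), Triangle autothreshold on a
256-bin histogram (bright objects on dark background), 8-connected
component labelling, per-object hole filling ("ROIs including holes"), and
a particle filter at `min_size_um2 = 20`. The minimum size is interpreted
as an **area** in µm² — particle filters are area filters, and at usual
pixel sizes a 20 µm *diameter* would discard essentially every cell.
The Triangle threshold is computed in-package (no installed R package
provides it): the chord runs from the histogram peak to the far end of the
longer tail and the threshold sits at the maximal chord–histogram
distance; it is exactly invariant to affine intensity rescaling and is the
method of choice when foreground is a small fraction of pixels.

Measurements deliberately read the **raw** channels — the median filter
exists only to define ROIs. Per-cell intensity is raw integrated density
divided by area in *pixels* (the mean raw pixel value): this convention
keeps a uniform field of value v at intensity v independent of pixel size,
and matches how integrated-density readouts behave on uncalibrated images.
ROI areas, in contrast, are physical (µm², via `pixel_size_um²`), which is
why the image reader refuses files without pixel-size metadata.

Dot counting replaces manual counting with a deterministic operator: local
3×3 maxima of the raw channel above a threshold (default 0.25 of the
channel maximum, making counts invariant to global intensity rescaling; an
absolute threshold is available per channel), greedily thinned to a
minimum separation of 3 px, brightest first, with row/column order as the
final tie-break. Positivity is `dots ≥ 3`. On well-separated synthetic
puncta the counts are exact; on real images with overlapping dots the
separation parameter is the one to tune, and positivity calls near the
3-dot threshold are the first to flip. Manual exclusion of wrongly
outlined cells is supported as an explicit ROI exclusion list, not an
automated heuristic.

Subpopulation intensities are compared with a two-sided Mann-Whitney
rank-sum test. For small samples (both n ≤ 8) the p-value is computed by
exhaustive enumeration of all `choose(n1+n2, n1)` assignments of the pooled
mid-ranks — exact under ties, where the classical exact distribution does
not apply; the permutation distribution of U is symmetric about
`n1·n2/2`, so the two-sided p is the mass at least as far from the centre
as observed. Larger samples use the normal approximation with continuity
correction.

The image generator renders non-overlapping uniform disks with Gaussian
puncta on a constant background plus optional Gaussian noise. It does not
model a microscope PSF, uneven illumination, or touching cells — so
segmentation scores from synthetic images say nothing about
nucleus-seeded splitting of cell clumps, which is out of scope.

## Cluster-subset coexpression

`subset_by_cluster_and_gene()` selects cells whose annotated cluster is in
a given list *and* whose expression of a gating gene exceeds a threshold;
`percent_expressing()` reports the share of those cells expressing a query
gene. Positivity defaults to **value > 0 on the stored matrix** — "a cell
expresses the gene" with no stated cutoff — and the threshold is a
parameter so alternative rules can be evaluated; subset size is monotone
non-increasing in it. Gene matching is exact and case-sensitive, with an
explicit alias map for synonym pairs (e.g. `c(Vgat = "Slc32a1")`). The
published reclustering of such subsets (highly-variable-gene selection,
PCA, Louvain) is a standard pipeline and intentionally not reimplemented
here.

The count-matrix generator draws, per cluster × gene, Bernoulli positivity
at programmed fractions with shifted-Poisson positive counts. It emulates
exactly the structure the counter assumes — labelled cells, sparse
nonnegative expression — and nothing else (no depth variation, no
normalisation artefacts, no cluster-correlated expression).

## Orchestration and reproducibility

`run_pipeline()` executes the configured stages from a single YAML config
with every parameter defaulting to the values above, writes delimited and
JSON outputs, and records provenance (package version, config hash, input
checksums). Outputs contain no timestamps, so identical inputs give
byte-identical summaries. All generator randomness flows through explicit
integer seeds. The package is script-free by design: its functions and
this vignette are the interface, and the pipeline driver replaces a
subcommand-style CLI.

## Problem sizes used in the test suite

The suite validates the classifier against an independent direct-count
oracle on 1000 random trains (two-epoch protocol, mixed effect sizes
including borderline ones), measures the stationary false-positive rate on
10,000 no-effect Poisson neurons (processed in batches of 1000), and
recovers a 60/10/30 excited/inhibited/none mixture over 500 neurons under
the full four-concentration protocol — sizes at which binomial error bands
are tight enough to be informative while a full run stays in the minutes
range on one CPU. Imaging checks use 256×256 px fixtures at 0.5 µm/px;
rank-test enumeration covers every group-size pair up to 8×8.

## Known limitations

* The classifier assumes a stationary baseline; drifting or bursting cells
  inflate the false-positive rate beyond the stationary bound.
* The Vm fallback uses per-bin mean potential; it does not detect
  sub-threshold oscillations or conductance changes.
* Segmentation has no mechanism for splitting touching cells; crowded
  fields should be quantified with a nucleus-seeded method instead.
* Dot counts saturate when puncta overlap within the separation radius;
  true counts above ~10 per cell at these densities are lower bounds.
* The exact rank test enumerates up to 8 per group (12,870 assignments);
  beyond that the normal approximation is used even under heavy ties.
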