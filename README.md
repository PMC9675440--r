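# arcquant

Quantitative analysis of pharmacological responses and marker coexpression
in arcuate (ARC) feeding-circuit neurons, for slice electrophysiologists and
imaging labs working on the melanocortin system. The package covers three
bespoke procedures that usually live in ad-hoc lab scripts, and ships
seedable synthetic-data generators with ground truth so every stage is
testable without raw recordings:

1. **3σ responder classification of patch-clamp recordings.** Spontaneous
   firing is binned (10 s bins); baseline mean `m` and sample SD `s` come
   from a 5-minute window (30 bins) before drug application. For each bath
   epoch the mean rate `f` over the last 5 minutes of the epoch gives
   `Δf = f − m`, and a neuron is *excited* if `Δf > 3s`, *inhibited* if
   `Δf < −3s`, otherwise *not responsive*. Per-bin z-scores
   `z_i = (f_i − m)/s` feed population heatmaps; neurons that fire no action
   potentials are classified on binned membrane potential instead.
2. **RNAscope image quantification.** Cell ROIs are segmented from a marker
   channel (2 px median filter → Triangle autothreshold → 8-connected
   components → hole filling → ≥ 20 µm² particle filter); transcript dots
   are counted as separated local maxima; a cell is positive for a probe at
   ≥ 3 dots; per-cell intensity is raw integrated density / area; and
   subpopulations (e.g. Drd2⁺ vs Drd2⁻ POMC cells) are compared with a
   two-sided Mann-Whitney rank-sum test (exact, tie-aware, for small
   samples).
3. **Cluster-subset coexpression counting** on an annotated cell × gene
   matrix: select cells in named clusters that express a gating gene
   (value > 0), then report the percentage expressing each query gene.

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe; results have `autoplot()` methods and the
rank test has broom-style `tidy()`/`glance()`.

## Worked example

```r
library(arcquant)
library(dplyr)

# sequential dopamine application: 0.3, 3, 10, 30 uM for 10 min each
protocol <- dopamine_protocol()

# simulate 24 neurons: 30% excited, 30% inhibited, strong effects
specs <- neuron_sim_specs(24, p_excited = 0.3, p_inhibited = 0.3,
                          effect_sd_mult = 8, seed = 3)
sim <- simulate_spike_trains(specs, protocol, seed = 4)

calls <- classify_responses(sim$spikes, protocol)
summarize_population(calls) %>%
  filter(concentration_uM == 30) %>%
  select(concentration_uM, n, pct_excited, pct_not_responsive, pct_inhibited)
#> # A tibble: 1 × 5
#>   concentration_uM     n pct_excited pct_not_responsive pct_inhibited
#>              <dbl> <int>       <dbl>              <dbl>         <dbl>
#> 1               30    24        20.8               54.2            25
```

At the top concentration the classifier recovers the realised mixture of
this draw: 5/24 excited (20.8%), 6/24 inhibited (25%), the rest unchanged
(the programmed 30/30/40 mixture is drawn per neuron, so small populations
fluctuate around it). Ground truth per
neuron and concentration is in `sim$truth`; `response_heatmap_table()` +
`autoplot()` draw the per-bin Δrate / z heatmap.

Imaging works the same way from simulated fixtures:

```r
cells <- image_cell_specs(3, radius_um = 5, body = c(Pomc = 100),
                          dots = c(Drd2 = 5))
img <- simulate_image(cells, seed = 7)
q <- quantify_image(img$image, seed_channel = "Pomc")
q$cells
#> # A tibble: 3 × 8
#>   roi_id area_um2 centroid_x_um centroid_y_um channel  dots positive intensity
#>    <int>    <dbl>         <dbl>         <dbl> <chr>   <int> <lgl>        <dbl>
#> 1      1     77.8          20.2          14.9 Drd2        5 TRUE          29.0
#> 2      2     76.5          34.9          97.4 Drd2        5 TRUE          29.5
#> 3      3     76.5         120.           52.4 Drd2        5 TRUE          29.2
```

Each 5 µm disk is recovered with area ≈ πr² = 78.5 µm², all five programmed
puncta are found, and every cell is called Drd2⁺ (≥ 3 dots). Percentages and
ratios then come from `coexpression_table()` / `positivity_ratio()`, and
`run_pipeline()` drives everything from a single YAML config, writing
delimited tables, JSON summaries and a provenance file.

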