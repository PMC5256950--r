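# nanomem

Quantitative analysis of plasma-membrane receptor **nanoclusters** from
fluorescence microscopy, in R.

Plant receptor kinases such as BRI1 and its co-receptor SERK3/BAK1 are not
spread evenly over the plasma membrane: surface-illumination imaging
(VAEM/TIRF) shows them concentrated in diffraction-limited puncta a few
hundred nanometres across. Quantifying that organisation — how many clusters
per µm², how many receptors per cluster, whether the receptors inside a
cluster interact, and how mobile they are — requires four different
measurements, each with its own analysis chain. `nanomem` implements all
four, together with a synthetic-data generator that produces ground-truthed
inputs for every stage, so each estimator can be validated end to end.

## What the package computes

**Nanocluster detection** (`rolling_ball_subtract`, `bandpass_subtract`,
`threshold_label`, `detect_clusters`, `summarize_clusters`). Images are
background-corrected (rolling ball, radius 50 px), band-pass filtered by
blur-and-subtract (Gaussian σ = 2 µm), thresholded (80 a.u.) and
particle-analysed with 8-connected labelling, minimum particle size 2 px,
optionally inside a per-cell ROI polygon. Summaries report cluster density
(clusters/µm²) and mean size (µm²); the equivalent diameter of a cluster of
area *A* is 2·√(*A*/π).

**Receptors per nanocluster** (`receptors_per_cluster`). The receptor
surface density (receptors/µm², e.g. from FCS) divided by the nanocluster
density, rounded to the nearest integer, with first-order SEM propagation.

**FLIM / FRET / IPS** (`simulate_decay_cube`, `fit_pixel`, `fit_cube`,
`apply_filters`, `fret_efficiency`, `ips_fraction`,
`cluster_lifetime_distribution`). Per-pixel TCSPC histograms (256 channels
at 40 MHz repetition) are fitted with mono- or bi-exponential decays
convolved with the instrument response function and wrapped at the
repetition period, by Poisson maximum likelihood (Neyman-weighted least
squares available for parity with common acquisition software). Pixels are
filtered on photon count (≥ 1200), reduced χ² (< 2) and lifetime window
(1500–2500 ps). FRET efficiency is *E* = 1 − τ_DA/τ_D, and the
interacting-pixel statistic (IPS) is the percentage of quality-filtered
pixels whose lifetime falls below the threshold τ_D·(1 − *E*_thr) with
*E*_thr = 0.13.

**FRAP** (`simulate_frap_trace`, `normalize_trace`, `fit_recovery`,
`fit_cross_section`). Traces are background-subtracted, divided by a
reference ROI to correct scan bleaching, normalized to pre-bleach 1 / first
post-bleach 0, and fitted with a single-exponential recovery. The mobile
fraction Mf and half-time t½ give the diffusion coefficient through the
Axelrod-style relation *D* = 0.224·*w*²/t½ for bleach-spot radius *w*.

**Photobleaching step counting** (`simulate_bleach_trace`, `count_steps`).
Single-cluster intensity traces are segmented by exact penalized
least-squares change-point detection (dynamic programming, penalty
3·σ̂²·log T); downward level changes larger than 3σ̂ are counted as
bleaching steps, bounding the number of fluorophores in a cluster.

**Pipeline** (`run_config`, `run_pipeline`). One seed drives every
simulator; the JSON run report is byte-identical across runs with the same
configuration and seed.

## Worked example

```r
library(nanomem)

# a synthetic VAEM snapshot: 0.55 clusters/um^2, 6 receptors each
sim <- simulate_membrane_stack(membrane_sim_params(
  field_px = 256, density_um2 = 0.55, receptors = 6, seed = 42))
summarize_clusters(detect_clusters(sim$stack))
#> <cluster_summary> 535 clusters / 1 image(s): 0.48 +/- NA per um^2, size 0.099 +/- 0.002 um^2

# receptors per nanocluster: 12 receptors/um^2 over 2 clusters/um^2
receptors_per_cluster(12, 2, receptor_sem = 1, cluster_sem = 0.4)$receptors
#> [1] 6

# donor-only FLIM image: fit, filter, summarize
donor <- simulate_decay_cube(flim_sim_params(dim_px = 32, tau_d_ps = 2402,
                                             photons_mean = 3000, seed = 1))
apply_filters(fit_cube(donor$cube, model = "mono"))
#> <lifetime_image> 1018/1024 pixels accepted; mean tau 2397 +/- 1.4 ps

# double-labelled image with 15 % interacting pixels: IPS statistic
double <- simulate_decay_cube(flim_sim_params(dim_px = 32, f_int = 0.15,
                                              photons_mean = 3000, seed = 2))
ips_fraction(apply_filters(fit_cube(double$cube, model = "mono")),
             tau_d_ref = 2402, e_threshold = 0.13)
#> <ips_result> IPS 16.5% (167/1011 px below 2090 ps; E_thr 13%)

# FRAP: mobile fraction and diffusion coefficient
frap <- simulate_frap_trace(frap_sim_params(mf = 0.28, d_um2_s = 0.003, seed = 3))
fit_recovery(normalize_trace(frap$trace), w_um = 1)
#> <frap_fit> Mf 28.3%, t_half 70.2 s, D 3.19e-03 um^2/s (w = 1.00 um)

# photobleaching staircase of a 6-receptor cluster
steps <- simulate_bleach_trace(bleach_sim_params(n_fluor = 6, seed = 4))
count_steps(steps$trace)
#> <step_fit> 6 bleaching step(s) (+0 upward), sigma 0.207, penalty 0.768
```

The detected density (0.48/µm² here) sits slightly below the generating
0.55/µm² because clusters closer than the diffraction limit merge into one
particle; the lifetime image recovers the 2402 ps donor lifetime to a few
ps; the IPS estimate tracks the generated interacting fraction; and the
FRAP fit returns the generating mobile fraction and diffusion coefficient.

## Documentation

The methods vignette (`vignettes/nanomem-methods.Rmd`) describes the
models, the estimators, the synthetic-data generators and their limits, and
the numerical choices in detail.
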