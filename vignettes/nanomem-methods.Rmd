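---
title: "Models and methods behind nanomem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanomem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomem)
```

`nanomem` quantifies the nanoscale organisation of plasma-membrane
receptors from four kinds of fluorescence measurements: surface-illumination
(VAEM/TIRF) images of receptor nanoclusters, per-pixel TCSPC decay
histograms for FRET-FLIM, FRAP recovery traces, and single-cluster
photobleaching traces. This vignette explains the models each estimator
assumes, the defaults and why they were chosen, what the synthetic-data
generators do and do not emulate, and the numerical decisions that a
maintainer would otherwise have to reverse-engineer.

## 1. Nanocluster detection

### Model and procedure

A VAEM image of a membrane sheet is modelled as diffraction-limited spots on
a smooth background. Detection proceeds in three stages, each individually
disableable:

1. **Rolling-ball background subtraction** (default radius 50 px),
   implemented as grayscale morphological opening with a disc structuring
   element — the flat-ball version of the classical rolling-ball estimate.
   EBImage's grayscale morphology operates on unit-range images, so the
   frame is affinely mapped to $[0,1]$ and back around the opening. A
   radius larger than the image degenerates to subtracting the global
   minimum.
2. **Band-pass by blur-and-subtract**: the image minus a heavily blurred
   copy of itself (Gaussian $\sigma$ = 2 µm, i.e. ~15.4 px at 130 nm
   pixels). The image is edge-padded by the kernel radius before blurring
   so the filter is defined for small images and free of wrap-around. The
   result may be negative; values are clipped at 0 before thresholding
   (immaterial for any positive threshold, but the behaviour must be
   defined).
3. **Threshold and particle analysis**: pixels strictly above the threshold
   (default 80 a.u., on the raw camera intensity scale of the band-pass
   image) are labelled by 8-connected component analysis; particles smaller
   than 2 px are discarded, which removes the isolated single pixels that
   spatially uncorrelated noise produces. Analysis can be restricted to a
   user-supplied ROI polygon (rasterised by an even-odd rule on pixel
   centres); there is no automatic cell segmentation.

Connected-component labelling is implemented in the package (vectorised
minimum-label propagation) because the package requires 8-connectivity —
the default of common particle-analysis tools — configurable down to 4.
The test suite checks it against an independent recursive flood fill on
1000 random masks.

Cluster records carry area (px and µm²), centroid, integrated intensity and
the equivalent diameter $2\sqrt{A/\pi}$. A five-pixel cluster at 130 nm
pixels has area 0.0845 µm² and equivalent diameter ≈ 328 nm — a typical
apparent nanocluster, and an upper bound on the physical cluster size since
the spot is diffraction-limited.

**Receptors per nanocluster** divides an independently measured receptor
surface density by the cluster density, rounds to the nearest integer, and
propagates the two SEMs to first order
($\sigma_r = r\sqrt{(\sigma_R/R)^2 + (\sigma_C/C)^2}$). A zero cluster
density is flagged undefined rather than returning infinity.

### Resolution limits, stated plainly

Two clusters closer than roughly twice the PSF FWHM (~0.45 µm here) merge
into one particle. Detection is therefore an estimator of the *resolvable*
cluster density: in simulations the detected count is unbiased within ~±20 %
against ground truth merged by single linkage at 3.5 px, from sparse
(0.25/µm²) to crowded (2/µm²) fields, while the raw count under-estimates
the true density increasingly with crowding (about −15 % at 0.55/µm²,
−40 % at 2/µm²). Published cluster densities obtained with
threshold-plus-particle-analysis pipelines have the same character.

## 2. TCSPC lifetime fitting, FRET and IPS

### Decay model

A pixel's photon arrival-time histogram over $n$ channels (default 256) of
width $w$ (repetition period $T = 1/f_{rep}$, default 40 MHz so
$w \approx 97.7$ ps) is modelled as

$$ m_k \;=\; N\sum_i g_i\, p_{\tau_i}(t_k) \;+\; b, $$

where $p_\tau$ is the exponential decay with lifetime $\tau$ convolved with
the instrument response function (IRF) and wrapped at the repetition period
(periodic steady state), $g_i$ are photon fractions, $N$ the decay photon
total and $b$ a flat baseline. For a parametric Gaussian IRF the
convolution has the closed exponentially-modified-Gaussian form, evaluated
at channel midpoints and summed over wrap periods; for a measured IRF
histogram the profile is computed by FFT circular convolution with a
half-channel phase correction that aligns the discrete convolution with the
midpoint-sampling convention (the two paths agree to ~10⁻³ away from the
rising edge, and the analytic path is checked against direct quadrature to
10⁻⁶ in the tests). The IRF default is a Gaussian of FWHM 300 ps centred
near channel 10 — a realistic envelope for a hybrid detector with ~100 ps
timing resolution. An IRF temporal shift is supported as a fit parameter
(`fit_shift = TRUE`) but is off by default: with a correctly calibrated IRF
a free shift only inflates variance.

### Objective and algorithm

TCSPC counts are Poisson, so the default objective is the Poisson deviance
(maximum likelihood); Neyman-weighted least squares
($\sum (y-m)^2/\max(y,1)$) is provided for parity with common acquisition
software, with the caveat that its weights bias lifetimes low by several
percent at a few thousand photons — one reason Poisson ML is the default.

Mono-exponential Poisson fits use a fast profiled structure: for fixed
$\tau$ the likelihood is concave in $(N, b)$ and solved by a damped 2×2
Newton iteration (with $b$ clamped at 0, and $N$ exactly the photon total
when $b = 0$); a Brent search over $\log\tau$ completes the fit in ~2 ms
per pixel. Bi-exponential fits (and Neyman or shift-fitting variants) use
Nelder–Mead on transformed parameters that enforce $\tau_1 < \tau_2$ and
positive amplitudes. Under the automatic model rule a bi-exponential is
attempted only when the mono fit's reduced $\chi^2$ is ≥ 2, and kept only
if it improves it. The per-pixel lifetime reported for bi fits is the
amplitude-weighted mean $\bar\tau = \sum a_i\tau_i / \sum a_i$, the
convention of standard lifetime-imaging software.

### Goodness of fit and quality filters

The reported reduced $\chi^2$ is Pearson — $\sum (y_k-m_k)^2/m_k$ over
channels with fitted expectation ≥ 1, divided by the degrees of freedom.
Pearson's per-channel expectation is exactly 1 for Poisson data, so the
statistic is calibrated (simulated correctly-specified fits average
1.0 ± 0.1) and the $\chi^2 < 2$ acceptance filter means what it says;
restricting to channels with expectation ≥ 1 keeps empty tail channels
from dominating. The Neyman convention is available
(`chi2_convention = "neyman"`) but is biased low over low-count channels.

A pixel is **accepted** when the fit converged, the photon count is
≥ 1200, the reduced $\chi^2$ is strictly below 2, and $\bar\tau$ lies in
1500–2500 ps (inclusive). Image statistics (mean lifetime ± SEM) are over
accepted pixels only.

### FRET efficiency and the interacting-pixel statistic

FRET efficiency is $E = 1 - \tau_{DA}/\tau_D$; tables conventionally print
it as an integer percent. The IPS statistic converts an efficiency
threshold (default $E_{thr} = 0.13$) into a lifetime threshold
$\tau_{thr} = \tau_D(1 - E_{thr})$ and reports the percentage of
quality-filtered pixels with $\bar\tau < \tau_{thr}$. The denominator is
the accepted pixels by default; because published descriptions of this
class of statistic are ambiguous between "all pixels" and "pixels passing
the filters", the denominator is a switch (`denominator = "all"`). IPS is
invariant to pixel permutation and to any intensity rescaling that
preserves photon counts, and `cluster_lifetime_distribution` pools
per-cluster mean lifetimes for clusters whose brightest pixel reaches 2000
photons.

A consistency point worth stating: a *population mean* lifetime reduction
of ~7 % (e.g. 2227 ps against a 2402 ps donor) does **not** place pixels
below a 13 % threshold. A double-labelled image shows IPS ≈ 15 % only if
~15 % of its pixels carry FRET well above the threshold while the rest sit
at the donor lifetime — the printed image mean is then the mixture average,
not the interacting-pixel lifetime. The simulator therefore parameterises
the interacting state by its own FRET efficiency, default 0.25 (τ ≈ 1800 ps
for a 2402 ps donor): a typical efficiency for a directly interacting
GFP–mCherry pair, safely above the detection threshold and inside the
1500–2500 ps acceptance window. Group comparison of mean lifetimes is
provided as Welch's *t*-test over accepted pixels (`compare_lifetimes`),
flagged as an interpretation aid since within-image pixels are not
independent.

## 3. FRAP

### Normalization

The bleach-ROI trace is background-subtracted and divided by the
(background-subtracted) reference ROI, which cancels scan bleaching
exactly when both ROIs bleach at the same rate; when no reference exists,
an exponential fitted to the pre-bleach frames is divided out instead
(`correction = "expfit"`). The trace is then rescaled so the pre-bleach
*mean* is 1 (all pre-bleach frames, for noise robustness, rather than the
last frame) and the first post-bleach point is 0. A reference that decays
to the background level aborts with a diagnostic. Normalizing an
already-normalized trace (flat reference) is the identity to 10⁻¹².

### Recovery model

Recovery is modelled as a single exponential,
$F(t) = c + a\,(1 - e^{-(t-t_0)/\tau_{rec}})$, fitted to the post-bleach
points by Levenberg–Marquardt, with a profiled-linear fallback (closed-form
$(c, a)$ for fixed $\tau$, Brent search on $\log\tau$) for the
near-singular case where recovery is faster than the sampling interval.
The floor $c$ is a nuisance parameter: normalization anchors the first
post-bleach point at exactly zero, so that single point's noise would
otherwise propagate one-for-one into the mobile fraction; re-estimating the
floor from all post-bleach points removes that variance, and a noiseless
trace gives $c = 0$. The mobile fraction is $M_f = a/(1-c)$, the half-time
$t_{1/2} = \tau_{rec}\ln 2$, and the diffusion coefficient
$D = 0.224\,w^2/t_{1/2}$ for a Gaussian bleach spot of radius $w$ — the
simplest model consistent with reported $(M_f, D)$ pairs, and identical to
the generator's model so parameter recovery is well posed. $w$ is a
required user input; it is rarely printed alongside published $(M_f, D)$
values, so published $D$ values cannot be re-derived without it — they are
validated on synthetic data instead. Full reaction–diffusion FRAP models
(uniform-disk Soumpasis, reaction-dominant) are out of scope.

The membrane cross-section analysis fits a 1-D Gaussian plus offset to an
intensity profile across the membrane (moment-based width initialisation
with a retry ladder, since Levenberg–Marquardt from a too-wide start can
diverge on noiseless profiles); the amplitude ratio of two fits quantifies
replenishment versus scan bleaching.

## 4. Photobleaching step counting

A single-cluster intensity trace is segmented into piecewise-constant
levels by **exact** penalized least-squares change-point detection: dynamic
programming over all segmentations (optimal partitioning, $O(T^2)$ with
cumulative sums), minimising total within-segment RSS plus
$\beta$ per changepoint. The default penalty is BIC-like,
$\beta = 3\,\hat\sigma^2\log T$, with $\hat\sigma$ from median absolute
first differences (robust to the steps themselves). The exact optimiser is
used instead of greedy binary segmentation because only it is guaranteed to
match exhaustive enumeration of changepoint placements — a property the
test suite verifies on short traces.

Counting rules: downward level changes larger than $3\hat\sigma$ (the
conventional detection threshold; smaller changes are indistinguishable
from noise-driven splits) are bleaching steps; upward changes (blinking
recovery) are reported but excluded from the fluorophore count;
single-frame excursions that return to the previous level are classified
as transients (outliers or blinks) and neither edge is counted. The count
is invariant to affine intensity rescaling because both the penalty and the
step threshold scale with $\hat\sigma^2$ and $\hat\sigma$.

## 5. The synthetic-data generators

Each generator draws from the same model family its estimator assumes, with
recorded ground truth, and is deterministic under a fixed seed.

**Membrane images** (`simulate_membrane_stack`): clusters placed by a
homogeneous spatial Poisson process; each cluster renders the summed
pixel-integrated Gaussian PSF of its fluorescent receptors
($\sigma$ default 110 nm ≈ 0.21 λ/NA for GFP at NA 1.49); flat background
(50 photons/px/frame); Poisson shot noise; then linear gain and Gaussian
read noise (EMCCD excess-noise factor deliberately omitted — detection is
threshold-driven, not noise-model-critical). Defaults: 130 nm pixels,
0.55 clusters/µm², 6 receptors/cluster, 200 photons/receptor/frame —
peak spot intensities a few hundred counts over background, matching the
punctate appearance and ~5 px apparent cluster size of receptor imaging at
the membrane. Fluorophore maturation is a parameter defaulting to 1
(perfect maturation), mirroring the assumption used when receptor counts
are derived from fluorescence. The snapshot is static: cluster dynamics,
endocytosis events and cell-wall autofluorescence are *not* emulated, so
passing tests validate the estimators on clustered-spot images, not those
confounds.

**Decay cubes** (`simulate_decay_cube`): each pixel is interacting with
probability `f_int`; each photon's arrival time is an IRF draw plus an
exponential lifetime draw, wrapped at the repetition period and binned —
so photon totals are Poisson, per-pixel histograms are exactly multinomial
in the model's channel probabilities, and channel sums equal the drawn
photon totals exactly (asserted in tests). Background photons are uniform
over the period. Defaults: 2402 ps donor lifetime, 3000 photons/pixel,
256 channels at 40 MHz, Gaussian IRF FWHM 300 ps, interacting-state FRET
efficiency 0.25 (see §2).

**FRAP traces** (`simulate_frap_trace`):
$F(t) = F_{pre}[(1-d) + d\,M_f R(t)]\,S(t)$ with single-exponential
recovery $R$, $t_{1/2} = 0.224\,w^2/D$, scan-bleach factor
$S(t) = e^{-k_{scan}t}$ applied to bleach and reference ROIs alike, plus
Gaussian noise. Defaults mirror a confocal receptor-FRAP experiment:
~500 s of recovery at 1 s sampling, 10 pre-bleach frames, bleach depth 0.8,
2 % noise. The generator shares the recovery parameterisation of the
estimator by design; it does not simulate diffusion on a lattice, so it
validates normalization and parameter recovery, not model adequacy for
arbitrary bleach geometries.

**Bleaching staircases** (`simulate_bleach_trace`): $N$ fluorophores with
geometric per-frame bleaching hazard (default 0.02 over 400 frames, so all
fluorophores bleach within the trace), unit step, Gaussian noise. Bleach
frames are drawn distinct and at least `min_gap` = 3 frames apart
(including before the first event): events closer than that merge into a
single observable discontinuity — or an unresolvable one-frame plateau —
making the true count unidentifiable from the trace at any penalty, which
would defeat the generator's purpose of providing recoverable ground
truth. This emulates the practice of counting steps on traces with
visually separated steps; it means the generator does not exercise the
(unidentifiable) near-simultaneous-bleaching regime.

## 6. Reproducibility and problem sizes

All randomness flows through explicit seeds; `run_pipeline` derives
per-stage seeds from one master seed and writes a JSON report that is
byte-identical across runs (timestamp aside). The test suite and the
acceptance script use desk-scale problem sizes chosen to exercise each
estimator with comfortable statistical margin: 48–128 px FLIM images at
3000 photons/pixel (lifetime SEM ~1 ps, binomial 3σ on a 15 % fraction
under 2 points), nine 128 px membrane images (~150 clusters each) for
density recovery, 100-seed simulation studies for step counting and FRAP
parameter grids. File formats are deliberately plain: calibrated TIFF +
JSON sidecar for images (integer data stored bit-exactly), a TSV + JSON
container for decay cubes, and CSV for traces.

## 7. Known limitations

- Cluster sizing is diffraction-bound: diameters are upper limits, and
  densities refer to resolvable clusters (§1).
- The FLIM fitter assumes a single lifetime class per pixel under the
  default mono model; spatial mixing within a pixel is only captured by
  the bi-exponential option.
- FRAP analysis is deliberately single-component; immobile-fraction
  heterogeneity or binding-dominated recoveries need richer models.
- Step counting bounds fluorophore number from below: fluorophores
  bleached before acquisition, or bleaching simultaneously, are invisible.
- No reader for proprietary instrument formats is included; decay cubes
  arrive through the documented text container or are simulated.
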