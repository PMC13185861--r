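---
title: "Quantifying motile-organoid behaviour and pooled expression variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motile-organoid behaviour and pooled expression variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(botmetrics)
```

Self-assembled mucociliary epidermal organoids ("biobots") propel themselves
with beating cilia; implanting neural precursor cells yields "neurobots"
whose movement may be modulated by spontaneous neural activity. This package
implements the quantitative read-outs used to compare such constructs:
trajectory kinematics, a spectral movement Complexity Index with surrogate
validation, body-shape morphometrics, and a pooled-sample gene-expression
variability analysis. This vignette documents the models, the parameters
that matter, the numerical choices, and the known limitations.

## Trajectory kinematics

A recording is a uniformly sampled centre-of-mass path $(x_t, y_t)$ in mm at
sampling rate $f_s$. From the per-step displacements $\Delta_i$ we compute:

* total distance $\sum_i \lVert\Delta_i\rVert$;
* mean speed, the mean of per-step speeds $\lVert\Delta_i\rVert f_s$;
* mean acceleration, the mean of
  $\lVert \vec v_{i+1} - \vec v_i \rVert f_s$ — the magnitude of the
  discrete velocity-vector difference, so sharp turns register as
  acceleration even at constant speed;
* minimum speed, the smallest per-step speed (an optional odd median window
  can smooth the speed series first; the default is no smoothing, so a
  single idle frame drives the minimum to zero — that sensitivity is the
  point of the metric, which separates constructs that idle from those that
  never stop);
* coverage: the well is gridded into square cells of side 0.1 mm and the
  percentage of unique visited cells over all cells of the well is reported.
  The denominator is the full arena, not the trajectory's bounding box, so
  well dimensions are a required input. Cell assignment is half-open: a
  point exactly on a boundary belongs to the lower-index cell.

Tracker drop-outs: interior gaps of at most 5 frames are linearly
interpolated; anything longer truncates the recording to its longest
contiguous valid segment, with a warning. The frame rate and well geometry
of the original videos are not published, so both are mandatory arguments
with no hidden defaults.

## The Complexity Index

The movement repertoire ranges from constant-radius circling to
spirograph-like patterns. A circling construct concentrates the power of
both coordinate series at a single frequency; more intricate paths spread
power over several discrete peaks. The Complexity Index (CI) counts those
peaks:

1. Welch power spectral densities of the $x$ and $y$ series are estimated
   with 400-s windows, 1 s of overlap, per-segment mean removal and a Hann
   taper (one-sided density normalisation, so the spectrum integrates to the
   signal variance). Frequency resolution is $1/400$ Hz.
2. Peaks are strict local maxima above a detection threshold stated in
   tracker units, 10 px$^2$/Hz by default, converted to mm$^2$/Hz with the
   square of the pixel scale (at 0.13 mm/px that is $\sim$0.17 mm$^2$/Hz).
   The zero-frequency bin is excluded — any off-centre path would otherwise
   contribute a spurious DC peak — and maxima within one bin merge, keeping
   the larger.
3. CI is the number of *unique* peak frequencies in the union of the two
   axes: frequencies within one bin width of each other (single-linkage over
   the sorted list) count once. A constant-diameter circle therefore scores
   CI = 1, an immobile construct CI = 0.

Relative complexity under a pharmacological treatment is the treatment CI
minus the mean CI of the consecutive control recordings — a difference, not
a ratio, so zero means "as complex as the average control".

Design notes: the taper is not dictated by the original description; Hann is
the standard Welch choice and peak *location* is taper-invariant for
resolvable tones (a boxcar option exists, and makes a single full-length
window numerically identical to the plain periodogram, which is how the
estimator is oracle-tested). Recordings shorter than one window fall back to
a single full-length segment and are flagged.

## Surrogate validation of spectral peaks

Each Welch peak can be re-examined in wavelet space: the coordinate series
is transformed with an analytic Morlet wavelet ($\omega_0 = 6$, scales in
octaves of width 0.125, zero padding to the next power of two), and its
time-averaged wavelet power per scale is compared against the same statistic
on phase-randomized surrogates — series with the original amplitude spectrum
but i.i.d. Fourier phases (Hermitian symmetry enforced, so the surrogate is
real and preserves mean and variance exactly). Per scale, the significance
threshold is the 95th percentile of 200 surrogate values; a peak passes when
the observed power at the scale nearest its frequency exceeds the threshold.
Peaks outside the wavelet's scale range are flagged untestable rather than
failed.

**Limitation, stated plainly.** The time-averaged wavelet power at a scale
is, by Parseval's relation, a function of the amplitude spectrum alone — the
very thing phase randomization preserves. Only edge effects of the finite
transform separate the observed statistic from its surrogates, so for a
strictly stationary sinusoid the observed value sits near the *centre* of
the surrogate distribution and the test has essentially no power; what the
construction genuinely probes is phase structure (nonlinearity,
nonstationarity), not the mere presence of a spectral peak. We implement the
documented construction faithfully and verify its well-posed properties
(exact amplitude-spectrum preservation; for white noise, scales exceed the
95th-percentile threshold at the nominal $\sim$5 % rate by exchangeability),
but peak detection itself should rest on the Welch threshold. The CI
pipeline accordingly treats surrogate validation as an optional annotation,
not a gate.

## Morphometrics

Body masks are binary grids (PNG or CSV; the largest connected component is
kept if there are several). Area is the foreground pixel count times the
squared pixel scale. Axes come from the moment-equivalent ellipse — the
ellipse with the region's second-order central moments; axis lengths are
$4\sqrt{\lambda}$ for the eigenvalues $\lambda$ of the pixel covariance
matrix, the standard region-property convention. The Roundness Index is
minor/major, so RI $\in (0, 1]$, with 1 a disc and small values elongated
bodies. (The alternative major/minor convention would exceed 1 and flip the
sign of every shape-behaviour correlation; elongated constructs must score
*lower*.) The implant ratio divides the summed area of implanted clumps by
the outer-shell area. `feature_table()` assembles per-construct
morphometric, neuroanatomical (neurite length, terminal count, MCC count —
measured externally and ingested as summaries) and behavioural columns,
normalising counts and lengths by area where area is present.

## Pooled expression variability

Bulk RNA-seq libraries here are *pools* of whole organoids, so each
FPKM value is the mean over the $n$ individuals in that pool
(FPKM $= 10^9 \cdot \text{counts} / (\text{gene length} \times
\text{library size})$). The spread across a group's pools therefore
estimates the standard error of the mean, and the individual-level variation
can be reconstructed:

$$\text{SE}_g = \text{sd}(\text{pools}_g), \qquad
  \sigma_g = \text{SE}_g \sqrt{n}, \qquad
  \text{CV}_g = \sigma_g / \bar{x}_g .$$

Choices the data force: the sd across 3–4 pools uses the $n-1$ denominator;
when pool sizes differ within a group, $n$ defaults to their arithmetic mean
(a fixed-$n$ override exists); the CV denominator is the group's own pool
mean, while *ranking* uses the grand mean across all pools of both groups.
Genes with a zero in any selected pool are discarded first (pools from a
discordant sequencing batch can be excluded before the filter).

For a pair of groups, genes are ranked by grand mean from highest to lowest
and split into 100 percentile bins of near-equal size (sizes differ by at
most one; larger bins sit at the high-abundance end). Per bin we report the
fraction of genes whose group-1 CV strictly exceeds the group-2 CV — ties
count as "not greater", a measure-zero event for continuous data but
possible in integer fixtures. Significance per bin comes from a
pair-preserving permutation test: gene order is shuffled 1000 times (each
gene's CV pair stays intact), bins are rebuilt, and the p-value is the
proportion of permuted fractions strictly farther in absolute value from the
permutation-distribution mean than the observed fraction. No $+1$
small-sample correction is applied, so $p = 0$ can occur; with discrete
fractions the strict inequality makes the test mildly conservative, and the
missing correction mildly anti-conservative — in calibration runs the
significant-bin rate lands near the nominal 0.05 (0.06 over ten replicate
nulls of 10,000 genes).

Group-level CV comparisons use Kruskal–Wallis with Tukey HSD on the
rank-transformed values; pool similarity uses Pearson correlation and PCA of
the $\log(x+1)$ matrix (the transform is a flag, since the original
description is silent).

## Reporting layer

`compare_groups()` wraps Kruskal–Wallis + Tukey-on-ranks (two or more
groups) and the one-sample t test against zero used for relative
complexity. `pairwise_correlations()` produces Fig-9-style panels: Pearson
$r$ with the two-tailed $t = r\sqrt{(n-2)/(1-r^2)}$ test and a robust linear
fit by iteratively reweighted least squares with Tukey's bisquare weight at
the conventional tuning constant 4.685, on pairwise-complete rows (fits need
$n \ge 3$; constant variables are flagged, not fit). Box summaries use
linear-interpolation quartiles and the 1.5 × IQR outlier rule.

## The synthetic-data generators

The generators define the conditions under which every pipeline is tested:

* **Trajectories** are sums of sinusoids per axis plus i.i.d. Gaussian
  coordinate jitter, at 1 Hz for 30 minutes — defaults matching the recorded
  trials; the orbit default is a 0.5 mm radius at 1/120 Hz. The
  `boundary_follow` motif walks the arena perimeter at constant speed. No
  published tracking-noise level exists, so the noise default is 0 and tests
  state their own small jitter (5–20 µm) explicitly. These motifs are
  kinematic descriptions, not a cilia/fluid model: they reproduce the
  spectral structure of the observed repertoire, so CI recovery on them
  validates the spectral pipeline, not any biophysics.
* **Masks** are rasterised ellipses (pixel-centre-inside rule) on grids fine
  enough that moment fits recover axes within two pixels.
* **Pooled expression** draws each gene's baseline abundance once from a
  log-normal (log-mean $\log 50$, log-sd 1.5 — an FPKM-like skew), then each
  individual from a log-normal with that arithmetic mean and a
  group-specific individual CV; a pool is the mean of its individuals.
  Log-normal individual abundance is our choice of the simplest positive
  model in which the CV is a free parameter. What the generator does *not*
  emulate: count noise at low abundance, batch effects, gene–gene
  correlation, or library-size variation — so a passing calibration here
  shows the inference machinery is correct, not that real libraries satisfy
  its assumptions.

All generators take an explicit seed and are bit-reproducible; analysis
problem sizes in the test-suite calibrations (10,000-gene nulls, ten
replicate seeds, 1000 permutations; twenty seeds per harmonic count for CI
recovery) were chosen to pin Monte-Carlo error well below the effect sizes
being checked.

## A worked null calibration

```{r null-calibration}
sim <- simulate_pooled_expression(pooled_sim_spec(
  2000,
  groups = list(g1 = list(n_pools = 3, pool_size = 10, individual_cv = 0.4),
                g2 = list(n_pools = 3, pool_size = 10, individual_cv = 0.4)),
  seed = 1))
filtered <- filter_genes(sim)
cfg <- permutation_config(n_bins = 50, n_perm = 1000, seed = 1)
bf <- permutation_test(
  bin_fractions(pooled_cv(filtered, "g1"), pooled_cv(filtered, "g2"), cfg), cfg)
mean(bf$fraction)      # ~0.5 under the exchangeable null
mean(bf$significant)   # ~alpha
```

## Known limitations

* The surrogate test's degeneracy for stationary tones, discussed above.
* CI conflates peak count with complexity: two trajectories with equal peak
  counts but very different phase coupling score identically.
* The coverage metric depends on the configured arena; there is no attempt
  to infer well geometry from the data.
* Morphometrics is strictly 2-D; no neurite tracing or MCC detection is
  performed from images — only their exported summary numbers are consumed.
* The pooled-CV inversion assumes pools are means of exchangeable
  individuals; unequal within-pool weighting or compositional effects would
  bias $\sigma$.
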