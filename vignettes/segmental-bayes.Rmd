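---
title: "Segmental Bayesian estimation of network conductances from spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental Bayesian estimation of network conductances from spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segbayes)
```

## The problem

Inferior-olive (IO) neurons fire at about 1 Hz, ride a subthreshold
membrane oscillation, and are electrically coupled to their neighbours
through gap junctions. Two conductances dominate the population firing
statistics: the GABAergic inhibitory conductance $g_i$, which mainly
controls the firing rate and regularity of individual cells, and the
gap-junctional conductance $g_c$, which controls synchrony across
cells. Neither is measurable directly in vivo; both leave a footprint
in extracellularly recorded spike trains. `segbayes` solves the
resulting inverse problem: given paired spike recordings of one neuron
group under a control condition (CON) and under a blocker — picrotoxin
(PIX, removes $g_i$) or carbenoxolone (CBX, removes $g_c$) — estimate
$(g_i, g_c)$ per condition on a discrete grid.

The inverse problem is ill-posed: the firing statistics depend largely
on the ratio of the two conductances, the recordings are
non-stationary, and any network model is vastly simpler than the real
tissue. The pipeline attacks each difficulty with a separate device:

1. a *commonality constraint*: within one neuron, the blocked
   conductance changes but the other one does not, so $g_c$ is shared
   between PIX and CON, and $g_i$ between CBX and CON — a delta-function
   prior that collapses one parameter axis exactly;
2. *segmentation*: the recording is cut into 50-s segments, features
   are computed per segment, and per-segment parameter estimates are
   allowed to jitter around one neuron-level value (a hierarchical
   Gaussian prior whose variances are selected by model evidence);
3. *simulation-based likelihood*: a network simulator is run on every
   grid cell and a Gaussian-mixture density fitted to the simulated
   feature scores serves as the likelihood $P(y \mid g_i, g_c)$.

## Feature vector (68 components)

Per segment and neuron triplet, with per-neuron features averaged over
the three neurons and pairwise features over the three unordered pairs:

| block | size | definition |
|---|---|---|
| FR | 1 | spikes per second in the segment |
| LV | 1 | local variation $\frac{1}{R-1}\sum_r 3(T_{r+1}-T_r)^2/(T_{r+1}+T_r)^2$ of the ISIs $T_r$ |
| ACG | 20 | autocorrelogram, ordered-pair lags binned at 50 ms over 0–1000 ms |
| CCG | 20 | crosscorrelogram, same bins, zero-lag included |
| MD | 25 | histogram of $s_l = 1-\exp(-2\,\min_m\lvert t_l^i - t_m^j\rvert/\bar d_j)$ over 25 equal bins on $[0,1]$ |
| SD | 1 | time-averaged SPIKE-distance (adaptive, parameter-free), in $[0,1]$ |

Choices the definitions leave open, and how this package resolves them:

* **Correlogram normalization.** The raw definitions are pair counts,
  which scale with rate and segment length; counts are divided by the
  reference train's spike count by default (`normalize = FALSE`
  restores raw counts). This keeps the forward model stable across
  firing-rate regimes.
* **Direction of pairwise features.** CCG and MD are asymmetric in
  $(i,j)$; both directions are computed and averaged within a pair
  before the triplet average, so the feature vector is invariant under
  neuron permutation (tested).
* **MD histogram.** 25 equal-width bins on $[0,1]$ with a right-closed
  last bin. For independent Poisson trains the nearest-spike distance
  is Exp($2\lambda$) and $\bar d_j = 1/\lambda$, so $s_l$ is exactly
  uniform — the factor 2 is the two-sided nearest-neighbour correction.
  This uniformity is an acceptance test.
* **Undefined features.** Segments too sparse to define a feature (an
  LV needs 2 ISIs, $\bar d_j$ needs 2 spikes, SPIKE-distance needs a
  spike in both trains) yield an `NA` sentinel and flag the row; flagged
  rows are excluded from forward-model fitting but reported.
* **Triplets.** In the 9-neuron simulated lattice the three rows are
  used (nearest-neighbour triplets); experimental-style 3-neuron
  recordings form a single triplet.
* **Time resolution** is fixed at 0.1 ms for storage and file
  round-trips: finer than the smallest feature bin (50 ms), coarse
  enough that text files reproduce trains exactly.

## The surrogate simulator

The biophysical IO model behind the original study is not published in
the source at hand, so the simulator here is an explicit surrogate that
preserves the two parameters' qualitative roles — nothing more. Each of
the $3\times3$ lattice neurons carries a damped stochastic harmonic
pair $(x, u)$ (subthreshold oscillation, ~4 Hz, damping 0.8/s) around a
baseline $b = b_0 + k_e g_e - k_i g_i$, plus a fast OU fluctuation $z$
(15 ms) standing in for synaptic bombardment; a spike is a threshold
crossing of $b + x + z$, followed by reset and a 20-ms refractory
period. A slow noise term shared across the lattice models common
afferent drive.

Gap junctions act twice, as they do physiologically: *diffusively*
(0.4/s per unit $g_c$ per edge, pulling neighbouring slow potentials
together) and by *spikelet transmission* (each spike depolarizes
lattice neighbours by $0.12\,g_c$). The spikelet pathway matters: pure
diffusion averages away precisely the fluctuations that drive threshold
crossings, so it suppresses firing long before it synchronizes spikes.
With both pathways the firing rate is nearly independent of $g_c$ while
spike synchrony rises steeply with it. Heterogeneity: the oscillator
conductance and each junction weight are jittered uniformly within ±5%.

The constants were fixed once, by inspecting the feature surfaces over
the full grid, to give (i) ~0.3–2.6 Hz firing, decreasing in $g_i$, and
(ii) mean pairwise SPIKE-distance falling from ~0.33 to ~0.07 as $g_c$
goes from 0 to 2. These two monotonicities — the minimal contracts the
inverse problem needs — are tested statistically over seeds. Absolute
conductance maps of the real IO are *not* reproduced and are not
claimed: every quantitative statement the tests make is about
self-consistency (simulate at known $(g_i,g_c)$, recover it).

A second, much faster generator (`generate_fixture` with
`generator = "renewal"`) produces gamma-renewal trains whose rate falls
with $g_i$ ($r = 2/(1+g_i)$ Hz, shape 2) and whose synchrony rises with
$g_c$ (a shared mother train copied with 12-ms jitter, sharing
probability $g_c/(g_c+0.6)$). It exists so unit tests run in seconds;
it makes no pretence of IO dynamics.

## Feature selection and embedding

Mutual information between each feature and the grid label uses the
plug-in histogram estimator: $P(g)$ uniform over populated cells,
$P(x\mid g)$ on 50 shared equal-width bins spanning the pooled range,
base-2 logs, $0\log 0 = 0$. The binning is a package choice (the source
method states only "histogram"). The plug-in estimator has the usual
positive bias $\approx (B-1)(G-1)/(2N\ln 2)$ bits; the independence
tests therefore use sample sizes at which this bias is below the stated
0.05-bit tolerance. Ranking is descending MI with index tie-breaks; the
top $k = 25$ features feed PCA.

PCA is computed on *z-scored* features — the blocks have
incommensurable units (Hz, normalized counts, fractions), so raw
covariance would be dominated by whichever block happens to have the
largest numeric scale. Standardization is switchable
(`standardize = FALSE`). Eigenvalues are also reported as fractions of
total variance. Components follow a largest-loading-positive sign
convention; the top 3 are kept.

## Forward model

Each grid cell's 3-D scores get an independent Gaussian mixture fitted
by variational Bayes (Dirichlet + Gaussian–Wishart conjugate model,
CAVI): `max_K = 20` components over-provisioned, weight concentration
$1/K$, scale prior from the per-cell diagonal variances, covariance
regularization $10^{-6}$, relative tolerance $10^{-5}$, three restarts
(k-means initialization with derived seeds) keeping the highest exact
variational bound. Components with posterior weight under $10^{-3}$
count as pruned when reporting the effective $K$; note that with $n$
points per cell the floor weight of an empty component is
$\alpha_0/(K\alpha_0+n)$, so the reported effective $K$ is only
meaningful for cells with a few hundred points or more. The reported
density uses posterior-mean parameters and is a proper density
(Monte-Carlo integration test).

Goodness of fit per cell is the two-sample energy test with logarithmic
kernel $R(r) = -\ln(r + 10^{-12})$ between the training scores and a
model sample of equal size, with a permutation p-value (the kernel and
permutation count, default 1000, are package choices). The acceptance
suite checks both the null calibration of the test and that ≥90% of
surrogate cells fit at $p > 0.1$.

## Hierarchical inference

Per segment $t$ and condition, the likelihood table stores
$\log P(y(t) \mid g_i, g_c)$ over all grid cells. The segment-level
prior is a product of axis-wise discrete Gaussians centred on the
neuron-level cell, renormalized on the grid; $\sigma = 0$ degenerates
to a point mass. Variance sharing follows the pairing: for PIX the
shared-$g_c$ axes use $\sigma_2$ while $g_i$ uses $\sigma_1$ (CON) and
$\sigma_3$ (PIX); for CBX the shared-$g_i$ axes use $\sigma_1$ while
$g_c$ uses $\sigma_2$ (CON) and $\sigma_3$ (CBX). This asymmetric
pattern is taken verbatim from the source model; a config switch is not
provided because the constrained axes make any other assignment
relabel-equivalent here.

All integrals are grid sums; all accumulation is in log space
(log-sum-exp). The integrated surface for one condition is two small
matrix products per segment, so the exhaustive evidence search over the
$\sigma$ lattice ($\{0, 0.025, \ldots, 0.5\}$ per axis, $21^3$
combinations; bin 0.025 from the source protocol, upper bound from its
stated optimization range, 0 included for the reduction identity) is
cheap: the two conditions depend on disjoint $\sigma$ pairs, so
surfaces are cached per axis value and each combination costs one
log-sum-exp. Evidence ties break toward smaller $(\sigma_1, \sigma_2,
\sigma_3)$ lexicographically; MAP ties break lexicographically along
the constrained axes (effectively smallest $g_i$, then $g_c$). With all
$\sigma = 0$ the segmental model reduces *bit-for-bit* to the
non-segmental model (tested), which is the product-over-segments
likelihood under the delta commonality prior.

**The $\sigma$ lattice must scale with the grid.** The default lattice
upper bound (0.5) is about a third of the full $g_i$ axis range (1.5).
On a reduced grid whose axes span only 0.2, a $\sigma$ of 0.2 or more
makes the renormalized discrete prior essentially uniform regardless of
its centre: the posterior over the neuron-level cell goes flat, the
evidence — which rewards per-segment flexibility — happily selects such
$\sigma$, and the MAP degenerates to the tie-break corner. Reduced-grid
experiments therefore use the proportionate lattice
$\{0, 0.025, 0.05\}$ (same 0.025 bin, upper bound $\approx$ range/3).
This is a geometry requirement, not a tuning knob: it reproduces, at
reduced scale, the relation the full-scale protocol had between its
$\sigma$ range and its grid.

The minimum-error baseline assigns each segment the cell whose nearest
simulated score is closest in 3-D (the vanishing-variance limit of a
one-Gaussian-per-sample mixture) and aggregates per condition by the
mode over segments — the source describes pooling per-segment estimates
into a distribution; the mode is this package's deterministic reading,
with ties toward smaller $g_i$ then $g_c$. The `pca_error_rate` of any
estimate is the mean distance of each data segment to the closest
simulated segment of the estimated cell.

## What the synthetic tests do and do not establish

The acceptance suite builds a reduced world: a 5×5 grid
($g_i \in [0.4, 0.6]$, $g_c \in [0.9, 1.1]$, step 0.05), 200-s
simulations, 10 realizations per cell — minutes on one CPU instead of
the production-scale 5000 s × 1271 cells. Ten realizations (120
segments per cell) is the observed minimum for this grid: with 3, the
per-cell density-estimation error (roughly a nat between neighbouring
cells) exceeds the 0.05-step likelihood signal and even raw
nearest-neighbour assignment scatters. Recovery fixtures are 500-s
paired recordings scored on all three lattice rows (30 segments per
condition), matching how the library pools triplets. Per-segment jitter
in fixtures is *continuous* (clamped at zero), not snapped to the
estimation grid: segments falling between or outside grid cells are
exactly the model mismatch the hierarchical prior is meant to absorb,
and with snapped jitter on a 5-cell axis there are no outliers left to
discount. Within that world the suite checks that the *segmental*
estimator recovers the generating cell within one grid step in ≥80% of
seeded runs, and that under injected per-segment jitter
($\sigma_{true} = 0.1$) the segmental estimator's mean absolute error
does not exceed the non-segmental one — the qualitative ordering that
motivates the hierarchical model. A green suite
establishes internal consistency of the pipeline under a generator with
the right monotone structure; it does not establish that the surrogate
matches IO biophysics, that the estimates transfer to experimental
recordings, or that the original study's numerical results are
reproduced (they depend on an unpublished simulator and on experimental
data, and are out of scope).

## Known limitations

* The surrogate's conductance scale is arbitrary; only on-grid
  self-consistency is claimed.
* The plug-in MI estimator is biased at small samples; rankings are
  robust to this (the bias is shared across features) but absolute bit
  values at library scale should be read with the bias formula in mind.
* Effective mixture size reporting depends on per-cell sample size (see
  above); the production-scale value of ~8–9 components is not
  reproducible at desk scale and is reported, not asserted.
* No off-grid (continuous) estimation, no MCMC, no cross-neuron
  pooling: estimates are per neuron on the grid, as in the source
  method.
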