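---
title: "Color populations as a ground truth for PCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color populations as a ground truth for PCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PCAtruth)
```

## The model

A *color population* is a point $P = (P_1, P_2, P_3) \in [0,1]^3$. An
individual drawn from it is

$$x = P + R \cdot N,$$

with $R$ a fresh standard-normal 3-vector and $N$ the population's noise
scale. The three coordinates are deliberately minimal stand-ins for SNP
dosages: populations are maximally distinct points, within-population
variation is isotropic Gaussian, and the full geometry of the cohort is
known before any analysis runs. The generative notation admits a
multiplicative misreading ($P_i \cdot R \cdot N$); we implement the
additive form, since the multiplicative one would pin every zero
component at exactly zero — Black would be a single point, and Green and
Red would be indistinguishable in their off-components — destroying the
scatter geometry the model exists to provide.

Two deliberate non-features:

* **No clipping to $[0,1]$.** With $N = 0.01$, clipping would halve the
  noise on boundary components (all of them, for saturated colors) and
  bias every centroid inward. Values slightly outside the cube are
  harmless to PCA and keep the moments exact.
* **No allele-frequency realism.** The generator makes no attempt at
  site-frequency spectra, linkage or drift; it provides geometric ground
  truth, not evolutionary realism. Conclusions about *PCA's behaviour*
  transfer; conclusions about specific demographic histories do not.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `noise_sd` | 0.01 | per-component Gaussian SD; raised to 0.02–0.05 for projection/era cohorts and 0.17–0.25 for deliberately heterogeneous test populations |
| ancient era | mean 0.95, SD 0.05 | "brighter" variants of a 0/1 color pattern (higher diversity) |
| modern era | mean 0.60, SD 0.02 | "darker", tighter variants |
| `window_size` | 200 | SNP-like features per color component (600 total) |
| missingness rates | 0.5, 0.9 | entry-wise nullification fractions in the robustness recipes |
| noise-marker grid | 30, 300, 3000 | appended uniform $[0,1]$ markers |
| `K` | $\operatorname{round}(\sqrt n)$ | k-means cluster count, floor 1 |
| k-means restarts | 20 | best-inertia policy |

The era SD applies to all three dimensions of a color, since an era
specifies one SD, not one per component; a pattern with no nonzero
component (Black) keeps its zero mean and only inherits the era's SD.

### Seeds

A cohort has one root seed; each member population draws from a child
seed hashed from (root, member index, member name). Appending a
population therefore never changes the draws of earlier ones — the
property needed to study "the only thing that changed is the random
draw" sensitivity honestly. All randomized operations
(`injectMissingness`, `samplePairDistances`, k-means restarts, the
case-control simulator) take explicit seeds and restore the caller's RNG
state.

## The PCA engine

`fitPCA()` centers columns by their means and decomposes by SVD;
eigenvalues carry the sample $(n-1)$ normalization. There is no
per-marker variance scaling by default (a `scale` flag exists), matching
the plain SmartPCA-style analysis without outlier removal or
normalization. Because an eigenvector's sign is arbitrary, each
component is flipped so its largest-magnitude loading is positive; tests
compare configurations up to rotation/reflection where sign conventions
would otherwise bite.

Percent-variance values are rounded half away from zero for display
(8/9 prints as 89%); comparisons against printed integers use a ±1
percentage-point band.

`projectSample()` maps one held-out sample at a time into a fitted
basis, restricting the center and loadings to the features the sample
observes, then rescaling by $p / p_{\text{obs}}$ so score magnitudes
stay comparable across samples with different missingness. The factor
is configurable; it is exactly 1 for complete samples. No
shrinkage-style correction is applied — the datasets here are small or
LD-free, where projection shrinkage is not the operative problem.
Samples are never projected jointly.

## Distances, clusters, and agreement

Distance reports carry, per pair, the original-space and top-$k$
score-space Euclidean distances on raw (unrescaled) scores. Two exact
properties anchor the module: at $k = r$ the two distances agree
(centering plus orthonormal rotation is an isometry), and at $k < r$ the
PC distance can only contract. Min–max normalization (applied per
column, mapping min to 0 and max to 1) reproduces the 0–1 axes used for
distortion scatterplots; it is undefined, and errors, on constant
columns. The grey-bar distances printed alongside some published color
analyses use an unstated scaling that is inconsistent with raw all-PC
Euclidean distances, so raw plus min–max normalized values are the only
distances this package reports.

Cluster homogeneity follows the square-root rule $K = \sqrt n$, rounded
half away from zero (the rule's source states only "the square root");
a cluster is homogeneous iff its members carry one label. Singleton
clusters are vacuously homogeneous and inflate the metric, so their
count is reported separately. `K` may be recomputed per cohort or fixed
across comparisons — both modes are reachable by passing `K` explicitly.

Configuration agreement between two PCA outcomes is the symmetric
Procrustes sum of squares $m^2_{12}$ (via `vegan::procrustes`): 0 for
identical geometry after translation, rotation/reflection and scaling,
on a dimensionless 0–1 scale. This absorbs the sign and axis-order
flips that plague naive score comparisons.

## Window expansion, missingness, noise

`expandWindows()` spreads each color component across a window of 200
features. The reverse operation is the missing-aware per-component mean.
Two readings of "evenly divided across a window" exist: dividing the
value by 200 (rejected — it shrinks component variance $200^2$-fold
against any per-feature noise and makes recovery from 90% missingness
impossible) and replicating it (implemented). Pure replication makes the
round trip exact, which is the tested invariant; the robustness recipes
additionally draw fresh per-feature noise (SD 0.01) at expansion so each
windowed feature is an independent noisy reading of its component — that
is what makes 90% missingness informative: with ~20 observed replicates
per component the collapse error is $N/\sqrt{20}$, and the recovered
structure is geometrically indistinguishable from the original
(Procrustes disagreement $< 0.05$; measured values are orders of
magnitude smaller).

Noise markers are independent uniform $[0,1]$ features appended to the
**raw three-component** color data. The grid 30 / 300 / 3000 spans
structure-dominated to noise-dominated regimes: by the Marchenko–Pastur
bound, the top noise eigenvalue at $m = 3000$, $n = 300$ is
$\tfrac{1}{12}(1 + \sqrt{10})^2 \approx 1.4$, well above the structure
eigenvalues of the three color components ($\approx 0.5$), so the top
PCs become noise and cluster homogeneity collapses to the chance level
of the label distribution; at $m = 300$ the bound
($\approx 0.33$) stays below the structure and the key features
survive. The explained variance of PC1–PC2 falls monotonically along
the grid. A "low-level noise in all markers" perturbation
(`perturbAllMarkers`) uses a uniform width of 0.1 by default; the
magnitude is not pinned by any source and is exposed as a parameter.

## The case-control experiment

The stratified design mirrors a minority-mismatch scenario: a cohort of
300 Red and 20 Blue individuals, all Blues forced into the control arm,
arms evenly sized at 160. Markers are binomial(2, $f$) with $f$ tied to
the population color means on the logit scale (`structure_spread`), so
marker structure mirrors color structure and the top PCs of the
(window-expanded) cohort correlate with population membership by
construction. Causal markers add a $\pm$`effect_size`$/2$ logit shift
between arms, i.e. a per-allele log-odds difference of `effect_size`.

The default effect size is 0.4, chosen by a Wald power calculation: at
$n = 320$ and typical dosage variance the slope SE is $\approx 0.16$,
putting per-marker power near 0.7 at $\alpha = 0.05$ — high enough to
count true positives, low enough that the adjusted-versus-unadjusted
comparison is not censored at the ceiling (at log-OR 1 every scan finds
every causal marker and the comparison degenerates).

Association is logistic regression with a Wald test on the dosage term
(chosen over contingency statistics because PC covariates must enter the
model); the unadjusted path also reports the Cochran–Armitage trend
statistic as a cross-check. Separation is diagnosed on the dosage
coefficient itself — a diverging estimate or exploding SE — not on
`glm`'s global fitted-probability warning, which fires innocently
whenever covariates fit a few samples perfectly. Separated markers are
excluded from significance counts.

"Worse after adjustment" is operationalized per replicate as: fewer
true positives, more false positives, and a larger median causal
p-value than the unadjusted scan. The experiment grid —
{structured, random} labeling × {2, 10} adjustment PCs × replicate
seeds — is configuration-driven rather than hard-coded, since the
composition of a fixed "12 analyses" set is not derivable from the main
text of any single source.

## The experiment registry

`experimentRegistry()` pins every synthetic test case as data: cohort
colors, sizes, noise SDs, stages, seed. Entries whose published
description gives sizes only as a set (e.g. "$n$ = 50, 5, 100 or 25"
without assignment) or whose color lists contain evident typos (White
given as $[1,1,0]$, Blue as $[1,0,0]$) carry `ambiguous = TRUE` and a
pinned choice; the pinned values are visible in the object and in every
run's manifest. Each run writes scores, distance and cluster tables and
a YAML manifest from which the run is exactly reproducible.

## Problem sizes and test design

The test suite regenerates all fixtures in code. Moment checks use
$10^5$ draws; property loops use 20–100 random mini-cohorts ($n \le 24$,
$p = 3$); the exhaustive clustering oracle enumerates all
$\binom{12}{6} = 924$ relabelings of a 12-sample cohort against a
hypergeometric closed form; the robustness recipes run at the registry's
native sizes ($300 \times 600$); the adjustment experiment uses 20
replicates of 220 markers. These sizes were chosen so the full suite
exercises every contract at comfortable statistical resolution while
remaining a coffee-break run on one core.

## Limitations

* The generator's populations are isotropic Gaussians around fixed
  points; real populations have correlated markers, admixture clines and
  drift. Passing tests certify PCA's geometric behaviour, not the
  biology of any particular dataset.
* Real-data replications (downloaded genotype panels, LD pruning,
  marker-class annotations) are intentionally out of scope; the
  EIGENSTRAT/PLINK readers let users run the same pipeline on their own
  matrices.
* The printed homogeneity percentages and Kruskal–Wallis statistics of
  published human-data analyses require those cohorts and are not
  asserted anywhere; the package reproduces the procedures and their
  qualitative behaviour on synthetic colors.
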