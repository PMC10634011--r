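---
title: "Methods: digital quantification of tau pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital quantification of tau pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taupath)
```

## The problem

Progressive supranuclear palsy (PSP) is a primary 4-repeat tauopathy whose
post-mortem staging rests on semi-quantitative visual grading of tau
pathology. `taupath` implements a fully digital alternative for brightfield
H-DAB immunohistochemistry: it separates stains, detects candidate tau
objects by DAB-optical-density thresholding, describes each object with 54
features, classifies objects into the four PSP tau morphologies — coiled
bodies (CB, oligodendroglial), neurofibrillary tangles (NFT, neuronal),
tufted astrocytes (TA, astrocytic, the PSP hallmark) and tau fragments (TF,
threads not attributable to a cell body) — computes per-region densities,
and relates those densities to pathological stage and clinical severity
(PSPRS) with rank correlations and Bayesian regression.

Because annotated whole slides cannot ship with a package, a synthetic
slide simulator is a first-class component: it renders H-DAB-like tiles
with exact ground truth so that every downstream stage is tested
quantitatively.

## Stain model

Brightfield absorbance follows Beer–Lambert: transmitted intensity per RGB
channel is $I = I_0\,10^{-M^\top c}$, where the rows of $M$ are unit
optical-density (OD) stain vectors (haematoxylin, DAB, and a residual
vector completed as the normalised cross-product of the two dyes) and $c$
holds per-stain densities. `rgb_to_od()` uses
$\mathrm{OD} = -\log_{10}((I+\varepsilon)/I_0)$, clipped at zero, with a
one-grey-level guard $\varepsilon = I_0/255$ so OD stays finite at zero
intensity; `deconvolve()` solves the exact 3×3 linear system per pixel and
clips negative densities to zero (absorbance is non-negative). With the
guard disabled the mixing/unmixing pair is exact to numerical precision,
which the tests verify at 1e-6. The default stain vectors are the standard
published H-DAB pair; they are configurable because scanners and staining
batches differ.

Feature extraction sees seven channels: R, G, B on the unit scale, DAB and
haematoxylin OD, brightness (RGB mean) and saturation
((max−min)/max, 0 for black). Brightness/saturation follow the
hue–saturation–brightness convention since no sharper definition is
standard.

## Detection

Tau objects are pixels whose (optionally Gaussian-smoothed) DAB OD is
*strictly above* the threshold, grouped into connected components inside
the region mask. Defaults mirror a standard thresholder configuration:
threshold 0.25, no smoothing (sigma 0 skips the filter entirely), minimum
object size 5 µm². Connectivity defaults to 8 so that thin diagonal TF
threads survive as single objects. Holes inside components are retained —
CB annuli are morphologically meaningful — and object area counts only
supra-threshold pixels, exactly `n_pixels * mpp^2`. Components are ordered
by the scan position of their first pixel, so detection is deterministic.

## The 54-feature vector

Six morphology features, 35 intensity statistics (min, max, mean, median,
population SD for each of the 7 channels), and 13 Haralick texture
features on the DAB channel, in a fixed documented order
(`feature_names()`).

Morphology conventions, chosen where the source material leaves the
geometry unspecified:

* **Length** is the boundary of the pixel mask measured as the total
  length of exposed pixel edges (the "crack" boundary), including hole
  boundaries. This makes a 10×10-pixel square at 1 µm/px have perimeter
  exactly 40 µm and a single pixel 4·mpp, both of which pin the
  definition. The trade-off is deliberate: a crack boundary overestimates
  the length of smooth curves (a digitised disc measures ≈ 8r rather than
  2πr), so circularity $4\pi A/L^2$ of a disc sits near 0.62 rather than
  1. An alternative smoothed-contour perimeter would flip both
  properties; only one convention can hold, and the exact pixel-boundary
  arithmetic was kept because it is reproducible bit-for-bit and
  internally consistent across object sizes. Classification is
  unaffected — features only need to rank shapes consistently.
* **Max/min diameter** are rotating-calliper (Feret) diameters of the
  convex hull of the pixel corner points; **solidity** is mask area over
  that hull's area. A digitised convex shape's pixel union is itself
  slightly non-convex, so disc solidity sits a little below 1 (~0.95 at
  r = 20 px); rectangles give exactly 1.

Haralick features use per-object min–max rescaling, 32 grey levels,
distance 1, the four symmetric directions, base-2 logarithms, and
direction-averaged features — standard texture-analysis defaults, since
only the feature list itself is prescribed. Constant objects receive the
deterministic limits ASM = IDM = 1 and zero for every spread or entropy
term, with correlation defined as 0 at zero variance, so training never
sees undefined values. All 13 features are verified against a brute-force
double-loop GLCM oracle at 1e-10.

## Classification

The screening stage (tau vs non-tau) and four region-specific typing
stages (cortex, putamen, STN/GP, dentate; the latter two without TA,
which is essentially absent there) are balanced random forests:
probability forests whose per-tree bootstraps under-sample majority
classes to the minority count. The under-sampling strategies mirror the
imbalanced-learning conventions: `auto` (= not minority) and `all`
equalise every class, `not majority` spares the largest class,
`majority` reduces only the largest. The forests are fitted with
`ranger` using class-wise bootstrap fractions; the balanced-bootstrap
semantics themselves are implemented and tested in the package.

Hyper-parameters are tuned by random search over the full printed
candidate space with stratified k-fold cross-validation; within each
fold, standardisation is fitted on the training split only, recursive
feature elimination (dropping the 2 least important features per
iteration by impurity importance; elimination forests capped at 300
trees since only the ranking matters) reduces to the candidate's feature
count, and the held-out fold is scored by mean one-vs-rest PR-AUC
computed with the average-precision step rule. The best candidate is the
first sampled maximiser. The final model refits standardisation and
feature selection on the full training set.

Decision rules: the screening model uses plain argmax with ties broken
toward tau (screening should keep candidates). Typing models use
threshold-moving: per class, the score threshold maximising one-vs-rest
F1 along the PR curve, evaluated on the grid of observed scores with
ties broken toward the smallest threshold (maximises recall at equal
F1), tuned on the final forest's out-of-bag scores. An object passing
exactly one class threshold gets that label; zero or multiple passes
yield *Ambiguous*, which is excluded from every downstream count while
the region area is unchanged.

## Quantification and staging correlation

Density is objects per µm² of the quantified region (grey matter for
cortex, whole nucleus otherwise); total tau sums all four types and the
hallmark aggregate excludes TF. Densities are log10-transformed before
regression because they are strongly right-skewed; zeros are floored at
half the smallest positive density observed (recorded in the output) —
the handling of zeros is this package's choice. Spearman correlations
use mid-ranks for ties and a two-sided t-approximation p-value, and are
checked against a rank-then-Pearson oracle; being rank-based they are
invariant to any strictly monotone transform of density, which is
property-tested.

## Bayesian clinicopathological analysis

The clinical model is a Gaussian linear regression of the last PSPRS
total on neuropathology (categorical stage with stage 2 as reference, or
a log tau density) with disease duration and the PSPRS-to-death interval
as covariates. "Mixed" appears in the original model naming but the
stated formulas carry no grouping term, so the model is fixed-effects
with a disabled donor-grouping hook. Priors: normal(0, 100) on
coefficients (50 and 150 as sensitivity settings), student-t(3, 53.5,
12.6) on the intercept and half student-t(3, 0, 12.6) on sigma — the
intercept location/scale default to the outcome median and MAD when not
given. The intercept prior applies to the intercept of the
*mean-centred* design matrix, the convention of standard Bayesian
regression software; the intercept is mapped back to the natural scale
afterwards. Coefficients are reported on the natural scale (an optional
standardisation switch was considered and rejected to keep coefficients
in PSPRS points).

Sampling uses JAGS with 4 chains and 10,000 warmup + 10,000 retained
iterations per chain for the full analysis; simulation studies in the
tests use reduced budgets behind the same convergence gate (split-chain
potential scale reduction < 1.05; non-convergence warns, never returns
silently). The ROPE is ±0.1 of the outcome SD over included records —
[−1.24, 1.24] PSPRS points for the 28 complete donor records — and a
coefficient is practically null only if its 95% credible interval lies
fully inside. The reported ROPE percentage is the share of
credible-interval draws inside the ROPE.

Model comparison uses marginal likelihoods computed deterministically:
coefficients are integrated analytically conditional on (sigma,
intercept) via the conjugate Gaussian step, and the intercept and sigma
are integrated by two-dimensional Gauss–Legendre quadrature in their
prior-quantile domains (48 nodes per dimension). This makes BF(A, A) = 1
exactly and log BF antisymmetric by construction, with the conventional
3 and 1/3 evidence cut-offs. A bridge-type stochastic estimator was
rejected: at this problem size the quadrature is cheaper and has no
warm-up sensitivity.

One printed figure reports a ROPE of ±1.26 for a subcortical subset
without stating the records or standardisation that produce it; both
values are accepted as configuration inputs and no guess is made.

## What the simulator does and does not emulate

`generate_tile()` plants non-overlapping objects (1-pixel separation so
8-connected components stay distinct) with class-specific morphology:
CB as small compact discs or annuli (20–60 µm²), NFT as elongated
flame-like ellipses (70–160 µm², aspect 2.5–4), TA as large stellate
shapes with 5–9 radial arms (200–450 µm²), TF as thin curvilinear
random-walk threads, non-tau artefacts as granules absorbing in DAB
*plus* residual (off the DAB colour vector), and haematoxylin nuclei as
scenery. Objects carry multiplicative within-object density texture and
tiles get additive Gaussian OD noise (SD 0.02, applied before
exponentiation and clipped at 0). No quantitative size distributions are
published for the four types, so these ranges are engineering choices
made once: they respect the qualitative descriptions (CB smaller than
NFT; TA largest; TF thread-like) and are deliberately separable.

Passing tests on this simulator therefore demonstrate that the
*machinery* is correct — detection is exact, features are oracle-equal,
the classifiers recover separable classes, densities and correlations
follow their definitions — not that the pipeline reaches any particular
accuracy on real slides, where class overlap, staining variability,
iron-granule confounds and annotation ambiguity dominate. The study's
own performance tables require its slides and are out of scope here.

## Problem sizes and numerical choices in the test-suite

The suite trains on a synthetic cohort of 10 donors × 4 region groups
(320×320 px tiles at 0.5 µm/px, one tile per donor and region; the
STN/GP profile is TF-dominated to stress imbalance) and evaluates on 3
held-out donors; tuning uses 3 random-search candidates and 5 stratified
folds. These sizes give roughly 40–300 training objects per class and
region, chosen so per-class thresholds are estimated from adequately
populated out-of-bag scores. Bayesian simulation studies use n = 30
cohorts (coverage) and n = 200 (prior washout) with reduced MCMC budgets
behind the convergence gate. The clinical analysis always runs at the
full 4 × 20,000-iteration budget.

## Known limitations

* The crack-boundary length convention overestimates smooth-contour
  perimeters (see above); circularity is consistent but not comparable
  with smoothed-polygon implementations.
* `label`/`screen_label` are prediction columns; ground-truth classes
  from the simulator are kept in `class` to avoid collisions.
* The marginal-likelihood quadrature covers Gaussian coefficient priors
  with the package's intercept/sigma priors; other prior families would
  need the bridge-type estimator.
* The simulator does not model slide-preparation artefacts (folds,
  bubbles), stain bleed-through beyond the linear model, or whole-slide
  pyramids; region masks are inputs throughout.
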