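---
title: "Methods: maximum-entropy suitability, habitat dynamics and niche overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy suitability, habitat dynamics and niche overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the model
and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the
design decisions taken where the design was genuinely open.  It states
no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The presence–background maximum-entropy model

Given `m` presence cells and `N` background cells drawn from the study
region, the model maximizes over coefficients $\beta$

$$\frac{1}{m}\sum_{\text{presences}}\eta(x)\;-\;
  \log\!\!\sum_{\text{background}}\!\!e^{\eta(x)}\;-\;
  \sum_j \lambda_j |\beta_j|,
  \qquad \eta(x)=\sum_j \beta_j f_j(x).$$

This is the Gibbs/maximum-entropy estimator: the raw output
$q(x)=e^{\eta(x)}/Z$ is the distribution over background cells closest
to uniform (maximum entropy) among those matching the presence feature
means to within the per-feature slack implied by $\lambda_j$.  Its
assumptions are the usual ones of the presence–background design:
occurrences are an unbiased (after thinning) sample proportional to
occupancy, the background characterizes available environment, and the
response is stationary across the region.

**Features.**  Each climate variable is min–max scaled to $[0,1]$ on
the combined presence+background training sample.  Classes: linear
($z$), quadratic ($z^2$), product ($z_a z_b$), forward/reverse hinges
$\max(0,(z-k)/(1-k))$ and $\max(0,(k-z)/k)$, and step (threshold)
functions $\mathbf 1(z>k)$, with knots at up to 50 empirical quantiles
per variable per direction (`n_knots`, config-exposed).  Features
constant on the training sample are dropped.  Keeping every feature in
$[0,1]$ makes the penalty scaling meaningful and bounds the curvature
of the log-partition term.

**Penalty.** $\lambda_j = \mathrm{RM}\cdot r_{\text{class}}(m)\cdot
s_j/\sqrt m$, where $s_j$ is the feature's standard deviation over the
presences and $r_{\text{class}}$ interpolates the published per-class
default tables (linear/quadratic/product: 1.0 at $m=10$, 0.2 at 30,
0.05 at 100; hinge: 0.5; threshold: 2.0 at $m=0$ to 1.0 at 100),
shipped in `default_regularization()` and editable.  The
regularization multiplier RM scales all of them globally.

**Logistic output.** The mapped habitat suitability index is
$L(x) = c\,q(x)/(1+c\,q(x))$ with $c=e^{H}$, $H$ the entropy of $q$
over the training background.  A null model ($\beta=0$) therefore
scores exactly $0.5$ everywhere, and $L$ is a monotone transform of
$q$, so both outputs rank cells identically.  Projection onto new
climates clamps each variable to its training range by default;
clamping is the conservative choice for extrapolated scenario cells
and can be disabled.

## 2. Solver and numerical choices

The negated objective is convex.  `src/solver.cpp` implements a
working-set proximal-Newton method: an exact Hessian of the
log-partition term on the active feature set, an L1-penalized
quadratic subproblem solved by coordinate descent, an Armijo line
search on the true objective, and full Karush–Kuhn–Tucker (KKT) checks
that pull violating features into the working set.  Numerical
contract and safeguards:

* **Convergence** is declared at KKT stationarity residual
  $<10^{-6}$ (`tol`); the unit tests verify agreement with brute-force
  optimization of the same objective to $10^{-3}$ or better (observed
  $\sim10^{-6}$).  Objective-change stopping rules were tried first
  and rejected: they left coefficients $\sim4\times10^{-3}$ from the
  optimum.
* **Zero coefficients are exact** (soft-thresholding), so the
  parameter count `k` used by AICc is well defined.
* **`sd_floor = 0.05`** bounds $s_j$ from below on the 0–1 feature
  scale.  Without it, features almost constant over the presences get
  a vanishing penalty and quasi-separable configurations have their
  optimum at infinity.
* **`beta_max = 200`** is a box safeguard far above any ordinary fit
  (typical $|\beta|\lesssim 30$): completely separated data stop at
  the bound — with a warning naming the cause — instead of diverging.
* **Curvature subsampling**: when the active set is large the Hessian
  uses a deterministic stratified background subsample plus the
  highest-probability cells; the gradient (and hence the KKT check) is
  always exact, so this affects speed, not the solution.

## 3. Tuning, evaluation, aggregation

Candidates are the 8 regularization multipliers (0.5–4 by 0.5)
crossed with six feature-class sets (L, H, LQ, LQH, LQHP, LQHPT).
Each candidate is fitted to **all** presences (tuning uses no data
split, matching the AICc semantics of ENM tuning practice) and scored
by AICc with the raw output renormalized over every valid study cell:
$\ell=\sum_i \ln \hat q(x_i)$, $k=\#\{\beta_j\neq0\}$,
$\mathrm{AICc} = 2k - 2\ell + 2k(k+1)/(n-k-1)$, $+\infty$ when
$k \ge n-1$.  The candidate with $\Delta$AICc $=0$ wins; ties break by
smaller $k$, then smaller RM, then feature-class order as listed.
Within a feature class the RM path is fitted from strong to weak
penalty with warm starts, and all six classes reuse column subsets of
one master feature matrix.

Evaluation uses 15 random 75/25 presence splits against one shared
background draw (a config flag allows redrawing per replicate;
sharing reduces between-replicate variance and the source description
is silent on this).  AUC is the tie-corrected Mann–Whitney statistic;
TSS is maximized over all observed score thresholds, with sensitivity
counted as score $\ge t$ on test presences and specificity as score
$< t$ on background — the max-TSS convention, since no fixed
threshold is stated; a fixed threshold can be supplied instead.
Replicate maps are aggregated by cellwise arithmetic mean.

## 4. Variable selection and key factors

Pairwise Pearson correlations are computed on the
presence+background sample by default (config-exposed; the modelling
sample is what the collinearity actually acts on).  Elimination is
greedy: while any retained pair has $|r|>0.7$, the worst pair loses
its lower-contribution member (ties: lexicographically later name).
An elimination order had to be fixed because the rule's source
describes only the pairwise criterion; highest-$|r|$-first is
deterministic and order-insensitive, and the tests check equivalence
against an independent re-implementation.  Contributions for
tie-breaking come from a cheap all-variables pilot fit (LQ, RM 1).

Variable importance of the final model is the leave-one-variable-out
drop in regularized training gain, floored at zero and normalized to
100% — chosen over the path-dependent native "percent contribution"
because it is algorithm-independent and reproducible; with-only and
without jackknife gains are reported alongside.  Variables
contributing more than 10% are flagged as *key climate factors*, and a
pair's *common key factors* are the set intersection.

## 5. Habitat classes, areas, typologies

HSI bins are lower-closed with the top bin closed:
$[0,0.25)$ not, $[0.25,0.5)$ low, $[0.5,0.75)$ moderate,
$[0.75,1]$ high — the printed class edges overlap at the boundaries,
so a convention had to be chosen, and lower-closed keeps 0.25 "low"
and 1.0 "high".  Area percentages are cell counts over the region
mask (cosine-latitude weighting is available but off by default:
plain counting mirrors fixed-resolution reclassify-and-count GIS
workflows).  *Suitable habitat* is moderate + high.  The trend
typology compares unrounded values: *growing* if every future
scenario exceeds the current value strictly, *declining* if every one
is strictly below, else *fluctuating*.  Strictness makes the label
deterministic; the same rule serves habitat areas and overlap values.

## 6. Niche overlap and inference

Schoener's $D$ is computed on the replicate-mean logistic maps,
restricted to cells valid in both maps, each map normalized to sum
to 1 there.  The normalization domain (pairwise intersection rather
than the full region) is config-exposed; the intersection is the only
domain on which both distributions are defined.  $D$ is symmetric,
scale-invariant, 1 for identical and 0 for disjoint distributions;
overlap classes use the same lower-closed five-bin convention
(0.2/0.4/0.6/0.8).

Across-pair inference: classical one-way ANOVA, then Tamhane T2 —
pairwise Welch $t$ statistics with Welch–Satterthwaite degrees of
freedom against the two-sided critical value at the Šidák-adjusted
per-comparison level $\alpha' = 1-(1-\alpha)^{1/m}$ ($m$ pairs).  T2
with Šidák is the SPSS "Tamhane" procedure, which is what "the
Tamhane test" conventionally denotes.  The compact letter display is
built by insert-and-absorb on the non-significance graph, letters
ordered by decreasing group mean; a zero-variance pair with equal
means is non-significant by convention.

## 7. The synthetic world

The generator emulates the statistical structure the analysis
assumes, not any real landscape:

* **Climate layers**: white noise smoothed by FFT kernel convolution
  to correlation length `range_len` (default 10 cells on the default
  100×100 grid), empirically whitened and mixed through the Cholesky
  root of a target correlation matrix (default AR(1)-style,
  $\rho=0.6$), then rescaled — half the layers temperature-like
  (mean 8 °C, SD 6), half precipitation-like (mean 400 mm, SD 120,
  clamped at 0).  Whitening before mixing makes realized pairwise
  correlations equal the targets essentially exactly; without it,
  spatial autocorrelation leaves $O(0.15)$ sampling noise on a
  100×100 grid.
* **Species**: the true linear predictor is a sum of quadratic
  (Gaussian-niche) responses on one temperature-like and one
  precipitation-like layer, curvature weight 3, optima at +0.8/−0.4
  standardized units.  Weight 3 was chosen once, on realism grounds:
  it produces narrow endemics occupying single-digit to low-teen
  percentages of the region with fitted AUC near 0.9 — the regime of
  the endangered-holoparasite study system this package targets —
  whereas flatter niches (weight ≈ 1.5) give diffuse species
  (≈ 19% suitable area) that no tuned model can separate from
  background at AUC 0.85.
* **Presences**: cells drawn with probability proportional to true
  suitability (with replacement; duplicates are what spatial
  rarefaction then removes), jittered uniformly within the cell.
* **Futures**: temperature shifted by a stated warming plus a smooth
  anomaly field (SD 0.3 °C), precipitation scaled multiplicatively
  and clamped at 0; the four default scenarios span +1.0 to +3.2 °C
  and ×1.03 to ×1.09, a low-to-high emissions contrast.  Each
  scenario is the equally-weighted ensemble of 3 perturbed members,
  mirroring a small multi-model ensemble.
* **Pairs**: the host gets the default optima; the parasite the same
  optima shifted by `offset_delta` in standardized environmental
  space, so truth-level overlap decreases monotonically in the
  offset.

What a green test does **not** establish: the generator has no
sampling bias, no spatial sampling gaps, no observation error in
coordinates beyond within-cell jitter, torus-wraparound edge
artifacts in the fields, Gaussian marginals rather than the skewed
marginals of real bioclim layers, and niches that are exactly
representable by the model's own quadratic features.  Recovery
results on it are therefore an upper bound on real-data performance —
they validate the machinery, not field skill.

## 8. Determinism and seeds

Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds by a stable string hash of (master seed, stage,
species) so stages are independently reproducible, and every output
CSV records the config hash and master seed in a comment line.  Two
runs with the same config and seed are byte-identical (tested).

## 9. Known limitations

* One CRS (WGS84 decimal degrees); no reprojection.
* Rarefaction thins at the raster lattice; an explicit metric grid is
  approximated by choosing an equivalent cell size rather than true
  geodesic distance.
* No spatial cross-validation (checkerboard partitions), no
  sampling-bias surfaces, no cloglog output, no categorical features.
* The box safeguard means a completely separated fit returns bounded
  (large) coefficients with a warning rather than an error; its AICc
  typically removes it from model selection.
* ANOVA across pairs treats per-scenario overlap values as
  independent replicates, as the source analysis does; scenarios
  derived from one current climate are not truly independent.
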