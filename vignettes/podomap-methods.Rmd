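---
title: "Methods: ensemble suitability mapping and binomial geostatistics in podomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble suitability mapping and binomial geostatistics in podomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(podomap)
```

podomap maps a rare, environmentally limited disease in two stages: an
ensemble species-distribution model turns village endemicity records and
gridded environmental covariates into a suitability surface and a binary map
of environmental limits; a binomial logistic geostatistical model then turns
village case counts and that suitability surface into prevalence,
exceedance and burden maps. This vignette is the package's account of the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The suitability stage

Villages are endemic (1) when at least one confirmed case was recorded,
non-endemic (0) otherwise. Because true absences are scarce and uncertain,
training data are augmented with *pseudoabsences* drawn from terrain
presumed unsuitable. Presumed unsuitability is defined by the surface range
envelope: for each covariate, the interval between the 5th and 95th
percentiles of the values observed at endemic villages (percentiles use the
standard linear interpolation between order statistics, `quantile()` type
7). A cell is inside the envelope only if *every* covariate lies within its
interval; pseudoabsence sets (five sets of 500 points by default; surveyed
cells are excluded from candidacy) are uniform draws without replacement
from the outside cells, independent across sets.

Before training, covariates are screened for collinearity: of every pair
with |Pearson r| > 0.8 over presence plus background cells, the member with
the smaller absolute loading on the leading principal component is dropped.

Each pseudoabsence set is pooled with the presences and surveyed absences
and split into stratified 80/20 calibration/evaluation partitions
(`n_splits` per set, so 5 sets x 10 splits = 50 runs per learner by
default). Classes are weighted to an effective prevalence of 0.5, the usual
convention when pseudoabsences outnumber presences (the random forest
ignores case weights; its bootstrap makes weighting awkward and its rankings
are insensitive to it). Learners:

* **GLM** — binomial logistic regression with linear terms;
* **BRT** — gradient-boosted trees, learning rate 0.005 and interaction
  depth 4 (slow learning with enough interaction depth to capture up to
  four-way covariate interplay), bag fraction 0.5, tree count chosen by
  early stopping on an internal 20% validation split (capped at
  `max_trees`);
* **RF** — 500-tree random forest;
* **maxent** — optional adapter: a ridge-penalised logistic model on
  presence/background, an approximation rather than a reimplementation.

Evaluation on the held-out 20% uses the rank (Mann–Whitney) AUC with half
credit for ties, plus TSS and PCC at the member's own max-TSS threshold.
Members with AUC below 0.8 are excluded; the ensemble is the per-pixel
AUC-weighted mean of the rest, and per-pixel uncertainty is the unweighted
2.5–97.5 percentile band across kept members (the interval construction is
the package's choice; nothing canonical exists for ensemble bands).
"Best trade-off between sensitivity, specificity and PCC" is
operationalised as the threshold maximising TSS, ties broken by higher PCC
and then by the lower threshold; the suitability surface is binarised at
that threshold (suitable iff mean suitability >= threshold).

## The geostatistical stage

Within the environmental limits, counts follow

$$Y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
\mathrm{logit}(p_i) = \alpha + \beta\, s(x_i) + S(x_i) + Z_i,$$

with $s$ the ensemble suitability, $S$ a zero-mean stationary Gaussian
process with covariance $\sigma^2 e^{-d/\phi}$ (exponential correlation,
planar Euclidean distance on the grid coordinates), and $Z_i$ iid
$N(0, \tau^2)$ nugget effects capturing village-level extra-binomial
variation. This is the standard model-based-geostatistics formulation for
prevalence surveys.

**Estimation.** The marginal likelihood integrates over the latent effects
$T = S + Z$ at the villages. We first maximise its Laplace approximation
(inner Newton for the latent mode with step halving, warm-started across
outer Nelder-Mead iterations; the variance parameters are optimised on the
log scale). The Monte-Carlo refinement then simulates the latent effects
from their exact conditional distribution at the Laplace optimum —
preconditioned MALA in the whitened space of the Laplace precision, step
size adapted to ~57% acceptance during burn-in (1000 iterations, thinning
5, 500 kept samples by default) — and re-maximises the Geyer likelihood
*ratio* estimate under common random numbers; at the expansion point the
importance weights are identically one, which keeps the ratio well behaved
near the optimum.

**Standard errors** come from the numerical Hessian (central differences) of
the *Laplace-approximate* log-likelihood at the final estimate, not of the
Monte-Carlo ratio. With survey-scale binomial denominators the Laplace
curvature tracks the exact likelihood closely (we verified on simulated
surveys that the two profile log-likelihoods over $\phi$ agree to a fraction
of a unit), whereas the curvature of a finite-sample Monte-Carlo ratio is
systematically too sharp — a Jensen-type artefact that produces
anti-conservative intervals. Wald intervals are reported directly for
$\alpha, \beta$ and on the log scale (back-transformed) for
$\sigma^2, \phi, \tau^2$. When a variance component collapses to the zero
boundary the log-scale machinery degenerates; those parameters instead get a
one-dimensional likelihood-scan interval (others held at their estimates,
drop of $\chi^2_{1,0.95}/2$), with a lower bound reported as 0.

Parameters can be fixed (`opts$fix`), e.g. `list(sigma2 = 0)` for a
nugget-only model or `list(beta = 0)` for a likelihood-ratio null; with both
variance components fixed at zero the fit reduces exactly to `glm()`.
Duplicate village coordinates are an error by default (`duplicates =
"jitter"` to perturb).

**Prediction** is plug-in conditional simulation at the estimates: latent
village effects are drawn from their Gaussian (Laplace) approximation, the
spatial process is extended to prediction cells by conditional Gaussian
simulation (the nugget, being village-level noise, is excluded from spatial
prediction), and draws are mapped through the inverse logit. Surfaces report
the mean, percentile (not normal-approximation) 2.5/97.5 bounds, sd,
mean/sd ("number of standard errors", our reading of that map), and the
exceedance probability — the fraction of draws above the policy threshold
(1% by default). `n_sim` below 100 is refused because percentile intervals
become unstable. Cells outside the binary limits are not predicted.
Parameter uncertainty in $(\alpha,\beta,\sigma^2,\phi,\tau^2)$ is *not*
propagated (a deliberate plug-in choice; the dominant uncertainty at survey
scale is the latent field).

**Validation.** The empirical semivariogram of empirical-logit residuals
$\log\{(y+0.5)/(n-y+0.5)\} - (\hat\alpha + \hat\beta s)$ is compared with
curves from random permutations of residuals over locations. Residuals are
taken on the empirical-logit scale because the spatial effect is additive
there with stable variance; on the natural scale high-prevalence villages
dominate the semivariance and mask short-range structure. The envelope is
*simultaneous*: permutation curves are ranked by their maximum standardised
deviation from the permutation mean and the envelope spans the least extreme
95%, so "the observed curve stays inside the envelope at every bin" holds
with familywise probability 0.95 under exchangeability — a pointwise
envelope would not have that property. Default: 8 distance bins up to half
the maximum pair distance, 999 permutations.

## The raster engine

Grids are an in-memory matrix plus upper-left origin and square cell size;
two grids are aligned iff origin, cell size and shape match; cell membership
is half-open on both axes. I/O uses plain-text ESRI ASCII rasters
(`.asc`) — single-band, widely readable, and free of binary-format
dependencies. Nearest-neighbour alignment assigns each template cell the
value of the source cell with the nearest centre. Distance-to-features is
the exact two-pass lower-envelope Euclidean distance transform (O(cells)),
so it equals the exhaustive minimum over feature cells to machine precision.
Flow direction is D8: steepest positive descent among the 8 neighbours with
slope = drop/distance x 100 and diagonal distance cell x sqrt(2); ties break
by a fixed clockwise-from-east scan order (E, SE, S, SW, W, NW, N, NE, coded
1–8; 0 = sink), which makes the drainage graph deterministic and acyclic.
Accumulation counts upstream cells with unit weights (Kahn's algorithm; a
cycle, impossible for genuine strict-descent directions, is reported as
corrupted input). Missing data propagate: a derived cell touching nodata is
nodata. Reprojection, D-infinity routing and sink filling are out of scope.

## The synthetic-landscape generator

`sim_config()` fixes the whole synthetic world: covariates are standardised
Gaussian random fields (white noise smoothed by a Gaussian kernel of
length-scale 6 cells by default, via circular FFT convolution; length-scale
0 gives white noise; the grid must be wide enough for the kernel).
`simulate_hydro_covariates()` optionally rebuilds the distance-to-water and
flow-accumulation layers from auxiliary smooth fields using the raster
engine itself, so those derivations are exercised end to end. True
suitability is $\mathrm{logistic}(-2.5 + c^\top X)$ with coefficient norm
about 1.9 — chosen once so that most of the landscape is unsuitable with a
suitable minority, mirroring a country where only a few percent of the
landmass is suitable. The latent field $S$ is simulated *exactly* (dense
Cholesky up to 2500 cells, 2-D circulant embedding above that, padding
doubled until the embedding spectrum is non-negative, error otherwise).
Surveys sample distinct cells uniformly; the nugget is realised as a
village-level logit perturbation *before* the binomial draw, matching its
interpretation as non-spatial extra-binomial variation. Population is
log-normal over a smooth field, the adult (>= 15 y) fraction a smooth
surface around 0.55, and admin units are Voronoi cells of seeded points
(contiguous, covering). Defaults mirror a national mapping survey: 48
villages, 44–311 examined each, logit intercept $\alpha = -6$ and
suitability effect $\beta = 4$, $\sigma^2 = 1$, $\phi = 0.15 \times$ grid
width, $\tau^2 = 0.1$ — rare-but-present prevalence with villages mostly
carrying a handful of cases.

What passing tests on this world do **not** show about real data: the
generator has no sampling bias, no covariate measurement error, no
misdiagnosis, geodesic distances or realistic demography; covariates are
stationary and the prevalence model is exactly the fitted model. Two
consequences observed on the defaults are worth noting. First, with
$\alpha = -6$ and a few hundred examined per village, even unsuitable
villages record a case reasonably often, so endemicity labels are noisier
relative to the environment than in a real mapping survey where the disease
is impossible without the exposure; member AUCs on default synthetic
surveys therefore sit near, not above, the 0.8 inclusion cut. The pipeline
consequently treats the cut as non-strict by default (if no member passes,
the best member is kept and a warning is logged; `ensemble$strict_auc_cut =
TRUE` restores the hard error), while `build_ensemble()` itself always
errors. Second, the demonstration pipeline enlarges the survey to 150
villages so held-out AUCs are estimable; the generator's own default stays
at the survey-like 48.

## Problem sizes and runtime choices

The shipped tests run the parameter-recovery study at 25 replicates of 300
villages on a 60 x 60 km grid (about 9 s per Monte-Carlo fit on one CPU),
the variogram level check at 100 replicates of 100 villages with 199
permutations, and its power check at 20 replicates; the full suite takes
about five minutes. These sizes were chosen as the smallest at which the
statistical claims are meaningfully testable: coverage of 95% intervals is
asserted at the 80% level per parameter, which absorbs both Monte-Carlo
noise at 25 replicates and the genuine skewness of the range-parameter
likelihood on a domain only ~7 correlation ranges wide (occasional
realisations place the likelihood maximum far from the generating $\phi$,
and no honest interval covers on those).

## Known limitations

* Exceedance and interval maps are plug-in: parameter uncertainty is not
  propagated into the predictive draws.
* The MaxEnt adapter is a penalised logistic approximation, not MaxEnt.
* The variogram check validates the *absence of residual structure*, not
  the exponential family itself.
* Burden assumes a single adult fraction per cell; no further age
  structure. Population at risk counts all ages within suitable cells while
  case estimates use the adult population — the consistent reading of
  burden tables that mix the two.
* Grid coordinates are planar; real-world longitude/latitude inputs must be
  projected beforehand.
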