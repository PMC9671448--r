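---
title: "Methods: linked multilevel and spatial analysis of caesarean delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked multilevel and spatial analysis of caesarean delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cslink)
```

`cslink` packages the full analytical chain used to study caesarean section
(CS) use from linked household-survey and health-facility data: geolinkage,
PCA service scores, a three-level Bayesian logistic model with variance
partitioning, a hotspot suite, and spatially varying coefficient regression.
This vignette records the model, the tunable parameters, the numerical
choices, and what the synthetic-data validation does and does not
demonstrate.

## The three-level model

Women (level 1) are nested in survey clusters (level 2) nested in regions
(level 3). The binary outcome is CS use at the most recent birth:

$$\mathrm{logit}\,P(y_{ijk}=1) = \mathbf{x}_{ijk}'\boldsymbol\beta
 + u_j + v_k + \textstyle\sum_s a_{js} x_{ijks} + \sum_s b_{ks} x_{ijks},$$

with cluster intercepts $u_j \sim N(0, \sigma^2_C)$, region intercepts
$v_k \sim N(0, \sigma^2_R)$, and optional per-covariate random slopes
$a_{js}, b_{ks}$ with independent variances per covariate per level (no
slope–intercept correlation: this matches the reported per-variable
cluster/region variance rows and keeps the Gibbs updates conjugate). Priors
are weakly informative: $\beta \sim N(0, 1000)$ and every variance
$\sim \mathrm{InverseGamma}(0.01, 0.01)$.

### Sampler

The paper-scale software this mirrors exposes only its chain configuration,
not its transition kernel, so the kernel here is the package's own design:

* **Fixed effects** — component-wise random-walk Metropolis against the
  full-data likelihood.
* **Random effects** — a vectorized single-site sweep: all cluster effects
  are proposed and accepted/rejected simultaneously, valid because clusters
  are conditionally independent given the region effects and $\beta$;
  likewise for regions and each slope vector. Group-wise log-likelihood
  differences are computed by cumulative-sum aggregation over data sorted by
  (region, cluster), making each sweep $O(n)$.
* **Variances** — exact conjugate draws from
  $\mathrm{IG}(0.01 + m/2,\; 0.01 + \sum u_j^2/2)$.
* **Adaptation** — proposal scales follow a Robbins–Monro recursion toward
  35% acceptance (inside the conventional 0.2–0.5 band) during burn-in
  only, preserving ergodicity afterwards.
* **Post-sweeping** — stored draws fold random-effect group means into the
  parent level (cluster means into regions, the region mean into the
  intercept). Every linear predictor is unchanged; what is reported is the
  identified combination, which mixes far better than its unidentified
  parts. The chain itself is never recentred, so the variance full
  conditionals are untouched.

### Chain configurations

The survey-scale configuration is 175,000 iterations, 25,000 burn-in,
thinning 25 (`mcmc_config(scale = "paper")`). Under the natural accounting
`floor((175000 - 25000)/25)` this retains 6,000 draws; the source analysis
reports 7,000 retained draws, which arises if the burn-in is run *in
addition to* the iteration count (175,000/25 = 7,000). Both accountings are
implemented (`burnin_additional`), defaulting to the first; neither is
asserted to be the original intent. The default configuration is a
test-scale chain (15,000 / 5,000 / thin 5) that keeps simulation studies on
one CPU in minutes; posterior summaries at this scale carry visibly more
Monte Carlo error than survey-scale runs.

### Variance partitioning

On the latent-response scale the level-1 residual of a logistic model is
standard logistic with variance $\pi^2/3$, giving

$$ICC_C = \frac{\sigma^2_C}{\pi^2/3 + \sigma^2_C + \sigma^2_R}, \qquad
  ICC_R = \frac{\sigma^2_R}{\pi^2/3 + \sigma^2_C + \sigma^2_R}.$$

The source tables print both an explicit-residual and the latent form
without arbitrating; the latent form reproduces every printed ICC cell
exactly, so it is the reported default (`residual_mode = "latent_logistic"`),
with the explicit-$\sigma^2_e$ variant retained. PCV is
$(V_\mathrm{ref} - V_\mathrm{model})/V_\mathrm{ref}$ against the empty
model. DIC uses $p_D = \bar D - D(\bar\theta)$, where $D(\bar\theta)$ is
computed exactly from the stored mean linear predictor (the predictor is
linear in all parameters, so the mean predictor *is* the predictor at the
posterior mean).

## Covariate scales

Reported per-unit odds ratios of the scale of 28 per "one year" of age are
only plausible if continuous covariates were rescaled before fitting; the
original scaling is unstated. The generator and model therefore use an
explicit convention: age, age at first birth and parity are min–max scaled
to [0, 1] at generation (fixed plausible bounds 15–49, 12–49, 1–12), and
the linkage distance enters min–max scaled (`distance01`). The scale is a
config choice, not an assertion about the original analysis.

## Synthetic-data generator

`sim_config()` defaults encode the emulated design: 11 regions, 622
clusters (split as evenly as possible), 8–14 women per cluster (~11 on
average, ~6,900 women), 214 facilities with 179 providing CS, cluster
variance 1.04 and region variance 2.19 (the published empty-model
components), and an intercept of −4.58 calibrated once by Monte Carlo so
the marginal prevalence is ≈3.65% under those variances. Covariate
marginals (education 48%, rich household 40%, ANC categories 37/31/32%,
truncated-Poisson parity) are plausible national figures chosen once for
realism; none of the downstream validation depends on them. Facility
indicators come from a one-factor logistic model so that the PCA scores
have real structure to find. Regions are contiguous vertical strips of the
study rectangle — enough spatial structure for the linkage and hotspot
stages without emulating real geography. GPS displacement noise is a
configurable hook (`displacement_km`), default off.

What passing tests show: the estimators recover parameters from data that
match the model's own assumptions, and every spatial statistic agrees with
independent brute-force implementations. What they cannot show: robustness
to informative sampling weights, GPS displacement, real covariate
dependence structures, or model misspecification — none of which the
generator emulates.

## Spatial statistics

Distance-band weights are binary by default; Gi* uses self-inclusive binary
weights, the conventional fixed-distance-band hotspot practice (the source
names the tools, not the weighting scheme). Moran's I inference uses the
randomization-assumption variance with a two-sided normal test; its type-I
error is verified by permutation at desk scale. The incremental scan starts
at the mean nearest-neighbour distance with 10 bands of that width by
default, all configurable; ties at the peak go to the smallest band.
Hotspot classes follow the three standard confidence tiers (90/95/99%),
applied to Benjamini–Hochberg-adjusted two-sided p-values and signed by z.
A published global Moran's I above 1 is not reproducible without the
original data and exact weights, and no attempt is made to match it.

## SNVC regression

Cluster-level CS counts are first transformed: $y^* = \log(c + 0.5)$
(log-Gaussian approximation), optionally followed by a sinh-arcsinh ("SAL")
transformation $\sinh(\delta\,\mathrm{asinh}((z-a)/b) - \varepsilon)$ whose
four parameters are fitted by maximum likelihood; with $\varepsilon = 0,
\delta = 1$ it collapses to an affine rescaling of the log, and the exact
inverse is retained. The Moran eigenvector basis uses the exponential
kernel $\exp(-d/r)$ with the range $r$ fixed at the maximum
nearest-neighbour distance (a common spatial-filtering convention; the
source is silent), double-centring, and retention of eigenvalues above
0.25 of the maximum.

The mixed model
$$y^* = Xb + \sum_k \mathrm{diag}(x_k) E \gamma_k + \sum_k x_k \circ
  \delta_k + \epsilon,$$
with $\gamma_k \sim N(0, \tau_k^2 \Lambda(\alpha_k))$ and $\delta_k \sim
N(0, \psi_k^2)$, is fitted by profiled REML: the non-spatial random
coefficients act observation-wise, so they fold into a diagonal covariance
and only the spatial blocks require a Woodbury solve. $\Lambda(\alpha)$
scales shrinkage by $(\lambda_l/\lambda_1)^\alpha$, normalized to mean 1 so
$\tau^2$ and $\alpha$ stay separately interpretable — one decay exponent
per covariate keeps the family identifiable at a few hundred locations.
Degrees of freedom for the constant-coefficient t tests are $n -
\mathrm{rank}(X)$, a simple documented convention. Variances reaching the
boundary ($\hat\tau^2 \approx 0$) yield constant reported surfaces. The
cluster-level design includes log-births as an exposure covariate by
default, dropped automatically when cluster sizes are constant; covariates
are aggregated to cluster means.

## Numerical choices and degenerate inputs

* Bernoulli log-likelihoods use
  $\min(x,0) - \log(1 + e^{-|x|})$, stable for extreme linear predictors.
* PCA is correlation-based (indicators are mixed binary/ordinal); constant
  columns are dropped with a warning; component signs are fixed so each
  component's largest-magnitude loading is positive.
* Linkage ties go to the lexicographically smallest facility id; clusters
  beyond the buffer keep their nearest-facility distance, with
  `within_buffer` retained as a flag.
* Perfect separation is warned about and handled by the proper priors; data
  are never dropped.
* A Gi* neighbourhood covering all features has an undefined denominator
  and is reported as z = 0 with a flag.
* All pipeline randomness flows from one seed, fanned out as
  `seed + stage index`.

## Validation scale

The test suite runs simulation studies sized for a single CPU: parameter
recovery uses 20 replicates of ≈6,050 women in 605 clusters with the
test-scale chain; spatial oracle checks use ≤30-point instances; the Moran
calibration uses 1,000 permutations of 100 points; SVC recovery uses 150
locations with a planted smooth surface and 100 null replicates of 120
locations. These sizes are the package's validation design, chosen to make
the full suite routinely runnable.

## Known limitations

The sampler is a random-walk scheme: at survey scale it needs the long
thinned chains configured above, and badly separated or near-empty clusters
mix slowly (the priors keep them proper). The SNVC model is linear-Gaussian
on a transformed response, not an exact count likelihood. Survey weights,
geodesic distances and travel-time access are out of scope by design.
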