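---
title: "Predicting multivariate phenotypic evolution from standing genetic variation and selection"
author: "qgpredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multivariate phenotypic evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgpredict)
```

# The scientific problem

Whether multivariate phenotypic evolution can be predicted over tens of
generations depends on two quantities measured in an ancestral population:
the additive genetic covariance matrix **G** of the traits, and the
direction of selection, summarized either as selection differentials
**s** (the genetic covariance of each trait with relative fitness, per
Robertson's secondary theorem) or as direct selection gradients
**&beta;**. Lande's equation, &Delta;z&#772; = G&beta;, links one
generation of response to both; used retrospectively,
&beta;<sub>g</sub> = G<sup>-1</sup>s and &beta; = G<sup>-1</sup>&Delta;q&#772;
recover the gradients implied by observed differentials or divergence.

`qgpredict` implements this entire workflow for inbred-line panels of the
kind used in experimental evolution with *Caenorhabditis elegans*: seven
traits (the six transition rates between the locomotion states still,
forward and backward, treated on the natural-log scale, plus rescaled
body size), measured on panels of inbred lines derived from an ancestral
population and from evolved replicate populations, in two salt
environments. Because the lines are fully inbred and assumed codominant,
the among-line covariance estimates **2G**.

Every stage is mirrored by a synthetic-data generator with known ground
truth, so the estimators can be validated end to end.

# Movement traits as a continuous-time Markov chain

Locomotion in one dimension is modeled as a continuous-time Markov chain
over {S, F, B}. The generator **Q** holds the six free transition rates
(per second); each diagonal entry is minus the sum of its row, so
self-transition rates are never free parameters. Tracks are observed at a
fixed frame interval (0.25 s, i.e. 4 Hz), so the likelihood of pooled
one-frame transition counts `n` is
`sum(n * log(expm(Q * dt)))`, and estimation is done on ln q with
independent normal priors ln q ~ N(ln 2, 0.6). Two estimators are
offered: a quasi-Newton MAP (default, fast) and a random-walk Metropolis
sampler whose posterior mean is returned, matching the convention of
keeping posterior means as per-plate trait values. The matrix-logarithm
embedding of the row-normalized count matrix serves as an independent
oracle and as optimizer initialization; embedding failure is reported as
an explicit status because not every empirical transition matrix is
embeddable.

```{r ctmc}
Q <- transitionRateMatrix(c(q_SF = 0.3, q_SB = 0.2, q_FS = 0.5,
                            q_FB = 0.15, q_BS = 0.8, q_BF = 0.6))
tracks <- simulateCtmcTracks(Q, frameInterval = 0.25, duration = 300,
                             nTracks = 5, seed = 1)
fit <- estimateRates(countTransitions(tracks))
round(exp(logRates(fit)), 3)
```

Track simulation is exact-event (Gillespie) rather than a discrete-chain
shortcut, so the frame-discretization error present in real tracking data
is represented in the synthetic data too.

# Plasticity and divergence: MANOVA and canonical axes

The seven traits are fitted jointly in a sequential (Type-I) MANOVA with
terms in the order: standardized plate covariates (temperature, humidity,
log object density), year, block, environment, population, and the
environment-by-population interaction. Year precedes block because
blocks are nested in years. Wilks' lambda with Rao's F approximation
tests each term; the term SSCP matrices are eigendecomposed into
canonical traits — the leading axis of the environment SSCP is the main
axis of plasticity (&delta;p), that of the population SSCP the main axis
of divergence (d<sub>max</sub>). Covariate-adjusted least-square means
give per-replicate divergence vectors &Delta;q&#772;. Per-trait mixed
models (block and line random — the fixed/random asymmetry relative to
the MANOVA is deliberate and mirrors standard practice) provide line
BLUPs and evolved-vs-ancestor contrasts with single-step max-t
adjustment (Holm optional).

# G-matrix estimation

The multivariate mixed model for a trait vector y is

y = &mu; + &Sigma; &alpha;[T, H, D] + &gamma;<sub>year</sub> + &zeta;<sub>line</sub> + &eta;<sub>block</sub> + &epsilon;,

with all three covariates, their pairwise products and the three-way
product as fixed effects, and line, block and residual covariance
components. A blocked Gibbs sampler (compiled, RcppArmadillo) draws the
fixed effects and each random-effect block from their conditional
normals and the three covariance matrices from conditional
inverse-Wisharts. **G is half the line covariance.** Defaults follow
long-chain practice: 2.1 million iterations, 100,000 burn-in, thinning
2000, improper flat priors (nu = 0); a proper inverse-Wishart prior is
switchable. Parameter-expanded priors are not implemented; this is a
known limitation, and the flat prior is the default analysis path.

Numerical choices worth knowing:

* All random numbers are drawn through R's RNG, so `set.seed()` (via the
  `seed` slot of `mcmcSettings()`) makes every fit exactly reproducible.
* Covariance draws are floored at a relative eigenvalue of 1e-6. The
  flat prior places real mass near singular matrices for weakly
  identified components (few block levels); an unfloored chain can
  underflow there and the floor keeps it numerically alive without
  measurably changing well-identified posteriors.
* Retained-sample lag-1 autocorrelation above 0.05 triggers a warning.
* Samples are symmetric positive definite by construction.

Fitness enters as an eighth trait: the fitness-augmented fit's last
column per sample holds the selection differentials. Randomization nulls
(line and block labels shuffled, model refitted — by default with
chains shortened tenfold, a tractability compromise) give null
distributions of posterior modes, and a fitness-resampling loop
(fitness drawn per record from N(line mean, 2 SEM)) checks the
sensitivity of **s** to within-line fitness variability.

Posterior summaries are kernel-density modes (Silverman bandwidth,
configurable) and highest-posterior-density intervals (83% and 95%);
HPD rather than equal-tail because variance posteriors are skewed. Two
posteriors are declared different when their 83% HPD intervals do not
overlap, which for equal-variance normal posteriors behaves like a
~5%-level test (the calibration is verified against a brute-force
simulation in the test suite).

# Geometry and selection

`eigenG()` provides sorted decompositions with a fixed sign convention
(largest-magnitude loading positive) and eigenvalue clipping at
1e-12 x trace. Angles between trait-space directions are folded into
[0&deg;, 90&deg;] since v and -v span the same axis; their null
reference is the angle distribution between vectors with i.i.d. U(-1, 1)
components. Projected genetic variance is the Rayleigh quotient
r = v'Gv/|v|&sup2;, and &Pi; = r/&lambda;<sub>1</sub> &isin; [0, 1]
expresses it relative to the leading eigenvalue.

Random skewers compare population G-matrices: unit directions (U(-1,1)
components normalized; Gaussian-sphere sampling available) are projected
through each population's posterior; a skewer is retained when the
ancestral 95% HPD of projected variance is disjoint from at least one
evolved population's. The R-matrix of genetic differentiation is built
from the retained skewers as the among-population covariance of
mean-centered response vectors G<sub>p</sub>b (posterior-mean G per
population), scaled by 1/(n<sub>retained</sub>(n<sub>pop</sub>-1)); this
construction follows the random-skewers literature since the exact
formula is an interpretive choice. Its leading eigenvector e<sub>max</sub>
is the main canonical trait of genetic differentiation. With zero
retained skewers the R-matrix is reported as an explicit empty result,
never a zero matrix.

Selection inference solves G&beta; = s (or &Delta;q&#772;) per posterior
sample with a direct eigen-solver; samples whose condition number
exceeds 1e8 fall back to an eigenvalue-truncated pseudo-inverse and are
flagged. Joint uncertainty (sampling both G and s) pairs draws from the
two independent posteriors at random. Prediction diagnostics are the
folded angle between expected and observed divergence and the per-trait
magnitude ratios &Delta;q&#772;<sub>i</sub>/s<sub>i</sub>, whose grand
mean is an unweighted mean over replicate-by-trait cells with
|s<sub>i</sub>| above tolerance (unstable cells are excluded with a
logged count). Any display scaling of &beta; is presentation-only.

# The synthetic generator and what passing tests mean

`simulationConfig()` defaults encode the study conditions: 186/61/61/42
lines for the ancestral and three evolved populations, two plates per
line per environment, blocks nested in two assay years, breeding values
with covariance 2G, block and residual covariances, standardized plate
covariates acting through the seven-term effect structure, and per-line
relative fitness with among-line covariance 2s to the traits and mean 1.
The default 20 blocks reflect a protocol repeated many times across
years. Environments are simulated with independent line effects because
the residual cross-environment covariance structure for the same line is
not part of the model. Divergence vectors are generated directly as
G&beta; + noise rather than by simulating 50 generations of evolution.

The generator emulates the statistical structure the estimators assume
— multivariate-normal line, block and residual effects, exact CTMC
tracks. Real data deviate from this (non-normal residuals, semi-Markov
movement bouts, environment-correlated line effects), so passing
recovery tests demonstrates correctness of the estimators under their
own assumptions, not robustness to those deviations.

Problem sizes in the test and validation suites were set to exercise
every code path at panel scales where Monte-Carlo tolerances are
meaningful: parameter-recovery runs use 100 lines x 2 reps with chains
of a few hundred thousand iterations; the G used for recovery checks is
diagonal and signal-dominated so that the 28 element-wise coverage
checks are nearly independent and isolate what the check targets — the
propagation of line-sampling uncertainty — from the flat prior's known
mild small-sample bias in shrinkage-dominated regimes. Null
calibrations (Wilks, the 83% rule) use 2000 replicates.

# Known limitations

* The flat (nu = 0) covariance prior is the paper-standard default but
  is mildly miscalibrated for 7 traits with two replicates per line:
  element-wise frequentist coverage of 95% intervals is ~91-93% in
  shrinkage-dominated regimes. The proper inverse-Wishart option with
  nu = t + 1 removes the posterior-mean inflation if that matters for an
  application.
* Parameter-expanded priors, pedigree relatedness, dominance/epistasis
  terms, and repeated-measures residual structures are out of scope.
* The Markov assumption for movement is taken as given; no semi-Markov
  extension is provided.
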