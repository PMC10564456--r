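# qgpredict

Quantitative-genetic analysis of multivariate phenotypic evolution in
inbred-line panels, built around the locomotion behavior of
*Caenorhabditis elegans*: seven traits (the six natural-log transition
rates between the movement states still, forward and backward, plus
rescaled body size) measured on panels of inbred lines from an ancestral
and several evolved populations in two environments.

The package asks, and lets you ask of your own data, whether the
direction and magnitude of multivariate phenotypic evolution are
predictable from ancestral standing genetic variation and selection:

* **Movement traits.** Locomotion is a continuous-time Markov chain over
  {S, F, B} with generator Q; rows of Q sum to zero, so only the six
  between-state rates are free. Rates are estimated per plate from
  frame-sampled tracks (4 Hz) by MAP or Metropolis sampling under a
  ln q ~ N(ln 2, 0.6) prior, on the natural-log scale.
* **Plasticity and divergence.** A sequential MANOVA with Wilks tests;
  eigendecomposition of term SSCP matrices yields the canonical axes of
  plasticity (delta_p) and divergence (d_max); covariate-adjusted
  least-square means give per-replicate divergence vectors; univariate
  mixed models give line BLUPs and adjusted contrasts.
* **G-matrices.** A compiled blocked Gibbs sampler for the multivariate
  mixed model (covariates, year, random line and block effects) returns
  the posterior of G = half the among-line covariance, its
  fitness-augmented form G_qw whose last column holds the selection
  differentials s = cov_g(trait, relative fitness), randomization nulls,
  and 83%/95% HPD summaries.
* **Geometry.** Eigen-analysis (g_max), folded angles, projected
  variance r = v'Gv/|v|^2 and its ratio Pi = r/lambda_1, null angle
  distributions, and random-skewers comparison across populations
  yielding the R-matrix and e_max.
* **Selection.** Lande's retrospective equation: beta_g = G^-1 s and
  beta = G^-1 dq per posterior sample, with prediction angles
  Theta(s, dq) and magnitude ratios dq_i/s_i.
* **Synthetic data.** Generators for line panels (among-line covariance
  2G), per-line fitness (covariance 2s, mean 1), Gillespie state tracks,
  divergence vectors G beta + noise, and the neutral drift expectation
  1 - (1 - 1/(2 Ne))^t — ground truth for every estimator.

## Worked example

```r
library(qgpredict)

## transition-rate estimation from simulated tracks
Q <- transitionRateMatrix(c(q_SF = 0.3, q_SB = 0.2, q_FS = 0.5,
                            q_FB = 0.15, q_BS = 0.8, q_BF = 0.6))
tracks <- simulateCtmcTracks(Q, 0.25, 300, nTracks = 5, seed = 1)
fit <- estimateRates(countTransitions(tracks))
round(exp(logRates(fit)), 3)
#>  q_SF  q_SB  q_FS  q_FB  q_BS  q_BF
#> 0.318 0.210 0.524 0.176 0.844 0.626

## a small synthetic study end to end
cfg <- simulationConfig(nLines = c(A6140 = 25, GA1_50 = 15), seed = 5)
res <- runPipeline(cfg, settings = mcmcSettings(quick = TRUE, seed = 6),
                   seed = 11, nSkewers = 40, nNullAngles = 100)
res$axes$d_max            # leading canonical axis of divergence
#> CanonicalTrait (100.0% of variation)
#>        q_SF        q_SB        q_FS        q_FB        q_BS        q_BF
#>      -0.417       0.185       0.021       0.432      -0.022       0.666
#> size_scaled
#>      -0.400
mean(res$selection$theta$GA1_50)  # angle between s and observed divergence
#> [1] 56.1
median(res$geometry$nullAngles)   # null reference for that angle
#> [1] 73.9
```

The estimated rates sit within sampling error of the generator's rates
(roughly 100-400 observed transitions per rate at this track length).
`res$axes$d_max` is the unit trait combination carrying the divergence
between the two simulated populations (100% here because two populations
define a single divergence axis). The angle posterior compares the
selection differentials with the observed divergence: 0 degrees means
selection predicts the direction of evolution perfectly, while random
7-trait directions give the null median of ~74 degrees; at this toy
panel size the posterior (mean 56 degrees) is only weakly below the
null.

A command-line front-end over the same pipeline is installed at
`inst/scripts/run_pipeline.R` (flags `--config`, `--table`, `--seed`,
`--out`, `--quick`).

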