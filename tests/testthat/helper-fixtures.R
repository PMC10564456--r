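## Shared fixtures: small simulation configs, reference rate matrices and
## quick MCMC settings used across the suite.

traits7 <- qgpredict::phenotypeTraits()

quick_settings <- function(seed = 1L, nIterations = 20000L, burnIn = 4000L,
                           thin = 40L) {
  mcmcSettings(nIterations = nIterations, burnIn = burnIn, thin = thin,
               seed = seed)
}

small_config <- function(nLines = 60L, seed = 1L, ...) {
  simulationConfig(nLines = nLines, seed = seed, ...)
}

ref_Q <- function() {
  transitionRateMatrix(c(q_SF = 0.3, q_SB = 0.2, q_FS = 0.5,
                         q_FB = 0.15, q_BS = 0.8, q_BF = 0.6))
}

## random PSD matrix with unit-scale eigenvalues
random_psd <- function(d, seed = 1L) {
  set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  (A %*% t(A)) / d + diag(0.1, d)
}

## synthetic tight posterior around a fixed G: Wishart noise at large df
synthetic_gposterior <- function(G, nSamples = 300L, df = 5000L, seed = 1L) {
  set.seed(seed)
  t <- nrow(G)
  arr <- array(NA_real_, c(t, t, nSamples))
  for (k in seq_len(nSamples)) {
    W <- stats::rWishart(1, df, G / df)[, , 1]
    arr[, , k] <- (W + t(W)) / 2
  }
  new("GPosterior", G = arr, blockCov = arr, residCov = arr,
      traits = paste0("tr", seq_len(t)),
      autocorr = matrix(0, t, t), settings = NULL)
}
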