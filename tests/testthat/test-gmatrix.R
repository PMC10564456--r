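## Gibbs-sampler tests run on deliberately small panels with short chains;
## full-scale parameter recovery lives in the acceptance suite.

make_panel <- function(nLines = 50L, seed = 1L, fitness = FALSE, ...) {
  cfg <- small_config(nLines = nLines, seed = seed, ...)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  if (fitness) panel <- simulateFitness(panel, cfg)
  list(cfg = cfg, panel = panel)
}

test_that("retained samples are deterministic given seed and settings", {
  p <- make_panel(nLines = 30L, seed = 2L)
  st <- quick_settings(seed = 9L, nIterations = 6000L, burnIn = 1000L,
                       thin = 10L)
  g1 <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  g2 <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  expect_identical(gSamples(g1), gSamples(g2))
})

test_that("results are invariant to row order of the input table", {
  p <- make_panel(nLines = 30L, seed = 3L)
  ## short chain: floating-point summation-order differences amplify
  ## chaotically over long chains, so compare before they can grow
  st <- quick_settings(seed = 4L, nIterations = 1000L, burnIn = 200L,
                       thin = 5L)
  g1 <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  set.seed(99)
  perm <- sample(nrow(p$panel))
  g2 <- suppressWarnings(fitMvlmm(p$panel[perm, ], settings = st))
  expect_lt(max(abs(gSamples(g1) - gSamples(g2))), 1e-6)
})

test_that("every retained covariance sample is symmetric PSD", {
  p <- make_panel(nLines = 40L, seed = 5L)
  st <- quick_settings(seed = 6L, nIterations = 8000L, burnIn = 2000L,
                       thin = 20L)
  gp <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  for (arr in list(gSamples(gp), gp@blockCov, gp@residCov)) {
    for (k in seq_len(dim(arr)[3])) {
      m <- arr[, , k]
      expect_lt(max(abs(m - t(m))), 1e-10)
      expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
                0)
    }
  }
})

test_that("posterior mean tracks the realized among-line covariance", {
  p <- make_panel(nLines = 80L, seed = 7L)
  st <- quick_settings(seed = 8L, nIterations = 30000L, burnIn = 6000L,
                       thin = 40L)
  gp <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  realized <- cov(attr(p$panel, "breeding_values")[["high_salt.A6140"]]) / 2
  est <- posteriorMeanG(gp)
  ## diagonal within ~40% relative error at this panel size
  expect_lt(max(abs(diag(est) / diag(realized) - 1)), 0.4)
})

test_that("unreplicated designs are refused", {
  p <- make_panel(nLines = 30L, seed = 9L)
  single <- p$panel[!duplicated(p$panel$line_id), ]
  expect_error(fitMvlmm(single, settings = quick_settings()),
               "not identifiable")
})

test_that("the augmented fit returns selection differentials near truth", {
  p <- make_panel(nLines = 80L, seed = 10L, fitness = TRUE)
  st <- quick_settings(seed = 11L, nIterations = 30000L, burnIn = 6000L,
                       thin = 40L)
  gq <- suppressWarnings(fitGqw(p$panel, settings = st))
  expect_s4_class(gq, "GqwPosterior")
  s <- selectionDifferentials(gq)
  expect_equal(ncol(s), 7L)
  covered <- 0L
  for (i in 1:7) {
    ci <- credibleInterval(s[, i], 0.95)
    covered <- covered +
      (p$cfg@sTrue[i] >= ci[1] && p$cfg@sTrue[i] <= ci[2])
  }
  expect_gte(covered, 5L)
  ## trait sub-block comparable to a separate G fit, element-wise 83% CIs
  gp <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  agree <- 0L
  for (i in 1:7) {
    a <- gq@G[i, i, ]; b <- gp@G[i, i, ]
    agree <- agree + !comparePosteriors(a, b)
  }
  expect_gte(agree, 6L)
})

test_that("records lacking fitness are dropped with a message", {
  p <- make_panel(nLines = 30L, seed = 12L, fitness = TRUE)
  p$panel$fitness[1:3] <- NA
  expect_message(
    suppressWarnings(fitGqw(p$panel, settings = quick_settings(
      seed = 1L, nIterations = 4000L, burnIn = 1000L, thin = 10L))),
    "dropping 3")
  expect_error(fitGqw(p$panel[, setdiff(names(p$panel), "fitness")]),
               "fitness")
})

test_that("randomization nulls separate a strong G from shuffled data", {
  p <- make_panel(nLines = 60L, seed = 13L)
  st <- quick_settings(seed = 14L, nIterations = 12000L, burnIn = 3000L,
                       thin = 30L)
  gp <- suppressWarnings(fitMvlmm(p$panel, settings = st))
  nulls <- suppressWarnings(
    nullGDistribution(p$panel, nShuffles = 12L, settings = st, seed = 15L,
                      chainScale = 0.5))
  expect_equal(nrow(nulls), 12L)
  ## observed genetic-variance modes exceed the null 95% envelope
  above <- 0L
  for (tr in traits7) {
    obs <- posteriorMode(gp@G[match(tr, traits7), match(tr, traits7), ])
    env_hi <- quantile(nulls[, paste(tr, tr, sep = ":")], 0.975)
    above <- above + (obs > env_hi)
  }
  expect_gte(above, 6L)
  ## reproducible under the same seed
  nulls2 <- suppressWarnings(
    nullGDistribution(p$panel, nShuffles = 3L, settings = st, seed = 15L,
                      chainScale = 0.5))
  expect_equal(nulls[1:3, ], nulls2, tolerance = 1e-12)
  expect_error(nullGDistribution(p$panel, nShuffles = 1L), "at least 2")
})

test_that("pure-noise data stay inside their randomization envelope", {
  t <- 7
  cfg <- simulationConfig(nLines = 50L, G = matrix(0, t, t),
                          Vblock = diag(0.02, t), Eresid = diag(0.25, t),
                          covariateEffects = matrix(0, 7, t),
                          sTrue = rep(0, t), Vw = 0.1,
                          betaTrue = rep(0, t), seed = 16L)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  st <- quick_settings(seed = 17L, nIterations = 10000L, burnIn = 2000L,
                       thin = 20L)
  gp <- suppressWarnings(fitMvlmm(panel, settings = st))
  nulls <- suppressWarnings(
    nullGDistribution(panel, nShuffles = 12L, settings = st, seed = 18L,
                      chainScale = 0.5))
  inside <- 0L
  for (tr in traits7) {
    i <- match(tr, traits7)
    obs <- posteriorMode(gp@G[i, i, ])
    env <- quantile(nulls[, paste(tr, tr, sep = ":")], c(0.025, 0.975))
    inside <- inside + (obs >= env[1] && obs <= env[2])
  }
  expect_gte(inside, 5L)
})

test_that("fitness resampling is exact at zero SEM and grows with it", {
  p <- make_panel(nLines = 40L, seed = 19L, fitness = TRUE)
  st <- quick_settings(seed = 20L, nIterations = 6000L, burnIn = 1500L,
                       thin = 15L)
  lines <- unique(p$panel$line_id)
  sem0 <- setNames(rep(0, length(lines)), lines)
  r0 <- suppressWarnings(
    gqwFitnessSensitivity(p$panel, sem0, nResamples = 3L, settings = st,
                          seed = 21L))
  base <- attr(r0, "baseline")
  for (r in 1:3) expect_equal(unname(r0[r, ]), unname(base),
                              tolerance = 1e-12)
  ## dispersion grows monotonically with the SEM scale
  disp <- vapply(c(0.05, 0.3), function(scl) {
    sem <- setNames(rep(scl, length(lines)), lines)
    rs <- suppressWarnings(
      gqwFitnessSensitivity(p$panel, sem, nResamples = 6L, settings = st,
                            seed = 22L))
    mean(apply(rs, 2, sd))
  }, numeric(1))
  expect_gt(disp[2], disp[1])
  ## baseline inside the resampling envelope at moderate SEM
  sem <- setNames(rep(0.05, length(lines)), lines)
  rs <- suppressWarnings(
    gqwFitnessSensitivity(p$panel, sem, nResamples = 8L, settings = st,
                          seed = 23L))
  for (i in 1:7) {
    rng <- range(rs[, i])
    expect_gte(base[i], rng[1] - 3 * sd(rs[, i]) - 1e-6)
    expect_lte(base[i], rng[2] + 3 * sd(rs[, i]) + 1e-6)
  }
  ## missing SEMs default to zero with a warning
  expect_warning(
    suppressMessages(gqwFitnessSensitivity(
      p$panel, sem[1:5], nResamples = 2L, settings = st, seed = 24L)),
    "SEM")
})
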