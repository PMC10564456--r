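test_that("line panels are deterministic given the seed", {
  cfg <- small_config(nLines = 20L, seed = 42L)
  p1 <- simulateLinePanel(cfg)
  p2 <- simulateLinePanel(cfg)
  expect_identical(p1, p2)
  p3 <- simulateLinePanel(small_config(nLines = 20L, seed = 43L))
  expect_false(identical(p1[, traits7], p3[, traits7]))
})

test_that("with no genetic or block variance only residual noise remains", {
  t <- 7
  cfg <- simulationConfig(nLines = 400L, repsPerLine = 2L,
                          G = matrix(0, t, t), Vblock = matrix(0, t, t),
                          Eresid = diag(0.2, t),
                          covariateEffects = matrix(0, 7, t),
                          sTrue = rep(0, t), Vw = 0.1,
                          betaTrue = rep(0, t),
                          yearEffects = c(0, 0), seed = 5L)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  lm_ <- aggregate(panel[, traits7], by = list(panel$line_id), mean)[, -1]
  v <- diag(cov(as.matrix(lm_)))
  ## line means of 2 reps: variance E/2 = 0.1; MC SE ~ v * sqrt(2/(n-1))
  expect_true(all(abs(v - 0.1) < 3 * 0.1 * sqrt(2 / 399)))
})

test_that("among-line covariance of line means matches 2G + E/reps", {
  cfg <- simulationConfig(nLines = 200L, repsPerLine = 2L, seed = 11L)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  lm_ <- as.matrix(aggregate(panel[, traits7],
                             by = list(panel$line_id), mean)[, -1])
  emp <- cov(lm_)
  expected <- 2 * cfg@G + cfg@Eresid / 2
  n <- nrow(lm_)
  for (i in 1:7) for (j in i:7) {
    mc_se <- sqrt((expected[i, i] * expected[j, j] + expected[i, j]^2) /
                    (n - 1))
    expect_lt(abs(emp[i, j] - expected[i, j]), 3.5 * mc_se)
  }
})

test_that("non-PSD covariance inputs are rejected with the matrix named", {
  t <- 7
  bad <- diag(1, t); bad[1, 1] <- -1
  expect_error(simulationConfig(G = bad), "G")
  expect_error(simulationConfig(Eresid = bad), "Eresid")
  ## augmented trait-fitness matrix must also be PSD
  expect_error(simulationConfig(sTrue = rep(1, 7), Vw = 1e-4), "2Vw")
})

test_that("simulated fitness has mean one and the target line covariance", {
  cfg <- simulationConfig(nLines = 200L, seed = 3L)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  panel <- simulateFitness(panel, cfg)
  expect_lt(abs(mean(tapply(panel$fitness, panel$line_id, mean)) - 1), 1e-6)
  bv <- attr(panel, "breeding_values")[["high_salt.A6140"]]
  w <- attr(panel, "line_fitness")[rownames(bv)]
  emp <- cov(bv, w)
  for (i in 1:7) {
    mc_se <- sqrt((2 * cfg@G[i, i] * 2 * cfg@Vw +
                     (2 * cfg@sTrue[i])^2) / (nrow(bv) - 1))
    expect_lt(abs(emp[i] - 2 * cfg@sTrue[i]), 3.5 * mc_se)
  }
})

test_that("zero trait-fitness covariance yields near-zero line covariance", {
  cfg <- simulationConfig(nLines = 300L, sTrue = rep(0, 7), Vw = 0.1,
                          seed = 9L)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  panel <- simulateFitness(panel, cfg)
  bv <- attr(panel, "breeding_values")[["high_salt.A6140"]]
  w <- attr(panel, "line_fitness")[rownames(bv)]
  emp <- cov(bv, w)
  for (i in 1:7) {
    mc_se <- sqrt(2 * cfg@G[i, i] * 2 * cfg@Vw / (nrow(bv) - 1))
    expect_lt(abs(emp[i]), 3.5 * mc_se)
  }
})

test_that("Gillespie tracks reproduce the stationary distribution", {
  Q <- ref_Q()
  tr <- simulateCtmcTracks(Q, 0.25, 4000, nTracks = 5L, seed = 2L)
  pi0 <- stationaryDistribution(Q)
  freq <- table(factor(tr$state, levels = movementStates())) / nrow(tr)
  ## effective sample size reduced by autocorrelation; be generous
  for (s in movementStates())
    expect_lt(abs(freq[[s]] - pi0[[s]]), 0.02)
})

test_that("one-step transition frequencies match the matrix exponential", {
  Q <- ref_Q()
  dt <- 0.25
  tr <- simulateCtmcTracks(Q, dt, 5000, nTracks = 10L, seed = 4L)
  n <- countTransitions(tr)
  P_emp <- n / rowSums(n)
  P_true <- as.matrix(Matrix::expm(rateMatrix(Q) * dt))
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(P_true[i, j] * (1 - P_true[i, j]) / rowSums(n)[i])
    expect_lt(abs(P_emp[i, j] - P_true[i, j]), 4 * se + 1e-6)
  }
})

test_that("zero-duration tracks hold a single state", {
  tr <- simulateCtmcTracks(ref_Q(), 0.25, 0, nTracks = 3L, seed = 1L)
  expect_equal(nrow(tr), 3L)
  expect_true(all(tr$frame == 0L))
})

test_that("invalid generators are rejected", {
  q <- rateMatrix(ref_Q())
  q[1, 1] <- 0   # rows no longer sum to zero
  expect_error(simulateCtmcTracks(q, 0.25, 10), "sum to zero")
})

test_that("divergence vectors follow G beta exactly at zero noise", {
  G <- random_psd(7, seed = 2L)
  beta <- c(1, -0.5, 0.25, 0, 2, -1, 0.3)
  dq <- simulateDivergence(G, beta, nReplicates = 2L, replicateNoise = 0)
  expect_equal(dq[[1]], as.numeric(G %*% beta), tolerance = 1e-12)
  expect_equal(dq[[1]], dq[[2]])
  expect_equal(simulateDivergence(diag(7), beta, 1L, 0)[[1]], beta)
  expect_equal(simulateDivergence(G, rep(0, 7), 1L, 0)[[1]], rep(0, 7))
  expect_error(simulateDivergence(G, 1:3), "dimension")
})

test_that("divergence round-trips through the phenotypic gradients", {
  G <- random_psd(7, seed = 8L)
  beta <- rnorm(7)
  dq <- simulateDivergence(G, beta, 1L, 0)[[1]]
  rec <- phenotypicGradients(G, dq)
  expect_lt(max(abs(rec[1, ] - beta)), 1e-8)
})

test_that("drift loss follows the per-generation decay", {
  expect_equal(expectedDriftLoss(1000, 0), 0)
  expect_equal(expectedDriftLoss(1000, 50, "outcrossing"),
               1 - (1 - 1 / 2000)^50, tolerance = 1e-12)
  loss_selfing <- expectedDriftLoss(1000, 50, "complete_selfing")
  expect_equal(loss_selfing, 1 - (1 - 1 / 1000)^50, tolerance = 1e-12)
  expect_lt(loss_selfing, 0.05)
  expect_error(expectedDriftLoss(-1, 10), "positive")
})
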