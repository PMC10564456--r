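## Fixtures: small panels with and without factor effects.

null_table <- function(n = 80L, t = 7L, seed = 1L) {
  set.seed(seed)
  data.frame(
    line_id = sprintf("L%03d", rep(seq_len(n / 2), each = 2)),
    population = "A6140",
    environment = rep(c("low_salt", "high_salt"), n / 2),
    block = sprintf("B%d", sample(4, n, replace = TRUE)),
    year = "Y1",
    temperature = rnorm(n), humidity = rnorm(n), log_density = rnorm(n),
    setNames(as.data.frame(matrix(rnorm(n * t), n, t)), traits7[1:t]))
}

test_that("Wilks lambda reduces to the ANOVA F for one trait", {
  tb <- null_table(seed = 3L)
  tb$q_SF <- tb$q_SF + 0.8 * (tb$environment == "high_salt")
  mv <- fitManova(tb, traits = "q_SF",
                  termOrder = c("temperature", "humidity", "log_density",
                                "block", "environment"))
  a <- anova(lm(q_SF ~ temperature + humidity + log_density + block +
                  environment, data = qgpredict:::.model_frame(tb, "q_SF")))
  expect_equal(mv[["environment"]]@approxF, a["environment", "F value"],
               tolerance = 1e-10)
  expect_equal(mv[["environment"]]@pValue, a["environment", "Pr(>F)"],
               tolerance = 1e-8)
})

test_that("a huge factor effect with tiny noise drives Wilks toward zero", {
  tb <- null_table(seed = 5L)
  for (tr in traits7) tb[[tr]] <- tb[[tr]] * 0.01
  tb$q_SB <- tb$q_SB + 2 * (tb$environment == "high_salt")
  mv <- fitManova(tb)
  expect_lt(mv[["environment"]]@wilks, 1e-3)
  expect_lt(mv[["environment"]]@pValue, 1e-10)
})

test_that("sequential SSCPs and the residual sum to the total centered SSCP", {
  tb <- null_table(seed = 7L)
  tb$q_FS <- tb$q_FS + 0.5 * (tb$environment == "high_salt")
  mv <- fitManova(tb)
  tot <- Reduce(`+`, lapply(mv, function(r) r@SSCP))
  Y <- as.matrix(tb[, traits7])
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  expect_equal(tot, unname(crossprod(Yc)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Wilks lambda is invariant to nonsingular trait reparameterization",
{
  tb <- null_table(seed = 11L)
  tb$q_SF <- tb$q_SF + 0.4 * (tb$environment == "high_salt")
  mv1 <- fitManova(tb)
  set.seed(2)
  A <- matrix(rnorm(49), 7)          # almost surely nonsingular
  Y2 <- as.matrix(tb[, traits7]) %*% A
  tb2 <- tb
  tb2[, traits7] <- Y2
  mv2 <- fitManova(tb2)
  expect_equal(mv1[["environment"]]@wilks, mv2[["environment"]]@wilks,
               tolerance = 1e-8)
})

test_that("rank-deficient designs are reported", {
  tb <- null_table(seed = 13L)
  tb$humidity <- tb$temperature            # aliased covariate
  expect_error(fitManova(tb), "rank-deficient|aliased")
})

test_that("the SSCP axis isolates a single shifted trait", {
  tb <- null_table(n = 200L, seed = 17L)
  for (tr in traits7) tb[[tr]] <- tb[[tr]] * 0.05
  tb$q_SF <- tb$q_SF + 1.5 * (tb$environment == "high_salt")
  mv <- fitManova(tb)
  ax <- sscpAxis(mv[["environment"]])
  expect_gt(abs(traitLoadings(ax)["q_SF"]), 0.99)
  expect_gt(percentVariance(ax), 99)
  ## equal shifts on two traits load them equally
  tb2 <- null_table(n = 200L, seed = 19L)
  for (tr in traits7) tb2[[tr]] <- tb2[[tr]] * 0.05
  shift <- 1.5 * (tb2$environment == "high_salt")
  tb2$q_SF <- tb2$q_SF + shift
  tb2$q_SB <- tb2$q_SB + shift
  ax2 <- sscpAxis(fitManova(tb2)[["environment"]])
  l <- traitLoadings(ax2)
  expect_lt(abs(abs(l["q_SF"]) - abs(l["q_SB"])), 0.05)
  ## percent variances over all axes sum to 100
  sscp <- mv[["environment"]]@SSCP
  pct <- sum(vapply(1:7, function(k) percentVariance(sscpAxis(sscp, k)),
                    numeric(1)))
  expect_equal(pct, 100, tolerance = 1e-8)
  expect_error(sscpAxis(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("eigenvector sign convention flips consistently with the traits", {
  tb <- null_table(seed = 23L)
  tb$q_SF <- tb$q_SF + 0.6 * (tb$environment == "high_salt")
  ax1 <- sscpAxis(fitManova(tb)[["environment"]])
  tb2 <- tb
  tb2[, traits7] <- -tb2[, traits7]
  ax2 <- sscpAxis(fitManova(tb2)[["environment"]])
  expect_equal(abs(traitLoadings(ax1)), abs(traitLoadings(ax2)),
               tolerance = 1e-6)
})

test_that("divergence vectors recover planted population shifts", {
  cfg <- simulationConfig(nLines = c(A6140 = 80L, GA1_50 = 50L), seed = 31L)
  shifts <- matrix(0, 1, 7, dimnames = list("GA1_50", traits7))
  shifts["GA1_50", "q_FS"] <- 0.5
  panel <- simulateLinePanel(cfg, environments = "high_salt",
                             meanShifts = shifts)
  dv <- divergenceVectors(panel)
  se <- attr(dv, "se")
  expect_equal(nrow(dv), 1L)
  expect_lt(abs(dv$q_FS - 0.5), 3 * se[1, "q_FS"] + 0.1)
  ## missing ancestor is an error
  expect_error(divergenceVectors(panel[panel$population != "A6140", ]),
               "ancestor")
})

test_that("balanced designs agree with raw population mean differences", {
  set.seed(37)
  n <- 240L
  tb <- data.frame(
    line_id = sprintf("L%03d", rep(1:(n / 2), each = 2)),
    population = rep(c("A6140", "GA1_50"), each = n / 2),
    environment = "high_salt",
    block = rep(sprintf("B%d", 1:4), n / 4),
    year = "Y1",
    temperature = rnorm(n), humidity = rnorm(n), log_density = rnorm(n),
    setNames(as.data.frame(matrix(rnorm(n * 7, sd = 0.2), n, 7)), traits7))
  tb$q_BF <- tb$q_BF + 0.7 * (tb$population == "GA1_50")
  dv <- divergenceVectors(tb)
  raw <- mean(tb$q_BF[tb$population == "GA1_50"]) -
    mean(tb$q_BF[tb$population == "A6140"])
  expect_lt(abs(dv$q_BF - raw), 0.08)
})

test_that("univariate BLUPs shrink and contrasts recover planted effects", {
  cfg <- simulationConfig(nLines = c(A6140 = 60L, GA1_50 = 40L), seed = 41L)
  shifts <- matrix(0, 1, 7, dimnames = list("GA1_50", traits7))
  shifts["GA1_50", "q_SF"] <- 0.6
  panel <- simulateLinePanel(cfg, environments = "high_salt",
                             meanShifts = shifts)
  fit <- fitUnivariate(panel, "q_SF")
  expect_s4_class(fit$model, "lmerMod")
  ctr <- fit$contrasts
  expect_equal(nrow(ctr), 1L)
  expect_lt(abs(ctr$estimate - 0.6), 3 * ctr$SE)
  ## shrinkage: BLUP spread within a population never exceeds the raw
  ## line-mean spread
  anc <- panel[panel$population == "A6140", ]
  raw <- tapply(anc$q_SF, anc$line_id, mean)
  blup <- fit$blups[names(raw)]
  expect_lte(var(blup), var(raw))
})

test_that("zero line variance shrinks BLUPs toward the population mean", {
  t <- 7
  cfg <- simulationConfig(nLines = 50L, G = matrix(0, t, t),
                          Vblock = diag(0.02, t), Eresid = diag(0.3, t),
                          covariateEffects = matrix(0, 7, t),
                          sTrue = rep(0, t), Vw = 0.1,
                          betaTrue = rep(0, t), seed = 43L)
  panel <- simulateLinePanel(cfg, environments = "high_salt")
  fit <- suppressMessages(fitUnivariate(panel, "q_SB"))
  raw <- tapply(panel$q_SB, panel$line_id, mean)
  expect_lt(var(fit$blups[names(raw)]), 0.25 * var(raw))
})
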