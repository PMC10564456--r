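## Bayesian estimation of the G-matrix: the multivariate mixed model with
## line and block random effects fitted by a blocked Gibbs sampler
## (compiled; see src/gibbs.cpp), plus randomization nulls and
## fitness-resampling sensitivity for the fitness-augmented model.

#' @useDynLib qgpredict, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' MCMC settings for G-matrix estimation
#'
#' Defaults are the long-chain settings used for inbred-line panels: 2.1
#' million iterations, 100,000 burn-in, thinning 2000 (1000 retained
#' samples), improper flat covariance priors (degree of belief nu = 0).
#' Shorter chains (see \code{quick}) are appropriate for simulation
#' studies and testing.
#'
#' @param nIterations,burnIn,thin chain controls.
#' @param prior "flat" (improper, nu = 0) or "invwishart" (proper, with
#'   \code{priorV}, \code{priorNu}).
#' @param priorV inverse-Wishart scale matrix (proper prior only).
#' @param priorNu inverse-Wishart degrees of belief.
#' @param seed integer RNG seed.
#' @param quick logical; if TRUE, a reduced chain (60,000 iterations,
#'   10,000 burn-in, thin 100) for quick runs.
#' @return An \linkS4class{McmcSettings}.
#' @export
mcmcSettings <- function(nIterations = 2100000L, burnIn = 100000L,
                         thin = 2000L, prior = c("flat", "invwishart"),
                         priorV = NULL, priorNu = 0, seed = 1L,
                         quick = FALSE) {
  prior <- match.arg(prior)
  if (quick) {
    nIterations <- 60000L; burnIn <- 10000L; thin <- 100L
  }
  s <- new("McmcSettings", nIterations = as.integer(nIterations),
           burnIn = as.integer(burnIn), thin = as.integer(thin),
           prior = prior, priorV = priorV, priorNu = as.numeric(priorNu),
           seed = as.integer(seed))
  validObject(s)
  s
}

.design_matrix <- function(table) {
  cv <- as.matrix(table[, c("temperature", "humidity", "log_density")])
  X <- cbind(intercept = 1, cv,
             "t:h" = cv[, 1] * cv[, 2], "t:d" = cv[, 1] * cv[, 3],
             "h:d" = cv[, 2] * cv[, 3],
             "t:h:d" = cv[, 1] * cv[, 2] * cv[, 3])
  if ("year" %in% names(table)) {
    yr <- factor(table$year)
    if (nlevels(yr) > 1L)
      X <- cbind(X, stats::model.matrix(~yr)[, -1, drop = FALSE])
  }
  X
}

.run_gibbs <- function(Y, X, line, block, settings) {
  t <- ncol(Y)
  nl <- length(unique(line)); nb <- length(unique(block))
  if (settings@prior == "flat") {
    if (nl < t + 1L || nb < t + 1L)
      stop("flat prior needs more line (", nl, ") and block (", nb,
           ") levels than traits + 1 (", t + 1L, ")")
    pv <- matrix(0, t, t); nu <- 0
  } else {
    pv <- if (is.null(settings@priorV)) diag(1e-3, t) else
      as.matrix(settings@priorV)
    nu <- if (settings@priorNu > 0) settings@priorNu else t + 1
  }
  set.seed(settings@seed)
  gibbs_mvlmm_cpp(Y, X, line, block,
                  settings@nIterations, settings@burnIn, settings@thin,
                  nu, pv, settings@prior == "flat")
}

.lag1_autocorr <- function(Garr) {
  t <- dim(Garr)[1]
  ac <- matrix(NA_real_, t, t)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    x <- Garr[i, j, ]
    if (sd(x) > 0)
      ac[i, j] <- stats::cor(x[-length(x)], x[-1])
  }
  ac
}

#' Fit the multivariate mixed model and return the G posterior
#'
#' Gibbs sampler for the seven-trait model with fixed effects of the three
#' standardized plate covariates, their pairwise and three-way
#' interactions, and year, plus random line and block effects. G is half
#' the among-line covariance (fully inbred, codominant lines). Retained
#' samples whose lag-1 autocorrelation exceeds 0.05 for any element are
#' flagged with a warning.
#'
#' @param table phenotype table (one population/environment subset).
#' @param traits character, response columns.
#' @param settings an \linkS4class{McmcSettings}.
#' @return A \linkS4class{GPosterior}.
#' @export
fitMvlmm <- function(table, traits = .TRAITS, settings = mcmcSettings()) {
  table <- .model_frame(table, traits)
  Y <- as.matrix(table[, traits])
  if (anyNA(Y)) {
    keep <- complete.cases(Y)
    message("dropping ", sum(!keep), " records with missing trait values")
    table <- table[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  line <- as.integer(factor(table$line_id)) - 1L
  block <- as.integer(factor(table$block)) - 1L
  if (!anyDuplicated(line))
    stop("no line is replicated: among-line and residual covariance are ",
         "not identifiable")
  X <- .design_matrix(table)
  res <- .run_gibbs(Y, X, line, block, settings)
  ac <- .lag1_autocorr(res$G)
  if (any(abs(ac) > 0.05, na.rm = TRUE))
    warning("retained-sample lag-1 autocorrelation above 0.05 for ",
            sum(abs(ac) > 0.05, na.rm = TRUE),
            " G elements; consider a longer thinning interval")
  new("GPosterior", G = res$G, blockCov = res$blockCov,
      residCov = res$residCov, traits = traits, autocorr = ac,
      settings = settings)
}

#' Fit the fitness-augmented model (selection differentials)
#'
#' The trait vector is expanded with per-line relative fitness and the
#' same mixed model is fitted over the augmented response; the last column
#' of each retained sample holds the genetic trait-fitness covariances,
#' the selection differentials. Lines lacking fitness (or traits) are
#' dropped with a logged count.
#'
#' @param table phenotype table with a \code{fitness} column.
#' @param traits trait columns (fitness excluded).
#' @param settings an \linkS4class{McmcSettings}.
#' @return A \linkS4class{GqwPosterior}.
#' @export
fitGqw <- function(table, traits = .TRAITS, settings = mcmcSettings()) {
  if (!"fitness" %in% names(table))
    stop("table lacks a 'fitness' column; join per-line fitness first")
  keep <- complete.cases(table[, c(traits, "fitness")])
  if (any(!keep))
    message("dropping ", sum(!keep),
            " records lacking fitness or trait values")
  table <- table[keep, , drop = FALSE]
  aug <- c(traits, "fitness")
  table2 <- .model_frame(table, aug)
  Y <- as.matrix(table2[, aug])
  line <- as.integer(factor(table2$line_id)) - 1L
  block <- as.integer(factor(table2$block)) - 1L
  if (!anyDuplicated(line))
    stop("no line is replicated: model not identifiable")
  X <- .design_matrix(table2)
  res <- .run_gibbs(Y, X, line, block, settings)
  new("GqwPosterior", G = res$G, blockCov = res$blockCov,
      residCov = res$residCov, traits = aug,
      autocorr = .lag1_autocorr(res$G), settings = settings,
      fitnessName = "fitness")
}

#' Randomization null distribution for the G-matrix
#'
#' Shuffles inbred-line and block identities independently, refits the
#' model per shuffle (with a chain shortened by \code{chainScale} for
#' tractability), and collects the posterior mode of every distinct G
#' element plus the trace into a null distribution.
#'
#' @param table phenotype table.
#' @param nShuffles number of label randomizations (>= 2).
#' @param settings baseline \linkS4class{McmcSettings}.
#' @param seed RNG seed governing the shuffles.
#' @param traits trait columns.
#' @param chainScale factor by which null chains are shortened.
#' @return matrix with one row per shuffle; columns are the lower-triangle
#'   G elements ("trait_i:trait_j") and "trace".
#' @export
nullGDistribution <- function(table, nShuffles = 1000L,
                              settings = mcmcSettings(), seed = 1L,
                              traits = .TRAITS, chainScale = 0.1) {
  if (nShuffles < 2L) stop("nShuffles must be at least 2")
  t <- length(traits)
  short <- mcmcSettings(
    nIterations = max(2000L, as.integer(settings@nIterations * chainScale)),
    burnIn = max(500L, as.integer(settings@burnIn * chainScale)),
    thin = max(1L, as.integer(settings@thin * chainScale)),
    prior = settings@prior, priorV = settings@priorV,
    priorNu = settings@priorNu, seed = settings@seed)
  idx <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  cols <- c(paste(traits[idx[, 1]], traits[idx[, 2]], sep = ":"), "trace")
  out <- matrix(NA_real_, nShuffles, length(cols),
                dimnames = list(NULL, cols))
  set.seed(seed)
  shuffle_seeds <- sample.int(2^31 - 2, nShuffles)
  for (s in seq_len(nShuffles)) {
    set.seed(shuffle_seeds[s])
    tb <- table
    tb$line_id <- sample(tb$line_id)
    tb$block <- sample(tb$block)
    short@seed <- shuffle_seeds[s]
    gp <- suppressWarnings(fitMvlmm(tb, traits, short))
    Garr <- gp@G
    modes <- apply(idx, 1, function(ij)
      posteriorMode(Garr[ij[1], ij[2], ]))
    out[s, ] <- c(modes,
                  posteriorMode(apply(Garr, 3, function(m) sum(diag(m)))))
  }
  out
}

#' Sensitivity of selection differentials to within-line fitness noise
#'
#' Regenerates the fitness-augmented fit many times, each time drawing
#' every record's fitness from a normal with the line's mean and twice the
#' line's standard error of the mean as standard deviation (emulating a
#' random split of the fitness assay), and collects the posterior-mean
#' selection differentials per resample.
#'
#' @param table phenotype table with \code{fitness}.
#' @param sem named numeric, per-line standard error of mean fitness;
#'   missing lines default to 0 with a warning.
#' @param nResamples number of resampled fits.
#' @param settings \linkS4class{McmcSettings} for the resample fits.
#' @param seed RNG seed.
#' @param traits trait columns.
#' @return matrix nResamples x nTraits of posterior-mean selection
#'   differentials, with the baseline fit's differentials as
#'   \code{attr(, "baseline")}.
#' @export
gqwFitnessSensitivity <- function(table, sem, nResamples = 500L,
                                  settings = mcmcSettings(quick = TRUE),
                                  seed = 1L, traits = .TRAITS) {
  stopifnot("fitness" %in% names(table))
  lines <- unique(table$line_id)
  if (is.null(names(sem))) stop("sem must be named by line_id")
  missing_sem <- setdiff(lines, names(sem))
  if (length(missing_sem)) {
    warning(length(missing_sem), " lines lack a SEM; defaulting to 0")
    sem[missing_sem] <- 0
  }
  line_mean <- tapply(table$fitness, table$line_id, mean)
  set.seed(seed)
  res_seeds <- sample.int(2^31 - 2, nResamples)
  t <- length(traits)
  out <- matrix(NA_real_, nResamples, t, dimnames = list(NULL, traits))
  for (r in seq_len(nResamples)) {
    set.seed(res_seeds[r])
    tb <- table
    tb$fitness <- rnorm(nrow(tb),
                        mean = line_mean[tb$line_id],
                        sd = 2 * sem[tb$line_id])
    ## chain seed fixed at the baseline's so a zero-SEM resample
    ## reproduces the baseline fit exactly
    gq <- fitGqw(tb, traits, settings)
    out[r, ] <- apply(gq@G[seq_len(t), t + 1L, , drop = FALSE], 1, mean)
  }
  base <- fitGqw(table, traits, settings)
  attr(out, "baseline") <- apply(base@G[seq_len(t), t + 1L, , drop = FALSE],
                                 1, mean)
  out
}
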