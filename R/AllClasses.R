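#' @import methods
#' @importFrom stats rnorm rchisq runif rexp density optim rbinom sd var
#'   cov setNames complete.cases
NULL

## Canonical trait order used throughout: six log transition rates between
## the movement states still (S), forward (F) and backward (B), plus body
## size rescaled so its phenotypic variance is comparable to the rates.
.TRAITS <- c("q_SF", "q_SB", "q_FS", "q_FB", "q_BS", "q_BF", "size_scaled")
.STATES <- c("S", "F", "B")
.POPULATIONS <- c("A6140", "GA1_50", "GA2_50", "GA4_50")
.ENVIRONMENTS <- c("low_salt", "high_salt")

.check_symmetric_psd <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    return(sprintf("%s must be a square matrix", name))
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    return(sprintf("%s must be symmetric", name))
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    return(sprintf("%s must be positive semi-definite (min eigenvalue %.3g)",
                   name, min(ev)))
  TRUE
}

#' Configuration of the synthetic inbred-line study
#'
#' Holds the ground-truth parameters from which synthetic phenotype panels,
#' fitness records, divergence vectors and state tracks are generated: the
#' genetic covariance matrix \code{G} (among-line covariance is \code{2 G}
#' for fully inbred lines), block and residual covariances, plate-covariate
#' effects, the trait-fitness covariance vector \code{sTrue}, fitness genetic
#' variance \code{Vw}, and true selection gradients \code{betaTrue}.
#'
#' @slot nLines named integer vector, lines per population.
#' @slot repsPerLine integer, plates per line per environment.
#' @slot nBlocks integer, assay blocks.
#' @slot nYears integer, assay years (fixed year shifts).
#' @slot nTraits integer, number of traits (7).
#' @slot G symmetric PSD matrix, genetic covariance (log-rate^2 units).
#' @slot Vblock symmetric PSD matrix, block covariance.
#' @slot Eresid symmetric PSD matrix, residual covariance.
#' @slot covariateEffects 7 x nTraits matrix of coefficients for the three
#'   standardized plate covariates, their pairwise products and the
#'   three-way product.
#' @slot sTrue numeric, trait-fitness genetic covariances.
#' @slot Vw numeric(1), genetic variance of relative fitness.
#' @slot betaTrue numeric, true directional selection gradients.
#' @slot yearEffects numeric, fixed shift per year (applied to all traits).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nLines = "integer", repsPerLine = "integer", nBlocks = "integer",
    nYears = "integer", nTraits = "integer",
    G = "matrix", Vblock = "matrix", Eresid = "matrix",
    covariateEffects = "matrix",
    sTrue = "numeric", Vw = "numeric", betaTrue = "numeric",
    yearEffects = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  t <- object@nTraits
  msgs <- character()
  for (nm in c("G", "Vblock", "Eresid")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(t, t)))
      msgs <- c(msgs, sprintf("%s must be %d x %d", nm, t, t))
    else {
      ok <- .check_symmetric_psd(m, nm)
      if (!isTRUE(ok)) msgs <- c(msgs, ok)
    }
  }
  if (length(object@sTrue) != t) msgs <- c(msgs, "sTrue must have nTraits entries")
  if (length(object@betaTrue) != t) msgs <- c(msgs, "betaTrue must have nTraits entries")
  if (!identical(dim(object@covariateEffects), c(7L, t)))
    msgs <- c(msgs, "covariateEffects must be 7 x nTraits")
  if (length(msgs) == 0L && length(object@sTrue) == t) {
    aug <- 2 * rbind(cbind(object@G, object@sTrue),
                     c(object@sTrue, object@Vw))
    ok <- .check_symmetric_psd(aug, "[[2G, 2s], [2s', 2Vw]]")
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
  }
  if (any(object@nLines < 1L)) msgs <- c(msgs, "nLines must be positive")
  if (object@repsPerLine < 1L) msgs <- c(msgs, "repsPerLine must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Generator matrix of the movement-state Markov chain
#'
#' A 3 x 3 continuous-time Markov chain generator over the movement states
#' still (S), forward (F), backward (B). Off-diagonal entries are the
#' per-second transition rates \code{q[i, j] > 0}; each diagonal entry is
#' minus the sum of its row's off-diagonals, so rows sum to zero and the
#' self-transition rates are never free parameters.
#'
#' @slot q 3 x 3 numeric matrix with zero row sums.
#' @export
setClass("TransitionRateMatrix", representation(q = "matrix"))

setValidity("TransitionRateMatrix", function(object) {
  q <- object@q
  if (!is.matrix(q) || nrow(q) != ncol(q))
    return("q must be a square matrix")
  off <- q[row(q) != col(q)]
  if (any(!is.finite(q))) return("q must be finite")
  if (any(off < 0)) return("off-diagonal rates must be non-negative")
  if (max(abs(rowSums(q))) > 1e-8 * max(1, max(abs(q))))
    return("rows of a generator matrix must sum to zero")
  TRUE
})

#' Fitted transition-rate matrix with uncertainty
#'
#' Result of estimating the six free transition rates from pooled
#' one-frame transition counts, by posterior-mode (MAP) optimization or by
#' Metropolis sampling under the log-normal rate prior.
#'
#' @slot Q the estimated \linkS4class{TransitionRateMatrix}.
#' @slot logRates named numeric, natural-log point estimates of the six
#'   off-diagonal rates (the scale on which all downstream analysis runs).
#' @slot samples matrix of posterior draws of log rates (MCMC method), or a
#'   0-row matrix for MAP.
#' @slot method "map" or "mcmc".
#' @slot se named numeric, approximate standard errors of the log rates
#'   (curvature-based for MAP, posterior SD for MCMC).
#' @slot convergence logical, optimizer/chain health flag.
#' @slot logPosterior numeric(1), value at the point estimate.
#' @export
setClass("RateFit",
  representation(Q = "TransitionRateMatrix", logRates = "numeric",
                 samples = "matrix", method = "character", se = "numeric",
                 convergence = "logical", logPosterior = "numeric"))

#' Posterior sample of a G-matrix
#'
#' Retained MCMC samples of the genetic covariance matrix (half the
#' among-line covariance of fully inbred lines), together with the block and
#' residual covariance samples of the same multivariate mixed model and
#' lag-1 autocorrelation diagnostics of the retained chain.
#'
#' @slot G array, nTraits x nTraits x nSamples of G-matrix draws.
#' @slot blockCov array of block covariance draws.
#' @slot residCov array of residual covariance draws.
#' @slot traits character, trait names.
#' @slot autocorr matrix, lag-1 autocorrelation of each G element.
#' @slot settings the \linkS4class{McmcSettings} used.
#' @export
setClass("GPosterior",
  representation(G = "array", blockCov = "array", residCov = "array",
                 traits = "character", autocorr = "matrix",
                 settings = "ANY"))

setValidity("GPosterior", function(object) {
  d <- dim(object@G)
  if (length(d) != 3L) return("G must be a 3-d array")
  if (d[1] != d[2]) return("G samples must be square")
  if (length(object@traits) != d[1]) return("traits must match G dimension")
  TRUE
})

#' Posterior sample of a fitness-augmented G-matrix
#'
#' As \linkS4class{GPosterior} but over the traits plus relative fitness;
#' the last column of each sample holds the genetic trait-fitness
#' covariances, i.e. the selection differentials.
#'
#' @slot fitnessName character, name of the fitness column (last trait).
#' @export
setClass("GqwPosterior", contains = "GPosterior",
         representation(fitnessName = "character"))

#' SSCP matrix and Wilks test for one MANOVA term
#'
#' @slot factorName model term.
#' @slot SSCP sums-of-squares and cross-products matrix.
#' @slot df numeric, term degrees of freedom.
#' @slot wilks numeric, Wilks' lambda (NA for the residual term).
#' @slot approxF numeric, Rao's F approximation.
#' @slot numDf,denDf numeric, F degrees of freedom.
#' @slot pValue numeric.
#' @export
setClass("SscpResult",
  representation(factorName = "character", SSCP = "matrix", df = "numeric",
                 wilks = "numeric", approxF = "numeric", numDf = "numeric",
                 denDf = "numeric", pValue = "numeric"))

#' Canonical trait (unit eigenvector with its share of variation)
#'
#' A composite trait: a unit-norm loading vector over the measured traits
#' plus the percent of matrix variation its eigenvalue explains. Sign is
#' fixed so the largest-magnitude loading is positive.
#'
#' @slot loadings named unit numeric vector.
#' @slot percentVariance numeric(1), in percent.
#' @export
setClass("CanonicalTrait",
  representation(loadings = "numeric", percentVariance = "numeric"))

setValidity("CanonicalTrait", function(object) {
  n <- sqrt(sum(object@loadings^2))
  if (abs(n - 1) > 1e-6) return("loadings must have unit norm")
  TRUE
})

#' Mode and nested credible intervals of a posterior scalar
#'
#' @slot mode numeric(1), kernel-density posterior mode.
#' @slot ci83 numeric(2), 83% highest-posterior-density interval.
#' @slot ci95 numeric(2), 95% HPD interval.
#' @export
setClass("CredibleSummary",
  representation(mode = "numeric", ci83 = "numeric", ci95 = "numeric"))

setValidity("CredibleSummary", function(object) {
  if (length(object@ci83) != 2L || length(object@ci95) != 2L)
    return("intervals must have two endpoints")
  if (object@ci83[1] < object@ci95[1] - 1e-9 ||
      object@ci83[2] > object@ci95[2] + 1e-9)
    return("ci83 must be contained in ci95")
  TRUE
})

#' Random-skewers comparison of population G-matrices
#'
#' @slot skewers matrix, one unit direction per row.
#' @slot summaries data.frame, per skewer and population the posterior mode
#'   and 95% HPD of the projected genetic variance, plus the retained flag.
#' @slot retained integer, indices of skewers whose ancestral and evolved
#'   projected-variance 95% intervals are disjoint.
#' @slot R matrix, among-population covariance of responses to retained
#'   skewers (the R-matrix), or a 0 x 0 matrix when none are retained.
#' @slot eMax \linkS4class{CanonicalTrait} or NULL, leading axis of R.
#' @export
setClass("SkewersResult",
  representation(skewers = "matrix", summaries = "data.frame",
                 retained = "integer", R = "matrix", eMax = "ANY"))

#' MCMC settings for the multivariate mixed model
#'
#' Defaults follow long-chain practice for inbred-line G-matrix estimation:
#' 2.1 million iterations, 100,000 burn-in, thinning interval 2000 (1000
#' retained samples), improper flat covariance priors (nu = 0).
#'
#' @slot nIterations,burnIn,thin integers.
#' @slot prior "flat" or "invwishart".
#' @slot priorV matrix or NULL, inverse-Wishart scale (proper prior).
#' @slot priorNu numeric, inverse-Wishart degrees of belief.
#' @slot seed integer.
#' @export
setClass("McmcSettings",
  representation(nIterations = "integer", burnIn = "integer", thin = "integer",
                 prior = "character", priorV = "ANY", priorNu = "numeric",
                 seed = "integer"))

setValidity("McmcSettings", function(object) {
  kept <- (object@nIterations - object@burnIn) %/% object@thin
  if (object@burnIn >= object@nIterations) return("burnIn must be below nIterations")
  if (kept < 2L) return("settings retain fewer than 2 samples")
  if (!object@prior %in% c("flat", "invwishart"))
    return("prior must be 'flat' or 'invwishart'")
  TRUE
})
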