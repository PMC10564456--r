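## Retrospective selection analysis: selection differentials from the
## fitness-augmented G posterior, genetic and phenotypic selection
## gradients by solving G beta = target per posterior sample, and the
## prediction diagnostics (folded angle and magnitude ratio between
## expected and observed divergence).

#' Selection differentials from a fitness-augmented posterior
#'
#' Extracts, per retained sample, the trait-fitness genetic covariance
#' column of the augmented matrix.
#'
#' @param gqw a \linkS4class{GqwPosterior}.
#' @return matrix nSamples x nTraits of selection differentials.
#' @export
selectionDifferentials <- function(gqw) {
  stopifnot(is(gqw, "GqwPosterior"))
  d <- dim(gqw@G)
  t <- d[1] - 1L
  s <- t(gqw@G[seq_len(t), t + 1L, , drop = TRUE])
  if (d[3] == 1L) s <- matrix(s, 1L, t)
  colnames(s) <- gqw@traits[seq_len(t)]
  s
}

.solve_g <- function(G, target, condLimit = 1e8) {
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- eg$values
  cond <- if (min(lam) > 0) max(lam) / min(lam) else Inf
  if (is.finite(cond) && cond <= condLimit) {
    beta <- eg$vectors %*% ((t(eg$vectors) %*% target) / lam)
    list(beta = as.numeric(beta), flagged = FALSE, cond = cond)
  } else {
    keep <- lam > max(lam) / condLimit
    beta <- eg$vectors[, keep, drop = FALSE] %*%
      ((t(eg$vectors[, keep, drop = FALSE]) %*% target) / lam[keep])
    list(beta = as.numeric(beta), flagged = TRUE, cond = cond)
  }
}

.gradients <- function(gSource, target, condLimit) {
  Garr <- if (is(gSource, "GPosterior")) gSamples(gSource) else {
    a <- array(as.matrix(gSource), c(nrow(gSource), ncol(gSource), 1))
    a
  }
  ns <- dim(Garr)[3]
  t <- dim(Garr)[1]
  tm <- if (is.matrix(target)) target else
    matrix(target, ns, t, byrow = TRUE)
  beta <- matrix(NA_real_, ns, t)
  flagged <- logical(ns); cond <- numeric(ns)
  for (k in seq_len(ns)) {
    sol <- .solve_g(Garr[, , k], tm[min(k, nrow(tm)), ], condLimit)
    beta[k, ] <- sol$beta
    flagged[k] <- sol$flagged
    cond[k] <- sol$cond
  }
  if (is(gSource, "GPosterior")) colnames(beta) <- traitNames(gSource)
  attr(beta, "flagged") <- flagged
  attr(beta, "condition") <- cond
  beta
}

#' Genetic selection gradients (retrospective Lande equation)
#'
#' Solves \code{G beta_g = s} for every posterior G sample with the
#' selection-differential vector held fixed. Samples whose condition
#' number exceeds \code{condLimit} use an eigenvalue-truncated
#' pseudo-inverse and are flagged (never silently).
#'
#' @param gPosterior a \linkS4class{GPosterior} or a single G matrix.
#' @param s fixed selection-differential vector.
#' @param condLimit condition-number threshold for truncation.
#' @return matrix nSamples x nTraits of gradients with attributes
#'   \code{flagged} (per-sample truncation flag) and \code{condition}.
#' @export
geneticGradients <- function(gPosterior, s, condLimit = 1e8) {
  .gradients(gPosterior, s, condLimit)
}

#' Phenotypic selection gradients from observed divergence
#'
#' As \code{\link{geneticGradients}} with the observed divergence vector
#' in place of the selection differentials: \code{G beta = dq}.
#' \code{scaleDivisor} is display-only and never applied to the returned
#' estimates.
#'
#' @param gPosterior a \linkS4class{GPosterior} or a single G matrix.
#' @param dq fixed divergence vector for one replicate population.
#' @param condLimit condition-number threshold.
#' @param scaleDivisor optional display scaling, returned as an attribute.
#' @return matrix of gradients as in \code{\link{geneticGradients}}.
#' @export
phenotypicGradients <- function(gPosterior, dq, condLimit = 1e8,
                                scaleDivisor = NULL) {
  beta <- .gradients(gPosterior, dq, condLimit)
  if (!is.null(scaleDivisor)) attr(beta, "displayScale") <- scaleDivisor
  beta
}

#' Gradients with both G and s sampled
#'
#' Draws G and the selection differentials independently from their
#' respective posteriors (the two posteriors come from separate fits),
#' resampling the shorter set if sample counts differ, and solves
#' \code{G beta = s} pairwise; credible intervals are wider than the
#' fixed-s version.
#'
#' @param gPosterior a \linkS4class{GPosterior}.
#' @param gqw a \linkS4class{GqwPosterior} (source of s samples).
#' @param condLimit condition-number threshold.
#' @param seed RNG seed for pairing.
#' @return matrix of gradients with a \code{ciExcludesZero} attribute
#'   (per trait, whether the 95% HPD excludes 0).
#' @export
gradientsJoint <- function(gPosterior, gqw, condLimit = 1e8, seed = 1L) {
  sArr <- selectionDifferentials(gqw)
  Garr <- gSamples(gPosterior)
  ng <- dim(Garr)[3]; ns <- nrow(sArr)
  set.seed(seed)
  if (ns != ng) sArr <- sArr[sample.int(ns, ng, replace = TRUE), , drop = FALSE]
  beta <- .gradients(gPosterior, sArr, condLimit)
  if (nrow(beta) >= 100) {
    excl <- apply(beta, 2, function(x) {
      ci <- credibleInterval(x, 0.95)
      ci[1] > 0 || ci[2] < 0
    })
    attr(beta, "ciExcludesZero") <- excl
  }
  beta
}

#' Angle between expected and observed divergence
#'
#' Folded angle (degrees) between the selection-differential vector
#' (fixed, or one per posterior sample) and a fixed observed divergence
#' vector, with the null reference from \code{\link{nullAngles}}.
#'
#' @param sSource numeric vector or nSamples x nTraits matrix of
#'   selection differentials.
#' @param dq fixed divergence vector.
#' @return numeric vector of angles (length 1 for a fixed s).
#' @export
predictionAngle <- function(sSource, dq) {
  if (is.matrix(sSource))
    apply(sSource, 1, vectorAngle, v2 = dq)
  else vectorAngle(sSource, dq)
}

#' Magnitude ratio of observed to expected divergence
#'
#' Per-trait ratios \code{dq_i / s_i}; traits whose |s_i| falls below
#' \code{tol} are flagged unstable and excluded from the grand mean (an
#' unweighted mean over the remaining trait cells), with a logged count.
#'
#' @param dq observed divergence vector.
#' @param sSource numeric vector or matrix (one s per posterior sample).
#' @param tol instability threshold on |s_i|.
#' @return For a vector s: list(ratios, grandMean, excluded). For a
#'   matrix: list(ratios matrix, grandMean per sample, excluded counts).
#' @export
magnitudeRatio <- function(dq, sSource, tol = 1e-8) {
  one <- function(s) {
    unstable <- abs(s) < tol
    r <- ifelse(unstable, NA_real_, dq / s)
    list(ratios = r, grandMean = mean(r[!unstable]),
         excluded = sum(unstable))
  }
  if (is.matrix(sSource)) {
    res <- apply(sSource, 1, one)
    ratios <- t(vapply(res, `[[`, numeric(length(dq)), "ratios"))
    excl <- vapply(res, `[[`, numeric(1), "excluded")
    if (sum(excl) > 0)
      message(sum(excl), " trait cells excluded as unstable (|s| < tol)")
    list(ratios = ratios,
         grandMean = vapply(res, `[[`, numeric(1), "grandMean"),
         excluded = excl)
  } else {
    res <- one(sSource)
    if (res$excluded > 0)
      message(res$excluded, " trait cells excluded as unstable (|s| < tol)")
    res
  }
}
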