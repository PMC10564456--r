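## Eigen-geometry of G-matrices: canonical traits, folded angles between
## trait-space directions, projected genetic variance and its ratio to the
## leading eigenvalue, null angle distributions, and the random-skewers
## comparison of population G-matrices (R-matrix, e_max).

#' Eigendecomposition of a G-matrix
#'
#' Sorted decomposition with the sign convention that each eigenvector's
#' largest-magnitude loading is positive; small negative eigenvalues
#' (within \code{tol * trace}) are clipped at zero.
#'
#' @param G symmetric matrix.
#' @param tol relative clipping tolerance.
#' @return list with \code{values} (eigenvalues, descending),
#'   \code{vectors} (columns g1 = g_max, ...), \code{percent} (percent
#'   variance per axis), \code{clipped} (number of clipped eigenvalues).
#' @export
eigenG <- function(G, tol = 1e-12) {
  G <- as.matrix(G)
  if (max(abs(G - t(G))) > 1e-8 * max(1, max(abs(G))))
    stop("G must be symmetric")
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  clip <- tol * max(sum(abs(diag(G))), 1)
  neg <- ev$values < 0
  bad <- ev$values < -clip
  if (any(bad))
    message(sum(bad), " negative eigenvalues clipped at 0")
  ev$values[neg] <- 0
  V <- ev$vectors
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(G)
  tot <- sum(ev$values)
  list(values = ev$values, vectors = V,
       percent = if (tot > 0) 100 * ev$values / tot else
         rep(100 / length(ev$values), length(ev$values)),
       clipped = sum(bad))
}

#' Leading canonical trait of a G-matrix
#'
#' @param G symmetric matrix.
#' @param which eigenvector index (1 = g_max).
#' @return A \linkS4class{CanonicalTrait}.
#' @export
gmaxTrait <- function(G, which = 1L) {
  eg <- eigenG(G)
  new("CanonicalTrait",
      loadings = setNames(eg$vectors[, which], rownames(eg$vectors)),
      percentVariance = eg$percent[which])
}

#' Folded angle between two trait-space directions, in degrees
#'
#' \code{acos(|v1 . v2| / (|v1| |v2|))}: the absolute value folds angles
#' into [0, 90] degrees, since v and -v span the same canonical trait.
#'
#' @param v1,v2 non-zero numeric vectors of equal length.
#' @return numeric(1) angle in degrees.
#' @export
vectorAngle <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors differ in length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  ct <- abs(sum(v1 * v2)) / (n1 * n2)
  (180 / pi) * acos(min(ct, 1))
}

#' Genetic variance along a direction
#'
#' The Rayleigh quotient \code{v' G v / |v|^2}: the variance of breeding
#' values projected on \code{v}.
#'
#' @param G symmetric PSD matrix.
#' @param v non-zero direction.
#' @return numeric(1).
#' @export
projectVariance <- function(G, v) {
  if (sqrt(sum(v^2)) == 0) stop("zero vector has no direction")
  as.numeric(t(v) %*% as.matrix(G) %*% v) / sum(v^2)
}

#' Proportion of maximal genetic variance along a direction
#'
#' \code{projectVariance(G, v) / lambda_1}, between 0 (no variance along
#' \code{v}) and 1 (\code{v} spans the leading eigenspace).
#'
#' @param G symmetric PSD matrix.
#' @param v non-zero direction.
#' @return numeric(1) in [0, 1].
#' @export
piRatio <- function(G, v) {
  l1 <- eigenG(G)$values[1]
  if (l1 <= 0) stop("G has no genetic variance (lambda_1 = 0)")
  min(projectVariance(G, v) / l1, 1)
}

#' Null distribution of angles between random directions
#'
#' Folded angles between pairs of vectors with i.i.d. U(-1, 1)
#' components, the null reference for observed trait-space angles.
#'
#' @param dim trait-space dimension.
#' @param n number of random pairs.
#' @param seed RNG seed.
#' @return numeric vector of n angles in [0, 90] degrees.
#' @export
nullAngles <- function(dim = 7L, n = 1000L, seed = 1L) {
  if (n < 2L) stop("n must be at least 2")
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    vectorAngle(runif(dim, -1, 1), runif(dim, -1, 1))
  }, numeric(1))
}

#' Posterior projected variance against a randomization null
#'
#' Projects each posterior G sample along a fixed direction and contrasts
#' the posterior with the 95% envelope of randomized-data posterior modes
#' (from \code{\link{nullGDistribution}} projected on the same direction).
#'
#' @param gPosterior a \linkS4class{GPosterior}.
#' @param v fixed direction.
#' @param nullModes numeric vector of null posterior modes of the
#'   projected variance (one per randomization).
#' @return list with \code{summary} (a \linkS4class{CredibleSummary} of
#'   the posterior projection), \code{nullEnvelope} (2.5/97.5 percentiles
#'   of the null modes), and \code{significant} (posterior mode outside
#'   the envelope).
#' @export
varianceAlongWithNull <- function(gPosterior, v, nullModes) {
  if (!length(nullModes)) stop("empty null set")
  proj <- apply(gSamples(gPosterior), 3, projectVariance, v = v)
  sm <- credibleSummary(proj, minSamples = min(100L, length(proj)))
  env <- unname(stats::quantile(nullModes, c(0.025, 0.975)))
  list(summary = sm, nullEnvelope = env,
       significant = sm@mode < env[1] || sm@mode > env[2])
}

#' Project null G-element modes along a direction
#'
#' Reassembles each shuffle's posterior-mode G from the element-wise modes
#' returned by \code{\link{nullGDistribution}} and projects it on \code{v}.
#'
#' @param nullG matrix from \code{\link{nullGDistribution}}.
#' @param v direction.
#' @param traits trait names used to build \code{nullG}.
#' @return numeric vector of null projected variances (one per shuffle).
#' @export
projectNullModes <- function(nullG, v, traits = .TRAITS) {
  t <- length(traits)
  idx <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  apply(nullG, 1, function(row) {
    m <- matrix(0, t, t)
    m[idx] <- row[seq_len(nrow(idx))]
    m <- m + t(m) - diag(diag(m))
    projectVariance(m, v)
  })
}

#' Random-skewers comparison of population G-matrices
#'
#' Projects each of \code{nVectors} random unit directions (i.i.d.
#' U(-1, 1) components, normalized) through every population's posterior
#' G samples. A skewer is retained when the ancestral population's 95%
#' HPD of projected variance is disjoint from that of at least one
#' evolved population. The R-matrix accumulates, over retained skewers,
#' the among-population covariance of the mean-centered response vectors
#' \code{G_p b} (posterior-mean G per population), scaled by
#' \code{1 / (n_retained (n_pop - 1))}; its leading eigenvector is e_max,
#' the main canonical trait of genetic differentiation.
#'
#' @param posteriors named list of \linkS4class{GPosterior}, the first
#'   element (or \code{ancestor}) being the ancestral population.
#' @param nVectors number of random skewers.
#' @param seed RNG seed.
#' @param ancestor name or index of the ancestral population.
#' @param sampling "uniform" (U(-1,1) cube, the package convention) or
#'   "gaussian" (uniform on the sphere).
#' @return A \linkS4class{SkewersResult}; when no skewer is retained, the
#'   R slot is a 0 x 0 matrix and eMax is NULL.
#' @export
randomSkewers <- function(posteriors, nVectors = 1000L, seed = 1L,
                          ancestor = 1L,
                          sampling = c("uniform", "gaussian")) {
  sampling <- match.arg(sampling)
  if (length(posteriors) < 2L) stop("need at least two population posteriors")
  t <- length(traitNames(posteriors[[1]]))
  if (!all(vapply(posteriors, function(p) length(traitNames(p)) == t,
                  logical(1))))
    stop("population posteriors differ in trait dimension")
  if (is.character(ancestor)) ancestor <- match(ancestor, names(posteriors))
  set.seed(seed)
  B <- if (sampling == "uniform")
    matrix(runif(nVectors * t, -1, 1), nVectors, t)
  else matrix(rnorm(nVectors * t), nVectors, t)
  B <- B / sqrt(rowSums(B^2))
  npop <- length(posteriors)
  pop_names <- if (!is.null(names(posteriors))) names(posteriors) else
    paste0("pop", seq_len(npop))
  ci_lo <- ci_hi <- md <- matrix(NA_real_, nVectors, npop,
                                 dimnames = list(NULL, pop_names))
  for (p in seq_len(npop)) {
    Garr <- gSamples(posteriors[[p]])
    for (k in seq_len(nVectors)) {
      proj <- apply(Garr, 3, projectVariance, v = B[k, ])
      ci <- credibleInterval(proj, 0.95, minSamples = min(100L, length(proj)))
      ci_lo[k, p] <- ci[1]; ci_hi[k, p] <- ci[2]
      md[k, p] <- mean(proj)
    }
  }
  evolved <- setdiff(seq_len(npop), ancestor)
  retained <- which(vapply(seq_len(nVectors), function(k) {
    any(ci_hi[k, ancestor] < ci_lo[k, evolved] |
          ci_hi[k, evolved] < ci_lo[k, ancestor])
  }, logical(1)))
  summaries <- data.frame(
    skewer = rep(seq_len(nVectors), npop),
    population = rep(pop_names, each = nVectors),
    mean = as.vector(md), ci95_lo = as.vector(ci_lo),
    ci95_hi = as.vector(ci_hi),
    retained = rep(seq_len(nVectors) %in% retained, npop))
  if (!length(retained)) {
    return(new("SkewersResult", skewers = B, summaries = summaries,
               retained = integer(0), R = matrix(numeric(0), 0, 0),
               eMax = NULL))
  }
  Gmean <- lapply(posteriors, posteriorMeanG)
  R <- matrix(0, t, t)
  for (k in retained) {
    resp <- vapply(Gmean, function(g) as.numeric(g %*% B[k, ]),
                   numeric(t))                      # t x npop
    resp <- resp - rowMeans(resp)
    R <- R + resp %*% t(resp)
  }
  R <- R / (length(retained) * (npop - 1))
  dimnames(R) <- list(traitNames(posteriors[[1]]), traitNames(posteriors[[1]]))
  new("SkewersResult", skewers = B, summaries = summaries,
      retained = as.integer(retained), R = R, eMax = gmaxTrait(R))
}
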