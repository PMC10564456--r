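## Estimation of movement-state transition rates from discretely observed
## tracks. Locomotion in one dimension is summarized by the six transition
## rates between still (S), forward (F) and backward (B); self-transition
## rates are constrained so generator rows sum to zero and are never free
## parameters.

.OFFDIAG <- cbind(row = c(1L, 1L, 2L, 2L, 3L, 3L),
                  col = c(2L, 3L, 1L, 3L, 1L, 2L))
.RATE_NAMES <- c("q_SF", "q_SB", "q_FS", "q_FB", "q_BS", "q_BF")

.theta_to_Q <- function(theta) {
  q <- matrix(0, 3, 3, dimnames = list(.STATES, .STATES))
  q[.OFFDIAG] <- exp(theta)
  diag(q) <- -rowSums(q)
  q
}

#' Create a transition-rate matrix from the six free rates
#'
#' @param rates named or ordered numeric of the six off-diagonal rates
#'   (order \code{q_SF, q_SB, q_FS, q_FB, q_BS, q_BF}), per second.
#' @return A \linkS4class{TransitionRateMatrix}.
#' @export
transitionRateMatrix <- function(rates) {
  if (!is.null(names(rates))) rates <- rates[.RATE_NAMES]
  stopifnot(length(rates) == 6L, all(is.finite(rates)), all(rates > 0))
  q <- .theta_to_Q(log(as.numeric(rates)))
  new("TransitionRateMatrix", q = q)
}

.track_list <- function(tracks) {
  if (is.data.frame(tracks)) {
    stopifnot(all(c("track_id", "frame", "state") %in% names(tracks)))
    tracks <- lapply(split(tracks, tracks$track_id),
                     function(d) d$state[order(d$frame)])
  }
  if (is.character(tracks)) tracks <- list(tracks)
  tracks
}

#' Count one-frame transitions pooled over tracks
#'
#' @param tracks a data.frame (\code{track_id, frame, state}) or a list of
#'   character state sequences over \{S, F, B\}.
#' @param dropShort tracks with fewer than 2 frames contribute no
#'   transitions; their number is reported in \code{attr(, "dropped")}.
#' @return 3 x 3 integer matrix \code{n[i, j]} of observed i -> j frame
#'   pairs, with \code{attr(, "dropped")} short-track count.
#' @export
countTransitions <- function(tracks, dropShort = TRUE) {
  tracks <- .track_list(tracks)
  n <- matrix(0L, 3, 3, dimnames = list(.STATES, .STATES))
  dropped <- 0L
  for (tr in tracks) {
    s <- match(tr, .STATES)
    if (anyNA(s))
      stop("states outside the {S, F, B} alphabet: ",
           paste(unique(tr[is.na(s)]), collapse = ", "))
    if (length(s) < 2L) { dropped <- dropped + 1L; next }
    from <- s[-length(s)]; to <- s[-1L]
    idx <- (to - 1L) * 3L + from
    tab <- tabulate(idx, nbins = 9L)
    n <- n + matrix(tab, 3, 3)
  }
  storage.mode(n) <- "integer"
  attr(n, "dropped") <- dropped
  n
}

.transition_prob <- function(Q, dt) {
  P <- as.matrix(Matrix::expm(Q * dt))
  P[P < 0] <- 0
  P
}

.log_posterior <- function(theta, n, dt, mu, sd) {
  P <- .transition_prob(.theta_to_Q(theta), dt)
  sum(n * log(pmax(P, 1e-300))) - sum((theta - mu)^2) / (2 * sd^2)
}

#' Estimate transition rates from pooled counts
#'
#' Maximizes (MAP) or samples (random-walk Metropolis) the posterior of the
#' six log rates: the discrete-observation likelihood
#' \code{sum(n[i,j] log(expm(Q dt)[i,j]))} plus independent normal priors
#' \code{ln q ~ N(ln 2, 0.6)} on the log scale. The row-sum-zero constraint
#' holds by construction, so self-transition rates are never estimated.
#' For \code{method = "mcmc"} the point estimate is the posterior mean of
#' the log rates, matching the downstream convention that all analysis is
#' on the natural-log scale.
#'
#' @param counts 3 x 3 matrix from \code{\link{countTransitions}}.
#' @param frameInterval seconds between frames (0.25 = 4 Hz).
#' @param priorMu,priorSd log-normal prior location and standard deviation
#'   of \code{ln q}.
#' @param method "map" (default, quasi-Newton) or "mcmc" (Metropolis).
#' @param nIter,burnIn,thin,proposalSd Metropolis controls.
#' @param seed RNG seed for the sampler.
#' @return A \linkS4class{RateFit}.
#' @export
estimateRates <- function(counts, frameInterval = 0.25,
                          priorMu = log(2), priorSd = 0.6,
                          method = c("map", "mcmc"),
                          nIter = 20000L, burnIn = 5000L, thin = 10L,
                          proposalSd = 0.08, seed = 1L) {
  method <- match.arg(method)
  n <- as.matrix(counts)
  stopifnot(identical(dim(n), c(3L, 3L)))
  if (any(n < 0)) stop("negative transition counts")
  total <- sum(n)
  if (total == 0) stop("no observed transitions; rate estimation refused")

  ## initialization: embedding oracle if valid, else occupancy-weighted
  ## empirical rates, else the prior mode
  emb <- discreteEmbedding(n, frameInterval)
  if (emb$status == "ok") {
    theta0 <- log(pmax(emb$Q@q[.OFFDIAG], 1e-4))
  } else {
    emp <- n / pmax(rowSums(n), 1) / frameInterval
    theta0 <- log(pmax(emp[.OFFDIAG], 0.05))
  }
  theta0[!is.finite(theta0)] <- priorMu

  if (method == "map") {
    fit <- optim(theta0, function(th) -.log_posterior(th, n, frameInterval,
                                                      priorMu, priorSd),
                 method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-12))
    if (fit$convergence != 0)
      warning("MAP optimizer did not report convergence (code ",
              fit$convergence, ")")
    theta <- setNames(fit$par, .RATE_NAMES)
    se <- rep(NA_real_, 6)
    h <- try(solve(fit$hessian), silent = TRUE)
    if (!inherits(h, "try-error")) se <- sqrt(pmax(diag(h), 0))
    new("RateFit", Q = new("TransitionRateMatrix", q = .theta_to_Q(theta)),
        logRates = theta, samples = matrix(numeric(0), 0, 6),
        method = "map", se = setNames(se, .RATE_NAMES),
        convergence = fit$convergence == 0, logPosterior = -fit$value)
  } else {
    set.seed(seed)
    theta <- theta0
    lp <- .log_posterior(theta, n, frameInterval, priorMu, priorSd)
    kept <- matrix(NA_real_, (nIter - burnIn) %/% thin, 6,
                   dimnames = list(NULL, .RATE_NAMES))
    k <- 0L; acc <- 0L; acc_win <- 0L; step <- proposalSd
    for (it in seq_len(nIter)) {
      prop <- theta + rnorm(6, 0, step)
      lp_prop <- .log_posterior(prop, n, frameInterval, priorMu, priorSd)
      if (log(runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop
        acc_win <- acc_win + 1L
        if (it > burnIn) acc <- acc + 1L
      }
      ## Robbins-Monro-style step tuning toward ~23% acceptance, frozen
      ## after burn-in so the retained chain targets a fixed kernel
      if (it <= burnIn && it %% 200L == 0L) {
        rate <- acc_win / 200
        step <- step * exp(rate - 0.23)
        acc_win <- 0L
      }
      if (it > burnIn && (it - burnIn) %% thin == 0L) {
        k <- k + 1L
        kept[k, ] <- theta
      }
    }
    acc <- acc / max(nIter - burnIn, 1L)
    post_mean <- colMeans(kept)
    new("RateFit",
        Q = new("TransitionRateMatrix", q = .theta_to_Q(post_mean)),
        logRates = post_mean, samples = kept, method = "mcmc",
        se = apply(kept, 2, sd),
        convergence = acc > 0.05,
        logPosterior = .log_posterior(post_mean, n, frameInterval,
                                      priorMu, priorSd))
  }
}

#' Matrix-logarithm embedding oracle for transition rates
#'
#' Row-normalizes the count matrix to an empirical one-step transition
#' matrix and takes its matrix logarithm divided by the frame interval.
#' When the logarithm is a valid generator this recovers Q exactly from
#' exact transition proportions; it serves as an independent cross-check
#' and as optimizer initialization. Not every stochastic matrix is
#' embeddable, so failure is an explicit status, not an error.
#'
#' @param counts 3 x 3 non-negative matrix.
#' @param frameInterval seconds between frames.
#' @param tol tolerance for negative off-diagonal entries of the logm,
#'   relative to the largest rate.
#' @return list(status, Q) with status one of "ok", "degenerate"
#'   (no off-diagonal signal), "embedding_failure"; Q is a
#'   \linkS4class{TransitionRateMatrix} when status is "ok", else NULL.
#' @export
discreteEmbedding <- function(counts, frameInterval = 0.25, tol = 1e-6) {
  n <- as.matrix(counts)
  rs <- rowSums(n)
  if (any(rs == 0)) return(list(status = "embedding_failure", Q = NULL))
  P <- n / rs
  if (sum(n[row(n) != col(n)]) == 0)
    return(list(status = "degenerate", Q = NULL))
  L <- try(suppressWarnings(pracma::logm(P)), silent = TRUE)
  if (inherits(L, "try-error") || any(!is.finite(L)) ||
      max(abs(Im(as.complex(L)))) > 1e-8)
    return(list(status = "embedding_failure", Q = NULL))
  Qh <- Re(L) / frameInterval
  off <- Qh[row(Qh) != col(Qh)]
  scale <- max(abs(Qh), 1e-12)
  if (any(off < -tol * scale))
    return(list(status = "embedding_failure", Q = NULL))
  Qh[row(Qh) != col(Qh)] <- pmax(Qh[row(Qh) != col(Qh)], 0)
  diag(Qh) <- 0
  diag(Qh) <- -rowSums(Qh)
  dimnames(Qh) <- list(.STATES, .STATES)
  list(status = "ok", Q = new("TransitionRateMatrix", q = Qh))
}
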