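## Synthetic-data generators with known ground truth for every downstream
## stage: inbred-line phenotype panels, per-line fitness, Gillespie state
## tracks, divergence vectors, and the neutral drift expectation.

.default_G <- function() {
  ## A structured ground-truth G on the log-rate scale: one dominant axis
  ## (the still-to-X rates covary positively with each other and with body
  ## size, negatively with the remaining rates), mirroring the covariance
  ## pattern typical of inbred-line locomotion panels.
  v <- c(0.25, 0.30, 0.15, 0.30, 0.10, 0.30, 0.25)
  sgn <- c(1, 1, -1, -1, -1, -1, 1)
  R <- 0.55 * outer(sgn, sgn)
  diag(R) <- 1
  G <- diag(sqrt(v)) %*% R %*% diag(sqrt(v))
  dimnames(G) <- list(.TRAITS, .TRAITS)
  (G + t(G)) / 2
}

.default_s <- function() {
  setNames(c(0.06, 0.08, -0.05, -0.04, -0.03, -0.05, 0.07), .TRAITS)
}

#' Build a simulation configuration
#'
#' Defaults reproduce the study conditions of the inbred-line panels:
#' 186/61/61/42 lines for the ancestral and three evolved populations, two
#' plates (replicates) per line, blocks nested in two assay years, seven
#' traits, among-line covariance \code{2 G}, standardized plate covariates
#' acting through main effects, pairwise and three-way interactions, and a
#' fitness-augmented covariance \code{2 [[G, s], [s', Vw]]}.
#'
#' @param nLines integer vector (recycled over populations) of lines per
#'   population.
#' @param repsPerLine plates per line per environment.
#' @param nBlocks number of assay blocks.
#' @param nYears number of assay years.
#' @param G,Vblock,Eresid symmetric PSD covariance matrices (traits scale).
#' @param covariateEffects 7 x nTraits coefficient matrix for the
#'   temperature/humidity/log-density effect structure.
#' @param sTrue trait-fitness genetic covariance vector.
#' @param Vw genetic variance of relative fitness.
#' @param betaTrue true selection gradient vector.
#' @param yearEffects fixed additive shift per year.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nLines = c(186L, 61L, 61L, 42L),
                             repsPerLine = 2L,
                             nBlocks = 20L,
                             nYears = 2L,
                             G = .default_G(),
                             Vblock = diag(0.05, 7),
                             Eresid = diag(0.20, 7),
                             covariateEffects = NULL,
                             sTrue = .default_s(),
                             Vw = 0.10,
                             betaTrue = NULL,
                             yearEffects = NULL,
                             seed = 1L) {
  nTraits <- nrow(G)
  nLines <- rep_len(as.integer(nLines), length(nLines))
  if (is.null(names(nLines)))
    names(nLines) <- .POPULATIONS[seq_along(nLines)]
  if (is.null(covariateEffects)) {
    ## modest main effects, weaker interactions
    covariateEffects <- rbind(matrix(0.10, 3, nTraits),
                              matrix(0.03, 3, nTraits),
                              matrix(0.01, 1, nTraits))
  }
  if (is.null(betaTrue)) {
    G0 <- G
    betaTrue <- as.numeric(solve(G0 + diag(1e-8, nTraits), sTrue))
  }
  if (is.null(yearEffects)) yearEffects <- seq_len(nYears) * 0.05 - 0.05
  rownames(covariateEffects) <- c("temperature", "humidity", "log_density",
                                  "t:h", "t:d", "h:d", "t:h:d")
  G <- as.matrix(G)
  dimnames(G) <- list(.TRAITS[seq_len(nTraits)], .TRAITS[seq_len(nTraits)])
  cfg <- new("SimulationConfig",
             nLines = nLines, repsPerLine = as.integer(repsPerLine),
             nBlocks = as.integer(nBlocks), nYears = as.integer(nYears),
             nTraits = as.integer(nTraits),
             G = G, Vblock = as.matrix(Vblock), Eresid = as.matrix(Eresid),
             covariateEffects = covariateEffects,
             sTrue = as.numeric(sTrue), Vw = as.numeric(Vw),
             betaTrue = as.numeric(betaTrue),
             yearEffects = as.numeric(yearEffects), seed = as.integer(seed))
  validObject(cfg)
  cfg
}

.rmvnorm <- function(n, sigma) {
  p <- nrow(sigma)
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  L <- ev$vectors %*% diag(sqrt(ev$values), p)
  matrix(rnorm(n * p), n, p) %*% t(L)
}

.assert_psd <- function(m, name) {
  ok <- .check_symmetric_psd(as.matrix(m), name)
  if (!isTRUE(ok)) stop(ok, call. = FALSE)
}

#' Simulate an inbred-line phenotype panel
#'
#' Draws per-line breeding values with covariance \code{2 G} (the
#' among-line doubling for fully inbred lines), block effects with
#' covariance \code{Vblock}, i.i.d. standard-normal plate covariates pushed
#' through the seven-term effect structure, fixed year shifts, and residual
#' noise with covariance \code{Eresid}, independently in each environment.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param environments character, environments to simulate (independent
#'   line effects in each).
#' @param meanShifts optional population x trait matrix of true mean
#'   divergence added to evolved populations (rownames = population).
#' @return A phenotype table (data.frame) with design columns
#'   \code{line_id, population, environment, block, year}, standardized
#'   covariates, and the seven traits. The true per-line breeding values
#'   are attached as \code{attr(, "breeding_values")}.
#' @export
simulateLinePanel <- function(config,
                              environments = c("low_salt", "high_salt"),
                              meanShifts = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .assert_psd(config@G, "G")
  .assert_psd(config@Vblock, "Vblock")
  .assert_psd(config@Eresid, "Eresid")
  set.seed(config@seed)
  t <- config@nTraits
  traits <- .TRAITS[seq_len(t)]
  pops <- names(config@nLines)
  blocks_per_year <- split(seq_len(config@nBlocks),
                           rep(seq_len(config@nYears), length.out = config@nBlocks))
  rows <- list()
  bvs <- list()
  for (env in environments) {
    block_eff <- .rmvnorm(config@nBlocks, config@Vblock)
    for (p in seq_along(pops)) {
      nl <- config@nLines[p]
      a <- .rmvnorm(nl, 2 * config@G)   # breeding values, among-line cov 2G
      line_ids <- sprintf("%s_L%03d", pops[p], seq_len(nl))
      rownames(a) <- line_ids
      bvs[[paste(env, pops[p], sep = ".")]] <- a
      shift <- numeric(t)
      if (!is.null(meanShifts) && pops[p] %in% rownames(meanShifts))
        shift <- as.numeric(meanShifts[pops[p], ])
      n_obs <- nl * config@repsPerLine
      line_idx <- rep(seq_len(nl), each = config@repsPerLine)
      block <- sample(config@nBlocks, n_obs, replace = TRUE)
      year <- rep(NA_integer_, n_obs)
      for (y in seq_along(blocks_per_year))
        year[block %in% blocks_per_year[[y]]] <- y
      covars <- matrix(rnorm(n_obs * 3), n_obs, 3,
                       dimnames = list(NULL, c("temperature", "humidity",
                                               "log_density")))
      X <- cbind(covars,
                 covars[, 1] * covars[, 2], covars[, 1] * covars[, 3],
                 covars[, 2] * covars[, 3],
                 covars[, 1] * covars[, 2] * covars[, 3])
      mu <- X %*% config@covariateEffects +
        a[line_idx, , drop = FALSE] +
        block_eff[block, , drop = FALSE] +
        matrix(config@yearEffects[year], n_obs, t) +
        matrix(shift, n_obs, t, byrow = TRUE)
      y_obs <- mu + .rmvnorm(n_obs, config@Eresid)
      colnames(y_obs) <- traits
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = line_ids[line_idx],
        population = pops[p],
        environment = env,
        block = sprintf("B%02d", block),
        year = sprintf("Y%d", year),
        covars, y_obs,
        stringsAsFactors = FALSE)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  ## covariates are standardized over the analysis set, as done before any
  ## model fitting on real plate covariates
  for (cv in c("temperature", "humidity", "log_density"))
    panel[[cv]] <- as.numeric(scale(panel[[cv]]))
  attr(panel, "breeding_values") <- bvs
  attr(panel, "seed") <- config@seed
  panel
}

#' Attach simulated relative fitness to a panel
#'
#' Draws one relative-fitness value per line whose among-line covariance
#' with the trait breeding values is \code{2 sTrue} and whose among-line
#' variance is \code{2 Vw}, using the conditional normal of the
#' fitness-augmented covariance \code{2 [[G, s], [s', Vw]]}; fitness is
#' then divided by its mean so the panel mean is 1 (a relative-fitness
#' proxy).
#'
#' @param panel output of \code{\link{simulateLinePanel}}.
#' @param config the \linkS4class{SimulationConfig} used to build it.
#' @param environment which environment's breeding values fitness covaries
#'   with (fitness is expressed in the novel environment).
#' @return The panel with a \code{fitness} column (constant within line;
#'   \code{NA} for lines of other environments is not used since fitness is
#'   per line). Per-line values are in \code{attr(, "line_fitness")}.
#' @export
simulateFitness <- function(panel, config, environment = "high_salt") {
  stopifnot(is(config, "SimulationConfig"))
  bvs <- attr(panel, "breeding_values")
  if (is.null(bvs)) stop("panel lacks breeding values; was it produced by simulateLinePanel()?")
  if (is.null(panel$line_id)) stop("panel lacks line identifiers")
  keys <- grep(paste0("^", environment, "\\."), names(bvs), value = TRUE)
  if (!length(keys)) stop("no breeding values for environment ", environment)
  a <- do.call(rbind, bvs[keys])
  G2 <- 2 * config@G
  s2 <- 2 * config@sTrue
  ## conditional distribution of fitness given trait breeding values
  w_coef <- solve(G2 + diag(1e-10, nrow(G2)), s2)
  cond_var <- max(2 * config@Vw - sum(s2 * w_coef), 0)
  gw <- as.numeric(a %*% w_coef) + rnorm(nrow(a), 0, sqrt(cond_var))
  w <- 1 + gw
  w <- w / mean(w)
  names(w) <- rownames(a)
  panel$fitness <- unname(w[panel$line_id])
  attr(panel, "line_fitness") <- w
  panel
}

#' Gillespie simulation of movement-state tracks
#'
#' Exact-event simulation of the continuous-time Markov chain over
#' \{S, F, B\} defined by generator \code{Q}, sampled at the camera frame
#' interval. Tracks start from the stationary distribution.
#'
#' @param Q a \linkS4class{TransitionRateMatrix} or 3 x 3 generator matrix.
#' @param frameInterval seconds between sampled frames (0.25 = 4 Hz).
#' @param duration track duration in seconds.
#' @param nTracks number of independent tracks.
#' @param seed integer RNG seed.
#' @return A data.frame with columns \code{track_id, frame, state}.
#' @export
simulateCtmcTracks <- function(Q, frameInterval = 0.25, duration = 60,
                               nTracks = 1L, seed = 1L) {
  q <- if (is(Q, "TransitionRateMatrix")) Q@q else as.matrix(Q)
  Qobj <- new("TransitionRateMatrix", q = unname(q))
  validObject(Qobj)
  if (any(q[row(q) != col(q)] <= 0))
    stop("off-diagonal rates must be strictly positive for simulation")
  set.seed(seed)
  k <- nrow(q)
  pi0 <- stationaryDistribution(Qobj)
  n_frames <- floor(duration / frameInterval) + 1L
  out <- vector("list", nTracks)
  for (tr in seq_len(nTracks)) {
    state <- sample.int(k, 1L, prob = pi0)
    states <- integer(n_frames)
    t_now <- 0
    next_frame <- 1L
    t_frame <- 0
    while (next_frame <= n_frames) {
      rate <- -q[state, state]
      t_jump <- t_now + rexp(1L, rate)
      while (next_frame <= n_frames && t_frame <= t_jump) {
        states[next_frame] <- state
        next_frame <- next_frame + 1L
        t_frame <- (next_frame - 1L) * frameInterval
      }
      probs <- q[state, ]
      probs[state] <- 0
      state <- sample.int(k, 1L, prob = probs)
      t_now <- t_jump
    }
    out[[tr]] <- data.frame(track_id = sprintf("T%04d", tr),
                            frame = seq_len(n_frames) - 1L,
                            state = .STATES[states],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "frame_interval") <- frameInterval
  res
}

#' Stationary distribution of a CTMC generator
#'
#' Solves \code{pi Q = 0} with \code{sum(pi) = 1} via the null space of
#' \code{t(Q)}.
#'
#' @param Q a \linkS4class{TransitionRateMatrix} or generator matrix.
#' @return Named numeric vector of stationary state frequencies.
#' @export
stationaryDistribution <- function(Q) {
  q <- if (is(Q, "TransitionRateMatrix")) Q@q else as.matrix(Q)
  ns <- pracma::nullspace(t(q))
  if (is.null(ns) || ncol(ns) < 1L) stop("generator has no stationary distribution")
  v <- abs(ns[, 1])
  setNames(v / sum(v), .STATES[seq_len(nrow(q))])
}

#' Simulate divergence vectors from true selection gradients
#'
#' Inverts the retrospective gradient relation: the expected multivariate
#' divergence is \code{G betaTrue}, to which independent per-trait normal
#' replicate noise is added.
#'
#' @param G symmetric PSD genetic covariance matrix.
#' @param betaTrue true gradient vector.
#' @param nReplicates number of replicate populations.
#' @param replicateNoise standard deviation of i.i.d. per-trait noise.
#' @param seed integer RNG seed.
#' @return A list of divergence vectors (one per replicate).
#' @export
simulateDivergence <- function(G, betaTrue, nReplicates = 3L,
                               replicateNoise = 0, seed = 1L) {
  G <- as.matrix(G)
  .assert_psd(G, "G")
  if (length(betaTrue) != nrow(G)) stop("betaTrue and G dimensions differ")
  set.seed(seed)
  dq <- as.numeric(G %*% betaTrue)
  lapply(seq_len(nReplicates), function(i)
    dq + rnorm(length(dq), 0, replicateNoise))
}

#' Expected neutral loss of genetic variance under drift
#'
#' Cumulative fraction of genetic variance expected to be lost over a
#' number of generations when variance decays by a factor
#' \code{1 - 1/(2 Ne)} per generation; under complete selfing the effective
#' size is halved.
#'
#' @param Ne effective population size.
#' @param generations number of generations (>= 0).
#' @param mating "outcrossing" or "complete_selfing".
#' @return Fraction of variance lost, in [0, 1).
#' @export
expectedDriftLoss <- function(Ne, generations,
                              mating = c("outcrossing", "complete_selfing")) {
  mating <- match.arg(mating)
  if (Ne <= 0) stop("Ne must be positive")
  if (generations < 0) stop("generations must be non-negative")
  neEff <- if (mating == "complete_selfing") Ne / 2 else Ne
  1 - (1 - 1 / (2 * neEff))^generations
}
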