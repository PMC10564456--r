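## End-to-end orchestration: validate inputs, derive per-stage seeds from
## the global seed, run simulate -> rates -> manova -> G / Gqw -> geometry
## / skewers -> selection, and write stage outputs plus a run manifest.

#' Validate (and lightly repair) a phenotype table
#'
#' Checks the schema, audits factor levels, and verifies that the three
#' plate covariates are standardized (mean 0, sd 1); unstandardized
#' covariates are re-standardized with a warning.
#'
#' @param table data.frame or path to a phenotype CSV.
#' @param traits required trait columns.
#' @param populations allowed population labels (NULL to skip the audit).
#' @return The validated table (covariates standardized).
#' @export
validateTable <- function(table, traits = .TRAITS,
                          populations = .POPULATIONS) {
  if (is.character(table)) table <- readPhenotypeTable(table)
  needed <- c("line_id", "population", "block",
              "temperature", "humidity", "log_density", traits)
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  if (!is.null(populations)) {
    bad <- setdiff(unique(table$population), populations)
    if (length(bad))
      stop("unknown population labels: ", paste(bad, collapse = ", "))
  }
  if ("environment" %in% names(table)) {
    bad <- setdiff(unique(table$environment), .ENVIRONMENTS)
    if (length(bad))
      stop("unknown environment labels: ", paste(bad, collapse = ", "))
  }
  for (cv in c("temperature", "humidity", "log_density")) {
    x <- table[[cv]]
    if (abs(mean(x)) > 0.05 || abs(sd(x) - 1) > 0.05) {
      warning("covariate '", cv, "' not standardized; re-standardizing")
      table[[cv]] <- if (sd(x) > 0) (x - mean(x)) / sd(x) else x - mean(x)
    }
  }
  table
}

#' Deterministic per-stage seed
#'
#' Derives a stage seed from the global seed and the stage name so every
#' stochastic stage is reproducible in isolation.
#'
#' @param globalSeed integer.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
stageSeed <- function(globalSeed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(globalSeed) * 7919 + h * 104729) %% (2^31 - 1)) + 1L
}

#' Run the analysis pipeline end-to-end
#'
#' On synthetic data (default) or a supplied phenotype table: simulate the
#' panel and fitness, fit the MANOVA and extract the plasticity (delta_p)
#' and divergence (d_max) canonical axes and divergence vectors, fit the
#' ancestral G and fitness-augmented G posteriors, run the geometry and
#' random-skewers comparisons, and compute genetic/phenotypic gradients
#' with prediction angles and magnitude ratios. Writes stage CSV/JSON
#' outputs and a machine-readable manifest under \code{outDir}.
#'
#' @param simConfig \linkS4class{SimulationConfig} (ignored when
#'   \code{table} is supplied with fitness).
#' @param table optional phenotype table with a fitness column.
#' @param settings \linkS4class{McmcSettings} for all posterior fits.
#' @param outDir output directory (created); NULL to skip file output.
#' @param seed global seed; every stage derives its own via
#'   \code{\link{stageSeed}}.
#' @param nSkewers,nNullAngles randomization counts.
#' @param environment focal environment for the G-matrix stages.
#' @return list of stage results (panel, manova, axes, divergence,
#'   gPosteriors, gqw, skewers, selection, manifest).
#' @export
runPipeline <- function(simConfig = simulationConfig(),
                        table = NULL,
                        settings = mcmcSettings(quick = TRUE),
                        outDir = NULL, seed = 1L,
                        nSkewers = 1000L, nNullAngles = 1000L,
                        environment = "high_salt") {
  t0 <- Sys.time()
  stages <- character(0)
  tick <- function(name) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    stages <<- c(stages, name)
  }
  if (is.null(table)) {
    tick("simulate")
    simConfig@seed <- stageSeed(seed, "simulate")
    table <- simulateLinePanel(simConfig)
    table <- simulateFitness(table, simConfig, environment = environment)
  }
  table <- validateTable(table, populations = NULL)

  tick("manova")
  mv <- fitManova(table)
  env_term <- if ("environment" %in% names(mv)) "environment" else NULL
  pop_term <- if ("population" %in% names(mv)) "population" else NULL
  axes <- list()
  if (!is.null(env_term)) axes$delta_p <- sscpAxis(mv[[env_term]])
  if (!is.null(pop_term)) axes$d_max <- sscpAxis(mv[[pop_term]])
  dv <- if (!is.null(pop_term)) divergenceVectors(table) else NULL

  tick("fit-g")
  pops <- unique(table$population)
  sub_env <- table[table$environment == environment, , drop = FALSE]
  gPost <- list()
  for (p in pops) {
    st <- settings
    st@seed <- stageSeed(seed, paste0("fit-g-", p))
    gPost[[p]] <- fitMvlmm(sub_env[sub_env$population == p, , drop = FALSE],
                           settings = st)
  }
  anc <- pops[1]

  tick("fit-gqw")
  stq <- settings; stq@seed <- stageSeed(seed, "fit-gqw")
  gqw <- fitGqw(sub_env[sub_env$population == anc, , drop = FALSE],
                settings = stq)

  tick("geometry")
  Ganc <- posteriorMeanG(gPost[[anc]])
  geom <- list(gmax = gmaxTrait(Ganc),
               nullAngles = nullAngles(ncol(Ganc), nNullAngles,
                                       stageSeed(seed, "null-angles")))
  if (!is.null(axes$d_max))
    geom$theta_dmax_gmax <- vectorAngle(traitLoadings(axes$d_max),
                                        traitLoadings(geom$gmax))

  skew <- NULL
  if (length(gPost) >= 2L) {
    tick("skewers")
    skew <- randomSkewers(gPost, nVectors = nSkewers,
                          seed = stageSeed(seed, "skewers"), ancestor = anc)
  }

  tick("selection")
  sPost <- selectionDifferentials(gqw)
  sHat <- colMeans(sPost)
  sel <- list(s = sPost,
              betaG = geneticGradients(gPost[[anc]], sHat))
  if (!is.null(dv)) {
    sel$betaP <- list(); sel$theta <- list(); sel$ratio <- list()
    for (i in seq_len(nrow(dv))) {
      if (dv$environment[i] != environment && dv$environment[i] != "all")
        next
      id <- dv$population[i]
      dq <- divergenceVector(dv, id, dv$environment[i])
      sel$betaP[[id]] <- phenotypicGradients(gPost[[anc]], dq)
      sel$theta[[id]] <- predictionAngle(sPost, dq)
      sel$ratio[[id]] <- magnitudeRatio(dq, sHat)
    }
  }

  manifest <- list(
    seed = seed,
    stageSeeds = setNames(lapply(stages, function(s) stageSeed(seed, s)),
                          stages),
    settings = list(nIterations = settings@nIterations,
                    burnIn = settings@burnIn, thin = settings@thin,
                    prior = settings@prior),
    nRecords = nrow(table),
    populations = as.list(table(table$population)),
    runtimeSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    rVersion = as.character(getRversion()))

  res <- list(panel = table, manova = mv, axes = axes, divergence = dv,
              gPosteriors = gPost, gqw = gqw, geometry = geom,
              skewers = skew, selection = sel, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePhenotypeTable(table, file.path(outDir, "phenotypes.csv"))
    utils::write.csv(wilksTable(mv), file.path(outDir, "manova_wilks.csv"),
                     row.names = FALSE)
    if (!is.null(dv))
      utils::write.csv(dv, file.path(outDir, "divergence.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      lapply(axes, function(a) list(loadings = as.list(traitLoadings(a)),
                                    percent = percentVariance(a))),
      file.path(outDir, "canonical_axes.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
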