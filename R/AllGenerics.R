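#' Accessors for qgpredict objects
#'
#' Small generic surface over the S4 containers: posterior sample arrays,
#' trait names, loadings, rate matrices.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gSamples", function(x, ...) standardGeneric("gSamples"))

#' @rdname accessors
#' @export
setGeneric("traitNames", function(x, ...) standardGeneric("traitNames"))

#' @rdname accessors
#' @export
setGeneric("posteriorMeanG", function(x, ...) standardGeneric("posteriorMeanG"))

#' @rdname accessors
#' @export
setGeneric("traitLoadings", function(x, ...) standardGeneric("traitLoadings"))

#' @rdname accessors
#' @export
setGeneric("percentVariance", function(x, ...) standardGeneric("percentVariance"))

#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(x, ...) standardGeneric("rateMatrix"))

#' @rdname accessors
#' @export
setGeneric("logRates", function(x, ...) standardGeneric("logRates"))

#' @rdname accessors
#' @export
setGeneric("wilksTable", function(x, ...) standardGeneric("wilksTable"))

#' @rdname accessors
#' @export
setMethod("gSamples", "GPosterior", function(x, ...) x@G)

#' @rdname accessors
#' @export
setMethod("traitNames", "GPosterior", function(x, ...) x@traits)

#' @rdname accessors
#' @export
setMethod("posteriorMeanG", "GPosterior", function(x, ...) {
  m <- apply(x@G, c(1, 2), mean)
  dimnames(m) <- list(x@traits, x@traits)
  m
})

#' @rdname accessors
#' @export
setMethod("traitLoadings", "CanonicalTrait", function(x, ...) x@loadings)

#' @rdname accessors
#' @export
setMethod("percentVariance", "CanonicalTrait", function(x, ...) x@percentVariance)

#' @rdname accessors
#' @export
setMethod("rateMatrix", "RateFit", function(x, ...) x@Q@q)

#' @rdname accessors
#' @export
setMethod("rateMatrix", "TransitionRateMatrix", function(x, ...) x@q)

#' @rdname accessors
#' @export
setMethod("logRates", "RateFit", function(x, ...) x@logRates)

setMethod("show", "TransitionRateMatrix", function(object) {
  cat("TransitionRateMatrix (per-second rates, rows sum to 0)\n")
  print(round(object@q, 4))
})

setMethod("show", "RateFit", function(object) {
  cat(sprintf("RateFit [%s]%s\n", object@method,
              if (object@convergence) "" else " (NOT converged)"))
  print(round(exp(object@logRates), 4))
})

setMethod("show", "GPosterior", function(object) {
  d <- dim(object@G)
  cat(sprintf("%s: %d x %d genetic covariance, %d retained samples\n",
              class(object), d[1], d[2], d[3]))
  cat("posterior mean G:\n")
  print(round(posteriorMeanG(object), 4))
})

setMethod("show", "CanonicalTrait", function(object) {
  cat(sprintf("CanonicalTrait (%.1f%% of variation)\n", object@percentVariance))
  print(round(object@loadings, 3))
})

setMethod("show", "SscpResult", function(object) {
  cat(sprintf("SSCP term '%s': df = %g", object@factorName, object@df))
  if (is.finite(object@wilks))
    cat(sprintf(", Wilks = %.4g, approx F = %.3g (%g, %g), p = %.3g",
                object@wilks, object@approxF, object@numDf, object@denDf,
                object@pValue))
  cat("\n")
})

setMethod("show", "CredibleSummary", function(object) {
  cat(sprintf("mode %.4g; 83%% HPD [%.4g, %.4g]; 95%% HPD [%.4g, %.4g]\n",
              object@mode, object@ci83[1], object@ci83[2],
              object@ci95[1], object@ci95[2]))
})

setMethod("show", "SkewersResult", function(object) {
  cat(sprintf("SkewersResult: %d skewers, %d retained\n",
              nrow(object@skewers), length(object@retained)))
  if (!is.null(object@eMax)) {
    cat("e_max:\n")
    print(round(object@eMax@loadings, 3))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %s lines/population, %d reps, ",
                     "%d blocks, %d years, %d traits, seed %d\n"),
              paste(object@nLines, collapse = "/"), object@repsPerLine,
              object@nBlocks, object@nYears, object@nTraits, object@seed))
})

setMethod("show", "McmcSettings", function(object) {
  kept <- (object@nIterations - object@burnIn) %/% object@thin
  cat(sprintf("McmcSettings: %d iterations, %d burn-in, thin %d (%d retained), %s prior\n",
              object@nIterations, object@burnIn, object@thin, kept, object@prior))
})
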