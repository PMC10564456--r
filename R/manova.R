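## Multivariate and univariate models of phenotypic plasticity and
## divergence. The multivariate route fits a sequential (Type-I) MANOVA,
## tests terms with Wilks' lambda, and eigendecomposes term SSCP matrices
## into canonical traits; the univariate route fits per-trait mixed models
## (block random) for line BLUPs and evolved-vs-ancestor contrasts.

.default_terms <- function(table) {
  terms <- c("temperature", "humidity", "log_density")
  ## year precedes block: blocks are nested in years, so the coarse factor
  ## takes its sequential share first and block keeps its within-year df
  for (f in c("year", "block", "environment", "population"))
    if (f %in% names(table) && length(unique(table[[f]])) > 1L)
      terms <- c(terms, f)
  if (all(c("environment", "population") %in% terms))
    terms <- c(terms, "environment:population")
  terms
}

.model_frame <- function(table, traits) {
  miss <- setdiff(c(traits, "line_id"), names(table))
  if (length(miss)) stop("table lacks columns: ", paste(miss, collapse = ", "))
  for (f in c("block", "year", "environment", "population", "line_id"))
    if (f %in% names(table)) table[[f]] <- factor(table[[f]])
  table
}

#' Fit the sequential MANOVA of the seven-trait phenotype
#'
#' Traits are the multivariate response; model terms enter in the stated
#' order (default: standardized plate covariates, block, year, environment,
#' population, environment:population) and each term's sums-of-squares and
#' cross-products (SSCP) matrix is sequential (Type I). Significance uses
#' Wilks' lambda with Rao's F approximation.
#'
#' @param table phenotype table (see \code{\link{simulateLinePanel}}).
#' @param traits character, response columns.
#' @param termOrder character vector of model terms, in fitting order.
#' @return Named list of \linkS4class{SscpResult}, one per term plus
#'   \code{"Residuals"}; the underlying \code{manova} fit is attached as
#'   \code{attr(, "fit")}.
#' @export
fitManova <- function(table, traits = .TRAITS, termOrder = NULL) {
  table <- .model_frame(table, traits)
  if (is.null(termOrder)) termOrder <- .default_terms(table)
  Y <- as.matrix(table[, traits])
  rhs <- paste(termOrder, collapse = " + ")
  fml <- stats::as.formula(paste("Y ~", rhs))
  if (length(traits) == 1L) return(.fit_anova1(table, traits, termOrder))
  fit <- tryCatch(stats::manova(fml, data = table),
                  error = function(e) stop("MANOVA fit failed: ",
                                           conditionMessage(e), call. = FALSE))
  ## rank check: a term whose columns are all aliased carries no df and
  ## signals a deficient design (partial aliasing from nesting is fine)
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    asn <- fit$assign[fit$assign > 0]
    labs <- attr(stats::terms(fit), "term.labels")
    aliased_cols <- apply(alias, 1, any)[-1]   # drop intercept
    for (k in unique(asn)) {
      if (all(aliased_cols[asn == k]))
        stop("rank-deficient design; term fully aliased: ", labs[k])
    }
  }
  sm <- summary(fit, test = "Wilks")
  st <- sm$stats
  SS <- sm$SS
  out <- list()
  for (term in rownames(st)) {
    if (term == "Residuals") {
      out[[term]] <- new("SscpResult", factorName = term,
                         SSCP = as.matrix(SS[[term]]),
                         df = unname(st[term, "Df"]),
                         wilks = NA_real_, approxF = NA_real_,
                         numDf = NA_real_, denDf = NA_real_,
                         pValue = NA_real_)
    } else {
      out[[term]] <- new("SscpResult", factorName = term,
                         SSCP = as.matrix(SS[[term]]),
                         df = unname(st[term, "Df"]),
                         wilks = unname(st[term, "Wilks"]),
                         approxF = unname(st[term, "approx F"]),
                         numDf = unname(st[term, "num Df"]),
                         denDf = unname(st[term, "den Df"]),
                         pValue = unname(st[term, "Pr(>F)"]))
    }
  }
  attr(out, "fit") <- fit
  out
}

## Single-response degeneration: the sequential ANOVA, with Wilks' lambda
## collapsing to SSE / (SSE + SSH) and the exact F test.
.fit_anova1 <- function(table, trait, termOrder) {
  fml <- stats::as.formula(paste(trait, "~", paste(termOrder, collapse = " + ")))
  fit <- stats::lm(fml, data = table)
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    asn <- fit$assign[fit$assign > 0]
    labs <- attr(stats::terms(fit), "term.labels")
    for (k in unique(asn)) {
      if (all(alias[-1][asn == k]))
        stop("rank-deficient design; term fully aliased: ", labs[k])
    }
  }
  a <- stats::anova(fit)
  sse <- a["Residuals", "Sum Sq"]
  out <- list()
  for (term in rownames(a)) {
    ssh <- a[term, "Sum Sq"]
    if (term == "Residuals") {
      out[[term]] <- new("SscpResult", factorName = term,
                         SSCP = matrix(ssh, dimnames = list(trait, trait)),
                         df = a[term, "Df"], wilks = NA_real_,
                         approxF = NA_real_, numDf = NA_real_,
                         denDf = NA_real_, pValue = NA_real_)
    } else {
      out[[term]] <- new("SscpResult", factorName = term,
                         SSCP = matrix(ssh, dimnames = list(trait, trait)),
                         df = a[term, "Df"],
                         wilks = sse / (sse + ssh),
                         approxF = a[term, "F value"],
                         numDf = a[term, "Df"],
                         denDf = a["Residuals", "Df"],
                         pValue = a[term, "Pr(>F)"])
    }
  }
  attr(out, "fit") <- fit
  out
}

#' Tabulate Wilks tests of a fitted MANOVA
#'
#' @param x result of \code{\link{fitManova}}.
#' @param ... unused.
#' @return data.frame with one row per term (factor, df, wilks, approxF,
#'   numDf, denDf, p).
#' @export
setMethod("wilksTable", "list", function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(factor = r@factorName, df = r@df, wilks = r@wilks,
               approxF = r@approxF, numDf = r@numDf, denDf = r@denDf,
               p = r@pValue)))
})

#' Leading canonical axis of an SSCP (or covariance) matrix
#'
#' Eigendecomposes a symmetric matrix and returns the requested
#' eigenvector as a unit-norm canonical trait, its sign fixed so the
#' largest-magnitude loading is positive, with the percent of total
#' variation (eigenvalue share) it explains.
#'
#' @param sscp an \linkS4class{SscpResult} or symmetric matrix.
#' @param which eigenvector index (1 = leading).
#' @return A \linkS4class{CanonicalTrait}.
#' @export
sscpAxis <- function(sscp, which = 1L) {
  m <- if (is(sscp, "SscpResult")) sscp@SSCP else as.matrix(sscp)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("SSCP matrix must be symmetric")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- ev$vectors[, which]
  if (v[which.max(abs(v))] < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  names(v) <- colnames(m)
  lam <- pmax(ev$values, 0)
  new("CanonicalTrait", loadings = v,
      percentVariance = 100 * lam[which] / sum(lam))
}

#' Covariate-adjusted divergence vectors from the ancestor
#'
#' Least-square population means per environment from per-trait linear
#' models sharing the MANOVA fixed-effect structure; divergence of each
#' evolved population is its least-square mean minus the ancestor's, per
#' environment.
#'
#' @param table phenotype table containing the ancestor population.
#' @param traits character, trait columns.
#' @param ancestor reference population label.
#' @return data.frame with columns \code{population, environment} and one
#'   column per trait (the divergence vector), with standard errors in
#'   \code{attr(, "se")}.
#' @export
divergenceVectors <- function(table, traits = .TRAITS, ancestor = "A6140") {
  table <- .model_frame(table, traits)
  if (!ancestor %in% levels(table$population))
    stop("ancestor population '", ancestor, "' absent from table")
  has_env <- "environment" %in% names(table) &&
    nlevels(table$environment) > 1L
  envs <- if (has_env) levels(table$environment) else "all"
  pops <- setdiff(levels(table$population), ancestor)
  grid <- expand.grid(population = c(ancestor, pops), environment = envs,
                      stringsAsFactors = FALSE)
  est <- matrix(NA_real_, nrow(grid), length(traits),
                dimnames = list(NULL, traits))
  se <- est
  for (tr in traits) {
    terms <- .default_terms(table)
    fml <- stats::as.formula(paste(tr, "~", paste(terms, collapse = " + ")))
    fit <- stats::lm(fml, data = table)
    spec <- if (has_env) ~ population | environment else ~population
    emm <- as.data.frame(emmeans::emmeans(fit, spec))
    for (i in seq_len(nrow(grid))) {
      sel <- emm$population == grid$population[i]
      if (has_env) sel <- sel & emm$environment == grid$environment[i]
      est[i, tr] <- emm$emmean[sel]
      se[i, tr] <- emm$SE[sel]
    }
  }
  out <- grid[grid$population != ancestor, , drop = FALSE]
  dq <- matrix(NA_real_, nrow(out), length(traits),
               dimnames = list(NULL, traits))
  dq_se <- dq
  for (i in seq_len(nrow(out))) {
    ref <- which(grid$population == ancestor &
                   grid$environment == out$environment[i])
    j <- which(grid$population == out$population[i] &
                 grid$environment == out$environment[i])
    dq[i, ] <- est[j, ] - est[ref, ]
    dq_se[i, ] <- sqrt(se[j, ]^2 + se[ref, ]^2)
  }
  res <- cbind(out, as.data.frame(dq))
  rownames(res) <- NULL
  attr(res, "se") <- dq_se
  res
}

#' Extract one divergence vector
#'
#' @param dv result of \code{\link{divergenceVectors}}.
#' @param population,environment selectors.
#' @param traits trait columns.
#' @return Named numeric divergence vector.
#' @export
divergenceVector <- function(dv, population, environment = NULL,
                             traits = .TRAITS) {
  sel <- dv$population == population
  if (!is.null(environment)) sel <- sel & dv$environment == environment
  if (sum(sel) != 1L) stop("selection does not identify a single row")
  unlist(dv[sel, traits])
}

#' Univariate mixed model: line BLUPs and population contrasts
#'
#' Fits one trait with the fixed-effect structure of the MANOVA except
#' that block is a random effect (as is line identity, whose conditional
#' means give the per-line BLUPs). Evolved-vs-ancestor contrasts are
#' multiplicity-adjusted (single-step max-t by default, Holm optional).
#'
#' @param table phenotype table.
#' @param trait single trait column name.
#' @param ancestor reference population label.
#' @param adjust "mvt" (single-step) or "holm".
#' @return list with elements \code{model} (the lmer fit), \code{blups}
#'   (named per-line predictions: population least-square mean plus line
#'   effect), \code{contrasts} (data.frame of evolved - ancestor
#'   estimates with adjusted p-values), and \code{singular} flag.
#' @export
fitUnivariate <- function(table, trait, ancestor = "A6140",
                          adjust = c("mvt", "holm")) {
  adjust <- match.arg(adjust)
  table <- .model_frame(table, trait)
  terms <- setdiff(.default_terms(table), "block")
  fml <- stats::as.formula(paste(trait, "~", paste(terms, collapse = " + "),
                                 "+ (1 | block) + (1 | line_id)"))
  fit <- lme4::lmer(fml, data = table,
                    control = lme4::lmerControl(check.conv.singular =
                      lme4::.makeCC(action = "ignore", tol = 1e-4)))
  singular <- lme4::isSingular(fit)
  if (singular)
    message("random-effects fit is singular for trait ", trait)
  ## per-line BLUP: population LS mean (+ environment average) + line effect
  multi_pop <- "population" %in% terms
  if (multi_pop) {
    emm_line <- as.data.frame(emmeans::emmeans(fit, ~population))
    popmean <- setNames(emm_line$emmean, emm_line$population)
  } else {
    gm <- as.data.frame(emmeans::emmeans(fit, "1"))$emmean
    popmean <- setNames(rep(gm, nlevels(table$population)),
                        levels(table$population))
  }
  re <- lme4::ranef(fit)$line_id
  line_pop <- tapply(as.character(table$population), table$line_id,
                     function(x) x[1])
  blups <- setNames(popmean[line_pop[rownames(re)]] + re[, 1], rownames(re))
  contrasts <- NULL
  if (multi_pop) {
    emm <- emmeans::emmeans(fit, ~population)
    ctr <- emmeans::contrast(emm, "trt.vs.ctrl",
                             ref = which(levels(table$population) == ancestor),
                             adjust = adjust)
    contrasts <- as.data.frame(ctr)
  }
  list(model = fit, blups = blups, contrasts = contrasts,
       singular = singular)
}
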