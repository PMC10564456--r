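## Posterior summaries: kernel-density modes, highest-posterior-density
## intervals, and the 83%-interval non-overlap rule for contrasting two
## posteriors (approximately a 5%-level test for homoscedastic normal
## posteriors).

#' Kernel-density posterior mode
#'
#' @param samples numeric vector of posterior draws (>= 100 unless
#'   \code{minSamples} is lowered).
#' @param bw kernel bandwidth rule (see \code{\link[stats]{density}});
#'   default Silverman's.
#' @param minSamples minimum draws required.
#' @return numeric(1), abscissa of the density maximum.
#' @export
posteriorMode <- function(samples, bw = "nrd0", minSamples = 100L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < minSamples)
    stop("need at least ", minSamples, " samples")
  if (sd(samples) == 0) return(samples[1])
  d <- density(samples, bw = bw)
  d$x[which.max(d$y)]
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing the stated posterior mass, found by
#' scanning windows of the sorted draws.
#'
#' @param samples numeric posterior draws.
#' @param level credible mass, typically 0.83 or 0.95.
#' @param minSamples minimum draws required.
#' @return numeric(2), interval endpoints.
#' @export
credibleInterval <- function(samples, level = 0.95, minSamples = 100L) {
  samples <- sort(samples[is.finite(samples)])
  n <- length(samples)
  if (n < minSamples) stop("need at least ", minSamples, " samples")
  k <- max(1L, ceiling(level * n))
  if (k >= n) return(c(samples[1], samples[n]))
  widths <- samples[(k + 1):n] - samples[1:(n - k)]
  i <- which.min(widths)
  c(samples[i], samples[i + k])
}

#' Mode with nested 83% and 95% HPD intervals
#'
#' @param samples numeric posterior draws.
#' @param minSamples minimum draws required.
#' @return A \linkS4class{CredibleSummary}. The 83% interval is clipped
#'   into the 95% interval (they can cross by a sliver when the HPD
#'   windows land on different sample pairs).
#' @export
credibleSummary <- function(samples, minSamples = 100L) {
  ci95 <- credibleInterval(samples, 0.95, minSamples)
  ci83 <- credibleInterval(samples, 0.83, minSamples)
  ci83 <- c(max(ci83[1], ci95[1]), min(ci83[2], ci95[2]))
  m <- posteriorMode(samples, minSamples = minSamples)
  m <- min(max(m, ci95[1]), ci95[2])
  new("CredibleSummary", mode = m, ci83 = ci83, ci95 = ci95)
}

#' Contrast two posteriors by the 83%-interval rule
#'
#' Two posterior distributions are declared different when their 83%
#' highest-posterior-density intervals do not overlap; for two
#' equal-variance normal posteriors this behaves approximately like a
#' 5%-level test.
#'
#' @param a,b numeric posterior draws.
#' @param level interval mass for the rule (0.83).
#' @param minSamples minimum draws per posterior.
#' @return logical(1), TRUE when the intervals are disjoint.
#' @export
comparePosteriors <- function(a, b, level = 0.83, minSamples = 100L) {
  ia <- credibleInterval(a, level, minSamples)
  ib <- credibleInterval(b, level, minSamples)
  ia[2] < ib[1] || ib[2] < ia[1]
}
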