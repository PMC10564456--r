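## Plain-text I/O: phenotype tables as CSV (with a commented seed header),
## movement-state tracks as TSV, simulation configuration from YAML.

.PHENO_COLS <- c("line_id", "population", "environment", "block", "year",
                 "temperature", "humidity", "log_density")

#' Write a phenotype table to CSV
#'
#' @param table phenotype table.
#' @param path output file.
#' @param seed optional integer recorded in a header comment.
#' @return path, invisibly.
#' @export
writePhenotypeTable <- function(table, path, seed = attr(table, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(as.data.frame(table)[, c(
    intersect(.PHENO_COLS, names(table)),
    setdiff(names(table), .PHENO_COLS))],
    con, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' @param path CSV file (comment lines start with '#').
#' @return data.frame; a seed header, if present, is kept as
#'   \code{attr(, "seed")}.
#' @export
readPhenotypeTable <- function(path) {
  first <- readLines(path, n = 1L)
  tb <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "# seed:"))
    attr(tb, "seed") <- as.integer(sub("# seed:\\s*", "", first))
  tb
}

#' Write state tracks to TSV
#'
#' @param tracks data.frame (track_id, frame, state).
#' @param path output file.
#' @param frameInterval seconds; recorded in a header comment.
#' @return path, invisibly.
#' @export
writeStateTracks <- function(tracks, path,
                             frameInterval = attr(tracks, "frame_interval")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(frameInterval))
    writeLines(sprintf("# frame_interval: %g", frameInterval), con)
  utils::write.table(tracks, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read state tracks from TSV
#'
#' @param path TSV file (track_id, frame, state).
#' @return data.frame with \code{attr(, "frame_interval")} when the header
#'   records it.
#' @export
readStateTracks <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  bad <- setdiff(unique(tr$state), .STATES)
  if (length(bad))
    stop("unknown movement states in ", path, ": ",
         paste(bad, collapse = ", "))
  if (startsWith(first, "# frame_interval:"))
    attr(tr, "frame_interval") <-
      as.numeric(sub("# frame_interval:\\s*", "", first))
  tr
}

#' Build a simulation configuration from a YAML file
#'
#' Scalar fields map directly to \code{\link{simulationConfig}} arguments;
#' matrix fields (G, Vblock, Eresid, covariateEffects) are given as lists
#' of rows.
#'
#' @param path YAML file.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  as_mat <- function(x) if (is.null(x)) NULL else do.call(rbind, x)
  args <- list()
  for (nm in c("nLines", "repsPerLine", "nBlocks", "nYears", "sTrue", "Vw",
               "betaTrue", "yearEffects", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  for (nm in c("G", "Vblock", "Eresid", "covariateEffects"))
    if (!is.null(y[[nm]])) args[[nm]] <- as_mat(y[[nm]])
  do.call(simulationConfig, args)
}
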