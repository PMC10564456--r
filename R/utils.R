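#' Canonical trait, state and population labels
#'
#' The package-wide trait order: the six natural-log transition rates
#' between still (S), forward (F) and backward (B), then rescaled body
#' size.
#'
#' @return character vector of column labels.
#' @export
phenotypeTraits <- function() .TRAITS

#' @rdname phenotypeTraits
#' @export
movementStates <- function() .STATES

#' @rdname phenotypeTraits
#' @export
populationLabels <- function() .POPULATIONS
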