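#' @include AllClasses.R
NULL

#' Spectrum identifiers
#' @param x an object holding spectra
#' @return character vector of spectrum identifiers.
#' @export
setGeneric("spectrumIds", function(x) standardGeneric("spectrumIds"))

#' Spectrum metadata table
#' @param x an object holding spectra
#' @return data.frame of per-spectrum metadata.
#' @export
setGeneric("spectraData", function(x) standardGeneric("spectraData"))

#' Peak lists
#' @param x an object holding spectra
#' @return named list of two-column (\code{mz}, \code{intensity}) matrices.
#' @export
setGeneric("peaksData", function(x) standardGeneric("peaksData"))

#' Training-set structure identifiers
#' @param x an [MsmsSplit-class]
#' @return character vector of first-block InChIKeys.
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' Validation-set structure identifiers
#' @param x an [MsmsSplit-class]
#' @return character vector of first-block InChIKeys.
#' @export
setGeneric("validationIds", function(x) standardGeneric("validationIds"))

#' Test-set structure identifiers
#' @param x an [MsmsSplit-class]
#' @return character vector of first-block InChIKeys.
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' Train-test similarity of the test structures
#'
#' For each test structure, the maximum Tanimoto similarity between it and
#' any training structure.
#' @param x an [MsmsSplit-class]
#' @return named numeric vector on \code{[0, 1]}.
#' @export
setGeneric("ttSimilarity", function(x) standardGeneric("ttSimilarity"))

#' Fraction of covered grid cells
#' @param x a [CoverageGrid-class]
#' @param ... unused
#' @return numeric scalar in \code{[0, 1]}.
#' @export
setGeneric("coverage", function(x, ...) standardGeneric("coverage"))

#' Coverage of the region of interest
#'
#' Fraction of covered cells among the 30-cell region with mean train-test
#' similarity in (0.55, 0.85) and pairwise similarity above 0.5, the zone
#' of structural analogs distant from the training set.
#' @param x a [CoverageGrid-class]
#' @return numeric scalar in \code{[0, 1]}.
#' @export
setGeneric("roiCoverage", function(x) standardGeneric("roiCoverage"))
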