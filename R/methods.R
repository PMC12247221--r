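#' @include AllClasses.R AllGenerics.R
NULL

## ----------------------------- MsmsSpectra --------------------------------

#' @describeIn MsmsSpectra number of spectra
#' @param x an \code{MsmsSpectra}
#' @export
setMethod("length", "MsmsSpectra", function(x) length(x@peaks))

#' @describeIn MsmsSpectra spectrum identifiers
#' @export
setMethod("spectrumIds", "MsmsSpectra", function(x) x@meta$spectrum_id)

#' @describeIn MsmsSpectra metadata table (one row per spectrum)
#' @export
setMethod("spectraData", "MsmsSpectra", function(x) x@meta)

#' @describeIn MsmsSpectra named list of peak matrices
#' @export
setMethod("peaksData", "MsmsSpectra", function(x) x@peaks)

#' @describeIn MsmsSpectra subset by index, logical, or spectrum_id
#' @param i index/logical/character selector
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "MsmsSpectra", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@meta$spectrum_id)
    if (anyNA(i)) .stopf("lookup_error", "unknown spectrum_id in subset")
    initialize(x, peaks = x@peaks[i],
               meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "MsmsSpectra", function(object) {
    n <- length(object)
    np <- if (n) sum(vapply(object@peaks, nrow, integer(1))) else 0L
    cat(sprintf("MsmsSpectra with %d spectra (%d peaks total)\n", n, np))
    ann <- sum(!is.na(object@meta$structure_ref))
    cat(sprintf("  structure-annotated: %d; metadata columns: %d\n",
                ann, ncol(object@meta)))
    invisible(NULL)
})

## Bind two MsmsSpectra collections (used by fixture generator).
#' Concatenate spectra collections
#' @param x,y [MsmsSpectra-class] objects with identical metadata columns
#' @return combined [MsmsSpectra-class]
#' @export
concatSpectra <- function(x, y) {
    common <- union(names(x@meta), names(y@meta))
    for (col in setdiff(common, names(x@meta))) x@meta[[col]] <- NA
    for (col in setdiff(common, names(y@meta))) y@meta[[col]] <- NA
    MsmsSpectra(c(x@peaks, y@peaks), rbind(x@meta[common], y@meta[common]))
}

## ------------------------------ MsmsSplit ---------------------------------

#' @describeIn MsmsSplit training structures
#' @param x an \code{MsmsSplit}
#' @export
setMethod("trainIds", "MsmsSplit", function(x) x@train)

#' @describeIn MsmsSplit validation structures
#' @export
setMethod("validationIds", "MsmsSplit", function(x) x@validation)

#' @describeIn MsmsSplit test structures
#' @export
setMethod("testIds", "MsmsSplit", function(x) x@test)

#' @describeIn MsmsSplit per-test-structure train-test similarity
#' @export
setMethod("ttSimilarity", "MsmsSplit", function(x) x@ttSimilarity)

setMethod("show", "MsmsSplit", function(object) {
    cat(sprintf(
        "MsmsSplit: %d train / %d validation / %d test structures\n",
        length(object@train), length(object@validation),
        length(object@test)))
    if (length(object@ttSimilarity)) {
        q <- quantile(object@ttSimilarity, c(0, .5, 1))
        cat(sprintf("  train-test similarity: min %.3f / median %.3f / max %.3f\n",
                    q[1], q[2], q[3]))
    }
    invisible(NULL)
})

## ----------------------------- CoverageGrid -------------------------------

#' @describeIn CoverageGrid fraction of cells at or above the pair threshold
#' @param x a \code{CoverageGrid}
#' @param ... unused
#' @export
setMethod("coverage", "CoverageGrid", function(x, ...) {
    mean(x@counts >= x@threshold)
})

#' @describeIn CoverageGrid coverage of the analog-search region of interest
#' @export
setMethod("roiCoverage", "CoverageGrid", function(x) {
    roi <- .roiCells(x)
    mean(x@counts[roi$rows, roi$cols] >= x@threshold)
})

## ROI: pairwise similarity > 0.5 and mean train-test similarity in
## (0.55, 0.85) -> 5 pairwise bins x 6 tt bins = 30 cells.
.roiCells <- function(x) {
    rows <- which(x@pairwiseEdges[-length(x@pairwiseEdges)] >= 0.5 - 1e-9)
    cols <- which(x@ttEdges[-length(x@ttEdges)] >= 0.55 - 1e-9 &
                  x@ttEdges[-1L] <= 0.85 + 1e-9)
    list(rows = rows, cols = cols)
}

setMethod("show", "CoverageGrid", function(object) {
    cat(sprintf(
        "CoverageGrid %dx%d (pairwise x train-test), threshold %d ordered pairs\n",
        nrow(object@counts), ncol(object@counts), object@threshold))
    cat(sprintf("  pairs binned: %d (+%d below train-test range)\n",
                sum(object@counts), object@nOutside))
    cat(sprintf("  coverage: %.1f%%; region of interest: %.1f%%\n",
                100 * coverage(object), 100 * roiCoverage(object)))
    invisible(NULL)
})

#' Coverage grid counts
#' @param x a [CoverageGrid-class]
#' @return integer matrix of ordered-pair counts (pairwise x train-test bins).
#' @export
gridCounts <- function(x) x@counts
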