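#' @import methods
NULL

## ---------------------------------------------------------------------------
## MsmsSpectra: a collection of MS/MS spectra (ragged peak lists + metadata)
## ---------------------------------------------------------------------------

#' MsmsSpectra: a collection of MS/MS spectra
#'
#' Container pairing per-spectrum peak matrices with a harmonized metadata
#' table. Peaks are two-column numeric matrices (\code{mz}, \code{intensity})
#' with strictly increasing m/z; metadata is one row per spectrum keyed by
#' \code{spectrum_id}. Acquisition fields (\code{adduct},
#' \code{collision_energy} in eV, \code{ionization_method},
#' \code{mass_analyzer}, \code{dissociation_method}, \code{manufacturer},
#' \code{ion_mode}, \code{source_library}) and the planar-structure reference
#' \code{structure_ref} (first InChIKey block) may be \code{NA} when unknown.
#'
#' @slot peaks list of numeric matrices, one per spectrum, columns
#'   \code{mz} (Th) and \code{intensity} (arbitrary abundance units).
#' @slot meta data.frame with one row per spectrum; must contain
#'   \code{spectrum_id} (unique, non-empty) and \code{precursor_mz} (> 0).
#'
#' @seealso [readMgf()], [writeMgf()], [selectForMl()]
#' @exportClass MsmsSpectra
setClass("MsmsSpectra",
    representation(peaks = "list", meta = "data.frame"))

.META_OPTIONAL <- c(
    "charge", "adduct", "collision_energy", "ionization_method",
    "mass_analyzer", "dissociation_method", "manufacturer", "ion_mode",
    "source_library", "compound_name", "structure_ref")

setValidity("MsmsSpectra", function(object) {
    p <- object@peaks
    m <- object@meta
    if (!all(c("spectrum_id", "precursor_mz") %in% names(m)))
        return("meta must contain spectrum_id and precursor_mz")
    if (length(p) != nrow(m))
        return("number of peak matrices and metadata rows differ")
    if (anyDuplicated(m$spectrum_id))
        return("spectrum_id values must be unique")
    if (any(is.na(m$precursor_mz)) || any(m$precursor_mz <= 0))
        return("precursor_mz must be present and > 0")
    for (i in seq_along(p)) {
        pk <- p[[i]]
        if (!is.matrix(pk) || ncol(pk) != 2L)
            return(sprintf("peaks[[%d]] is not a two-column matrix", i))
        if (nrow(pk) > 1L && any(diff(pk[, 1L]) <= 0))
            return(sprintf("peaks[[%d]] m/z not strictly increasing", i))
        if (any(pk[, 2L] < 0))
            return(sprintf("peaks[[%d]] has negative intensities", i))
    }
    TRUE
})

#' Construct an MsmsSpectra object
#'
#' @param peaks list of two-column numeric matrices (\code{mz},
#'   \code{intensity}); duplicate m/z values within a spectrum are summed and
#'   rows are sorted by m/z.
#' @param meta data.frame with at least \code{spectrum_id} and
#'   \code{precursor_mz}; missing optional metadata columns are added as
#'   \code{NA}.
#' @return An [MsmsSpectra-class] object.
#' @examples
#' sp <- MsmsSpectra(
#'     peaks = list(cbind(mz = c(100, 200), intensity = c(10, 1000))),
#'     meta = data.frame(spectrum_id = "s1", precursor_mz = 250.1))
#' length(sp)
#' @export
MsmsSpectra <- function(peaks, meta) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    for (col in .META_OPTIONAL)
        if (is.null(meta[[col]])) meta[[col]] <- rep(NA, nrow(meta))
    peaks <- lapply(peaks, .tidyPeaks)
    names(peaks) <- meta$spectrum_id
    rownames(meta) <- NULL
    new("MsmsSpectra", peaks = peaks, meta = meta)
}

## sort by m/z and merge duplicate m/z rows (summing intensity)
.tidyPeaks <- function(pk) {
    pk <- as.matrix(pk)
    colnames(pk) <- c("mz", "intensity")
    if (nrow(pk) == 0L) return(pk)
    pk <- pk[order(pk[, 1L]), , drop = FALSE]
    if (anyDuplicated(pk[, 1L])) {
        agg <- rowsum(pk[, 2L], group = pk[, 1L])
        pk <- cbind(mz = as.numeric(rownames(agg)), intensity = agg[, 1L])
    }
    pk
}

## ---------------------------------------------------------------------------
## Fingerprints: fixed-length binary fingerprints for a set of structures
## ---------------------------------------------------------------------------

#' Fingerprints: binary structure fingerprints
#'
#' Fixed-length binary fingerprints for a set of standardized structures,
#' stored as a logical matrix with one row per structure (rownames are
#' first-block InChIKeys).
#'
#' @slot bits logical matrix, structures x bit positions.
#' @slot params list recording the fingerprint parameters (bit length,
#'   maximum path length, bits set per path).
#' @exportClass Fingerprints
setClass("Fingerprints",
    representation(bits = "matrix", params = "list"))

setValidity("Fingerprints", function(object) {
    if (!is.logical(object@bits)) return("bits must be a logical matrix")
    if (is.null(rownames(object@bits))) return("bits must have rownames")
    if (anyDuplicated(rownames(object@bits)))
        return("duplicate structure identifiers in fingerprints")
    empty <- rowSums(object@bits) == 0
    if (any(empty))
        return(sprintf("all-zero fingerprint for %s",
                       rownames(object@bits)[which(empty)[1L]]))
    TRUE
})

## ---------------------------------------------------------------------------
## MsmsSplit: train/validation/test split with per-test-structure similarity
## ---------------------------------------------------------------------------

#' MsmsSplit: structure-level train/validation/test split
#'
#' Disjoint train/validation/test sets of planar structures (first-block
#' InChIKeys) together with, for every test structure, its train-test
#' similarity: the maximum Tanimoto similarity between that structure and
#' any training structure.
#'
#' @slot train,validation,test character vectors of first-block InChIKeys;
#'   pairwise disjoint.
#' @slot ttSimilarity named numeric vector on \code{[0, 1]}, one entry per
#'   test structure.
#' @slot config the split configuration used (list).
#' @seealso [splitStructures()], [coverageGrid()]
#' @exportClass MsmsSplit
setClass("MsmsSplit",
    representation(train = "character", validation = "character",
                   test = "character", ttSimilarity = "numeric",
                   config = "list"))

setValidity("MsmsSplit", function(object) {
    sets <- list(object@train, object@validation, object@test)
    if (length(unique(unlist(sets))) != sum(lengths(sets)))
        return("train/validation/test sets are not disjoint")
    if (!setequal(names(object@ttSimilarity), object@test))
        return("ttSimilarity must be named by exactly the test structures")
    tt <- object@ttSimilarity
    if (length(tt) && (any(tt < 0) || any(tt > 1)))
        return("ttSimilarity outside [0, 1]")
    TRUE
})

## ---------------------------------------------------------------------------
## CoverageGrid: 2-D audit histogram over (pairwise sim x train-test sim)
## ---------------------------------------------------------------------------

#' CoverageGrid: test-pair coverage audit
#'
#' Two-dimensional histogram of ordered test pairs over pairwise Tanimoto
#' similarity (10 bins of width 0.1 on \code{[0, 1]}) and mean train-test
#' similarity (12 bins of width 0.05 on \code{[0.4, 1]}). Bins are
#' left-inclusive; the top bin of each axis also includes the upper limit.
#' A cell counts as covered when it holds at least \code{threshold} ordered
#' pairs. Pairs whose mean train-test similarity falls below 0.4 lie outside
#' the grid and are tallied in \code{nOutside}.
#'
#' @slot counts integer matrix, 10 pairwise bins x 12 train-test bins.
#' @slot pairwiseEdges,ttEdges numeric bin edges.
#' @slot threshold ordered-pair count for a cell to count as covered.
#' @slot nOutside ordered pairs below the train-test range of the grid.
#' @seealso [coverageGrid()], [coverage()], [roiCoverage()]
#' @exportClass CoverageGrid
setClass("CoverageGrid",
    representation(counts = "matrix", pairwiseEdges = "numeric",
                   ttEdges = "numeric", threshold = "numeric",
                   nOutside = "numeric"))

setValidity("CoverageGrid", function(object) {
    if (any(object@counts < 0)) return("negative cell counts")
    if (nrow(object@counts) != length(object@pairwiseEdges) - 1L ||
        ncol(object@counts) != length(object@ttEdges) - 1L)
        return("counts dimensions do not match bin edges")
    TRUE
})
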