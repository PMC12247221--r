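## Annotation validation and spectrum-selection filters producing the
## ML-ready subset of a harmonized spectral library.

#' Cleaning configuration
#'
#' Thresholds for peak preprocessing and spectrum selection. Boundary
#' conventions (documented, tested): peak removal uses strict \code{<} on
#' relative intensity (a peak exactly at the threshold is kept); the m/z
#' range is inclusive on both ends; significant fragmentation requires
#' strictly more than \code{sigPeakCountExclusiveMin} peaks with relative
#' intensity strictly above \code{sigPeakRelIntensity}.
#'
#' @param maxPrecursorDa discard spectra with precursor mass above this (Da).
#' @param minRelIntensity relative-intensity floor for peaks (fraction of
#'   base peak).
#' @param mzMin,mzMax retained m/z range (Th), inclusive.
#' @param sigPeakRelIntensity relative intensity a peak must exceed to count
#'   as significant.
#' @param sigPeakCountExclusiveMin significant-peak count that must be
#'   exceeded (default 4, i.e. at least 5 such peaks).
#' @param maxPpmError precursor validation tolerance (ppm).
#' @param excludedLibraries source libraries dropped outright.
#' @param ionMode retained ion mode.
#' @return a validated list of class \code{CleaningConfig}.
#' @export
cleaningConfig <- function(maxPrecursorDa = 1500, minRelIntensity = 0.001,
                           mzMin = 10, mzMax = 2000,
                           sigPeakRelIntensity = 0.02,
                           sigPeakCountExclusiveMin = 4L,
                           maxPpmError = 50,
                           excludedLibraries = character(0),
                           ionMode = "positive") {
    stopifnot(minRelIntensity > 0, minRelIntensity < sigPeakRelIntensity,
              sigPeakRelIntensity < 1, mzMin < mzMax, maxPpmError > 0)
    structure(list(maxPrecursorDa = maxPrecursorDa,
                   minRelIntensity = minRelIntensity,
                   mzMin = mzMin, mzMax = mzMax,
                   sigPeakRelIntensity = sigPeakRelIntensity,
                   sigPeakCountExclusiveMin = as.integer(
                       sigPeakCountExclusiveMin),
                   maxPpmError = maxPpmError,
                   excludedLibraries = excludedLibraries,
                   ionMode = ionMode),
              class = "CleaningConfig")
}

#' Validate precursor masses against structure annotations
#'
#' Compares the theoretical precursor m/z (neutral monoisotopic mass plus
#' adduct offset, divided by absolute charge) against the observed
#' precursor, in ppm of the theoretical value. Spectra lacking a canonical
#' adduct or a structure annotation are unverifiable and rejected.
#'
#' @param spectra an [MsmsSpectra-class]; metadata must carry
#'   \code{structure_ref} and canonical \code{adduct}.
#' @param structures structure table with \code{inchikey14} and
#'   \code{monoisotopic_mass}.
#' @param adducts adduct table from [adductMap()].
#' @param maxPpm tolerance in ppm.
#' @return data.frame with columns \code{spectrum_id}, \code{keep},
#'   \code{ppm_error}, \code{reason}.
#' @export
validatePrecursor <- function(spectra, structures, adducts = adductMap(),
                              maxPpm = 50) {
    m <- spectraData(spectra)
    mono <- structures$monoisotopic_mass[
        match(m$structure_ref, structures$inchikey14)]
    known_adduct <- m$adduct %in% adducts$canonical
    theo <- rep(NA_real_, nrow(m))
    ok <- known_adduct & !is.na(mono)
    theo[ok] <- theoreticalMz(mono[ok], m$adduct[ok], adducts)
    ppm <- 1e6 * abs(m$precursor_mz - theo) / theo
    keep <- !is.na(ppm) & ppm <= maxPpm
    reason <- ifelse(!ok, "unverifiable",
                     ifelse(keep, "ok", "ppm_error"))
    data.frame(spectrum_id = m$spectrum_id, keep = keep,
               ppm_error = ppm, reason = reason,
               stringsAsFactors = FALSE)
}

#' Preprocess peak lists
#'
#' Rescales intensities to the base peak (maximum intensity becomes 1.0),
#' then removes peaks with relative intensity strictly below
#' \code{minRelIntensity}, then removes peaks outside the inclusive
#' \code{[mzMin, mzMax]} range. Idempotent. Spectra whose peaks are all
#' removed are flagged (and dropped by [selectForMl()]).
#'
#' @param spectra an [MsmsSpectra-class] (each spectrum with >= 1 peak).
#' @param cfg a [cleaningConfig()].
#' @return list with elements \code{spectra} (processed
#'   [MsmsSpectra-class]) and \code{empty} (logical: spectra that lost all
#'   peaks; these are retained in \code{spectra} with zero-row peaks).
#' @export
preprocessPeaks <- function(spectra, cfg = cleaningConfig()) {
    p <- peaksData(spectra)
    out <- vector("list", length(p))
    empty <- logical(length(p))
    for (i in seq_along(p)) {
        pk <- p[[i]]
        if (nrow(pk) == 0L) { out[[i]] <- pk; empty[i] <- TRUE; next }
        rel <- pk[, 2L] / max(pk[, 2L])
        keep <- rel >= cfg$minRelIntensity &
            pk[, 1L] >= cfg$mzMin & pk[, 1L] <= cfg$mzMax
        pk <- cbind(mz = pk[keep, 1L], intensity = rel[keep])
        if (nrow(pk)) {  # re-normalize so the retained base peak is 1.0
            pk[, 2L] <- pk[, 2L] / max(pk[, 2L])
        } else empty[i] <- TRUE
        out[[i]] <- pk
    }
    list(spectra = MsmsSpectra(out, spectraData(spectra)), empty = empty)
}

#' Significant-fragmentation test
#'
#' TRUE for spectra with strictly more than
#' \code{sigPeakCountExclusiveMin} peaks whose relative intensity strictly
#' exceeds \code{sigPeakRelIntensity} (defaults: more than 4 peaks above
#' 2 percent).
#'
#' @param spectra a preprocessed [MsmsSpectra-class].
#' @param cfg a [cleaningConfig()].
#' @return logical vector, one entry per spectrum.
#' @export
hasSignificantFragmentation <- function(spectra, cfg = cleaningConfig()) {
    vapply(peaksData(spectra), function(pk) {
        if (nrow(pk) == 0L) return(FALSE)
        rel <- pk[, 2L] / max(pk[, 2L])
        sum(rel > cfg$sigPeakRelIntensity) > cfg$sigPeakCountExclusiveMin
    }, logical(1))
}

#' Select the machine-learning-ready subset
#'
#' Applies, in order: source-library exclusion, missing-structure drop,
#' ion-mode filter, precursor-mass ceiling, precursor validation
#' (ppm), peak preprocessing (dropping emptied spectra), and the
#' significant-fragmentation test. The drop report attributes each
#' rejected spectrum to the first rule that failed it, so
#' \code{kept + sum(drops) == input}.
#'
#' @param spectra harmonized [MsmsSpectra-class].
#' @param structures structure table (see [validatePrecursor()]).
#' @param cfg a [cleaningConfig()].
#' @param adducts adduct table from [adductMap()].
#' @return list with \code{spectra} (kept, preprocessed) and \code{report}
#'   (named integer vector of per-rule drop counts plus \code{kept} and
#'   \code{input}).
#' @export
selectForMl <- function(spectra, structures, cfg = cleaningConfig(),
                        adducts = adductMap()) {
    m <- spectraData(spectra)
    n <- nrow(m)
    report <- c(excluded_library = 0L, missing_structure = 0L,
                ion_mode = 0L, precursor_mass = 0L,
                precursor_validation = 0L, empty_after_preprocess = 0L,
                insignificant_fragmentation = 0L)
    alive <- rep(TRUE, n)
    drop <- function(bad, rule) {
        bad <- bad & alive
        report[rule] <<- report[rule] + sum(bad)
        alive[bad] <<- FALSE
    }
    drop(m$source_library %in% cfg$excludedLibraries, "excluded_library")
    drop(.isMissing(m$structure_ref) |
             !(m$structure_ref %in% structures$inchikey14),
         "missing_structure")
    drop(is.na(m$ion_mode) | m$ion_mode != cfg$ionMode, "ion_mode")
    drop(m$precursor_mz > cfg$maxPrecursorDa, "precursor_mass")
    val <- validatePrecursor(spectra, structures, adducts, cfg$maxPpmError)
    drop(!val$keep, "precursor_validation")

    kept <- spectra[which(alive)]
    prep <- preprocessPeaks(kept, cfg)
    report["empty_after_preprocess"] <- sum(prep$empty)
    kept <- prep$spectra[which(!prep$empty)]
    sig <- hasSignificantFragmentation(kept, cfg)
    report["insignificant_fragmentation"] <- sum(!sig)
    kept <- kept[which(sig)]

    list(spectra = kept,
         report = c(report, kept = length(kept), input = n))
}
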