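## Spectrum-pair dataset construction: exhaustive (All-Pairs) and
## criteria-filtered enumeration, plus pre-batched training epochs with an
## optionally biased pairwise-similarity target distribution.

#' Pair filtering criteria
#'
#' Criteria for the "Filtered" pair datasets: identical ionization method,
#' mass analyzer and adduct; collision-energy difference strictly below
#' \code{maxCeDiff} eV (skipped when either spectrum lacks a collision
#' energy, unless \code{ceRequired}); precursor mass difference strictly
#' below \code{maxPrecursorDiff} Da. Equality criteria fail when the field
#' is missing on either side (equality cannot be verified).
#'
#' @param requireSameIonization,requireSameAnalyzer,requireSameAdduct
#'   logical flags enabling the equality criteria.
#' @param maxCeDiff collision-energy tolerance in eV (strict \code{<}).
#' @param ceRequired strict mode: a pair with a missing collision energy
#'   fails instead of skipping the criterion.
#' @param maxPrecursorDiff precursor m/z difference ceiling in Da
#'   (strict \code{<}).
#' @return a validated list of class \code{PairCriteria}.
#' @export
pairCriteria <- function(requireSameIonization = TRUE,
                         requireSameAnalyzer = TRUE,
                         requireSameAdduct = TRUE,
                         maxCeDiff = 5, ceRequired = FALSE,
                         maxPrecursorDiff = 200) {
    stopifnot(maxCeDiff > 0, maxPrecursorDiff > 0)
    structure(list(requireSameIonization = requireSameIonization,
                   requireSameAnalyzer = requireSameAnalyzer,
                   requireSameAdduct = requireSameAdduct,
                   maxCeDiff = maxCeDiff, ceRequired = ceRequired,
                   maxPrecursorDiff = maxPrecursorDiff),
              class = "PairCriteria")
}

#' Evaluate the pair criteria for one spectrum pair
#'
#' @param a,b single-row metadata (lists or one-row data.frames) with
#'   fields \code{ionization_method}, \code{mass_analyzer}, \code{adduct},
#'   \code{collision_energy}, \code{precursor_mz}.
#' @param criteria a [pairCriteria()].
#' @return list with \code{pass} (logical) and \code{firstFail} (name of
#'   the first failing criterion, or \code{NA}).
#' @export
pairPassesFilter <- function(a, b, criteria = pairCriteria()) {
    fail <- function(name) list(pass = FALSE, firstFail = name)
    eqOk <- function(x, y) !.isMissing(x) && !.isMissing(y) && x == y
    if (criteria$requireSameIonization &&
        !eqOk(a$ionization_method, b$ionization_method))
        return(fail("ionization_method"))
    if (criteria$requireSameAnalyzer &&
        !eqOk(a$mass_analyzer, b$mass_analyzer))
        return(fail("mass_analyzer"))
    if (criteria$requireSameAdduct && !eqOk(a$adduct, b$adduct))
        return(fail("adduct"))
    ce_a <- a$collision_energy; ce_b <- b$collision_energy
    if (is.na(ce_a) || is.na(ce_b)) {
        if (criteria$ceRequired) return(fail("collision_energy_missing"))
    } else if (!(abs(ce_a - ce_b) < criteria$maxCeDiff)) {
        return(fail("collision_energy"))
    }
    if (!(abs(a$precursor_mz - b$precursor_mz) < criteria$maxPrecursorDiff))
        return(fail("precursor_mass"))
    list(pass = TRUE, firstFail = NA_character_)
}

#' Enumerate spectrum pairs
#'
#' Builds the All-Pairs (criteria = NULL) or Filtered pair table over a
#' spectra collection. All ordered pairs of distinct spectra are
#' enumerated (n(n-1) pairs; with \code{ordered = FALSE} each unordered
#' pair appears once with the lexicographically smaller spectrum id
#' first). Spectra without a structure annotation present in \code{M} are
#' excluded up front with a message. Pairs are processed in chunks so
#' memory stays proportional to the output.
#'
#' @param spectra an [MsmsSpectra-class] with \code{structure_ref} set.
#' @param M all-pair similarity matrix over the structures (target
#'   similarities are looked up here).
#' @param criteria a [pairCriteria()] or NULL for All-Pairs.
#' @param ordered logical; enumerate ordered (default) or unordered pairs.
#' @param ttSim optional named train-test similarity vector (e.g.
#'   [ttSimilarity()] of a split); adds \code{mean_tt_similarity}.
#' @return data.frame with columns \code{spectrum_id_a},
#'   \code{spectrum_id_b}, \code{inchikey14_a}, \code{inchikey14_b},
#'   \code{target_similarity} and \code{mean_tt_similarity} (NA when
#'   \code{ttSim} is absent).
#' @export
enumeratePairs <- function(spectra, M, criteria = NULL, ordered = TRUE,
                           ttSim = NULL) {
    m <- spectraData(spectra)
    usable <- !.isMissing(m$structure_ref) & m$structure_ref %in% rownames(M)
    if (any(!usable))
        .msg("excluding %d spectra without a usable structure",
             sum(!usable))
    m <- m[usable, , drop = FALSE]
    n <- nrow(m)
    if (n < 2L) return(.emptyPairTable())
    ij <- if (ordered) {
        cbind(rep(seq_len(n), each = n), rep(seq_len(n), times = n))
    } else {
        t(combn(n, 2L))
    }
    ij <- ij[ij[, 1L] != ij[, 2L], , drop = FALSE]
    if (!ordered) {  # smaller spectrum id first
        swap <- m$spectrum_id[ij[, 1L]] > m$spectrum_id[ij[, 2L]]
        ij[swap, ] <- ij[swap, c(2L, 1L)]
    }
    if (!is.null(criteria))
        ij <- ij[.pairsPassVec(m, ij[, 1L], ij[, 2L], criteria), ,
                 drop = FALSE]
    ka <- m$structure_ref[ij[, 1L]]
    kb <- m$structure_ref[ij[, 2L]]
    tt <- if (is.null(ttSim)) rep(NA_real_, nrow(ij))
          else (ttSim[ka] + ttSim[kb]) / 2
    data.frame(spectrum_id_a = m$spectrum_id[ij[, 1L]],
               spectrum_id_b = m$spectrum_id[ij[, 2L]],
               inchikey14_a = ka, inchikey14_b = kb,
               target_similarity = M[cbind(ka, kb)],
               mean_tt_similarity = unname(tt),
               stringsAsFactors = FALSE)
}

## vectorized pair criteria, semantics identical to pairPassesFilter()
.pairsPassVec <- function(m, ia, ib, criteria) {
    eqv <- function(x) {
        a <- x[ia]; b <- x[ib]
        !.isMissing(a) & !.isMissing(b) & a == b
    }
    pass <- rep(TRUE, length(ia))
    if (criteria$requireSameIonization)
        pass <- pass & eqv(m$ionization_method)
    if (criteria$requireSameAnalyzer) pass <- pass & eqv(m$mass_analyzer)
    if (criteria$requireSameAdduct) pass <- pass & eqv(m$adduct)
    ce_a <- m$collision_energy[ia]; ce_b <- m$collision_energy[ib]
    ce_missing <- is.na(ce_a) | is.na(ce_b)
    ce_ok <- ifelse(ce_missing, !criteria$ceRequired,
                    abs(ce_a - ce_b) < criteria$maxCeDiff)
    pass <- pass & ce_ok
    pass & (abs(m$precursor_mz[ia] - m$precursor_mz[ib]) <
                criteria$maxPrecursorDiff)
}

.emptyPairTable <- function() {
    data.frame(spectrum_id_a = character(0), spectrum_id_b = character(0),
               inchikey14_a = character(0), inchikey14_b = character(0),
               target_similarity = numeric(0),
               mean_tt_similarity = numeric(0), stringsAsFactors = FALSE)
}

## --------------------------- biased sampling ------------------------------

#' Biased similarity bin edges
#'
#' Unequal-width bin edges \eqn{e_i = (i/n)^{c}} that, under equiprobable
#' bin selection, bias sampled pairs toward high pairwise similarity: with
#' 20 bins and exponent 0.3 half of the bins lie above
#' \eqn{0.5^{0.3} \approx 0.812}, so half of the sampled pairs have target
#' similarity above that edge.
#'
#' @param nBins number of bins (default 20).
#' @param exponent edge exponent in (0, 1]; 1 gives uniform edges.
#' @return numeric vector of \code{nBins + 1} strictly increasing edges
#'   from 0 to 1.
#' @examples
#' biasedBinEdges(20, 0.3)[11]  # 0.5^0.3
#' @export
biasedBinEdges <- function(nBins = 20L, exponent = 0.3) {
    stopifnot(nBins >= 2L, exponent > 0, exponent <= 1)
    (seq(0L, nBins) / nBins)^exponent
}

#' Biased-sampler configuration
#'
#' @param nBins number of similarity bins for the biased scheme.
#' @param edgeExponent exponent applied to the bin edges (see
#'   [biasedBinEdges()]).
#' @param pairsPerEpoch pairs drawn per epoch.
#' @param nEpochs number of epochs to generate.
#' @param seed integer seed.
#' @return a validated list of class \code{BiasedSamplerConfig}.
#' @export
biasedSamplerConfig <- function(nBins = 20L, edgeExponent = 0.3,
                                pairsPerEpoch, nEpochs = 1L, seed = 1L) {
    stopifnot(edgeExponent > 0, edgeExponent < 1, nBins >= 2L,
              pairsPerEpoch >= 1L, nEpochs >= 1L)
    structure(list(nBins = as.integer(nBins), edgeExponent = edgeExponent,
                   pairsPerEpoch = as.integer(pairsPerEpoch),
                   nEpochs = as.integer(nEpochs), seed = as.integer(seed)),
              class = "BiasedSamplerConfig")
}

## One batch of bin-uniform draws: bins (among non-empty ones) are selected
## equiprobably, then a pair is drawn uniformly inside each selected bin.
## Exposed for distribution checks; sampling with replacement.
#' Draw pairs with a bin-uniform similarity distribution
#'
#' Bins the pair pool by target similarity on the supplied edges
#' (left-inclusive, top bin closed), then repeatedly selects a non-empty
#' bin uniformly at random and a pair uniformly within it.
#'
#' @param pairs pair table (see [enumeratePairs()]).
#' @param edges similarity bin edges (e.g. [biasedBinEdges()] or
#'   \code{seq(0, 1, 0.1)}).
#' @param n number of draws.
#' @return integer vector of row indices into \code{pairs}, length
#'   \code{n} (with replacement).
#' @export
drawPairsByBin <- function(pairs, edges, n) {
    bin <- .binIndex(pairs$target_similarity, edges)
    nonempty <- sort(unique(bin[!is.na(bin)]))
    if (!length(nonempty)) .stopf("empty_pool", "no pairs to draw from")
    by_bin <- split(seq_len(nrow(pairs)), bin)
    chosen_bins <- sample(as.character(nonempty), n, replace = TRUE)
    vapply(chosen_bins, function(b) {
        rows <- by_bin[[b]]
        rows[sample.int(length(rows), 1L)]
    }, integer(1), USE.NAMES = FALSE)
}

#' Sample pre-batched training epochs
#'
#' Replicates the coverage-first pair sampling scheme: each epoch first
#' covers every training structure (one pair containing each first-block
#' InChIKey), then fills up to \code{pairsPerEpoch} by equiprobable
#' similarity-bin draws -- ten uniform bins in \code{"uniform10"} mode, or
#' the exponent-biased 20-bin edges in \code{"biased20"} mode. Within-bin
#' selection is uniform without replacement inside an epoch (bins falling
#' empty are redrawn; exhausted pools fall back to replacement) and
#' independent across epochs. Structures with no eligible pair are dropped
#' from the coverage pass with a message.
#'
#' @param pairs training pair table restricted to train structures
#'   (see [enumeratePairs()]).
#' @param cfg a [biasedSamplerConfig()].
#' @param mode \code{"uniform10"} or \code{"biased20"}.
#' @return list of \code{nEpochs} data.frames (epoch tables).
#' @export
sampleEpochs <- function(pairs, cfg, mode = c("biased20", "uniform10")) {
    mode <- match.arg(mode)
    if (!nrow(pairs))
        .stopf("empty_pool", "no pairs to sample epochs from")
    edges <- if (mode == "biased20")
        biasedBinEdges(cfg$nBins, cfg$edgeExponent)
        else seq(0, 1, by = 0.1)
    keys <- sort(unique(c(pairs$inchikey14_a, pairs$inchikey14_b)))
    rows_of_key <- lapply(keys, function(k)
        which(pairs$inchikey14_a == k | pairs$inchikey14_b == k))
    names(rows_of_key) <- keys
    uncovered <- lengths(rows_of_key) == 0L
    if (any(uncovered))
        .msg("%d structures have no eligible pair; dropped from coverage",
             sum(uncovered))
    keys <- keys[!uncovered]
    bin <- .binIndex(pairs$target_similarity, edges)
    by_bin <- split(seq_len(nrow(pairs)), bin)

    .withSeed(cfg$seed, {
        lapply(seq_len(cfg$nEpochs), function(e) {
            cover <- vapply(keys, function(k) {
                rows <- rows_of_key[[k]]
                rows[sample.int(length(rows), 1L)]
            }, integer(1), USE.NAMES = FALSE)
            taken <- unique(cover)
            n_fill <- max(0L, cfg$pairsPerEpoch - length(taken))
            fill <- integer(0)
            if (n_fill > 0L) {
                avail <- lapply(by_bin, setdiff, y = taken)
                nonempty <- names(avail)[lengths(avail) > 0L]
                for (i in seq_len(n_fill)) {
                    if (!length(nonempty)) {  # all pools used: replacement
                        fill <- c(fill, drawPairsByBin(pairs, edges,
                                                       n_fill - i + 1L))
                        break
                    }
                    b <- nonempty[sample.int(length(nonempty), 1L)]
                    rows <- avail[[b]]
                    r <- rows[sample.int(length(rows), 1L)]
                    fill <- c(fill, r)
                    avail[[b]] <- setdiff(rows, r)
                    if (!length(avail[[b]]))
                        nonempty <- setdiff(nonempty, b)
                }
            }
            pairs[c(taken, fill),
                  c("spectrum_id_a", "spectrum_id_b", "inchikey14_a",
                    "inchikey14_b", "target_similarity")]
        })
    })
}

## ------------------------------ serialization -----------------------------

#' Write training epochs as keyed Parquet tables
#'
#' Writes one Parquet file per epoch into a directory, keyed
#' \code{epoch_0000.parquet}, \code{epoch_0001.parquet}, ... with columns
#' \code{spectrum_id_a}, \code{spectrum_id_b}, \code{inchikey14_a},
#' \code{inchikey14_b}, \code{target_similarity}.
#'
#' @param epochs non-empty list of epoch tables from [sampleEpochs()].
#' @param path output directory.
#' @param overwrite replace an existing directory (default FALSE: error).
#' @return the path, invisibly.
#' @export
writeEpochs <- function(epochs, path, overwrite = FALSE) {
    if (!length(epochs)) .stopf("empty_input", "no epochs to write")
    if (dir.exists(path) || file.exists(path)) {
        if (!overwrite)
            .stopf("exists_error", "refusing to overwrite %s", path)
        unlink(path, recursive = TRUE)
    }
    dir.create(path, recursive = TRUE)
    cols <- c("spectrum_id_a", "spectrum_id_b", "inchikey14_a",
              "inchikey14_b", "target_similarity")
    for (i in seq_along(epochs)) {
        arrow::write_parquet(
            epochs[[i]][cols],
            file.path(path, sprintf("epoch_%04d.parquet", i - 1L)))
    }
    invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
    files <- sort(list.files(path, pattern = "^epoch_\\d+\\.parquet$",
                             full.names = TRUE))
    lapply(files, function(f) as.data.frame(arrow::read_parquet(f)))
}

#' Write / read a test-pair table as Parquet
#'
#' Fixed schema: InChIKeys, spectrum ids, target similarity and train-test
#' similarity per pair.
#'
#' @param pairs pair table (see [enumeratePairs()]).
#' @param path Parquet file.
#' @param overwrite replace an existing file (default FALSE: error).
#' @return the path (write) / data.frame (read).
#' @export
writeTestPairsParquet <- function(pairs, path, overwrite = FALSE) {
    if (file.exists(path) && !overwrite)
        .stopf("exists_error", "refusing to overwrite %s", path)
    cols <- c("inchikey14_a", "inchikey14_b", "spectrum_id_a",
              "spectrum_id_b", "target_similarity", "mean_tt_similarity")
    arrow::write_parquet(pairs[cols], path)
    invisible(path)
}

#' @rdname writeTestPairsParquet
#' @export
readTestPairsParquet <- function(path) {
    as.data.frame(arrow::read_parquet(path))
}
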