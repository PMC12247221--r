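## Shared fixtures built in code. The full benchmark fixture (300
## structures, 1500 spectra) is expensive enough to cache across test
## files within the session.

.fixture_cache <- new.env(parent = emptyenv())

benchFixture <- function() {
    if (is.null(.fixture_cache$fx)) {
        fx <- generateBenchmarkFixture(fixtureConfig())
        .fixture_cache$fx <- fx
        .fixture_cache$M <- pairwiseSimilarityMatrix(fx$fingerprints)
        .fixture_cache$sel <- selectForMl(
            fx$spectra, fx$structures,
            cleaningConfig(excludedLibraries = fx$excludedLibrary))
    }
    list(fx = .fixture_cache$fx, M = .fixture_cache$M,
         sel = .fixture_cache$sel)
}

toyPeaks <- function(mz, intensity) cbind(mz = mz, intensity = intensity)

## minimal spectra collection with sensible defaults
toySpectra <- function(n = 3, peaks = NULL, precursor = NULL, ...) {
    if (is.null(peaks))
        peaks <- lapply(seq_len(n), function(i)
            toyPeaks(c(100, 150, 200) + i, c(0.2, 1, 0.5)))
    if (is.null(precursor)) precursor <- 300 + seq_len(n)
    meta <- data.frame(spectrum_id = sprintf("s%02d", seq_len(n)),
                       precursor_mz = precursor,
                       stringsAsFactors = FALSE)
    extra <- list(...)
    for (col in names(extra)) meta[[col]] <- extra[[col]]
    MsmsSpectra(peaks, meta)
}

## symmetric unit-diagonal similarity matrix from a list of
## (i, j, value) triples over ids
toySimMatrix <- function(ids, triples = list()) {
    M <- matrix(0.1, length(ids), length(ids),
                dimnames = list(ids, ids))
    diag(M) <- 1
    for (tr in triples) {
        M[tr[[1]], tr[[2]]] <- M[tr[[2]], tr[[1]]] <- tr[[3]]
    }
    M
}

## logical fingerprint vector from 1-based on-bit positions
bitsVec <- function(on, nbits = 8) {
    v <- logical(nbits)
    v[on] <- TRUE
    v
}

## a small standing prediction table: 4 queries x 6 candidates
toyPredictionTable <- function(seed = 5) {
    withr::with_seed(seed, {
        rows <- list()
        for (q in 1:4) {
            true <- round(runif(6), 3)
            pred <- round(runif(6), 3)
            rows[[q]] <- data.frame(
                query_id = sprintf("q%d", q),
                candidate_id = sprintf("q%d_c%d", q, 1:6),
                predicted = pred, true_similarity = true,
                query_inchikey14 = sprintf("QK%012d", q),
                candidate_inchikey14 = sprintf("CK%d%011d", q, 1:6),
                mean_tt_similarity = round(runif(6, 0.4, 1), 3),
                stringsAsFactors = FALSE)
        }
        do.call(rbind, rows)
    })
}
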