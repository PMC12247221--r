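## Structure-aware train/validation/test splitting.
##
## Three phases: (1) seed the test set with structures that are maximally
## dissimilar from everything else, selected per train-test-similarity
## histogram bin; (2) add high-pairwise-similarity structures by random
## walks on the >0.7 similarity graph; (3) balance the train-test
## similarity histogram by eroding training structures that keep test
## structures too similar to the training set, capped at a maximum
## erosion fraction. A 2-D coverage grid audits the resulting ordered
## test pairs.

#' Split configuration
#'
#' @param dataPointsPerBin target number of test structures per train-test
#'   similarity bin (phases 1 and 3).
#' @param numTestRoots number of random-walk roots (phase 2).
#' @param ttBinLo,ttBinHi train-test similarity range that is binned for
#'   balancing (defaults 0.4 and 1.0).
#' @param nTtBins number of evenly spaced balancing bins on
#'   \code{[ttBinLo, ttBinHi]} (default 13).
#' @param walkEdgeThreshold pairwise similarity strictly above which two
#'   structures are connected in the walk graph (default 0.7).
#' @param minRootDegreeExclusive roots must have degree strictly greater
#'   than this (default 3, i.e. degree >= 4).
#' @param walkLength number of random-walk steps per root (default 4).
#' @param maxTrainErosion stop balancing once this fraction of the original
#'   training set has been removed (default 0.8).
#' @param nValidationStructures validation structures drawn uniformly from
#'   the final training pool (default 500).
#' @param seed integer seed governing all randomness in the split.
#' @return a validated list of class \code{SplitConfig}.
#' @export
splitConfig <- function(dataPointsPerBin, numTestRoots,
                        ttBinLo = 0.4, ttBinHi = 1.0, nTtBins = 13L,
                        walkEdgeThreshold = 0.7,
                        minRootDegreeExclusive = 3L, walkLength = 4L,
                        maxTrainErosion = 0.8,
                        nValidationStructures = 500L, seed = 1L) {
    stopifnot(ttBinLo < ttBinHi, maxTrainErosion > 0, maxTrainErosion < 1,
              nTtBins >= 1L, walkLength >= 1L)
    structure(list(dataPointsPerBin = as.integer(dataPointsPerBin),
                   numTestRoots = as.integer(numTestRoots),
                   ttBinLo = ttBinLo, ttBinHi = ttBinHi,
                   nTtBins = as.integer(nTtBins),
                   walkEdgeThreshold = walkEdgeThreshold,
                   minRootDegreeExclusive = as.integer(
                       minRootDegreeExclusive),
                   walkLength = as.integer(walkLength),
                   maxTrainErosion = maxTrainErosion,
                   nValidationStructures = as.integer(
                       nValidationStructures),
                   seed = as.integer(seed)),
              class = "SplitConfig")
}

## bin edges rounded to 10 decimals so decimal-valued thresholds compare
## exactly against data on the same grid
.ttEdges <- function(cfg) round(seq(cfg$ttBinLo, cfg$ttBinHi,
                                    length.out = cfg$nTtBins + 1L), 10)

#' Train-test similarity of one or more test structures
#'
#' The maximum pairwise Tanimoto similarity between each test structure and
#' all training structures; 0 for an empty training set.
#'
#' @param testIds,trainIds character vectors of structure ids present in
#'   \code{M}.
#' @param M all-pair similarity matrix (see
#'   [pairwiseSimilarityMatrix()]).
#' @return named numeric vector, one entry per test id.
#' @export
trainTestSimilarity <- function(testIds, trainIds, M) {
    if (!all(c(testIds, trainIds) %in% rownames(M)))
        .stopf("lookup_error", "unknown structure id in similarity lookup")
    if (!length(trainIds))
        return(setNames(rep(0, length(testIds)), testIds))
    sub <- M[testIds, trainIds, drop = FALSE]
    setNames(apply(sub, 1L, max), testIds)
}

#' Phase 1: seed with maximally dissimilar structures
#'
#' Bins every structure by its maximum similarity to any other structure
#' (the histogram uses the balancing bins on \code{[ttBinLo, ttBinHi]} plus
#' one underflow bin below \code{ttBinLo}) and selects up to
#' \code{dataPointsPerBin} structures uniformly at random from each bin.
#' Underfilled bins are allowed.
#'
#' @param M all-pair similarity matrix.
#' @param cfg a [splitConfig()]. The caller is responsible for seeding
#'   (see [splitStructures()]).
#' @return character vector of selected structure ids.
#' @export
phase1SelectDissimilar <- function(M, cfg) {
    if (cfg$dataPointsPerBin <= 0L) return(character(0))
    ids <- rownames(M)
    if (length(ids) < 2L) return(character(0))
    D <- M
    diag(D) <- -Inf
    maxsim <- apply(D, 1L, max)
    edges <- c(0, .ttEdges(cfg))  # prepend the underflow bin [0, ttBinLo)
    bin <- .binIndex(pmin(pmax(maxsim, 0), 1), edges)
    selected <- character(0)
    for (b in sort(unique(bin))) {
        members <- ids[which(bin == b)]
        k <- min(cfg$dataPointsPerBin, length(members))
        selected <- c(selected, .sampleVec(members, k))
    }
    selected
}

## sample() without its scalar-x surprise
.sampleVec <- function(x, k) {
    if (length(x) <= 1L || k >= length(x)) return(head(x, k))
    sample(x, k)
}

#' Phase 2: random-walk selection of structural neighborhoods
#'
#' Builds a graph whose nodes are structures and whose edges connect pairs
#' with similarity strictly above \code{walkEdgeThreshold}, samples
#' \code{numTestRoots} roots (without replacement) among nodes of degree
#' strictly greater than \code{minRootDegreeExclusive}, and performs one
#' uniform random walk of \code{walkLength} steps from each root. Returns
#' the union of roots and visited nodes. If fewer eligible roots exist than
#' requested, all are used with a warning.
#'
#' @inheritParams phase1SelectDissimilar
#' @return character vector of structure ids (possibly empty).
#' @export
phase2RandomWalk <- function(M, cfg) {
    A <- M > cfg$walkEdgeThreshold
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    deg <- igraph::degree(g)
    eligible <- names(deg)[deg > cfg$minRootDegreeExclusive]
    if (!length(eligible)) return(character(0))
    if (length(eligible) < cfg$numTestRoots)
        warning(sprintf(
            "only %d eligible random-walk roots (requested %d)",
            length(eligible), cfg$numTestRoots))
    roots <- .sampleVec(eligible, min(cfg$numTestRoots, length(eligible)))
    visited <- character(0)
    for (r in roots) {
        w <- igraph::random_walk(g, start = r, steps = cfg$walkLength + 1L)
        visited <- c(visited, names(w))
    }
    unique(c(roots, visited))
}

#' Phase 3: balance train-test similarity by training-set erosion
#'
#' Starting from the initial test set, iterates over the balancing bins
#' from low to high train-test similarity. For the first underfilled bin,
#' structures are sampled from the next non-empty higher bin and, for each
#' sampled structure, every training structure with similarity strictly
#' above the current bin's upper bound is removed from the training set --
#' forcing the moved structure's train-test similarity to at most that
#' bound. Stops when all bins hold \code{dataPointsPerBin} structures or
#' when \code{maxTrainErosion} of the original training set has been
#' eroded. Finally draws the validation set uniformly from the surviving
#' training pool.
#'
#' @param train,test disjoint character vectors of structure ids.
#' @inheritParams phase1SelectDissimilar
#' @return an [MsmsSplit-class].
#' @export
phase3BalanceByErosion <- function(train, test, M, cfg) {
    stopifnot(!length(intersect(train, test)))
    edges <- .ttEdges(cfg)
    nb <- cfg$nTtBins
    orig_n <- length(train)
    erosion_cap <- cfg$maxTrainErosion * orig_n
    exhausted <- rep(FALSE, nb)

    binOf <- function(tt) .binIndex(tt, edges)  # NA below/above range
    tt <- trainTestSimilarity(test, train, M)
    repeat {
        bins <- binOf(tt)
        counts <- tabulate(bins[!is.na(bins)], nbins = nb)
        under <- which(counts < cfg$dataPointsPerBin & !exhausted)
        if (!length(under) || (orig_n - length(train)) >= erosion_cap)
            break
        b <- under[1L]
        donor_bins <- which(counts > 0L)
        donor_bins <- donor_bins[donor_bins > b]
        if (!length(donor_bins)) { exhausted[b] <- TRUE; next }
        db <- donor_bins[1L]
        need <- cfg$dataPointsPerBin - counts[b]
        donors <- .sampleVec(names(tt)[which(bins == db)],
                             min(need, counts[db]))
        removed_any <- FALSE
        for (d in donors) {
            if ((orig_n - length(train)) >= erosion_cap) break
            too_close <- train[M[d, train] > edges[b + 1L]]
            if (length(too_close)) {
                train <- setdiff(train, too_close)
                removed_any <- TRUE
            }
        }
        if (!removed_any) { exhausted[b] <- TRUE; next }
        tt <- trainTestSimilarity(test, train, M)
    }

    val <- .sampleVec(sort(train),
                      min(cfg$nValidationStructures, length(train)))
    train <- setdiff(train, val)
    new("MsmsSplit", train = train, validation = val, test = test,
        ttSimilarity = trainTestSimilarity(test, train, M),
        config = unclass(cfg))
}

#' Structure-aware train/validation/test split
#'
#' Runs the three phases under the configuration's seed: dissimilarity
#' seeding, random-walk neighborhood selection, and erosion balancing.
#' Identical inputs and seed yield an identical split.
#'
#' @param M all-pair similarity matrix over deduplicated structures
#'   (first-block InChIKey dimnames).
#' @param cfg a [splitConfig()].
#' @return an [MsmsSplit-class].
#' @examples
#' \dontrun{
#' M <- pairwiseSimilarityMatrix(fingerprintStructures(structures))
#' sp <- splitStructures(M, splitConfig(dataPointsPerBin = 5,
#'                                      numTestRoots = 10, seed = 1))
#' }
#' @export
splitStructures <- function(M, cfg) {
    .withSeed(cfg$seed, {
        p1 <- phase1SelectDissimilar(M, cfg)
        p2 <- phase2RandomWalk(M, cfg)
        test <- sort(unique(c(p1, p2)))
        train <- setdiff(rownames(M), test)
        phase3BalanceByErosion(train, test, M, cfg)
    })
}

## ----------------------------- coverage grid ------------------------------

#' Coverage grid over ordered test pairs
#'
#' Bins ordered test pairs by pairwise similarity (10 bins of width 0.1)
#' and mean train-test similarity (12 bins of width 0.05 on
#' \code{[0.4, 1]}); bins are left-inclusive and the top bin of each axis
#' includes its upper limit. Pairs with mean train-test similarity below
#' 0.4 fall outside the grid and are only tallied.
#'
#' @param pairwiseSim numeric vector of pairwise Tanimoto similarities,
#'   one entry per ordered pair.
#' @param meanTt numeric vector (same length) of mean train-test
#'   similarities of the two pair members.
#' @param threshold ordered-pair count for a cell to count as covered
#'   (default 200 ordered pairs = 100 unique pairs).
#' @return a [CoverageGrid-class].
#' @export
coverageGrid <- function(pairwiseSim, meanTt, threshold = 200) {
    stopifnot(length(pairwiseSim) == length(meanTt))
    pw_edges <- round(seq(0, 1, by = 0.1), 10)
    tt_edges <- round(seq(0.4, 1, by = 0.05), 10)
    pi_ <- .binIndex(pairwiseSim, pw_edges)
    ti <- .binIndex(meanTt, tt_edges)
    inside <- !is.na(pi_) & !is.na(ti)
    counts <- matrix(0L, nrow = 10L, ncol = 12L,
                     dimnames = list(
                         sprintf("pw_%.1f", pw_edges[-11L]),
                         sprintf("tt_%.2f", tt_edges[-13L])))
    if (any(inside)) {
        tab <- table(factor(pi_[inside], levels = 1:10),
                     factor(ti[inside], levels = 1:12))
        counts[] <- as.integer(tab)
    }
    new("CoverageGrid", counts = counts, pairwiseEdges = pw_edges,
        ttEdges = tt_edges, threshold = threshold,
        nOutside = sum(!inside))
}

#' Coverage grid of a split's exhaustive ordered test pairs
#'
#' Enumerates all ordered pairs of distinct test structures of a split,
#' weights each structure pair by the number of ordered spectrum pairs it
#' contributes (\code{nSpectra[a] * nSpectra[b]} when per-structure
#' spectrum counts are supplied, otherwise 1), and audits them with
#' [coverageGrid()].
#'
#' @param split an [MsmsSplit-class].
#' @param M all-pair similarity matrix.
#' @param nSpectra optional named integer vector of spectra per test
#'   structure.
#' @param threshold covered-cell threshold in ordered pairs.
#' @return a [CoverageGrid-class].
#' @export
testPairCoverage <- function(split, M, nSpectra = NULL, threshold = 200) {
    ids <- testIds(split)
    tt <- ttSimilarity(split)
    if (length(ids) < 2L)
        return(coverageGrid(numeric(0), numeric(0), threshold))
    idx <- which(outer(seq_along(ids), seq_along(ids), "!="))
    a <- ((idx - 1L) %% length(ids)) + 1L
    b <- ((idx - 1L) %/% length(ids)) + 1L
    pw <- M[cbind(ids[a], ids[b])]
    mt <- (tt[ids[a]] + tt[ids[b]]) / 2
    w <- if (is.null(nSpectra)) rep(1L, length(a))
         else as.integer(nSpectra[ids[a]] * nSpectra[ids[b]])
    coverageGrid(rep(pw, w), rep(mt, w), threshold)
}
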