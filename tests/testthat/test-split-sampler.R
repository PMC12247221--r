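test_that("train-test similarity is the max over training structures", {
    ids <- sprintf("K%02d", 1:6)
    M <- toySimMatrix(ids, list(list("K01", "K02", 0.9),
                                list("K01", "K03", 0.6),
                                list("K04", "K05", 0.3)))
    ## brute-force oracle over a 5-structure training set
    tt <- trainTestSimilarity("K01", ids[-1], M)
    expect_equal(unname(tt), max(M["K01", ids[-1]]))
    expect_equal(unname(tt), 0.9)
    ## duplicate in training (similarity 1.0 on the diagonal path)
    M2 <- toySimMatrix(ids, list(list("K01", "K06", 1.0)))
    expect_equal(unname(trainTestSimilarity("K01", ids[-1], M2)), 1.0)
    ## empty training set is defined as 0
    expect_equal(unname(trainTestSimilarity("K01", character(0), M)), 0)
    expect_error(trainTestSimilarity("NOPE", ids, M),
                 class = "lookup_error")
})

test_that("phase 1 fills each histogram bin up to the quota", {
    ## 15 mutually-similar pairs planted so that each of 5 bins holds
    ## 6 structures (3 pairs x 2) with a known max similarity
    ids <- sprintf("S%02d", 1:30)
    vals <- rep(c(0.42, 0.52, 0.62, 0.72, 0.82), each = 3)
    triples <- lapply(seq_len(15), function(p)
        list(ids[2 * p - 1], ids[2 * p], vals[p]))
    M <- toySimMatrix(ids, triples)
    M[M == 0.1] <- 0  # keep planted values the max for every structure
    diag(M) <- 1
    cfg <- splitConfig(dataPointsPerBin = 3, numTestRoots = 0,
                       nTtBins = 12, seed = 9)
    sel <- withr::with_seed(9, phase1SelectDissimilar(M, cfg))
    D <- M; diag(D) <- -Inf
    maxsim <- apply(D, 1, max)
    expect_identical(as.integer(table(maxsim[sel])), rep(3L, 5))
    ## zero quota -> empty selection
    cfg0 <- splitConfig(dataPointsPerBin = 0, numTestRoots = 0, seed = 9)
    expect_identical(withr::with_seed(9, phase1SelectDissimilar(M, cfg0)),
                     character(0))
})

test_that("phase 2 random walks stay in the similarity graph", {
    ## star K1,5: only the center has degree >= 4
    ids <- c("CTR", sprintf("LF%d", 1:5))
    M <- toySimMatrix(ids, lapply(1:5, function(i)
        list("CTR", sprintf("LF%d", i), 0.8)))
    M[M == 0.1] <- 0.2  # below the 0.7 edge threshold
    diag(M) <- 1
    cfg <- splitConfig(dataPointsPerBin = 0, numTestRoots = 1, seed = 4)
    sel <- withr::with_seed(4, phase2RandomWalk(M, cfg))
    expect_true("CTR" %in% sel)
    expect_true(all(sel %in% ids))

    ## no node of degree >= 4 -> empty set
    M2 <- toySimMatrix(ids, list(list("CTR", "LF1", 0.8)))
    expect_identical(withr::with_seed(4, phase2RandomWalk(M2, cfg)),
                     character(0))

    ## seeded determinism on a denser 20-node graph
    ids3 <- sprintf("N%02d", 1:20)
    M3 <- withr::with_seed(8, {
        A <- matrix(runif(400), 20, dimnames = list(ids3, ids3))
        (A + t(A)) / 2
    })
    diag(M3) <- 1
    cfg3 <- splitConfig(dataPointsPerBin = 0, numTestRoots = 3, seed = 5)
    s1 <- withr::with_seed(5, phase2RandomWalk(M3, cfg3))
    s2 <- withr::with_seed(5, phase2RandomWalk(M3, cfg3))
    expect_identical(s1, s2)
})

test_that("phase 3 moves donors down a bin by eroding close train structures", {
    ## bins of width 0.05: [0.5, 0.55) empty; donor A sits in [0.55, 0.60)
    ## because of train neighbor N1 at 0.57; next-closest neighbor N2 at
    ## 0.52. Moving A must remove N1 (similarity > 0.55) and leave A with
    ## train-test similarity 0.52.
    ids <- c("A", "B1", "B2", "N1", "N2", "F1", "F2", "F3", "F4")
    M <- toySimMatrix(ids, list(
        list("A", "N1", 0.57), list("A", "N2", 0.52),
        list("B1", "F1", 0.42), list("B2", "F2", 0.47)))
    cfg <- splitConfig(dataPointsPerBin = 1, numTestRoots = 0,
                       nTtBins = 12, nValidationStructures = 0, seed = 2)
    split <- withr::with_seed(2, phase3BalanceByErosion(
        train = c("N1", "N2", "F1", "F2", "F3", "F4"),
        test = c("A", "B1", "B2"), M, cfg))
    expect_false("N1" %in% trainIds(split))
    expect_true("N2" %in% trainIds(split))
    expect_equal(unname(ttSimilarity(split)["A"]), 0.52)
    ## moved structure's similarity is at most the target bin's upper bound
    expect_lte(ttSimilarity(split)["A"], 0.55)
})

test_that("phase 3 leaves a fully balanced split untouched", {
    ids <- c("T1", "T2", "R1", "R2")
    M <- toySimMatrix(ids, list(list("T1", "R1", 0.45),
                                list("T2", "R2", 0.45)))
    cfg <- splitConfig(dataPointsPerBin = 0, numTestRoots = 0,
                       nValidationStructures = 0, seed = 3)
    split <- withr::with_seed(3, phase3BalanceByErosion(
        train = c("R1", "R2"), test = c("T1", "T2"), M, cfg))
    expect_setequal(trainIds(split), c("R1", "R2"))
})

test_that("full split on the benchmark fixture honors its contract", {
    b <- benchFixture()
    cfg <- splitConfig(dataPointsPerBin = 6, numTestRoots = 8,
                       nTtBins = 12, nValidationStructures = 30, seed = 7)
    split <- splitStructures(b$M, cfg)

    ## disjointness by inchikey14
    expect_length(intersect(trainIds(split), testIds(split)), 0)
    expect_length(intersect(trainIds(split), validationIds(split)), 0)
    expect_length(intersect(validationIds(split), testIds(split)), 0)

    ## recompute-and-assert: the reported train-test similarity is the
    ## true maximum over the final training set
    tt <- ttSimilarity(split)
    recomputed <- trainTestSimilarity(testIds(split), trainIds(split),
                                      b$M)
    expect_equal(tt[testIds(split)], recomputed)

    ## erosion bound: the balancing loop removes at most 80% of the
    ## original training pool (validation is drawn after balancing)
    n_orig <- nrow(b$M) - length(testIds(split))
    n_after_balance <- length(trainIds(split)) +
        length(validationIds(split))
    expect_lte(n_orig - n_after_balance, 0.8 * n_orig)

    ## phase 3 never increases any test structure's similarity: against
    ## the pre-balancing training pool every similarity is >= the final
    pre <- trainTestSimilarity(
        testIds(split), setdiff(rownames(b$M), testIds(split)), b$M)
    expect_true(all(tt[names(pre)] <= pre + 1e-12))

    ## seeded determinism: byte-identical serialization on rerun
    split2 <- splitStructures(b$M, cfg)
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    writeSplitJson(split, f1)
    writeSplitJson(split2, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("coverage grid bins pairs left-inclusively with a closed top bin", {
    ## zero pairs
    g <- coverageGrid(numeric(0), numeric(0))
    expect_equal(coverage(g), 0)
    expect_identical(dim(gridCounts(g)), c(10L, 12L))

    ## a pair at pairwise exactly 1.0 lands in the top pairwise bin
    g <- coverageGrid(1.0, 0.7, threshold = 1)
    expect_identical(unname(which(gridCounts(g) > 0, arr.ind = TRUE)),
                     matrix(c(10L, 7L), 1))

    ## planted >= threshold pairs in every cell -> coverage 1.0
    centers_pw <- seq(0.05, 0.95, 0.1)
    centers_tt <- seq(0.425, 0.975, 0.05)
    pw <- rep(rep(centers_pw, each = length(centers_tt)), times = 200)
    tt <- rep(rep(centers_tt, times = length(centers_pw)), times = 200)
    g <- coverageGrid(pw, tt, threshold = 200)
    expect_equal(coverage(g), 1)
    expect_equal(roiCoverage(g), 1)
    expect_identical(sum(gridCounts(g)), length(pw))

    ## pairs below the train-test range stay out of the grid but are
    ## tallied
    g <- coverageGrid(c(0.5, 0.5), c(0.3, 0.5), threshold = 1)
    expect_identical(sum(gridCounts(g)), 1L)
    expect_equal(g@nOutside, 1)

    ## a split-level audit returns the full 10 x 12 matrix end to end
    b <- benchFixture()
    cfg <- splitConfig(dataPointsPerBin = 6, numTestRoots = 8,
                       nTtBins = 12, nValidationStructures = 30, seed = 7)
    split <- splitStructures(b$M, cfg)
    grid <- testPairCoverage(split, b$M)
    expect_identical(dim(gridCounts(grid)), c(10L, 12L))
    n_test <- length(testIds(split))
    expect_identical(sum(gridCounts(grid)) + as.integer(grid@nOutside),
                     n_test * (n_test - 1L))
})
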