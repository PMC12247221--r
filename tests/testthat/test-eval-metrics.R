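test_that("rmse and its binning match hand calculations", {
    expect_equal(rmse(c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.6)),
                 sqrt(mean(c(0.01, 0.01, 0.09))))
    tab <- toyPredictionTable()
    ## perfect predictions: zero in every non-empty bin
    perfect <- tab
    perfect$predicted <- perfect$true_similarity
    br <- binnedRmse(perfect)
    expect_true(all(br$rmse[br$n > 0] == 0))
    ## constant error 0.1 gives RMSE 0.1 in every non-empty bin
    const <- tab[tab$true_similarity <= 0.85, ]
    const$predicted <- const$true_similarity + 0.1
    br <- binnedRmse(const)
    expect_equal(br$rmse[br$n > 0], rep(0.1, sum(br$n > 0)))
    ## empty bins are excluded from the bin average
    expect_false(is.na(binAveragedRmse(const, above = 0.6)))
    ## true similarity 1.0 lands in the top bin
    one <- tab[1, ]; one$true_similarity <- 1; one$predicted <- 0.9
    br <- binnedRmse(one)
    expect_identical(br$n[10], 1L)
})

test_that("top candidate similarity matches the brute-force oracle", {
    tab <- toyPredictionTable()
    for (exclude in c(FALSE, TRUE)) {
        cfg <- rankingConfig(kValues = c(1L, 3L, 10L),
                             excludeIdentical = exclude)
        got <- topCandidateSimilarity(tab, cfg)
        for (r in seq_len(nrow(got)))
            expect_equal(got$value[r],
                         oracleTopCandidate(tab, got$k[r], exclude))
    }
    ## k covering all candidates makes the predictor irrelevant
    cfg <- rankingConfig(kValues = 6L)
    shuffled <- tab
    shuffled$predicted <- rev(shuffled$predicted)
    expect_equal(topCandidateSimilarity(tab, cfg)$value,
                 topCandidateSimilarity(shuffled, cfg)$value)
})

test_that("theoretical maximum bounds the metric; exclusion lowers it", {
    tab <- toyPredictionTable()
    cfg <- rankingConfig(kValues = c(1L, 3L))
    tmax <- theoreticalMaximum(tab, cfg, mode = "max")
    tcs <- topCandidateSimilarity(tab, cfg)
    expect_true(all(tcs$value <= tmax$value + 1e-12))

    ## an identical-structure candidate contributes 1.0 until excluded
    tab2 <- data.frame(
        query_id = "q", candidate_id = c("c1", "c2"),
        predicted = c(0.9, 0.1), true_similarity = c(1, 0.4),
        query_inchikey14 = "QKEY",
        candidate_inchikey14 = c("QKEY", "OTHER"))
    expect_equal(theoreticalMaximum(tab2, rankingConfig(kValues = 1L),
                                    mode = "max")$value, 1)
    expect_equal(theoreticalMaximum(
        tab2, rankingConfig(kValues = 1L, excludeIdentical = TRUE),
        mode = "max")$value, 0.4)

    ## the as-quoted kth-highest reading is also reported
    both <- theoreticalMaximum(tab, rankingConfig(kValues = c(1L, 3L)))
    expect_setequal(unique(both$mode), c("max", "kth"))
    kth <- both[both$mode == "kth", ]
    expect_true(all(diff(kth$value) <= 1e-12))  # non-increasing in k
})

test_that("top rank reproduces the worked example and the oracle", {
    ## single query: true top-3 candidates placed at predicted ranks
    ## 21, 42, 13 -> metric 13
    n <- 50
    true <- seq(0.98, by = -0.02, length.out = n)
    pred_rank <- integer(n)
    pred_rank[1:3] <- c(21L, 42L, 13L)
    pred_rank[4:n] <- withr::with_seed(17,
        sample(setdiff(seq_len(n), c(21L, 42L, 13L))))
    tab <- data.frame(
        query_id = "q", candidate_id = sprintf("c%02d", 1:n),
        predicted = 1 - pred_rank / (n + 1), true_similarity = true,
        query_inchikey14 = "QKEY",
        candidate_inchikey14 = sprintf("K%03d", 1:n))
    expect_identical(topRank(tab, rankingConfig(kValues = 3L))$value, 13)

    ## oracle predictor scores 1 at every k
    oracle_tab <- toyPredictionTable()
    oracle_tab$predicted <- oracle_tab$true_similarity
    tr <- topRank(oracle_tab, rankingConfig(kValues = c(1L, 3L)))
    expect_equal(tr$value, c(1, 1))

    ## ties: structures sharing a ground-truth value share one rank
    tie_tab <- data.frame(
        query_id = "q", candidate_id = sprintf("c%d", 1:4),
        predicted = c(0.1, 0.2, 0.9, 0.6),
        true_similarity = c(0.8, 0.8, 0.5, 0.3),
        query_inchikey14 = "QKEY",
        candidate_inchikey14 = sprintf("K%d", 1:4))
    ## k = 2: ranks are {c1,c2}=1, {c3}=2; true top-2 = {c1,c2,c3};
    ## predicted order c3,c4,c2,c1 -> best predicted rank is 1 (c3)
    expect_equal(topRank(tie_tab, rankingConfig(kValues = 2L))$value, 1)
    ## k = 1: true top set {c1,c2} with predicted ranks 3 and 4 -> 3
    expect_equal(topRank(tie_tab, rankingConfig(kValues = 1L))$value, 3)

    ## randomized fixture against the dense-ranking oracle
    tab <- toyPredictionTable()
    for (exclude in c(FALSE, TRUE)) {
        cfg <- rankingConfig(kValues = c(1L, 2L, 3L),
                             excludeIdentical = exclude)
        got <- topRank(tab, cfg)
        for (r in seq_len(nrow(got)))
            expect_equal(got$value[r],
                         oracleTopRank(tab, got$k[r], exclude))
    }
})

test_that("metric monotonicity and dominance properties hold", {
    b <- benchFixture()
    ## build a moderately sized prediction table from the fixture pairs
    sp <- b$sel$spectra
    m <- spectraData(sp)
    keep <- spectrumIds(sp)[!duplicated(m$structure_ref)][1:40]
    sub <- sp[keep]
    pairs <- enumeratePairs(sub, b$M)
    withr::with_seed(23, {
        random_tab <- data.frame(
            query_id = pairs$spectrum_id_a,
            candidate_id = pairs$spectrum_id_b,
            predicted = runif(nrow(pairs)),
            true_similarity = pairs$target_similarity,
            query_inchikey14 = pairs$inchikey14_a,
            candidate_inchikey14 = pairs$inchikey14_b)
    })
    oracle_tab <- random_tab
    oracle_tab$predicted <- oracle_tab$true_similarity
    cfg <- rankingConfig(kValues = c(1L, 3L, 10L))

    for (tab in list(random_tab, oracle_tab)) {
        tcs <- topCandidateSimilarity(tab, cfg)
        expect_true(all(diff(tcs$value) >= -1e-12))  # non-decreasing in k
        tr <- topRank(tab, cfg)
        expect_true(all(diff(tr$value) <= 1e-12))  # non-increasing in k
        tmax <- theoreticalMaximum(tab, cfg, mode = "max")
        expect_true(all(tcs$value <= tmax$value + 1e-12))
    }
    ## the oracle predictor attains the bound and dominates the random one
    tcs_o <- topCandidateSimilarity(oracle_tab, cfg)
    tcs_r <- topCandidateSimilarity(random_tab, cfg)
    tmax <- theoreticalMaximum(oracle_tab, cfg, mode = "max")
    expect_equal(tcs_o$value[1], tmax$value[1])
    expect_true(all(tcs_o$value >= tcs_r$value - 1e-12))
    expect_true(all(topRank(oracle_tab, cfg)$value <=
                    topRank(random_tab, cfg)$value + 1e-12))
    expect_equal(topRank(oracle_tab, cfg)$value, rep(1, 3))

    ## row-order invariance
    perm <- withr::with_seed(9, sample(nrow(random_tab)))
    expect_equal(topRank(random_tab[perm, ], cfg),
                 topRank(random_tab, cfg), ignore_attr = TRUE)
    expect_equal(topCandidateSimilarity(random_tab[perm, ], cfg),
                 topCandidateSimilarity(random_tab, cfg),
                 ignore_attr = TRUE)
})

test_that("train-test stratification partitions rows exactly", {
    tab <- toyPredictionTable()
    rmseFun <- function(d) rmse(d$predicted, d$true_similarity)
    strat <- stratifyByTt(tab, rmseFun)
    expect_identical(sum(strat$n_rows), nrow(tab))
    ## per-bin values match per-partition recomputation
    edges <- seq(0.4, 1, 0.05)
    for (b in which(strat$n_rows > 0)) {
        rows <- tab$mean_tt_similarity >= strat$tt_lo[b] &
            (tab$mean_tt_similarity < strat$tt_hi[b] |
             (b == 12 & tab$mean_tt_similarity == 1))
        expect_equal(strat$metric[[b]], rmseFun(tab[rows, ]))
    }
    ## all rows in one bin: that bin equals the global metric
    one <- tab
    one$mean_tt_similarity <- 0.62
    strat <- stratifyByTt(one, rmseFun)
    expect_equal(strat$metric[[5]], rmseFun(one))
    expect_identical(sum(strat$n_rows > 0), 1L)
    ## a row at exactly 1.0 goes to the closed top bin
    one$mean_tt_similarity <- 1
    strat <- stratifyByTt(one, rmseFun)
    expect_identical(strat$n_rows[12], nrow(one))
})

test_that("seed aggregation reports mean and sd per k", {
    t1 <- data.frame(k = c(1, 10), value = c(0.4, 0.6))
    t2 <- data.frame(k = c(1, 10), value = c(0.5, 0.7))
    agg <- aggregateSeeds(list(t1, t2))
    expect_equal(agg$mean, c(0.45, 0.65))
    expect_equal(agg$sd, c(sd(c(0.4, 0.5)), sd(c(0.6, 0.7))))
})
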