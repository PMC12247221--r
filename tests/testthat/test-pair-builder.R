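## small harmonized spectra set with controlled metadata for pair tests
pairFixtureSpectra <- function() {
    toySpectra(5,
        precursor = c(300, 302, 300, 450, 520),
        adduct = c("[M+H]+", "[M+H]+", "[M+Na]+", "[M+H]+", "[M+H]+"),
        ionization_method = "ESI",
        mass_analyzer = c("Orbitrap", "Orbitrap", "Orbitrap", "Orbitrap",
                          "TOF"),
        collision_energy = c(20, 24.9, 20, NA, 20),
        structure_ref = c("KEYA", "KEYA", "KEYB", "KEYB", "KEYC"))
}

pairFixtureM <- function()
    toySimMatrix(c("KEYA", "KEYB", "KEYC"),
                 list(list("KEYA", "KEYB", 0.8),
                      list("KEYA", "KEYC", 0.3),
                      list("KEYB", "KEYC", 0.5)))

test_that("pair criteria match on equality, CE window and precursor gap", {
    a <- list(ionization_method = "ESI", mass_analyzer = "Orbitrap",
              adduct = "[M+H]+", collision_energy = 20,
              precursor_mz = 300)
    same <- pairPassesFilter(a, a)
    expect_true(same$pass)
    ## CE difference exactly 5 eV fails (strict <); 4.9 passes
    b <- a; b$collision_energy <- 25
    expect_false(pairPassesFilter(a, b)$pass)
    expect_identical(pairPassesFilter(a, b)$firstFail,
                     "collision_energy")
    b$collision_energy <- 24.9
    expect_true(pairPassesFilter(a, b)$pass)
    ## missing CE: skipped by default, fails in strict mode
    b$collision_energy <- NA
    expect_true(pairPassesFilter(a, b)$pass)
    expect_false(pairPassesFilter(a, b,
                                  pairCriteria(ceRequired = TRUE))$pass)
    ## precursor gap of exactly 200 Da fails (strict <)
    b <- a; b$precursor_mz <- 500
    expect_false(pairPassesFilter(a, b)$pass)
    expect_identical(pairPassesFilter(a, b)$firstFail, "precursor_mass")
    ## first failing criterion is reported in evaluation order
    b <- a; b$ionization_method <- "APCI"; b$adduct <- "[M+Na]+"
    expect_identical(pairPassesFilter(a, b)$firstFail,
                     "ionization_method")
})

test_that("pair enumeration is exhaustive and filtering is a subset", {
    sp <- pairFixtureSpectra()
    M <- pairFixtureM()
    all_pairs <- enumeratePairs(sp, M)
    expect_identical(nrow(all_pairs), 5L * 4L)
    unord <- enumeratePairs(sp, M, ordered = FALSE)
    expect_identical(nrow(unord), 10L)
    expect_true(all(unord$spectrum_id_a < unord$spectrum_id_b))

    ## brute-force recount with the single-pair filter as oracle
    filt <- enumeratePairs(sp, M, criteria = pairCriteria())
    m <- spectraData(sp)
    expected <- 0L
    for (i in 1:5) for (j in 1:5) {
        if (i == j) next
        if (pairPassesFilter(m[i, ], m[j, ], pairCriteria())$pass)
            expected <- expected + 1L
    }
    expect_identical(nrow(filt), expected)
    expect_gt(nrow(filt), 0L)

    ## subset chains: strict-CE set within filtered set within all pairs
    strict <- enumeratePairs(sp, M,
                             criteria = pairCriteria(ceRequired = TRUE))
    key <- function(d) paste(d$spectrum_id_a, d$spectrum_id_b)
    expect_true(all(key(filt) %in% key(all_pairs)))
    expect_true(all(key(strict) %in% key(filt)))

    ## target similarity equals the matrix lookup for the structure pair
    expect_equal(all_pairs$target_similarity,
                 M[cbind(all_pairs$inchikey14_a,
                         all_pairs$inchikey14_b)])

    ## same-structure different-spectrum pairs carry target 1.0
    self_struct <- all_pairs[all_pairs$inchikey14_a ==
                             all_pairs$inchikey14_b, ]
    expect_gt(nrow(self_struct), 0)
    expect_true(all(self_struct$target_similarity == 1))
})

test_that("biased edges follow the exponent transform", {
    e <- biasedBinEdges(20, 0.3)
    expect_length(e, 21)
    expect_equal(e[1], 0)
    expect_equal(e[21], 1)
    expect_true(all(diff(e) > 0))
    expect_equal(e[11], 0.5^0.3, tolerance = 1e-12)
    expect_equal(e[11], 0.8122, tolerance = 1e-4)
    ## exponent 1 gives uniform edges
    expect_equal(biasedBinEdges(10, 1), seq(0, 1, 0.1))
})

test_that("bin-uniform draws hit non-empty bins equiprobably", {
    withr::with_seed(31, {
        pairs <- data.frame(target_similarity = runif(20000))
        edges <- biasedBinEdges(20, 0.3)
        idx <- drawPairsByBin(pairs, edges, 20000)
        sims <- pairs$target_similarity[idx]
        occ <- table(findInterval(sims, edges, rightmost.closed = TRUE))
        p <- as.numeric(occ) / sum(occ)
        ## occupancy KL divergence from the equiprobable target is small
        kl <- sum(p * log(p / (1 / 20)))
        expect_lt(kl, 0.01)
    })
})

test_that("epoch sampling covers every training structure first", {
    sp <- pairFixtureSpectra()
    M <- pairFixtureM()
    pairs <- enumeratePairs(sp, M)
    keys <- sort(unique(c(pairs$inchikey14_a, pairs$inchikey14_b)))
    ## pairsPerEpoch equal to the key count: the epoch is the coverage pass
    cfg <- biasedSamplerConfig(pairsPerEpoch = length(keys), nEpochs = 3,
                               seed = 12)
    epochs <- sampleEpochs(pairs, cfg, mode = "biased20")
    for (ep in epochs) {
        expect_lte(nrow(ep), length(keys))
        expect_setequal(keys,
                        intersect(keys, c(ep$inchikey14_a,
                                          ep$inchikey14_b)))
    }
    ## a larger epoch still covers all keys and reaches the quota
    cfg2 <- biasedSamplerConfig(pairsPerEpoch = 15, nEpochs = 2, seed = 12)
    epochs2 <- sampleEpochs(pairs, cfg2, mode = "uniform10")
    for (ep in epochs2) {
        expect_identical(nrow(ep), 15L)
        expect_setequal(keys,
                        intersect(keys, c(ep$inchikey14_a,
                                          ep$inchikey14_b)))
    }
    ## seeded determinism
    epochs3 <- sampleEpochs(pairs, cfg2, mode = "uniform10")
    expect_identical(epochs2, epochs3)
})

test_that("epoch and pair tables round-trip through their containers", {
    sp <- pairFixtureSpectra()
    M <- pairFixtureM()
    pairs <- enumeratePairs(sp, M,
                            ttSim = c(KEYA = 0.5, KEYB = 0.7, KEYC = 0.9))
    dir <- withr::local_tempdir()

    ## epochs: keyed tables, refusal to overwrite, read-back equality
    cfg <- biasedSamplerConfig(pairsPerEpoch = 8, nEpochs = 2, seed = 3)
    epochs <- sampleEpochs(pairs, cfg)
    epath <- file.path(dir, "epochs")
    writeEpochs(epochs, epath)
    expect_identical(sort(list.files(epath)),
                     c("epoch_0000.parquet", "epoch_0001.parquet"))
    back <- readEpochs(epath)
    for (i in seq_along(epochs))
        expect_equal(back[[i]],
                     `rownames<-`(epochs[[i]], NULL))
    expect_error(writeEpochs(epochs, epath), class = "exists_error")
    expect_error(writeEpochs(list(), file.path(dir, "none")),
                 class = "empty_input")

    ## test pairs parquet keeps the full schema
    ppath <- file.path(dir, "pairs.parquet")
    writeTestPairsParquet(pairs, ppath)
    back <- readTestPairsParquet(ppath)
    expect_identical(nrow(back), nrow(pairs))
    expect_equal(back$target_similarity, pairs$target_similarity)
    expect_equal(back$mean_tt_similarity, pairs$mean_tt_similarity)
    expect_error(writeTestPairsParquet(pairs, ppath),
                 class = "exists_error")
})
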