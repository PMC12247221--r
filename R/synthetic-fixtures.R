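## Synthetic benchmark fixtures: families of related 2-D structures whose
## simulated spectra share peaks in proportion to shared substructure, with
## realistic metadata missingness. The fixture's contract is statistical
## (similarity correlation, metadata coverage), not chemical fidelity:
## fragment m/z values are hashed substructure features, not bond
## cleavages.

## Scaffold cores (R marks the substitution site) and the substituent pool.
## One family = one core decorated with distinct substituents, so
## within-family Tanimoto is high and between-family Tanimoto low.
.FIXTURE_CORES <- c(
    "c1ccc(R)cc1",            # benzene
    "c1ccnc(R)c1",            # pyridine
    "c1ccc2cc(R)ccc2c1",      # naphthalene
    "c1ccc2c(c1)cc(R)[nH]2",  # indole
    "c1ccc2nc(R)ccc2c1",      # quinoline
    "c1coc(R)c1",             # furan
    "c1csc(R)c1",             # thiophene
    "C1CCC(R)CC1",            # cyclohexane
    "C1CCN(R)CC1",            # piperidine (N-substituted)
    "c1cnc(R)nc1",            # pyrimidine
    "c1cc(R)n(C)c1",          # N-methylpyrrole
    "CCCCCCCCR",              # octyl chain
    "CC(C)CC(R)C(C)C",        # branched alkane
    "c1ccc(-c2ccc(R)cc2)cc1", # biphenyl
    "C1CCOC(R)C1")            # tetrahydropyran

.FIXTURE_SUBS <- c("O", "N", "Cl", "F", "Br", "C", "CC", "CCC", "CCCC",
                   "CCO", "CO", "OC", "C(=O)O", "C(=O)OC", "C(=O)N",
                   "C#N", "C(C)C", "CCN", "OC(=O)C", "S")

#' Fixture configuration
#'
#' @param nFamilies number of structure families (scaffolds), at most 15.
#' @param membersPerFamily structures per family, at most 20.
#' @param spectraPerStructure simulated spectra per structure.
#' @param ceMissingFraction probability that a spectrum lacks collision
#'   energy (default 0.7072, the missingness level typical of public
#'   libraries).
#' @param instrumentProfiles list of named lists with fields
#'   \code{ionization_method}, \code{mass_analyzer}, \code{manufacturer},
#'   \code{dissociation_method}.
#' @param adductPool canonical adducts drawn per spectrum.
#' @param noisePeakRate expected Poisson count of random noise peaks per
#'   spectrum.
#' @param intensityJitter lognormal sd of multiplicative intensity noise.
#' @param seed integer seed; the whole fixture is deterministic per seed.
#' @return a validated list of class \code{FixtureConfig}.
#' @export
fixtureConfig <- function(nFamilies = 15L, membersPerFamily = 20L,
                          spectraPerStructure = 5L,
                          ceMissingFraction = 0.7072,
                          instrumentProfiles = list(
                              list(ionization_method = "ESI",
                                   mass_analyzer = "Orbitrap",
                                   manufacturer = "Thermo",
                                   dissociation_method = "HCD"),
                              list(ionization_method = "ESI",
                                   mass_analyzer = "TOF",
                                   manufacturer = "Bruker",
                                   dissociation_method = "CID")),
                          adductPool = c("[M+H]+", "[M+Na]+"),
                          noisePeakRate = 3, intensityJitter = 0.1,
                          seed = 42L) {
    stopifnot(nFamilies >= 1L, nFamilies <= length(.FIXTURE_CORES),
              membersPerFamily >= 1L,
              membersPerFamily <= length(.FIXTURE_SUBS),
              spectraPerStructure >= 1L,
              ceMissingFraction >= 0, ceMissingFraction <= 1,
              noisePeakRate >= 0, intensityJitter >= 0)
    structure(list(nFamilies = as.integer(nFamilies),
                   membersPerFamily = as.integer(membersPerFamily),
                   spectraPerStructure = as.integer(spectraPerStructure),
                   ceMissingFraction = ceMissingFraction,
                   instrumentProfiles = instrumentProfiles,
                   adductPool = adductPool,
                   noisePeakRate = noisePeakRate,
                   intensityJitter = intensityJitter,
                   seed = as.integer(seed)),
              class = "FixtureConfig")
}

#' Generate the fixture's structure families
#'
#' Builds structures from the hardcoded scaffold cores and substituent
#' pool, standardizes them, and drops inchikey14 duplicates (none arise
#' from the shipped pools). Deterministic per seed.
#'
#' @param cfg a [fixtureConfig()].
#' @return structure table (see [standardizeStructures()]) with an extra
#'   \code{family} column.
#' @export
generateStructures <- function(cfg = fixtureConfig()) {
    smiles <- character(0); family <- integer(0)
    .withSeed(cfg$seed, {
        for (f in seq_len(cfg$nFamilies)) {
            subs <- .sampleVec(.FIXTURE_SUBS, cfg$membersPerFamily)
            smiles <- c(smiles,
                        vapply(subs, function(s)
                            gsub("R", s, .FIXTURE_CORES[f], fixed = TRUE),
                            character(1)))
            family <- c(family, rep(f, length(subs)))
        }
    })
    st <- standardizeStructures(unname(smiles))
    st$family <- family
    dup <- duplicated(st$inchikey14)
    if (any(dup)) {
        .msg("dropping %d duplicate fixture structures", sum(dup))
        st <- st[!dup, , drop = FALSE]
    }
    rownames(st) <- NULL
    st
}

## Deterministic peak template of a structure: each selected fingerprint
## bit maps to a fixed global m/z and base intensity, so structures with
## shared substructure share fragment peaks.
.peakTemplate <- function(onBits, maxPeaks = 30L) {
    b <- onBits - 1L  # zero-based
    sel_key <- (b * 2654435761) %% 2147483647
    b <- b[order(sel_key)][seq_len(min(maxPeaks, length(b)))]
    mz <- 50 + ((b * 7919) %% 94000) / 100
    int <- ((b * 48271) %% 900) / 1000 + 0.1
    cbind(mz = mz, intensity = int)
}

#' Simulate one spectrum of a structure
#'
#' Fragment peaks derive deterministically from the structure's
#' fingerprint bits (shared substructure implies shared peaks); Poisson
#' noise peaks and lognormal intensity jitter are added on top, and the
#' precursor m/z is the monoisotopic mass under the chosen adduct. Uses
#' the current RNG state (callers seed once for a whole fixture).
#'
#' @param monoisotopicMass neutral monoisotopic mass (Da).
#' @param onBits integer positions (1-based) of the structure's
#'   fingerprint on-bits.
#' @param adduct canonical adduct.
#' @param cfg a [fixtureConfig()].
#' @param adducts adduct table from [adductMap()].
#' @return list with \code{peaks} matrix and \code{precursor_mz}.
#' @export
simulateSpectrum <- function(monoisotopicMass, onBits, adduct,
                             cfg = fixtureConfig(),
                             adducts = adductMap()) {
    pk <- .peakTemplate(onBits)
    if (cfg$intensityJitter > 0)
        pk[, 2L] <- pk[, 2L] * rlnorm(nrow(pk), 0, cfg$intensityJitter)
    n_noise <- if (cfg$noisePeakRate > 0) rpois(1L, cfg$noisePeakRate)
               else 0L
    if (n_noise > 0L)
        pk <- rbind(pk, cbind(mz = runif(n_noise, 50, 990),
                              intensity = runif(n_noise, 0.01, 0.3)))
    list(peaks = .tidyPeaks(pk),
         precursor_mz = theoreticalMz(monoisotopicMass, adduct, adducts))
}

#' Simulate spectra for a structure table
#'
#' Draws \code{spectraPerStructure} spectra per structure with metadata
#' (adduct, instrument profile, collision energy with realistic
#' missingness) and simulated peaks; fully deterministic per seed.
#'
#' @param structures structure table from [generateStructures()].
#' @param fp [Fingerprints-class] of the structures.
#' @param cfg a [fixtureConfig()].
#' @param adducts adduct table.
#' @return an [MsmsSpectra-class].
#' @export
generateSpectra <- function(structures, fp, cfg = fixtureConfig(),
                            adducts = adductMap()) {
    bits <- fingerprintBits(fp)
    peaks <- list(); meta <- list()
    .withSeed(cfg$seed + 1L, {
        for (s in seq_len(nrow(structures))) {
            key <- structures$inchikey14[s]
            on_bits <- which(bits[key, ])
            for (r in seq_len(cfg$spectraPerStructure)) {
                adduct <- sample(cfg$adductPool, 1L)
                prof <- cfg$instrumentProfiles[[
                    sample.int(length(cfg$instrumentProfiles), 1L)]]
                ce <- if (runif(1L) < cfg$ceMissingFraction) NA_real_
                      else sample(c(10, 20, 30, 40), 1L)
                sim <- simulateSpectrum(structures$monoisotopic_mass[s],
                                        on_bits, adduct, cfg, adducts)
                peaks[[length(peaks) + 1L]] <- sim$peaks
                meta[[length(meta) + 1L]] <- data.frame(
                    spectrum_id = sprintf("SYN%05d", length(peaks)),
                    precursor_mz = sim$precursor_mz,
                    charge = 1L, adduct = adduct,
                    collision_energy = ce,
                    ionization_method = prof$ionization_method,
                    mass_analyzer = prof$mass_analyzer,
                    dissociation_method = prof$dissociation_method,
                    manufacturer = prof$manufacturer,
                    ion_mode = "positive",
                    source_library = "SYNTH-LIB",
                    compound_name = sprintf("synthetic compound %d", s),
                    structure_ref = key,
                    stringsAsFactors = FALSE)
            }
        }
    })
    MsmsSpectra(peaks, do.call(rbind, meta))
}

#' Generate the on-disk benchmark fixture
#'
#' Produces a complete fixture exercising harmonize - select - split -
#' pairs - score - evaluate: spectra MGF, metadata CSV and structures
#' CSV, with known counts of planted defects (precursor ppm error, sparse
#' fragmentation, excluded source library, over-limit precursor mass,
#' missing structure annotation, negative ion mode), each planted in a
#' distinct otherwise-clean spectrum.
#'
#' @param cfg a [fixtureConfig()].
#' @param dir output directory (created if needed).
#' @param planted named integer vector of defect counts; names among
#'   \code{bad_ppm}, \code{sparse}, \code{excluded_library},
#'   \code{heavy_precursor}, \code{missing_structure},
#'   \code{negative_mode}.
#' @return list with \code{spectra} ([MsmsSpectra-class]),
#'   \code{structures}, \code{fingerprints}, \code{planted},
#'   \code{excludedLibrary} (the library name used for the planted
#'   exclusion defect) and \code{paths}.
#' @export
generateBenchmarkFixture <- function(cfg = fixtureConfig(), dir = NULL,
                                     planted = c(bad_ppm = 3L, sparse = 3L,
                                                 excluded_library = 3L,
                                                 heavy_precursor = 3L,
                                                 missing_structure = 3L,
                                                 negative_mode = 3L)) {
    st <- generateStructures(cfg)
    fp <- fingerprintStructures(st)
    sp <- generateSpectra(st, fp, cfg)
    m <- spectraData(sp)
    p <- peaksData(sp)
    stopifnot(sum(planted) <= length(sp))
    excl_lib <- "GNPS-USER-CONTRIB"

    ## plant each defect into its own block of spectra
    idx <- 0L
    take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
    for (defect in names(planted)) {
        rows <- take(planted[[defect]])
        switch(defect,
            bad_ppm = { m$precursor_mz[rows] <-
                m$precursor_mz[rows] * (1 + 100e-6) },
            sparse = { for (r in rows)
                p[[r]] <- p[[r]][seq_len(min(3L, nrow(p[[r]]))), ,
                                 drop = FALSE] },
            excluded_library = { m$source_library[rows] <- excl_lib },
            heavy_precursor = { m$precursor_mz[rows] <- 1600 },
            missing_structure = { m$structure_ref[rows] <- NA_character_ },
            negative_mode = { m$ion_mode[rows] <- "negative" })
    }
    sp <- MsmsSpectra(p, m)

    paths <- NULL
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        paths <- list(mgf = file.path(dir, "spectra.mgf"),
                      meta = file.path(dir, "metadata.csv"),
                      structures = file.path(dir, "structures.csv"))
        writeMgf(sp, paths$mgf)
        writeSpectraMeta(sp, paths$meta)
        writeStructureTable(st, paths$structures)
    }
    list(spectra = sp, structures = st, fingerprints = fp,
         planted = planted, excludedLibrary = excl_lib, paths = paths)
}
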