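## 2-D structure standardization, identity, and Tanimoto similarity.
##
## Standardization mirrors common spectral-library cleaning practice:
## largest covalently bonded fragment (salt stripping), charge
## neutralization, stereochemistry removal, and tautomer canonicalization.
## Chemistry goes through OpenBabel via ChemmineOB/ChemmineR; tautomers are
## collapsed by an InChI round-trip (InChI's mobile-hydrogen normalization
## assigns one representation to a tautomer family, and converting that
## InChI back to SMILES yields one canonical member deterministically).

## --------------------------- OpenBabel plumbing ---------------------------

## Cached lookups of ChemmineOB's low-level SWIG bindings: the exported
## convertFormat() forwards only generic options and aborts a multi-molecule
## stream at the first parse error, so conversions are run per molecule here.
.obEnv <- new.env(parent = emptyenv())

.obFun <- function(name) {
    if (is.null(.obEnv[[name]]))
        .obEnv[[name]] <- utils::getFromNamespace(name, "ChemmineOB")
    .obEnv[[name]]
}

## Convert one molecule between text formats. Returns NA_character_ when
## OpenBabel cannot parse/convert the input.
.obConvert <- function(src, from, to, genopts = character(),
                       outopts = character()) {
    conv <- .obFun("OBConversion")(.obFun("istreamFromString")(src),
                                   out <- .obFun("ostreamToString")())
    .obFun("OBConversion_SetInAndOutFormats")(conv, from, to)
    for (g in genopts)
        .obFun("OBConversion_AddOption")(conv, g, "GENOPTIONS", "")
    for (o in outopts)
        .obFun("OBConversion_AddOption")(conv, o, "OUTOPTIONS", "")
    n <- .obFun("OBConversion_Convert")(conv)
    txt <- .obFun("stringFromOstream")(out)
    if (n < 1L || !nzchar(trimws(txt))) return(NA_character_)
    ## strip trailing title/tab/newline; first whitespace-delimited token
    strsplit(trimws(sub("\t.*$", "", txt)), "[ \t\r\n]+")[[1L]][1L]
}

.canonicalSmiles <- function(smi, genopts = character())
    .obConvert(smi, "SMI", "CAN", genopts = genopts, outopts = "i")

## Net formal charge read off bracket atoms of a SMILES string.
.netCharge <- function(smi) {
    brackets <- regmatches(smi, gregexpr("\\[[^][]*\\]", smi))[[1L]]
    if (!length(brackets)) return(0L)
    chg <- 0L
    for (b in brackets) {
        m <- regmatches(b, gregexpr("[+-][0-9]*", b))[[1L]]
        for (tok in m) {
            sgn <- if (startsWith(tok, "+")) 1L else -1L
            num <- substring(tok, 2L)
            chg <- chg + sgn * if (nzchar(num)) as.integer(num) else 1L
        }
    }
    chg
}

## Heavy-atom count of a parseable SMILES (hydrogens are implicit in
## OpenBabel's molecule object, so the atom count is the heavy-atom count).
.heavyAtoms <- function(smi) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                    error = function(e) NULL)
    if (is.null(sdf) || length(sdf) < 1L) return(NA_integer_)
    ab <- ChemmineR::atomblock(sdf[[1L]])
    sum(!grepl("^H_", rownames(ab)))
}

## --------------------------- standardization ------------------------------

#' Standardize 2-D structures
#'
#' Applies, in order: largest covalently-bonded-fragment selection (salt
#' removal; ties broken by heavy-atom count, then lexicographically smaller
#' canonical SMILES), charge neutralization, stereochemistry removal, and
#' tautomer canonicalization (InChI round-trip). Molecules that cannot be
#' neutralized (e.g. quaternary ammonium) keep their charge and are flagged
#' via \code{formal_charge != 0}.
#'
#' @param smiles character vector of raw SMILES.
#' @param ids optional identifiers used as rownames of the result.
#' @return data.frame with columns \code{raw_smiles},
#'   \code{canonical_smiles}, \code{inchikey} (27 characters),
#'   \code{inchikey14} (first block), \code{monoisotopic_mass} (Da) and
#'   \code{formal_charge}.
#' @examples
#' standardizeStructures("CC(=O)[O-].[Na+]")$canonical_smiles
#' @export
standardizeStructures <- function(smiles, ids = NULL) {
    if (is.null(ids)) ids <- names(smiles)
    res <- lapply(smiles, .standardizeOne)
    out <- do.call(rbind, res)
    out$raw_smiles <- smiles
    out <- out[c("raw_smiles", "canonical_smiles", "inchikey", "inchikey14",
                 "monoisotopic_mass", "formal_charge")]
    rownames(out) <- ids
    out
}

.standardizeOne <- function(smi) {
    if (is.na(smi) || !nzchar(trimws(smi)))
        .stopf("parse_error", "unparseable SMILES: %s", deparse(smi))
    smi <- trimws(smi)

    ## 1. largest covalently bonded fragment ('.' never occurs inside
    ##    brackets, so a textual split is exact)
    frags <- strsplit(smi, ".", fixed = TRUE)[[1L]]
    frags <- frags[nzchar(frags)]
    cans <- vapply(frags, .canonicalSmiles, character(1))
    if (anyNA(cans))
        .stopf("parse_error", "unparseable SMILES: %s", smi)
    if (length(frags) > 1L) {
        heavy <- vapply(cans, .heavyAtoms, integer(1))
        ord <- order(-heavy, cans)
        frag <- cans[ord[1L]]
    } else {
        frag <- cans[1L]
    }

    ## 2. neutralize; 3. strip stereochemistry
    neutral <- .canonicalSmiles(frag, genopts = "neutralize")
    if (is.na(neutral)) neutral <- frag

    ## 4. tautomer canonicalization via InChI round-trip
    inchi <- .obConvert(neutral, "SMI", "INCHI")
    can <- if (!is.na(inchi)) .obConvert(inchi, "INCHI", "CAN",
                                         outopts = "i") else NA_character_
    if (is.na(can)) can <- neutral
    ## InChI reconstruction can drop canonicality; re-canonicalize
    can <- .canonicalSmiles(can)
    if (is.na(can))
        .stopf("parse_error", "standardization failed for SMILES: %s", smi)

    ikey <- .obConvert(can, "SMI", "INCHIKEY")
    if (is.na(ikey) || nchar(ikey) != 27L)
        .stopf("parse_error", "InChIKey generation failed for SMILES: %s",
               smi)
    mono <- .monoMass(can)
    data.frame(canonical_smiles = can, inchikey = ikey,
               inchikey14 = substr(ikey, 1L, 14L),
               monoisotopic_mass = mono,
               formal_charge = .netCharge(can),
               stringsAsFactors = FALSE)
}

.monoMass <- function(smi) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                    error = function(e) NULL)
    if (is.null(sdf) || length(sdf) < 1L) return(NA_real_)
    as.numeric(ChemmineR::exactMassOB(sdf))[1L]
}

## --------------------------- structure tables -----------------------------

#' Read / write structure tables
#'
#' Structure tables are CSV files with columns \code{spectrum_id},
#' \code{raw_smiles}, \code{canonical_smiles}, \code{inchikey},
#' \code{inchikey14} (and optionally \code{monoisotopic_mass},
#' \code{formal_charge}).
#'
#' @param path CSV file path.
#' @return \code{readStructureTable}: data.frame.
#' @export
readStructureTable <- function(path) {
    if (!file.exists(path)) .stopf("io_error", "no such file: %s", path)
    read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readStructureTable
#' @param structures data.frame as returned by [standardizeStructures()],
#'   optionally with a \code{spectrum_id} column.
#' @export
writeStructureTable <- function(structures, path) {
    write.csv(structures, path, row.names = FALSE)
    invisible(path)
}

## ------------------------------- Tanimoto ---------------------------------

#' Tanimoto similarity of two binary fingerprints
#'
#' \eqn{|a \wedge b| / |a \vee b|}. Undefined (an error) when both
#' fingerprints are all-zero.
#'
#' @param a,b logical vectors of equal length.
#' @return numeric scalar in \code{[0, 1]}.
#' @examples
#' a <- b <- logical(8); a[1:3] <- TRUE; b[2:4] <- TRUE
#' tanimoto(a, b)  # 2 / 4
#' @export
tanimoto <- function(a, b) {
    if (length(a) != length(b))
        .stopf("length_error", "fingerprints differ in length")
    u <- sum(a | b)
    if (u == 0)
        .stopf("undefined_similarity",
               "Tanimoto undefined for two all-zero fingerprints")
    sum(a & b) / u
}

#' All-pair Tanimoto similarity matrix
#'
#' Symmetric unit-diagonal matrix of Tanimoto similarities between the
#' fingerprints of a deduplicated structure set.
#'
#' @param fp a [Fingerprints-class] object (rownames are first-block
#'   InChIKeys; duplicates are an error).
#' @return numeric matrix with \code{dimnames} set to the structure ids.
#' @seealso [fingerprintStructures()]
#' @export
pairwiseSimilarityMatrix <- function(fp) {
    stopifnot(is(fp, "Fingerprints"))
    B <- fp@bits
    if (anyDuplicated(rownames(B)))
        .stopf("duplicate_structure",
               "duplicate inchikey14 entries in fingerprint set")
    storage.mode(B) <- "integer"
    common <- tcrossprod(B)
    n_on <- rowSums(B)
    uni <- outer(n_on, n_on, "+") - common
    M <- common / uni
    diag(M) <- 1
    dimnames(M) <- list(rownames(fp@bits), rownames(fp@bits))
    M
}
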