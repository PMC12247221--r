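## Reading/writing spectra (MGF, CSV metadata, combined JSON) and
## harmonizing acquisition metadata.
##
## MGF has no single standard; the dialect written here is: one
## BEGIN IONS/END IONS block per spectrum with KEY=VALUE headers
## TITLE (spectrum_id), PEPMASS, CHARGE, and nonstandard keys ADDUCT,
## COLLISION_ENERGY, IONMODE, followed by "mz intensity" peak lines.
## All remaining metadata travels in a companion CSV keyed by spectrum_id.

## ------------------------------- MGF --------------------------------------

#' Read an MGF file
#'
#' Parses BEGIN IONS/END IONS blocks. Blocks without a PEPMASS header are
#' skipped with a warning; a block left unterminated is an error naming the
#' block index.
#'
#' @param path MGF file.
#' @return an [MsmsSpectra-class] object (empty when the file has no blocks).
#' @seealso [writeMgf()], [readMsmsLibrary()]
#' @export
readMgf <- function(path) {
    if (!file.exists(path)) .stopf("io_error", "no such file: %s", path)
    lines <- readLines(path)
    starts <- which(lines == "BEGIN IONS")
    ends <- which(lines == "END IONS")
    if (length(starts) != length(ends) ||
        (length(starts) && any(ends < starts)))
        .stopf("mgf_error", "malformed MGF block %d in %s",
               length(ends) + 1L, path)
    peaks <- list(); meta <- list()
    for (b in seq_along(starts)) {
        body <- lines[seq(starts[b] + 1L, ends[b] - 1L)]
        body <- body[nzchar(trimws(body))]
        is_hdr <- grepl("=", body, fixed = TRUE) &
            !grepl("^[0-9.]", trimws(body))
        hdr <- body[is_hdr]
        keys <- toupper(sub("=.*$", "", hdr))
        vals <- sub("^[^=]*=", "", hdr)
        names(vals) <- keys
        if (!"PEPMASS" %in% keys) {
            warning(sprintf("MGF block %d: missing PEPMASS, skipped", b))
            next
        }
        pk_lines <- trimws(body[!is_hdr])
        pk <- if (length(pk_lines)) {
            fields <- strsplit(pk_lines, "[ \t]+")
            cbind(mz = as.numeric(vapply(fields, `[`, "", 1L)),
                  intensity = as.numeric(vapply(fields, `[`, "", 2L)))
        } else matrix(numeric(0), 0L, 2L,
                      dimnames = list(NULL, c("mz", "intensity")))
        charge <- if ("CHARGE" %in% keys)
            suppressWarnings(as.integer(sub("\\+$", "", vals["CHARGE"])))
            else NA_integer_
        ce <- if ("COLLISION_ENERGY" %in% keys)
            suppressWarnings(as.numeric(vals["COLLISION_ENERGY"]))
            else NA_real_
        meta[[length(meta) + 1L]] <- data.frame(
            spectrum_id = if ("TITLE" %in% keys) vals[["TITLE"]]
                          else sprintf("block_%04d", b),
            precursor_mz = as.numeric(
                strsplit(vals[["PEPMASS"]], "[ \t]+")[[1L]][1L]),
            charge = charge,
            adduct = if ("ADDUCT" %in% keys) vals[["ADDUCT"]]
                     else NA_character_,
            collision_energy = ce,
            ion_mode = if ("IONMODE" %in% keys) vals[["IONMODE"]]
                       else NA_character_,
            stringsAsFactors = FALSE)
        peaks[[length(peaks) + 1L]] <- pk
    }
    if (!length(meta))
        return(MsmsSpectra(list(), data.frame(
            spectrum_id = character(0), precursor_mz = numeric(0))))
    MsmsSpectra(peaks, do.call(rbind, meta))
}

#' Write spectra to MGF
#'
#' Writes the dialect described in [readMgf()]. Peak values are printed with
#' six decimal places, so write-read round trips preserve peaks to 1e-6 and
#' a second write is byte-identical to the first.
#'
#' @param spectra an [MsmsSpectra-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMgf <- function(spectra, path) {
    m <- spectraData(spectra)
    p <- peaksData(spectra)
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(length(spectra))) {
        lines <- c("BEGIN IONS",
                   paste0("TITLE=", m$spectrum_id[i]),
                   paste0("PEPMASS=", sprintf("%.6f", m$precursor_mz[i])))
        if (!is.na(m$charge[i]))
            lines <- c(lines, sprintf("CHARGE=%d+", m$charge[i]))
        if (!is.na(m$adduct[i]))
            lines <- c(lines, paste0("ADDUCT=", m$adduct[i]))
        if (!is.na(m$collision_energy[i]))
            lines <- c(lines, sprintf("COLLISION_ENERGY=%.6g",
                                      m$collision_energy[i]))
        if (!is.na(m$ion_mode[i]))
            lines <- c(lines, paste0("IONMODE=", m$ion_mode[i]))
        pk <- p[[i]]
        if (nrow(pk))
            lines <- c(lines, sprintf("%.6f %.6f", pk[, 1L], pk[, 2L]))
        writeLines(c(lines, "END IONS"), con)
    }
    invisible(path)
}

## ----------------------- metadata CSV / JSON ------------------------------

#' Read an MGF plus its companion metadata CSV
#'
#' Joins metadata CSV columns (keyed by \code{spectrum_id}) onto the spectra
#' read from the MGF; CSV values take precedence where both carry a field.
#'
#' @param mgfPath MGF file.
#' @param metaPath metadata CSV with a \code{spectrum_id} column.
#' @return an [MsmsSpectra-class].
#' @export
readMsmsLibrary <- function(mgfPath, metaPath) {
    sp <- readMgf(mgfPath)
    meta <- read.csv(metaPath, stringsAsFactors = FALSE)
    if (!"spectrum_id" %in% names(meta))
        .stopf("io_error", "metadata CSV lacks spectrum_id column")
    m <- spectraData(sp)
    idx <- match(m$spectrum_id, meta$spectrum_id)
    for (col in setdiff(names(meta), "spectrum_id")) {
        vals <- meta[[col]][idx]
        if (col %in% names(m)) {
            take <- !.isMissing(vals)
            m[[col]][take] <- vals[take]
        } else m[[col]] <- vals
    }
    MsmsSpectra(peaksData(sp), m)
}

#' Write the per-spectrum metadata table as CSV
#' @param spectra an [MsmsSpectra-class]
#' @param path output CSV
#' @return the path, invisibly.
#' @export
writeSpectraMeta <- function(spectra, path) {
    write.csv(spectraData(spectra), path, row.names = FALSE)
    invisible(path)
}

#' Read / write combined JSON spectra
#'
#' One JSON record per spectrum carrying all metadata fields plus \code{mz}
#' and \code{intensity} arrays.
#'
#' @param spectra an [MsmsSpectra-class]
#' @param path JSON file
#' @return \code{readSpectraJson}: an [MsmsSpectra-class];
#'   \code{writeSpectraJson}: the path, invisibly.
#' @export
writeSpectraJson <- function(spectra, path) {
    m <- spectraData(spectra)
    p <- peaksData(spectra)
    recs <- lapply(seq_len(length(spectra)), function(i) {
        rec <- as.list(m[i, , drop = FALSE])
        rec$mz <- p[[i]][, 1L]
        rec$intensity <- p[[i]][, 2L]
        rec
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    invisible(path)
}

#' @rdname writeSpectraJson
#' @export
readSpectraJson <- function(path) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    null2na <- function(x) if (is.null(x)) NA else x
    meta <- do.call(rbind, lapply(recs, function(r) {
        flds <- r[setdiff(names(r), c("mz", "intensity"))]
        as.data.frame(lapply(flds, null2na), stringsAsFactors = FALSE)
    }))
    peaks <- lapply(recs, function(r)
        cbind(mz = as.numeric(unlist(r$mz)),
              intensity = as.numeric(unlist(r$intensity))))
    MsmsSpectra(peaks, meta)
}

## ----------------------- collision-energy parsing -------------------------

#' Collision-energy parsing rules
#'
#' Ordered, user-editable rule list (regular expressions with one numeric
#' capture group) applied to compound-name and instrument annotations. The
#' shipped rules capture explicit eV-style annotations only; normalized
#' collision energy (NCE, a percentage) is deliberately not converted.
#'
#' @param path optional CSV overriding the shipped rules (columns
#'   \code{pattern}, \code{field}, \code{note}).
#' @return data.frame of rules, in application order.
#' @export
collisionEnergyRules <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "collision_energy_rules.csv",
                            package = "SpecSimBench", mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
}

#' Parse collision energy from free-text annotations
#'
#' Applies the ordered rule list to the compound name and the instrument
#' field; the first matching rule wins. Returns the value in eV, or
#' \code{NA} when no rule matches or the matched token is not numeric.
#'
#' @param compoundName,instrumentField character vectors (recycled).
#' @param rules rule table from [collisionEnergyRules()].
#' @return numeric vector of collision energies (eV), \code{NA} when absent.
#' @examples
#' parseCollisionEnergy("Foo CollisionEnergy:35", "")
#' @export
parseCollisionEnergy <- function(compoundName, instrumentField = "",
                                 rules = collisionEnergyRules()) {
    n <- max(length(compoundName), length(instrumentField))
    compoundName <- rep_len(as.character(compoundName), n)
    instrumentField <- rep_len(as.character(instrumentField), n)
    vapply(seq_len(n), function(i)
        .parseCeOne(compoundName[i], instrumentField[i], rules), numeric(1))
}

.parseCeOne <- function(nm, instr, rules) {
    for (r in seq_len(nrow(rules))) {
        texts <- switch(rules$field[r],
                        name = nm, instrument = instr, c(nm, instr))
        for (txt in texts) {
            if (is.na(txt) || !nzchar(txt)) next
            m <- regmatches(txt, regexec(rules$pattern[r], txt,
                                         perl = TRUE, ignore.case = TRUE))[[1L]]
            if (length(m) >= 2L) {
                val <- suppressWarnings(as.numeric(m[2L]))
                if (is.na(val)) {
                    warning(sprintf(
                        "collision-energy token '%s' is not numeric", m[2L]))
                    return(NA_real_)
                }
                return(val)
            }
        }
    }
    NA_real_
}

## --------------------------- adduct harmonization -------------------------

#' Curated adduct map
#'
#' Loads the curated positive-mode adduct list: canonical adduct notation,
#' total mass offset (Da) added to the neutral monoisotopic mass, absolute
#' charge, and known raw spelling variants.
#'
#' @param path optional CSV overriding the shipped list (columns
#'   \code{canonical}, \code{mass_offset}, \code{charge}, \code{variants};
#'   variants separated by \code{|}).
#' @return data.frame with one row per canonical adduct.
#' @export
adductMap <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "adducts.csv",
                            package = "SpecSimBench", mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
}

#' Harmonize adduct annotations
#'
#' Maps raw adduct spellings (whitespace, bracket and charge-notation
#' variants) to the curated canonical form; unknown spellings map to
#' \code{NA}. Idempotent on canonical forms.
#'
#' @param raw character vector of raw adduct annotations.
#' @param map adduct table from [adductMap()].
#' @return character vector of canonical adducts or \code{NA}.
#' @examples
#' harmonizeAdduct(c("M+H", "[M+H]+", "M+foo"))
#' @export
harmonizeAdduct <- function(raw, map = adductMap()) {
    norm <- gsub("[[:space:]]", "", as.character(raw))
    ## "1+" -> "+" style charge, e.g. [M+H]1+ -> [M+H]+
    norm <- sub("\\]1\\+$", "]+", norm)
    core <- function(x) sub("\\+*$", "", gsub("\\[|\\]", "", x))
    canon_core <- core(map$canonical)
    out <- rep(NA_character_, length(norm))
    for (i in seq_along(norm)) {
        if (is.na(norm[i]) || !nzchar(norm[i])) next
        hit <- which(map$canonical == norm[i])
        if (!length(hit)) {
            variants <- strsplit(map$variants, "|", fixed = TRUE)
            hit <- which(vapply(variants, function(v) norm[i] %in% v,
                                logical(1)))
        }
        if (!length(hit)) hit <- which(canon_core == core(norm[i]))
        if (length(hit)) out[i] <- map$canonical[hit[1L]]
    }
    out
}

#' Theoretical precursor m/z under an adduct
#'
#' \eqn{(M + \mathrm{offset}) / |z|} for neutral monoisotopic mass M.
#'
#' @param monoisotopicMass neutral monoisotopic mass (Da).
#' @param adduct canonical adduct string.
#' @param map adduct table from [adductMap()].
#' @return theoretical precursor m/z (Th).
#' @export
theoreticalMz <- function(monoisotopicMass, adduct, map = adductMap()) {
    i <- match(adduct, map$canonical)
    (monoisotopicMass + map$mass_offset[i]) / abs(map$charge[i])
}

## ------------------------ instrument propagation --------------------------

#' Instrument annotation rules
#'
#' Case-insensitive word-boundary patterns mapping free-text instrument
#' annotations to harmonized ionization method, mass analyzer, dissociation
#' method and manufacturer values.
#'
#' @param path optional CSV overriding the shipped rules (columns
#'   \code{pattern}, \code{field}, \code{value}).
#' @return data.frame of rules.
#' @export
instrumentRules <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "instrument_rules.csv",
                            package = "SpecSimBench", mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
}

#' Propagate instrument metadata from a free-text annotation
#'
#' Applies the substring rule table to derive the four harmonized
#' instrument fields. Explicit provenance values (the \code{explicit}
#' argument) override derived ones. If two rules assign conflicting values
#' to the same field, all four derived fields are set to missing with a
#' warning.
#'
#' @param annotation free-text instrument annotation (single string).
#' @param explicit named list of trusted values
#'   (\code{ionization_method}, \code{mass_analyzer},
#'   \code{dissociation_method}, \code{manufacturer}) that win over
#'   derived ones.
#' @param rules rule table from [instrumentRules()].
#' @return named character vector with entries \code{ionization_method},
#'   \code{mass_analyzer}, \code{dissociation_method},
#'   \code{manufacturer} (\code{NA} when unknown).
#' @examples
#' propagateInstrumentMetadata("CID, ESI, Q-Exactive")
#' @export
propagateInstrumentMetadata <- function(annotation, explicit = list(),
                                        rules = instrumentRules()) {
    fields <- c("ionization_method", "mass_analyzer",
                "dissociation_method", "manufacturer")
    out <- setNames(rep(NA_character_, 4L), fields)
    if (!is.na(annotation) && nzchar(annotation)) {
        conflict <- FALSE
        for (r in seq_len(nrow(rules))) {
            pat <- paste0("\\b", rules$pattern[r], "\\b")
            if (grepl(pat, annotation, ignore.case = TRUE, perl = TRUE)) {
                f <- rules$field[r]; v <- rules$value[r]
                if (!is.na(out[f]) && out[f] != v) conflict <- TRUE
                else out[f] <- v
            }
        }
        if (conflict) {
            warning(sprintf(
                "conflicting instrument annotations in '%s'; fields dropped",
                annotation))
            out[] <- NA_character_
        }
    }
    for (f in intersect(names(explicit), fields))
        if (!.isMissing(explicit[[f]])) out[f] <- explicit[[f]]
    out
}

## ----------------------------- harmonization ------------------------------

#' Harmonize an MsmsSpectra collection
#'
#' Applies adduct harmonization, collision-energy parsing (from compound
#' name and instrument annotation, filling only missing values) and
#' instrument-metadata propagation across a spectra collection.
#'
#' @param spectra an [MsmsSpectra-class]; the metadata may carry
#'   \code{instrument} (free-text annotation) and \code{compound_name}
#'   columns used for derivation.
#' @param adducts,ceRules,instRules rule tables (defaults: shipped files).
#' @return the harmonized [MsmsSpectra-class].
#' @export
harmonizeSpectra <- function(spectra, adducts = adductMap(),
                             ceRules = collisionEnergyRules(),
                             instRules = instrumentRules()) {
    m <- spectraData(spectra)
    m$adduct <- harmonizeAdduct(m$adduct, adducts)
    instr <- if (is.null(m$instrument)) rep("", nrow(m)) else m$instrument
    cn <- if (is.null(m$compound_name)) rep("", nrow(m)) else m$compound_name
    need_ce <- is.na(m$collision_energy)
    if (any(need_ce))
        m$collision_energy[need_ce] <-
            parseCollisionEnergy(cn[need_ce], instr[need_ce], ceRules)
    for (i in seq_len(nrow(m))) {
        explicit <- list(ionization_method = m$ionization_method[i],
                         mass_analyzer = m$mass_analyzer[i],
                         dissociation_method = m$dissociation_method[i],
                         manufacturer = m$manufacturer[i])
        derived <- propagateInstrumentMetadata(
            if (is.na(instr[i])) "" else instr[i], explicit, instRules)
        m$ionization_method[i] <- derived["ionization_method"]
        m$mass_analyzer[i] <- derived["mass_analyzer"]
        m$dissociation_method[i] <- derived["dissociation_method"]
        m$manufacturer[i] <- derived["manufacturer"]
    }
    MsmsSpectra(peaksData(spectra), m)
}
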