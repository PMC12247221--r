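## Path-based (Daylight-style) hashed binary fingerprints.
##
## Linear paths of 1..maxPathLength bonds are enumerated on the heavy-atom
## graph of the canonical SMILES; each path's canonical string (the
## lexicographic minimum of its forward and reverse readings of element
## symbols and bond orders) is hashed and sets bitsPerPath bit positions.
## Hand-written because the environment's chemistry toolkits offer no
## 2048-bit path fingerprint (OpenBabel's FP2 is fixed at 1021 bits).

#' Path fingerprints for standardized structures
#'
#' Computes deterministic fixed-length binary path fingerprints from
#' canonical SMILES and returns them keyed by first-block InChIKey.
#' Structures sharing an \code{inchikey14} are collapsed to one fingerprint
#' (identical canonical structure implies identical bits).
#'
#' @param structures data.frame from [standardizeStructures()] with columns
#'   \code{canonical_smiles} and \code{inchikey14}.
#' @param nbits fingerprint length in bits (default 2048).
#' @param maxPathLength maximum path length in bonds (default 7).
#' @param bitsPerPath bit positions set per distinct path (default 2).
#' @return a [Fingerprints-class] object.
#' @examples
#' st <- standardizeStructures(c("CCO", "c1ccccc1O"))
#' fp <- fingerprintStructures(st)
#' dim(fingerprintBits(fp))
#' @export
fingerprintStructures <- function(structures, nbits = 2048L,
                                  maxPathLength = 7L, bitsPerPath = 2L) {
    stopifnot(all(c("canonical_smiles", "inchikey14") %in% names(structures)))
    dedup <- !duplicated(structures$inchikey14)
    smi <- structures$canonical_smiles[dedup]
    keys <- structures$inchikey14[dedup]
    bits <- matrix(FALSE, nrow = length(smi), ncol = nbits,
                   dimnames = list(keys, NULL))
    for (i in seq_along(smi)) {
        on <- .smilesPathBits(smi[i], nbits, maxPathLength, bitsPerPath)
        bits[i, on + 1L] <- TRUE
    }
    new("Fingerprints", bits = bits,
        params = list(nbits = nbits, maxPathLength = maxPathLength,
                      bitsPerPath = bitsPerPath, kind = "linear-path"))
}

#' Fingerprint bit matrix
#' @param fp a [Fingerprints-class]
#' @return logical matrix (structures x bits) with inchikey14 rownames.
#' @export
fingerprintBits <- function(fp) fp@bits

## zero-based on-bit positions for one molecule
.smilesPathBits <- function(smi, nbits, maxlen, bits_per_path) {
    g <- .molGraph(smi)
    paths <- .enumeratePaths(g$atoms, g$bonds, maxlen)
    if (!length(paths)) paths <- g$atoms  # bond-less molecule: lone atoms
    on <- integer(0)
    for (p in paths) {
        h <- .hashString(p)
        for (k in seq_len(bits_per_path)) {
            on <- c(on, h %% nbits)
            h <- (h * 33 + 113) %% 2147483647
        }
    }
    sort(unique(on))
}

## heavy-atom graph (element symbols + bond order table) of a SMILES
.molGraph <- function(smi) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                    error = function(e) NULL)
    if (is.null(sdf) || length(sdf) < 1L)
        .stopf("parse_error", "unparseable SMILES: %s", smi)
    ab <- ChemmineR::atomblock(sdf[[1L]])
    bb <- ChemmineR::bondblock(sdf[[1L]])
    el <- sub("_.*$", "", rownames(ab))
    keep <- el != "H"
    idx <- cumsum(keep)
    bonds <- matrix(0L, 0L, 3L)
    if (length(bb) && nrow(bb)) {
        b <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]),
                   as.integer(bb[, 3L]))
        ok <- keep[b[, 1L]] & keep[b[, 2L]]
        b <- b[ok, , drop = FALSE]
        if (nrow(b))
            bonds <- cbind(idx[b[, 1L]], idx[b[, 2L]], b[, 3L])
    }
    list(atoms = el[keep], bonds = bonds)
}

## all distinct simple paths of 1..maxlen bonds, canonicalized
.enumeratePaths <- function(atoms, bonds, maxlen) {
    n <- length(atoms)
    if (n == 0L || nrow(bonds) == 0L) return(character(0))
    adj <- vector("list", n)
    for (k in seq_len(nrow(bonds))) {
        i <- bonds[k, 1L]; j <- bonds[k, 2L]; o <- bonds[k, 3L]
        adj[[i]] <- c(adj[[i]], list(c(j, o)))
        adj[[j]] <- c(adj[[j]], list(c(i, o)))
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    visited <- logical(n)
    dfs <- function(v, s_atoms, s_bonds) {
        if (length(s_bonds)) {
            fwd <- paste0(s_atoms, c(s_bonds, ""), collapse = "")
            bwd <- paste0(rev(s_atoms), c(rev(s_bonds), ""), collapse = "")
            assign(if (fwd <= bwd) fwd else bwd, TRUE, envir = seen)
        }
        if (length(s_bonds) >= maxlen) return(invisible(NULL))
        for (nb in adj[[v]]) {
            w <- nb[1L]
            if (!visited[w]) {
                visited[w] <<- TRUE
                dfs(w, c(s_atoms, atoms[w]),
                    c(s_bonds, as.character(nb[2L])))
                visited[w] <<- FALSE
            }
        }
        invisible(NULL)
    }
    for (v in seq_len(n)) {
        visited[v] <- TRUE
        dfs(v, atoms[v], character(0))
        visited[v] <- FALSE
    }
    ls(seen)
}
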