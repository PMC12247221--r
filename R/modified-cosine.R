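## Modified cosine similarity: the classical algorithmic baseline for
## MS/MS structural-analog comparison. Peaks of two spectra may match
## directly (|mz_a - mz_b| <= tol) or shifted by the precursor mass
## difference (|mz_a - (mz_b + delta)| <= tol, delta = prec_a - prec_b);
## among candidate matches a one-to-one assignment is chosen greedily by
## descending weight product, and the matched weight products are
## normalized by the two spectra's weight norms.

#' Modified cosine parameters
#'
#' @param fragmentTolerance peak matching tolerance (Th), inclusive.
#' @param mzPower exponent applied to peak m/z in the weights.
#' @param intensityPower exponent applied to base-peak-normalized peak
#'   intensities in the weights.
#' @return a list of class \code{ModifiedCosineParams}. Defaults follow
#'   common practice for analog search: tolerance 0.10, m/z power 0,
#'   intensity power 0.5.
#' @export
modifiedCosineParams <- function(fragmentTolerance = 0.10, mzPower = 0.0,
                                 intensityPower = 0.50) {
    stopifnot(fragmentTolerance > 0)
    structure(list(fragmentTolerance = fragmentTolerance,
                   mzPower = mzPower, intensityPower = intensityPower),
              class = "ModifiedCosineParams")
}

#' Modified cosine similarity of two spectra
#'
#' @param peaksA,peaksB two-column (\code{mz}, \code{intensity}) matrices
#'   with at least one peak each.
#' @param precursorA,precursorB precursor m/z values (Th); required, the
#'   shifted-match condition is undefined without them.
#' @param params a [modifiedCosineParams()].
#' @param assignment \code{"greedy"} (descending weight product, the
#'   behavior of reference implementations) or \code{"exact"} (optimal
#'   one-to-one assignment by branch and bound; intended for small
#'   spectra and oracle testing).
#' @return list with \code{score} in \code{[0, 1]} and \code{nMatched}
#'   (matched peak count).
#' @examples
#' pk <- cbind(mz = c(100, 150, 200), intensity = c(0.5, 1, 0.2))
#' modifiedCosine(pk, pk, 300, 300)$score  # 1
#' @export
modifiedCosine <- function(peaksA, peaksB, precursorA, precursorB,
                           params = modifiedCosineParams(),
                           assignment = c("greedy", "exact")) {
    assignment <- match.arg(assignment)
    if (is.na(precursorA) || is.na(precursorB))
        .stopf("missing_precursor",
               "precursor m/z required for the modified cosine shift")
    if (!nrow(peaksA) || !nrow(peaksB))
        .stopf("empty_spectrum", "modified cosine needs non-empty spectra")
    wA <- .cosWeights(peaksA, params)
    wB <- .cosWeights(peaksB, params)
    delta <- precursorA - precursorB
    tol <- params$fragmentTolerance

    ## candidate matches: direct OR precursor-shifted
    cand <- list()
    for (i in seq_len(nrow(peaksA))) {
        direct <- abs(peaksA[i, 1L] - peaksB[, 1L]) <= tol
        shifted <- abs(peaksA[i, 1L] - (peaksB[, 1L] + delta)) <= tol
        js <- which(direct | shifted)
        if (length(js))
            cand[[length(cand) + 1L]] <-
                cbind(i = i, j = js, p = wA[i] * wB[js])
    }
    if (!length(cand))
        return(list(score = 0, nMatched = 0L))
    cand <- do.call(rbind, cand)

    total <- switch(assignment,
                    greedy = .assignGreedy(cand),
                    exact = .assignExact(cand))
    list(score = min(1, total$sum / (sqrt(sum(wA^2)) * sqrt(sum(wB^2)))),
         nMatched = total$n)
}

.cosWeights <- function(pk, params) {
    rel <- pk[, 2L] / max(pk[, 2L])
    pk[, 1L]^params$mzPower * rel^params$intensityPower
}

## one-to-one assignment, greedy by descending product (deterministic
## tie-break on i then j)
.assignGreedy <- function(cand) {
    ord <- order(-cand[, "p"], cand[, "i"], cand[, "j"])
    used_i <- integer(0); used_j <- integer(0)
    s <- 0; n <- 0L
    for (r in ord) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (i %in% used_i || j %in% used_j) next
        used_i <- c(used_i, i); used_j <- c(used_j, j)
        s <- s + cand[r, "p"]; n <- n + 1L
    }
    list(sum = s, n = n)
}

## exact maximum-weight one-to-one assignment over the candidate list
## (branch and bound on the product-sorted list; for oracle use on small
## spectra)
.assignExact <- function(cand) {
    ord <- order(-cand[, "p"])
    cand <- cand[ord, , drop = FALSE]
    suffix <- rev(cumsum(rev(cand[, "p"])))
    best <- new.env(parent = emptyenv())
    best$sum <- 0; best$n <- 0L
    recurse <- function(r, used_i, used_j, acc, nacc) {
        if (acc > best$sum ||
            (acc == best$sum && nacc > best$n)) {
            best$sum <- acc; best$n <- nacc
        }
        if (r > nrow(cand)) return(invisible(NULL))
        if (acc + suffix[r] <= best$sum) return(invisible(NULL))  # bound
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (!(i %in% used_i) && !(j %in% used_j))
            recurse(r + 1L, c(used_i, i), c(used_j, j),
                    acc + cand[r, "p"], nacc + 1L)
        recurse(r + 1L, used_i, used_j, acc, nacc)
        invisible(NULL)
    }
    recurse(1L, integer(0), integer(0), 0, 0L)
    list(sum = best$sum, n = best$n)
}

#' Score a pair table with the modified cosine baseline
#'
#' Produces a prediction table (one row per pair) with the modified cosine
#' score as the predicted value, preserving the ground-truth target and
#' train-test similarity columns. Pairs referencing spectra absent from
#' the collection are skipped with a message.
#'
#' @param pairs pair table (see [enumeratePairs()]).
#' @param spectra an [MsmsSpectra-class] holding the referenced spectra.
#' @param params a [modifiedCosineParams()].
#' @return prediction table with columns \code{query_id},
#'   \code{candidate_id}, \code{predicted}, \code{true_similarity},
#'   \code{query_inchikey14}, \code{candidate_inchikey14},
#'   \code{mean_tt_similarity}.
#' @export
scorePairTable <- function(pairs, spectra,
                           params = modifiedCosineParams()) {
    ids <- spectrumIds(spectra)
    ok <- pairs$spectrum_id_a %in% ids & pairs$spectrum_id_b %in% ids
    if (any(!ok))
        .msg("skipping %d pairs with unloadable spectra", sum(!ok))
    pairs <- pairs[ok, , drop = FALSE]
    p <- peaksData(spectra)
    prec <- setNames(spectraData(spectra)$precursor_mz, ids)
    predicted <- vapply(seq_len(nrow(pairs)), function(r) {
        a <- pairs$spectrum_id_a[r]; b <- pairs$spectrum_id_b[r]
        modifiedCosine(p[[a]], p[[b]], prec[[a]], prec[[b]], params)$score
    }, numeric(1))
    data.frame(query_id = pairs$spectrum_id_a,
               candidate_id = pairs$spectrum_id_b,
               predicted = predicted,
               true_similarity = pairs$target_similarity,
               query_inchikey14 = pairs$inchikey14_a,
               candidate_inchikey14 = pairs$inchikey14_b,
               mean_tt_similarity = pairs$mean_tt_similarity,
               stringsAsFactors = FALSE)
}
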