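## Brute-force oracles, independent of the package implementations.

oracleTopCandidate <- function(table, k, exclude = FALSE) {
    if (exclude)
        table <- table[table$query_inchikey14 !=
                       table$candidate_inchikey14, ]
    mean(vapply(split(table, table$query_id), function(d) {
        d <- d[order(-d$predicted, d$candidate_id), ]
        max(d$true_similarity[seq_len(min(k, nrow(d)))])
    }, numeric(1)))
}

oracleTopRank <- function(table, k, exclude = FALSE) {
    if (exclude)
        table <- table[table$query_inchikey14 !=
                       table$candidate_inchikey14, ]
    mean(vapply(split(table, table$query_id), function(d) {
        struct_sim <- tapply(d$true_similarity, d$candidate_inchikey14,
                             max)
        uniq <- sort(unique(unname(struct_sim)), decreasing = TRUE)
        gt_rank <- match(struct_sim[d$candidate_inchikey14], uniq)
        ord <- order(-d$predicted, d$candidate_id)
        pred_rank <- integer(nrow(d))
        pred_rank[ord] <- seq_len(nrow(d))
        min(pred_rank[gt_rank <= k])
    }, numeric(1)))
}

## exhaustive best one-to-one matching over all candidate peak matches
oracleModifiedCosine <- function(pkA, pkB, precA, precB,
                                 params = modifiedCosineParams()) {
    w <- function(pk) (pk[, 2] / max(pk[, 2]))^params$intensityPower *
        pk[, 1]^params$mzPower
    wA <- w(pkA); wB <- w(pkB)
    delta <- precA - precB
    cand <- expand.grid(i = seq_len(nrow(pkA)), j = seq_len(nrow(pkB)))
    ok <- abs(pkA[cand$i, 1] - pkB[cand$j, 1]) <=
        params$fragmentTolerance |
        abs(pkA[cand$i, 1] - (pkB[cand$j, 1] + delta)) <=
            params$fragmentTolerance
    cand <- cand[ok, , drop = FALSE]
    best <- 0
    n <- nrow(cand)
    if (n > 0) {
        for (mask in seq_len(2^n) - 1L) {
            sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
            if (anyDuplicated(cand$i[sel]) || anyDuplicated(cand$j[sel]))
                next
            best <- max(best, sum(wA[cand$i[sel]] * wB[cand$j[sel]]))
        }
    }
    best / (sqrt(sum(wA^2)) * sqrt(sum(wB^2)))
}
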