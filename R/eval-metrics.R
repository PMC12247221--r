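## Retrieval and ranking evaluation: binned RMSE, Top Candidate Similarity
## with its theoretical maximum, Top-Rank with structure-level tie
## grouping, and train-test similarity stratification.
##
## A prediction table simulates database retrieval within the test set:
## one row per (query spectrum, candidate spectrum) with the model's
## predicted score and the ground-truth Tanimoto similarity of the two
## underlying structures. Metrics are pure functions of the table; the
## multi-seed aggregation helper combines tables from repeated runs.

.PT_COLS <- c("query_id", "candidate_id", "predicted", "true_similarity",
              "query_inchikey14", "candidate_inchikey14")

.checkPredictionTable <- function(table) {
    miss <- setdiff(.PT_COLS, names(table))
    if (length(miss))
        .stopf("schema_error", "prediction table lacks columns: %s",
               paste(miss, collapse = ", "))
    if (any(table$true_similarity < 0 | table$true_similarity > 1))
        .stopf("schema_error", "true_similarity outside [0, 1]")
    if (any(table$query_id == table$candidate_id))
        .stopf("schema_error", "self-pairs in prediction table")
    invisible(table)
}

#' Ranking configuration
#'
#' @param kValues positive increasing ranks at which metrics are reported.
#' @param excludeIdentical drop candidates sharing the query's planar
#'   structure (first-block InChIKey) before evaluation.
#' @return a list of class \code{RankingConfig}.
#' @export
rankingConfig <- function(kValues = c(1L, 3L, 10L),
                          excludeIdentical = FALSE) {
    stopifnot(all(kValues >= 1L), !is.unsorted(kValues, strictly = TRUE))
    structure(list(kValues = as.integer(kValues),
                   excludeIdentical = excludeIdentical),
              class = "RankingConfig")
}

## apply the identical-structure exclusion
.applyExclusion <- function(table, cfg) {
    if (isTRUE(cfg$excludeIdentical))
        table <- table[table$query_inchikey14 != table$candidate_inchikey14,
                       , drop = FALSE]
    table
}

## candidate ordering by predicted score (desc), ties broken by id
.predOrder <- function(d) order(-d$predicted, d$candidate_id)

## -------------------------------- RMSE ------------------------------------

#' Root mean square error
#' @param predicted,true numeric vectors of equal length.
#' @return numeric scalar.
#' @export
rmse <- function(predicted, true) {
    stopifnot(length(predicted) == length(true), length(true) > 0L)
    sqrt(mean((predicted - true)^2))
}

#' RMSE binned by ground-truth similarity
#'
#' Computes the RMSE between predicted scores and true Tanimoto
#' similarities within equal-width ground-truth bins (left-inclusive, top
#' bin includes 1.0). Empty bins are reported as \code{NA} and excluded
#' from bin averages.
#'
#' @param table prediction table (see package overview).
#' @param nBins number of uniform bins on \code{[0, 1]} (default 10).
#' @return data.frame with \code{bin_lo}, \code{bin_hi}, \code{n},
#'   \code{rmse}.
#' @seealso [binAveragedRmse()]
#' @export
binnedRmse <- function(table, nBins = 10L) {
    .checkPredictionTable(table)
    edges <- round(seq(0, 1, length.out = nBins + 1L), 10)
    bin <- .binIndex(table$true_similarity, edges)
    out <- data.frame(bin_lo = edges[-(nBins + 1L)], bin_hi = edges[-1L],
                      n = 0L, rmse = NA_real_)
    for (b in seq_len(nBins)) {
        rows <- which(bin == b)
        out$n[b] <- length(rows)
        if (length(rows))
            out$rmse[b] <- rmse(table$predicted[rows],
                                table$true_similarity[rows])
    }
    out
}

#' Bin-averaged RMSE over a similarity range
#'
#' Unweighted mean of the per-bin RMSEs whose bins lie entirely at or
#' above \code{above} (e.g. \code{above = 0.6} averages the bins covering
#' structurally related pairs).
#'
#' @inheritParams binnedRmse
#' @param above lower ground-truth similarity limit.
#' @return numeric scalar (NA when all covered bins are empty).
#' @export
binAveragedRmse <- function(table, above = 0.6, nBins = 10L) {
    br <- binnedRmse(table, nBins)
    sel <- br$bin_lo >= above - 1e-9
    mean(br$rmse[sel], na.rm = TRUE)
}

## ------------------------ Top Candidate Similarity ------------------------

#' Top Candidate Similarity
#'
#' For each query, candidates are sorted by predicted score (descending,
#' ties broken by candidate id) and the maximum ground-truth similarity
#' among the first k candidates is taken; values are averaged over
#' queries. Queries with fewer candidates than k use all available and
#' are flagged.
#'
#' @param table prediction table.
#' @param cfg a [rankingConfig()].
#' @return data.frame with \code{k}, \code{value}, \code{n_queries},
#'   \code{n_short} (queries with fewer than k candidates).
#' @export
topCandidateSimilarity <- function(table, cfg = rankingConfig()) {
    .checkPredictionTable(table)
    table <- .applyExclusion(table, cfg)
    per_query <- split(table, table$query_id)
    out <- lapply(cfg$kValues, function(k) {
        vals <- vapply(per_query, function(d) {
            ord <- .predOrder(d)
            max(d$true_similarity[ord[seq_len(min(k, length(ord)))]])
        }, numeric(1))
        short <- vapply(per_query, function(d) nrow(d) < k, logical(1))
        data.frame(k = k, value = mean(vals),
                   n_queries = length(vals), n_short = sum(short))
    })
    do.call(rbind, out)
}

#' Theoretical maximum of Top Candidate Similarity
#'
#' Upper bound on [topCandidateSimilarity()]. Two readings are returned:
#' \code{"max"} (default interpretation) averages, over queries, the
#' maximum ground-truth similarity among eligible candidates -- the bound
#' actually attainable by max-at-k retrieval, constant in k; \code{"kth"}
#' averages the kth-highest ground-truth similarity.
#'
#' @inheritParams topCandidateSimilarity
#' @param mode \code{"max"}, \code{"kth"}, or \code{"both"} (default).
#' @return data.frame with \code{mode}, \code{k}, \code{value}.
#' @export
theoreticalMaximum <- function(table, cfg = rankingConfig(),
                               mode = c("both", "max", "kth")) {
    mode <- match.arg(mode)
    .checkPredictionTable(table)
    table <- .applyExclusion(table, cfg)
    per_query <- split(table$true_similarity, table$query_id)
    rows <- list()
    if (mode %in% c("both", "max")) {
        v <- mean(vapply(per_query, max, numeric(1)))
        rows <- c(rows, lapply(cfg$kValues, function(k)
            data.frame(mode = "max", k = k, value = v)))
    }
    if (mode %in% c("both", "kth")) {
        rows <- c(rows, lapply(cfg$kValues, function(k) {
            v <- mean(vapply(per_query, function(s) {
                s <- sort(s, decreasing = TRUE)
                s[min(k, length(s))]
            }, numeric(1)))
            data.frame(mode = "kth", k = k, value = v)
        }))
    }
    do.call(rbind, rows)
}

## -------------------------------- Top-Rank --------------------------------

#' Top-Rank
#'
#' For each query, candidates are dense-ranked by ground-truth similarity
#' at the structure level: all candidates whose structures share a
#' ground-truth similarity value occupy one rank j, and the next most
#' similar structures take rank j + 1. The true top-k set consists of the
#' candidates with ground-truth rank at most k. The metric is the minimum
#' predicted rank (position in the predicted ordering, ties broken by
#' candidate id) within that set, averaged over queries. A query whose
#' three most similar structures sit at predicted ranks 21, 42 and 13
#' scores 13 at k = 3.
#'
#' @param table prediction table.
#' @param cfg a [rankingConfig()].
#' @return data.frame with \code{k}, \code{value} (mean best predicted
#'   rank), \code{n_queries}, \code{n_skipped} (queries with no eligible
#'   candidate after exclusion).
#' @export
topRank <- function(table, cfg = rankingConfig()) {
    .checkPredictionTable(table)
    table <- .applyExclusion(table, cfg)
    per_query <- split(table, table$query_id)
    out <- lapply(cfg$kValues, function(k) {
        vals <- vapply(per_query, function(d) {
            if (!nrow(d)) return(NA_real_)
            ## structure-level ground-truth similarities, dense-ranked
            struct_sim <- tapply(d$true_similarity, d$candidate_inchikey14,
                                 max)
            uniq <- sort(unique(unname(struct_sim)), decreasing = TRUE)
            gt_rank_of_struct <- setNames(match(struct_sim, uniq),
                                          names(struct_sim))
            gt_rank <- gt_rank_of_struct[d$candidate_inchikey14]
            pred_rank <- integer(nrow(d))
            pred_rank[.predOrder(d)] <- seq_len(nrow(d))
            min(pred_rank[gt_rank <= k])
        }, numeric(1))
        data.frame(k = k, value = mean(vals, na.rm = TRUE),
                   n_queries = sum(!is.na(vals)),
                   n_skipped = sum(is.na(vals)))
    })
    do.call(rbind, out)
}

## ----------------------------- stratification -----------------------------

#' Stratify a metric by train-test similarity
#'
#' Partitions the prediction table into mean train-test similarity bins
#' (width 0.05 on \code{[0.4, 1]}, left-inclusive, top bin closed) and
#' applies a metric function to each non-empty partition.
#'
#' @param table prediction table with a \code{mean_tt_similarity} column.
#' @param metricFun function taking a prediction table (e.g.
#'   [topRank()], [topCandidateSimilarity()], or
#'   \code{function(d) rmse(d$predicted, d$true_similarity)}).
#' @param ... passed on to \code{metricFun}.
#' @return data.frame with \code{tt_lo}, \code{tt_hi}, \code{n_rows} and a
#'   list-column \code{metric} of per-bin results (NULL for empty bins).
#' @export
stratifyByTt <- function(table, metricFun, ...) {
    if (is.null(table$mean_tt_similarity))
        .stopf("schema_error", "mean_tt_similarity column required")
    edges <- round(seq(0.4, 1, by = 0.05), 10)
    bin <- .binIndex(table$mean_tt_similarity, edges)
    out <- data.frame(tt_lo = edges[-length(edges)], tt_hi = edges[-1L],
                      n_rows = 0L)
    out$metric <- vector("list", nrow(out))
    for (b in seq_len(nrow(out))) {
        rows <- which(bin == b)
        out$n_rows[b] <- length(rows)
        if (length(rows))
            out$metric[[b]] <- metricFun(table[rows, , drop = FALSE], ...)
    }
    out
}

#' Aggregate metric tables across seeds
#'
#' Combines per-seed metric data.frames (as returned by [topRank()] or
#' [topCandidateSimilarity()]) into mean and standard deviation per k.
#'
#' @param tables list of metric data.frames with columns \code{k},
#'   \code{value}.
#' @return data.frame with \code{k}, \code{mean}, \code{sd}, \code{n_seeds}.
#' @export
aggregateSeeds <- function(tables) {
    all <- do.call(rbind, lapply(tables, function(t) t[c("k", "value")]))
    ks <- sort(unique(all$k))
    do.call(rbind, lapply(ks, function(k) {
        v <- all$value[all$k == k]
        data.frame(k = k, mean = mean(v), sd = stats::sd(v),
                   n_seeds = length(v))
    }))
}
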