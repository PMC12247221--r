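## Internal helpers shared across the package.

#' @importFrom stats rlnorm rpois runif setNames aggregate quantile
#' @importFrom utils read.csv write.csv head tail
NULL

## Deterministic 31-bit string hash (djb2 variant kept inside double
## precision: h < 2^31 so h*33 + c < 2^37 << 2^53).
.hashString <- function(s) {
    h <- 5381
    for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2147483647
    h
}

## Left-inclusive bin index over explicit edges; the top bin is closed
## (includes the upper edge). Values outside [min, max] map to NA.
.binIndex <- function(x, edges) {
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    i[is.na(x) | x < edges[1L] | x > edges[length(edges)]] <- NA_integer_
    i
}

## Stop with a classed condition so callers/tests can be precise.
.stopf <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(
        class = c(class, "SpecSimBench_error", "error", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

.msg <- function(fmt, ...) message("[SpecSimBench] ", sprintf(fmt, ...))

## Single source of RNG discipline: evaluate expr under a seed without
## disturbing the caller's RNG state.
.withSeed <- function(seed, expr) {
    withr::with_seed(as.integer(seed), expr)
}

.isMissing <- function(x) is.na(x) | (is.character(x) & !nzchar(x))
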