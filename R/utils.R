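`%||%` <- function(a, b) if (is.null(a)) b else a

geomMean <- function(x) exp(mean(log(x[x > 0])))

#' Geometric dose grid
#'
#' @param from,to positive endpoints (mg kg^-1).
#' @param length.out number of levels.
#' @return strictly increasing numeric vector.
#' @export
geomSeq <- function(from, to, length.out) {
    stopifnot(from > 0, to > from, length.out >= 2)
    exp(seq(log(from), log(to), length.out = length.out))
}

# Deterministic per-id RNG stream: combine a base seed with a stable string
# hash, kept inside 32-bit integer range.
stableSeed <- function(seed, id) {
    h <- 0
    for (v in utf8ToInt(as.character(id))) h <- (h * 31 + v) %% 2147483563
    as.integer((as.numeric(seed) %% 2147483563 * 69069 + h) %% 2147483563)
}

# Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}
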