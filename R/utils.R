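#' @useDynLib neonet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor lm.fit pt qt rnorm runif sd t.test var
#' @importFrom utils read.table write.table
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. Every stochastic operation in the package funnels through
# this so explicit seeds never clobber the session RNG.
with_seed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
        stop("`seed` must be a single non-missing number", call. = FALSE)
    }
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had_seed) {
            assign(".Random.seed", old, envir = globalenv())
        } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
        }
    }, add = TRUE)
    set.seed(as.integer(seed))
    expr
}

# Spawn a stream of child seeds from one master seed, keeping them well below
# .Machine$integer.max so they remain valid 32-bit seeds.
child_seeds <- function(seed, n) {
    with_seed(seed, sample.int(2147483646L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
    is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= 0
}
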