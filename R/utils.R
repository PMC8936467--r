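#' @importFrom stats median pnorm pt rnorm runif rexp rpois rlnorm rgamma
#'   setNames quantile cor predict sd var complete.cases
#' @importFrom utils write.table head
NULL

# Deterministic substream seeds: every source of randomness in the package
# draws its seed from a master seed plus a named offset, so independent
# stages never share a stream and everything is reproducible from one integer.
.SUBSTREAMS <- c(events = 1L, expression = 2L, clinical = 3L, survival = 4L,
                 censoring = 5L, immune = 6L, scoring = 7L, folds = 8L,
                 forest = 9L, files = 10L)

subSeed <- function(seed, stream, index = 0L) {
    off <- .SUBSTREAMS[[stream]]
    as.integer((as.numeric(seed) * 131L + off * 7919 + index * 104729) %%
               2147483647)
}

.msg <- function(...) message("[PrognoSig] ", ...)

# rowwise medians without a matrixStats dependency
rowMedians <- function(x) apply(x, 1L, median)

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
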