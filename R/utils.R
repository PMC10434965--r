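#' @importFrom withr with_seed
NULL

# Run expr under a temporary RNG state when seed is non-NULL; the caller's
# global RNG stream is never disturbed.
withSeedIfGiven <- function(seed, expr) {
    if (is.null(seed)) {
        eval.parent(substitute(expr))
    } else {
        stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
        withr::with_seed(as.integer(seed), eval.parent(substitute(expr)))
    }
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

# Alt-allele frequency per marker from a samples x markers dosage matrix,
# ignoring missing entries. All-missing markers give NaN.
altFreq <- function(G) colMeans(G, na.rm = TRUE) / 2

# Minor allele frequency; NaN propagates for all-missing markers.
mafOf <- function(G) {
    p <- altFreq(G)
    pmin(p, 1 - p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
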