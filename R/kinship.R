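#' Structure-adjusted pairwise kinship estimates
#'
#' @slot sampleIDs sample identifiers.
#' @slot phi symmetric pairwise kinship matrix; the diagonal holds the
#'   self-kinship estimate (1 + inbreeding)/2 in expectation.
#' @slot mu individual-specific allele-frequency matrix (samples x
#'   markers), clipped inside (0, 1).
#' @slot nPcs number of principal components used for the adjustment.
#' @slot nMarkersUsed per-dyad counts of markers where both genotypes were
#'   called.
#' @slot clipEps the clipping bound applied to mu.
#' @export
setClass("KinshipResult", representation(
    sampleIDs = "character", phi = "matrix", mu = "matrix",
    nPcs = "integer", nMarkersUsed = "matrix", clipEps = "numeric"))

setValidity("KinshipResult", function(object) {
    msg <- character()
    if (!isSymmetric(unname(object@phi), tol = 1e-8))
        msg <- c(msg, "phi must be symmetric")
    if (length(object@mu) &&
        (min(object@mu) <= 0 || max(object@mu) >= 1))
        msg <- c(msg, "mu must lie strictly inside (0, 1)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "KinshipResult", function(object) {
    n <- length(object@sampleIDs)
    off <- object@phi[upper.tri(object@phi)]
    cat("KinshipResult:", n, "samples,", n * (n - 1) / 2, "dyads,",
        object@nPcs, "PC adjustment\n")
    cat(sprintf("  dyad kinship mean %.4f (SD %.4f), range [%.4f, %.4f]\n",
                mean(off, na.rm = TRUE), stats::sd(off, na.rm = TRUE),
                min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
})

#' @describeIn pcrelate The symmetric kinship matrix.
#' @export
kinshipMatrix <- function(kin) kin@phi

#' @describeIn pcrelate Per-sample self-kinship (diagonal of phi).
#' @export
selfKinship <- function(kin) diag(kin@phi)

#' @describeIn pcrelate Dyad table: id_a, id_b, kinship, n_markers, each
#'   unordered pair once (n(n-1)/2 rows).
#' @export
kinshipDyads <- function(kin) {
    idx <- which(upper.tri(kin@phi), arr.ind = TRUE)
    data.frame(id_a = kin@sampleIDs[idx[, 1]],
               id_b = kin@sampleIDs[idx[, 2]],
               kinship = kin@phi[idx],
               n_markers = kin@nMarkersUsed[idx],
               stringsAsFactors = FALSE)
}

#' PC-adjusted pairwise kinship estimation (PC-Relate estimator)
#'
#' Individual-specific allele frequencies mu_is are obtained by ordinary
#' least squares of each marker's dosage on an intercept plus the leading
#' principal components (computed on the same dataset); the fitted value
#' halved gives mu, clipped to [eps, 1 - eps]. Pairwise kinship is
#'
#'   phi_ij = sum_s (g_is - 2 mu_is)(g_js - 2 mu_js) /
#'            [4 sum_s sqrt(mu_is(1-mu_is)) sqrt(mu_js(1-mu_js))]
#'
#' with sums over markers where both genotypes are called (no imputation).
#' With `nPcs = 0` the regression is intercept-only, mu collapses to the
#' sample allele frequency, and phi equals the classical
#' frequency-standardized kinship estimator. Dyads with zero usable
#' markers get NaN with a warning. The iterative unrelated-set refinement
#' of the original estimator is not performed; PCs come from all samples.
#'
#' @param ds a [GenotypeDataset-class] with polymorphic markers.
#' @param nPcs number of PCs for the structure adjustment
#'   (0 <= nPcs < nSamples).
#' @param eps clipping bound for mu (markers where mu was clipped still
#'   contribute, with the clipped value).
#' @param scaling passed to the embedded PCA.
#' @param kin a `KinshipResult` (for the accessors documented here).
#' @return A [KinshipResult-class].
#' @export
pcrelate <- function(ds, nPcs = 2, eps = 0.01,
                     scaling = c("binomial", "sd")) {
    scaling <- match.arg(scaling)
    stopifnot(is(ds, "GenotypeDataset"), nPcs >= 0, eps > 0, eps < 0.5)
    G <- dosages(ds)
    n <- nrow(G); m <- ncol(G)
    if (nPcs >= n)
        stop("nPcs must be smaller than the number of samples")
    X <- matrix(1, n, 1)
    if (nPcs > 0) {
        pca <- fitPca(ds, nPcs, scaling = scaling)
        X <- cbind(X, pcaProject(pca, ds))
    }
    called <- !is.na(G)
    anyMiss <- colSums(!called) > 0
    fitted <- matrix(NA_real_, n, m)
    if (any(!anyMiss)) {
        idx <- which(!anyMiss)
        XtXi <- solve(crossprod(X))
        B <- XtXi %*% crossprod(X, G[, idx, drop = FALSE])
        fitted[, idx] <- X %*% B
    }
    for (j in which(anyMiss)) {
        ok <- called[, j]
        if (sum(ok) <= ncol(X)) {
            fitted[, j] <- mean(G[ok, j])
            next
        }
        fit <- stats::lm.fit(X[ok, , drop = FALSE], G[ok, j])
        fitted[, j] <- X %*% fit$coefficients
    }
    mu <- clip01(fitted / 2, eps)
    R <- (G - 2 * mu)
    R[!called] <- 0
    S <- sqrt(mu * (1 - mu))
    S[!called] <- 0
    num <- tcrossprod(R)
    den <- 4 * tcrossprod(S)
    phi <- num / den
    counts <- tcrossprod(called * 1L)
    if (any(counts[upper.tri(counts)] == 0))
        warning("dyad(s) with zero usable markers; kinship undefined")
    dimnames(phi) <- dimnames(counts) <- list(sampleIDs(ds), sampleIDs(ds))
    new("KinshipResult", sampleIDs = sampleIDs(ds), phi = phi, mu = mu,
        nPcs = as.integer(nPcs), nMarkersUsed = counts, clipEps = eps)
}

#' Classify dyads into relationship degrees
#'
#' Kinship above the first threshold is 1st degree; within (t2, t1] 2nd;
#' within (t3, t2] 3rd; at or below t3 unrelated. Default thresholds are
#' the standard powers-of-two midpoints 2^-5/2, 2^-7/2, 2^-9/2.
#'
#' @param kin a [KinshipResult-class].
#' @param thresholds strictly decreasing positive vector (t1, t2, t3).
#' @return data.frame: id_a, id_b, kinship, n_markers, degree; the
#'   thresholds used are attached as attribute `"thresholds"`.
#' @export
classifyDegree <- function(kin, thresholds = c(2^-2.5, 2^-3.5, 2^-4.5)) {
    stopifnot(length(thresholds) == 3, all(diff(thresholds) < 0),
              all(thresholds > 0))
    dy <- kinshipDyads(kin)
    dy$degree <- cut(dy$kinship,
                     breaks = c(-Inf, rev(thresholds), Inf),
                     labels = c("unrelated", "3rd", "2nd", "1st"),
                     right = TRUE)
    dy$degree <- as.character(dy$degree)
    attr(dy, "thresholds") <- thresholds
    dy
}

dyadFrame <- function(x) {
    if (is(x, "KinshipResult")) return(kinshipDyads(x))
    stopifnot(all(c("id_a", "id_b", "kinship") %in% colnames(x)))
    x
}

#' Correlate kinship estimates from two marker panels
#'
#' Dyads are matched by unordered sample-id pair over the shared samples;
#' Pearson's product-moment correlation and its t statistic
#' t = r sqrt(df) / sqrt(1 - r^2), df = dyads - 2, are reported.
#'
#' @param kinA,kinB [KinshipResult-class] objects or dyad data.frames
#'   (id_a, id_b, kinship).
#' @return list with `r`, `t`, `df`, `nDyads`.
#' @export
compareKinship <- function(kinA, kinB) {
    da <- dyadFrame(kinA)
    db <- dyadFrame(kinB)
    sharedSamples <- intersect(unique(c(da$id_a, da$id_b)),
                               unique(c(db$id_a, db$id_b)))
    if (length(sharedSamples) < 3)
        stop("need at least 3 shared samples")
    pairKey <- function(a, b)
        paste(pmin(a, b), pmax(a, b), sep = "|")
    da <- da[da$id_a %in% sharedSamples & da$id_b %in% sharedSamples, ]
    ka <- stats::setNames(da$kinship, pairKey(da$id_a, da$id_b))
    db <- db[db$id_a %in% sharedSamples & db$id_b %in% sharedSamples, ]
    kb <- stats::setNames(db$kinship, pairKey(db$id_a, db$id_b))
    common <- intersect(names(ka), names(kb))
    x <- ka[common]; y <- kb[common]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    nD <- length(x)
    if (nD < 3) stop("fewer than 3 matched dyads")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero variance in a kinship vector; r undefined")
        return(list(r = NA_real_, t = NA_real_, df = nD - 2L, nDyads = nD))
    }
    r <- stats::cor(x, y)
    df <- nD - 2L
    t <- r * sqrt(df) / sqrt(1 - r^2)
    list(r = r, t = t, df = df, nDyads = nD)
}
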