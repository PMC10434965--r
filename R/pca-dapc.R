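#' Principal components model for genotype dosages
#'
#' Stores everything needed to reproduce and re-apply a genotype PCA:
#' per-marker imputation values (mean dosage), centering means, scaling
#' divisors, the orthonormal loading matrix and the eigenvalues of the
#' sample covariance of the standardized matrix.
#'
#' @slot center,scale,impute per-marker standardization parameters.
#' @slot loadings markers x K orthonormal loading matrix.
#' @slot eigenvalues non-increasing, non-negative.
#' @slot totalVar trace of the standardized covariance matrix.
#' @slot markerKeys,markerRef,markerAlt identity of the fitted markers.
#' @slot scaling `"binomial"` (sqrt(2 p (1-p))) or `"sd"`.
#' @export
setClass("PCAModel", representation(
    center = "numeric", scale = "numeric", impute = "numeric",
    loadings = "matrix", eigenvalues = "numeric", totalVar = "numeric",
    markerKeys = "character", markerRef = "character",
    markerAlt = "character", scaling = "character"))

setValidity("PCAModel", function(object) {
    msg <- character()
    K <- ncol(object@loadings)
    if (length(object@eigenvalues) != K)
        msg <- c(msg, "one eigenvalue per loading column required")
    if (K > 1 && any(diff(object@eigenvalues) > 1e-8))
        msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-8))
        msg <- c(msg, "eigenvalues must be non-negative")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PCAModel", function(object) {
    cat("PCAModel:", nrow(object@loadings), "markers,",
        ncol(object@loadings), "components\n")
    vf <- varianceFractions(object)
    cat("  leading variance fractions:",
        paste(sprintf("%.3f", utils::head(vf, 5)), collapse = " "), "\n")
})

#' @describeIn fitPca Per-axis fractions of total variance, non-increasing.
#' @param model a `PCAModel`.
#' @export
varianceFractions <- function(model) model@eigenvalues / model@totalVar

# Standardized (imputed, centered, scaled) matrix for a raw dosage matrix
# given standardization parameters.
standardizeDosages <- function(G, impute, center, scale) {
    na <- which(is.na(G))
    if (length(na))
        G[na] <- impute[((na - 1L) %/% nrow(G)) + 1L]
    sweep(sweep(G, 2, center, "-"), 2, scale, "/")
}

stdParams <- function(G, scaling) {
    mu <- colMeans(G, na.rm = TRUE)
    if (any(is.nan(mu)))
        stop("marker(s) with all genotypes missing; filter them first")
    scale <- if (scaling == "binomial") {
        p <- mu / 2
        sqrt(2 * p * (1 - p))
    } else {
        apply(G, 2, stats::sd, na.rm = TRUE)
    }
    scale[!is.finite(scale) | scale == 0] <- 1
    list(impute = mu, center = mu, scale = scale)
}

# Eigendecomposition of the sample covariance of Z without forming the
# m x m covariance when m > n (Gram-matrix route; identical spectrum).
covEigen <- function(Z, K) {
    n <- nrow(Z); m <- ncol(Z)
    if (m > n) {
        ev <- eigen(tcrossprod(Z) / (n - 1), symmetric = TRUE)
        lambda <- pmax(ev$values, 0)
        keep <- seq_len(K)
        d <- sqrt(pmax(lambda[keep] * (n - 1), .Machine$double.eps))
        V <- crossprod(Z, ev$vectors[, keep, drop = FALSE]) /
            rep(d, each = m)
        list(values = lambda[keep], vectors = V,
             total = sum(Z^2) / (n - 1))
    } else {
        ev <- eigen(crossprod(Z) / (n - 1), symmetric = TRUE)
        lambda <- pmax(ev$values, 0)
        list(values = lambda[seq_len(K)],
             vectors = ev$vectors[, seq_len(K), drop = FALSE],
             total = sum(lambda))
    }
}

#' Fit a PCA on genotype dosages
#'
#' Missing dosages are mean-imputed per marker; columns are centered by
#' mean dosage and scaled by the binomial standard deviation
#' sqrt(2 p (1 - p)) of the estimated ALT-allele frequency (plain standard
#' deviation via `scaling = "sd"`; zero-variance markers get divisor 1).
#' Loadings and eigenvalues are those of the sample covariance of the
#' standardized matrix.
#'
#' @param ds a [GenotypeDataset-class] with no all-missing marker.
#' @param K number of components, at most min(nSamples - 1, nMarkers).
#' @param scaling `"binomial"` or `"sd"`.
#' @return A [PCAModel-class].
#' @export
fitPca <- function(ds, K, scaling = c("binomial", "sd")) {
    scaling <- match.arg(scaling)
    stopifnot(is(ds, "GenotypeDataset"))
    G <- dosages(ds)
    n <- nrow(G); m <- ncol(G)
    kmax <- min(n - 1L, m)
    if (K > kmax)
        stop("K = ", K, " exceeds min(nSamples - 1, nMarkers) = ", kmax)
    sp <- stdParams(G, scaling)
    Z <- standardizeDosages(G, sp$impute, sp$center, sp$scale)
    ev <- covEigen(Z, K)
    mi <- markerInfo(ds)
    new("PCAModel", center = sp$center, scale = sp$scale,
        impute = sp$impute, loadings = ev$vectors,
        eigenvalues = ev$values, totalVar = ev$total,
        markerKeys = markerKeys(ds), markerRef = mi$ref,
        markerAlt = mi$alt, scaling = scaling)
}

#' @describeIn fitPca Project a dataset onto the model's components using
#'   the stored standardization (never refit). Markers must match the
#'   model's.
#' @param ds a [GenotypeDataset-class].
#' @export
pcaProject <- function(model, ds) {
    checkMarkerMatch(model, ds)
    G <- dosages(ds)
    Z <- standardizeDosages(G, model@impute, model@center, model@scale)
    S <- Z %*% model@loadings
    rownames(S) <- sampleIDs(ds)
    S
}

checkMarkerMatch <- function(model, ds) {
    keys <- markerKeys(ds)
    if (!identical(keys, model@markerKeys)) {
        miss <- setdiff(model@markerKeys, keys)
        if (length(miss))
            stop("dataset lacks model marker(s): ",
                 paste(utils::head(miss, 5), collapse = ", "),
                 if (length(miss) > 5) " ...")
        stop("dataset markers do not match the model (order or extras)")
    }
    mi <- markerInfo(ds)
    if (!identical(mi$ref, model@markerRef) ||
        !identical(mi$alt, model@markerAlt))
        stop("allele orientation differs from the model; harmonize first")
    invisible(TRUE)
}

#' Discriminant analysis of principal components (DAPC) model
#'
#' @slot pca the embedded [PCAModel-class] with K retained components.
#' @slot A K x D discriminant coefficient matrix (a' W a = 1 per axis).
#' @slot eigenvalues generalized eigenvalues; their shares are the per-axis
#'   percentages of interpopulation variance.
#' @slot centroids group centroids in discriminant space (g x D).
#' @slot groups population levels in assignment tie-break order.
#' @slot markerLoadings markers x D loadings on the standardized dosages
#'   (B = L A).
#' @slot contributions markers x D normalized squared loadings; each column
#'   sums to 1.
#' @slot discScores training-sample discriminant scores.
#' @slot trainLabels training-sample population labels.
#' @export
setClass("DAPCModel", representation(
    pca = "PCAModel", A = "matrix", eigenvalues = "numeric",
    centroids = "matrix", groups = "character", markerLoadings = "matrix",
    contributions = "matrix", discScores = "matrix",
    trainLabels = "character"))

setValidity("DAPCModel", function(object) {
    msg <- character()
    D <- ncol(object@A)
    if (D > 0) {
        sums <- colSums(object@contributions)
        if (any(abs(sums - 1) > 1e-6))
            msg <- c(msg, "per-axis contributions must sum to 1")
    }
    if (!all(is.finite(object@centroids)))
        msg <- c(msg, "centroids must be finite")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DAPCModel", function(object) {
    cat("DAPCModel:", length(object@groups), "populations,",
        ncol(object@pca@loadings), "PCs,", ncol(object@A),
        "discriminant axes\n")
    share <- object@eigenvalues / sum(object@eigenvalues)
    cat("  interpopulation variance shares:",
        paste(sprintf("%.3f", share), collapse = " "), "\n")
})

#' @describeIn fitDapc Per-marker contributions (normalized squared
#'   loadings) on each discriminant axis.
#' @export
markerContributions <- function(model) model@contributions

# Discriminant axes from PC scores and group labels: solve the
# W^{-1} B_g generalized eigenproblem via the Cholesky factor of W,
# scaled so a' W a = 1.
discriminantAxes <- function(S, labels, D) {
    groups <- unique(labels)
    n <- nrow(S); g <- length(groups); K <- ncol(S)
    grand <- colMeans(S)
    W <- matrix(0, K, K)
    Bg <- matrix(0, K, K)
    for (grp in groups) {
        Sg <- S[labels == grp, , drop = FALSE]
        mg <- colMeans(Sg)
        Wc <- sweep(Sg, 2, mg, "-")
        W <- W + crossprod(Wc)
        Bg <- Bg + nrow(Sg) * tcrossprod(mg - grand)
    }
    W <- W / (n - g)
    Bg <- Bg / (n - 1)
    R <- tryCatch(chol(W), error = function(e)
        stop("within-group scatter is singular; retain fewer PCs"))
    M <- backsolve(R, t(backsolve(R, t(Bg), transpose = TRUE)),
                   transpose = TRUE)
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    A <- backsolve(R, ev$vectors[, seq_len(D), drop = FALSE])
    list(A = A, eigenvalues = pmax(ev$values[seq_len(D)], 0),
         groups = groups)
}

#' Fit a DAPC with a-priori population labels
#'
#' Computes PC scores ([fitPca()]), forms within- and between-group scatter
#' of the scores, and solves the generalized eigenproblem for discriminant
#' axes scaled to unit within-group variance. Per-marker loadings on each
#' axis (on the standardized dosage scale) and their normalized squared
#' contributions are populated for marker selection.
#'
#' @param ds a labelled [GenotypeDataset-class] with at least two
#'   populations of at least two samples each.
#' @param K number of principal components to retain.
#' @param D number of discriminant axes (default min(groups - 1, K)).
#' @param scaling passed to [fitPca()].
#' @param model a `DAPCModel` (for the accessors documented here).
#' @return A [DAPCModel-class].
#' @export
fitDapc <- function(ds, K, D = NULL, scaling = c("binomial", "sd")) {
    scaling <- match.arg(scaling)
    labels <- popLabels(ds)
    if (is.null(labels))
        stop("dataset has no population labels")
    tab <- table(labels)
    if (length(tab) < 2 || any(tab < 2))
        stop("need >= 2 populations with >= 2 samples each")
    g <- length(tab)
    D <- D %||% min(g - 1L, K)
    stopifnot(D >= 1, D <= min(g - 1L, K))
    pca <- fitPca(ds, K, scaling = scaling)
    S <- pcaProject(pca, ds)
    ax <- discriminantAxes(S, labels, D)
    disc <- S %*% ax$A
    centroids <- do.call(rbind, lapply(ax$groups, function(grp)
        colMeans(disc[labels == grp, , drop = FALSE])))
    rownames(centroids) <- ax$groups
    B <- pca@loadings %*% ax$A
    contrib <- sweep(B^2, 2, colSums(B^2), "/")
    rownames(B) <- rownames(contrib) <- pca@markerKeys
    new("DAPCModel", pca = pca, A = ax$A, eigenvalues = ax$eigenvalues,
        centroids = centroids, groups = ax$groups,
        markerLoadings = B, contributions = contrib,
        discScores = disc, trainLabels = labels)
}

#' Assign samples to populations with a fitted DAPC
#'
#' New samples are standardized with the model's stored means, scales and
#' imputation values (never refit), projected through the PC loadings and
#' discriminant coefficients, and assigned by posterior membership:
#' posterior for group k is proportional to exp(-squared distance to
#' centroid k / 2) in discriminant space (isotropic Gaussian, equal
#' priors). Argmax ties break by population order.
#'
#' @param model a [DAPCModel-class].
#' @param ds a [GenotypeDataset-class] whose markers match the model.
#' @return list with `assigned` (character), `posterior` (samples x groups,
#'   rows sum to 1) and `scores` (discriminant coordinates).
#' @export
predictDapc <- function(model, ds) {
    S <- pcaProject(model@pca, ds)
    disc <- S %*% model@A
    d2 <- outer(rowSums(disc^2), rowSums(model@centroids^2), "+") -
        2 * disc %*% t(model@centroids)
    d2 <- d2 - apply(d2, 1, min)            # stabilize the softmax
    post <- exp(-0.5 * d2)
    post <- post / rowSums(post)
    colnames(post) <- model@groups
    rownames(post) <- sampleIDs(ds)
    assigned <- model@groups[apply(post, 1, which.max)]
    list(assigned = stats::setNames(assigned, sampleIDs(ds)),
         posterior = post, scores = disc)
}

#' Cross-validation report for DAPC population assignment
#'
#' @slot kGrid candidate numbers of retained PCs.
#' @slot meanSuccess per-K mean held-out assignment success in [0, 1].
#' @slot rmse per-K root mean squared error, sqrt(mean((1 - success)^2)).
#' @slot chosenK grid point minimizing RMSE (smallest K on ties).
#' @slot successMatrix replicate x K held-out success fractions.
#' @slot nRep,trainFrac,seed the cross-validation settings.
#' @export
setClass("XValReport", representation(
    kGrid = "integer", meanSuccess = "numeric", rmse = "numeric",
    chosenK = "integer", successMatrix = "matrix", nRep = "integer",
    trainFrac = "numeric", seed = "integer"))

setValidity("XValReport", function(object) {
    msg <- character()
    if (any(object@meanSuccess < 0 | object@meanSuccess > 1))
        msg <- c(msg, "success values must be in [0, 1]")
    if (!object@chosenK %in% object@kGrid)
        msg <- c(msg, "chosenK must belong to the grid")
    if (length(msg)) msg else TRUE
})

setMethod("show", "XValReport", function(object) {
    cat("XValReport:", object@nRep, "replicates, train fraction",
        object@trainFrac, "\n")
    df <- data.frame(K = object@kGrid,
                     mean_success = round(object@meanSuccess, 4),
                     rmse = round(object@rmse, 4))
    print(df, row.names = FALSE)
    cat("  chosen K:", object@chosenK, " (mean success ",
        sprintf("%.4f", object@meanSuccess[match(object@chosenK,
                                                 object@kGrid)]),
        ")\n", sep = "")
})

#' @describeIn crossvalidateDapc RMSE-optimal number of PCs.
#' @param report an `XValReport`.
#' @export
chosenK <- function(report) report@chosenK

#' @describeIn crossvalidateDapc Mean held-out success at the chosen K.
#' @export
successAtChosenK <- function(report)
    report@meanSuccess[match(report@chosenK, report@kGrid)]

defaultKGrid <- function(n, g, m, trainFrac) {
    nTrain <- floor(n * trainFrac)
    kmax <- min(nTrain - g, m, 100L)
    if (kmax < 1) stop("too few samples for cross-validation")
    sort(unique(pmax(1L, round(seq(kmax / 10, kmax, length.out = 10)))))
}

# Stratified train/test split: ceiling(holdFrac * n_g) held out per group,
# at least one.
stratifiedHoldout <- function(labels, trainFrac) {
    test <- integer()
    for (grp in unique(labels)) {
        idx <- which(labels == grp)
        nTest <- max(1L, round((1 - trainFrac) * length(idx)))
        test <- c(test, sample(idx, nTest))
    }
    test
}

#' Repeated stratified cross-validation of DAPC assignment
#'
#' Per replicate, a stratified split holds out (1 - trainFrac) of each
#' population; a DAPC is fitted on the training samples (standardization
#' and PCA refit on training data only) and the held-out samples are
#' assigned; success is the fraction assigned to their true population.
#' Per grid point K the mean success and RMSE = sqrt(mean((1 - success)^2))
#' over replicates are reported; the chosen K minimizes RMSE (smallest K
#' on ties). One PCA per replicate at max(kGrid) serves all K via the
#' nesting of principal components.
#'
#' @param ds a labelled [GenotypeDataset-class]; every population must be
#'   large enough to leave at least one held-out sample (size >= 2).
#' @param kGrid candidate PC counts (default: 10 evenly spaced values up to
#'   min(nTrain - groups, nMarkers, 100)).
#' @param nRep number of replicates.
#' @param trainFrac training fraction per population.
#' @param seed integer seed; fixed seed gives an identical report.
#' @param scaling passed to the embedded PCA.
#' @return An [XValReport-class].
#' @export
crossvalidateDapc <- function(ds, kGrid = NULL, nRep = 100,
                              trainFrac = 0.9, seed = NULL,
                              scaling = c("binomial", "sd")) {
    scaling <- match.arg(scaling)
    labels <- popLabels(ds)
    if (is.null(labels)) stop("dataset has no population labels")
    tab <- table(labels)
    if (any(tab < 2))
        stop("population(s) too small to hold out a sample: ",
             paste(names(tab)[tab < 2], collapse = ", "))
    G <- dosages(ds)
    n <- nrow(G); m <- ncol(G); g <- length(tab)
    kGrid <- as.integer(kGrid %||% defaultKGrid(n, g, m, trainFrac))
    stopifnot(all(kGrid >= 1))
    kmax <- max(kGrid)
    success <- matrix(NA_real_, nrow = nRep, ncol = length(kGrid))
    withSeedIfGiven(seed, {
        for (rep in seq_len(nRep)) {
            testIdx <- stratifiedHoldout(labels, trainFrac)
            trainIdx <- setdiff(seq_len(n), testIdx)
            Gtr <- G[trainIdx, , drop = FALSE]
            sp <- stdParams(Gtr, scaling)
            Ztr <- standardizeDosages(Gtr, sp$impute, sp$center, sp$scale)
            km <- min(kmax, length(trainIdx) - 1L, m)
            ev <- covEigen(Ztr, km)
            Str <- Ztr %*% ev$vectors
            Zte <- standardizeDosages(G[testIdx, , drop = FALSE],
                                      sp$impute, sp$center, sp$scale)
            Ste <- Zte %*% ev$vectors
            labTr <- labels[trainIdx]
            labTe <- labels[testIdx]
            for (ki in seq_along(kGrid)) {
                K <- min(kGrid[ki], km)
                D <- min(g - 1L, K)
                ax <- tryCatch(
                    discriminantAxes(Str[, seq_len(K), drop = FALSE],
                                     labTr, D),
                    error = function(e) NULL)
                if (is.null(ax)) { success[rep, ki] <- NA; next }
                discTr <- Str[, seq_len(K), drop = FALSE] %*% ax$A
                cent <- do.call(rbind, lapply(ax$groups, function(grp)
                    colMeans(discTr[labTr == grp, , drop = FALSE])))
                discTe <- Ste[, seq_len(K), drop = FALSE] %*% ax$A
                d2 <- outer(rowSums(discTe^2), rowSums(cent^2), "+") -
                    2 * discTe %*% t(cent)
                pred <- ax$groups[apply(d2, 1, which.min)]
                success[rep, ki] <- mean(pred == labTe)
            }
        }
    })
    meanSuccess <- colMeans(success, na.rm = TRUE)
    rmse <- sqrt(colMeans((1 - success)^2, na.rm = TRUE))
    chosen <- kGrid[which.min(rmse)]
    new("XValReport", kGrid = kGrid, meanSuccess = meanSuccess,
        rmse = rmse, chosenK = as.integer(chosen),
        successMatrix = success, nRep = as.integer(nRep),
        trainFrac = trainFrac,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
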