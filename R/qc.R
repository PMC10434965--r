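#' QC stage report
#'
#' Records what a QC operation removed and why: removed samples with their
#' missing fractions, removed markers attributed to exactly one rule (the
#' first that fired), and the thresholds used. Counts reconcile:
#' `nrow(markersRemoved) == input markers - output markers`.
#'
#' @slot stage name of the QC operation.
#' @slot samplesRemoved data.frame: sample_id, miss_frac.
#' @slot markersRemoved data.frame: marker key, rule, value.
#' @slot thresholds named list of thresholds used.
#' @slot nInputMarkers,nOutputMarkers,nInputSamples,nOutputSamples counts.
#' @export
setClass("QCReport", representation(
    stage = "character",
    samplesRemoved = "data.frame",
    markersRemoved = "data.frame",
    thresholds = "list",
    nInputMarkers = "integer",
    nOutputMarkers = "integer",
    nInputSamples = "integer",
    nOutputSamples = "integer"))

setValidity("QCReport", function(object) {
    if (nrow(object@markersRemoved) !=
        object@nInputMarkers - object@nOutputMarkers)
        return("marker removal counts do not reconcile")
    if (nrow(object@samplesRemoved) !=
        object@nInputSamples - object@nOutputSamples)
        return("sample removal counts do not reconcile")
    TRUE
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport [", object@stage, "]\n", sep = "")
    cat("  samples: ", object@nInputSamples, " -> ",
        object@nOutputSamples, "\n", sep = "")
    cat("  markers: ", object@nInputMarkers, " -> ",
        object@nOutputMarkers, "\n", sep = "")
    if (nrow(object@markersRemoved)) {
        tab <- table(object@markersRemoved$rule)
        for (r in names(tab))
            cat("    removed by ", r, ": ", tab[[r]], "\n", sep = "")
    }
    cat("  thresholds:",
        paste(names(object@thresholds), unlist(object@thresholds),
              sep = "=", collapse = ", "), "\n")
})

qcReport <- function(stage, dsIn, dsOut, samplesRemoved = NULL,
                     markersRemoved = NULL, thresholds = list()) {
    new("QCReport", stage = stage,
        samplesRemoved = samplesRemoved %||%
            data.frame(sample_id = character(), miss_frac = numeric()),
        markersRemoved = markersRemoved %||%
            data.frame(marker = character(), rule = character(),
                       value = numeric()),
        thresholds = thresholds,
        nInputMarkers = nMarkers(dsIn), nOutputMarkers = nMarkers(dsOut),
        nInputSamples = nSamples(dsIn), nOutputSamples = nSamples(dsOut))
}

#' @describeIn filterMissingness Accessor for the removed-marker table.
#' @export
markersRemoved <- function(report) report@markersRemoved

#' @describeIn filterMissingness Accessor for the removed-sample table.
#' @export
samplesRemoved <- function(report) report@samplesRemoved

subsetDS <- function(ds, samples = NULL, markers = NULL) {
    x <- ds
    if (!is.null(markers)) x <- x[markers, ]
    if (!is.null(samples)) x <- x[, samples]
    x
}

#' Filter samples and markers by genotype missingness
#'
#' Samples whose missing fraction is at least `maxSampleMiss` are removed
#' first; markers whose missing fraction over the remaining samples is at
#' least `maxMarkerMiss` are removed second. Both boundaries are inclusive
#' (a sample with exactly 10% missing genotypes is excluded at the default
#' threshold).
#'
#' @param ds a [GenotypeDataset-class].
#' @param maxSampleMiss,maxMarkerMiss thresholds in [0, 1].
#' @param report a [QCReport-class] (for the accessors documented here).
#' @return list with `dataset` (filtered) and `report` ([QCReport-class]).
#' @export
filterMissingness <- function(ds, maxSampleMiss = 0.10,
                              maxMarkerMiss = 0.10) {
    stopifnot(is(ds, "GenotypeDataset"),
              maxSampleMiss >= 0, maxSampleMiss <= 1,
              maxMarkerMiss >= 0, maxMarkerMiss <= 1)
    G <- dosages(ds)
    sampMiss <- rowMeans(is.na(G))
    dropS <- which(sampMiss >= maxSampleMiss)
    keepS <- setdiff(seq_len(nrow(G)), dropS)
    markMiss <- colMeans(is.na(G[keepS, , drop = FALSE]))
    dropM <- which(markMiss >= maxMarkerMiss)
    keepM <- setdiff(seq_len(ncol(G)), dropM)
    if (!length(keepS) || !length(keepM))
        stop("no samples or markers survive the missingness filter")
    out <- subsetDS(ds, samples = keepS, markers = keepM)
    rep <- qcReport("missingness", ds, out,
                    samplesRemoved = data.frame(
                        sample_id = sampleIDs(ds)[dropS],
                        miss_frac = unname(sampMiss[dropS])),
                    markersRemoved = data.frame(
                        marker = markerKeys(ds)[dropM],
                        rule = rep("missingness", length(dropM)),
                        value = unname(markMiss[dropM])),
                    thresholds = list(maxSampleMiss = maxSampleMiss,
                                      maxMarkerMiss = maxMarkerMiss))
    list(dataset = out, report = rep)
}

#' Filter markers by minor allele frequency
#'
#' MAF is computed from non-missing dosages. Monomorphic markers (MAF = 0,
#' including markers with every genotype missing) are always removed;
#' polymorphic markers are retained iff MAF >= `minMaf` (inclusive
#' boundary).
#'
#' @param ds a [GenotypeDataset-class].
#' @param minMaf threshold in [0, 0.5].
#' @return list with `dataset` and `report`.
#' @export
filterMaf <- function(ds, minMaf = 0.05) {
    stopifnot(is(ds, "GenotypeDataset"), minMaf >= 0, minMaf <= 0.5)
    G <- dosages(ds)
    maf <- mafOf(G)
    allMissing <- is.nan(maf)
    mono <- !allMissing & maf == 0
    low <- !allMissing & !mono & maf < minMaf
    dropM <- which(allMissing | mono | low)
    keepM <- setdiff(seq_len(ncol(G)), dropM)
    rule <- character(length(dropM))
    rule[allMissing[dropM]] <- "maf_undefined"
    rule[mono[dropM]] <- "monomorphic"
    rule[low[dropM]] <- "maf"
    out <- subsetDS(ds, markers = keepM)
    rep <- qcReport("maf", ds, out,
                    markersRemoved = data.frame(
                        marker = markerKeys(ds)[dropM],
                        rule = rule,
                        value = unname(maf[dropM])),
                    thresholds = list(minMaf = minMaf))
    list(dataset = out, report = rep)
}

#' Mask low-quality genotypes and filter markers on depth and missingness
#'
#' Genotypes with GQ below `minGq` are set missing; markers with mean depth
#' (over all samples) below `minMeanDp` are then removed; finally markers
#' whose missing fraction exceeds `maxMarkerMiss` are removed. Requires DP
#' and GQ assays.
#'
#' @param ds a [GenotypeDataset-class] with DP and GQ.
#' @param minGq genotypes with GQ < minGq are masked (default 30).
#' @param minMeanDp markers with mean DP < minMeanDp are removed
#'   (default 10; the boundary itself is kept).
#' @param maxMarkerMiss markers with missing fraction > maxMarkerMiss are
#'   removed (default 0.10; the boundary itself is kept).
#' @return list with `dataset` and `report`.
#' @export
maskLowQuality <- function(ds, minGq = 30, minMeanDp = 10,
                           maxMarkerMiss = 0.10) {
    stopifnot(is(ds, "GenotypeDataset"))
    DP <- depthMatrix(ds)
    GQ <- qualMatrix(ds)
    if (is.null(DP) || is.null(GQ))
        stop("dataset has no DP/GQ annotations; skip the quality-mask stage")
    G <- dosages(ds)
    G[!is.na(GQ) & GQ < minGq] <- NA
    meanDp <- colMeans(DP, na.rm = TRUE)
    lowDp <- meanDp < minMeanDp
    missFrac <- colMeans(is.na(G))
    highMiss <- !lowDp & missFrac > maxMarkerMiss
    dropM <- which(lowDp | highMiss)
    keepM <- setdiff(seq_len(ncol(G)), dropM)
    mi <- markerInfo(ds)
    masked <- GenotypeDataset(G, chrom = mi$chrom, pos = mi$pos,
                              ref = mi$ref, alt = mi$alt, id = mi$id,
                              samples = sampleIDs(ds),
                              population = popLabels(ds), DP = DP, GQ = GQ)
    out <- subsetDS(masked, markers = keepM)
    rule <- ifelse(lowDp[dropM], "mean_depth", "missingness_after_mask")
    rep <- qcReport("quality", ds, out,
                    markersRemoved = data.frame(
                        marker = markerKeys(ds)[dropM],
                        rule = rule,
                        value = ifelse(lowDp[dropM], meanDp[dropM],
                                       missFrac[dropM])),
                    thresholds = list(minGq = minGq, minMeanDp = minMeanDp,
                                      maxMarkerMiss = maxMarkerMiss))
    list(dataset = out, report = rep)
}

# Squared Pearson correlation of two dosage vectors over pairwise-complete
# observations; defined as 0 with fewer than 2 complete pairs or zero
# variance.
r2Pair <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(0)
    x <- x[ok]; y <- y[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
    stats::cor(x, y)^2
}

#' Prune markers in linkage disequilibrium
#'
#' Slides a base-pair window (anchored at the left marker, advanced `step`
#' markers at a time, never spanning chromosomes) and, whenever two
#' surviving markers within `windowBp` of each other have squared Pearson
#' dosage correlation above `r2Max`, removes one of the pair: the member
#' with higher missingness, ties broken by lower MAF, then by larger
#' position. With `step = 1` no surviving same-chromosome pair within
#' `windowBp` has r^2 above `r2Max` (auditable with [ldPruneAudit()]).
#' r^2 uses pairwise-complete observations; with fewer than two complete
#' pairs it is defined as 0.
#'
#' @param ds a [GenotypeDataset-class] (markers sorted, as enforced by the
#'   class).
#' @param windowBp window span in base pairs (pairs with position
#'   difference <= windowBp are tested).
#' @param step number of markers the window anchor advances at a time.
#' @param r2Max retain pairs iff r^2 <= r2Max.
#' @param windowMarkers optional marker-count window: when given, the
#'   window is the next `windowMarkers - 1` markers instead of a bp span.
#' @return list with `dataset` and `report`.
#' @export
ldPrune <- function(ds, windowBp = 1000, step = 1, r2Max = 0.5,
                    windowMarkers = NULL) {
    stopifnot(is(ds, "GenotypeDataset"), r2Max >= 0, r2Max <= 1, step >= 1)
    G <- dosages(ds)
    mi <- markerInfo(ds)
    m <- ncol(G)
    miss <- colMeans(is.na(G))
    maf <- mafOf(G)
    maf[is.nan(maf)] <- 0
    alive <- rep(TRUE, m)
    for (ch in unique(mi$chrom)) {
        idx <- which(mi$chrom == ch)
        anchors <- idx[seq(1L, length(idx), by = step)]
        for (i in anchors) {
            if (!alive[i]) next
            if (is.null(windowMarkers)) {
                js <- idx[idx > i & mi$pos[idx] - mi$pos[i] <= windowBp]
            } else {
                after <- idx[idx > i]
                js <- utils::head(after, windowMarkers - 1L)
            }
            for (j in js) {
                if (!alive[i]) break
                if (!alive[j]) next
                if (r2Pair(G[, i], G[, j]) > r2Max) {
                    drop <- pickLdVictim(i, j, miss, maf, mi$pos)
                    alive[drop] <- FALSE
                }
            }
        }
    }
    dropM <- which(!alive)
    out <- subsetDS(ds, markers = which(alive))
    rep <- qcReport("ld", ds, out,
                    markersRemoved = data.frame(
                        marker = markerKeys(ds)[dropM],
                        rule = rep("ld", length(dropM)),
                        value = rep(NA_real_, length(dropM))),
                    thresholds = list(windowBp = windowBp, step = step,
                                      r2Max = r2Max))
    list(dataset = out, report = rep)
}

# Which of a violating pair to remove: higher missingness, then lower MAF,
# then larger position. Deterministic.
pickLdVictim <- function(i, j, miss, maf, pos) {
    if (miss[i] != miss[j]) return(if (miss[i] > miss[j]) i else j)
    if (maf[i] != maf[j]) return(if (maf[i] < maf[j]) i else j)
    if (pos[i] > pos[j]) i else j
}

#' Audit the LD-pruning post-condition
#'
#' Exhaustively scans every same-chromosome marker pair within `windowBp`
#' and reports those with r^2 above `r2Max`.
#'
#' @inheritParams ldPrune
#' @return data.frame of violating pairs (empty when the post-condition
#'   holds).
#' @export
ldPruneAudit <- function(ds, windowBp = 1000, r2Max = 0.5) {
    G <- dosages(ds)
    mi <- markerInfo(ds)
    bad <- list()
    for (ch in unique(mi$chrom)) {
        idx <- which(mi$chrom == ch)
        for (a in seq_along(idx)) {
            i <- idx[a]
            for (b in seq_along(idx)[-seq_len(a)]) {
                j <- idx[b]
                if (mi$pos[j] - mi$pos[i] > windowBp) break
                r2 <- r2Pair(G[, i], G[, j])
                if (r2 > r2Max)
                    bad[[length(bad) + 1L]] <-
                        data.frame(chrom = ch, pos_i = mi$pos[i],
                                   pos_j = mi$pos[j], r2 = r2)
            }
        }
    }
    if (length(bad)) do.call(rbind, bad) else
        data.frame(chrom = character(), pos_i = integer(),
                   pos_j = integer(), r2 = numeric())
}
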