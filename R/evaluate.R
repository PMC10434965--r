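#' Cross-platform genotype concordance report
#'
#' Every (shared sample x harmonized shared site) cell is classified into
#' exactly one of five categories; counts sum to the full grid and both
#' percentages use that grid as denominator.
#'
#' @slot nSamples,nSites shared samples and harmonized shared sites.
#' @slot cells named counts: identical, discordant,
#'   missing_in_A_called_in_B, called_in_A_missing_in_B, missing_in_both.
#' @slot percentIdentical,percentDiscordant percentages of all cells.
#' @slot missingnessRatio missing_in_A_called_in_B /
#'   called_in_A_missing_in_B (NaN when the denominator is 0).
#' @slot perSite per-site discordance table.
#' @slot swappedSites sites compared after REF/ALT swap harmonization.
#' @slot droppedSites shared sites dropped with reasons.
#' @export
setClass("ConcordanceReport", representation(
    nSamples = "integer", nSites = "integer", cells = "numeric",
    percentIdentical = "numeric", percentDiscordant = "numeric",
    missingnessRatio = "numeric", perSite = "data.frame",
    swappedSites = "data.frame", droppedSites = "data.frame"))

setValidity("ConcordanceReport", function(object) {
    if (sum(object@cells) != object@nSamples * object@nSites)
        return("cell counts must sum to shared samples x shared sites")
    TRUE
})

setMethod("show", "ConcordanceReport", function(object) {
    cat("ConcordanceReport:", object@nSamples, "shared samples x",
        object@nSites, "harmonized shared sites\n")
    for (nm in names(object@cells))
        cat(sprintf("  %-26s %d\n", nm, object@cells[[nm]]))
    cat(sprintf("  identical: %.2f%%  discordant: %.2f%%\n",
                object@percentIdentical, object@percentDiscordant))
    cat("  reciprocal missingness ratio:",
        if (is.nan(object@missingnessRatio)) "undefined (0/0)"
        else sprintf("%.2f", object@missingnessRatio), "\n")
    if (nrow(object@swappedSites))
        cat("  REF/ALT-swapped sites harmonized:",
            nrow(object@swappedSites), "\n")
    if (nrow(object@droppedSites))
        cat("  sites dropped:", nrow(object@droppedSites), "\n")
})

#' @describeIn concordance The five cell counts.
#' @export
concordanceCells <- function(report) report@cells

#' Genotype concordance between two datasets on harmonized shared sites
#'
#' Samples are matched by id and sites by (chrom, pos). Allele
#' harmonization: identical REF/ALT compare dosages directly; swapped
#' REF/ALT compare dosage in A against (2 - dosage in B) and log the swap;
#' any other allele combination drops the site with a log entry. Each
#' remaining cell is classified as identical, discordant, missing in A
#' called in B, called in A missing in B, or missing in both.
#'
#' @param dsA,dsB [GenotypeDataset-class] objects.
#' @param report a `ConcordanceReport` (for the accessor documented here).
#' @return A [ConcordanceReport-class].
#' @export
concordance <- function(dsA, dsB) {
    stopifnot(is(dsA, "GenotypeDataset"), is(dsB, "GenotypeDataset"))
    samples <- intersect(sampleIDs(dsA), sampleIDs(dsB))
    if (!length(samples)) stop("no shared samples")
    keysA <- markerKeys(dsA); keysB <- markerKeys(dsB)
    shared <- intersect(keysA, keysB)
    if (!length(shared)) stop("no shared sites")
    ia <- match(shared, keysA); ib <- match(shared, keysB)
    miA <- markerInfo(dsA)[ia, ]; miB <- markerInfo(dsB)[ib, ]
    direct <- miA$ref == miB$ref & miA$alt == miB$alt
    swapped <- !direct & miA$ref == miB$alt & miA$alt == miB$ref
    dropped <- !direct & !swapped
    GA <- dosages(dsA)[samples, ia, drop = FALSE]
    GB <- dosages(dsB)[samples, ib, drop = FALSE]
    GB[, swapped] <- 2L - GB[, swapped]
    keep <- which(!dropped)
    if (!length(keep))
        stop("no shared sites remain after allele harmonization")
    GA <- GA[, keep, drop = FALSE]
    GB <- GB[, keep, drop = FALSE]
    callA <- !is.na(GA); callB <- !is.na(GB)
    ident <- callA & callB & GA == GB
    disc <- callA & callB & GA != GB
    cells <- c(identical = sum(ident, na.rm = TRUE),
               discordant = sum(disc, na.rm = TRUE),
               missing_in_A_called_in_B = sum(!callA & callB),
               called_in_A_missing_in_B = sum(callA & !callB),
               missing_in_both = sum(!callA & !callB))
    total <- length(samples) * length(keep)
    perSite <- data.frame(key = shared[keep],
                          n_identical = colSums(ident, na.rm = TRUE),
                          n_discordant = colSums(disc, na.rm = TRUE),
                          row.names = NULL, stringsAsFactors = FALSE)
    ratio <- cells[["missing_in_A_called_in_B"]] /
        cells[["called_in_A_missing_in_B"]]
    new("ConcordanceReport",
        nSamples = length(samples), nSites = length(keep),
        cells = cells,
        percentIdentical = 100 * cells[["identical"]] / total,
        percentDiscordant = 100 * cells[["discordant"]] / total,
        missingnessRatio = ratio,
        perSite = perSite,
        swappedSites = data.frame(key = shared[swapped],
                                  stringsAsFactors = FALSE),
        droppedSites = data.frame(
            key = shared[dropped],
            reason = rep("incompatible alleles", sum(dropped)),
            stringsAsFactors = FALSE))
}

#' Per-sample target coverage profile
#'
#' For every sample and threshold t, the proportion of targets with depth
#' >= t (each per-sample curve is non-increasing in t), plus per-sample and
#' grand depth moments.
#'
#' @param depthTable numeric samples x targets depth matrix (>= 0).
#' @param thresholds increasing threshold grid.
#' @param reportAt,reportProp the summary counts samples whose proportion
#'   at depth `reportAt` exceeds `reportProp`.
#' @return list with `curves` (samples x thresholds), `thresholds`,
#'   `perSampleMean`, `perSampleSD`, `grandMean`, `grandSD`, and
#'   `nSamplesAbove` (samples with curve at `reportAt` > `reportProp`).
#' @export
coverageProfile <- function(depthTable, thresholds = 1:100,
                            reportAt = 10, reportProp = 0.9) {
    D <- as.matrix(depthTable)
    if (!length(D)) stop("empty depth table")
    stopifnot(all(D >= 0, na.rm = TRUE), length(thresholds) >= 1,
              !is.unsorted(thresholds, strictly = TRUE))
    curves <- vapply(thresholds, function(t) rowMeans(D >= t, na.rm = TRUE),
                     numeric(nrow(D)))
    curves <- matrix(curves, nrow = nrow(D),
                     dimnames = list(rownames(D), paste0("ge", thresholds)))
    atReport <- rowMeans(D >= reportAt, na.rm = TRUE)
    list(curves = curves, thresholds = thresholds,
         perSampleMean = rowMeans(D, na.rm = TRUE),
         perSampleSD = apply(D, 1, stats::sd, na.rm = TRUE),
         grandMean = mean(D, na.rm = TRUE),
         grandSD = stats::sd(as.vector(D), na.rm = TRUE),
         nSamplesAbove = sum(atReport > reportProp))
}

panelPositions <- function(panel) {
    if (is(panel, "PanelSelection"))
        return(panel@markers[, c("chrom", "pos")])
    stopifnot(all(c("chrom", "pos") %in% colnames(panel)))
    panel[, c("chrom", "pos")]
}

#' Classify called SNPs relative to a target panel
#'
#' Called SNPs absent from the panel are assigned the distance (bp) to the
#' nearest panel target on the same chromosome (infinite when the
#' chromosome carries no target) and classified near/far at `nearBp`
#' (inclusive). Far SNPs are grouped into clusters whenever consecutive
#' far SNPs on a chromosome are at most `clusterGap` apart; the fraction
#' of non-target SNPs with MAF below `mafCut` is also reported.
#'
#' @param dsCalled a [GenotypeDataset-class] of called SNPs.
#' @param panel a [PanelSelection-class] or data.frame with chrom, pos.
#' @param nearBp near/far boundary (bp, inclusive).
#' @param mafCut MAF threshold for the low-MAF fraction.
#' @param clusterGap maximum within-cluster gap between far SNPs (bp).
#' @return list with `table` (per non-target SNP: key, chrom, pos,
#'   distance, class, maf), `nNear`, `nFar`, `fracNear`, `clusters`
#'   (chrom, start, end, n), `fracLowMaf`, `nTargets` (called SNPs that
#'   are panel targets).
#' @export
classifyOfftarget <- function(dsCalled, panel, nearBp = 150,
                              mafCut = 0.05, clusterGap = 10000) {
    pp <- panelPositions(panel)
    if (!nrow(pp)) stop("empty panel")
    mi <- markerInfo(dsCalled)
    key <- paste(mi$chrom, mi$pos, sep = ":")
    pkey <- paste(pp$chrom, pp$pos, sep = ":")
    isTarget <- key %in% pkey
    off <- which(!isTarget)
    dist <- rep(Inf, length(off))
    for (ch in unique(mi$chrom[off])) {
        tpos <- sort(pp$pos[pp$chrom == ch])
        sel <- which(mi$chrom[off] == ch)
        if (!length(tpos)) next
        opos <- mi$pos[off[sel]]
        idx <- findInterval(opos, tpos)
        lo <- ifelse(idx >= 1, abs(opos - tpos[pmax(idx, 1)]), Inf)
        hi <- ifelse(idx < length(tpos),
                     abs(tpos[pmin(idx + 1, length(tpos))] - opos), Inf)
        dist[sel] <- pmin(lo, hi)
    }
    cls <- ifelse(dist <= nearBp, "near", "far")
    maf <- mafOf(dosages(dsCalled))[off]
    tab <- data.frame(key = key[off], chrom = mi$chrom[off],
                      pos = mi$pos[off], distance = dist, class = cls,
                      maf = maf, row.names = NULL, stringsAsFactors = FALSE)
    farTab <- tab[tab$class == "far", , drop = FALSE]
    clusters <- list()
    for (ch in unique(farTab$chrom)) {
        p <- sort(farTab$pos[farTab$chrom == ch])
        grp <- cumsum(c(1, diff(p) > clusterGap))
        for (gidx in unique(grp)) {
            pg <- p[grp == gidx]
            clusters[[length(clusters) + 1L]] <-
                data.frame(chrom = ch, start = min(pg), end = max(pg),
                           n = length(pg))
        }
    }
    clusters <- if (length(clusters)) do.call(rbind, clusters) else
        data.frame(chrom = character(), start = integer(),
                   end = integer(), n = integer())
    list(table = tab,
         nNear = sum(cls == "near"), nFar = sum(cls == "far"),
         fracNear = if (nrow(tab)) mean(cls == "near") else NaN,
         clusters = clusters,
         fracLowMaf = if (nrow(tab)) mean(maf < mafCut, na.rm = TRUE)
                      else NaN,
         nTargets = sum(isTarget))
}

#' Screen named loci for genotype class counts
#'
#' For each requested locus, counts of hom-ref / het / hom-alt / missing
#' genotypes across samples; loci absent from the dataset are reported as
#' not assayed.
#'
#' @param ds a [GenotypeDataset-class].
#' @param loci data.frame with columns chrom, pos and optionally label.
#' @return data.frame: label, chrom, pos, assayed, hom_ref, het, hom_alt,
#'   missing (counts partition the samples for assayed loci).
#' @export
screenLoci <- function(ds, loci) {
    stopifnot(all(c("chrom", "pos") %in% colnames(loci)))
    label <- loci$label %||% paste(loci$chrom, loci$pos, sep = ":")
    keys <- markerKeys(ds)
    G <- dosages(ds)
    out <- lapply(seq_len(nrow(loci)), function(i) {
        k <- paste(loci$chrom[i], loci$pos[i], sep = ":")
        j <- match(k, keys)
        if (is.na(j))
            return(data.frame(label = label[i], chrom = loci$chrom[i],
                              pos = loci$pos[i], assayed = FALSE,
                              hom_ref = NA_integer_, het = NA_integer_,
                              hom_alt = NA_integer_,
                              missing = NA_integer_))
        g <- G[, j]
        data.frame(label = label[i], chrom = loci$chrom[i],
                   pos = loci$pos[i], assayed = TRUE,
                   hom_ref = sum(g == 0, na.rm = TRUE),
                   het = sum(g == 1, na.rm = TRUE),
                   hom_alt = sum(g == 2, na.rm = TRUE),
                   missing = sum(is.na(g)))
    })
    do.call(rbind, out)
}
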