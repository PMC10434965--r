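#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays assayNames colData<-
NULL

#' Container for diploid biallelic SNP genotypes
#'
#' `GenotypeDataset` extends `RangedSummarizedExperiment`: rows are markers
#' (a `GRanges` of width-1 SNP positions carrying REF/ALT alleles), columns
#' are samples, and the `"dosage"` assay counts ALT alleles per genotype
#' (0, 1, 2 or `NA` for missing). Optional `"DP"` and `"GQ"` assays hold
#' per-genotype sequencing depth and genotype quality. An optional
#' `population` column in `colData` carries a-priori source-population
#' labels.
#'
#' Coordinates are 1-based inclusive throughout (VCF convention); markers
#' are kept sorted by chromosome then position and (chrom, pos) pairs are
#' unique.
#'
#' @export
setClass("GenotypeDataset", contains = "RangedSummarizedExperiment")

validGenotypeDataset <- function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    rr <- rowRanges(object)
    if (length(rr)) {
        if (any(start(rr) < 1L))
            msg <- c(msg, "marker positions must be >= 1")
        key <- paste(as.character(seqnames(rr)), start(rr))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (chrom, pos) marker coordinates")
        ord <- order(as.integer(seqnames(rr)), start(rr))
        if (!identical(ord, seq_along(rr)))
            msg <- c(msg, "markers must be sorted by chromosome then position")
        if (!all(c("ref", "alt") %in% colnames(mcols(rr))))
            msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
    }
    d <- assay(object, "dosage")
    if (!all(d[!is.na(d)] %in% 0:2))
        msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    for (nm in c("DP", "GQ")) {
        if (nm %in% assayNames(object)) {
            a <- assay(object, nm)
            if (any(a[!is.na(a)] < 0))
                msg <- c(msg, paste0(nm, " must be non-negative"))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeDataset", validGenotypeDataset)

#' Construct a GenotypeDataset from plain matrices
#'
#' @param dosage numeric matrix, samples x markers, entries in
#'   \{0, 1, 2, NA\} counting ALT alleles.
#' @param chrom,pos,ref,alt per-marker chromosome, 1-based position and
#'   REF/ALT alleles.
#' @param id optional per-marker identifier (defaults to `chrom_pos`).
#' @param samples sample identifiers (defaults to rownames of `dosage`).
#' @param population optional per-sample population label.
#' @param DP,GQ optional samples x markers depth and genotype-quality
#'   matrices.
#' @return A [GenotypeDataset-class] object with markers sorted by
#'   chromosome then position.
#' @examples
#' g <- matrix(c(0, 1, 2, 0), nrow = 2,
#'             dimnames = list(c("s1", "s2"), NULL))
#' ds <- GenotypeDataset(g, chrom = c("1", "1"), pos = c(100, 200),
#'                       ref = c("A", "C"), alt = c("G", "T"))
#' nMarkers(ds)
#' @export
GenotypeDataset <- function(dosage, chrom, pos, ref, alt, id = NULL,
                            samples = rownames(dosage), population = NULL,
                            DP = NULL, GQ = NULL) {
    dosage <- as.matrix(dosage)
    m <- ncol(dosage)
    n <- nrow(dosage)
    if (is.null(samples))
        samples <- paste0("S", seq_len(n))
    stopifnot(length(chrom) == m, length(pos) == m,
              length(ref) == m, length(alt) == m,
              !anyDuplicated(samples))
    chrom <- as.character(chrom)
    if (is.null(id))
        id <- paste(chrom, pos, sep = "_")
    # order markers by chromosome (order of first appearance) then position
    lev <- unique(chrom)
    ord <- order(match(chrom, lev), pos)
    reord <- function(M) if (is.null(M)) NULL else as.matrix(M)[, ord, drop = FALSE]
    dosage <- reord(dosage)
    rr <- GRanges(factor(chrom[ord], levels = lev),
                  IRanges(start = pos[ord], width = 1L))
    mcols(rr) <- DataFrame(ref = as.character(ref)[ord],
                           alt = as.character(alt)[ord],
                           id = as.character(id)[ord])
    names(rr) <- mcols(rr)$id
    assays <- list(dosage = t(dosage))
    if (!is.null(DP)) assays$DP <- t(reord(DP))
    if (!is.null(GQ)) assays$GQ <- t(reord(GQ))
    assays <- lapply(assays, function(a) {
        dimnames(a) <- list(names(rr), samples)
        a
    })
    cd <- DataFrame(row.names = samples)
    if (!is.null(population))
        cd$population <- as.character(population)
    se <- SummarizedExperiment(assays = assays, rowRanges = rr, colData = cd)
    new("GenotypeDataset", se)
}

#' @describeIn GenotypeDataset Number of markers (rows).
#' @param x,object a `GenotypeDataset`.
#' @export
nMarkers <- function(x) nrow(x)

#' @describeIn GenotypeDataset Number of samples (columns).
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeDataset Sample identifiers.
#' @export
sampleIDs <- function(x) colnames(x)

#' @describeIn GenotypeDataset Dosage matrix, samples x markers, NA =
#'   missing.
#' @export
dosages <- function(x) t(assay(x, "dosage"))

#' @describeIn GenotypeDataset Per-genotype depth matrix (samples x
#'   markers) or NULL.
#' @export
depthMatrix <- function(x)
    if ("DP" %in% assayNames(x)) t(assay(x, "DP")) else NULL

#' @describeIn GenotypeDataset Per-genotype quality matrix (samples x
#'   markers) or NULL.
#' @export
qualMatrix <- function(x)
    if ("GQ" %in% assayNames(x)) t(assay(x, "GQ")) else NULL

#' @describeIn GenotypeDataset Per-sample population labels (or NULL when
#'   unset).
#' @export
popLabels <- function(x) {
    cd <- colData(x)
    if ("population" %in% colnames(cd)) as.character(cd$population) else NULL
}

#' @describeIn GenotypeDataset Assign per-sample population labels.
#' @param value character vector of labels, one per sample.
#' @export
`popLabels<-` <- function(x, value) {
    stopifnot(length(value) == ncol(x))
    colData(x)$population <- as.character(value)
    x
}

#' @describeIn GenotypeDataset Marker table: chrom, pos, ref, alt, id.
#' @export
markerInfo <- function(x) {
    rr <- rowRanges(x)
    data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
               ref = mcols(rr)$ref, alt = mcols(rr)$alt, id = mcols(rr)$id,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn GenotypeDataset `"chrom:pos"` keys identifying each marker.
#' @export
markerKeys <- function(x) {
    rr <- rowRanges(x)
    paste(as.character(seqnames(rr)), start(rr), sep = ":")
}

setMethod("show", "GenotypeDataset", function(object) {
    cat("GenotypeDataset:", nrow(object), "markers x", ncol(object),
        "samples\n")
    d <- assay(object, "dosage")
    cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(d))))
    pops <- popLabels(object)
    if (!is.null(pops)) {
        tab <- table(pops)
        cat("  populations:",
            paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
            "\n")
    }
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})
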