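#' @importFrom Biostrings readDNAStringSet subseq DNAStringSet
NULL

#' A reduced SNP panel selected from discriminant contributions
#'
#' @slot markers data.frame of the selected markers: key (`chrom:pos`),
#'   chrom, pos, and per-axis contribution.
#' @slot axes indices of the discriminant axes used.
#' @slot percentile the percentile cut applied per axis.
#' @slot thresholds per-axis contribution values at the cut.
#' @slot excludedChroms chromosomes excluded from the panel.
#' @slot nExcluded markers dropped by the chromosome exclusion after
#'   selection.
#' @export
setClass("PanelSelection", representation(
    markers = "data.frame", axes = "integer", percentile = "numeric",
    thresholds = "numeric", excludedChroms = "character",
    nExcluded = "integer"))

setMethod("show", "PanelSelection", function(object) {
    cat("PanelSelection:", nrow(object@markers), "markers from",
        length(object@axes), "discriminant axes at the",
        paste0(object@percentile, "th"), "percentile\n")
    if (object@nExcluded > 0)
        cat("  excluded", object@nExcluded, "marker(s) on chromosome(s):",
            paste(object@excludedChroms, collapse = ", "), "\n")
    tab <- table(object@markers$chrom)
    cat("  chromosomes represented:", length(tab), "\n")
})

#' @describeIn selectPanel Selected marker keys (`chrom:pos`).
#' @export
panelKeys <- function(panel) panel@markers$key

# Upper-tail percentile selection: the top ceil((1 - p/100) * m) values,
# with ties at the boundary value all included.
topTailSelect <- function(values, percentile) {
    m <- length(values)
    # small epsilon guards the ceiling against floating-point drift
    # (e.g. (1 - 95/100) * 100 = 5.000000000000004)
    k <- ceiling(m * (100 - percentile) / 100 - 1e-9)
    if (k == 0) return(list(sel = logical(m), threshold = Inf))
    thr <- sort(values, decreasing = TRUE)[k]
    list(sel = values >= thr, threshold = thr)
}

#' Select panel markers from DAPC discriminant contributions
#'
#' For each of the first `nAxes` discriminant axes the per-marker
#' contributions (normalized squared loadings) are cut at the given
#' percentile of their empirical distribution: the top
#' ceil((1 - percentile/100) x markers) contributions per axis are
#' selected, ties at the boundary included. A marker enters the panel if
#' selected on any used axis (union; a pooled single-threshold mode is
#' available). Markers on excluded chromosomes are dropped after selection
#' and counted.
#'
#' @param model a [DAPCModel-class].
#' @param percentile percentile cut in (0, 100).
#' @param nAxes number of leading discriminant axes to use.
#' @param excludeChroms chromosomes to exclude (default mitochondrial).
#' @param pooled if TRUE, one threshold is taken on the pooled
#'   contributions of all used axes instead of per axis.
#' @param panel a `PanelSelection` (for the accessors documented here).
#' @return A [PanelSelection-class].
#' @export
selectPanel <- function(model, percentile = 95, nAxes = 2,
                        excludeChroms = "MT", pooled = FALSE) {
    stopifnot(is(model, "DAPCModel"))
    if (percentile <= 0 || percentile >= 100)
        stop("percentile must be inside (0, 100)")
    D <- ncol(model@contributions)
    if (nAxes > D)
        stop("model has only ", D, " discriminant axes")
    C <- model@contributions[, seq_len(nAxes), drop = FALSE]
    m <- nrow(C)
    if (pooled) {
        cut <- topTailSelect(as.vector(C), percentile)
        sel <- rowSums(C >= cut$threshold) > 0
        thresholds <- rep(cut$threshold, nAxes)
    } else {
        sel <- logical(m)
        thresholds <- numeric(nAxes)
        for (d in seq_len(nAxes)) {
            cut <- topTailSelect(C[, d], percentile)
            sel <- sel | cut$sel
            thresholds[d] <- cut$threshold
        }
    }
    keys <- model@pca@markerKeys
    parts <- strsplit(keys, ":", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- as.integer(vapply(parts, `[`, "", 2L))
    onExcluded <- chrom %in% excludeChroms
    nExcluded <- sum(sel & onExcluded)
    keep <- which(sel & !onExcluded)
    markers <- data.frame(key = keys[keep], chrom = chrom[keep],
                          pos = pos[keep], stringsAsFactors = FALSE)
    markers <- cbind(markers,
                     stats::setNames(as.data.frame(C[keep, , drop = FALSE]),
                                     paste0("contrib_LD",
                                            seq_len(nAxes))))
    rownames(markers) <- NULL
    new("PanelSelection", markers = markers,
        axes = seq_len(nAxes), percentile = percentile,
        thresholds = thresholds,
        excludedChroms = as.character(excludeChroms),
        nExcluded = as.integer(nExcluded))
}

#' Summarize a panel and derive capture-probe intervals
#'
#' Probe intervals are 1-based inclusive, centered on the SNP with the SNP
#' at base probeLength/2 + 1 of the probe (the 61st base of a 120-mer):
#' [pos - probeLength/2, pos + probeLength/2 - 1]. Intervals extending
#' below position 1 are clipped and flagged. Per-chromosome marker counts
#' and the mean/SD of counts over the declared autosome set are reported;
#' when a reference FASTA is supplied, probe sequences are extracted
#' (uppercase) and flagged if they contain N or a homopolymer run of 15 or
#' more bases.
#'
#' @param panel a [PanelSelection-class].
#' @param probeLength probe length in bases.
#' @param fasta optional reference FASTA covering all panel chromosomes.
#' @param autosomes chromosome names making up the declared autosome set
#'   for the mean/SD summary.
#' @return list with `probes` (data.frame: key, chrom, start, end,
#'   clipped, and sequence/flag columns when fasta is given),
#'   `perChromosome` (data.frame: chrom, n), `autosomeMean`, `autosomeSD`,
#'   and `nMarkers`.
#' @export
summarizePanel <- function(panel, probeLength = 120, fasta = NULL,
                           autosomes = as.character(1:19)) {
    stopifnot(is(panel, "PanelSelection"), probeLength >= 1)
    mk <- panel@markers
    half <- floor(probeLength / 2)
    start <- mk$pos - half
    end <- start + probeLength - 1L
    clipped <- start < 1L
    start <- pmax(start, 1L)
    probes <- data.frame(key = mk$key, chrom = mk$chrom, start = start,
                         end = end, clipped = clipped,
                         stringsAsFactors = FALSE)
    if (!is.null(fasta)) {
        ref <- Biostrings::readDNAStringSet(fasta)
        names(ref) <- sub("\\s.*$", "", names(ref))
        missing <- setdiff(unique(mk$chrom), names(ref))
        if (length(missing))
            stop("FASTA lacks chromosome(s): ",
                 paste(missing, collapse = ", "))
        seqs <- toupper(vapply(seq_len(nrow(probes)), function(i) {
            as.character(Biostrings::subseq(ref[[probes$chrom[i]]],
                                            probes$start[i],
                                            min(probes$end[i],
                                                length(ref[[probes$chrom[i]]]))))
        }, ""))
        probes$sequence <- seqs
        probes$has_n <- grepl("N", seqs, fixed = TRUE)
        probes$homopolymer <- grepl("A{15,}|C{15,}|G{15,}|T{15,}", seqs)
    }
    allChroms <- unique(c(autosomes, unique(mk$chrom)))
    counts <- vapply(allChroms, function(ch) sum(mk$chrom == ch), 0L)
    perChrom <- data.frame(chrom = allChroms, n = unname(counts),
                           stringsAsFactors = FALSE)
    autoN <- perChrom$n[perChrom$chrom %in% autosomes]
    list(probes = probes, perChromosome = perChrom,
         autosomeMean = mean(autoN), autosomeSD = stats::sd(autoN),
         nMarkers = nrow(mk))
}

#' Write probe intervals as BED (0-based half-open)
#'
#' Internal 1-based inclusive intervals [start, end] become BED rows
#' `chrom  start-1  end  key`.
#'
#' @param summary result of [summarizePanel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
panelToBed <- function(summary, path) {
    pr <- summary$probes
    utils::write.table(data.frame(pr$chrom, pr$start - 1L, pr$end, pr$key),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the selected-marker table as TSV
#'
#' @param panel a [PanelSelection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanelTable <- function(panel, path) {
    utils::write.table(panel@markers, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
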