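#' @importFrom vcfR read.vcfR getFIX extract.gt
#' @importFrom utils read.table write.table
NULL

GT_DOSAGE <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)

#' Write a GenotypeDataset as plain-text VCF 4.2
#'
#' Emits GT (and DP/GQ when the dataset carries them) per genotype; missing
#' genotypes are encoded `./.`. Output is uncompressed text.
#'
#' @param ds a [GenotypeDataset-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(ds, path) {
    stopifnot(is(ds, "GenotypeDataset"))
    G <- dosages(ds)
    DP <- depthMatrix(ds)
    GQ <- qualMatrix(ds)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=panelforge",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"))
    fmt <- "GT"
    if (!is.null(DP)) {
        hdr <- c(hdr, paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                             "Description=\"Read depth\">"))
        fmt <- paste0(fmt, ":DP")
    }
    if (!is.null(GQ)) {
        hdr <- c(hdr, paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                             "Description=\"Genotype quality\">"))
        fmt <- paste0(fmt, ":GQ")
    }
    hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", sampleIDs(ds)),
                        collapse = "\t"))
    mi <- markerInfo(ds)
    gtChar <- c("0/0", "0/1", "1/1")
    lines <- hdr
    if (nMarkers(ds) > 0) {
        cells <- matrix(ifelse(is.na(G), "./.", gtChar[G + 1L]),
                        nrow = nrow(G))
        if (!is.null(DP))
            cells <- matrix(paste(cells, ifelse(is.na(DP), ".", DP),
                                  sep = ":"), nrow = nrow(G))
        if (!is.null(GQ))
            cells <- matrix(paste(cells, ifelse(is.na(GQ), ".", GQ),
                                  sep = ":"), nrow = nrow(G))
        body <- vapply(seq_len(nMarkers(ds)), function(j) {
            paste(c(mi$chrom[j], mi$pos[j], mi$id[j], mi$ref[j], mi$alt[j],
                    ".", "PASS", ".", fmt, cells[, j]), collapse = "\t")
        }, "")
        lines <- c(lines, body)
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a VCF into a GenotypeDataset
#'
#' Biallelic SNP records become dosage columns (phase is ignored;
#' half-missing genotypes are treated as missing). Sites with more than two
#' observed alleles are excluded from the dosage matrix and reported in
#' `multiallelicRecords()`; indel/non-SNP records are skipped and reported
#' in `skippedRecords()`. DP and GQ are loaded when present in FORMAT.
#'
#' @param path a VCF file (plain or gzip; parsed with vcfR).
#' @return A [GenotypeDataset-class]; excluded-site reports are stored in
#'   its metadata.
#' @export
readVcfGenotypes <- function(path) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(getFIX(vcf), stringsAsFactors = FALSE)
    n_rec <- nrow(fix)
    if (n_rec == 0) {
        samples <- colnames(vcf@gt)[-1] %||% character()
        ds <- GenotypeDataset(matrix(NA_integer_, length(samples), 0,
                                     dimnames = list(samples, NULL)),
                              chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              samples = samples)
        metadata(ds)$multiallelic <- emptyMultiallelic()
        metadata(ds)$skipped <- emptySkipLog()
        return(ds)
    }
    fix$POS <- as.integer(fix$POS)
    for (ch in unique(fix$CHROM)) {
        p <- fix$POS[fix$CHROM == ch]
        if (is.unsorted(p, strictly = FALSE))
            stop("non-monotone positions on chromosome ", ch,
                 " (first offending record at position ",
                 p[which(diff(p) < 0)[1] + 1L], ")")
    }
    gtRaw <- vcfR::extract.gt(vcf, element = "GT")
    gtNorm <- gsub("|", "/", gtRaw, fixed = TRUE)

    multi <- grepl(",", fix$ALT, fixed = TRUE)
    isSnp <- !multi & nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
        fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
    skip <- !multi & !isSnp

    # carriers of any non-reference allele at multiallelic sites
    carriers <- if (any(multi)) {
        apply(gtNorm[multi, , drop = FALSE], 1, function(g) {
            al <- unlist(strsplit(g[!is.na(g)], "/", fixed = TRUE))
            sum(vapply(strsplit(g[!is.na(g)], "/", fixed = TRUE),
                       function(a) any(a != "0" & a != "."), NA))
        })
    } else integer()
    multiRec <- data.frame(chrom = fix$CHROM[multi], pos = fix$POS[multi],
                           ref = fix$REF[multi], alt = fix$ALT[multi],
                           n_alleles = 1L +
                               vapply(strsplit(fix$ALT[multi], ","),
                                      length, 0L),
                           n_carriers = as.integer(carriers),
                           stringsAsFactors = FALSE)
    skipRec <- data.frame(chrom = fix$CHROM[skip], pos = fix$POS[skip],
                          ref = fix$REF[skip], alt = fix$ALT[skip],
                          reason = rep("not a biallelic SNP", sum(skip)),
                          stringsAsFactors = FALSE)

    keep <- which(isSnp)
    gt <- gtNorm[keep, , drop = FALSE]
    G <- matrix(GT_DOSAGE[gt], nrow = length(keep),
                dimnames = dimnames(gt))
    grab <- function(el) {
        fmt <- vcf@gt[, "FORMAT"]
        if (!any(grepl(paste0("(^|:)", el, "(:|$)"), fmt))) return(NULL)
        M <- vcfR::extract.gt(vcf, element = el, as.numeric = TRUE)
        t(M[keep, , drop = FALSE])
    }
    ids <- fix$ID[keep]
    ids[is.na(ids) | ids == "."] <-
        paste(fix$CHROM[keep], fix$POS[keep], sep = "_")[is.na(ids) | ids == "."]
    ds <- GenotypeDataset(t(G), chrom = fix$CHROM[keep], pos = fix$POS[keep],
                          ref = fix$REF[keep], alt = fix$ALT[keep],
                          id = ids, samples = colnames(gt),
                          DP = grab("DP"), GQ = grab("GQ"))
    metadata(ds)$multiallelic <- multiRec
    metadata(ds)$skipped <- skipRec
    ds
}

emptyMultiallelic <- function()
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), n_alleles = integer(),
               n_carriers = integer(), stringsAsFactors = FALSE)

emptySkipLog <- function()
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), reason = character(),
               stringsAsFactors = FALSE)

#' @describeIn readVcfGenotypes Sites excluded for showing more than two
#'   alleles, with carrier counts.
#' @param ds a [GenotypeDataset-class] returned by `readVcfGenotypes()`.
#' @export
multiallelicRecords <- function(ds)
    metadata(ds)$multiallelic %||% emptyMultiallelic()

#' @describeIn readVcfGenotypes Non-SNP records skipped at load time.
#' @export
skippedRecords <- function(ds)
    metadata(ds)$skipped %||% emptySkipLog()

#' Attach a-priori population labels from a two-column TSV
#'
#' The file must contain exactly one `sample_id <TAB> population` row for
#' every dataset sample; extra, missing or duplicated samples are errors.
#'
#' @param path tab-separated file with two columns (no header).
#' @param ds a [GenotypeDataset-class].
#' @return `ds` with population labels attached.
#' @export
readPopLabels <- function(path, ds) {
    stopifnot(is(ds, "GenotypeDataset"))
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("sample_id", "population"))
    dup <- unique(tab$sample_id[duplicated(tab$sample_id)])
    if (length(dup))
        stop("duplicate label rows for sample(s): ",
             paste(dup, collapse = ", "))
    extra <- setdiff(tab$sample_id, sampleIDs(ds))
    if (length(extra))
        stop("label file sample(s) absent from dataset: ",
             paste(extra, collapse = ", "))
    missing <- setdiff(sampleIDs(ds), tab$sample_id)
    if (length(missing))
        stop("dataset sample(s) absent from label file: ",
             paste(missing, collapse = ", "))
    popLabels(ds) <- tab$population[match(sampleIDs(ds), tab$sample_id)]
    ds
}

#' Write per-sample population labels as a two-column TSV
#'
#' @param ds a labelled [GenotypeDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePopLabels <- function(ds, path) {
    pops <- popLabels(ds)
    if (is.null(pops)) stop("dataset carries no population labels")
    utils::write.table(data.frame(sampleIDs(ds), pops),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a pedigree kinship truth table as TSV
#'
#' @param truth data.frame with columns sample_a, sample_b, kinship, degree
#'   (as produced by [simPedigree()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
    stopifnot(all(c("sample_a", "sample_b", "kinship", "degree") %in%
                  colnames(truth)))
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
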