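#' @importFrom jsonlite write_json
NULL

#' Assemble and validate an end-to-end run configuration
#'
#' Collects every stage's parameters (defaults mirror the workflow's
#' standard settings) plus input paths, output directory and master seed.
#' When no input VCF is given the synthetic-data stage generates the input
#' with `sim` (a [simConfig()]).
#'
#' @param vcf,labels optional input VCF and two-column population-label
#'   TSV; both NULL means simulate.
#' @param sim a [simConfig()] used when simulating.
#' @param pedigree optional family-design list (see [simPedigree()]); when
#'   given, each simulated population embeds these pedigree units (founder
#'   frequencies drawn per population under the drift model) and the truth
#'   table is written alongside the input.
#' @param qc list: maxSampleMiss, maxMarkerMiss, minMaf, ldWindowBp,
#'   ldStep, ldR2, useQualityMask, minGq, minMeanDp.
#' @param dapc list: kGrid (NULL = default grid), fixedK (skip
#'   cross-validation and use this K), nRep, trainFrac.
#' @param panel list: percentile, nAxes, excludeChroms, probeLength.
#' @param kinship list: nPcs, thresholds.
#' @param outDir output directory (created).
#' @param seed master integer seed.
#' @return validated config list of class `"RunConfig"`.
#' @export
pipelineConfig <- function(vcf = NULL, labels = NULL,
                           sim = simConfig(), pedigree = NULL,
                           qc = list(), dapc = list(), panel = list(),
                           kinship = list(),
                           outDir = tempfile("panelforge_run_"),
                           seed = 1L) {
    qc <- utils::modifyList(list(maxSampleMiss = 0.10, maxMarkerMiss = 0.10,
                                 minMaf = 0.05, ldWindowBp = 1000,
                                 ldStep = 1, ldR2 = 0.5,
                                 useQualityMask = FALSE, minGq = 30,
                                 minMeanDp = 10), qc)
    dapc <- utils::modifyList(list(kGrid = NULL, fixedK = NULL,
                                   nRep = 100, trainFrac = 0.9), dapc)
    panel <- utils::modifyList(list(percentile = 95, nAxes = 2,
                                    excludeChroms = "MT",
                                    probeLength = 120), panel)
    kinship <- utils::modifyList(list(nPcs = 2,
                                      thresholds = c(2^-2.5, 2^-3.5,
                                                     2^-4.5)), kinship)
    cfg <- list(vcf = vcf, labels = labels, sim = sim,
                pedigree = pedigree, qc = qc,
                dapc = dapc, panel = panel, kinship = kinship,
                outDir = outDir, seed = as.integer(seed))
    class(cfg) <- "RunConfig"
    cfg
}

stageMsg <- function(...) message("[panelforge] ", ...)

#' Run the chip-to-panel workflow end to end
#'
#' Stages, in fixed order: obtain genotypes (load VCF + labels, or
#' simulate), QC (sample/marker missingness, MAF, optional quality mask,
#' LD pruning), DAPC with cross-validated choice of PC count, panel
#' selection from discriminant contributions, restriction of the genotypes
#' to the panel, re-assignment and kinship on the reduced panel, and
#' comparison of full-set versus panel kinship. All intermediate artifacts
#' are written under `outDir` and listed in the returned manifest, which
#' together with the parameter echo and seed reproduces the run exactly.
#'
#' @param config a [pipelineConfig()].
#' @return the run manifest (named list), invisibly written as
#'   `manifest.json` in `outDir`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)
    manifest <- list(package = "panelforge",
                     version = as.character(utils::packageVersion("panelforge")),
                     seed = config$seed,
                     parameters = config[c("qc", "dapc", "panel",
                                           "kinship")],
                     outputs = list())
    addOut <- function(name, path) {
        manifest$outputs[[name]] <<- basename(path)
        path
    }

    if (!is.null(config$vcf)) {
        stageMsg("loading ", config$vcf)
        ds <- readVcfGenotypes(config$vcf)
        if (!is.null(config$labels))
            ds <- readPopLabels(config$labels, ds)
    } else {
        stageMsg("simulating input dataset")
        sim <- config$sim
        sim$seed <- sim$seed %||% config$seed
        freqs <- simStructuredFreqs(sim)
        if (is.null(config$pedigree)) {
            ds <- simGenotypes(freqs, sim)
        } else {
            ds <- NULL
            markers <- NULL
            truth <- NULL
            for (k in seq_len(sim$nPops)) {
                pk <- simPedigree(freqs$freqs[k, ], config$pedigree,
                                  seed = sim$seed + 10L + k,
                                  prefix = paste0("pop", k),
                                  population = paste0("pop", k),
                                  markers = markers)
                markers <- markerInfo(pk$dataset)
                ds <- if (is.null(ds)) pk$dataset else
                    bindSamples(ds, pk$dataset)
                truth <- rbind(truth, pk$truth)
            }
            writeTruthTable(truth, addOut("truth", out("truth.tsv")))
        }
        if (sim$missRate > 0 || sim$errorRate > 0)
            ds <- corruptGenotypes(ds, sim$missRate, sim$errorRate,
                                   seed = sim$seed + 2L)
        writeVcfGenotypes(ds, addOut("input_vcf", out("input.vcf")))
        writePopLabels(ds, addOut("labels", out("labels.tsv")))
    }
    if (is.null(popLabels(ds)))
        stop("stage qc: population labels are required downstream")

    stageMsg("qc: missingness")
    st <- filterMissingness(ds, config$qc$maxSampleMiss,
                            config$qc$maxMarkerMiss)
    reports <- list(missingness = st$report)
    stageMsg("qc: MAF")
    st <- filterMaf(st$dataset, config$qc$minMaf)
    reports$maf <- st$report
    if (isTRUE(config$qc$useQualityMask)) {
        stageMsg("qc: quality mask")
        st <- maskLowQuality(st$dataset, config$qc$minGq,
                             config$qc$minMeanDp, config$qc$maxMarkerMiss)
        reports$quality <- st$report
    }
    stageMsg("qc: LD pruning")
    st <- ldPrune(st$dataset, config$qc$ldWindowBp, config$qc$ldStep,
                  config$qc$ldR2)
    reports$ld <- st$report
    dsQc <- st$dataset
    writeVcfGenotypes(dsQc, addOut("qc_vcf", out("filtered.vcf")))
    qcTab <- do.call(rbind, lapply(reports, function(r)
        if (nrow(r@markersRemoved) == 0) NULL else
        data.frame(stage = r@stage, marker = r@markersRemoved$marker,
                   rule = r@markersRemoved$rule)))
    qcTab <- qcTab %||% data.frame(stage = character(),
                                   marker = character(),
                                   rule = character())
    utils::write.table(qcTab, addOut("qc_report", out("qc_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    if (is.null(config$dapc$fixedK)) {
        stageMsg("DAPC cross-validation")
        xval <- crossvalidateDapc(dsQc, kGrid = config$dapc$kGrid,
                                  nRep = config$dapc$nRep,
                                  trainFrac = config$dapc$trainFrac,
                                  seed = config$seed)
        K <- chosenK(xval)
        utils::write.table(
            data.frame(K = xval@kGrid, mean_success = xval@meanSuccess,
                       rmse = xval@rmse),
            addOut("xval_report", out("xval_report.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$chosenK <- K
        manifest$xvalMeanSuccess <- successAtChosenK(xval)
    } else {
        K <- config$dapc$fixedK
        manifest$chosenK <- K
    }
    stageMsg("DAPC fit at K = ", K)
    model <- fitDapc(dsQc, K)
    pred <- predictDapc(model, dsQc)
    assign <- data.frame(sample = sampleIDs(dsQc),
                         population = popLabels(dsQc),
                         assigned = unname(pred$assigned),
                         round(pred$posterior, 6))
    utils::write.table(assign,
                       addOut("assignments", out("assignments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stageMsg("panel selection")
    pan <- selectPanel(model, config$panel$percentile, config$panel$nAxes,
                       config$panel$excludeChroms)
    writePanelTable(pan, addOut("panel_table", out("panel.tsv")))
    panSum <- summarizePanel(pan, config$panel$probeLength)
    panelToBed(panSum, addOut("panel_bed", out("panel.bed")))
    manifest$panelSize <- nrow(pan@markers)

    stageMsg("restricting genotypes to the panel")
    dsPanel <- dsQc[markerKeys(dsQc) %in% panelKeys(pan), ]
    writeVcfGenotypes(dsPanel, addOut("panel_vcf", out("panel.vcf")))

    stageMsg("panel-based assignment")
    modelPanel <- fitDapc(dsPanel, min(K, nSamples(dsPanel) - 2L,
                                       nMarkers(dsPanel) - 1L))
    predPanel <- predictDapc(modelPanel, dsPanel)
    manifest$panelSelfAssignment <-
        mean(predPanel$assigned == popLabels(dsPanel))

    stageMsg("kinship on full and panel marker sets")
    kinFull <- pcrelate(dsQc, config$kinship$nPcs)
    kinPanel <- pcrelate(dsPanel, config$kinship$nPcs)
    degFull <- classifyDegree(kinFull, config$kinship$thresholds)
    utils::write.table(degFull,
                       addOut("kinship_full", out("kinship_full.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    degPanel <- classifyDegree(kinPanel, config$kinship$thresholds)
    utils::write.table(degPanel,
                       addOut("kinship_panel", out("kinship_panel.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cmp <- compareKinship(kinFull, kinPanel)
    manifest$kinshipComparison <- cmp

    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stageMsg("done; manifest at ", out("manifest.json"))
    invisible(manifest)
}
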