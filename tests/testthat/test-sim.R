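test_that("Balding-Nichols frequencies have the model's moments", {
    # F = 0 degenerates to the ancestral frequency exactly
    cfg0 <- simConfig(nPops = 3, nMarkers = 50, fst = 0, seed = 1)
    fr0 <- simStructuredFreqs(cfg0)
    for (k in 1:3) expect_equal(fr0$freqs[k, ], fr0$ancestral)

    # near-fixation as F -> 1
    cfg99 <- simConfig(nPops = 1, nMarkers = 2000, fst = 0.999, seed = 2,
                       ancFreqRange = c(0.5, 0.5))
    fr99 <- simStructuredFreqs(cfg99)
    expect_gt(mean(fr99$freqs < 0.01 | fr99$freqs > 0.99), 0.95)

    # Var[freq] = F p (1 - p): 10,000 replicate draws at p = 0.5, F = 0.1
    cfgV <- simConfig(nPops = 1, nMarkers = 10000, fst = 0.1, seed = 3,
                      ancFreqRange = c(0.5, 0.5))
    frV <- simStructuredFreqs(cfgV)
    expect_equal(mean(frV$freqs), 0.5, tolerance = 0.01)
    expect_equal(var(as.vector(frV$freqs)), 0.1 * 0.25, tolerance = 0.05)

    expect_error(simConfig(fst = 1))
})

test_that("genotype draws follow Hardy-Weinberg and the target FST", {
    # empty marker set is valid
    cfgE <- simConfig(nPops = 1, nPerPop = 3, nMarkers = 0, seed = 1)
    dsE <- simGenotypes(simStructuredFreqs(cfgE), cfgE)
    expect_equal(nMarkers(dsE), 0L)

    # mean dosage 2p under HWE
    cfgH <- simConfig(nPops = 1, nPerPop = 300, nMarkers = 200, fst = 0,
                      ancFreqRange = c(0.5, 0.5), seed = 4)
    dsH <- simGenotypes(simStructuredFreqs(cfgH), cfgH)
    expect_equal(mean(dosages(dsH)), 1.0, tolerance = 0.02)

    # Hudson FST recovers the drift parameter
    cfgF <- simConfig(nPops = 2, nPerPop = 100, nMarkers = 2000, fst = 0.1,
                      seed = 5)
    dsF <- simGenotypes(simStructuredFreqs(cfgF), cfgF)
    G <- dosages(dsF)
    pops <- popLabels(dsF)
    fst <- hudsonFst(G[pops == "pop1", ], G[pops == "pop2", ])
    expect_equal(fst, 0.1, tolerance = 0.015)

    # positions strictly increasing within chromosome
    mi <- markerInfo(dsF)
    for (ch in unique(mi$chrom))
        expect_true(all(diff(mi$pos[mi$chrom == ch]) > 0))
})

test_that("LD blocks produce high within-block r2 that pruning removes", {
    cfg <- simConfig(nPops = 1, nPerPop = 120, nMarkers = 120, fst = 0,
                     ldBlockSize = 4, ldLeak = 0.02, seed = 6)
    ds <- simGenotypes(simStructuredFreqs(cfg), cfg)
    viol <- ldPruneAudit(ds, windowBp = 1000, r2Max = 0.5)
    expect_gt(nrow(viol), 10)     # blocks really are in LD
    pruned <- ldPrune(ds, windowBp = 1000, r2Max = 0.5)
    expect_equal(nrow(ldPruneAudit(pruned$dataset, 1000, 0.5)), 0L)
})

test_that("pedigree gene-dropping is Mendelian-consistent with a complete truth table", {
    res <- simPedigree(runif(300, 0.2, 0.8),
                       list(parentOffspring = 1, fullSib = 1, halfSib = 1,
                            cousin = 1, unrelated = 2), seed = 7)
    ds <- res$dataset
    ped <- res$pedigree
    G <- dosages(ds)
    # every child compatible with its parents at every marker
    transmissible <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
    for (i in which(!is.na(ped$sire))) {
        gs <- G[ped$sire[i], ]
        gd <- G[ped$dam[i], ]
        gc <- G[ped$id[i], ]
        ok <- vapply(seq_along(gc), function(s) {
            any(outer(transmissible[[as.character(gs[s])]],
                      transmissible[[as.character(gd[s])]], "+") == gc[s])
        }, NA)
        expect_true(all(ok))
    }
    # truth table: known samples, kinship values from the closed set
    expect_true(all(res$truth$sample_a %in% sampleIDs(ds)))
    expect_true(all(res$truth$sample_b %in% sampleIDs(ds)))
    expect_true(all(res$truth$kinship %in% c(0.25, 0.125, 0.0625, 0)))
    expect_false(any(duplicated(t(apply(res$truth[, 1:2], 1, sort)))))
    # expected coefficients per relationship class
    deg <- res$truth
    expect_true(all(deg$kinship[deg$degree == "1st"] == 0.25))
    expect_true(all(deg$kinship[deg$degree == "2nd"] == 0.125))
    expect_true(all(deg$kinship[deg$degree == "3rd"] == 0.0625))
    # full sibs realize ~0.25 allele-sharing kinship at 5,000 markers,
    # measured against the true founder frequencies (independent oracle)
    q <- runif(5000, 0.2, 0.8)
    sib <- simPedigree(q, list(fullSib = 3), seed = 8)
    G <- dosages(sib$dataset)
    R <- sweep(G, 2, 2 * q, "-")
    phi <- tcrossprod(R) / (4 * sum(q * (1 - q)))
    sibDyads <- subset(sib$truth, degree == "1st" &
                       grepl("_c", sample_a) & grepl("_c", sample_b))
    est <- mapply(function(a, b) phi[a, b],
                  sibDyads$sample_a, sibDyads$sample_b)
    expect_equal(length(est), 3L)
    expect_true(all(abs(est - 0.25) < 0.03))
})

test_that("cyclic pedigrees are rejected", {
    bad <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                      dam = c(NA, NA))
    expect_error(simPedigree(rep(0.5, 10), bad, seed = 1), "cyclic")
})

test_that("corruptGenotypes injects missingness and errors at the stated rates", {
    G <- matrix(sample(0:2, 10000, replace = TRUE), nrow = 50)
    rownames(G) <- paste0("s", 1:50)
    ds <- toyDataset(G, pos = seq_len(200) * 1000)
    # identity at zero rates
    expect_identical(dosages(corruptGenotypes(ds, 0, 0, seed = 1)),
                     dosages(ds))
    # everything missing at rate 1
    expect_true(all(is.na(dosages(corruptGenotypes(ds, 1, 0, seed = 1)))))
    # missing fraction within 3 binomial SDs of 0.1 on 10,000 genotypes
    out <- corruptGenotypes(ds, 0.1, 0, seed = 2)
    sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
    expect_lt(abs(mean(is.na(dosages(out))) - 0.1), sd3)
    # errors move genotypes to a different valid dosage
    err <- corruptGenotypes(ds, 0, 0.2, seed = 3)
    changed <- dosages(err) != G
    expect_equal(mean(changed), 0.2, tolerance = 3 * sqrt(0.2 * 0.8 / 1e4))
    expect_true(all(dosages(err)[changed] %in% 0:2))
    expect_true(all(dosages(err)[changed] != G[changed]))
})

test_that("sequencing artefacts match the requested depth regime", {
    G <- matrix(1, 40, 250, dimnames = list(paste0("s", 1:40), NULL))
    ds <- toyDataset(G, pos = seq_len(250) * 500)
    out <- simSeqArtifacts(ds, meanDepth = 27.6, depthDispersion = 11,
                           seed = 4)
    DP <- depthMatrix(out)
    expect_equal(mean(DP), 27.6, tolerance = 0.3)
    # dispersion: var = mu + mu^2 / size
    expect_equal(var(as.vector(DP)), 27.6 + 27.6^2 / 11, tolerance = 8)
    expect_true(all(qualMatrix(out) <= 99))
    expect_true(all(is.na(dosages(out)[DP == 0])))
    # zero depth leaves everything missing
    z <- simSeqArtifacts(ds, meanDepth = 0, seed = 5)
    expect_true(all(depthMatrix(z) == 0))
    expect_true(all(is.na(dosages(z))))
    expect_error(simSeqArtifacts(ds, depthDispersion = -1), "positive")
})

test_that("identical seed and config give byte-identical VCF output", {
    gen <- function() {
        cfg <- simConfig(nPops = 2, nPerPop = 10, nMarkers = 60, fst = 0.05,
                         missRate = 0.05, seed = 99)
        ds <- simGenotypes(simStructuredFreqs(cfg), cfg)
        ds <- corruptGenotypes(ds, cfg$missRate, cfg$errorRate, seed = 100)
        ds <- simSeqArtifacts(ds, cfg$meanDepth, cfg$depthDispersion,
                              seed = 101)
        f <- tempfile(fileext = ".vcf")
        writeVcfGenotypes(ds, f)
        f
    }
    f1 <- gen(); f2 <- gen()
    expect_identical(readLines(f1), readLines(f2))
    # and the global RNG stream is untouched by seeded generators
    set.seed(42); before <- runif(1)
    set.seed(42); invisible(gen()); after <- runif(1)
    expect_identical(before, after)
})
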