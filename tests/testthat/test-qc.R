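test_that("missingness filter removes samples first, then markers, inclusively", {
    # complete matrix: nothing removed
    G <- matrix(1, 4, 10, dimnames = list(paste0("s", 1:4), NULL))
    ds <- toyDataset(G)
    out <- filterMissingness(ds)
    expect_equal(nSamples(out$dataset), 4L)
    expect_equal(nMarkers(out$dataset), 10L)

    # a sample with exactly 10% missing is removed at the 0.10 threshold
    G2 <- G
    G2[1, 1] <- NA                       # 1/10 = 10% missing
    out2 <- filterMissingness(toyDataset(G2), 0.10, 0.10)
    expect_equal(samplesRemoved(out2$report)$sample_id, "s1")

    # brute-force enumeration on a hand-placed fixture (4 x 20: a single
    # missing genotype is 5% for a sample, 25% for a marker over 4 samples)
    set.seed(11)
    G3 <- matrix(sample(0:2, 80, replace = TRUE), 4, 20,
                 dimnames = list(paste0("s", 1:4), NULL))
    G3[2, c(1, 4, 6, 11)] <- NA          # s2: 20% missing -> removed
    G3[1, 7] <- NA                       # marker 7: 1/3 after s2 removed
    G3[4, 9] <- NA                       # marker 9: 1/3 -> removed
    out3 <- filterMissingness(toyDataset(G3), 0.10, 0.10)
    # oracle: recompute removals by direct enumeration
    sampMiss <- rowMeans(is.na(G3))
    expSamp <- names(which(sampMiss >= 0.10))
    expect_equal(expSamp, "s2")
    keep <- setdiff(rownames(G3), expSamp)
    markMiss <- colMeans(is.na(G3[keep, , drop = FALSE]))
    expMark <- which(markMiss >= 0.10)
    expect_equal(samplesRemoved(out3$report)$sample_id, expSamp)
    expect_equal(nMarkers(out3$dataset), 20L - length(expMark))
    expect_setequal(markersRemoved(out3$report)$marker,
                    markerKeys(toyDataset(G3))[expMark])
})

test_that("MAF filter removes monomorphic and low-MAF markers, inclusive boundary", {
    G <- rbind(c(0, 0, 0, 2),
               c(0, 0, 1, 2),
               c(0, 1, 2, 2),
               c(0, 0, 0, 2))
    rownames(G) <- paste0("s", 1:4)
    ds <- toyDataset(G)
    out <- filterMaf(ds, 0.05)
    rem <- markersRemoved(out$report)
    # marker 1 invariant (all 0), marker 4 invariant (all 2): removed
    expect_setequal(rem$rule[rem$marker %in% c("1:1000", "1:4000")],
                    "monomorphic")
    # marker 3: dosages 0,1,2,0 -> alt 3/8 = 0.375 retained
    expect_true("1:3000" %in% markerKeys(out$dataset))
    # marker 2: alt 1/8 = 0.125 retained at 0.05 but removed at 0.2
    expect_true("1:2000" %in% markerKeys(out$dataset))
    strict <- filterMaf(ds, 0.2)
    expect_false("1:2000" %in% markerKeys(strict$dataset))
    # inclusive boundary: MAF exactly equal to the threshold is retained
    exact <- filterMaf(ds, 0.125)
    expect_true("1:2000" %in% markerKeys(exact$dataset))
    # minMaf = 0: only monomorphic markers removed
    zero <- filterMaf(ds, 0)
    expect_equal(nMarkers(zero$dataset), 2L)
    # all-missing marker removed with MAF flagged undefined
    G[, 2] <- NA
    outNA <- filterMaf(toyDataset(G), 0.05)
    remNA <- markersRemoved(outNA$report)
    expect_equal(remNA$rule[remNA$marker == "1:2000"], "maf_undefined")
})

test_that("quality mask blanks low-GQ cells then filters markers on depth and missingness", {
    G <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
    GQ <- matrix(99, 4, 3)
    # identity when all GQ = 99 and all DP = 30
    ds <- toyDataset(G, DP = matrix(30, 4, 3), GQ = GQ)
    id <- maskLowQuality(ds)
    expect_equal(unname(dosages(id$dataset)), unname(G))
    expect_equal(nrow(markersRemoved(id$report)), 0L)
    # one genotype below the GQ threshold is masked; with enough samples
    # the marker's missingness stays under 10% and it survives
    G20 <- matrix(1, 20, 3, dimnames = list(paste0("t", 1:20), NULL))
    GQ2 <- matrix(99, 20, 3); GQ2[1, 1] <- 29
    out <- maskLowQuality(toyDataset(G20, DP = matrix(30, 20, 3),
                                     GQ = GQ2))
    expect_true(is.na(dosages(out$dataset)[1, 1]))
    expect_true("1:1000" %in% markerKeys(out$dataset))
    # mean DP {12, 9.5, 10}: middle marker removed, boundary 10 kept
    DP <- cbind(c(12, 12, 12, 12), c(9, 10, 9, 10), c(10, 10, 10, 10))
    out3 <- maskLowQuality(toyDataset(G, DP = DP, GQ = GQ))
    expect_equal(markersRemoved(out3$report)$marker, "1:2000")
    expect_equal(markersRemoved(out3$report)$rule, "mean_depth")
    expect_true(all(c("1:1000", "1:3000") %in%
                    markerKeys(out3$dataset)))
    # absent DP/GQ directs the user to skip the stage
    expect_error(maskLowQuality(toyDataset(G)), "skip")
})

test_that("LD pruning removes one of a duplicated pair and honors the tie rule", {
    set.seed(12)
    x <- sample(0:2, 40, replace = TRUE, prob = c(1, 2, 1))
    G <- cbind(x, x)
    rownames(G) <- paste0("s", 1:40)
    ds <- toyDataset(G, pos = c(1000, 1100))
    out <- ldPrune(ds)
    expect_equal(nMarkers(out$dataset), 1L)
    # equal missingness and MAF: the larger position is removed
    expect_equal(markersRemoved(out$report)$marker, "1:1100")
    # the member with higher missingness loses regardless of position
    G2 <- cbind(x, x)
    G2[1:3, 1] <- NA
    out2 <- ldPrune(toyDataset(G2, pos = c(1000, 1100)))
    expect_equal(markersRemoved(out2$report)$marker, "1:1000")
})

test_that("independent markers survive pruning and chained LD resolves minimally", {
    ds <- twoPopDataset(60, 150, fst = 0, seed = 13)
    out <- ldPrune(ds, windowBp = 1000, r2Max = 0.5)
    expect_equal(nMarkers(out$dataset), 150L)

    # three-marker chain: r2(1,2) and r2(2,3) high, r2(1,3) low
    set.seed(14)
    n <- 200
    m2 <- sample(0:2, n, replace = TRUE, prob = c(1, 2, 1))
    flip <- function(g, k) {
        idx <- sample(n, k)
        g[idx] <- sample(0:2, k, replace = TRUE)
        g
    }
    m1 <- flip(m2, 8)
    m3 <- flip(m2, 8)
    G <- cbind(m1, m2, m3)
    rownames(G) <- paste0("s", 1:n)
    ds3 <- toyDataset(G, pos = c(1000, 1400, 1800))
    r12 <- cor(m1, m2)^2; r23 <- cor(m2, m3)^2; r13 <- cor(m1, m3)^2
    expect_gt(r12, 0.5); expect_gt(r23, 0.5)
    out3 <- ldPrune(ds3, windowBp = 1000, r2Max = 0.5)
    # brute force: smallest removal set over all subsets that clears the
    # audit, under the documented tie rule the pruner keeps {m1, m3} when
    # r2(1,3) <= 0.5
    if (r13 <= 0.5) {
        expect_equal(markerKeys(out3$dataset), c("1:1000", "1:1800"))
    }
    expect_equal(nrow(ldPruneAudit(out3$dataset, 1000, 0.5)), 0L)
})

test_that("filters are idempotent and report counts reconcile", {
    set.seed(15)
    G <- matrix(sample(c(0:2, NA), 600, replace = TRUE,
                       prob = c(4, 3, 3, 0.5)), 20, 30,
                dimnames = list(paste0("s", 1:20), NULL))
    ds <- toyDataset(G)
    f1 <- filterMissingness(ds, 0.15, 0.15)
    f2 <- filterMissingness(f1$dataset, 0.15, 0.15)
    expect_equal(markerKeys(f2$dataset), markerKeys(f1$dataset))
    expect_equal(sampleIDs(f2$dataset), sampleIDs(f1$dataset))
    m1 <- filterMaf(f1$dataset, 0.05)
    m2 <- filterMaf(m1$dataset, 0.05)
    expect_equal(markerKeys(m2$dataset), markerKeys(m1$dataset))
    l1 <- ldPrune(m1$dataset)
    l2 <- ldPrune(l1$dataset)
    expect_equal(markerKeys(l2$dataset), markerKeys(l1$dataset))
    expect_equal(nMarkers(ds) - nMarkers(l1$dataset),
                 nrow(markersRemoved(f1$report)) +
                 nrow(markersRemoved(m1$report)) +
                 nrow(markersRemoved(l1$report)))
})
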