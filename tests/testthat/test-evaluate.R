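test_that("a dataset is 100% concordant with itself", {
    set.seed(40)
    G <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10,
                dimnames = list(paste0("s", 1:6), NULL))
    ds <- toyDataset(G)
    rep <- concordance(ds, ds)
    cells <- concordanceCells(rep)
    expect_equal(unname(cells[["discordant"]]), 0)
    expect_equal(unname(cells[["missing_in_A_called_in_B"]]), 0)
    expect_equal(unname(cells[["called_in_A_missing_in_B"]]), 0)
    expect_equal(unname(cells[["identical"]]), sum(!is.na(G)))
    expect_true(is.nan(rep@missingnessRatio))
    expect_equal(sum(cells), 6 * 10)
})

test_that("swapped REF/ALT sites are harmonized and logged", {
    G1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(paste0("s", 1:3), NULL))
    dsA <- toyDataset(G1, pos = 100, ref = "A", alt = "G")
    # same genotypes stored against swapped alleles: dosages complement
    dsB <- toyDataset(2 - G1, pos = 100, ref = "G", alt = "A")
    rep <- concordance(dsA, dsB)
    expect_equal(unname(concordanceCells(rep)[["identical"]]), 3)
    expect_equal(unname(concordanceCells(rep)[["discordant"]]), 0)
    expect_equal(rep@swappedSites$key, "1:100")
    # incompatible alleles are dropped and logged, not compared
    dsC <- toyDataset(G1, pos = 100, ref = "A", alt = "T")
    expect_error(concordance(dsA, dsC), "shared")   # no sites survive
    G2 <- cbind(G1, G1)
    dsA2 <- toyDataset(G2, pos = c(100, 200),
                       ref = c("A", "C"), alt = c("G", "T"))
    dsC2 <- toyDataset(G2, pos = c(100, 200),
                       ref = c("A", "C"), alt = c("G", "A"))
    rep2 <- concordance(dsA2, dsC2)
    expect_equal(rep2@droppedSites$key, "1:200")
    expect_equal(rep2@nSites, 1L)
})

test_that("five concordance cells partition the grid and swap transposes missingness", {
    set.seed(41)
    G <- matrix(sample(c(0:2, NA), 80, replace = TRUE), 8, 10,
                dimnames = list(paste0("s", 1:8), NULL))
    H <- G
    H[sample(length(H), 20)] <- sample(c(0:2, NA), 20, replace = TRUE)
    dsA <- toyDataset(G)
    dsB <- toyDataset(H)
    ab <- concordanceCells(concordance(dsA, dsB))
    ba <- concordanceCells(concordance(dsB, dsA))
    expect_equal(sum(ab), 80)
    expect_equal(ab[["identical"]], ba[["identical"]])
    expect_equal(ab[["discordant"]], ba[["discordant"]])
    expect_equal(ab[["missing_in_A_called_in_B"]],
                 ba[["called_in_A_missing_in_B"]])
    expect_equal(ab[["called_in_A_missing_in_B"]],
                 ba[["missing_in_A_called_in_B"]])
})

test_that("reciprocal missingness ratio reproduces the printed-count arithmetic", {
    # 375 one-way missing vs 46 the other way -> ratio 8.15
    expect_equal(round(375 / 46, 2), 8.15)
    # constructed small grid with asymmetric missingness
    G <- matrix(1, 10, 10, dimnames = list(paste0("s", 1:10), NULL))
    H <- G
    G[1, 1:8] <- NA      # 8 missing in A called in B
    H[2, 1:2] <- NA      # 2 called in A missing in B
    rep <- concordance(toyDataset(G), toyDataset(H))
    expect_equal(unname(rep@missingnessRatio), 4)
})

test_that("coverage curves are non-increasing and match hand computation", {
    D <- rbind(s1 = c(20, 20, 20, 20), s2 = c(0, 5, 10, 40))
    cp <- coverageProfile(D, thresholds = c(1, 5, 10, 20, 40))
    expect_equal(unname(cp$curves["s1", ]), c(1, 1, 1, 1, 0))
    expect_equal(unname(cp$curves["s2", ]), c(0.75, 0.75, 0.5, 0.25, 0.25))
    expect_true(all(apply(cp$curves, 1, function(x) all(diff(x) <= 0))))
    expect_equal(unname(cp$perSampleMean), c(20, 13.75))
    expect_equal(unname(cp$perSampleSD), c(0, sd(c(0, 5, 10, 40))))
    expect_equal(cp$grandMean, mean(D))
    # all-zero depths give an all-zero curve
    cp0 <- coverageProfile(matrix(0, 2, 3), thresholds = 1:5)
    expect_true(all(cp0$curves == 0))
    expect_error(coverageProfile(matrix(numeric(), 0, 0)), "empty")
    # all depths 20 at t = 10: proportion 1 for every sample
    cp20 <- coverageProfile(matrix(20, 3, 4), thresholds = c(10))
    expect_true(all(cp20$curves == 1))
    expect_equal(cp20$nSamplesAbove, 3L)
})

test_that("off-target SNPs are classified near/far with clusters and a low-MAF fraction", {
    # panel targets at 1:10000 and 2:50000
    panel <- data.frame(chrom = c("1", "2"), pos = c(10000, 50000))
    # 11 called non-target SNPs: 6 near (<= 150 bp) and 5 far
    chrom <- c(rep("1", 7), rep("2", 4), "3")
    pos <- c(10000,                       # target itself
             10050, 10100, 10149, 9900, 9990, 10150,   # 6 near on chr 1
             50200,                       # 200 bp away -> far
             120000, 121000,              # far cluster of two (chr 2)
             300000,                      # far singleton (chr 2)
             7777)                        # chr 3 has no target -> far
    G <- matrix(rep(c(0, 1), 6), nrow = 12, ncol = length(pos))
    G[, 4] <- 0                           # monomorphic -> MAF 0 < 0.05
    G[, 5] <- c(rep(0, 11), 1)            # MAF 1/24 < 0.05
    rownames(G) <- paste0("s", 1:12)
    ds <- GenotypeDataset(G, chrom = chrom, pos = pos,
                          ref = rep("A", length(pos)),
                          alt = rep("G", length(pos)))
    res <- classifyOfftarget(ds, panel, nearBp = 150, mafCut = 0.05,
                             clusterGap = 10000)
    expect_equal(res$nTargets, 1L)
    expect_equal(nrow(res$table), 11L)
    near <- res$table[res$table$class == "near", ]
    far <- res$table[res$table$class == "far", ]
    expect_equal(nrow(near), 6L)
    expect_equal(nrow(far), 5L)
    expect_true(all(near$distance <= 150))
    expect_true("1:10150" %in% near$key)  # boundary distance is inclusive
    expect_true(is.infinite(far$distance[far$chrom == "3"]))
    # clusters: 50200 alone, {120000, 121000}, 300000 alone, chr3 alone
    expect_equal(nrow(res$clusters), 4L)
    expect_equal(sort(res$clusters$n), c(1, 1, 1, 2))
    expect_equal(res$fracLowMaf, 2 / 11)
    # every called SNP is exactly one of target/near/far
    expect_equal(res$nTargets + res$nNear + res$nFar, nMarkers(ds))
})

test_that("locus screening counts genotype classes and reports unassayed loci", {
    G <- matrix(c(0, 1, 2, NA), 4, 2, dimnames = list(paste0("s", 1:4),
                                                      NULL))
    G[, 2] <- 0
    ds <- toyDataset(G, pos = c(100, 200))
    loci <- data.frame(chrom = c("1", "1", "7"),
                       pos = c(100, 200, 999),
                       label = c("locA", "locB", "locC"))
    tab <- screenLoci(ds, loci)
    expect_equal(unname(unlist(tab[1, c("hom_ref", "het", "hom_alt",
                                        "missing")])), c(1, 1, 1, 1))
    # all-hom-ref pattern (the resistance-screen outcome shape)
    expect_equal(unname(unlist(tab[2, c("hom_ref", "het", "hom_alt",
                                        "missing")])), c(4, 0, 0, 0))
    expect_false(tab$assayed[3])
    # counts partition samples at assayed loci
    expect_equal(sum(tab[1, c("hom_ref", "het", "hom_alt", "missing")]),
                 4)
})
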