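# Shared fixture builders and independent oracles.

# Small dataset straight from a samples x markers dosage matrix, markers on
# one chromosome at 1 kb spacing unless positions given.
toyDataset <- function(G, pos = NULL, chrom = NULL, ref = NULL, alt = NULL,
                       population = NULL, DP = NULL, GQ = NULL) {
    m <- ncol(G)
    if (is.null(rownames(G)))
        rownames(G) <- paste0("s", seq_len(nrow(G)))
    GenotypeDataset(G,
                    chrom = chrom %||% rep("1", m),
                    pos = pos %||% seq(1000, by = 1000, length.out = m),
                    ref = ref %||% rep("A", m),
                    alt = alt %||% rep("G", m),
                    population = population, DP = DP, GQ = GQ)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hudson-type FST estimator (ratio of sums) for two populations, used as an
# independent check on the drift simulator.
hudsonFst <- function(G1, G2) {
    p1 <- colMeans(G1, na.rm = TRUE) / 2
    p2 <- colMeans(G2, na.rm = TRUE) / 2
    n1 <- 2 * colSums(!is.na(G1))
    n2 <- 2 * colSums(!is.na(G2))
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
}

# Mean estimated kinship per true degree class, matching dyads by
# unordered id pair.
kinshipByDegree <- function(kin, truth) {
    dy <- kinshipDyads(kin)
    merged <- rbind(
        merge(dy, truth, by.x = c("id_a", "id_b"),
              by.y = c("sample_a", "sample_b")),
        merge(dy, truth, by.x = c("id_b", "id_a"),
              by.y = c("sample_a", "sample_b")))
    stats::aggregate(kinship.x ~ degree, merged, mean)
}

# Two drifted populations with embedded pedigrees on a shared marker map.
twoPopPedigrees <- function(nMarkers, fst, design, seed) {
    cfg <- simConfig(nPops = 2, nPerPop = 10, nMarkers = nMarkers,
                     fst = fst, seed = seed)
    fr <- simStructuredFreqs(cfg)
    p1 <- simPedigree(fr$freqs[1, ], design, seed = seed + 1,
                      prefix = "a", population = "pop1")
    p2 <- simPedigree(fr$freqs[2, ], design, seed = seed + 2,
                      prefix = "b", population = "pop2",
                      markers = markerInfo(p1$dataset))
    list(dataset = bindSamples(p1$dataset, p2$dataset),
         truth = rbind(p1$truth, p2$truth))
}

# Quick two-population HWE dataset for structure/assignment tests.
twoPopDataset <- function(nPerPop, nMarkers, fst, seed, ...) {
    cfg <- simConfig(nPops = 2, nPerPop = nPerPop, nMarkers = nMarkers,
                     fst = fst, seed = seed, ...)
    simGenotypes(simStructuredFreqs(cfg), cfg)
}
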