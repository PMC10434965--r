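#' Simulation configuration for structured genotype datasets
#'
#' Bundles and validates the parameters of the synthetic-data generator:
#' population structure under the Balding-Nichols drift model, local
#' linkage disequilibrium via latent-haplotype copying, genotype
#' missingness/error, and capture-sequencing depth/quality annotations.
#'
#' @param nPops number of populations.
#' @param nPerPop diploid samples per population.
#' @param nMarkers number of biallelic SNP markers (>= 0).
#' @param fst per-population drift parameter F in [0, 1); population allele
#'   frequencies are Beta-distributed around the ancestral frequency p with
#'   variance F p (1 - p). F = 0 means no drift.
#' @param ancFreqRange interval within (0, 1) from which ancestral allele
#'   frequencies are drawn uniformly. The default (0.05, 0.95) avoids
#'   monomorphic draws dominating small simulations.
#' @param ldBlockSize markers per LD block (1 = independent markers).
#' @param ldLeak per-marker probability that a latent haplotype lineage is
#'   re-drawn within a block; 0 gives maximal within-block LD.
#' @param missRate,errorRate per-genotype missingness and perturbation
#'   probabilities applied by [corruptGenotypes()].
#' @param meanDepth expected sequencing reads per genotype (negative
#'   binomial mean) used by [simSeqArtifacts()].
#' @param depthDispersion negative-binomial size parameter (variance =
#'   mu + mu^2 / size); the default 11 reproduces a mean ~27.6x, SD ~9.8x
#'   capture-coverage regime.
#' @param structure `"star"` (each population drifts independently from the
#'   ancestor) or `"chain"` (populations drift sequentially from their
#'   neighbour, emulating isolation by distance).
#' @param seed integer seed making the whole generator reproducible.
#' @return A validated list of class `"SimConfig"`.
#' @examples
#' cfg <- simConfig(nPops = 2, nPerPop = 20, nMarkers = 100, fst = 0.1,
#'                  seed = 1)
#' @export
simConfig <- function(nPops = 2L, nPerPop = 50L, nMarkers = 1000L,
                      fst = 0.1, ancFreqRange = c(0.05, 0.95),
                      ldBlockSize = 1L, ldLeak = 0.1,
                      missRate = 0, errorRate = 0,
                      meanDepth = 27.6, depthDispersion = 11,
                      structure = c("star", "chain"), seed = NULL) {
    structure <- match.arg(structure)
    stopifnot(nPops >= 1, nPerPop >= 1, nMarkers >= 0,
              fst >= 0, fst < 1,
              length(ancFreqRange) == 2, all(ancFreqRange > 0),
              all(ancFreqRange < 1), ancFreqRange[1] <= ancFreqRange[2],
              ldBlockSize >= 1,
              ldLeak >= 0, ldLeak <= 1,
              missRate >= 0, missRate <= 1,
              errorRate >= 0, errorRate <= 1,
              meanDepth >= 0, depthDispersion > 0)
    cfg <- list(nPops = as.integer(nPops), nPerPop = as.integer(nPerPop),
                nMarkers = as.integer(nMarkers), fst = fst,
                ancFreqRange = ancFreqRange,
                ldBlockSize = as.integer(ldBlockSize), ldLeak = ldLeak,
                missRate = missRate, errorRate = errorRate,
                meanDepth = meanDepth, depthDispersion = depthDispersion,
                structure = structure, seed = seed)
    class(cfg) <- "SimConfig"
    cfg
}

# One Balding-Nichols draw of population frequencies around ancestral p.
bnDraw <- function(p, fst) {
    if (fst == 0) return(p)
    stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate structured per-population allele frequencies
#'
#' Draws ancestral allele frequencies uniformly on `ancFreqRange`, then
#' derives each population's frequencies under the Balding-Nichols model:
#' Beta(p(1-F)/F, (1-p)(1-F)/F) around ancestral p, so that
#' E[freq] = p and Var[freq] = F p (1 - p). With `structure = "chain"` each
#' population drifts from the previous one instead of the common ancestor.
#'
#' @param config a [simConfig()] object.
#' @return A list with `ancestral` (length-nMarkers vector) and `freqs`
#'   (nPops x nMarkers matrix, rownames `pop1..popK`).
#' @export
simStructuredFreqs <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    withSeedIfGiven(config$seed, {
        p <- stats::runif(config$nMarkers, config$ancFreqRange[1],
                          config$ancFreqRange[2])
        freqs <- matrix(NA_real_, nrow = config$nPops,
                        ncol = config$nMarkers,
                        dimnames = list(paste0("pop", seq_len(config$nPops)),
                                        NULL))
        prev <- p
        for (k in seq_len(config$nPops)) {
            src <- if (config$structure == "chain") prev else p
            freqs[k, ] <- bnDraw(src, config$fst)
            prev <- freqs[k, ]
        }
        list(ancestral = p, freqs = freqs)
    })
}

# Lay nMarkers SNPs on a synthetic genome of 19 autosomes + X, positions
# strictly increasing within chromosome. Markers in the same LD block are
# placed close together (10-300 bp apart); blocks are separated by larger
# gaps so block structure and the bp pruning window line up. Blocks never
# span chromosomes.
placeMarkers <- function(nMarkers, blockSize) {
    chroms <- c(as.character(1:19), "X")
    if (nMarkers == 0)
        return(data.frame(chrom = character(), pos = integer(),
                          block = integer()))
    nBlocks <- ceiling(nMarkers / blockSize)
    # contiguous chromosome chunks keep the emitted order identical to the
    # sorted (chrom, pos) order, so dataset columns align with the input
    # frequency vector
    base <- nBlocks %/% length(chroms)
    extra <- nBlocks %% length(chroms)
    blockChrom <- rep(chroms, base + (seq_along(chroms) <= extra))
    blockOf <- rep(seq_len(nBlocks), each = blockSize)[seq_len(nMarkers)]
    chrom <- blockChrom[blockOf]
    pos <- integer(nMarkers)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        b <- blockOf[idx]
        gap <- ifelse(c(TRUE, diff(b) != 0L),
                      sample(2000:10000, length(idx), replace = TRUE),
                      sample(10:300, length(idx), replace = TRUE))
        pos[idx] <- cumsum(gap)
    }
    data.frame(chrom = chrom, pos = pos, block = blockOf)
}

# Draw one population's genotypes (n x m dosage matrix) with LD blocks via
# latent-haplotype copying: each individual carries two latent uniform
# lineages per block; an allele at marker s is 1 iff its lineage's uniform
# is below q_s. A lineage's uniform is re-drawn with probability ldLeak at
# each marker, so r^2 between block-mates decays with ldLeak.
drawPopGenotypes <- function(q, n, block, ldLeak) {
    m <- length(q)
    G <- matrix(0L, nrow = n, ncol = m)
    for (hap in 1:2) {
        U <- matrix(stats::runif(n * m), nrow = n, ncol = m)
        keep <- matrix(stats::runif(n * m) >= ldLeak, nrow = n, ncol = m)
        newBlock <- c(TRUE, diff(block) != 0L)
        for (s in seq_len(m)) {
            if (!newBlock[s]) {
                carry <- keep[, s]
                U[carry, s] <- U[carry, s - 1L]
            }
        }
        G <- G + (sweep(U, 2, q, "<") * 1L)
    }
    G
}

randomAlleles <- function(m) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    list(ref = unname(ref), alt = unname(alt))
}

#' Simulate genotypes for structured populations
#'
#' Draws within-population Hardy-Weinberg genotypes at the frequencies in
#' `freqs`, placing markers on a synthetic genome (19 autosomes + X) with
#' strictly increasing positions. Markers within an LD block copy a shared
#' latent haplotype pair, each lineage switching with probability
#' `ldLeak` per marker; `ldBlockSize = 1` gives independent markers.
#' Sex chromosomes are placed but inherited autosomally.
#'
#' @param freqs result of [simStructuredFreqs()], or an nPops x nMarkers
#'   frequency matrix.
#' @param config the [simConfig()] used to generate `freqs`.
#' @return A [GenotypeDataset-class] with population labels
#'   `pop1..popK` and samples `pop<k>_<i>`.
#' @export
simGenotypes <- function(freqs, config) {
    stopifnot(inherits(config, "SimConfig"))
    F <- if (is.list(freqs)) freqs$freqs else as.matrix(freqs)
    stopifnot(all(F >= 0 & F <= 1), nrow(F) == config$nPops)
    m <- ncol(F)
    withSeedIfGiven(if (is.null(config$seed)) NULL else config$seed + 1L, {
        map <- placeMarkers(m, config$ldBlockSize)
        al <- randomAlleles(m)
        G <- matrix(0L, nrow = 0L, ncol = m)
        for (k in seq_len(config$nPops)) {
            Gk <- drawPopGenotypes(F[k, ], config$nPerPop, map$block,
                                   config$ldLeak)
            G <- rbind(G, Gk)
        }
        samples <- paste0(rep(rownames(F) %||%
                                  paste0("pop", seq_len(config$nPops)),
                              each = config$nPerPop),
                          "_", rep(seq_len(config$nPerPop), config$nPops))
        pops <- rep(rownames(F) %||% paste0("pop", seq_len(config$nPops)),
                    each = config$nPerPop)
        rownames(G) <- samples
        GenotypeDataset(G, chrom = map$chrom, pos = map$pos,
                        ref = al$ref, alt = al$alt,
                        population = pops)
    })
}

# Pedigree kinship by the standard recursion, parents before children.
# ped: data.frame(id, sire, dam), NA parent = founder.
pedigreeKinship <- function(ped) {
    n <- nrow(ped)
    idx <- stats::setNames(seq_len(n), ped$id)
    phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
    for (i in seq_len(n)) {
        si <- ped$sire[i]; di <- ped$dam[i]
        for (j in seq_len(i - 1L)) {
            v <- 0
            if (!is.na(si)) v <- v + 0.5 * phi[idx[[si]], j]
            if (!is.na(di)) v <- v + 0.5 * phi[idx[[di]], j]
            phi[i, j] <- phi[j, i] <- v
        }
        f <- if (!is.na(si) && !is.na(di)) phi[idx[[si]], idx[[di]]] else 0
        phi[i, i] <- 0.5 * (1 + f)
    }
    phi
}

# Detect cycles (an individual being its own ancestor).
assertAcyclic <- function(ped) {
    idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
    state <- integer(nrow(ped))  # 0 unseen, 1 in progress, 2 done
    visit <- function(i) {
        if (state[i] == 1L) stop("cyclic pedigree at individual ", ped$id[i])
        if (state[i] == 2L) return(invisible())
        state[i] <<- 1L
        for (p in c(ped$sire[i], ped$dam[i]))
            if (!is.na(p)) visit(idx[[p]])
        state[i] <<- 2L
    }
    for (i in seq_len(nrow(ped))) visit(i)
    invisible(TRUE)
}

# Build a pedigree table from family-design counts. Each unit is an
# independent family; founders across units are unrelated.
designToPedigree <- function(design, prefix = "ped") {
    rows <- list()
    add <- function(id, sire = NA, dam = NA)
        rows[[length(rows) + 1L]] <<- data.frame(id = id, sire = sire,
                                                 dam = dam)
    u <- 0L
    rep_unit <- function(n, f) for (k in seq_len(n %||% 0L)) {
        u <<- u + 1L
        f(paste0(prefix, "_u", u))
    }
    rep_unit(design$parentOffspring, function(b) {
        add(paste0(b, "_p1")); add(paste0(b, "_p2"))
        add(paste0(b, "_c1"), paste0(b, "_p1"), paste0(b, "_p2"))
    })
    rep_unit(design$fullSib, function(b) {
        add(paste0(b, "_p1")); add(paste0(b, "_p2"))
        add(paste0(b, "_c1"), paste0(b, "_p1"), paste0(b, "_p2"))
        add(paste0(b, "_c2"), paste0(b, "_p1"), paste0(b, "_p2"))
    })
    rep_unit(design$halfSib, function(b) {
        add(paste0(b, "_f")); add(paste0(b, "_m1")); add(paste0(b, "_m2"))
        add(paste0(b, "_c1"), paste0(b, "_f"), paste0(b, "_m1"))
        add(paste0(b, "_c2"), paste0(b, "_f"), paste0(b, "_m2"))
    })
    rep_unit(design$cousin, function(b) {
        add(paste0(b, "_g1")); add(paste0(b, "_g2"))
        add(paste0(b, "_s1"), paste0(b, "_g1"), paste0(b, "_g2"))
        add(paste0(b, "_s2"), paste0(b, "_g1"), paste0(b, "_g2"))
        add(paste0(b, "_u1")); add(paste0(b, "_u2"))
        add(paste0(b, "_c1"), paste0(b, "_s1"), paste0(b, "_u1"))
        add(paste0(b, "_c2"), paste0(b, "_s2"), paste0(b, "_u2"))
    })
    rep_unit(design$unrelated, function(b) add(paste0(b, "_i1")))
    do.call(rbind, rows)
}

degreeFromKinship <- function(phi) {
    lab <- rep("unrelated", length(phi))
    lab[abs(phi - 0.25) < 1e-9] <- "1st"
    lab[abs(phi - 0.125) < 1e-9] <- "2nd"
    lab[abs(phi - 0.0625) < 1e-9] <- "3rd"
    lab
}

#' Simulate a pedigreed genotype dataset with a kinship truth table
#'
#' Founders draw Hardy-Weinberg genotypes at the supplied allele
#' frequencies; descendants are produced by Mendelian gene-dropping (one
#' allele transmitted from each parent per marker, independent across
#' markers). The truth table lists every sample pair involving at least one
#' non-founder with its pedigree kinship coefficient and degree class.
#'
#' @param founderFreqs numeric vector of ALT-allele frequencies, one per
#'   marker.
#' @param design either a list of family counts
#'   (`parentOffspring`, `fullSib`, `halfSib`, `cousin`, `unrelated`) or a
#'   pedigree `data.frame` with columns `id`, `sire`, `dam` (NA = founder;
#'   parents must be acyclic).
#' @param seed integer seed.
#' @param prefix sample-id prefix for design-generated pedigrees.
#' @param population optional population label attached to all samples.
#' @param markers optional marker map (data.frame with chrom, pos, ref,
#'   alt) shared across calls, e.g. `markerInfo()` of an earlier dataset;
#'   generated when NULL.
#' @return list with `dataset` (a [GenotypeDataset-class]) and `truth`
#'   (data.frame: sample_a, sample_b, kinship, degree), each unordered pair
#'   stored once.
#' @examples
#' res <- simPedigree(rep(0.5, 200), list(fullSib = 1), seed = 1)
#' subset(res$truth, degree == "1st")
#' @export
simPedigree <- function(founderFreqs, design, seed = NULL, prefix = "ped",
                        population = NULL, markers = NULL) {
    q <- as.numeric(founderFreqs)
    stopifnot(all(q >= 0 & q <= 1))
    ped <- if (is.data.frame(design)) design else
        designToPedigree(design, prefix = prefix)
    stopifnot(!is.null(ped), nrow(ped) >= 1, !anyDuplicated(ped$id))
    # parents must be defined rows; order so parents precede children
    for (p in c(ped$sire, ped$dam))
        if (!is.na(p) && !p %in% ped$id)
            stop("parent '", p, "' not in pedigree")
    assertAcyclic(ped)
    ord <- order(vapply(seq_len(nrow(ped)), function(i) {
        depth <- function(i) {
            ps <- c(ped$sire[i], ped$dam[i])
            ps <- ps[!is.na(ps)]
            if (!length(ps)) return(0L)
            1L + max(vapply(match(ps, ped$id), depth, 0L))
        }
        depth(i)
    }, 0L))
    ped <- ped[ord, , drop = FALSE]
    m <- length(q)
    withSeedIfGiven(seed, {
        n <- nrow(ped)
        H1 <- matrix(0L, n, m)
        H2 <- matrix(0L, n, m)
        rownames(H1) <- rownames(H2) <- ped$id
        for (i in seq_len(n)) {
            for (h in 1:2) {
                p <- if (h == 1) ped$sire[i] else ped$dam[i]
                hap <- if (is.na(p)) {
                    (stats::runif(m) < q) * 1L
                } else {
                    pick <- stats::runif(m) < 0.5
                    ifelse(pick, H1[p, ], H2[p, ])
                }
                if (h == 1) H1[i, ] <- hap else H2[i, ] <- hap
            }
        }
        if (is.null(markers)) {
            map <- placeMarkers(m, 1L)
            al <- randomAlleles(m)
            markers <- data.frame(chrom = map$chrom, pos = map$pos,
                                  ref = al$ref, alt = al$alt)
        }
        stopifnot(nrow(markers) == m)
        ds <- GenotypeDataset(H1 + H2, chrom = markers$chrom,
                              pos = markers$pos,
                              ref = markers$ref, alt = markers$alt,
                              population = if (is.null(population)) NULL
                                           else rep(population, n))
        phi <- pedigreeKinship(ped)
        founder <- is.na(ped$sire) & is.na(ped$dam)
        pairs <- which(upper.tri(phi), arr.ind = TRUE)
        keep <- !(founder[pairs[, 1]] & founder[pairs[, 2]])
        pairs <- pairs[keep, , drop = FALSE]
        truth <- data.frame(sample_a = ped$id[pairs[, 1]],
                            sample_b = ped$id[pairs[, 2]],
                            kinship = phi[pairs],
                            stringsAsFactors = FALSE)
        truth$degree <- degreeFromKinship(truth$kinship)
        list(dataset = ds, truth = truth, pedigree = ped)
    })
}

#' Inject missingness and genotyping error
#'
#' Each called genotype is set missing with probability `missRate`; each
#' surviving genotype is then perturbed to a different valid dosage with
#' probability `errorRate`. Marker and sample metadata are untouched.
#'
#' @param ds a [GenotypeDataset-class].
#' @param missRate,errorRate probabilities in [0, 1].
#' @param seed integer seed.
#' @return The corrupted [GenotypeDataset-class].
#' @export
corruptGenotypes <- function(ds, missRate = 0, errorRate = 0, seed = NULL) {
    stopifnot(is(ds, "GenotypeDataset"),
              missRate >= 0, missRate <= 1, errorRate >= 0, errorRate <= 1)
    G <- dosages(ds)
    withSeedIfGiven(seed, {
        called <- which(!is.na(G))
        drop <- called[stats::runif(length(called)) < missRate]
        G[drop] <- NA
        called <- which(!is.na(G))
        flip <- called[stats::runif(length(called)) < errorRate]
        if (length(flip)) {
            old <- G[flip]
            shift <- 1L + (stats::runif(length(flip)) < 0.5)
            G[flip] <- (old + shift) %% 3L
        }
        mi <- markerInfo(ds)
        GenotypeDataset(G, chrom = mi$chrom, pos = mi$pos, ref = mi$ref,
                        alt = mi$alt, id = mi$id, samples = sampleIDs(ds),
                        population = popLabels(ds),
                        DP = depthMatrix(ds), GQ = qualMatrix(ds))
    })
}

#' Overlay capture-sequencing depth and genotype-quality annotations
#'
#' Per-genotype depth DP is drawn independently from a negative binomial
#' with mean `meanDepth` and size `depthDispersion`; genotype quality is the
#' deterministic map GQ = min(gqCap, round(gqSlope * DP)). Genotypes with
#' DP = 0 are set missing.
#'
#' @param ds a [GenotypeDataset-class].
#' @param meanDepth,depthDispersion negative-binomial mean and size
#'   (size > 0; variance = mu + mu^2/size).
#' @param gqSlope,gqCap parameters of the GQ map (defaults 3 and 99: 10x
#'   depth maps to the conventional GQ 30 filter boundary).
#' @param seed integer seed.
#' @return A [GenotypeDataset-class] with DP and GQ assays filled in.
#' @export
simSeqArtifacts <- function(ds, meanDepth = 27.6, depthDispersion = 11,
                            gqSlope = 3, gqCap = 99, seed = NULL) {
    stopifnot(is(ds, "GenotypeDataset"), meanDepth >= 0)
    if (depthDispersion <= 0)
        stop("depthDispersion must be positive")
    G <- dosages(ds)
    withSeedIfGiven(seed, {
        DP <- matrix(stats::rnbinom(length(G), size = depthDispersion,
                                    mu = meanDepth),
                     nrow = nrow(G), dimnames = dimnames(G))
        GQ <- pmin(round(gqSlope * DP), gqCap)
        G[DP == 0L] <- NA
        mi <- markerInfo(ds)
        GenotypeDataset(G, chrom = mi$chrom, pos = mi$pos, ref = mi$ref,
                        alt = mi$alt, id = mi$id, samples = sampleIDs(ds),
                        population = popLabels(ds), DP = DP, GQ = GQ)
    })
}

#' Concatenate the samples of two datasets sharing the same markers
#'
#' @param ds1,ds2 [GenotypeDataset-class] objects with identical marker
#'   tables and disjoint sample ids.
#' @return A combined [GenotypeDataset-class].
#' @export
bindSamples <- function(ds1, ds2) {
    stopifnot(identical(markerInfo(ds1), markerInfo(ds2)),
              !any(sampleIDs(ds1) %in% sampleIDs(ds2)))
    mi <- markerInfo(ds1)
    hasDP <- !is.null(depthMatrix(ds1)) && !is.null(depthMatrix(ds2))
    hasGQ <- !is.null(qualMatrix(ds1)) && !is.null(qualMatrix(ds2))
    p1 <- popLabels(ds1); p2 <- popLabels(ds2)
    pops <- if (is.null(p1) && is.null(p2)) NULL else
        c(p1 %||% rep(NA_character_, nSamples(ds1)),
          p2 %||% rep(NA_character_, nSamples(ds2)))
    GenotypeDataset(rbind(dosages(ds1), dosages(ds2)),
                    chrom = mi$chrom, pos = mi$pos, ref = mi$ref,
                    alt = mi$alt, id = mi$id,
                    samples = c(sampleIDs(ds1), sampleIDs(ds2)),
                    population = pops,
                    DP = if (hasDP) rbind(depthMatrix(ds1),
                                          depthMatrix(ds2)) else NULL,
                    GQ = if (hasGQ) rbind(qualMatrix(ds1),
                                          qualMatrix(ds2)) else NULL)
}
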