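# panelforge

Tools for the "chip-to-panel" workflow in wildlife and pest population
genetics: start from a dense genotyping-array dataset, select a reduced
panel of SNPs that carry most of the information about source-population
membership, and evaluate how well that panel performs when samples are
re-genotyped with it — for population assignment, cross-platform genotype
concordance, sequencing coverage, and kinship inference. The motivating use
case is monitoring of wild house mouse (*Mus musculus*) populations on
adjoining farms, where managers need to assign trapped animals to source
populations and detect close relatives from a few thousand markers rather
than a full array.

The package is written in Bioconductor style: genotypes live in a
`GenotypeDataset` (an extension of `RangedSummarizedExperiment` whose rows
are SNPs, columns are samples, and whose `dosage` assay counts ALT alleles,
with optional per-genotype `DP`/`GQ`), and every analysis step is an
exported function operating on it. A synthetic-data module simulates
structured, pedigreed populations with sequencing artefacts, so the whole
workflow runs and is tested without any external data.

## The methods in brief

**Marker selection by DAPC.** Discriminant analysis of principal
components first reduces the standardized dosage matrix by PCA (markers
centered by mean dosage and scaled by the binomial SD `sqrt(2p(1-p))`),
then finds axes `a` maximizing the between- over within-population scatter
of the PC scores, solving the generalized eigenproblem `W⁻¹B a = λ a`
scaled so `aᵀWa = 1`. Each marker's contribution to axis `d` is its
normalized squared loading `c_{jd} = B_{jd}² / Σ_j B_{jd}²`; the panel is
the union over the leading axes of the top-percentile contributions. The
number of PCs is chosen by repeated stratified cross-validation: per
replicate a DAPC trained on 90% of each population assigns the held-out
10%, and the K minimizing `sqrt(mean((1 - success)²))` is retained — the
same procedure doubles as the measure of assignment performance.

**Structure-adjusted kinship.** Pairwise kinship uses the PC-Relate family
of moment estimators: individual-specific allele frequencies `μ̂_is` are
predicted per marker by OLS of dosage on the leading PCs, and

    φ̂_ij = Σ_s (g_is − 2μ̂_is)(g_js − 2μ̂_js) /
           [ 4 Σ_s √(μ̂_is(1−μ̂_is)) √(μ̂_js(1−μ̂_js)) ]

with sums over markers where both genotypes are called. With zero PCs this
collapses to the classical frequency-standardized estimator. Dyads are
classified into 1st/2nd/3rd degree/unrelated at the powers-of-two midpoint
thresholds (2^-5/2, 2^-7/2, 2^-9/2).

**QC and evaluation.** Sample/marker missingness filters (inclusive ≥ 10%
boundaries), MAF filtering (monomorphic markers always removed), GQ/depth
masking, and windowed LD pruning (1 kb base-pair window, step 1, removing
one of any surviving pair with dosage `r² > 0.5`). Cross-platform
concordance classifies every shared sample × harmonized shared site cell
into identical / discordant / one-sided missing / both missing, after
REF/ALT swap harmonization. Coverage profiling, off-target SNP
classification (nearest-target distance, 150 bp near/far boundary, far-SNP
clustering) and targeted-locus screening round out the evaluation.

**Simulation.** Population structure follows the Balding–Nichols model
(population frequencies Beta-distributed around an ancestral frequency
with variance `F·p(1−p)`), local LD comes from latent-haplotype copying
within marker blocks, pedigrees are produced by Mendelian gene-dropping
with an exact kinship truth table, and sequencing artefacts are negative
binomial depths with a deterministic GQ map.

## Worked example

```r
library(panelforge)

cfg  <- simConfig(nPops = 2, nPerPop = 40, nMarkers = 4000, fst = 0.1,
                  seed = 7)
ds   <- simGenotypes(simStructuredFreqs(cfg), cfg)
ds
#> GenotypeDataset: 4000 markers x 80 samples
#>   missing genotypes: 0.00%
#>   populations: pop1 (40), pop2 (40)
#>   assays: dosage

st <- filterMissingness(ds)
st <- filterMaf(st$dataset)        # removes 270 low-MAF/monomorphic SNPs
st <- ldPrune(st$dataset)

xv <- crossvalidateDapc(st$dataset, kGrid = c(10, 20, 40), nRep = 20,
                        seed = 7)
xv
#> XValReport: 20 replicates, train fraction 0.9
#>   K mean_success rmse
#>  10            1    0
#>  20            1    0
#>  40            1    0
#>   chosen K:10 (mean success 1.0000)

model <- fitDapc(st$dataset, chosenK(xv))
pan   <- selectPanel(model, percentile = 95, nAxes = 1)
pan
#> PanelSelection: 187 markers from 1 discriminant axes at the 95th percentile
#>   chromosomes represented: 20
```

At this drift level (`F = 0.1`, roughly farm-scale differentiation) every
held-out animal is assigned to its source population at every K on the
grid, and the 95th-percentile cut keeps the ~5% of markers (187 of 3,730)
that carry the most between-population information. `summarizePanel()`
turns the selection into 120-nt capture-probe intervals (BED/FASTA
output).

Kinship on a pedigreed simulation, classical estimator (one population):

```r
ped <- simPedigree(runif(5000, 0.05, 0.95),
                   list(parentOffspring = 2, fullSib = 2, halfSib = 4,
                        cousin = 4, unrelated = 30), seed = 11)
kin <- pcrelate(ped$dataset, nPcs = 0)
deg <- classifyDegree(kin)
```

Averaged over dyads of known degree this recovers the pedigree
expectations 0.25 / 0.125 / 0.0625 (estimated means 0.234 / 0.105 / 0.045
at 5,000 markers, with 99.9% of dyads classified to the correct degree
band). In multi-population samples, `pcrelate(ds, nPcs = 2)` removes the
drift-induced inflation that the classical estimator shows for
within-population dyads.

`runPipeline(pipelineConfig(...))` chains all stages (simulate/load → QC →
cross-validated DAPC → panel selection → panel-restricted re-analysis →
kinship comparison) and writes every artifact plus a manifest that makes
the run reproducible bit for bit.

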