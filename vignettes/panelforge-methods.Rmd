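---
title: "panelforge: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{panelforge: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the parameters that matter,
the numerical conventions, and the places where a genuinely open design
choice had to be made. The companion README shows a worked example; the
test suite and `scripts/acceptance.R` compute every empirical number this
package claims.

## The workflow

`panelforge` implements a design-then-validate loop for reduced SNP
panels. A dense genotype matrix with a-priori population labels is
filtered (missingness, MAF, genotype quality, LD), a DAPC is fitted with
the number of principal components chosen by repeated stratified
cross-validation, markers are ranked by their contribution to the leading
discriminant axes, and the top percentile becomes the capture panel. The
panel is then evaluated the way a re-genotyping experiment would be:
assignment success on held-out samples, genotype concordance between the
platforms, coverage profiles, off-target calls, and agreement of
structure-adjusted kinship estimates between the full and reduced marker
sets.

## Genotype standardization and PCA

Dosages (ALT-allele counts, 0/1/2) are mean-imputed per marker, centered
by the mean dosage, and scaled by the binomial standard deviation
`sqrt(2 p̂ (1 − p̂))` with `p̂` the estimated ALT frequency. This is the
standard scaling for genotype PCA: it weights markers by their expected
information under Hardy–Weinberg rather than their realized variance.
Plain standard-deviation scaling is available (`scaling = "sd"`) because
both conventions are in circulation and downstream DAPC results differ
only mildly; the binomial form is the default. Zero-variance markers get
divisor 1 so they contribute nothing rather than NaNs.

Eigenvectors are computed from the sample covariance of the standardized
matrix; when markers outnumber samples the spectrum is obtained from the
n × n Gram matrix (mathematically identical, much faster at chip scale).
Imputation values, centering means and scales are stored in the model and
re-used verbatim when projecting new samples — prediction never refits
standardization.

`fitPca` requires K ≤ min(n − 1, m) and refuses all-missing markers
(these must be removed by QC first).

## DAPC, posterior membership, and cross-validation

With PC scores S and labels g, the discriminant axes solve
`W⁻¹B a = λ a`, where W is the pooled within-population covariance of S
(divisor n − g) and B the between-population scatter (divisor n − 1);
axes are scaled so `aᵀWa = 1`. The number of axes is min(g − 1, K). The
eigenvalue shares are reported as per-axis percentages of
interpopulation variance. Per-marker loadings on an axis are `B = L·a` on
the standardized-dosage scale, and the selection statistic is the
normalized squared loading (contribution), which sums to 1 per axis —
magnitude, not sign, is what ranks a marker's discriminatory value; the
signed loadings are kept in the model for inspection.

Posterior membership uses an isotropic Gaussian in discriminant space with
equal priors: posterior ∝ exp(−d²/2) to each centroid. Assignment is the
posterior argmax, ties broken deterministically by population order. A
Mahalanobis/shared-covariance variant was considered and rejected as the
default because the isotropic form matches the behaviour users of the
established DAPC implementation expect.

Cross-validation repeats a stratified split (90% of each population to
train, at least one sample held out), refits standardization and PCA on
the training samples only, and scores the held-out assignment. Per
candidate K we report mean success and `RMSE = sqrt(mean((1 −
success)²))`; the chosen K minimizes RMSE, with the smallest K winning
ties. When the two criteria disagree the RMSE winner is chosen — the mean
success at that K is always reported alongside, so the disagreement is
visible. One PCA per replicate at the largest grid K serves every smaller
K, since principal components are nested.

## QC conventions

* Missingness: samples are filtered before markers; both boundaries are
  inclusive (a sample missing exactly 10% of genotypes is removed at the
  default 0.10).
* MAF: monomorphic markers (including all-missing ones, flagged
  `maf_undefined`) are always removed; polymorphic markers are retained
  iff MAF ≥ `minMaf`. The inclusive boundary is the more common
  convention where "MAF > x" and "minimum MAF of x" are used
  interchangeably; it is configurable.
* Quality mask: genotypes with GQ < 30 are set missing; markers with mean
  depth < 10× (boundary kept) and then markers with more than 10% missing
  genotypes are removed, in that order. The stage requires DP/GQ and says
  so rather than silently passing.
* LD pruning: a base-pair window (default 1,000 bp) anchored at the left
  marker and advanced one marker at a time, never spanning chromosomes.
  r² is the squared Pearson correlation of dosages over
  pairwise-complete observations — no imputation inside a QC step — and
  is defined as 0 when fewer than two complete pairs exist. When a pair
  exceeds `r2Max` the member with higher missingness is removed, ties
  broken by lower MAF, then by larger position: the more informative
  marker survives and the rule is deterministic. With step 1 the
  post-condition (no surviving same-chromosome pair within the window
  above `r2Max`) holds and is auditable with `ldPruneAudit()`; larger
  steps trade that guarantee for speed. A marker-count window variant is
  available (`windowMarkers`) since "window size 1 kb" conventions vary
  between tools.

Every filter attributes each removed marker to exactly one rule (the
first that fired) and the report reconciles: removals sum to the
input/output difference. Filters are idempotent.

## Panel selection

For each used axis the threshold is the k-th largest contribution with
`k = ceil((1 − percentile/100) · m)`; markers at or above it are selected,
so boundary ties are all included and 100 distinct contributions at the
95th percentile select exactly 5. (A small epsilon inside the ceiling
guards against floating-point drift in `(1 − p/100)·m`.) Markers selected
on *any* used axis enter the panel — the union, not the intersection; a
pooled mode that thresholds the combined contribution distribution is
available (`pooled = TRUE`) since either reading of "the 95th percentile
of two axes" is defensible. Markers on excluded chromosomes (default MT,
which would dominate capture libraries) are dropped after selection and
counted.

Probe intervals are 1-based inclusive, length `probeLength`, centered
with the SNP at base `probeLength/2 + 1` — the 61st base of a 120-mer.
"Centered" is ambiguous for even lengths, so the convention is stated and
tested. Intervals that would start before position 1 are clipped and
flagged. BED export converts to 0-based half-open coordinates. When a
reference FASTA is supplied, probe sequences are extracted uppercase and
flagged (not removed) if they contain N or a homopolymer run of 15+
bases — a stand-in for the vendor's off-target screening, which is out of
scope.

## Concordance, coverage, off-target calls

Concordance matches samples by id and sites by (chrom, pos). Sites with
identical REF/ALT are compared directly; swapped REF/ALT are compared as
`gA` vs `2 − gB` and logged; anything else (different ALT, indels) is
dropped and logged, and the run errors if nothing survives. No strand
flipping is attempted: both platforms in this workflow share a reference
orientation, and strand-ambiguous harmonization is documented as out of
scope. The denominator for the identical/discordant percentages is the
full shared-sample × harmonized-site grid, including missing cells; the
reciprocal missingness ratio is reported as undefined on a 0/0.

Coverage profiles are per-sample proportions of targets at or above each
threshold (non-increasing by construction). Off-target classification
assigns each called non-panel SNP its distance to the nearest same-
chromosome target (infinite if none), near/far at an inclusive 150 bp —
the span of a capture sequencing read — and groups far SNPs into clusters
when consecutive ones lie within 10 kb. The cluster gap is our
operationalization of qualitative clustering; it is a parameter, not a
claim.

## Kinship

The estimator regresses each marker's dosage on an intercept plus the
leading PCs (OLS across samples with called genotypes), halves the fitted
value to get an individual-specific allele frequency `μ̂`, clips it to
[0.01, 0.99], and forms the moment ratio

    φ̂_ij = Σ_s (g_is − 2μ̂_is)(g_js − 2μ̂_js) /
           [4 Σ_s √(μ̂_is(1−μ̂_is)) √(μ̂_js(1−μ̂_js))]

over markers where both genotypes are called. Markers whose `μ̂` was
clipped still contribute (the clipped value is used) so per-dyad marker
counts stay stable. With `nPcs = 0` the fitted value is the marker mean
and the estimator reduces exactly to the classical frequency-standardized
form — a reduction the tests verify to 1e−10 against an independent
implementation. The diagonal holds the analogous self-moment, (1 +
inbreeding)/2 in expectation.

Two deliberate simplifications, both documented limitations:

* PCs and the OLS fits use **all** samples — the original method's
  iterative unrelated-set refinement is not implemented. Consequently,
  when the number of PCs exceeds the true dimension of population
  structure, the extra PCs align with the strongest family blocks in the
  sample and absorb part of the very relatedness being estimated. In our
  two-population simulations with embedded pedigrees this attenuates
  related-dyad estimates by roughly 0.01–0.025 depending on class — inside
  the ±0.03 recovery tolerance the tests assert, but a real analysis with
  many large families should use fewer PCs (match the structure
  dimension) or an implementation with unrelated-set refinement.
* Degree thresholds default to the powers-of-two midpoints (2^−5/2,
  2^−7/2, 2^−9/2 ≈ 0.177/0.088/0.044); they are configurable since no
  universal convention exists.

The default of 2 PCs suits the two-site study design the package
emulates; it is a parameter everywhere.

## The synthetic-data generator

The generator's job is to emulate the study conditions the workflow was
built for, not to be a general population-genetics simulator.

* **Structure**: ancestral frequencies Uniform(0.05, 0.95) (avoiding
  monomorphic draws dominating small simulations), population frequencies
  Beta(p(1−F)/F, (1−p)(1−F)/F) — mean p, variance F·p(1−p). F = 0 returns
  p exactly; F = 1 is rejected as degenerate. A chain mode drifts each
  population from its neighbour to mimic isolation by distance; the
  default star drifts all from the ancestor. Farm-scale differentiation
  in the motivating system is emulated at F ≈ 0.1; tests also exercise
  0.01–0.05.
* **Genome**: 19 autosomes + X, positions strictly increasing, markers in
  an LD block placed 10–300 bp apart and blocks 2–10 kb apart so block
  structure and the 1 kb pruning window interact the way array data does.
  Sex chromosomes are placed but inherited autosomally — a documented
  simplification.
* **LD**: individuals carry two latent uniform lineages per block; an
  allele is 1 iff its lineage's uniform lies below the marker frequency,
  and each lineage re-draws with probability `ldLeak` per marker. This
  latent-haplotype copying produces tunable within-block r² that decays
  with leak rate — sufficient to exercise r² pruning — but it is not a
  coalescent: no recombination map, no allele-frequency/LD correlation,
  no long-range decay. Tests passing on it say nothing about those
  features of real data.
* **Pedigrees**: founders draw Hardy–Weinberg genotypes; descendants get
  one allele from each parent per marker, independently across markers
  (no linkage in transmission). The truth table carries exact pedigree
  kinship from the standard recursion, so estimator recovery is checked
  against truth, not against another estimator. Cyclic pedigrees are
  rejected.
* **Artefacts**: genotypes are set missing with probability `missRate`
  and perturbed to a different valid dosage with probability `errorRate`.
  Depths are negative binomial with mean `meanDepth` and size
  `depthDispersion`; the defaults (27.6, 11) reproduce the capture
  coverage regime of the motivating study (mean ≈ 27.6×, SD ≈ 9.8×). GQ
  is the deterministic map `min(99, round(3·DP))` — no published GQ model
  exists for this pipeline and only the ≥ 30 threshold matters
  downstream, so the slope is chosen to put the conventional GQ 30
  boundary at 10× depth. DP = 0 forces a missing genotype.
* **Reproducibility**: every stochastic function takes an explicit seed
  and restores the caller's RNG state; identical seed and configuration
  give byte-identical VCF output.

## Problem sizes in the tests

The suite exercises the workflow at sizes chosen to make Monte Carlo
error small relative to the tolerances asserted: cross-validated
assignment at 2 × 150 samples × 3,500 markers (100 replicates), kinship
recovery at 5,000 markers with ~60 pedigree dyads per run, LD-pruning
audits over 50 random fixtures, and a chip-scale end-to-end run at 70,000
markers for the full design-then-validate loop. Oracle-equivalence checks
(PCA/DAPC eigenstructure, the classical-kinship reduction) run on
fixtures small enough for dense brute-force linear algebra.

## Known limitations

Beyond the simulator's simplifications listed above: no imputation or
phasing anywhere (the workflow is dosage-based and phase is ignored on
input); no Hardy–Weinberg or sex-check QC; no strand-ambiguity handling in
concordance; no thermodynamic probe design; kinship reports the dyad
coefficient only (no k0/k2 decomposition or IBD segments); and the
pipeline consumes called genotypes — read processing, alignment and
variant calling happen upstream.
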