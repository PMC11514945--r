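# devostate

Developmental-status-aware decomposition of bulk transcriptomes.

Adult tissues and tumors carry transcriptional traces of *fetal* cell
programs; in cancer, the resurgence of those programs is a quantitative
signature of dedifferentiation. `devostate` is for computational biologists
who have (a) an annotated single-cell reference with both fetal and adult
cells of a tissue and (b) bulk RNA-seq cohorts of that tissue, and who want
a per-sample measure of how "fetal" each bulk transcriptome is — plus the
statistics to relate that measure to hallmarks, survival, markers, CRISPR
dependencies and drug response.

## Method at a glance

1. **Signature matrix.** From UMI counts with (tissue, cell type,
   fetal/adult stage) annotations: drop cells with < 500 UMIs, CPM-
   normalize, drop states with < 20 cells, form 10 "mega cell" replicates
   per state (mean CPM of a random half of its cells), test each state
   one-vs-rest per gene (Mann–Whitney U, BH adjustment), take the top 200
   genes with adjusted p < 0.01 by log2 fold change, remove exclusion-list
   genes before truncation, and pool per-state mean CPM over all cells into
   a genes × states matrix *S* with a fetal/adult label per state.
2. **Decomposition.** For a bulk TPM profile *m* (FPKM is converted by
   TPM = FPKM / ΣFPKM × 10⁶), solve *m ≈ S f* for relative fractions
   *f ≥ 0, Σf = 1* — by linear ν-support-vector regression (ν ∈ {0.25, 0.5,
   0.75}, z-scored inputs, lowest-RMSE fit kept, negative coefficients
   clipped, renormalized) or by non-negative least squares.
3. **Fetalness index.** fetalness(sample) = Σ of its fractions over
   fetal-labelled states ∈ [0, 1].
4. **Downstream.** iPAGE-style mutual-information enrichment of gene sets
   in genes correlated with the index (15 rank bins, permutation p, signed
   via the per-bin profile); fetal-centroid k-nearest-neighbor enrichment
   in 10-PC space; Cox / Kaplan–Meier survival association; stem-cell
   marker correlation shift; CERES < −0.5 dependency enrichment (Fisher);
   drug-AUC Spearman correlations.

Everything is testable offline: seeded generators produce annotated
references with planted markers, Dirichlet mixtures with known fractions,
survival cohorts with a planted hazard, and gene-set designs with a planted
enrichment.

## Worked example

```r
library(devostate)

# a synthetic tissue: 4 fetal + 4 adult states, planted markers
sim <- simulateReference(n_genes = 1000, n_cells_per_state = 100, seed = 11)
sig <- buildSignature(sim$reference, seed = 12)
sig
#> SignatureMatrix: 762 signature genes x 8 cell states
#>   4 fetal / 4 adult states

# noisy bulk mixtures with known ground truth, then decomposition
hq   <- filterCells(sim$reference)
prof <- stateMeanCPM(normalizeCPM(hq), hq)
mx   <- simulateMixtures(prof, n_samples = 50, noise_sigma = 0.2, seed = 13)
res  <- decomposeCohort(mx$bulk, sig, solver = "nnls")
res
#> CellStateFractions: 50 samples x 8 cell states ( 50 decomposed )
#>   4 fetal / 4 adult states; solver: nnls

fi <- fetalnessIndex(res)
round(head(fi, 4), 3)
#> sample0001 sample0002 sample0003 sample0004
#>      0.702      0.396      0.772      0.558

truef <- rowSums(mx$fractions[, grep(":fetal$", colnames(mx$fractions))])
cor(fi, truef, method = "spearman")
#> [1] 0.978

# survival association of the index (planted log-hazard 2 per unit)
surv <- simulateSurvivalCohort(fi, beta = 2, baseline_hazard = 0.02,
                               censor_rate = 0.3, seed = 14)
coxAssociation(fi, surv, min_events = 5)
#>     hr ci_lo ci_hi loghr    se       p  n events
#> 1 1.73  1.17  2.57 0.551 0.201 0.00608 50     31
```

The fetalness values are each sample's estimated total fetal cell-state
mass; here they track the generator's ground truth at Spearman ρ = 0.978
despite σ = 0.2 multiplicative noise, and the Cox fit recovers a hazard
ratio of 1.73 per SD of the index (p ≈ 0.006) from the planted effect.

There is also a command-line interface (`inst/scripts/devostate`) with
subcommands `build-signature`, `decompose`, `embed`, `neighbor-enrich`,
`enrich`, `survival`, `depmap-enrich`, `drug-corr` and `simulate`; every run
writes a `*.manifest.json` with parameters, seeds and input/output
checksums, and `rerunFromManifest()` replays a run byte-for-byte.

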