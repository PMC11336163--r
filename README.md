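# poplayers

Layered population-genomic structure from RAD-seq SNP genotypes.

Population structure in high-gene-flow marine fishes is rarely the first
signal in a SNP dataset. In Arctic gadids (and many other taxa) it sits
underneath several stronger layers: interspecific hybrids and individuals
carrying another species' mitochondria, Mbp-scale chromosomal inversions
whose three arrangement genotypes (AA/AB/BB) masquerade as "populations",
sex-linked genomic segments, and a minority of high-differentiation outlier
loci that dominate every ordination. `poplayers` implements the sequential
peeling of those layers as tested, reusable R functions, for population
geneticists working with ddRAD/RAD-seq biallelic SNP matrices (VCF in,
tibbles out).

## What it computes

* **Species screen** — binomial-likelihood ancestry (block-EM `admixture_em()`
  with fivefold cross-validation over K), combined with diagnostic
  mitochondrial sites into a per-sample class: pure focal species, second
  species, admixed, or focal-nuclear with introgressed mtDNA
  (`classify_species()`, `species_summary()`).
* **Inversion detection & karyotyping** — windowed aggregation of squared
  PCA allele loadings with a robust genome-wide background
  (`detect_aggregated_regions()`), site-level mean r² in a 100 kbp–5 Mbp
  window (`site_mean_r2_profile()`), then local PCA + k-means on PC1 with
  the heterozygosity signature of arrangement heterozygotes
  (`karyotype_region()`): for a region with inversion-allele frequency *p*,
  karyotype classes follow Hardy–Weinberg (p², 2pq, q²) and the AB cluster
  is the heterozygosity maximum.
* **Sex-linked segments** — a genotype-level RADSex-style scan: per-marker
  2×2 sex-association tests (chi-square with continuity correction, exact
  where appropriate) under Bonferroni control, with signed male-minus-female
  bias (`sex_scan()`).
* **Outlier partition** — a PCAdapt-style scan: per-locus z-scores from
  regressions on the leading PCs, robust Mahalanobis D², genomic-inflation
  (λ) rescaling, chi-square p-values and Benjamini–Hochberg q-values
  (`pcadapt_outliers()`).
* **Population structure & diversity** — mean-imputed centered PCA
  (`pca_genotypes()`), DAPC with BIC cluster discovery (`find_clusters()`,
  `dapc_genotypes()`), pairwise Weir–Cockerham θ with locus bootstrap
  (`wc_fst()`), per-individual inbreeding F (`individual_inbreeding()`),
  Kruskal–Wallis + Dunn group tests (`group_het_tests()`).
* **QC** — the usual SNP/sample filter cascade with a count ledger,
  KING-robust kinship (`king_kinship()`) and relatedness pruning, one SNP
  per RAD locus, two-stage LD pruning (`ld_prune()`).
* **Synthetic data** — `sim_config()` / `simulate_dataset()` generate a full
  dataset with known truth (two species, hybrids/backcrosses with maternal
  mtDNA, island-model demes at target FST via Balding–Nichols draws,
  planted inversions, an XY-like segment, related pairs), so every stage of
  the pipeline is testable without sequence data.

All of it is chained by `run_pipeline()`, which mirrors the staged design:
QC → species screen → MAF re-filter → inversion/sex detection → region
removal → structure → outlier partition → LD pruning → final structure,
with every removal appended to a filtering ledger.

## Worked example

Simulate a full-feature dataset (two species, three demes at FST 0.01, a
16-Mbp inversion on chr09 at inversion-allele frequency 0.3, a 1.9-Mbp
male-limited segment on chr13, three BC2 backcrosses, related pairs), then
run the whole pipeline:

```r
library(poplayers)

cfg <- sim_config(seed = 11, n_loci = 2000,
                  hybrid_spec = tibble::tibble(class = "BC2", n = 3,
                                               maternal = "A"))
sim <- simulate_dataset(cfg)
sim$geno
#> <geno> 134 samples x 1997 loci (5 chromosomes), 5.4% missing

run <- run_pipeline(sim$geno, sim$samples, pipeline_config(seed = 1))
run$ledger
#> # A tibble: 10 × 4
#>    step                        n_snps n_loci n_samples
#>    <chr>                        <int>  <int>     <int>
#>  1 input                         1997   1429       134
#>  2 snp_filter                    1955   1406       134
#>  3 sample_missingness            1955   1406       134
#>  4 relatedness                   1955   1406       132
#>  5 one_snp_per_locus             1406   1406       132
#>  6 remove_speciesA_and_admixed   1406   1406       120
#>  7 maf_refilter                  1095   1095       120
#>  8 remove_flagged_regions         921    921       120
#>  9 remove_outlier_loci            911    911       120
#> 10 ld_prune                       430    430       120
```

The ledger reads like the filtering table of a RAD-seq paper: 2 related
samples pruned (the planted duplicate and parent–offspring pairs), 12
samples dropped at the species stage (9 second-species individuals and the
3 backcrosses — mito-discordant focal-species samples are deliberately
retained), then flagged regions, outlier loci and linked loci removed.

The inversion stage recovered the planted chr09 region and karyotyped it:

```r
run$stages$inversions$karyotypes[[1]]
#> <karyotype_call> chr09:7055052-23679945 (165 SNPs)
#>   AA=60  AB=49  BB=11
#>   p_inv = 0.296, confirmed = TRUE
```

`p_inv` estimates the planted 0.3; `confirmed` means PC1 showed three modes
and the AB cluster was the heterozygosity maximum. The sex stage located
the planted male-limited segment from the unfiltered input matrix:

```r
run$stages$sex$regions
#> # A tibble: 1 × 4
#>   chrom    start      end n_significant
#>   <chr>    <dbl>    <dbl>         <int>
#> 1 chr13 16125807 17841458            21
```

Each fitted object has `tidy()` / `glance()` / `autoplot()` methods, e.g.
`autoplot(pca_genotypes(run$geno), colour = ...)` for ordination plots or
`autoplot(run$stages$sex$scan)` for the sex-association Manhattan plot.

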