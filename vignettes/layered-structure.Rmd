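---
title: "Peeling layered genomic structure: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peeling layered genomic structure: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`poplayers` analyses a biallelic SNP dosage matrix (samples × loci, entries
0/1/2/missing) the way a population geneticist working on a high-gene-flow
marine fish has to: by removing, in order, every signal that is *stronger*
than population structure before interpreting population structure itself.
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open.

## The layered workflow

The fixed stage order in `run_pipeline()` encodes an epistemic hierarchy:

1. **QC** — per-SNP filters (MAF, missingness, heterozygosity, depth),
   per-sample missingness, kinship pruning, one SNP per RAD locus.
2. **Species screen** — K = 2 ancestry plus diagnostic mtDNA sites; the
   second species and admixed individuals are removed. Individuals with
   focal-species nuclear genomes but the other species' mtDNA are
   *retained*: maternal introgression does not disqualify a nuclear genome
   from population analyses, and keeping them is itself a finding worth
   tabulating (`species_summary()`).
3. **Inversion and sex screens** on the species-clean matrix, then removal
   of every confirmed region.
4. **Structure** (PCA, DAPC, ancestry) on the region-free matrix.
5. **Outlier partition** and removal, then **LD pruning**, then a final
   structure pass on the neutral, unlinked set.

Each removal appends a row to a count ledger, so the provenance of the
final locus set is a table, not a narrative.

## Models and estimators

### PCA on dosages

`pca_genotypes()` centers each locus by its mean dosage and replaces
missing calls by that mean (zero after centering) — the mean-imputation
convention of genlight-style PCAs. The SVD of the centered matrix gives
sample scores, unit-norm locus loadings, and eigenvalues `d²/(n−1)`.
Dosages are centered but **not** variance-scaled by default (`scale =
FALSE`); scaling equalizes the influence of rare and common alleles, which
is undesirable when loading profiles are later used to localize signal.
Axis signs are unidentifiable; they are canonicalized so the
largest-magnitude loading on each axis is positive, which makes runs
reproducible but carries no meaning.

Mean imputation shrinks scores of high-missingness samples toward the
origin. That bias is acceptable here because samples above 30 % missingness
have already been removed.

### Ancestry (admixture model)

`admixture_em()` maximizes the standard binomial admixture likelihood
$$L=\sum_{il}\left[g_{il}\ln\!\sum_k q_{ik}f_{kl} + (2-g_{il})\ln\!\sum_k q_{ik}(1-f_{kl})\right]$$
by block EM updates of the ancestry matrix Q and cluster frequencies F,
skipping missing entries. EM is monotone in the log-likelihood (asserted in
the tests at every iteration), converges to local optima only, and is
slower than the quasi-Newton acceleration of dedicated tools — hence
multiple random restarts (default 5; Q from a flat Dirichlet, F from
jittered global frequencies) with the best likelihood kept. Convergence is
relative: `tol = 1e-6` on the log-likelihood. F is clamped to
`[1e-6, 1−1e-6]`, so "fixed" cluster frequencies are never exactly 0/1 and
pure individuals sit near, not at, the simplex boundary.

A consequence worth knowing: when the two species' diagnostic allele
frequencies differ by 0.96 (the generator default), a *pure* focal
individual still carries a few of the other species' alleles, and its
maximum-likelihood minor ancestry is ≈ 0.015, not 0. Hybrid thresholds must
sit above this floor; the default `admix_threshold = 0.05` separates that
floor from the BC2–BC1 range (0.125–0.25) comfortably.

`admixture_cv_error()` masks 1/folds of the non-missing genotypes per fold,
refits, and scores squared prediction error of masked dosages against
`2·QF`. Masking destroys signal: with weak structure (FST ≈ 0.05) reliable
K selection needed ≥ 5 folds and ≥ 200 EM iterations in our tests; three
folds mask a third of the data and push selection toward K = 1.

### Cluster discovery and DAPC

`find_clusters()` runs multi-restart k-means on retained PC scores for
k = 1…k_max and scores each solution with
`BIC(k) = n·ln(WSS_k/n) + k·ln(n)`. This hard-assignment BIC is the
convention of the tool it mirrors, not a proper mixture BIC: on
*low-dimensional, strongly separated* toy data it keeps rewarding splits
and drifts toward k_max. With realistic inputs — a few informative axes
plus many noise axes, which is what genetic PC scores look like — the WSS
gain beyond the true k is negligible and the penalty dominates, so the
minimum lands correctly. Use it on a generous set of PCs, not on two.

`dapc_genotypes()` retains the fewest PCs reaching `var_retained` (default
0.80, the "ca. 80 % of variation" convention) and runs linear discriminant
analysis on them; discriminant loadings are back-rotated through the PC
rotation to locus space for loading profiles. A singular within-cluster
scatter (possible with duplicated samples) is handled by an infinitesimal
ridge jitter, with a warning.

### Linkage disequilibrium

`pairwise_r2()` is the squared Pearson correlation of dosages over jointly
non-missing samples — composite genotypic LD, the genotype-mode statistic
of standard toolkits; no phasing is assumed anywhere. The site-level
profile averages r² over partners at 100 kbp–5 Mbp (inclusive) on the same
chromosome: the lower bound excludes trivial short-range LD, the upper
bound targets the Mbp scale at which recombination-suppressed blocks
(inversions) stand out. Sites without in-window partners are flagged
(`NA`), never zero-filled — a zero would fake evidence of equilibrium.

`ld_prune()` is a greedy keep-first scan in genome order (drop a locus if
r² > 0.05 with a retained locus within 10 Mbp, or r² > 0.1 with a retained
locus on another chromosome). Greedy keep-first matches the "keep the
first SNP" spirit of RAD pipelines and makes the retained set stable under
re-scan; the inter-chromosome stage compares against retained loci only,
which keeps the scan near-linear. A minimum of 20 joint observations
(`min_obs`) guards against noise r² from tiny overlaps.

### Inversion detection and karyotyping

Detection (`detect_aggregated_regions()`) replaces visual inspection of
loading profiles with an explicit rule: sum squared loadings (or mean r²)
in 1-Mbp windows, flag windows exceeding `median + 4·MAD`, merge flagged
windows within 2 Mbp, snap region bounds to the outermost contributing
SNPs, and discard regions supported by fewer than 10 SNPs. The robust
background is estimated **genome-wide**: a 16-Mbp block spans more than
half of its own chromosome, so a per-chromosome background would swallow
it. Chromosomes with fewer than 10 windows are skipped (no basis for a
background) with a warning.

Karyotyping (`karyotype_region()`) is local PCA on the region's SNPs,
k-means (k = 3, 25 restarts) on PC1, clusters ordered along PC1 with the
middle cluster called AB. Because ancestral arrangement polarity is
unknowable from genotypes alone, AA is defined as the *larger* homozygote
cluster; this convention is invariant under allele recoding. A call is
`confirmed` only if (a) a Gaussian mixture on PC1 supports three modes by
BIC and (b) the AB cluster has the strictly highest mean observed
heterozygosity. Both conditions are necessary: on pure-noise SNPs k-means
happily splits the continuous PC1 blob into three, and the middle slice is
mildly heterozygote-enriched for purely geometric reasons — only the
multimodality requirement rejects it. Samples farther than 3 within-cluster
SDs from every center are left `unassigned`. The inversion-allele frequency
is `p_inv = (2·n_BB + n_AB) / (2·n_assigned)`, and under random mating the
karyotype classes should fit Hardy–Weinberg (p², 2pq, q²) — asserted by a
goodness-of-fit test on simulated data.

### Sex-linked markers

`sex_scan()` is a genotype-level analog of a read-level presence/absence
sex scan. Reads are out of scope, so "presence" is a non-missing genotype
(mode `presence`, default), with alt-carrier and allele-dosage modes as
alternatives. Each marker gives a 2×2 table of sex × property, tested by
chi-square with continuity correction; Fisher's exact test replaces it
whenever an expected cell is < 5 *or an observed cell is 0* — the zero-cell
table is exactly the fully-sex-limited pattern being hunted, and the
chi-square approximation is poorest there. Bonferroni control uses the
number of *tested* markers (those with ≥ `min_per_sex` eligible individuals
per sex); untested markers are reported as untested, never as p = 1. Bias
is the signed male-minus-female frequency, so a positive significant
segment is XY-like (male heterogamety) — inferred, not assumed.

In the pipeline the scan runs on the **unfiltered input matrix**:
presence/absence sex markers are ~50 % missing by construction and can
never survive a 10 % missingness filter, mirroring why read-level scans run
before SNP filtering.

### Outlier scan

`pcadapt_outliers()` regresses each standardized locus on the first K
(default 2) PC score directions; the K-vector of t-like z-scores is
summarized by a Mahalanobis distance with robust location (coordinate-wise
median) and MAD-based diagonal scatter — the z-components are
near-uncorrelated by construction since the score directions are
orthogonal, so a full robust covariance is unnecessary (and is the kind of
refinement that destabilizes small-n scans). The genomic inflation factor
λ = median(D²)/median(χ²_K) rescales distances before upper-tail χ²_K
p-values; q-values are Benjamini–Hochberg (slightly conservative relative
to adaptive π₀ estimators). Flags: `q < 0.05` (FDR set) and `p < 0.05/L`
(Bonferroni set). The pipeline removes the FDR set by default.

A calibration note: with outliers planted as Balding–Nichols draws at 10×
the background FST, many "outlier" loci realize small cross-deme divergence
by chance — no scan can recover those. Realized false-discovery proportion
stays well under the nominal rate in our simulations, but power against
this planting model plateaus below what a fixed-effect-size planting would
give.

### Differentiation, diversity, kinship

`wc_fst()` implements the Weir & Cockerham (1984) variance components
a/b/c per biallelic locus with unequal sample sizes, multi-locus
θ = Σa/Σ(a+b+c), and a bootstrap over loci (default 1000 replicates) for
the one-sided test of θ ≤ 0 plus a percentile CI. Loci monomorphic across
the pair, or with fewer than two genotyped samples in either group, are
excluded.

`individual_inbreeding()` reproduces the method-of-moments statistic of
VCFtools `--het`: per sample, `F = (O_hom − E_hom)/(L − E_hom)` with the
small-sample correction `2n/(2n−1)` in the expected homozygosity.
Monomorphic loci are excluded (they carry no information and would inflate
both O and E).

`king_kinship()` is the KING-robust within-pair estimator
φ = (N_Aa,Aa − 2·N_AA,aa)/(N_Aa,i + N_Aa,j): ≈ 0.5 for duplicates, 0.25
for parent–offspring, 0 for unrelated pairs *under homogeneous
frequencies*. Two caveats are documented behaviour, not bugs: pairs of
inversion heterozygotes share excess heterozygosity at divergent sites and
can reach φ ≈ 0.15; and the denominator can be 0 for heterozygote-free
pairs (reported as undefined). The pruning threshold default is 0.177 (the
conventional 2nd-degree cutoff); the higher member-by-missingness is
dropped, ties broken lexicographically, iterating until no flagged pair
survives.

`group_het_tests()` wraps the rank-based Kruskal–Wallis H (with tie
correction) and hand-computed Dunn pairwise z-tests on mean ranks with the
same tie correction; the default multiplicity adjustment is Bonferroni.

## The synthetic-data generator

`simulate_dataset()` emulates the *statistical structure* the analyses
assume, not the sequencing process:

* **Two species** with near-fixed divergence at a diagnostic subset of loci
  (default 25 % of background loci at an allele-frequency gap of 0.96) and
  species-diagnostic maternal mtDNA (two diagnostic sites, with a small
  no-call rate).
* **Hybrids by explicit pedigree**: F1 = one gamete per species; BCg =
  gamete of the previous hybrid × fresh recurrent-parent gamete, free
  recombination between loci; expected minor ancestry 0.5^(g+1); mtDNA
  follows the declared maternal lineage.
* **Demes** via Balding–Nichols draws: locus frequency per deme
  ~ Beta(p(1−F)/F, (1−p)(1−F)/F) around an ancestral p ~ U(0.05, 0.95),
  with F the target FST (default 0.01, the weak-differentiation regime of
  marine fish). Outlier loci get F multiplied by 10 (capped at 0.8) in a
  default 10 % of neutral loci.
* **Inversions**: each sample draws an arrangement count from
  Binomial(2, p_inv); at a "divergent" fraction (default 80 %) of region
  loci the two arrangements are internally near-monomorphic haplotype
  groups (alt frequency 0.05 vs 0.95), so AB samples are heterozygous at
  those sites and all region loci are correlated through the shared
  karyotype. There is no within-region recombination gradient.
* **Sex**: an XY-like segment where a default 60 % of region markers are
  male-limited at the presence level (present in 90 % of males, 2 % of
  females, absent = missing); sex is recorded for a default 50 % of
  individuals, mirroring partially-sexed field collections.
* **Nuisance**: uniform random missingness (5 %), lognormal per-locus
  median depth (median 30×), RAD loci carrying 1–3 SNPs within 90 bp, one
  duplicate and one parent–offspring pair.

All randomness flows from a single seed through a fixed draw order, so a
configuration is a complete specification of its dataset (asserted
byte-identical in the tests).

**What passing tests do and do not show.** The generator has no linked
selection, no isolation-by-distance, no batch effects, no
genotyping-error model, no allele dropout, no within-inversion
recombination, and missingness independent of genotype. Tests passing on
this data demonstrate that the estimators recover the structures they
model under their own assumptions — not that those assumptions hold in any
particular empirical dataset.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; BED input is converted at
  the reader boundary. Region membership and distance windows are
  inclusive on both ends.
* Missing dosage is `NA`, never 0; statistics use sitewise/pairwise
  complete observations except where mean imputation is stated (PCA,
  outlier scan).
* Strict vs inclusive thresholds in QC: MAF and missingness are strict
  inequalities (`maf > min`, `missing < max`); heterozygosity and depth
  bounds are inclusive. The heterozygosity screen defaults to *observed*
  heterozygosity (the paralog-collapse signature) with expected-H as an
  option.
* All-missing or monomorphic loci yield `NA` statistics, not errors;
  all-monomorphic matrices, empty subsets, and K ≥ n requests abort with
  explicit messages.
* Reported percentages round half away from zero at one decimal
  (`round_half_up()`), so 2.56 % prints as 2.6.
* Test and acceptance problem sizes — 10²–10³ samples × 10³–5·10³ loci,
  200 null replicates, 500 permutations, 1000 bootstrap replicates — were
  chosen as the smallest sizes at which the binomial/Monte-Carlo noise of
  each checked quantity is comfortably inside its assertion band.

## Open design decisions

* The kinship flag in the source study reads "Φ < 0.3" where only "> 0.3"
  is coherent (removing the *least* related pairs is meaningless); we
  implement "remove above threshold" with 0.177 as default and 0.3
  available.
* Whether the inter-chromosomal LD prune should be exhaustive is
  unknowable from the description of the original tool; the greedy
  retained-set variant is the default and the only implemented mode, for
  its complexity and stability properties.
* Chromosome naming is treated as opaque strings; the package never
  resolves chromosome↔accession pairings.
* A two-peak chromosome may be one inversion or two; detection reports
  whatever the merge gap implies (2 Mbp default) and karyotyping accepts
  manual region input, so both readings can be tested.
* The final outlier removal uses the FDR set by default; the Bonferroni
  set is a configuration flag.

## Known limitations

* The admixture EM is an order of magnitude slower than quasi-Newton
  implementations; it is intended for 10²–10³ samples × 10³–10⁴ loci.
* LD computations build per-chromosome correlation matrices; beyond ~10⁴
  loci per chromosome, memory becomes the constraint.
* Karyotyping assumes exactly three PC1 modes; a fixed or absent inversion
  (one or two modes) is reported unconfirmed rather than re-modelled.
* Inversion detection requires the aggregated signal to reach a leading PC
  axis; a rare inversion confined to deep axes needs the LD-profile route
  or manual regions.
* The sex scan's presence mode inherits the biases of genotype
  missingness; with depth data available, a read-level scan remains the
  stronger instrument.
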