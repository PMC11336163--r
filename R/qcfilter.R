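#' Create an empty filter ledger
#'
#' The ledger mirrors the staged filtering table of a RAD-seq study: one row
#' per step with the SNP, RAD-locus and sample counts retained after it.
#'
#' @return an empty ledger tibble
#' @export
new_ledger <- function() {
  tibble(step = character(), n_snps = integer(), n_loci = integer(),
         n_samples = integer())
}

#' Append a ledger row describing the current state of a genotype matrix
#' @param ledger a ledger tibble (or `NULL` to start one)
#' @param step label of the filtering step just applied
#' @param g the [geno()] object after the step
#' @return the ledger with one more row
#' @export
ledger_add <- function(ledger, step, g) {
  if (is.null(ledger)) ledger <- new_ledger()
  n_rad <- if ("locus_id" %in% names(g$loci))
    length(unique(g$loci$locus_id)) else n_loci(g)
  bind_rows(ledger, tibble(step = step, n_snps = n_loci(g),
                           n_loci = as.integer(n_rad),
                           n_samples = n_samples(g)))
}

#' SNP-level filter on frequency, missingness, heterozygosity and depth
#'
#' Retains loci with `maf > maf_min`, `missing_rate < max_missing_rate`,
#' heterozygosity `<= het_max` and (when median depth is available) median
#' depth inside `depth_range` (inclusive). The heterozygosity screen targets
#' paralog collapse; by default it uses observed heterozygosity, with
#' expected heterozygosity available via `het_mode`.
#'
#' @param g a [geno()] object
#' @param maf_min minimum minor allele frequency (strict)
#' @param max_missing_rate maximum per-locus missing rate (strict)
#' @param het_max maximum heterozygosity (inclusive bound)
#' @param het_mode `"observed"` (default) or `"expected"`
#' @param depth_range length-2 numeric, inclusive median-depth bounds, or
#'   `NULL` to skip
#' @return list with `geno` (filtered) and `stats` (the per-locus statistics
#'   with a logical `kept` column)
#' @export
snp_filter <- function(g, maf_min = 0.01, max_missing_rate = 0.10,
                       het_max = 0.6, het_mode = c("observed", "expected"),
                       depth_range = c(10, 95)) {
  het_mode <- match.arg(het_mode)
  st <- site_allele_stats(g)
  het <- if (het_mode == "observed") st$h_obs else st$h_exp
  keep <- !is.na(st$maf) & st$maf > maf_min &
    st$missing_rate < max_missing_rate & het <= het_max
  if (!is.null(depth_range) && "median_depth" %in% names(g$loci)) {
    dp <- g$loci$median_depth
    keep <- keep & (is.na(dp) |
                      (dp >= depth_range[1] & dp <= depth_range[2]))
  }
  if (!any(keep)) abort("snp_filter removed every locus")
  list(geno = subset_geno(g, loci = keep), stats = mutate(st, kept = keep))
}

#' Drop samples with excessive missing data
#'
#' @param g a [geno()] object
#' @param max_missing maximum per-sample fraction of missing genotypes
#'   (strict: samples with a rate above the threshold are dropped)
#' @return list with `geno` and `removed` (sample ids dropped)
#' @export
sample_filter <- function(g, max_missing = 0.30) {
  rate <- rowMeans(is.na(g$G))
  drop <- rate > max_missing
  if (all(drop)) abort("sample_filter removed every sample")
  list(geno = if (any(drop)) subset_geno(g, samples = g$samples[!drop]) else g,
       removed = g$samples[drop])
}

#' Robust pairwise kinship (KING within-pair estimator)
#'
#' For each sample pair, over the jointly non-missing loci, computes
#' \deqn{\phi = (N_{Aa,Aa} - 2 N_{AA,aa}) / (N_{Aa,i} + N_{Aa,j})}
#' where \eqn{N_{Aa,Aa}} counts loci where both are heterozygous,
#' \eqn{N_{AA,aa}} loci with opposite homozygotes, and the denominator sums
#' the two members' heterozygous-locus counts. This is the robust estimator
#' behind VCFtools' `relatedness2`: ~0.5 for duplicates, ~0.25 for
#' parent-offspring, near 0 for unrelated pairs.
#'
#' @param g a [geno()] object
#' @param min_sites minimum shared non-missing loci; pairs below it get
#'   `NA` phi
#' @return tibble (sample_i, sample_j, phi, n_sites), one row per unordered
#'   pair
#' @export
king_kinship <- function(g, min_sites = 100) {
  check_that(n_samples(g) >= 2, "need at least two samples")
  G <- g$G
  n <- nrow(G)
  obs <- !is.na(G)
  het <- (G == 1L) & obs
  alt2 <- (G == 2L) & obs
  ref0 <- (G == 0L) & obs
  # pairwise counts via crossproducts of indicator matrices
  mode(obs) <- "numeric"; mode(het) <- "numeric"
  mode(alt2) <- "numeric"; mode(ref0) <- "numeric"
  n_shared <- tcrossprod(obs)
  n_hh <- tcrossprod(het)
  n_opp <- tcrossprod(ref0, alt2) + tcrossprod(alt2, ref0)
  # heterozygous counts of each member restricted to shared non-missing loci
  het_i <- het %*% t(obs)
  pairs <- which(upper.tri(n_shared), arr.ind = TRUE)
  denom <- het_i[pairs] + t(het_i)[pairs]
  phi <- (n_hh[pairs] - 2 * n_opp[pairs]) / denom
  phi[denom == 0] <- NA_real_
  ns <- n_shared[pairs]
  phi[ns < min_sites] <- NA_real_
  tibble(sample_i = g$samples[pairs[, 1]], sample_j = g$samples[pairs[, 2]],
         phi = phi, n_sites = as.integer(ns))
}

#' Remove one member of each related pair
#'
#' Greedy pruning: pairs with `phi > phi_threshold` are resolved by dropping
#' the member with more missing data (ties broken by lexicographic sample
#' id), iterating until no flagged pair remains among survivors.
#'
#' @param g a [geno()] object
#' @param pairs kinship tibble from [king_kinship()] computed on `g`
#' @param phi_threshold kinship above which a pair is considered related;
#'   the default 0.177 is the conventional 2nd-degree cutoff
#' @return list with `geno` and `removed` sample ids
#' @export
prune_related <- function(g, pairs, phi_threshold = 0.177) {
  miss <- rowMeans(is.na(g$G))
  names(miss) <- g$samples
  removed <- character(0)
  flagged <- pairs |> filter(!is.na(.data$phi), .data$phi > phi_threshold)
  while (nrow(flagged) > 0) {
    p <- flagged[1, ]
    cand <- c(p$sample_i, p$sample_j)
    drop <- cand[order(-miss[cand], cand)][1]
    removed <- c(removed, drop)
    flagged <- flagged |>
      filter(.data$sample_i != drop, .data$sample_j != drop)
  }
  out <- if (length(removed) > 0)
    subset_geno(g, samples = setdiff(g$samples, removed)) else g
  list(geno = out, removed = removed)
}

#' Keep a single SNP per RAD locus
#'
#' Retains the lowest-position SNP of each RAD locus (the `locus_id` column
#' of the locus table, or an explicit map).
#'
#' @param g a [geno()] object
#' @param locus_id optional character vector of RAD-locus ids aligned with
#'   the loci of `g`; defaults to `g$loci$locus_id`
#' @return a [geno()] object with one SNP per RAD locus
#' @export
one_snp_per_locus <- function(g, locus_id = NULL) {
  locus_id <- locus_id %||% g$loci[["locus_id"]]
  if (is.null(locus_id)) abort("no RAD locus annotation (locus_id) available")
  check_that(length(locus_id) == n_loci(g),
             "locus_id must annotate every SNP")
  ord <- order(match(g$loci$chrom, unique(g$loci$chrom)), g$loci$pos)
  first <- ord[!duplicated(locus_id[ord])]
  subset_geno(g, loci = sort(first))
}
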