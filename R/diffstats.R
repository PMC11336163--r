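#' PCA-based outlier locus scan (Mahalanobis distance on PC regressions)
#'
#' Each locus' standardized dosages are regressed on the first K principal
#' component score vectors; the resulting K-vector of z-scores (regression
#' coefficients scaled to unit residual variance) is summarized by a
#' Mahalanobis distance with robust location (coordinate-wise median) and
#' scatter (MAD-based diagonal). The genomic inflation factor
#' `lambda = median(D2) / qchisq(0.5, K)` rescales the distances before
#' upper-tail chi-square(K) p-values; q-values are Benjamini-Hochberg.
#' Loci are flagged at `q < fdr` and, more conservatively, at the
#' Bonferroni threshold `p < 0.05 / L`.
#'
#' @param g a [geno()] object with at least 50 loci
#' @param K number of PC axes to regress on (default 2)
#' @param fdr false discovery rate for the q-value flag
#' @return object of class `outlier_scan`: tibble `table` (chrom, pos, id,
#'   d2, p_value, q_value, flag_fdr, flag_bonferroni), `lambda`, `K`,
#'   z-score matrix `z`
#' @export
pcadapt_outliers <- function(g, K = 2, fdr = 0.05) {
  L <- n_loci(g)
  n <- n_samples(g)
  check_that(L >= 50, "need at least 50 loci")
  check_that(K < n, "K must be smaller than the number of samples")
  X <- g$G
  ctr <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, ctr)
  X[is.na(X)] <- 0
  sdv <- apply(X, 2, sd)
  keep <- sdv > 0
  Xs <- sweep(X[, keep, drop = FALSE], 2, sdv[keep], "/")
  sv <- svd(X)
  U <- sv$u[, seq_len(K), drop = FALSE]   # orthonormal score directions
  beta <- crossprod(U, Xs)                # K x L' regression coefficients
  ss_tot <- colSums(Xs^2)
  res_var <- pmax(ss_tot - colSums(beta^2), 0) / pmax(n - K - 1, 1)
  z <- sweep(beta, 2, sqrt(pmax(res_var, 1e-12)), "/")
  med <- apply(z, 1, median)
  madv <- apply(z, 1, mad)
  madv[madv == 0] <- apply(z, 1, sd)[madv == 0]
  d2k <- unname(colSums(((z - med) / madv)^2))
  d2 <- rep(NA_real_, L)
  d2[keep] <- d2k
  lambda <- median(d2k) / qchisq(0.5, df = K)
  p <- pchisq(d2 / lambda, df = K, lower.tail = FALSE)
  q <- rep(NA_real_, L)
  q[keep] <- p.adjust(p[keep], method = "BH")
  L_tested <- sum(keep)
  tab <- tibble(
    chrom = g$loci$chrom, pos = g$loci$pos, id = g$loci$id,
    d2 = d2, p_value = p, q_value = q,
    flag_fdr = !is.na(q) & q < fdr,
    flag_bonferroni = !is.na(p) & p < 0.05 / L_tested)
  structure(list(table = tab, lambda = lambda, K = K, fdr = fdr, z = z),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat("<outlier_scan> K = ", x$K, ", lambda = ", sprintf("%.3f", x$lambda),
      "; ", sum(x$table$flag_fdr), " FDR outliers / ",
      sum(x$table$flag_bonferroni), " Bonferroni outliers of ",
      nrow(x$table), " loci\n", sep = "")
  invisible(x)
}

#' @export
tidy.outlier_scan <- function(x, ...) x$table

#' @export
glance.outlier_scan <- function(x, ...) {
  tibble(K = x$K, lambda = x$lambda, n_loci = nrow(x$table),
         n_fdr = sum(x$table$flag_fdr),
         n_bonferroni = sum(x$table$flag_bonferroni))
}

#' Manhattan plot of an outlier scan
#' @param object an `outlier_scan`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.outlier_scan <- function(object, ...) {
  ggplot(object$table, aes(.data$pos / 1e6, -log10(.data$p_value),
                           colour = .data$flag_fdr)) +
    geom_point(size = 0.5, alpha = 0.7) +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = expression(-log[10](p)),
         colour = "outlier (FDR)") +
    theme_minimal()
}

#' Outlier/neutral partition arithmetic
#'
#' Turns outlier counts into the percentages and neutral-set size reported
#' in a filtering ledger (percentages rounded half-up to one decimal).
#'
#' @param n_total total loci screened
#' @param n_outlier outlier count (or a logical flag vector to count)
#' @return tibble (n_total, n_outlier, n_neutral, pct_outlier)
#' @export
outlier_partition_counts <- function(n_total, n_outlier) {
  if (is.logical(n_outlier)) n_outlier <- sum(n_outlier)
  check_that(n_outlier <= n_total, "outlier count exceeds total")
  tibble(n_total = n_total, n_outlier = n_outlier,
         n_neutral = n_total - n_outlier,
         pct_outlier = pct(n_outlier, n_total))
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for two
# groups of genotypes at one biallelic locus; vectorised over loci.
wc_components <- function(G1, G2) {
  n1 <- unname(colSums(!is.na(G1))); n2 <- unname(colSums(!is.na(G2)))
  p1 <- unname(colSums(G1, na.rm = TRUE)) / (2 * n1)
  p2 <- unname(colSums(G2, na.rm = TRUE)) / (2 * n2)
  h1 <- unname(colSums(G1 == 1L, na.rm = TRUE)) / n1
  h2 <- unname(colSums(G2 == 1L, na.rm = TRUE)) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ok <- n1 >= 2 & n2 >= 2 & is.finite(a) & is.finite(b) & is.finite(cc) &
    (pbar > 0 & pbar < 1)
  list(a = a[ok], abc = (a + b + cc)[ok], n_loci = sum(ok))
}

#' Pairwise Weir-Cockerham FST with locus bootstrap
#'
#' Multi-locus theta for every pair of groups,
#' `theta = sum(a) / sum(a + b + c)` over the Weir & Cockerham (1984)
#' variance components for biallelic loci with unequal sample sizes.
#' Significance of departure from zero is assessed by bootstrap over loci
#' (resampling with replacement): `p` is the fraction of replicates with
#' `theta* <= 0`, and a percentile confidence interval is reported.
#'
#' @param g a [geno()] object
#' @param groups per-sample group labels aligned with `g$samples`
#' @param n_boot bootstrap replicates (0 to skip)
#' @param seed RNG seed for the bootstrap
#' @return object of class `fst_result`: tibble `pairs` (group_i, group_j,
#'   theta, n_loci, p_boot, ci_lo, ci_hi) and matrix `theta_matrix`
#' @export
wc_fst <- function(g, groups, n_boot = 1000, seed = 1) {
  groups <- as.character(groups)
  check_that(length(groups) == n_samples(g),
             "groups must be aligned with the samples")
  lev <- unique(groups)
  check_that(length(lev) >= 2, "need at least 2 groups")
  set.seed(seed)
  out <- list()
  theta_m <- matrix(NA_real_, length(lev), length(lev),
                    dimnames = list(lev, lev))
  diag(theta_m) <- 0
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    comp <- wc_components(g$G[groups == lev[i], , drop = FALSE],
                          g$G[groups == lev[j], , drop = FALSE])
    if (comp$n_loci == 0) {
      out[[length(out) + 1]] <- tibble(
        group_i = lev[i], group_j = lev[j], theta = NA_real_,
        n_loci = 0L, p_boot = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
      next
    }
    theta <- sum(comp$a) / sum(comp$abc)
    p_boot <- ci <- c(NA_real_, NA_real_)
    pb <- NA_real_
    if (n_boot > 0) {
      nl <- comp$n_loci
      tb <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nl, nl, replace = TRUE)
        sum(comp$a[idx]) / sum(comp$abc[idx])
      }, numeric(1))
      pb <- mean(tb <= 0)
      ci <- quantile(tb, c(0.025, 0.975), names = FALSE)
    }
    theta_m[lev[i], lev[j]] <- theta_m[lev[j], lev[i]] <- theta
    out[[length(out) + 1]] <- tibble(
      group_i = lev[i], group_j = lev[j], theta = theta,
      n_loci = comp$n_loci, p_boot = pb, ci_lo = ci[1], ci_hi = ci[2])
  }
  structure(list(pairs = bind_rows(out), theta_matrix = theta_m,
                 n_boot = n_boot), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result> pairwise Weir-Cockerham theta (",
      x$n_boot, " bootstrap reps)\n", sep = "")
  print(round(x$theta_matrix, 4))
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$pairs

#' Per-individual inbreeding coefficients (method-of-moments F)
#'
#' For each sample, over its non-missing loci: observed homozygous count
#' `O_hom`, expected homozygous count
#' `E_hom = sum(1 - 2 p (1-p) * 2n/(2n-1))` using the locus-wise sample
#' allele frequency `p` and genotyped count `n`, and
#' `F = (O_hom - E_hom) / (L - E_hom)` — the statistic reported by
#' VCFtools' `--het`.
#'
#' @param g a [geno()] object
#' @param min_sites minimum non-missing loci per sample (below: `NA` F)
#' @return tibble (sample_id, o_hom, e_hom, n_sites, f)
#' @export
individual_inbreeding <- function(g, min_sites = 50) {
  G <- g$G
  n_l <- unname(colSums(!is.na(G)))
  p <- unname(colSums(G, na.rm = TRUE)) / (2 * n_l)
  e_hom_l <- 1 - 2 * p * (1 - p) * (2 * n_l / pmax(2 * n_l - 1, 1))
  usable <- n_l > 0 & p > 0 & p < 1     # monomorphic sites carry no signal
  obs <- !is.na(G[, usable, drop = FALSE])
  o_hom <- unname(rowSums((G[, usable, drop = FALSE] != 1L) & obs,
                          na.rm = TRUE))
  e_hom <- as.vector(obs %*% e_hom_l[usable])
  L <- unname(rowSums(obs))
  f <- ifelse(L - e_hom != 0, (o_hom - e_hom) / (L - e_hom), NA_real_)
  f[L < min_sites] <- NA_real_
  tibble(sample_id = g$samples, o_hom = o_hom, e_hom = e_hom,
         n_sites = as.integer(L), f = f)
}

#' Kruskal-Wallis and Dunn's post-hoc tests on grouped values
#'
#' Rank-based Kruskal-Wallis H with tie correction (via
#' [stats::kruskal.test()]) followed by Dunn's pairwise z-tests on mean
#' ranks with the same tie correction; pairwise p-values are two-sided
#' normal with a configurable multiplicity adjustment.
#'
#' @param values numeric vector (e.g. per-individual inbreeding F)
#' @param groups group labels aligned with `values`
#' @param p_adjust `"bonferroni"` (default), `"BH"` or `"none"`
#' @return list with `kw` (tibble: statistic, df, p_value) and `dunn`
#'   (tibble: group_i, group_j, z, p_value, p_adjusted)
#' @export
group_het_tests <- function(values, groups,
                            p_adjust = c("bonferroni", "BH", "none")) {
  p_adjust <- match.arg(p_adjust)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  lev <- unique(groups)
  check_that(length(lev) >= 2, "need at least 2 groups")
  check_that(all(table(groups) >= 3), "every group needs >= 3 values")
  kw <- kruskal.test(values, factor(groups))
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  nn <- tapply(rk, groups, length)
  pairs <- utils::combn(lev, 2)
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    gi <- pairs[1, k]; gj <- pairs[2, k]
    (rbar[[gi]] - rbar[[gj]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[[gi]] + 1 / nn[[gj]]))
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  list(
    kw = tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                p_value = kw$p.value),
    dunn = tibble(group_i = pairs[1, ], group_j = pairs[2, ], z = z,
                  p_value = p,
                  p_adjusted = p.adjust(p, method = if (p_adjust == "none")
                    "none" else p_adjust)))
}

#' Classify samples into species / hybrid / mito-discordant categories
#'
#' Combines K = 2 nuclear ancestry proportions with diagnostic mtDNA calls.
#' The mtDNA species is `A` when the A-diagnostic allele is present, `B`
#' when the B-diagnostic allele is present, `unclassified` when neither (or
#' both, with a warning). Nuclear status is `admixed` when the minor
#' ancestry is at least `admix_threshold`, otherwise the majority cluster's
#' pure class. Decision table: nuclear A -> `pure_A` (any mtDNA); nuclear
#' admixed -> `admixed`; nuclear B with mtDNA A -> `B_with_A_mtDNA`;
#' nuclear B otherwise -> `pure_B`.
#'
#' @param Q samples-x-2 ancestry matrix (rows on the simplex); the cluster
#'   corresponding to species A is identified via `a_cluster`
#' @param samples sample ids aligned with the rows of `Q`
#' @param mtdna tibble with `sample_id` and diagnostic-site columns named
#'   `mtdna_<pos>` (e.g. `mtdna_4894`, `mtdna_5138`)
#' @param diagnostic list describing the two diagnostic sites, defaults
#'   `list(A = list(col = "mtdna_4894", base = "T"), B = list(col =
#'   "mtdna_5138", base = "C"))`
#' @param a_cluster which column of `Q` is the species-A cluster; default
#'   picks the minority cluster (fewer majority-assigned samples)
#' @param admix_threshold minor-ancestry cutoff for calling a sample admixed
#' @return tibble of class `species_calls` (sample_id, q_a, nuclear,
#'   mtdna_species, class)
#' @export
classify_species <- function(Q, samples, mtdna,
                             diagnostic = list(
                               A = list(col = "mtdna_4894", base = "T"),
                               B = list(col = "mtdna_5138", base = "C")),
                             a_cluster = NULL, admix_threshold = 0.05) {
  Q <- as.matrix(Q)
  check_that(ncol(Q) == 2, "classification needs K = 2 ancestry")
  check_that(all(abs(rowSums(Q) - 1) < 1e-6), "Q rows must sum to 1")
  if (is.null(a_cluster))
    a_cluster <- which.min(colSums(Q > 0.5))
  q_a <- Q[, a_cluster]
  m <- mtdna[match(samples, mtdna$sample_id), , drop = FALSE]
  getd <- function(side) {
    col <- diagnostic[[side]]$col
    if (!col %in% names(m)) return(rep(FALSE, length(samples)))
    v <- as.character(m[[col]])
    !is.na(v) & v == diagnostic[[side]]$base
  }
  has_a <- getd("A"); has_b <- getd("B")
  if (any(has_a & has_b))
    warn("conflicting diagnostic mtDNA alleles; affected samples unclassified")
  mt <- ifelse(has_a & has_b, "unclassified",
               ifelse(has_a, "A", ifelse(has_b, "B", "unclassified")))
  minor <- pmin(q_a, 1 - q_a)
  nuclear <- ifelse(minor >= admix_threshold, "admixed",
                    ifelse(q_a > 0.5, "A", "B"))
  class <- dplyr::case_when(
    nuclear == "A" ~ "pure_A",
    nuclear == "admixed" ~ "admixed",
    nuclear == "B" & mt == "A" ~ "B_with_A_mtDNA",
    nuclear == "B" ~ "pure_B",
    TRUE ~ "unclassified")
  res <- tibble(sample_id = samples, q_a = q_a, nuclear = nuclear,
                mtdna_species = mt, class = class)
  class(res) <- c("species_calls", class(res))
  res
}

#' Per-ecoregion species/hybrid summary table
#'
#' Counts and percentages (rounded half-up to one decimal) of the second
#' species, admixed individuals, and focal-species individuals with
#' introgressed mtDNA, per ecoregion — the classic species-screen summary.
#'
#' @param calls a [classify_species()] result (or any tibble with
#'   `sample_id` and `class`)
#' @param ecoregions per-sample ecoregion labels aligned with `calls`
#' @return tibble (ecoregion, n, n_pure_A, pct_pure_A, n_admixed,
#'   pct_admixed, n_discordant, pct_discordant)
#' @export
species_summary <- function(calls, ecoregions) {
  tibble(ecoregion = ecoregions, class = calls$class) |>
    group_by(.data$ecoregion) |>
    summarise(
      n = n(),
      n_pure_A = sum(.data$class == "pure_A"),
      n_admixed = sum(.data$class == "admixed"),
      n_discordant = sum(.data$class == "B_with_A_mtDNA"),
      .groups = "drop") |>
    mutate(pct_pure_A = pct(.data$n_pure_A, .data$n),
           pct_admixed = pct(.data$n_admixed, .data$n),
           pct_discordant = pct(.data$n_discordant, .data$n)) |>
    select("ecoregion", "n", "n_pure_A", "pct_pure_A", "n_admixed",
           "pct_admixed", "n_discordant", "pct_discordant")
}
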