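#' Composite genotypic LD between two loci
#'
#' Squared Pearson correlation of alternate-allele dosages over the jointly
#' non-missing samples — the genotype-mode r-squared of standard SNP
#' toolkits. Undefined (`NA`) when fewer than `min_obs` joint observations
#' remain or either locus is monomorphic in the joint subset.
#'
#' @param g a [geno()] object
#' @param i,j locus indices (or locus ids)
#' @param min_obs minimum joint non-missing observations
#' @return r-squared in \[0, 1\], or `NA`
#' @export
pairwise_r2 <- function(g, i, j, min_obs = 20) {
  if (is.character(i)) i <- match(i, g$loci$id)
  if (is.character(j)) j <- match(j, g$loci$id)
  x <- g$G[, i]; y <- g$G[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_obs) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

# full pairwise r^2 matrix for a block of loci (pairwise-complete)
r2_matrix <- function(G_block) {
  suppressWarnings(cor(G_block, use = "pairwise.complete.obs"))^2
}

#' Site-level mean r-squared over a physical distance window
#'
#' For every site, averages r-squared against all partner sites on the same
#' chromosome at a distance between `min_bp` and `max_bp` (inclusive).
#' Spikes in this profile flag genomic blocks inherited as a unit
#' (inversions, other recombination-suppressed segments). Sites without any
#' in-window partner are flagged (`NA` mean, `n_pairs = 0`), never
#' zero-filled.
#'
#' @param g a [geno()] object (loci coordinate-sorted)
#' @param min_bp,max_bp inclusive distance window in bp
#' @param min_obs minimum joint observations per pair
#' @return tibble of class `ld_profile` (chrom, pos, id, n_pairs, mean_r2)
#' @export
site_mean_r2_profile <- function(g, min_bp = 1e5, max_bp = 5e6,
                                 min_obs = 20) {
  out <- vector("list", length(unique(g$loci$chrom)))
  for (ci in seq_along(unique(g$loci$chrom))) {
    ch <- unique(g$loci$chrom)[ci]
    idx <- which(g$loci$chrom == ch)
    pos <- g$loci$pos[idx]
    R2 <- r2_matrix(g$G[, idx, drop = FALSE])
    nobs <- crossprod(!is.na(g$G[, idx, drop = FALSE]))
    R2[nobs < min_obs] <- NA
    D <- abs(outer(pos, pos, "-"))
    in_win <- D >= min_bp & D <= max_bp
    diag(in_win) <- FALSE
    mean_r2 <- n_pairs <- numeric(length(idx))
    for (a in seq_along(idx)) {
      vals <- R2[a, in_win[a, ]]
      vals <- vals[!is.na(vals)]
      n_pairs[a] <- length(vals)
      mean_r2[a] <- if (length(vals) > 0) mean(vals) else NA_real_
    }
    out[[ci]] <- tibble(chrom = ch, pos = pos, id = g$loci$id[idx],
                        n_pairs = as.integer(n_pairs), mean_r2 = mean_r2)
  }
  res <- bind_rows(out)
  class(res) <- c("ld_profile", class(res))
  res
}

#' Manhattan-style plot of an LD profile
#' @param object an `ld_profile`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ld_profile <- function(object, ...) {
  ggplot(object, aes(.data$pos / 1e6, .data$mean_r2)) +
    geom_point(size = 0.4, alpha = 0.6) +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = expression(mean~r^2)) +
    theme_minimal()
}

#' Greedy two-stage LD pruning
#'
#' Left-to-right scan in genome order: a locus is dropped if its r-squared
#' with any already-retained locus within `window_bp` on the same
#' chromosome exceeds `r2_within`, or (in `between_mode = "greedy"`) with
#' any retained locus on another chromosome exceeds `r2_between`. The
#' retained set is stable under a second scan.
#'
#' @param g a [geno()] object
#' @param r2_within within-chromosome r-squared threshold
#' @param window_bp within-chromosome distance window (inclusive)
#' @param r2_between across-chromosome r-squared threshold
#' @param between_mode `"greedy"` (candidate vs retained loci, default) or
#'   `"none"` to skip the inter-chromosome stage
#' @param min_obs minimum joint observations; pairs below it are treated as
#'   uninformative (not pruned on)
#' @return a [geno()] object containing the retained loci
#' @export
ld_prune <- function(g, r2_within = 0.05, window_bp = 1e7, r2_between = 0.10,
                     between_mode = c("greedy", "none"), min_obs = 20) {
  between_mode <- match.arg(between_mode)
  L <- n_loci(g)
  chrom <- g$loci$chrom; pos <- g$loci$pos
  G <- g$G
  keep <- logical(L)
  kept_idx <- integer(0)
  r2_vs <- function(j, ref_idx) {
    if (length(ref_idx) == 0) return(numeric(0))
    r <- suppressWarnings(
      cor(G[, j], G[, ref_idx, drop = FALSE],
          use = "pairwise.complete.obs"))^2
    nob <- colSums(!is.na(G[, j]) & !is.na(G[, ref_idx, drop = FALSE]))
    r[nob < min_obs] <- NA
    r
  }
  for (j in seq_len(L)) {
    same <- kept_idx[chrom[kept_idx] == chrom[j] &
                       abs(pos[kept_idx] - pos[j]) <= window_bp]
    drop <- FALSE
    if (length(same) > 0) {
      r <- r2_vs(j, same)
      drop <- any(!is.na(r) & r > r2_within)
    }
    if (!drop && between_mode == "greedy") {
      other <- kept_idx[chrom[kept_idx] != chrom[j]]
      if (length(other) > 0) {
        r <- r2_vs(j, other)
        drop <- any(!is.na(r) & r > r2_between)
      }
    }
    if (!drop) {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  subset_geno(g, loci = keep)
}
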