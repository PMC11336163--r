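#' Detect genomic regions with aggregated signal
#'
#' Scans a genome-ordered per-site statistic (squared-loading track or LD
#' profile) in fixed windows and flags windows whose summed statistic
#' exceeds a robust threshold, `median + z_threshold * MAD`, with the
#' background estimated genome-wide (an Mbp-scale block can dominate its
#' own chromosome, so a per-chromosome background would mask it). Adjacent
#' flagged windows closer than `merge_gap_bp` are merged and region bounds
#' snapped to the outermost contributing SNPs. Chromosomes with fewer than
#' 10 windows are skipped with a warning.
#'
#' @param track tibble with columns `chrom`, `pos` and a per-site statistic
#'   named by `stat` (e.g. the `per_locus` element of [loading_profile()],
#'   or an [site_mean_r2_profile()] result)
#' @param stat name of the statistic column (default picks `sq_loading`
#'   or `mean_r2` automatically)
#' @param window_bp aggregation window width
#' @param z_threshold robust z-score threshold on window sums
#' @param merge_gap_bp flagged windows within this distance are merged
#' @param min_snps regions supported by fewer SNPs are discarded (isolated
#'   high-loading sites are not Mbp-scale structure)
#' @return a [regions_tbl()] tibble (possibly empty) with an extra
#'   `n_snps` column
#' @export
detect_aggregated_regions <- function(track, stat = NULL, window_bp = 1e6,
                                      z_threshold = 4, merge_gap_bp = 2e6,
                                      min_snps = 10) {
  if ("per_locus" %in% names(track)) track <- track$per_locus
  stat <- stat %||% intersect(c("sq_loading", "mean_r2"), names(track))[1]
  check_that(!is.na(stat) && stat %in% names(track),
             "no per-site statistic column found")
  # window sums per chromosome (empty windows contribute zero signal)
  win_tbl <- list()
  for (ch in unique(track$chrom)) {
    tc <- track[track$chrom == ch & !is.na(track[[stat]]), ]
    if (nrow(tc) == 0) next
    win <- floor((tc$pos - 1) / window_bp)
    sums <- tapply(tc[[stat]], win, sum)
    wid <- as.numeric(names(sums))
    all_wid <- seq(min(wid), max(wid))
    full <- setNames(numeric(length(all_wid)), all_wid)
    full[as.character(wid)] <- sums
    if (length(full) < 10) {
      warn(paste("chromosome", ch, "has fewer than 10 windows; skipped"))
      next
    }
    win_tbl[[ch]] <- tibble(chrom = ch, win = as.numeric(names(full)),
                            sum_stat = unname(full))
  }
  if (length(win_tbl) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_snps = integer()))
  wt <- bind_rows(win_tbl)
  med <- median(wt$sum_stat)
  s <- mad(wt$sum_stat)
  if (s == 0) s <- sd(wt$sum_stat)
  found <- list()
  if (!is.na(s) && s > 0) {
    gap_win <- ceiling(merge_gap_bp / window_bp)
    for (ch in names(win_tbl)) {
      wc <- wt[wt$chrom == ch, ]
      hot <- sort(wc$win[(wc$sum_stat - med) / s > z_threshold])
      if (length(hot) == 0) next
      tc <- track[track$chrom == ch & !is.na(track[[stat]]), ]
      grp <- cumsum(c(1, diff(hot) > gap_win))
      for (gk in unique(grp)) {
        w <- hot[grp == gk]
        lo <- min(w) * window_bp + 1
        hi <- (max(w) + 1) * window_bp
        snps <- tc$pos[tc$pos >= lo & tc$pos <= hi]
        if (length(snps) == 0) next
        found[[length(found) + 1]] <-
          tibble(chrom = ch, start = min(snps), end = max(snps),
                 n_snps = length(snps))
      }
    }
  }
  if (length(found) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_snps = integer()))
  bind_rows(found) |> filter(.data$n_snps >= min_snps)
}

#' Karyotype samples at a candidate inversion region
#'
#' PCA restricted to the region's SNPs, then k-means (k = 3, multiple
#' restarts) on the first-axis scores. Clusters are ordered along PC1; the
#' middle cluster is the putative arrangement heterozygote AB, and the two
#' outer clusters the arrangement homozygotes, labelled so that AA is the
#' larger one (ancestral state unknown). The call is `confirmed` only when
#' (a) a Gaussian mixture model on the PC1 scores supports three modes by
#' BIC (via \pkg{mclust}; a continuous blob of noise SNPs supports one) and
#' (b) the AB cluster has the strictly highest mean observed
#' heterozygosity over region SNPs — the diagnostic signature of a
#' polymorphic inversion. Samples whose PC1 score is farther than 3
#' within-cluster SDs from every center are left `unassigned`.
#'
#' @param g a [geno()] object
#' @param region one-row [regions_tbl()]
#' @param seed RNG seed for k-means
#' @param min_snps minimum polymorphic SNPs required inside the region
#' @return object of class `karyotype_call`: tibble `calls` (sample,
#'   karyotype, pc1), `cluster_het` (karyotype, n, mean_het, pc1_center),
#'   `p_inv` (frequency of the minor/inverted arrangement), `confirmed`,
#'   `region`
#' @export
karyotype_region <- function(g, region, seed = 1, min_snps = 10) {
  gr <- subset_geno(g, regions = region)
  st <- site_allele_stats(gr)
  poly <- !is.na(st$maf) & st$maf > 0
  check_that(sum(poly) >= min_snps,
             sprintf("only %d polymorphic SNPs in region (need >= %d)",
                     sum(poly), min_snps))
  check_that(n_samples(gr) >= 10, "need >= 10 samples")
  gr <- subset_geno(gr, loci = poly)
  pc <- pca_genotypes(gr, n_axes = 1)
  x <- pc$scores[, 1]
  set.seed(seed)
  km <- kmeans(x, centers = 3, nstart = 25, iter.max = 50)
  ord <- order(km$centers)
  lab3 <- c("left", "mid", "right")[match(km$cluster, ord)]
  if (min(table(km$cluster)) < 2)
    warn("a karyotype cluster has fewer than 2 members")
  # unassigned: farther than 3 cluster SDs from every center
  sds <- vapply(1:3, function(k) {
    v <- x[km$cluster == k]
    if (length(v) > 1) sd(v) else 0
  }, numeric(1))
  sds[sds == 0] <- max(sds, diff(range(x)) / 100)
  far <- vapply(seq_along(x), function(i)
    all(abs(x[i] - km$centers) / sds > 3), logical(1))
  lab3[far] <- "unassigned"

  # per-sample observed heterozygosity over region SNPs
  het_i <- rowSums(gr$G == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(gr$G)), 1)
  side_n <- table(factor(lab3, levels = c("left", "mid", "right")))
  homs <- if (side_n[["left"]] >= side_n[["right"]])
    c(left = "AA", right = "BB") else c(left = "BB", right = "AA")
  karyo <- dplyr::recode(lab3, left = homs[["left"]], mid = "AB",
                         right = homs[["right"]],
                         unassigned = "unassigned")
  cluster_het <- tibble(karyotype = karyo, het = het_i, pc1 = x) |>
    filter(.data$karyotype != "unassigned") |>
    group_by(.data$karyotype) |>
    summarise(n = n(), mean_het = mean(.data$het),
              pc1_center = mean(.data$pc1), .groups = "drop")
  hets <- setNames(cluster_het$mean_het, cluster_het$karyotype)
  bic <- mclust::mclustBIC(x, G = 1:3, verbose = FALSE)
  idx <- which(bic == max(bic, na.rm = TRUE), arr.ind = TRUE)[1, ]
  best_g <- as.numeric(rownames(bic)[idx[1]])
  confirmed <- best_g == 3 &&
    all(c("AA", "AB", "BB") %in% names(hets)) &&
    hets[["AB"]] > max(hets[["AA"]], hets[["BB"]])
  n_ab <- sum(karyo == "AB"); n_bb <- sum(karyo == "BB")
  n_assigned <- sum(karyo != "unassigned")
  structure(list(
    calls = tibble(sample = gr$samples, karyotype = karyo, pc1 = x,
                   het = het_i),
    cluster_het = cluster_het,
    p_inv = (2 * n_bb + n_ab) / (2 * n_assigned),
    confirmed = confirmed, pc1_modes = best_g,
    region = as_tibble(region)[, c("chrom", "start", "end")],
    n_snps = n_loci(gr)), class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  cat("<karyotype_call> ", x$region$chrom, ":", x$region$start, "-",
      x$region$end, " (", x$n_snps, " SNPs)\n", sep = "")
  tab <- table(x$calls$karyotype)
  cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "),
      "\n  p_inv = ", sprintf("%.3f", x$p_inv),
      ", confirmed = ", x$confirmed, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.karyotype_call <- function(x, ...) x$calls

#' @export
glance.karyotype_call <- function(x, ...) {
  bind_cols(x$region,
            tibble(n_snps = x$n_snps, p_inv = x$p_inv,
                   confirmed = x$confirmed))
}

#' PC1-by-heterozygosity plot of a karyotype call
#' @param object a `karyotype_call`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.karyotype_call <- function(object, ...) {
  ggplot(object$calls, aes(.data$pc1, .data$het, colour = .data$karyotype)) +
    geom_point(alpha = 0.8) +
    labs(x = "PC1 (region SNPs)", y = "observed heterozygosity",
         colour = "karyotype") +
    theme_minimal()
}

#' Length of a genomic region
#'
#' Inclusive-interval length: `end - start + 1` bp, with megabase
#' renderings at one decimal (rounded half-up) and at the nearest integer.
#'
#' @param region one-row [regions_tbl()] (or a tibble of regions)
#' @return tibble (chrom, start, end, bp, mbp, mbp_int)
#' @export
region_length <- function(region) {
  bp <- region$end - region$start + 1
  tibble(chrom = region$chrom, start = region$start, end = region$end,
         bp = bp,
         mbp = round_half_up(bp / 1e6, 1),
         mbp_int = round_half_up(bp / 1e6, 0))
}
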