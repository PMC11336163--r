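#' Per-marker association with phenotypic sex
#'
#' Genotype-level analog of a RADSex-style scan. For every marker a 2x2
#' table of sex against a carrier property is tested: in `presence` mode
#' the property is "marker genotyped (non-missing)" — the genotype-level
#' proxy for marker presence in presence/absence RAD data; in `carrier`
#' mode it is "carries the alternate allele"; in `dosage` mode allele
#' counts (2 per individual) are tested instead. Tables are tested by
#' chi-square with continuity correction, switching to Fisher's exact test
#' whenever any expected cell is below 5. Significance is controlled by
#' Bonferroni at `alpha` over the tested markers; `bias` is the signed
#' male-minus-female frequency of the property, so positive values are
#' male-biased (XY-like pattern: the male is the heterogametic sex). The
#' exact test also replaces the chi-square whenever an observed cell is
#' empty — the fully-sex-limited pattern — where the approximation is
#' poorest.
#'
#' Samples of unknown sex are excluded throughout. Markers failing the
#' `min_per_sex` eligibility gate are reported with `tested = FALSE` and
#' `NA` p-values, not p = 1.
#'
#' @param g a [geno()] object
#' @param sexes per-sample sex labels (`"F"`, `"M"`, anything else =
#'   unknown), aligned with `g$samples`
#' @param mode `"presence"` (default), `"carrier"` or `"dosage"`
#' @param min_per_sex minimum eligible individuals per sex at a marker (in
#'   presence mode, sexed individuals; otherwise sexed individuals with a
#'   non-missing call)
#' @param alpha family-wise error target for the Bonferroni threshold
#' @return tibble of class `sex_scan` (chrom, pos, id, mode, n_male,
#'   n_female, carrier_male, carrier_female, bias, p_value, tested,
#'   significant); the Bonferroni threshold is in attribute `p_threshold`
#' @export
sex_scan <- function(g, sexes, mode = c("presence", "carrier", "dosage"),
                     min_per_sex = 5, alpha = 0.05) {
  mode <- match.arg(mode)
  check_that(length(sexes) == n_samples(g),
             "sexes must be aligned with the samples")
  sexes <- normalize_sex(sexes)
  is_m <- sexes == "M"; is_f <- sexes == "F"
  if (sum(is_m) == 0 || sum(is_f) == 0)
    abort("need at least one individual of each sex")
  G <- g$G
  obs <- !is.na(G)
  carrier <- switch(mode,
    presence = obs,
    carrier = !is.na(G) & G >= 1L,
    dosage = NULL)
  if (mode == "dosage") {
    a <- unname(colSums(G[is_m, , drop = FALSE], na.rm = TRUE))
    b <- unname(colSums(G[is_f, , drop = FALSE], na.rm = TRUE))
    n_m <- 2 * unname(colSums(obs[is_m, , drop = FALSE]))
    n_f <- 2 * unname(colSums(obs[is_f, , drop = FALSE]))
    elig_m <- n_m / 2; elig_f <- n_f / 2
  } else {
    a <- unname(colSums(carrier[is_m, , drop = FALSE]))
    b <- unname(colSums(carrier[is_f, , drop = FALSE]))
    if (mode == "presence") {
      n_m <- rep(sum(is_m), ncol(G)); n_f <- rep(sum(is_f), ncol(G))
      elig_m <- n_m; elig_f <- n_f
    } else {
      n_m <- unname(colSums(obs[is_m, , drop = FALSE]))
      n_f <- unname(colSums(obs[is_f, , drop = FALSE]))
      elig_m <- n_m; elig_f <- n_f
    }
  }
  tested <- elig_m >= min_per_sex & elig_f >= min_per_sex
  f_m <- ifelse(n_m > 0, a / n_m, NA_real_)
  f_f <- ifelse(n_f > 0, b / n_f, NA_real_)

  # vectorised 2x2 chi-square with Yates continuity correction
  N <- n_m + n_f
  C <- a + b
  num <- pmax(abs(a * (n_f - b) - b * (n_m - a)) - N / 2, 0)
  den <- as.numeric(n_m) * n_f * C * (N - C)
  chi <- ifelse(den > 0, N * num^2 / den, 0)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  p[den == 0] <- 1  # marker constant across everyone: no evidence

  # exact test where any expected cell < 5, or any observed cell is empty
  # (a zero cell is exactly the fully-sex-limited pattern of interest and
  # the chi-square approximation is poorest there)
  e_min <- pmin(n_m * C, n_m * (N - C), n_f * C, n_f * (N - C)) / N
  o_min <- pmin(a, n_m - a, b, n_f - b)
  need_exact <- which(tested & den > 0 & (e_min < 5 | o_min == 0))
  for (j in need_exact) {
    p[j] <- stats::fisher.test(matrix(c(a[j], n_m[j] - a[j],
                                        b[j], n_f[j] - b[j]),
                                      2, byrow = TRUE))$p.value
  }
  p[!tested] <- NA_real_
  L_tested <- sum(tested)
  thr <- alpha / max(L_tested, 1)
  res <- tibble(
    chrom = g$loci$chrom, pos = g$loci$pos, id = g$loci$id, mode = mode,
    n_male = as.integer(elig_m), n_female = as.integer(elig_f),
    carrier_male = as.numeric(a), carrier_female = as.numeric(b),
    bias = f_m - f_f, p_value = p, tested = tested,
    significant = tested & !is.na(p) & p < thr)
  attr(res, "p_threshold") <- thr
  class(res) <- c("sex_scan", class(res))
  res
}

#' Span of the significant sex-associated segment
#'
#' Outermost significant markers per chromosome, as a [regions_tbl()].
#'
#' @param scan a [sex_scan()] result
#' @return regions tibble with an `n_significant` column (empty if nothing
#'   is significant)
#' @export
sex_scan_regions <- function(scan) {
  sig <- scan |> filter(.data$significant)
  if (nrow(sig) == 0)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_significant = integer()))
  sig |>
    group_by(.data$chrom) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n_significant = n(), .groups = "drop")
}

#' Manhattan plot of a sex scan with the Bonferroni threshold
#' @param object a `sex_scan` tibble
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.sex_scan <- function(object, ...) {
  thr <- attr(object, "p_threshold")
  df <- filter(object, .data$tested)
  ggplot(df, aes(.data$pos / 1e6, -log10(.data$p_value),
                 colour = .data$bias > 0)) +
    geom_point(size = 0.5, alpha = 0.7) +
    geom_hline(yintercept = -log10(thr), linetype = "dashed",
               colour = "red") +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = expression(-log[10](p)),
         colour = "male-biased") +
    theme_minimal()
}
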