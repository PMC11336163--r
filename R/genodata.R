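#' Genotype matrix container
#'
#' A `geno` object holds a samples-by-loci matrix of alternate-allele dosages
#' (0, 1, 2, or `NA` for a missing call) together with a locus table carrying
#' genomic coordinates. It is the common currency of every analysis in the
#' package. Dosages are unphased; multiallelic sites are not representable by
#' design (RAD-seq biallelic SNP catalogs only).
#'
#' @param G integer matrix, samples in rows, loci in columns, entries in
#'   \{0, 1, 2, NA\}
#' @param loci tibble with columns `chrom`, `pos` (1-based bp), `id`, `ref`,
#'   `alt`, and optionally `median_depth` and `locus_id` (RAD locus grouping)
#' @param samples character vector of unique sample ids, one per row of `G`
#' @return an object of class `geno`
#' @export
geno <- function(G, loci, samples = rownames(G)) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  loci <- as_tibble(loci)
  check_that(!is.null(samples) && length(samples) == nrow(G),
             "`samples` must name every row of `G`")
  check_that(!anyDuplicated(samples), "duplicate sample ids")
  check_that(ncol(G) == nrow(loci), "`loci` must describe every column of `G`")
  need <- c("chrom", "pos", "id", "ref", "alt")
  check_that(all(need %in% names(loci)),
             paste("locus table needs columns:", paste(need, collapse = ", ")))
  check_that(all(loci$pos >= 1), "locus positions must be >= 1")
  bad <- setdiff(unique(as.vector(G)), c(0L, 1L, 2L, NA_integer_))
  check_that(length(bad) == 0, "dosages must be 0, 1, 2 or NA")
  # canonical order: chromosome (appearance order), then position
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  G <- G[, ord, drop = FALSE]
  check_that(!anyDuplicated(paste(loci$chrom, loci$pos)),
             "duplicate (chrom, pos) locus coordinates")
  rownames(G) <- samples
  colnames(G) <- loci$id
  structure(list(G = G, loci = loci, samples = samples), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", length(x$samples), " samples x ", nrow(x$loci), " loci (",
      length(unique(x$loci$chrom)), " chromosomes), ",
      sprintf("%.1f%%", 100 * mean(is.na(x$G))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$G)

#' Number of samples / loci in a geno object
#' @param g a `geno` object
#' @return integer count
#' @export
n_samples <- function(g) length(g$samples)

#' @rdname n_samples
#' @export
n_loci <- function(g) nrow(g$loci)

#' Read a biallelic SNP genotype matrix from VCF
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}) into a [geno()] object. Only
#' biallelic SNP records are kept; multiallelic or indel records are skipped
#' and counted, never split. GT is decoded as alternate-allele dosage
#' (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> NA); phase is
#' ignored. Per-locus `median_depth` is the median of the per-sample FORMAT
#' DP values when present.
#'
#' @param path path to an (uncompressed or gzipped) VCF file
#' @param min_gq optional minimum genotype quality; calls with FORMAT GQ below
#'   it are set missing
#' @return a [geno()] object; the number of skipped non-biallelic-SNP records
#'   is attached as attribute `n_skipped` and reported via a message
#' @export
read_vcf <- function(path, min_gq = NULL) {
  if (!file.exists(path)) abort(paste("cannot read VCF:", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no records")
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    inform(paste("skipped", n_skipped, "non-biallelic-SNP record(s)"))
  if (!any(is_snp)) abort("VCF contains no biallelic SNP records")
  v <- v[is_snp, ]
  fix <- fix[is_snp, , drop = FALSE]

  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  core <- gsub("\\|", "/", gt)
  dos[core %in% c("0/0", "0")] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core %in% c("1/1", "1")] <- 2L
  if (!is.null(min_gq)) {
    gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    if (!is.null(gq)) dos[!is.na(gq) & gq < min_gq] <- NA_integer_
  }
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  med_dp <- if (is.null(dp) || all(is.na(dp))) rep(NA_real_, nrow(fix)) else
    unname(apply(dp, 1, function(x)
      if (all(is.na(x))) NA_real_ else median(x, na.rm = TRUE)))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  loci <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = make.unique(ids),
    ref = fix$REF, alt = fix$ALT, median_depth = med_dp
  )
  g <- geno(t(dos), loci, samples = colnames(gt))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write a geno object to an uncompressed VCF v4.2 file
#'
#' Emits GT for every call and, when `median_depth` is available, the locus
#' median as each sample's DP (per-sample depths are not retained by the
#' dosage model). Output is deterministic; a round trip through
#' [read_vcf()] preserves coordinates, alleles and dosages exactly.
#'
#' @param g a [geno()] object
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf <- function(g, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(paste("cannot write VCF:", path)))
  on.exit(close(con))
  has_dp <- "median_depth" %in% names(g$loci) && any(!is.na(g$loci$median_depth))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poplayers",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp)
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth (locus median)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$samples), collapse = "\t")
  )
  writeLines(hdr, con)
  if (n_loci(g) > 0) {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    fmt <- if (has_dp) "GT:DP" else "GT"
    lines <- vapply(seq_len(n_loci(g)), function(j) {
      d <- g$G[, j]
      cell <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
      if (has_dp) {
        dp <- g$loci$median_depth[j]
        cell <- paste0(cell, ":", ifelse(is.na(dp), ".", format(dp)))
      }
      paste(c(g$loci$chrom[j], g$loci$pos[j], g$loci$id[j], g$loci$ref[j],
              g$loci$alt[j], ".", "PASS", ".", fmt, cell), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated file with header columns `sample_id`, `ecoregion`, `site`,
#' `sex`, plus any number of `mtdna_<pos>` columns holding the base observed
#' at a diagnostic mitochondrial position (blank = missing). Sex is coerced
#' to `F`, `M` or `unknown`.
#'
#' @param path path to the TSV file
#' @return a tibble, one row per sample
#' @export
read_sample_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_that("sample_id" %in% names(tb), "sample table needs a sample_id column")
  if (anyDuplicated(tb$sample_id))
    abort("duplicated sample_id in sample table")
  tb$sex <- normalize_sex(tb$sex %||% rep(NA_character_, nrow(tb)))
  tb
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("F", "FEMALE")] <- "F"
  out[x %in% c("M", "MALE")] <- "M"
  out
}

#' Genomic region table
#'
#' Regions are 1-based, fully inclusive intervals (VCF convention).
#'
#' @param chrom chromosome names
#' @param start,end 1-based inclusive bounds, `start <= end`
#' @return tibble with columns chrom, start, end
#' @export
regions_tbl <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  check_that(all(start >= 1) && all(start <= end),
             "regions need 1 <= start <= end")
  tibble(chrom = as.character(chrom), start = start, end = end)
}

#' Read regions from a 3-column BED file
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention at this boundary (start + 1, end unchanged).
#'
#' @param path path to a BED file (no header, >= 3 columns)
#' @return a [regions_tbl()] tibble
#' @export
read_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  check_that(ncol(tb) >= 3, "BED file needs at least 3 columns")
  regions_tbl(tb[[1]], as.numeric(tb[[2]]) + 1, as.numeric(tb[[3]]))
}

#' Write regions to a 3-column BED file
#' @param regions a [regions_tbl()] tibble
#' @param path output path
#' @return invisibly, `path`
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(
    tibble(chrom = regions$chrom, start = regions$start - 1, end = regions$end),
    path, col_names = FALSE)
  invisible(path)
}

in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[k] &
                    pos >= regions$start[k] & pos <= regions$end[k])
  }
  hit
}

#' Subset a genotype matrix by samples, loci, or genomic regions
#'
#' Order-preserving subset. With `invert_regions = TRUE` the loci falling
#' inside any region are dropped (the "remove inversion / sex-linked
#' segment" operation); otherwise regions select loci to keep.
#'
#' @param g a [geno()] object
#' @param samples optional character vector of sample ids to keep
#' @param loci optional logical/integer index over loci to keep
#' @param regions optional [regions_tbl()]
#' @param invert_regions drop (rather than keep) loci inside `regions`
#' @return a [geno()] object
#' @export
subset_geno <- function(g, samples = NULL, loci = NULL, regions = NULL,
                        invert_regions = FALSE) {
  keep_s <- if (is.null(samples)) rep(TRUE, n_samples(g)) else {
    check_that(all(samples %in% g$samples), "unknown sample id in keep list")
    g$samples %in% samples
  }
  keep_l <- rep(TRUE, n_loci(g))
  if (!is.null(loci)) {
    keep_l <- if (is.logical(loci)) loci else seq_len(n_loci(g)) %in% loci
  }
  if (!is.null(regions)) {
    hit <- in_regions(g$loci$chrom, g$loci$pos, regions)
    keep_l <- keep_l & (if (invert_regions) !hit else hit)
  }
  if (!any(keep_s) || !any(keep_l))
    abort(sprintf("empty subset: %d samples, %d loci would remain",
                  sum(keep_s), sum(keep_l)))
  geno(g$G[keep_s, keep_l, drop = FALSE],
       g$loci[keep_l, , drop = FALSE],
       samples = g$samples[keep_s])
}

#' Per-locus allele and heterozygosity statistics
#'
#' For each locus: alternate-allele frequency `p_alt` (alt count over twice
#' the non-missing calls), minor allele frequency `maf`, `missing_rate`,
#' observed heterozygosity `h_obs` (fraction of non-missing calls that are
#' heterozygous) and expected heterozygosity `h_exp = 2p(1-p)`. Loci with no
#' non-missing call get `NA` statistics.
#'
#' @param g a [geno()] object
#' @return tibble with one row per locus (chrom, pos, id, n_called, p_alt,
#'   maf, missing_rate, h_obs, h_exp)
#' @export
site_allele_stats <- function(g) {
  G <- g$G
  n_called <- unname(colSums(!is.na(G)))
  alt <- unname(colSums(G, na.rm = TRUE))
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  het <- unname(colSums(G == 1L, na.rm = TRUE))
  tibble(
    chrom = g$loci$chrom, pos = g$loci$pos, id = g$loci$id,
    n_called = as.integer(n_called),
    p_alt = p_alt,
    maf = pmin(p_alt, 1 - p_alt),
    missing_rate = (nrow(G) - n_called) / nrow(G),
    h_obs = ifelse(n_called > 0, het / n_called, NA_real_),
    h_exp = 2 * p_alt * (1 - p_alt)
  )
}
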