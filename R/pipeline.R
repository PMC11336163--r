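#' Configuration for the full layered analysis pipeline
#'
#' Collects stage toggles and thresholds for [run_pipeline()]. Stage order
#' is fixed (QC, species screen, inversion/sex screen and removal,
#' structure, outlier partition, LD pruning, final structure); toggles only
#' switch stages off.
#'
#' @param seed RNG seed used by every stochastic stage
#' @param stages named logical vector switching stages on/off
#' @param maf_min,max_missing_rate,het_max,depth_range SNP filter thresholds
#'   (see [snp_filter()])
#' @param sample_max_missing per-sample missingness cutoff
#' @param kin_threshold kinship pruning threshold (see [prune_related()])
#' @param species_maf_min MAF re-filter applied after hybrid removal
#' @param admix_threshold minor-ancestry cutoff for the admixed class
#' @param detect_axes PCA axes scanned for aggregated loadings
#' @param z_threshold,window_bp,merge_gap_bp region detection parameters
#' @param remove_unconfirmed also remove detected regions whose karyotype
#'   call is not heterozygosity-confirmed
#' @param sex_mode,min_per_sex sex scan parameters (see [sex_scan()])
#' @param outlier_K,outlier_fdr outlier scan parameters; `outlier_set`
#'   chooses which flag drives removal (`"fdr"` or `"bonferroni"`)
#' @param r2_within,prune_window_bp,r2_between LD pruning thresholds
#' @param ancestry_K K for the final ancestry model (0 to skip)
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1,
                            stages = c(qc = TRUE, species = TRUE,
                                       inversions = TRUE, sex = TRUE,
                                       structure = TRUE, outliers = TRUE,
                                       ld_prune = TRUE),
                            maf_min = 0.01, max_missing_rate = 0.10,
                            het_max = 0.6, depth_range = c(10, 95),
                            sample_max_missing = 0.30,
                            kin_threshold = 0.177,
                            species_maf_min = 0.05,
                            admix_threshold = 0.05,
                            detect_axes = 1:6,
                            z_threshold = 4, window_bp = 1e6,
                            merge_gap_bp = 2e6,
                            remove_unconfirmed = FALSE,
                            sex_mode = "presence", min_per_sex = 5,
                            outlier_K = 2, outlier_fdr = 0.05,
                            outlier_set = c("fdr", "bonferroni"),
                            r2_within = 0.05, prune_window_bp = 1e7,
                            r2_between = 0.10,
                            ancestry_K = 3) {
  cfg <- as.list(environment())
  cfg$outlier_set <- match.arg(outlier_set)
  structure(cfg, class = "pipeline_config")
}

#' Run the layered genomic-structure pipeline
#'
#' Executes the study workflow on a genotype matrix and sample metadata:
#' SNP/sample/kinship QC, species screen (remove the second species and
#' admixed individuals, retaining mito-discordant focal-species samples),
#' MAF re-filter, inversion detection and karyotyping, sex-linked-segment
#' scan, removal of all flagged regions, structure analyses, outlier
#' partition, LD pruning, and a final structure pass on the neutral
#' unlinked set. Every removal appends a ledger row; the manifest captures
#' seed and thresholds so a rerun with the same inputs is byte-identical.
#'
#' @param g a [geno()] object
#' @param samples metadata tibble ([read_sample_table()] layout) covering
#'   the samples of `g`
#' @param config a [pipeline_config()]
#' @param output_dir optional directory for ledger TSV / manifest JSON /
#'   per-stage region BED output
#' @return list of class `pipeline_run`: `geno` (final), `ledger`,
#'   `stages` (per-stage results), `manifest`, and `error` (`NULL` on
#'   success; on stage failure, partial outputs plus the condition message)
#' @export
run_pipeline <- function(g, samples, config = pipeline_config(),
                         output_dir = NULL) {
  check_that(all(g$samples %in% samples$sample_id),
             "metadata must cover every genotyped sample")
  st <- config$stages
  res <- list()
  g_input <- g
  ledger <- ledger_add(NULL, "input", g)
  err <- NULL
  meta <- function(gg) samples[match(gg$samples, samples$sample_id), ]

  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      err <<- paste0(label, ": ", conditionMessage(e))
      NULL
    })
  }

  # ---- QC ------------------------------------------------------------------
  if (isTRUE(st[["qc"]]) && is.null(err)) run_stage("qc", {
    sf <- snp_filter(g, maf_min = config$maf_min,
                     max_missing_rate = config$max_missing_rate,
                     het_max = config$het_max,
                     depth_range = config$depth_range)
    g <- sf$geno
    ledger <- ledger_add(ledger, "snp_filter", g)
    sm <- sample_filter(g, max_missing = config$sample_max_missing)
    g <- sm$geno
    ledger <- ledger_add(ledger, "sample_missingness", g)
    kin <- king_kinship(g)
    pr <- prune_related(g, kin, phi_threshold = config$kin_threshold)
    g <- pr$geno
    ledger <- ledger_add(ledger, "relatedness", g)
    if ("locus_id" %in% names(g$loci)) {
      g <- one_snp_per_locus(g)
      ledger <- ledger_add(ledger, "one_snp_per_locus", g)
    }
    res$qc <- list(kinship = kin, removed_samples = c(sm$removed, pr$removed))
  })

  # ---- species screen ------------------------------------------------------
  if (isTRUE(st[["species"]]) && is.null(err)) run_stage("species", {
    fit <- admixture_em(g, K = 2, seed = config$seed, n_restarts = 3)
    calls <- classify_species(fit$Q, g$samples, meta(g),
                              admix_threshold = config$admix_threshold)
    res$species <- list(
      ancestry = fit, calls = calls,
      summary = species_summary(calls, meta(g)$ecoregion))
    keep <- calls$sample_id[calls$class %in% c("pure_B", "B_with_A_mtDNA")]
    g <- subset_geno(g, samples = keep)
    ledger <- ledger_add(ledger, "remove_speciesA_and_admixed", g)
    g <- snp_filter(g, maf_min = config$species_maf_min,
                     max_missing_rate = 1 + 1e-9, het_max = 1,
                     depth_range = NULL)$geno
    ledger <- ledger_add(ledger, "maf_refilter", g)
  })

  # ---- inversion detection & karyotyping -----------------------------------
  regions_to_drop <- list()
  if (isTRUE(st[["inversions"]]) && is.null(err)) run_stage("inversions", {
    pc <- pca_genotypes(g, n_axes = max(config$detect_axes))
    regs <- list()
    for (ax in config$detect_axes) {
      if (ax > ncol(pc$scores)) next
      prof <- loading_profile(pc, axis = ax, window_bp = config$window_bp)
      suppressWarnings(
        regs[[length(regs) + 1]] <- detect_aggregated_regions(
          prof, window_bp = config$window_bp,
          z_threshold = config$z_threshold,
          merge_gap_bp = config$merge_gap_bp))
    }
    regs <- bind_rows(regs)
    if (nrow(regs) > 0) {
      # merge overlapping detections across axes
      regs <- regs |> arrange(.data$chrom, .data$start)
      merged <- regs[1, ]
      for (k in seq_len(nrow(regs))[-1]) {
        last <- nrow(merged)
        if (regs$chrom[k] == merged$chrom[last] &&
            regs$start[k] <= merged$end[last] + config$merge_gap_bp) {
          merged$end[last] <- max(merged$end[last], regs$end[k])
        } else merged <- bind_rows(merged, regs[k, ])
      }
      karyos <- lapply(seq_len(nrow(merged)), function(k)
        tryCatch(karyotype_region(g, merged[k, ], seed = config$seed),
                 error = function(e) NULL))
      keep_reg <- vapply(karyos, function(kc)
        !is.null(kc) && (kc$confirmed || config$remove_unconfirmed),
        logical(1))
      res$inversions <- list(regions = merged, karyotypes = karyos)
      if (any(keep_reg))
        regions_to_drop$inversions <- merged[keep_reg, c("chrom", "start", "end")]
    } else res$inversions <- list(regions = regs, karyotypes = list())
  })

  # ---- sex-linked segment --------------------------------------------------
  # scanned on the unfiltered input matrix: presence/absence sex markers are
  # close to 50% missing by nature and would never survive the missingness
  # filter (mirrors running the read-level sex scan before SNP filtering)
  if (isTRUE(st[["sex"]]) && is.null(err)) run_stage("sex", {
    scan <- sex_scan(g_input, meta(g_input)$sex, mode = config$sex_mode,
                     min_per_sex = config$min_per_sex)
    segs <- sex_scan_regions(scan)
    res$sex <- list(scan = scan, regions = segs)
    if (nrow(segs) > 0)
      regions_to_drop$sex <- segs[, c("chrom", "start", "end")]
  })

  # ---- remove flagged regions ----------------------------------------------
  if (length(regions_to_drop) > 0 && is.null(err)) run_stage("region_removal", {
    drop <- bind_rows(regions_to_drop)
    g <- subset_geno(g, regions = drop, invert_regions = TRUE)
    ledger <- ledger_add(ledger, "remove_flagged_regions", g)
    res$removed_regions <- drop
  })

  # ---- structure on the region-free set ------------------------------------
  if (isTRUE(st[["structure"]]) && is.null(err)) run_stage("structure", {
    pc <- pca_genotypes(g, n_axes = 10)
    fc <- find_clusters(pc, k_max = min(6, n_samples(g) - 1),
                        n_pcs = min(10, ncol(pc$scores)),
                        seed = config$seed)
    dp <- if (fc$best_k >= 2)
      dapc_genotypes(g, fc$assignments) else NULL
    anc <- if (config$ancestry_K >= 1)
      admixture_em(g, K = config$ancestry_K, seed = config$seed,
                   n_restarts = 2) else NULL
    res$structure <- list(pca = pc, clusters = fc, dapc = dp,
                           ancestry = anc)
  })

  # ---- outlier partition ---------------------------------------------------
  if (isTRUE(st[["outliers"]]) && is.null(err)) run_stage("outliers", {
    sc <- pcadapt_outliers(g, K = config$outlier_K, fdr = config$outlier_fdr)
    flag <- if (config$outlier_set == "fdr") sc$table$flag_fdr else
      sc$table$flag_bonferroni
    res$outliers <- list(
      scan = sc,
      partition = outlier_partition_counts(n_loci(g), flag))
    if (any(flag)) {
      g <- subset_geno(g, loci = !flag)
      ledger <- ledger_add(ledger, "remove_outlier_loci", g)
    }
  })

  # ---- LD pruning ----------------------------------------------------------
  if (isTRUE(st[["ld_prune"]]) && is.null(err)) run_stage("ld_prune", {
    g <- ld_prune(g, r2_within = config$r2_within,
                   window_bp = config$prune_window_bp,
                   r2_between = config$r2_between)
    ledger <- ledger_add(ledger, "ld_prune", g)
  })

  # ---- final structure -----------------------------------------------------
  if (isTRUE(st[["structure"]]) && is.null(err)) run_stage("final_structure", {
    res$final <- list(pca = pca_genotypes(g, n_axes = 10))
  })

  manifest <- list(
    package = "poplayers",
    version = as.character(utils::packageVersion("poplayers")),
    seed = config$seed,
    stages = as.list(st),
    thresholds = config[setdiff(names(config), c("stages", "seed"))],
    final_n_snps = n_loci(g), final_n_samples = n_samples(g),
    error = err)
  out <- structure(list(geno = g, ledger = ledger, stages = res,
                        manifest = manifest, error = err),
                   class = "pipeline_run")
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    readr::write_tsv(ledger, file.path(output_dir, "ledger.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    if (!is.null(res$removed_regions))
      write_bed(res$removed_regions, file.path(output_dir, "removed_regions.bed"))
  }
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", if (!is.null(x$error))
    paste("FAILED at", x$error) else "complete", "\n")
  print(x$ledger)
  invisible(x)
}
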