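#' Configuration for the synthetic ddRAD dataset generator
#'
#' Bundles every knob of the generator into a validated list. The defaults
#' emulate the statistical structure of a two-gadid RAD-seq study: two
#' species with near-fixed nuclear divergence at a diagnostic subset of loci
#' and species-diagnostic maternal mtDNA; a small admixed (backcross)
#' contingent; three island-model populations within the focal species at
#' weak differentiation (FST ~ 0.01) plus a minority of elevated-divergence
#' outlier loci; an Mbp-scale chromosomal inversion with suppressed
#' recombination producing AA/AB/BB karyotype clusters; an XY-type
#' sex-linked segment with male-limited markers; uniform missingness, a
#' lognormal depth spectrum, and a few related sample pairs.
#'
#' @param seed integer seed fixing the entire output
#' @param n_loci approximate number of SNPs to generate
#' @param chrom_layout named numeric vector of chromosome lengths in bp
#' @param diag_frac fraction of background loci that are species-diagnostic
#' @param species_gap allele-frequency gap at diagnostic loci (pA = (1+gap)/2,
#'   pB = (1-gap)/2); default 0.96, i.e. near-fixed differences
#' @param n_pure_A number of pure individuals of the second species
#' @param hybrid_spec tibble(class, n, maternal) with class `"F1"` or
#'   `"BC<g>"` (recurrent parent is the focal species B) and maternal
#'   species `"A"` or `"B"`; `NULL` for none
#' @param pop_spec tibble(pop, ecoregion, n) of focal-species populations
#' @param fst island-model target FST among focal-species populations
#' @param outlier_frac fraction of neutral loci given elevated divergence
#' @param outlier_mult multiplier on the Balding-Nichols FST at outlier loci
#' @param inversion_spec tibble(chrom, start, end, p_inv, divergent_frac)
#'   of planted inversions; `NULL` for none
#' @param hap_eps residual within-haplotype-group diversity at divergent
#'   inversion loci (alt-allele frequency `hap_eps` on the ancestral
#'   arrangement, `1 - hap_eps` on the inverted one)
#' @param sex_spec list(chrom, start, end, male_limited_frac, present_male,
#'   present_female) describing the XY-like segment; `NULL` for none
#' @param sex_known_frac fraction of individuals with recorded phenotypic sex
#' @param n_discordant number of pure focal-species individuals carrying the
#'   other species' mtDNA (maternal introgression)
#' @param mtdna_missing_rate fraction of individuals whose diagnostic mtDNA
#'   sites failed to genotype
#' @param missing_rate genome-wide random genotype missingness
#' @param depth_meanlog,depth_sdlog lognormal parameters of per-locus median
#'   depth
#' @param related_pairs tibble(relationship, n) with relationship
#'   `"duplicate"` or `"parent_offspring"`; `NULL` for none
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       n_loci = 2000,
                       chrom_layout = c(chr02 = 25e6, chr05 = 28e6, chr09 = 28e6,
                                        chr13 = 28e6, chr14 = 25e6),
                       diag_frac = 0.25,
                       species_gap = 0.96,
                       n_pure_A = 9,
                       hybrid_spec = NULL,
                       pop_spec = tibble(
                         pop = c("pop1", "pop2", "pop3"),
                         ecoregion = c("Western Arctic", "Eastern Arctic",
                                       "Newfoundland-Labrador Shelves"),
                         n = c(40, 40, 40)),
                       fst = 0.01,
                       outlier_frac = 0.10,
                       outlier_mult = 10,
                       inversion_spec = tibble(
                         chrom = "chr09", start = 7350621, end = 23417670,
                         p_inv = 0.3, divergent_frac = 0.8),
                       hap_eps = 0.05,
                       sex_spec = list(chrom = "chr13", start = 16060190,
                                       end = 17944656, male_limited_frac = 0.6,
                                       present_male = 0.9, present_female = 0.02),
                       sex_known_frac = 0.5,
                       n_discordant = 4,
                       mtdna_missing_rate = 0.02,
                       missing_rate = 0.05,
                       depth_meanlog = log(30), depth_sdlog = 0.4,
                       related_pairs = tibble(
                         relationship = c("duplicate", "parent_offspring"),
                         n = c(1L, 1L))) {
  cfg <- list(seed = seed, n_loci = n_loci, chrom_layout = chrom_layout,
              diag_frac = diag_frac, species_gap = species_gap,
              n_pure_A = n_pure_A,
              hybrid_spec = if (is.null(hybrid_spec)) NULL else
                as_tibble(hybrid_spec),
              pop_spec = as_tibble(pop_spec), fst = fst,
              outlier_frac = outlier_frac, outlier_mult = outlier_mult,
              inversion_spec = if (is.null(inversion_spec)) NULL else
                as_tibble(inversion_spec),
              hap_eps = hap_eps, sex_spec = sex_spec,
              sex_known_frac = sex_known_frac, n_discordant = n_discordant,
              mtdna_missing_rate = mtdna_missing_rate,
              missing_rate = missing_rate,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              related_pairs = if (is.null(related_pairs)) NULL else
                as_tibble(related_pairs))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_that(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be scalar")
  check_that(!is.null(names(cfg$chrom_layout)) && all(cfg$chrom_layout > 0),
             "chrom_layout must be a named vector of positive lengths")
  for (p in c("diag_frac", "species_gap", "outlier_frac", "hap_eps",
              "sex_known_frac", "mtdna_missing_rate", "missing_rate"))
    check_that(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  check_that(cfg$fst > 0 && cfg$fst < 1, "fst must be in (0, 1)")
  check_that(all(cfg$pop_spec$n >= 0) && cfg$n_pure_A >= 0 &&
               cfg$n_discordant >= 0, "counts must be >= 0")
  reg_ok <- function(chrom, start, end) {
    chrom %in% names(cfg$chrom_layout) & start >= 1 &
      end <= cfg$chrom_layout[chrom] & start <= end
  }
  if (!is.null(cfg$inversion_spec)) {
    check_that(all(reg_ok(cfg$inversion_spec$chrom, cfg$inversion_spec$start,
                          cfg$inversion_spec$end)),
               "inversion region outside chrom_layout")
    check_that(all(cfg$inversion_spec$p_inv >= 0 & cfg$inversion_spec$p_inv <= 1),
               "p_inv must be in [0, 1]")
  }
  if (!is.null(cfg$sex_spec))
    check_that(all(reg_ok(cfg$sex_spec$chrom, cfg$sex_spec$start,
                          cfg$sex_spec$end)),
               "sex region outside chrom_layout")
  if (!is.null(cfg$hybrid_spec))
    check_that(all(grepl("^(F1|BC[0-9]+)$", cfg$hybrid_spec$class)),
               "hybrid class must be F1 or BC<g>")
  invisible(cfg)
}

# Balding-Nichols draw of deme frequencies around ancestral p with target FST
bn_freq <- function(p, fst) {
  rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

#' Simulate hybrid genotypes by explicit pedigree
#'
#' F1 individuals receive one gamete drawn from each species' allele
#' frequencies; each further backcross generation BCg crosses a gamete of
#' the previous hybrid against a fresh gamete of the recurrent (focal)
#' species, with free recombination among loci. Expected minor-species
#' ancestry is 0.5 for F1 and `0.5^(g+1)` for BCg.
#'
#' @param p_a,p_b allele-frequency vectors of the minor (A) and recurrent
#'   (B) species, equal length
#' @param class `"F1"` or `"BC<g>"`
#' @param n number of individuals
#' @return list with `G` (n x L dosage matrix), `expected_ancestry_A`
#'   (scalar pedigree expectation) and `realized_ancestry_A` (per-individual
#'   fraction of allele copies of A origin)
#' @export
simulate_hybrids <- function(p_a, p_b, class, n) {
  check_that(length(p_a) == length(p_b),
             "parental frequency vectors differ in length")
  if (!grepl("^(F1|BC[0-9]+)$", class)) abort(paste("unknown hybrid class:", class))
  g_back <- if (class == "F1") 0L else as.integer(sub("^BC", "", class))
  L <- length(p_a)
  G <- matrix(0L, n, L)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    # haplotypes carry (allele, origin); origin tracks the A-species fraction
    h1 <- rbinom(L, 1, p_a); o1 <- rep(1L, L)   # A gamete
    h2 <- rbinom(L, 1, p_b); o2 <- rep(0L, L)   # B gamete
    for (gen in seq_len(g_back)) {
      pick <- rbinom(L, 1, 0.5) == 1            # gamete from current hybrid
      h1 <- ifelse(pick, h1, h2); o1 <- ifelse(pick, o1, o2)
      h2 <- rbinom(L, 1, p_b); o2 <- rep(0L, L) # fresh recurrent-parent gamete
    }
    G[i, ] <- h1 + h2
    realized[i] <- mean(c(o1, o2))
  }
  list(G = G, expected_ancestry_A = 0.5^(g_back + 1),
       realized_ancestry_A = realized)
}

#' Closed-form expectations implied by a simulation configuration
#'
#' @param cfg a [sim_config()]
#' @return list with `fst_target` (pairwise expectation among focal
#'   populations), `karyotype_freq` (Hardy-Weinberg AA/AB/BB expectation per
#'   planted inversion), `hybrid_ancestry_A` (per hybrid class), and
#'   `kinship` (expected KING phi per planted relationship)
#' @export
expected_summaries <- function(cfg) {
  pops <- cfg$pop_spec$pop
  np <- length(pops)
  fst_mat <- matrix(if (np > 1) cfg$fst else 0, np, np,
                    dimnames = list(pops, pops))
  diag(fst_mat) <- 0
  kary <- NULL
  if (!is.null(cfg$inversion_spec)) {
    kary <- cfg$inversion_spec |>
      mutate(AA = (1 - .data$p_inv)^2,
             AB = 2 * .data$p_inv * (1 - .data$p_inv),
             BB = .data$p_inv^2) |>
      select("chrom", "start", "end", "AA", "AB", "BB")
  }
  hyb <- NULL
  if (!is.null(cfg$hybrid_spec)) {
    g <- rep(0L, nrow(cfg$hybrid_spec))
    bc <- cfg$hybrid_spec$class != "F1"
    g[bc] <- as.integer(sub("^BC", "", cfg$hybrid_spec$class[bc]))
    hyb <- setNames(0.5^(g + 1), cfg$hybrid_spec$class)
  }
  list(fst_target = fst_mat, karyotype_freq = kary, hybrid_ancestry_A = hyb,
       kinship = c(duplicate = 0.5, parent_offspring = 0.25))
}

# lay out RAD loci along chromosomes; some loci carry 2-3 SNPs within 90 bp
sim_loci <- function(cfg) {
  lens <- cfg$chrom_layout
  n_rad <- ceiling(cfg$n_loci / 1.4)
  chrom <- sample(names(lens), n_rad, replace = TRUE, prob = lens / sum(lens))
  start <- floor(runif(n_rad, 1, lens[chrom] - 100))
  n_snp <- sample(1:3, n_rad, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  loci <- tibble(
    chrom = rep(chrom, n_snp),
    rad_locus = rep(seq_len(n_rad), n_snp),
    offset = unlist(lapply(n_snp, function(k) sort(sample(0:89, k))))
  ) |>
    mutate(pos = start[.data$rad_locus] + .data$offset) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(match(.data$chrom, names(lens)), .data$pos)
  loci$id <- paste0(loci$chrom, ":", loci$pos)
  loci$rad_locus <- paste0("rad", loci$rad_locus)
  bases <- c("A", "C", "G", "T")
  loci$ref <- sample(bases, nrow(loci), replace = TRUE)
  loci$alt <- vapply(loci$ref, function(r) sample(setdiff(bases, r), 1), "")
  loci
}

#' Simulate a full synthetic dataset with known truth
#'
#' Generates a genotype matrix, a sample metadata table and a `truth` record
#' under the structure described in [sim_config()]. All randomness flows
#' from `cfg$seed`; the same configuration always yields identical output.
#'
#' Key guarantees: mtDNA is inherited maternally, so hybrid classes carry
#' the maternal species' diagnostic haplotype and planted discordant
#' individuals are focal-species nuclear genomes with the other species'
#' mtDNA; divergent loci inside a planted inversion are drawn from two
#' internally near-monomorphic haplotype groups, so arrangement
#' heterozygotes are heterozygous at those sites; male-limited sex markers
#' are present (non-missing, alt-carrying) predominantly in males.
#'
#' @param cfg a [sim_config()]
#' @return list with elements `geno` (a [geno()] object), `samples` (the
#'   metadata tibble in the layout read by [read_sample_table()]), and
#'   `truth` (per-sample and per-locus truth tibbles plus the config)
#' @export
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  loci <- sim_loci(cfg)
  L <- nrow(loci)

  # ---- locus classes -------------------------------------------------------
  cls <- rep("neutral", L)
  inv_idx <- list()
  if (!is.null(cfg$inversion_spec)) {
    for (k in seq_len(nrow(cfg$inversion_spec))) {
      inv_idx[[k]] <- which(in_regions(loci$chrom, loci$pos,
                                       cfg$inversion_spec[k, ]))
      cls[inv_idx[[k]]] <- "inversion"
    }
  }
  sex_idx <- integer(0)
  if (!is.null(cfg$sex_spec)) {
    sreg <- regions_tbl(cfg$sex_spec$chrom, cfg$sex_spec$start, cfg$sex_spec$end)
    sex_idx <- which(in_regions(loci$chrom, loci$pos, sreg))
    cls[sex_idx] <- "sex_region"
  }
  bg <- which(cls == "neutral")
  diag_idx <- sort(sample(bg, round(cfg$diag_frac * length(bg))))
  cls[diag_idx] <- "diagnostic"
  bg <- which(cls == "neutral")
  out_idx <- sort(sample(bg, round(cfg$outlier_frac * length(bg))))
  cls[out_idx] <- "outlier"

  # ---- allele frequencies --------------------------------------------------
  p0 <- runif(L, 0.05, 0.95)
  p_a <- p0                                  # second species (A)
  p_a[diag_idx] <- (1 + cfg$species_gap) / 2
  p0[diag_idx] <- (1 - cfg$species_gap) / 2  # focal species: near-absent allele
  pops <- cfg$pop_spec
  fst_loc <- rep(cfg$fst, L)
  fst_loc[out_idx] <- pmin(cfg$fst * cfg$outlier_mult, 0.8)
  p_pop <- vapply(seq_len(nrow(pops)), function(k) {
    p <- bn_freq(p0, fst_loc)
    p[diag_idx] <- p0[diag_idx]              # diagnostic gap held fixed
    p
  }, numeric(L))

  # ---- base samples --------------------------------------------------------
  sample_rows <- list(); G_rows <- list()
  add <- function(G_block, tb) {
    G_rows[[length(G_rows) + 1]] <<- G_block
    sample_rows[[length(sample_rows) + 1]] <<- tb
  }
  if (cfg$n_pure_A > 0) {
    n <- cfg$n_pure_A
    add(matrix(rbinom(n * L, 2, rep(p_a, each = n)), n, L),
        tibble(class = "pure_A", pop = "speciesA",
               ecoregion = rep_len(c("Western Arctic", "Eastern Arctic"), n),
               ancestry_A = 1, mtdna_species = "A"))
  }
  for (k in seq_len(nrow(pops))) {
    n <- pops$n[k]
    if (n == 0) next
    add(matrix(rbinom(n * L, 2, rep(p_pop[, k], each = n)), n, L),
        tibble(class = rep("pure_B", n), pop = pops$pop[k],
               ecoregion = pops$ecoregion[k], ancestry_A = 0,
               mtdna_species = "B"))
  }
  if (!is.null(cfg$hybrid_spec)) {
    for (k in seq_len(nrow(cfg$hybrid_spec))) {
      hs <- cfg$hybrid_spec[k, ]
      if (hs$n == 0) next
      hb <- simulate_hybrids(p_a, p_pop[, 1], hs$class, hs$n)
      add(hb$G, tibble(class = rep(hs$class, hs$n), pop = pops$pop[1],
                       ecoregion = pops$ecoregion[1],
                       ancestry_A = hb$realized_ancestry_A,
                       mtdna_species = hs$maternal %||% "B"))
    }
  }
  G <- do.call(rbind, G_rows)
  samp <- bind_rows(sample_rows)
  samp$sample_id <- sprintf("S%03d", seq_len(nrow(samp)))
  samp$related_to <- NA_character_

  # ---- planted inversions (karyotype per base sample) ----------------------
  kary_mat <- NULL
  if (!is.null(cfg$inversion_spec)) {
    kary_mat <- matrix(0L, nrow(samp), nrow(cfg$inversion_spec))
    for (k in seq_len(nrow(cfg$inversion_spec))) {
      reg <- cfg$inversion_spec[k, ]
      div <- sort(sample(inv_idx[[k]],
                         round(reg$divergent_frac * length(inv_idx[[k]]))))
      cls[div] <- "inversion_divergent"
      kc <- rbinom(nrow(samp), 2, reg$p_inv)   # inverted-haplotype copies
      kary_mat[, k] <- kc
      for (j in div) {
        # one Bernoulli per haplotype copy: eps on ancestral, 1-eps inverted
        G[, j] <- rbinom(nrow(samp), kc, 1 - cfg$hap_eps) +
          rbinom(nrow(samp), 2L - kc, cfg$hap_eps)
      }
    }
  }

  # ---- mito-nuclear discordance (before relatives are copied) --------------
  if (cfg$n_discordant > 0) {
    pool <- which(samp$class == "pure_B")
    disc <- sample(pool, min(cfg$n_discordant, length(pool)))
    samp$mtdna_species[disc] <- "A"
  }
  samp$sex <- sample(c("F", "M"), nrow(samp), replace = TRUE)

  # ---- related extras ------------------------------------------------------
  if (!is.null(cfg$related_pairs) && nrow(cfg$related_pairs) > 0) {
    b_pool <- which(samp$class == "pure_B")
    for (k in seq_len(nrow(cfg$related_pairs))) {
      rel <- cfg$related_pairs$relationship[k]
      for (j in seq_len(cfg$related_pairs$n[k])) {
        src <- sample(b_pool, 1)
        if (rel == "duplicate") {
          g_new <- G[src, ]
          kc_new <- if (is.null(kary_mat)) NULL else kary_mat[src, ]
          sex_new <- samp$sex[src]; mt_new <- samp$mtdna_species[src]
        } else {
          pk <- p_pop[, match(samp$pop[src], pops$pop)]
          par <- G[src, ]
          from_par <- ifelse(par == 1L, rbinom(L, 1, 0.5), par %/% 2L)
          g_new <- as.integer(from_par + rbinom(L, 1, pk))
          kc_new <- if (is.null(kary_mat)) NULL else rep(NA_integer_,
                                                         ncol(kary_mat))
          sex_new <- sample(c("F", "M"), 1); mt_new <- "B"
        }
        G <- rbind(G, g_new)
        if (!is.null(kary_mat)) kary_mat <- rbind(kary_mat, kc_new)
        samp <- bind_rows(samp, tibble(
          class = "pure_B", pop = samp$pop[src],
          ecoregion = samp$ecoregion[src], ancestry_A = 0,
          mtdna_species = mt_new,
          sample_id = sprintf("S%03d", nrow(samp) + 1),
          related_to = paste0(rel, ":", samp$sample_id[src]),
          sex = sex_new))
      }
    }
  }
  n <- nrow(samp)
  if (!is.null(kary_mat)) {
    for (k in seq_len(ncol(kary_mat)))
      samp[[paste0("karyotype_", k)]] <- c("AA", "AB", "BB")[kary_mat[, k] + 1L]
  }

  # ---- sex-linked male-limited markers (presence/absence at genotype level)
  samp$sex_known <- runif(n) < cfg$sex_known_frac
  if (!is.null(cfg$sex_spec) && length(sex_idx) > 0) {
    ml <- sort(sample(sex_idx,
                      round(cfg$sex_spec$male_limited_frac * length(sex_idx))))
    cls[ml] <- "sex_male_limited"
    is_m <- samp$sex == "M"
    p_pres <- ifelse(is_m, cfg$sex_spec$present_male,
                     cfg$sex_spec$present_female)
    for (j in ml)
      G[, j] <- ifelse(runif(n) < p_pres, 1L, NA_integer_)
  }

  # ---- missingness & depth -------------------------------------------------
  if (cfg$missing_rate > 0)
    G[matrix(runif(n * L) < cfg$missing_rate, n, L)] <- NA_integer_
  loci$median_depth <- round(rlnorm(L, cfg$depth_meanlog, cfg$depth_sdlog), 1)

  # ---- assemble ------------------------------------------------------------
  storage.mode(G) <- "integer"
  gobj <- geno(G, tibble(chrom = loci$chrom, pos = loci$pos, id = loci$id,
                         ref = loci$ref, alt = loci$alt,
                         median_depth = loci$median_depth,
                         locus_id = loci$rad_locus),
               samples = samp$sample_id)
  truth_loci <- gobj$loci |>
    left_join(tibble(id = loci$id, truth_class = cls), by = "id") |>
    select("chrom", "pos", "id", "truth_class")

  mt_missing <- runif(n) < cfg$mtdna_missing_rate
  meta <- tibble(
    sample_id = samp$sample_id,
    ecoregion = samp$ecoregion,
    site = paste0("site_", samp$pop),
    sex = normalize_sex(ifelse(samp$sex_known, samp$sex, "")),
    mtdna_4894 = ifelse(mt_missing, "",
                        ifelse(samp$mtdna_species == "A", "T", "C")),
    mtdna_5138 = ifelse(mt_missing, "",
                        ifelse(samp$mtdna_species == "B", "C", "T"))
  )
  list(geno = gobj, samples = meta,
       truth = list(samples = samp, loci = truth_loci, config = cfg))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `genotypes.vcf`, `samples.tsv`, `regions.bed` (planted inversion
#' and sex regions) and `truth.json` under `dir`.
#'
#' @param sim result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vcf(sim$geno, file.path(dir, "genotypes.vcf"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  cfg <- sim$truth$config
  regs <- list()
  if (!is.null(cfg$inversion_spec))
    regs$inv <- regions_tbl(cfg$inversion_spec$chrom, cfg$inversion_spec$start,
                            cfg$inversion_spec$end)
  if (!is.null(cfg$sex_spec))
    regs$sex <- regions_tbl(cfg$sex_spec$chrom, cfg$sex_spec$start,
                            cfg$sex_spec$end)
  if (length(regs) > 0)
    write_bed(bind_rows(regs), file.path(dir, "regions.bed"))
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(list(samples = sim$truth$samples,
                              loci = sim$truth$loci),
                         file.path(dir, "truth.json"))
  invisible(dir)
}
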