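test_that("the outlier scan is invariant to sample order", {
  sim <- simulate_dataset(sim_config(seed = 91, n_loci = 400, n_pure_A = 0,
                                     diag_frac = 0, inversion_spec = NULL,
                                     sex_spec = NULL, n_discordant = 0,
                                     related_pairs = NULL))
  g <- sim$geno
  sc1 <- pcadapt_outliers(g, K = 2)
  set.seed(1)
  perm <- sample(n_samples(g))
  gp <- geno(g$G[perm, ], g$loci, g$samples[perm])
  sc2 <- pcadapt_outliers(gp, K = 2)
  expect_equal(sc1$table$d2, sc2$table$d2, tolerance = 1e-8)
  expect_equal(sc1$table$p_value, sc2$table$p_value, tolerance = 1e-8)
  expect_equal(sc1$lambda, sc2$lambda, tolerance = 1e-8)
  expect_error(pcadapt_outliers(g, K = 1000), "smaller")
})

test_that("flags are consistent with thresholds and q is monotone in p", {
  sim <- simulate_dataset(sim_config(seed = 92, n_loci = 500, n_pure_A = 0,
                                     diag_frac = 0, inversion_spec = NULL,
                                     sex_spec = NULL, n_discordant = 0,
                                     related_pairs = NULL))
  sc <- pcadapt_outliers(sim$geno, K = 2)
  tab <- sc$table[!is.na(sc$table$q_value), ]
  expect_gt(sc$lambda, 0)
  expect_identical(tab$flag_fdr, tab$q_value < 0.05)
  ord <- order(tab$p_value)
  expect_true(all(diff(tab$q_value[ord]) >= -1e-12))
})

test_that("planted high-divergence loci are flagged with controlled FDP", {
  cfg <- sim_config(seed = 93, n_loci = 3000, n_pure_A = 0, diag_frac = 0,
                    outlier_frac = 0.1, inversion_spec = NULL,
                    sex_spec = NULL, n_discordant = 0, related_pairs = NULL,
                    pop_spec = tibble::tibble(
                      pop = c("p1", "p2", "p3"),
                      ecoregion = c("e1", "e2", "e3"), n = 100))
  sim <- simulate_dataset(cfg)
  sc <- pcadapt_outliers(sim$geno, K = 2)
  planted <- sim$truth$loci$truth_class == "outlier"
  flags <- sc$table$flag_fdr
  expect_gt(sum(flags), 20)
  expect_lte(mean(!planted[flags]), 0.10)          # realized FDP
  expect_gte(mean(flags[planted]), 0.25)           # power floor
  expect_gt(mean(flags[planted]) / max(mean(flags[!planted]), 1e-6), 10)
})

test_that("BH q-values equal a brute-force step-up", {
  set.seed(94)
  p <- runif(200)^2
  q <- p.adjust(p, method = "BH")     # the path used by the scan
  # brute force: q_i = min over j with p_j >= p_i of m*p_j/rank_j
  m <- length(p)
  ord <- order(p)
  stepup <- numeric(m)
  running <- Inf
  for (k in rev(seq_len(m))) {
    running <- min(running, m * p[ord[k]] / k)
    stepup[ord[k]] <- running
  }
  expect_equal(q, stepup, tolerance = 1e-12)
})

test_that("outlier partition arithmetic reproduces printed-count percentages", {
  a <- outlier_partition_counts(11233, 1553)
  expect_equal(a$pct_outlier, 13.8)
  expect_equal(a$n_neutral, 9680)
  expect_equal(outlier_partition_counts(11233, 465)$pct_outlier, 4.1)
  expect_equal(outlier_partition_counts(11233, 487)$pct_outlier, 4.3)
  expect_equal(pct(347, 487), 71.3)
  z <- outlier_partition_counts(500, 0)
  expect_equal(z$pct_outlier, 0)
  expect_equal(z$n_neutral, 500)
  expect_error(outlier_partition_counts(10, 11), "exceeds")
})

test_that("Weir-Cockerham theta is 1 at fixed differences, ~0 on a random split", {
  G <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  g <- make_geno(G)
  fr <- wc_fst(g, rep(c("a", "b"), each = 10), n_boot = 0)
  expect_equal(fr$pairs$theta, 1)

  set.seed(95)
  g2 <- random_geno(n = 80, L = 5000, miss = 0, seed = 95)
  split <- sample(rep(c("x", "y"), each = 40))
  fr2 <- wc_fst(g2, split, n_boot = 200, seed = 1)
  expect_lt(abs(fr2$pairs$theta), 0.005)
  expect_gt(fr2$pairs$p_boot, 0.05)
})

test_that("theta components match a literal per-locus transcription of WC84", {
  g <- random_geno(n = 24, L = 40, miss = 0.1, seed = 96)
  grp <- rep(c("a", "b"), each = 12)
  fr <- wc_fst(g, grp, n_boot = 0)
  # independent scalar implementation, straight from the published formulas
  num <- den <- 0
  for (l in seq_len(40)) {
    x1 <- g$G[grp == "a", l]; x1 <- x1[!is.na(x1)]
    x2 <- g$G[grp == "b", l]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    r <- 2; nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a; den <- den + a + b + cc
  }
  expect_equal(fr$pairs$theta, num / den, tolerance = 1e-12)
})

test_that("theta is invariant to allele-label swap and bounded by 1", {
  g <- random_geno(n = 30, L = 200, miss = 0.05, seed = 97)
  grp <- rep(c("a", "b"), each = 15)
  t1 <- wc_fst(g, grp, n_boot = 0)$pairs$theta
  gf <- geno(2L - g$G, g$loci, g$samples)
  t2 <- wc_fst(gf, grp, n_boot = 0)$pairs$theta
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_lte(t1, 1)
})

test_that("inbreeding F hits its algebraic limits and null expectation", {
  # fully homozygous sample among heterozygote-rich companions
  set.seed(98)
  L <- 400
  base <- matrix(rbinom(20 * L, 2, 0.5), 20, L)
  base[1, ] <- ifelse(base[1, ] >= 1, 2L, 0L)   # force homozygosity
  g <- make_geno(base)
  ib <- individual_inbreeding(g)
  expect_equal(ib$f[1], 1, tolerance = 1e-12)

  # fully heterozygous sample at p ~ 0.5 loci: strongly negative F
  het <- base; het[2, ] <- 1L
  ib2 <- individual_inbreeding(make_geno(het))
  expect_lt(ib2$f[2], 0)

  # random mating: mean F near zero
  g3 <- random_geno(n = 60, L = 2000, miss = 0.02, seed = 99)
  ib3 <- individual_inbreeding(g3)
  expect_lt(abs(mean(ib3$f)), 0.02)
})

test_that("Kruskal-Wallis/Dunn detects shifted groups, respects symmetry", {
  set.seed(100)
  vals <- c(rnorm(20), rnorm(20, 5), rnorm(20))   # group b shifted 5 SD
  grp <- rep(c("a", "b", "c"), each = 20)
  out <- group_het_tests(vals, grp)
  expect_lt(out$kw$p_value, 0.001)
  b_pairs <- out$dunn$group_i == "b" | out$dunn$group_j == "b"
  expect_true(all(out$dunn$p_adjusted[b_pairs] < 0.01))
  expect_gt(out$dunn$p_adjusted[!b_pairs], 0.05)
  # H invariant under group relabelling
  out2 <- group_het_tests(vals, rep(c("c", "a", "b"), each = 20))
  expect_equal(out$kw$statistic, out2$kw$statistic, tolerance = 1e-12)
  # Dunn z matches the rank-sum formula against kruskal.test machinery
  expect_equal(out$kw$statistic,
               unname(kruskal.test(vals, factor(grp))$statistic),
               tolerance = 1e-12)
  expect_error(group_het_tests(vals[1:5], c("a", "a", "a", "b", "b")),
               ">= 3")
})

test_that("species classification follows the decision table", {
  Q <- rbind(c(0.89, 0.11), c(0.999, 0.001), c(0.001, 0.999),
             c(0.97, 0.03), c(0.5, 0.5))
  mt <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    mtdna_4894 = c("C", "T", "C", "", "C"),    # T = species-A diagnostic
    mtdna_5138 = c("C", "T", "C", "", "C"))    # C = species-B diagnostic
  calls <- classify_species(Q, paste0("s", 1:5), mt, a_cluster = 2,
                            admix_threshold = 0.05)
  expect_equal(calls$class,
               c("admixed", "B_with_A_mtDNA", "pure_A", "pure_B", "admixed"))
  expect_equal(calls$mtdna_species, c("B", "A", "B", "unclassified", "B"))
  # conflicting diagnostics -> unclassified mtDNA with a warning
  mt$mtdna_4894[1] <- "T"
  expect_warning(c2 <- classify_species(Q, paste0("s", 1:5), mt,
                                        a_cluster = 2), "conflicting")
  expect_equal(c2$mtdna_species[1], "unclassified")
})

test_that("the ecoregion summary reproduces printed-count arithmetic", {
  # one ecoregion of 117 with 7 second-species, 3 admixed, 9 discordant
  classes <- c(rep("pure_A", 7), rep("admixed", 3),
               rep("B_with_A_mtDNA", 9), rep("pure_B", 98))
  calls <- tibble::tibble(sample_id = as.character(seq_along(classes)),
                          class = classes)
  sm <- species_summary(calls, rep("Western Arctic", 117))
  expect_equal(sm$n, 117)
  expect_equal(sm$pct_pure_A, 6.0)
  expect_equal(sm$pct_admixed, 2.6)    # 3/117 = 2.56 %, half-up
  expect_equal(sm$pct_discordant, 7.7)
})

test_that("classification on simulated truth is exact for clear thresholds", {
  cfg <- sim_config(seed = 101, n_loci = 800, n_pure_A = 10, diag_frac = 0.4,
                    outlier_frac = 0, inversion_spec = NULL, sex_spec = NULL,
                    n_discordant = 5, related_pairs = NULL,
                    mtdna_missing_rate = 0,
                    hybrid_spec = tibble::tibble(class = "BC1", n = 4,
                                                 maternal = "A"))
  sim <- simulate_dataset(cfg)
  fit <- admixture_em(sim$geno, K = 2, seed = 1, n_restarts = 3)
  calls <- classify_species(fit$Q, sim$geno$samples, sim$samples,
                            admix_threshold = 0.05)
  tr <- sim$truth$samples
  expect_true(all(calls$class[tr$class == "pure_A"] == "pure_A"))
  expect_true(all(calls$class[tr$class == "BC1"] == "admixed"))
  disc <- tr$class == "pure_B" & tr$mtdna_species == "A"
  expect_true(all(calls$class[disc] == "B_with_A_mtDNA"))
  expect_true(all(calls$class[tr$class == "pure_B" &
                                tr$mtdna_species == "B"] == "pure_B"))
})
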