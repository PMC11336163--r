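test_that("snp_filter applies each threshold as specified", {
  # locus 1: maf 0.005 (too rare); locus 2: h_obs 0.7 (paralog-like);
  # locus 3: 20% missing; locus 4: depth 5; locus 5: clean
  n <- 100
  G <- cbind(
    c(rep(1L, 1), rep(0L, n - 1)),
    c(rep(1L, 70), rep(0L, 30)),
    c(rep(NA_integer_, 20), rep(c(0L, 1L), 40)),
    rep(c(0L, 1L, 2L), length.out = n),
    rep(c(0L, 1L, 2L), length.out = n))
  g <- make_geno(G, median_depth = c(30, 30, 30, 5, 30))
  out <- snp_filter(g, maf_min = 0.01, max_missing_rate = 0.10,
                    het_max = 0.6, depth_range = c(10, 95))
  expect_equal(out$geno$loci$pos, 5)
  expect_equal(sum(out$stats$kept), 1)
  # expected-heterozygosity mode keeps the h_obs = 0.7 locus (h_exp < 0.6)
  out2 <- snp_filter(g, het_mode = "expected")
  expect_true(2 %in% out2$geno$loci$pos)
  expect_error(snp_filter(g, maf_min = 0.5), "every locus")
})

test_that("snp_filter survivors match a per-locus re-check oracle", {
  g <- random_geno(n = 60, L = 300, miss = 0.08, seed = 21)
  g$loci$median_depth <- round(rlnorm(300, log(30), 0.8), 1)
  g <- geno(g$G, g$loci, g$samples)
  out <- snp_filter(g, maf_min = 0.05, max_missing_rate = 0.10,
                    het_max = 0.6, depth_range = c(10, 95))
  recheck <- vapply(seq_len(300), function(j) {
    x <- g$G[, j]; ok <- !is.na(x)
    p <- sum(x[ok]) / (2 * sum(ok))
    min(p, 1 - p) > 0.05 && mean(!ok) < 0.10 && mean(x[ok] == 1) <= 0.6 &&
      (is.na(g$loci$median_depth[j]) ||
         (g$loci$median_depth[j] >= 10 && g$loci$median_depth[j] <= 95))
  }, logical(1))
  expect_equal(out$geno$loci$id, g$loci$id[recheck])
})

test_that("sample_filter drops samples above the missingness threshold", {
  G <- matrix(0L, 4, 100)
  G[2, 1:31] <- NA_integer_  # 31 % missing
  G[3, 1:30] <- NA_integer_  # exactly 30 %: retained (strict inequality)
  g <- make_geno(G)
  out <- sample_filter(g, max_missing = 0.30)
  expect_equal(out$removed, "s02")
  expect_equal(n_samples(out$geno), 3)
  clean <- make_geno(matrix(1L, 3, 10))
  expect_equal(sample_filter(clean)$removed, character(0))
})

test_that("KING kinship matches a brute-force pair oracle and is symmetric", {
  g <- random_geno(n = 6, L = 500, miss = 0.1, seed = 31)
  kin <- king_kinship(g, min_sites = 50)
  oracle <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    (sum(x == 1 & y == 1) - 2 * sum(abs(x - y) == 2)) /
      (sum(x == 1) + sum(y == 1))
  }
  for (r in seq_len(nrow(kin))) {
    i <- match(kin$sample_i[r], g$samples)
    j <- match(kin$sample_j[r], g$samples)
    expect_equal(kin$phi[r], oracle(g$G[i, ], g$G[j, ]), tolerance = 1e-12)
    # symmetric estimator: swapping the pair changes nothing
    expect_equal(kin$phi[r], oracle(g$G[j, ], g$G[i, ]), tolerance = 1e-12)
  }
})

test_that("duplicated samples score phi = 0.5; het-free pairs are undefined", {
  g <- random_geno(n = 5, L = 800, miss = 0, seed = 8)
  G <- rbind(g$G, g$G[1, ])
  gd <- make_geno(G, pos = g$loci$pos)
  kin <- king_kinship(gd, min_sites = 50)
  dup <- kin[kin$sample_i == "s01" & kin$sample_j == "s06", ]
  expect_equal(dup$phi, 0.5, tolerance = 1e-12)

  ghom <- make_geno(matrix(c(0L, 2L), 2, 200), pos = 1:200)
  kin0 <- king_kinship(ghom, min_sites = 10)
  expect_true(is.na(kin0$phi))
})

test_that("parent-offspring pairs score phi near 0.25", {
  set.seed(77)
  L <- 5000
  p <- runif(L, 0.1, 0.9)
  parent <- rbinom(L, 2, p)
  from_par <- ifelse(parent == 1L, rbinom(L, 1, 0.5), parent %/% 2L)
  child <- as.integer(from_par + rbinom(L, 1, p))
  others <- matrix(rbinom(3 * L, 2, rep(p, each = 3)), 3, L)
  g <- make_geno(rbind(parent, child, others), pos = 1:L)
  kin <- king_kinship(g, min_sites = 100)
  po <- kin$phi[kin$sample_i == "s01" & kin$sample_j == "s02"]
  expect_equal(po, 0.25, tolerance = 0.02 / 0.25)
  expect_true(all(abs(kin$phi[-1]) < 0.05))
})

test_that("prune_related removes one member per pair and clears all flags", {
  g <- random_geno(n = 6, L = 300, seed = 12)
  pairs <- tibble::tibble(sample_i = c("s01", "s02"),
                          sample_j = c("s02", "s03"),
                          phi = c(0.4, 0.3), n_sites = 300L)
  out <- prune_related(g, pairs, phi_threshold = 0.177)
  left <- pairs[!(pairs$sample_i %in% out$removed) &
                  !(pairs$sample_j %in% out$removed), ]
  expect_true(all(left$phi <= 0.177))
  # a single flagged pair loses exactly one member
  one <- prune_related(g, pairs[1, ], phi_threshold = 0.177)
  expect_length(one$removed, 1)
  # nothing above threshold: identity
  none <- prune_related(g, pairs, phi_threshold = 0.5)
  expect_identical(none$geno$G, g$G)
  expect_length(none$removed, 0)
})

test_that("one_snp_per_locus keeps the lowest-position SNP per RAD locus", {
  g <- make_geno(matrix(0:1, 4, 6), pos = c(10, 20, 30, 100, 200, 300),
                 locus_id = c("r1", "r1", "r1", "r2", "r3", "r3"))
  out <- one_snp_per_locus(g)
  expect_equal(out$loci$pos, c(10, 100, 200))
  # all-singleton annotation: identity
  g2 <- make_geno(matrix(0:1, 4, 3), pos = c(1, 2, 3),
                  locus_id = c("a", "b", "c"))
  expect_identical(one_snp_per_locus(g2)$G, g2$G)
  expect_error(one_snp_per_locus(random_geno(4, 5)), "locus_id")
})

test_that("one_snp_per_locus matches a group-by-min oracle on random input", {
  set.seed(9)
  g <- random_geno(n = 5, L = 80, seed = 9)
  g$loci$locus_id <- paste0("r", sample.int(30, 80, replace = TRUE))
  g <- geno(g$G, g$loci, g$samples)
  out <- one_snp_per_locus(g)
  oracle <- g$loci |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::slice_min(.data$pos, n = 1) |>
    dplyr::ungroup()
  expect_setequal(out$loci$id, oracle$id)
})

test_that("ledger counts never increase down the filtering cascade", {
  sim <- simulate_dataset(sim_config(seed = 14, n_loci = 600))
  g <- sim$geno
  led <- ledger_add(NULL, "input", g)
  f1 <- snp_filter(g); led <- ledger_add(led, "snp", f1$geno)
  f2 <- sample_filter(f1$geno); led <- ledger_add(led, "samples", f2$geno)
  f3 <- one_snp_per_locus(f2$geno); led <- ledger_add(led, "one_snp", f3)
  expect_true(all(diff(led$n_snps) <= 0))
  expect_true(all(diff(led$n_samples) <= 0))
  expect_true(all(diff(led$n_loci) <= 0))
})
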