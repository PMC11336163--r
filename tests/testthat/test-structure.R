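test_that("PCA equals a dense eigendecomposition of the covariance", {
  g <- random_geno(n = 30, L = 300, miss = 0.05, seed = 51)
  pc <- pca_genotypes(g)
  # oracle: eigen() on the covariance of the mean-imputed centered matrix
  X <- g$G
  X <- sweep(X, 2, colMeans(X, na.rm = TRUE))
  X[is.na(X)] <- 0
  ev <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  k <- 10
  expect_equal(pc$eigenvalues[1:k], ev$values[1:k], tolerance = 1e-8)
  for (a in 1:k) {
    dot <- abs(sum(pc$loadings[, a] * ev$vectors[, a]))
    expect_equal(dot, 1, tolerance = 1e-8)  # same axis up to sign
  }
  # eigenvalue sum conserves total variance
  expect_equal(sum(pc$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)
})

test_that("duplicated samples receive identical PCA scores", {
  g <- random_geno(n = 8, L = 120, miss = 0, seed = 52)
  gd <- make_geno(rbind(g$G, g$G[3, ]), pos = g$loci$pos)
  pc <- pca_genotypes(gd, n_axes = 5)
  expect_equal(unname(pc$scores[3, ]), unname(pc$scores[9, ]),
               tolerance = 1e-10)
  expect_error(pca_genotypes(make_geno(matrix(1L, 5, 4))), "monomorphic")
})

test_that("admixture EM: K = 1 closed form and monotone log-likelihood", {
  g <- random_geno(n = 25, L = 150, miss = 0.1, seed = 53)
  fit1 <- admixture_em(g, K = 1)
  expect_true(all(fit1$Q == 1))
  p <- site_allele_stats(g)$p_alt
  expect_equal(as.vector(fit1$F), p, tolerance = 1e-4)

  fit2 <- admixture_em(g, K = 2, seed = 2, n_restarts = 2, max_iter = 100)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-8 * abs(fit2$loglik)))
  expect_true(all(abs(rowSums(fit2$Q) - 1) < 1e-8))
  expect_true(all(fit2$F > 0 & fit2$F < 1))
  # determinism
  fit2b <- admixture_em(g, K = 2, seed = 2, n_restarts = 2, max_iter = 100)
  expect_identical(fit2$Q, fit2b$Q)
})

test_that("admixture at K = 2 separates two near-fixed species completely", {
  # near-fixed diagnostic divergence: pure individuals carry essentially no
  # foreign alleles, so their ML ancestry sits at the boundary
  cfg <- sim_config(seed = 54, n_loci = 800, n_pure_A = 12, diag_frac = 0.5,
                    species_gap = 0.99, outlier_frac = 0,
                    inversion_spec = NULL, sex_spec = NULL,
                    n_discordant = 0, related_pairs = NULL,
                    hybrid_spec = tibble::tibble(class = "F1", n = 3,
                                                 maternal = "A"),
                    pop_spec = tibble::tibble(
                      pop = c("p1", "p2", "p3"),
                      ecoregion = c("e1", "e2", "e3"), n = 15))
  sim <- simulate_dataset(cfg)
  fit <- admixture_em(sim$geno, K = 2, seed = 1, n_restarts = 3)
  pure <- sim$truth$samples$class %in% c("pure_A", "pure_B")
  maj <- apply(fit$Q, 1, max)
  expect_true(all(maj[pure] >= 0.99))
  cl <- apply(fit$Q, 1, which.max)
  expect_equal(length(unique(cl[sim$truth$samples$class == "pure_A"])), 1)
  expect_false(cl[sim$truth$samples$class == "pure_A"][1] %in%
                 cl[sim$truth$samples$class == "pure_B"])
  # F1 hybrids sit near the middle of the ancestry simplex
  expect_true(all(abs(fit$Q[sim$truth$samples$class == "F1", 1] - 0.5) < 0.1))
})

test_that("cross-validation error selects the simulated K", {
  single <- simulate_dataset(bare_cfg <- sim_config(
    seed = 55, n_loci = 400, n_pure_A = 0, diag_frac = 0, outlier_frac = 0,
    inversion_spec = NULL, sex_spec = NULL, n_discordant = 0,
    related_pairs = NULL,
    pop_spec = tibble::tibble(pop = "p1", ecoregion = "e1", n = 40)))
  cv1 <- admixture_cv_error(single$geno, K_values = 1:3, folds = 3, seed = 1,
                            n_restarts = 1, max_iter = 100)
  expect_equal(cv1$K[which.min(cv1$cv_error)], 1)

  three <- simulate_dataset(sim_config(
    seed = 56, n_loci = 600, n_pure_A = 0, diag_frac = 0, outlier_frac = 0,
    inversion_spec = NULL, sex_spec = NULL, n_discordant = 0,
    related_pairs = NULL, fst = 0.05,
    pop_spec = tibble::tibble(pop = c("p1", "p2", "p3"),
                              ecoregion = c("e1", "e2", "e3"), n = 40)))
  cv3 <- admixture_cv_error(three$geno, K_values = 1:3, folds = 5, seed = 1,
                            n_restarts = 1, max_iter = 200)
  expect_equal(cv3$K[which.min(cv3$cv_error)], 3)
  # determinism
  cv3b <- admixture_cv_error(three$geno, K_values = 1:3, folds = 5, seed = 1,
                             n_restarts = 1, max_iter = 200)
  expect_identical(cv3, cv3b)
  expect_error(admixture_cv_error(single$geno, K_values = 100), "K must")
})

test_that("find_clusters selects k by BIC on separable blobs", {
  # like genetic PC scores: a few informative axes plus many noise axes
  set.seed(57)
  centers <- rbind(c(0, 0), c(20, 0), c(10, 20))   # 10+ sigma separation
  blobs <- cbind(centers[rep(1:3, each = 20), ] + matrix(rnorm(120), 60),
                 matrix(rnorm(60 * 18), 60))
  fc <- find_clusters(blobs, k_max = 6, seed = 1)
  expect_equal(fc$best_k, 3)
  expect_equal(length(unique(fc$assignments)), 3)

  one <- matrix(rnorm(50 * 50), 50)
  expect_equal(find_clusters(one, k_max = 5, seed = 1)$best_k, 1)
  # determinism
  expect_identical(find_clusters(blobs, k_max = 6, seed = 1)$assignments,
                   find_clusters(blobs, k_max = 6, seed = 1)$assignments)
  expect_error(find_clusters(one, k_max = 50), "smaller")
})

test_that("DAPC reassigns duplicated-sample clusters perfectly", {
  set.seed(58)
  a <- rbinom(80, 2, 0.2); b <- rbinom(80, 2, 0.8)
  G <- rbind(matrix(rep(a, 5), 5, byrow = TRUE) ,
             matrix(rep(b, 5), 5, byrow = TRUE))
  G <- G + matrix(rbinom(800, 1, 0.02), 10)  # break exact ties
  G[G > 2] <- 2L
  g <- make_geno(G)
  dp <- dapc_genotypes(g, rep(c("x", "y"), each = 5))
  expect_equal(dp$reassignment, 1)
  expect_error(dapc_genotypes(g, rep("x", 10)), "at least 2")
})

test_that("DAPC discriminant scores are invariant to locus order", {
  sim <- simulate_dataset(sim_config(
    seed = 59, n_loci = 400, n_pure_A = 0, diag_frac = 0, outlier_frac = 0,
    inversion_spec = NULL, sex_spec = NULL, n_discordant = 0,
    related_pairs = NULL, fst = 0.05))
  g <- sim$geno
  grp <- sim$truth$samples$pop
  dp1 <- dapc_genotypes(g, grp)
  perm <- sample(n_loci(g))
  gp <- geno(g$G[, perm], g$loci[perm, ], g$samples)  # re-sorts internally
  dp2 <- dapc_genotypes(gp, grp)
  expect_equal(abs(dp1$scores), abs(dp2$scores), tolerance = 1e-6)
  # cluster-majority agreement with the simulated demes
  tab <- table(dp1$predicted, grp)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.90)
})

test_that("loading profiles aggregate unit-norm axes into windows", {
  g <- random_geno(n = 20, L = 200, seed = 60)
  pc <- pca_genotypes(g, n_axes = 3)
  prof <- loading_profile(pc, axis = 2, window_bp = 1e5)
  expect_equal(sum(prof$windows$sum_sq), 1, tolerance = 1e-8)
  # brute-force window sums
  oracle <- tapply(pc$loadings[, 2]^2, floor((g$loci$pos - 1) / 1e5), sum)
  expect_equal(unname(sort(prof$windows$sum_sq)),
               unname(sort(as.numeric(oracle))), tolerance = 1e-12)
  # a single unit loading carries the full mass of its window
  fake <- pc
  fake$loadings[, 1] <- 0
  fake$loadings[5, 1] <- 1
  p1 <- loading_profile(fake, axis = 1, window_bp = 1e5)
  expect_equal(max(p1$windows$sum_sq), 1)
  expect_equal(sum(p1$windows$sum_sq > 0), 1)
})
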