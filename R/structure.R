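#' Principal component analysis of a genotype matrix
#'
#' Centers each locus by its mean dosage, replaces missing calls by the
#' locus mean (i.e. zero after centering), and takes the singular value
#' decomposition of the centered matrix — the classic genlight-style PCA
#' for SNP dosages. Scores are the sample projections; loadings have unit
#' Euclidean norm per axis; eigenvalues are squared singular values divided
#' by (n - 1). Axis signs are canonicalized so the largest-magnitude
#' loading on each axis is positive.
#'
#' @param g a [geno()] object with at least 2 samples and 1 polymorphic locus
#' @param n_axes number of axes to retain (default: all)
#' @param scale also divide each locus by its dosage standard deviation
#' @return object of class `geno_pca` with elements `scores`, `loadings`,
#'   `eigenvalues` (all axes), `center`, `loci`, `var_total`
#' @export
pca_genotypes <- function(g, n_axes = NULL, scale = FALSE) {
  check_that(n_samples(g) >= 2, "need at least 2 samples")
  X <- g$G
  ctr <- colMeans(X, na.rm = TRUE)
  ctr[is.nan(ctr)] <- 0
  X <- sweep(X, 2, ctr)
  X[is.na(X)] <- 0
  if (scale) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  if (all(colSums(X != 0) == 0)) abort("all loci are monomorphic")
  sv <- svd(X)
  n <- nrow(X)
  eig <- sv$d^2 / (n - 1)
  k <- min(n_axes %||% length(sv$d), length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  # sign canonicalization: largest-|loading| per axis positive
  for (a in seq_len(k)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(g$samples, paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(g$loci$id, paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings, eigenvalues = eig,
                 center = ctr, loci = g$loci, var_total = sum(eig)),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("<geno_pca> ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " loci, ", ncol(x$scores), " axes retained\n", sep = "")
  pv <- 100 * x$eigenvalues[1:min(4, length(x$eigenvalues))] / x$var_total
  cat("  variance explained:", paste0(sprintf("%.1f%%", pv), collapse = ", "),
      "...\n")
  invisible(x)
}

#' @export
tidy.geno_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = as_tibble(x$scores, rownames = "sample") |>
      pivot_longer(-"sample", names_to = "axis", values_to = "score"),
    loadings = bind_cols(x$loci[, c("chrom", "pos", "id")],
                         as_tibble(x$loadings)),
    eigenvalues = tibble(axis = paste0("PC", seq_along(x$eigenvalues)),
                         eigenvalue = x$eigenvalues,
                         prop_variance = x$eigenvalues / x$var_total))
}

#' @export
glance.geno_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_loci = nrow(x$loadings),
         n_axes = ncol(x$scores), var_total = x$var_total)
}

#' Scatter plot of two PCA axes
#' @param object a `geno_pca`
#' @param axes length-2 integer, which axes to plot
#' @param colour optional vector (length = samples) used as point colour
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.geno_pca <- function(object, axes = c(1, 2), colour = NULL, ...) {
  df <- tibble(x = object$scores[, axes[1]], y = object$scores[, axes[2]])
  pv <- 100 * object$eigenvalues / object$var_total
  lab <- function(a) sprintf("PC%d (%.1f%%)", a, pv[a])
  p <- if (is.null(colour)) ggplot(df, aes(.data$x, .data$y)) else
    ggplot(mutate(df, colour = colour),
           aes(.data$x, .data$y, colour = .data$colour))
  p + geom_point(alpha = 0.8) +
    labs(x = lab(axes[1]), y = lab(axes[2]), colour = NULL) +
    theme_minimal()
}

# ---------------------------------------------------------------------------

#' Model-based ancestry estimation (block EM for the admixture model)
#'
#' Maximizes the standard binomial admixture likelihood
#' \deqn{L = \sum_{il} g_{il}\ln(\sum_k q_{ik} f_{kl}) +
#'       (2-g_{il})\ln(\sum_k q_{ik}(1-f_{kl}))}
#' over ancestry proportions Q and cluster allele frequencies F by EM block
#' updates, skipping missing genotypes. The log-likelihood is non-decreasing
#' at every iteration; several random restarts are run and the best kept.
#'
#' @param g a [geno()] object
#' @param K number of ancestral clusters (>= 1)
#' @param seed RNG seed for initialization
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations per restart
#' @param n_restarts number of random restarts
#' @return object of class `geno_admixture` with `Q` (samples x K), `F`
#'   (K x loci), `loglik`, `loglik_trace` (best restart), `converged`, `K`
#' @export
admixture_em <- function(g, K, seed = 1, tol = 1e-6, max_iter = 500,
                         n_restarts = 5) {
  check_that(K >= 1, "K must be >= 1")
  G <- g$G
  n <- nrow(G); L <- ncol(G)
  obs <- !is.na(G)
  Gm <- G; Gm[!obs] <- 0L
  G2m <- 2L - G; G2m[!obs] <- 0L
  Li <- rowSums(obs)
  p_glob <- colSums(Gm) / pmax(2 * colSums(obs), 1)
  clamp <- function(x, lo = 1e-6) pmin(pmax(x, lo), 1 - lo)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    Q <- matrix(rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    F_ <- clamp(matrix(rep(p_glob, each = K), K, L) +
                  matrix(runif(K * L, -0.1, 0.1), K, L))
    if (K == 1) { Q <- matrix(1, n, 1); F_ <- matrix(clamp(p_glob), 1, L) }
    ll_trace <- numeric(0)
    ll_old <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      H <- clamp(Q %*% F_, 1e-9)
      A <- Gm / H
      B <- G2m / (1 - H)
      ll <- sum(Gm * log(H) + G2m * log1p(-H))
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      Fnum <- F_ * (crossprod(Q, A))
      Fden <- Fnum + (1 - F_) * (crossprod(Q, B))
      Qnew <- Q * (A %*% t(F_) + B %*% t(1 - F_)) / (2 * pmax(Li, 1))
      Q <- Qnew / rowSums(Qnew)
      F_ <- clamp(Fnum / pmax(Fden, 1e-300))
    }
    if (is.null(best) || tail(ll_trace, 1) > best$loglik) {
      best <- list(Q = Q, F = F_, loglik = tail(ll_trace, 1),
                   loglik_trace = ll_trace, converged = converged)
    }
    if (K == 1) break
  }
  dimnames(best$Q) <- list(g$samples, paste0("Q", seq_len(K)))
  structure(c(best, list(K = K, samples = g$samples)),
            class = "geno_admixture")
}

#' @export
print.geno_admixture <- function(x, ...) {
  cat("<geno_admixture> K = ", x$K, ", ", nrow(x$Q), " samples, loglik = ",
      sprintf("%.2f", x$loglik),
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.geno_admixture <- function(x, ...) {
  as_tibble(x$Q, rownames = "sample") |>
    pivot_longer(-"sample", names_to = "cluster", values_to = "proportion")
}

#' @export
glance.geno_admixture <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, n_iter = length(x$loglik_trace),
         converged = x$converged)
}

#' Stacked ancestry bar plot
#' @param object a `geno_admixture`
#' @param order_by optional vector to order samples by (e.g. ecoregion)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.geno_admixture <- function(object, order_by = NULL, ...) {
  df <- tidy(object)
  lev <- if (is.null(order_by)) rownames(object$Q) else
    rownames(object$Q)[order(order_by)]
  df$sample <- factor(df$sample, levels = lev)
  ggplot(df, aes(.data$sample, .data$proportion, fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    labs(x = NULL, y = "ancestry proportion", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Cross-validation error of the admixture model over a range of K
#'
#' Masks 1/`folds` of the non-missing genotypes per fold, refits the model
#' on the remainder, and scores the mean squared prediction error of the
#' masked dosages against their fitted expectation `2 * Q F`.
#'
#' @param g a [geno()] object
#' @param K_values integer vector of K to evaluate
#' @param folds number of cross-validation folds
#' @param seed RNG seed (masking and initialization)
#' @param ... passed to [admixture_em()] (e.g. `n_restarts`, `max_iter`)
#' @return tibble (K, cv_error)
#' @export
admixture_cv_error <- function(g, K_values, folds = 5, seed = 1, ...) {
  check_that(all(K_values >= 1) && all(K_values < n_samples(g)),
             "K must be in [1, n_samples)")
  obs_idx <- which(!is.na(g$G))
  check_that(length(obs_idx) >= folds, "not enough genotypes to mask")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(obs_idx)))
  out <- lapply(K_values, function(K) {
    errs <- vapply(seq_len(folds), function(f) {
      mask <- obs_idx[fold_of == f]
      gm <- g
      gm$G[mask] <- NA_integer_
      fit <- admixture_em(gm, K, seed = seed + f, ...)
      pred <- 2 * (fit$Q %*% fit$F)
      mean((g$G[mask] - pred[mask])^2)
    }, numeric(1))
    tibble(K = K, cv_error = mean(errs))
  })
  bind_rows(out)
}

# ---------------------------------------------------------------------------

#' Cluster discovery on PC scores by k-means and BIC
#'
#' Runs multi-restart k-means on retained principal-component scores for
#' k = 1..`k_max` and scores each solution with
#' `BIC(k) = n log(WSS_k / n) + k log(n)`; the best k minimizes BIC.
#'
#' @param scores a `geno_pca` or a numeric score matrix (samples x axes)
#' @param k_max largest number of clusters to try (< number of samples)
#' @param n_pcs number of leading axes to use (default: all available)
#' @param seed RNG seed
#' @param nstart k-means restarts
#' @return list with `best_k`, `assignments` (integer vector for best k)
#'   and `bic` (tibble k, wss, bic)
#' @export
find_clusters <- function(scores, k_max, n_pcs = NULL, seed = 1, nstart = 10) {
  S <- if (inherits(scores, "geno_pca")) scores$scores else as.matrix(scores)
  n <- nrow(S)
  check_that(k_max < n, "k_max must be smaller than the number of samples")
  n_pcs <- min(n_pcs %||% ncol(S), ncol(S))
  S <- S[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k) {
    if (k == 1) {
      wss <- sum(sweep(S, 2, colMeans(S))^2)
      list(cluster = rep(1L, n), wss = wss)
    } else {
      km <- kmeans(S, centers = k, nstart = nstart, iter.max = 50)
      list(cluster = km$cluster, wss = km$tot.withinss)
    }
  })
  bic <- tibble(
    k = seq_len(k_max),
    wss = map_dbl(fits, "wss"),
    bic = n * log(map_dbl(fits, "wss") / n) + seq_len(k_max) * log(n))
  best_k <- bic$k[which.min(bic$bic)]
  list(best_k = best_k, assignments = fits[[best_k]]$cluster, bic = bic)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' PCA on the genotype matrix retaining the fewest axes that reach
#' `var_retained` of total variance, followed by linear discriminant
#' analysis on the retained scores. Discriminant allele loadings are
#' back-rotated to locus space through the retained-PC rotation, giving the
#' "loading profile" used to spot aggregated genomic signal.
#'
#' @param g a [geno()] object
#' @param groups factor-like cluster assignment per sample (>= 2 clusters,
#'   each with >= 2 members)
#' @param var_retained fraction of PCA variance to retain
#' @return object of class `geno_dapc` with `n_pcs`, `var_actual`,
#'   `scores` (discriminant scores), `loadings` (loci x axes, locus space),
#'   `assignments`, `posterior`, `reassignment` (proportion of samples
#'   whose LDA posterior matches their given group)
#' @export
dapc_genotypes <- function(g, groups, var_retained = 0.80) {
  groups <- as.factor(groups)
  check_that(nlevels(droplevels(groups)) >= 2, "need at least 2 clusters")
  check_that(all(table(groups) >= 2), "every cluster needs >= 2 members")
  pc <- pca_genotypes(g)
  cum <- cumsum(pc$eigenvalues) / pc$var_total
  n_pcs <- which(cum >= var_retained)[1] %||% length(cum)
  n_pcs <- min(n_pcs, ncol(pc$scores), nrow(pc$scores) - nlevels(groups))
  n_pcs <- max(n_pcs, 2)
  S <- pc$scores[, seq_len(n_pcs), drop = FALSE]
  fit <- tryCatch(
    MASS::lda(S, grouping = groups),
    error = function(e) {
      warn("within-cluster scatter singular; ridge jitter applied")
      MASS::lda(S + matrix(rnorm(length(S), 0, 1e-8), nrow(S)),
                grouping = groups)
    })
  pred <- stats::predict(fit, S)
  load_loci <- pc$loadings[, seq_len(n_pcs), drop = FALSE] %*% fit$scaling
  structure(list(
    n_pcs = n_pcs, var_actual = cum[n_pcs],
    scores = pred$x, loadings = load_loci, loci = g$loci,
    assignments = groups, posterior = pred$posterior,
    predicted = pred$class,
    reassignment = mean(pred$class == groups)), class = "geno_dapc")
}

#' @export
print.geno_dapc <- function(x, ...) {
  cat("<geno_dapc> ", x$n_pcs, " PCs retained (",
      sprintf("%.1f%%", 100 * x$var_actual), " variance), ",
      nlevels(x$assignments), " clusters, reassignment ",
      sprintf("%.1f%%", 100 * x$reassignment), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.geno_dapc <- function(x, ...) {
  as_tibble(x$scores) |>
    mutate(sample = rownames(x$scores), group = x$assignments,
           predicted = x$predicted, .before = 1)
}

#' @export
glance.geno_dapc <- function(x, ...) {
  tibble(n_pcs = x$n_pcs, var_retained = x$var_actual,
         n_clusters = nlevels(x$assignments), reassignment = x$reassignment)
}

#' Squared-loading profile along the genome with windowed aggregation
#'
#' Orders per-locus squared loadings of one axis by genomic coordinate and
#' sums them in fixed-width windows — the "allele loading profile" used to
#' flag aggregated signal (inversions, sex-linked blocks). With unit-norm
#' loadings the window sums of one axis total 1.
#'
#' @param x a `geno_pca` or `geno_dapc`
#' @param axis which axis to profile
#' @param window_bp window width in bp
#' @return list of class `loading_profile`: `per_locus` tibble
#'   (chrom, pos, id, sq_loading) and `windows` tibble
#'   (chrom, win_start, win_end, n_snps, sum_sq)
#' @export
loading_profile <- function(x, axis = 1, window_bp = 1e6) {
  check_that(axis <= ncol(x$loadings), "axis not available")
  per_locus <- tibble(chrom = x$loci$chrom, pos = x$loci$pos,
                      id = x$loci$id,
                      sq_loading = x$loadings[, axis]^2)
  windows <- per_locus |>
    mutate(win = floor((.data$pos - 1) / window_bp)) |>
    group_by(.data$chrom, .data$win) |>
    summarise(n_snps = n(), sum_sq = sum(.data$sq_loading), .groups = "drop") |>
    mutate(win_start = .data$win * window_bp + 1,
           win_end = (.data$win + 1) * window_bp) |>
    select("chrom", "win_start", "win_end", "n_snps", "sum_sq")
  structure(list(per_locus = per_locus, windows = windows,
                 axis = axis, window_bp = window_bp),
            class = "loading_profile")
}

#' Manhattan-style plot of a loading profile
#' @param object a `loading_profile`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.loading_profile <- function(object, ...) {
  ggplot(object$per_locus, aes(.data$pos / 1e6, .data$sq_loading)) +
    geom_point(size = 0.4, alpha = 0.6) +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = "squared loading") +
    theme_minimal()
}
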