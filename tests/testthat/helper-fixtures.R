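# small deterministic fixtures shared across test files

make_geno <- function(G, chrom = "chr1", pos = NULL, samples = NULL, ...) {
  G <- as.matrix(G)
  L <- ncol(G)
  pos <- pos %||% seq_len(L)
  chrom <- rep_len(chrom, L)
  geno(G,
       tibble::tibble(chrom = chrom, pos = pos,
                      id = paste0(chrom, ":", pos),
                      ref = "A", alt = "C", ...),
       samples = samples %||% sprintf("s%02d", seq_len(nrow(G))))
}

random_geno <- function(n = 30, L = 100, miss = 0.05, seed = 42,
                        chrom = "chr1", pos = NULL) {
  set.seed(seed)
  p <- runif(L, 0.05, 0.95)
  G <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  if (miss > 0) G[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  make_geno(G, chrom = chrom, pos = pos %||% sort(sample.int(1e6, L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
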