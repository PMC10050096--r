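# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the implementation they check.

# per-site scan: focal samples identical and no reference carries that class
oracle_distinguishing <- function(geno, focal_idx, ref_idx) {
  vapply(seq_len(nrow(geno)), function(i) {
    f <- geno[i, focal_idx]
    r <- geno[i, ref_idx]
    if (any(is.na(f)) || any(is.na(r))) return(FALSE)
    all(f == f[1]) && !any(r == f[1])
  }, TRUE)
}

# walk each chromosome's sorted sites once: het sites emit singletons and
# close any open homozygous run; hom sites extend the open run when within
# the merge gap, else start a new one
oracle_classify <- function(sites, merge_gap = 1000, segmental_span = 10000) {
  events <- list()
  for (ch in unique(sites$chrom)) {
    sub <- sites[sites$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    open <- NULL
    for (i in seq_len(nrow(sub))) {
      s <- sub[i, ]
      if (s$zygosity == "het") {
        if (!is.null(open)) { events[[length(events) + 1]] <- open; open <- NULL }
        events[[length(events) + 1]] <-
          list(kind = "point_mutation_gain_het", chrom = ch, positions = s$pos)
      } else {
        if (!is.null(open) && s$pos - max(open$positions) <= merge_gap) {
          open$positions <- c(open$positions, s$pos)
        } else {
          if (!is.null(open)) events[[length(events) + 1]] <- open
          open <- list(kind = "loh", chrom = ch, positions = s$pos)
        }
      }
    }
    if (!is.null(open)) events[[length(events) + 1]] <- open
  }
  do.call(rbind, lapply(events, function(e) {
    span <- max(e$positions) - min(e$positions) + 1
    kind <- if (e$kind == "point_mutation_gain_het") e$kind else
      if (span <= segmental_span) "gene_conversion_loh" else "segmental_loh"
    data.frame(kind = kind, chrom = e$chrom,
               start = min(e$positions) - 1L, end = max(e$positions),
               n_sites = length(e$positions), stringsAsFactors = FALSE)
  }))
}

# two-sided Fisher p by full enumeration of the hypergeometric support,
# using binomial coefficients only
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# PCA oracle: eigendecomposition of the covariance matrix
oracle_pca <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  e <- eigen(stats::cov(x), symmetric = TRUE)
  list(scores = xc %*% e$vectors,
       loadings = e$vectors,
       explained = e$values / sum(e$values))
}

# build a small genotype matrix from an integer matrix of 0/1/2/NA
toy_gm <- function(geno, chrom = "chr1", pos = NULL, depth = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("S", seq_len(ncol(geno)))
  sites <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                      ref = rep("A", n), alt = rep("G", n),
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, geno, depth, colnames(geno))
}
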