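IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

iupac_code <- function(a, b) {
  key <- paste0(pmin(a, b), pmax(a, b))
  code <- IUPAC_PAIR[key]
  if (any(is.na(code))) stop("not a heterozygous base pair: ", key[is.na(code)][1])
  unname(code)
}

#' Convert a genotype matrix to an IUPAC-coded alignment
#'
#' One aligned sequence per sample: homozygous-reference sites become the
#' reference base, homozygous-alternate the alternate base, and heterozygous
#' sites the two-base IUPAC ambiguity code (R, Y, S, W, K, M) — the diploid-
#' aware encoding used for genotype-model tree inference. Sites with a
#' missing call in any sample are dropped (and counted), so the alignment
#' has no missing symbols.
#'
#' @param gm a [genotype_matrix()] of biallelic SNPs.
#' @param path optional FASTA output path (written via Biostrings).
#' @return list of class `iupac_alignment`: `samples`, `seqs` (named
#'   character vector of equal-length sequences), `site_map`
#'   (data.frame chrom, pos of retained sites) and `n_dropped_missing`.
#' @export
to_iupac_fasta <- function(gm, path = NULL) {
  if (!all(gm$sites$ref %in% BASES & gm$sites$alt %in% BASES))
    stop("non-SNP alleles in matrix")
  complete <- !apply(is.na(gm$geno), 1, any)
  n_dropped <- sum(!complete)
  sub <- subset_sites(gm, complete)
  n <- nrow(sub$sites)
  het_code <- if (n) iupac_code(sub$sites$ref, sub$sites$alt) else character()
  seqs <- vapply(seq_along(sub$samples), function(j) {
    g <- sub$geno[, j]
    chars <- ifelse(g == 0L, sub$sites$ref,
                    ifelse(g == 2L, sub$sites$alt, het_code))
    paste(chars, collapse = "")
  }, "")
  names(seqs) <- sub$samples
  aln <- structure(list(samples = sub$samples, seqs = seqs,
                        site_map = sub$sites[, c("chrom", "pos")],
                        n_dropped_missing = n_dropped),
                   class = "iupac_alignment")
  if (!is.null(path))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  aln
}

#' Ambiguity-aware pairwise divergence matrix
#'
#' Mean per-site mismatch between every pair of samples, scoring shared
#' alleles fractionally: identical symbols 0; a heterozygote versus a
#' homozygote for one of its two alleles (or two heterozygotes sharing one
#' allele) 0.5; no shared allele 1. A companion sanity check for externally
#' inferred trees, not a substitute for model-based inference.
#'
#' @param aln an `iupac_alignment` from [to_iupac_fasta()].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_divergence <- function(aln) {
  n <- length(aln$samples)
  if (n < 2) stop("need >= 2 samples")
  split_chars <- lapply(aln$seqs, function(s) strsplit(s, "")[[1]])
  L <- unique(lengths(split_chars))
  if (length(L) != 1) stop("sequence length mismatch")
  allele_sets <- list(A = "A", C = "C", G = "G", T = "T",
                      M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                      S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"))
  ## per-symbol-pair mismatch score, precomputed
  syms <- names(allele_sets)
  score <- matrix(0, length(syms), length(syms), dimnames = list(syms, syms))
  for (a in syms) for (b in syms) {
    sa <- allele_sets[[a]]; sb <- allele_sets[[b]]
    score[a, b] <- if (identical(sa, sb)) 0 else
      if (length(intersect(sa, sb))) 0.5 else 1
  }
  d <- matrix(0, n, n, dimnames = list(aln$samples, aln$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- score[cbind(split_chars[[i]], split_chars[[j]])]
    d[i, j] <- d[j, i] <- mean(s)
  }
  d
}
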