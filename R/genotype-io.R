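#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (via vcfR), keeps biallelic SNP records only, and returns a
#' [genotype_matrix()]. Multi-allelic and indel records are excluded and
#' counted in the attached log. Genotypes are collapsed to classes
#' (0 hom-ref / 1 het / 2 hom-alt / NA missing); `DP` is read when present,
#' otherwise depths are recorded as missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples optional character vector restricting (and ordering) the
#'   sample columns; unknown names are an error.
#' @return A [genotype_matrix()] with attribute `log`, a list of exclusion
#'   counts (`n_multiallelic`, `n_indel`, `n_records`).
#' @export
read_vcf_matrix <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_records <- nrow(fix)
  if (n_records == 0) {
    gm <- genotype_matrix(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(integer(), 0, length(colnames(v@gt)) - 1),
      samples = colnames(v@gt)[-1])
    attr(gm, "log") <- list(n_records = 0L, n_multiallelic = 0L, n_indel = 0L)
    return(gm)
  }
  is_multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% BASES & fix$ALT %in% BASES
  keep <- !is_multi & is_snp
  log <- list(n_records = n_records,
              n_multiallelic = sum(is_multi),
              n_indel = sum(!is_multi & !is_snp))

  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- all_samples
  unknown <- setdiff(samples, all_samples)
  if (length(unknown))
    stop("unknown sample(s) in subset: ", paste(unknown, collapse = ", "))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, samples, drop = FALSE]
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt))
  gt_norm <- gsub("\\|", "/", gt)
  geno[gt_norm %in% c("0/0")] <- 0L
  geno[gt_norm %in% c("0/1", "1/0")] <- 1L
  geno[gt_norm %in% c("1/1")] <- 2L

  fmt <- strsplit(v@gt[1, 1], ":")[[1]]
  if ("DP" %in% fmt) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    dp <- dp[keep, samples, drop = FALSE]
    storage.mode(dp) <- "integer"
  } else {
    dp <- matrix(NA_integer_, nrow(gt), ncol(gt))
  }
  sites <- data.frame(chrom = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(sites, geno, dp, samples)
  attr(gm, "log") <- log
  gm
}

#' Hard-filter a genotype matrix on missingness and depth
#'
#' Removes every site with at least one missing genotype call, and every
#' site at which any sample's read depth is greater than or equal to
#' `depth_multiplier` times the global median depth (the study's cutoff of
#' 80 at a median of 40 corresponds to the default multiplier 2). The
#' threshold is computed on the matrix *before* any removal.
#'
#' @param gm a [genotype_matrix()].
#' @param depth_multiplier positive multiplier of the global median depth.
#' @param drop_missing drop sites with any missing call (default TRUE).
#' @return The filtered [genotype_matrix()] with attribute `filter_log`:
#'   `depth_threshold`, `n_removed_missing`, `n_removed_depth`, `n_in`,
#'   `n_out`.
#' @export
hard_filter <- function(gm, depth_multiplier = 2, drop_missing = TRUE) {
  stopifnot(depth_multiplier > 0)
  n_in <- nrow(gm$sites)
  med <- stats::median(gm$depth, na.rm = TRUE)
  threshold <- depth_multiplier * med
  miss <- if (drop_missing) apply(is.na(gm$geno), 1, any) else
    rep(FALSE, n_in)
  over <- if (all(is.na(gm$depth))) rep(FALSE, n_in) else
    apply(gm$depth >= threshold, 1, any) %in% TRUE
  keep <- !miss & !over
  out <- subset_sites(gm, keep)
  if (n_in > 0 && sum(keep) == 0)
    warning("all sites removed by hard_filter")
  attr(out, "filter_log") <- list(depth_threshold = threshold,
                                  n_removed_missing = sum(miss),
                                  n_removed_depth = sum(over & !miss),
                                  n_in = n_in, n_out = sum(keep))
  out
}

#' Normalize read depths per sample
#'
#' Divides each sample's depth at each SNP by that sample's median depth
#' across all retained SNPs, so that every sample's median normalized depth
#' is 1 and library-loading differences cancel. Per-contig means of the
#' normalized values are returned alongside.
#'
#' @param gm a filtered [genotype_matrix()] with depths.
#' @return list with `norm` (numeric matrix, sites x samples),
#'   `sample_medians` (the per-sample raw medians), and `contig_means`
#'   (data.frame: chrom x sample mean normalized depth).
#' @export
normalize_depth <- function(gm) {
  if (all(is.na(gm$depth))) stop("matrix has no depths")
  meds <- apply(gm$depth, 2, stats::median, na.rm = TRUE)
  zero <- which(meds == 0 | is.na(meds))
  if (length(zero))
    stop("sample(s) with all-zero depth: ",
         paste(gm$samples[zero], collapse = ", "))
  norm <- sweep(gm$depth, 2, meds, "/")
  colnames(norm) <- gm$samples
  cm <- stats::aggregate(norm, by = list(chrom = gm$sites$chrom), FUN = mean,
                         na.rm = TRUE)
  list(norm = norm, sample_medians = meds, contig_means = cm)
}

#' Export a genotype matrix to TSV
#'
#' Writes chrom, pos, ref, alt plus per-sample GT class and DP columns.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(gm, path) {
  df <- gm$sites
  gt <- as.data.frame(gm$geno)
  names(gt) <- paste0("GT_", gm$samples)
  dp <- as.data.frame(gm$depth)
  names(dp) <- paste0("DP_", gm$samples)
  utils::write.table(cbind(df, gt, dp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
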