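#' Windowed relative heterozygosity along chromosomes
#'
#' Tiles each chromosome into fixed-width windows and reports, per window,
#' the fraction of informative sites — sites heterozygous in the reference
#' sister clade — that are also heterozygous in all focal samples. Inside a
#' copy-neutral LOH the value collapses to ~0; outside it stays ~1. Windows
#' with no informative sites are reported with `rel_het = NA` (undefined,
#' not zero: such windows are homozygous in the references).
#'
#' @param gm a [genotype_matrix()].
#' @param roles a [sample_roles()] with at least one reference_sister and
#'   one focal sample.
#' @param window window width in bp (default 250000).
#' @param chrom_lengths optional named vector; defaults to the last SNP
#'   position per chromosome rounded up to a whole window.
#' @param sister_mode "all" (default; informative = het in every sister
#'   sample) or "any".
#' @return data.frame(chrom, start, end, n_sites, rel_het, partial), windows
#'   0-based half-open, tiling each chromosome without overlap.
#' @export
relative_heterozygosity <- function(gm, roles, window = 250000,
                                    chrom_lengths = NULL,
                                    sister_mode = c("all", "any")) {
  sister_mode <- match.arg(sister_mode)
  check_roles(gm, roles)
  if (window <= 0) stop("window must be positive")
  if (!length(roles$reference_sister)) stop("no reference_sister samples")
  sg <- gm$geno[, roles$reference_sister, drop = FALSE]
  het_n <- rowSums(sg == 1L, na.rm = TRUE)
  informative <- if (sister_mode == "all")
    het_n == length(roles$reference_sister) & !apply(is.na(sg), 1, any)
  else het_n >= 1
  fg <- gm$geno[, roles$focal, drop = FALSE]
  focal_het <- rowSums(fg == 1L, na.rm = TRUE) == length(roles$focal)

  tile_windows(gm$sites, window, chrom_lengths, function(in_win) {
    info <- in_win & informative
    n <- sum(info)
    c(n_sites = n,
      rel_het = if (n == 0) NA_real_ else sum(info & focal_het) / n)
  })
}

#' Windowed mean normalized depth per sample group
#'
#' Per window, the arithmetic mean of normalized depths over the retained
#' SNPs, separately for the focal group and the reference-sister group
#' (copy-neutral LOH: focal tracks reference at ~1; deletion: focal drops
#' to ~0.5).
#'
#' @param norm normalized depth matrix from [normalize_depth()].
#' @param gm the matching [genotype_matrix()].
#' @param roles a [sample_roles()].
#' @inheritParams relative_heterozygosity
#' @return data.frame(chrom, start, end, n_sites, depth_focal,
#'   depth_reference, partial).
#' @export
windowed_depth <- function(norm, gm, roles, window = 250000,
                           chrom_lengths = NULL) {
  check_roles(gm, roles)
  if (window <= 0) stop("window must be positive")
  ref_group <- if (length(roles$reference_sister)) roles$reference_sister else
    roles$reference
  tile_windows(gm$sites, window, chrom_lengths, function(in_win) {
    n <- sum(in_win)
    c(n_sites = n,
      depth_focal = if (n == 0) NA_real_ else
        mean(norm[in_win, roles$focal], na.rm = TRUE),
      depth_reference = if (n == 0) NA_real_ else
        mean(norm[in_win, ref_group], na.rm = TRUE))
  })
}

# tile chromosomes into [k*w, (k+1)*w) windows and apply `stat_fun` to the
# logical site-inclusion vector of each window
tile_windows <- function(sites, window, chrom_lengths, stat_fun) {
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      ceiling(max(sites$pos[sites$chrom == ch]) / window) * window, 0)
  }
  rows <- list()
  for (ch in chroms) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window)
    for (s in starts) {
      e <- min(s + window, len)
      in_win <- sites$chrom == ch & sites$pos - 1 >= s & sites$pos - 1 < e
      st <- stat_fun(in_win)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = s, end = e, t(st),
        partial = (e - s) < window, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
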