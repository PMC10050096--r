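#' Read a BED file as 0-based half-open intervals
#' @param path BED path (first three columns chrom, start, end).
#' @return data.frame(chrom, start, end).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

intervals_to_granges <- function(df, chrom_lengths = NULL, what = "interval") {
  levels <- unique(df$chrom)
  if (!is.null(chrom_lengths)) {
    bad <- which(df$end > chrom_lengths[df$chrom] | df$start < 0)
    if (length(bad))
      stop(what, " beyond chromosome end: record ", bad[1], " (",
           df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")")
    levels <- names(chrom_lengths)
  }
  GenomicRanges::GRanges(factor(df$chrom, levels = levels),
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

merged_bp_per_chrom <- function(gr, chroms) {
  red <- GenomicRanges::reduce(gr)
  bp <- tapply(BiocGenerics::width(red),
               as.character(GenomicRanges::seqnames(red)), sum)
  out <- stats::setNames(rep(0, length(chroms)), chroms)
  out[names(bp)] <- bp
  out
}

#' TE and exon proportions per chromosome with element-level exclusion
#'
#' Drops every transposable-element interval that overlaps any exon interval
#' and every exon interval that overlaps any TE (whole-element mutual
#' exclusion), merges each surviving set, and divides occupied base pairs by
#' the ungapped chromosome length. `mode = "base"` instead subtracts the
#' overlapping bases only.
#'
#' @param ungapped_lengths named vector of ungapped chromosome lengths (bp).
#' @param te,exon data.frames(chrom, start, end), 0-based half-open.
#' @param mode "element" (default) or "base" overlap exclusion.
#' @param chrom_lengths optional full lengths used for bounds checks
#'   (default `ungapped_lengths`).
#' @return data.frame(chrom, proportion_te, proportion_exon).
#' @export
feature_proportions <- function(ungapped_lengths, te, exon,
                                mode = c("element", "base"),
                                chrom_lengths = ungapped_lengths) {
  mode <- match.arg(mode)
  chroms <- names(ungapped_lengths)
  gr_te <- intervals_to_granges(te, chrom_lengths, "TE interval")
  gr_ex <- intervals_to_granges(exon, chrom_lengths, "exon interval")
  if (mode == "element") {
    ov <- GenomicRanges::findOverlaps(gr_te, gr_ex)
    keep_te <- setdiff(seq_along(gr_te), S4Vectors::queryHits(ov))
    keep_ex <- setdiff(seq_along(gr_ex), S4Vectors::subjectHits(ov))
    gr_te <- gr_te[keep_te]
    gr_ex <- gr_ex[keep_ex]
  } else {
    gr_te2 <- GenomicRanges::setdiff(GenomicRanges::reduce(gr_te),
                                     GenomicRanges::reduce(gr_ex))
    gr_ex <- GenomicRanges::setdiff(GenomicRanges::reduce(gr_ex),
                                    GenomicRanges::reduce(gr_te))
    gr_te <- gr_te2
  }
  data.frame(chrom = chroms,
             proportion_te = merged_bp_per_chrom(gr_te, chroms) /
               ungapped_lengths,
             proportion_exon = merged_bp_per_chrom(gr_ex, chroms) /
               ungapped_lengths,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Structural-variant proportion per chromosome
#'
#' Keeps intervals of length >= `min_len` bp (SVs defined as indels of 50 bp
#' or more), merges overlaps, and divides by the ungapped length.
#'
#' @param sv data.frame(chrom, start, end), 0-based half-open.
#' @param ungapped_lengths named vector of ungapped lengths (bp).
#' @param min_len minimum SV length in bp (default 50).
#' @param chrom_lengths optional full lengths for bounds checks.
#' @return data.frame(chrom, proportion_sv).
#' @export
sv_proportion <- function(sv, ungapped_lengths, min_len = 50,
                          chrom_lengths = ungapped_lengths) {
  chroms <- names(ungapped_lengths)
  sv <- sv[sv$end - sv$start >= min_len, , drop = FALSE]
  if (nrow(sv) == 0)
    return(data.frame(chrom = chroms, proportion_sv = 0,
                      row.names = NULL, stringsAsFactors = FALSE))
  gr <- intervals_to_granges(sv, chrom_lengths, "SV interval")
  data.frame(chrom = chroms,
             proportion_sv = merged_bp_per_chrom(gr, chroms) /
               ungapped_lengths,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Contigs per megabase
#' @param contig_counts named vector of contig counts per chromosome.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @return data.frame(chrom, contigs_per_mbp).
#' @export
contigs_per_mbp <- function(contig_counts, chrom_lengths) {
  chroms <- names(chrom_lengths)
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  stopifnot(all(chroms %in% names(contig_counts)))
  data.frame(chrom = chroms,
             contigs_per_mbp = unname(contig_counts[chroms] /
                                        (chrom_lengths / 1e6)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ungapped chromosome lengths from a gaps BED
#' @param chrom_lengths named vector of full lengths (bp).
#' @param gaps data.frame(chrom, start, end) of assembly-gap (N) runs,
#'   0-based half-open; overlapping runs are merged before subtraction.
#' @return named vector of ungapped lengths.
#' @export
ungapped_lengths <- function(chrom_lengths, gaps = NULL) {
  if (is.null(gaps) || nrow(gaps) == 0) return(chrom_lengths)
  gr <- intervals_to_granges(gaps, chrom_lengths, "gap interval")
  gap_bp <- merged_bp_per_chrom(gr, names(chrom_lengths))
  chrom_lengths - gap_bp
}

#' Full per-chromosome feature profile
#'
#' Combines ungapped length, contig density, TE/exon proportions (after
#' element-level mutual exclusion) and SV proportion into one table — the
#' profile used to flag supergene-like chromosomes (fragmented assembly,
#' TE-rich, exon-poor, SV-rich).
#'
#' @inheritParams feature_proportions
#' @inheritParams sv_proportion
#' @inheritParams contigs_per_mbp
#' @param gaps optional gaps BED data.frame.
#' @return data.frame(chrom, ungapped_length, contig_count, contigs_per_mbp,
#'   proportion_te, proportion_exon, proportion_sv).
#' @export
chromosome_profile <- function(chrom_lengths, contig_counts, te, exon, sv,
                               gaps = NULL, min_len = 50) {
  ug <- ungapped_lengths(chrom_lengths, gaps)
  fp <- feature_proportions(ug, te, exon, chrom_lengths = chrom_lengths)
  sp <- sv_proportion(sv, ug, min_len = min_len,
                      chrom_lengths = chrom_lengths)
  cm <- contigs_per_mbp(contig_counts, chrom_lengths)
  data.frame(chrom = names(chrom_lengths),
             ungapped_length = unname(ug),
             contig_count = unname(contig_counts[names(chrom_lengths)]),
             contigs_per_mbp = cm$contigs_per_mbp,
             proportion_te = fp$proportion_te,
             proportion_exon = fp$proportion_exon,
             proportion_sv = sp$proportion_sv,
             row.names = NULL, stringsAsFactors = FALSE)
}
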