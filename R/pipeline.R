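#' Run the full lineage-inference pipeline
#'
#' Executes the genomic workflow end to end: read VCF, hard-filter,
#' normalize depths, find distinguishing sites, localize large segmental
#' LOH regions chromosome by chromosome and check their copy-number status,
#' classify the remaining sites into point mutations and gene-conversion
#' tracts, scan windowed relative heterozygosity and depth, and estimate
#' generations since lineage origin from the de novo count. A chromosome is
#' treated as a segmental-LOH region when its maximal focal-homozygous run
#' over sister-informative sites spans more than `segmental_span` bp with at
#' least `loh_min_sites` supporting sites; sites on such chromosomes are
#' excluded from the short-event classification, which mirrors treating the
#' chromosome-scale event separately from the scattered small mutations.
#' All stage outputs are written as TSVs under `out_dir` together with a
#' JSON manifest of parameters and input hashes.
#'
#' @param vcf path to the multi-sample VCF.
#' @param roles a [sample_roles()].
#' @param out_dir output directory (created if absent); NULL = write nothing.
#' @param params list of stage parameters; recognized entries (with
#'   defaults): `depth_multiplier` (2), `merge_gap` (1000), `segmental_span`
#'   (10000), `loh_min_sites` (10), `window` (250000), `neutral_band`,
#'   `deletion_band`, `mu` (3.5e-9), `genome_size_haploid` (224e6),
#'   `ploidy_factor` (2).
#' @param chrom_lengths optional named vector used for window tiling and
#'   LOH outer bounds.
#' @return list (the result bundle): `gm`, `filter_log`, `norm`, `sites`
#'   (distinguishing sites), `events` (short events plus one row per
#'   segmental region), `by_chrom`, `loh` (list of segmental regions with
#'   boundaries and copy-number status; empty when none), `windows_het`,
#'   `windows_depth`, `generations`, `params`.
#' @export
run_pipeline <- function(vcf, roles, out_dir = NULL, params = list(),
                         chrom_lengths = NULL) {
  p <- utils::modifyList(list(depth_multiplier = 2, merge_gap = 1000,
                              segmental_span = 10000, loh_min_sites = 10,
                              window = 250000,
                              neutral_band = c(0.85, 1.15),
                              deletion_band = c(0.35, 0.65),
                              mu = 3.5e-9, genome_size_haploid = 224e6,
                              ploidy_factor = 2), params)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  gm_raw <- stage("read_vcf", read_vcf_matrix(vcf))
  stage("roles", check_roles(gm_raw, roles))
  gm <- stage("hard_filter", hard_filter(gm_raw, p$depth_multiplier))
  nd <- stage("normalize_depth", normalize_depth(gm))
  sites <- stage("distinguishing_sites", find_distinguishing_sites(gm, roles))
  by_chrom <- summarize_by_chromosome(sites)

  ## chromosome-scale LOH scan: maximal focal-hom run per chromosome
  loh <- list()
  seg_events <- list()
  for (ch in unique(sites$chrom[sites$zygosity == "hom"])) {
    bounds <- tryCatch(
      locate_loh_boundaries(gm, roles, ch,
                            chrom_length = if (is.null(chrom_lengths))
                              NA else chrom_lengths[[ch]]),
      error = function(e) NULL)
    if (is.null(bounds) || bounds$span <= p$segmental_span ||
        bounds$n_sites < p$loh_min_sites) next
    cn <- stage("copy_neutral",
                check_copy_neutral(nd$norm, gm, roles, ch,
                                   bounds$inner_start - 1L, bounds$inner_end,
                                   p$neutral_band, p$deletion_band))
    loh[[length(loh) + 1]] <- c(bounds, list(chrom = ch, status = cn$status,
                                             depth_ratio = cn$ratio))
    seg_events[[length(seg_events) + 1]] <-
      data.frame(kind = "segmental_loh", chrom = ch,
                 start = bounds$inner_start - 1L, end = bounds$inner_end,
                 n_sites = bounds$n_sites, copy_number_status = cn$status,
                 stringsAsFactors = FALSE)
  }
  seg_chroms <- vapply(loh, `[[`, "", "chrom")
  short_sites <- sites[!(sites$chrom %in% seg_chroms), , drop = FALSE]
  events <- stage("classify_events",
                  classify_events(short_sites, p$merge_gap, p$segmental_span))
  events <- rbind(events, do.call(rbind, seg_events))
  events <- events[order(events$chrom, events$start), , drop = FALSE]
  rownames(events) <- NULL

  windows_het <- stage("relative_heterozygosity",
                       relative_heterozygosity(gm, roles, p$window,
                                               chrom_lengths))
  windows_depth <- stage("windowed_depth",
                         windowed_depth(nd$norm, gm, roles, p$window,
                                        chrom_lengths))
  n_de_novo <- sum(events$kind == "point_mutation_gain_het")
  generations <- estimate_generations(n_de_novo, p$mu,
                                      p$genome_size_haploid, p$ploidy_factor)
  bundle <- list(gm = gm, filter_log = attr(gm, "filter_log"), norm = nd,
                 sites = sites, events = events, by_chrom = by_chrom,
                 loh = loh, windows_het = windows_het,
                 windows_depth = windows_depth, generations = generations,
                 params = p)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, vcf)
  bundle
}

write_bundle <- function(bundle, out_dir, vcf) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_events_bed(bundle$events, file.path(out_dir, "events.bed.tsv"))
  tsv(bundle$sites, "distinguishing_sites.tsv")
  tsv(bundle$by_chrom, "sites_by_chromosome.tsv")
  tsv(bundle$windows_het, "windows_relative_heterozygosity.tsv")
  tsv(bundle$windows_depth, "windows_normalized_depth.tsv")
  manifest <- list(input_vcf = vcf,
                   input_md5 = unname(tools::md5sum(vcf)),
                   params = bundle$params,
                   filter_log = bundle$filter_log,
                   n_distinguishing_sites = nrow(bundle$sites),
                   n_events = nrow(bundle$events))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(write_report(bundle), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Render a human-readable pipeline report
#'
#' @param bundle result of [run_pipeline()].
#' @return character vector of report lines (also usable via `writeLines`).
#' @export
write_report <- function(bundle) {
  lines <- c("Clonal lineage inference report",
             "===============================",
             sprintf("Sites after hard filter: %d (removed %d missing, %d over-depth; threshold %.1f)",
                     bundle$filter_log$n_out,
                     bundle$filter_log$n_removed_missing,
                     bundle$filter_log$n_removed_depth,
                     bundle$filter_log$depth_threshold),
             sprintf("Distinguishing sites: %d", nrow(bundle$sites)),
             "Per-chromosome shares:")
  if (nrow(bundle$by_chrom))
    lines <- c(lines, sprintf("  %s: %d (%.1f%%)", bundle$by_chrom$chrom,
                              bundle$by_chrom$n, bundle$by_chrom$pct))
  n_ev <- nrow(bundle$events)
  lines <- c(lines,
             if (n_ev == 0) "Events: none" else
               sprintf("Events: %d (%d gain-of-het point mutations, %d gene-conversion LOH, %d segmental LOH)",
                       n_ev,
                       sum(bundle$events$kind == "point_mutation_gain_het"),
                       sum(bundle$events$kind == "gene_conversion_loh"),
                       sum(bundle$events$kind == "segmental_loh")))
  if (length(bundle$loh)) {
    for (l in bundle$loh)
      lines <- c(lines,
                 sprintf("Segmental LOH region: %s:%d-%d (inner span %.2f Mbp, outer %s-%s), depth ratio %.2f => %s",
                         l$chrom, l$inner_start, l$inner_end, l$span / 1e6,
                         l$outer_start,
                         ifelse(is.na(l$outer_end), "chr-end", l$outer_end),
                         l$depth_ratio, l$status))
  } else lines <- c(lines, "Segmental LOH regions: none detected")
  g <- bundle$generations
  lines <- c(lines,
             sprintf("Expected de novo SNPs per generation: %.3f", g$expected_per_generation),
             sprintf("Generations since lineage origin: %.2f (95%% LR interval %.2f-%.2f)",
                     g$generations_estimate, g$conf_low, g$conf_high),
             sprintf("Windows scanned: %d (rel. het defined in %d)",
                     nrow(bundle$windows_het),
                     sum(!is.na(bundle$windows_het$rel_het))))
  lines
}
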