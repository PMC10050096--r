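#' Find sites distinguishing the focal sub-lineage
#'
#' A site qualifies when every focal sample carries the same genotype class
#' and no reference sample carries that class; reference samples are allowed
#' to vary among themselves. Missing calls are expected to have been removed
#' by [hard_filter()]; a site with a missing call in any focal or reference
#' sample never qualifies.
#'
#' @param gm a [genotype_matrix()].
#' @param roles a [sample_roles()].
#' @return data.frame with one row per distinguishing site: `site` (row
#'   index into `gm$sites`), `chrom`, `pos`, `focal_geno` (0/1/2) and
#'   `zygosity` ("het" or "hom"), sorted by position within chromosome.
#' @export
find_distinguishing_sites <- function(gm, roles) {
  check_roles(gm, roles)
  if (length(roles$focal) == 0) stop("no focal samples")
  fg <- gm$geno[, roles$focal, drop = FALSE]
  rg <- gm$geno[, roles$reference, drop = FALSE]
  focal_same <- !apply(is.na(fg), 1, any) &
    apply(fg, 1, function(r) length(unique(r)) == 1)
  shared <- fg[, 1]
  ref_all_differ <- !apply(is.na(rg), 1, any) &
    rowSums(rg == shared, na.rm = TRUE) == 0
  qual <- which(focal_same & ref_all_differ)
  out <- data.frame(site = qual,
                    chrom = gm$sites$chrom[qual],
                    pos = gm$sites$pos[qual],
                    focal_geno = shared[qual],
                    stringsAsFactors = FALSE)
  out$zygosity <- ifelse(out$focal_geno == 1L, "het", "hom")
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Classify distinguishing sites into mutation events
#'
#' Focal-heterozygous sites (gains of heterozygosity) each become one
#' `point_mutation_gain_het` event — a de novo point mutation. Focal-
#' homozygous sites (losses of heterozygosity) on one chromosome are merged
#' when consecutive sites lie within `merge_gap` bp of each other; a merged
#' run spanning at most `segmental_span` bp is called `gene_conversion_loh`
#' (a short tract), anything larger `segmental_loh` (a crossover-scale
#' event). Intervals are 0-based half-open over the supporting sites; a
#' single-site event at 1-based position p gets the interval [p-1, p).
#'
#' @param sites output of [find_distinguishing_sites()], position-sorted.
#' @param merge_gap maximum inter-site distance (bp) merged into one LOH
#'   event (default 1000, the sub-kilobase conversion-tract scale).
#' @param segmental_span span (bp) above which a merged LOH run is called
#'   segmental rather than gene conversion (default 10000).
#' @return data.frame of events: `kind`, `chrom`, `start`, `end`,
#'   `n_sites`, `copy_number_status` (initialized "untested"). The summed
#'   `n_sites` equals `nrow(sites)`.
#' @export
classify_events <- function(sites, merge_gap = 1000, segmental_span = 10000) {
  empty <- data.frame(kind = character(), chrom = character(),
                      start = integer(), end = integer(), n_sites = integer(),
                      copy_number_status = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0) return(empty)
  if (is.unsorted(order(sites$chrom, sites$pos)) ||
      any(unlist(tapply(sites$pos, sites$chrom, is.unsorted))))
    stop("sites must be sorted by (chromosome, position)")
  evs <- list()
  het <- sites[sites$zygosity == "het", , drop = FALSE]
  if (nrow(het))
    evs[[1]] <- data.frame(kind = "point_mutation_gain_het",
                           chrom = het$chrom, start = het$pos - 1L,
                           end = het$pos, n_sites = 1L,
                           stringsAsFactors = FALSE)
  hom <- sites[sites$zygosity == "hom", , drop = FALSE]
  if (nrow(hom)) {
    for (ch in unique(hom$chrom)) {
      sub <- sites[sites$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$pos), , drop = FALSE]
      hom_at <- which(sub$zygosity == "hom")
      p <- sub$pos[hom_at]
      ## new run when the gap is too large or a het site intervenes
      ## (a gain-of-het point mutation breaks a homozygous run, keeping
      ## events on a chromosome disjoint)
      brk <- diff(p) > merge_gap | diff(hom_at) > 1L
      grp <- cumsum(c(1L, as.integer(brk)))
      for (g in unique(grp)) {
        pg <- p[grp == g]
        span <- max(pg) - min(pg) + 1L
        evs[[length(evs) + 1]] <- data.frame(
          kind = if (span <= segmental_span) "gene_conversion_loh" else
            "segmental_loh",
          chrom = ch, start = min(pg) - 1L, end = max(pg),
          n_sites = length(pg), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, evs)
  out$copy_number_status <- "untested"
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localize the boundaries of a large LOH region
#'
#' Works over the informative sites of a chromosome — sites heterozygous in
#' all reference-sister samples — and finds the maximal run of consecutive
#' informative sites at which every focal sample is homozygous. The inner
#' bound is the first-to-last homozygous informative site; the outer bound
#' extends to the adjacent flanking heterozygous informative sites (or the
#' chromosome ends), so the true transition lies between inner and outer.
#'
#' @param gm a [genotype_matrix()].
#' @param roles a [sample_roles()] with at least one reference_sister.
#' @param chromosome chromosome name.
#' @param chrom_length optional chromosome length (bp) for outer bounds when
#'   the run touches a chromosome end.
#' @return list with 1-based `inner_start`, `inner_end`, `outer_start`,
#'   `outer_end`, `n_sites` (informative homozygous sites in the run) and
#'   `span` (= inner_end - inner_start + 1); NULL when no focal-homozygous
#'   informative run exists.
#' @export
locate_loh_boundaries <- function(gm, roles, chromosome, chrom_length = NA) {
  check_roles(gm, roles)
  sisters <- if (length(roles$reference_sister)) roles$reference_sister else
    roles$reference
  on_chr <- which(gm$sites$chrom == chromosome)
  if (!length(on_chr)) stop("chromosome not present: ", chromosome)
  sg <- gm$geno[on_chr, sisters, drop = FALSE]
  informative <- rowSums(sg == 1L, na.rm = TRUE) == length(sisters) &
    !apply(is.na(sg), 1, any)
  info_idx <- on_chr[informative]
  if (!length(info_idx)) stop("no informative (sister-het) sites on ", chromosome)
  fg <- gm$geno[info_idx, roles$focal, drop = FALSE]
  hom <- rowSums(fg != 1L & !is.na(fg)) == length(roles$focal)
  if (!any(hom)) return(NULL)
  r <- rle(hom)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- which(r$values)[which.max(r$lengths[r$values])]
  i0 <- starts[best]; i1 <- ends[best]
  pos <- gm$sites$pos[info_idx]
  inner_start <- pos[i0]; inner_end <- pos[i1]
  outer_start <- if (i0 > 1) pos[i0 - 1] + 1L else 1L
  outer_end <- if (i1 < length(pos)) pos[i1 + 1] - 1L else
    if (!is.na(chrom_length)) as.integer(chrom_length) else NA_integer_
  list(inner_start = inner_start, inner_end = inner_end,
       outer_start = outer_start, outer_end = outer_end,
       n_sites = i1 - i0 + 1L, span = inner_end - inner_start + 1L)
}

#' Classify the copy-number status of an interval from normalized depth
#'
#' Compares mean focal to mean reference normalized depth over the retained
#' SNPs inside an interval. A ratio near 1 marks a copy-neutral region (two
#' chromosome copies retained, as in crossover-derived LOH); a ratio near
#' 0.5 marks a hemizygous deletion; anything else is flagged untested.
#'
#' @param norm normalized depth matrix from [normalize_depth()].
#' @param gm the [genotype_matrix()] the depths belong to.
#' @param roles a [sample_roles()].
#' @param chromosome,start,end interval (0-based half-open).
#' @param neutral_band,deletion_band inclusive ratio bands (defaults
#'   0.85-1.15 and 0.35-0.65).
#' @return list with `ratio`, `status` in {"copy_neutral", "deletion_like",
#'   "untested"}, and the group means.
#' @export
check_copy_neutral <- function(norm, gm, roles, chromosome, start, end,
                               neutral_band = c(0.85, 1.15),
                               deletion_band = c(0.35, 0.65)) {
  check_roles(gm, roles)
  inside <- gm$sites$chrom == chromosome &
    gm$sites$pos - 1L >= start & gm$sites$pos - 1L < end
  if (!any(inside)) stop("no retained SNPs in interval")
  mf <- mean(norm[inside, roles$focal], na.rm = TRUE)
  mr <- mean(norm[inside, roles$reference], na.rm = TRUE)
  ratio <- mf / mr
  status <- if (ratio >= neutral_band[1] && ratio <= neutral_band[2])
    "copy_neutral" else if (ratio >= deletion_band[1] && ratio <= deletion_band[2])
      "deletion_like" else "untested"
  list(ratio = ratio, status = status, focal_mean = mf, reference_mean = mr)
}

#' Estimate generations since lineage origin from de novo mutation count
#'
#' With mutation rate `mu` per site per haploid genome per generation and
#' haploid genome size `G`, a diploid clonal genome accumulates
#' `ploidy_factor * mu * G` de novo SNPs per generation in expectation
#' (1.568, i.e. about 1.6, at mu = 3.5e-9 and G = 224 Mbp). The generation
#' estimate is the observed count divided by that expectation, with a
#' Poisson likelihood-ratio confidence interval.
#'
#' @param n_de_novo observed de novo SNP count (>= 0).
#' @param mu mutation rate per site per haploid genome per generation.
#' @param genome_size_haploid haploid genome size in bp.
#' @param ploidy_factor 2 for a diploid genome.
#' @param conf confidence level for the likelihood-ratio interval.
#' @return list with `expected_per_generation`, `generations_estimate`,
#'   `conf_low`, `conf_high`.
#' @export
estimate_generations <- function(n_de_novo, mu = 3.5e-9,
                                 genome_size_haploid = 224e6,
                                 ploidy_factor = 2, conf = 0.95) {
  if (mu <= 0 || genome_size_haploid <= 0 || ploidy_factor <= 0)
    stop("mu, genome size and ploidy factor must be positive")
  if (n_de_novo < 0) stop("n_de_novo must be >= 0")
  lambda <- ploidy_factor * mu * genome_size_haploid
  est <- n_de_novo / lambda
  crit <- stats::qchisq(conf, df = 1) / 2
  loglik <- function(g) {
    m <- lambda * g
    if (n_de_novo == 0) -m else n_de_novo * log(m) - m
  }
  lmax <- loglik(max(est, .Machine$double.eps))
  f <- function(g) loglik(g) - (lmax - crit)
  upper <- stats::uniroot(f, c(max(est, 1e-12), est + (crit + 10) / lambda +
                                 10 * sqrt(max(n_de_novo, 1)) / lambda))$root
  lower <- if (n_de_novo == 0) 0 else
    stats::uniroot(f, c(1e-12 / lambda, est))$root
  list(expected_per_generation = lambda, generations_estimate = est,
       conf_low = lower, conf_high = upper)
}

#' Per-chromosome counts and shares of distinguishing sites
#'
#' @param sites output of [find_distinguishing_sites()] (or any data.frame
#'   with a `chrom` column).
#' @param digits decimal places for the percentage (default 1).
#' @return data.frame(chrom, n, pct) sorted by decreasing count; `pct` is
#'   100 * n / total.
#' @export
summarize_by_chromosome <- function(sites, digits = 1) {
  if (nrow(sites) == 0)
    return(data.frame(chrom = character(), n = integer(), pct = numeric()))
  tab <- table(sites$chrom)
  out <- data.frame(chrom = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$n / sum(out$n), digits)
  out[order(-out$n), , drop = FALSE]
}

#' Gene-family variant enrichment (2x2 exact test)
#'
#' Tests whether a gene family carries more sequence variants than the rest
#' of a region, via Fisher's exact test on the 2x2 table
#' [[variants_in_set, genes_in_set], [variants_outside, genes_outside]].
#'
#' @param variants_in_set,genes_in_set,variants_outside,genes_outside
#'   non-negative counts.
#' @return list with `odds_ratio` (conditional MLE) and `p` (two-sided).
#' @export
family_variant_enrichment <- function(variants_in_set, genes_in_set,
                                      variants_outside, genes_outside) {
  counts <- c(variants_in_set, genes_in_set, variants_outside, genes_outside)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all-zero table")
  tab <- matrix(c(variants_in_set, variants_outside,
                  genes_in_set, genes_outside), nrow = 2)
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Write classified events as a BED-like TSV
#' @param events output of [classify_events()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_bed <- function(events, path) {
  utils::write.table(events[, c("chrom", "start", "end", "kind", "n_sites",
                                "copy_number_status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
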