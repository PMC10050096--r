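#' Simulation configuration for clonal lineage evolution
#'
#' Parameters of the forward simulator of diploid clonal genome evolution
#' under central-fusion automixis. The defaults mirror the study system: a
#' ~35x short-read design over a 224 Mbp haploid genome with a de novo
#' mutation rate of 3.5e-9 per site per haploid genome per generation.
#'
#' @param chromosome_lengths named numeric vector of chromosome lengths (bp).
#' @param founder_het_density expected heterozygous sites per bp in the
#'   founder (default 1e-3, a dense clonal-line heterozygous background).
#' @param mu de novo mutation rate per site per haploid genome per
#'   generation (default 3.5e-9).
#' @param crossover_rate expected crossovers per chromosome per meiosis.
#' @param conversion_rate expected gene-conversion tracts per genome per
#'   generation.
#' @param conversion_tract_mean mean gene-conversion tract length in bp
#'   (geometric distribution; default 300, well under 1 kbp).
#' @param mean_depth expected reads per site per sample (default 35).
#' @param depth_dispersion negative-binomial overdispersion; 0 degenerates
#'   to constant depth. The default 0.02 gives a coefficient of variation of
#'   about 0.22 at 35x, the mildly overdispersed-Poisson behavior of real
#'   short-read depth.
#' @param seed integer seed; the same seed yields bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chromosome_lengths,
                       founder_het_density = 1e-3,
                       mu = 3.5e-9,
                       crossover_rate = 0,
                       conversion_rate = 0,
                       conversion_tract_mean = 300,
                       mean_depth = 35,
                       depth_dispersion = 0.02,
                       seed = 1L) {
  if (is.null(names(chromosome_lengths)) || any(names(chromosome_lengths) == ""))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  rates <- c(founder_het_density, mu, crossover_rate, conversion_rate,
             mean_depth, depth_dispersion)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (conversion_tract_mean < 1) stop("conversion_tract_mean must be >= 1 bp")
  structure(list(chromosome_lengths = chromosome_lengths,
                 genome_size_haploid = sum(chromosome_lengths),
                 founder_het_density = founder_het_density,
                 mu = mu,
                 crossover_rate = crossover_rate,
                 conversion_rate = conversion_rate,
                 conversion_tract_mean = conversion_tract_mean,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic sub-seeds so each stage has its own reproducible stream
derive_seed <- function(cfg, k) {
  as.integer((as.double(cfg$seed) * 7919 + k * 104729) %% 2147483647)
}

BASES <- c("A", "C", "G", "T")

#' Simulate a diploid founder genome
#'
#' Draws the founder's heterozygous sites: per chromosome, a Poisson number
#' of sites with expectation `founder_het_density * length`, at distinct
#' uniform positions, each with a reference base and one alternate allele.
#' All founder sites are heterozygous; homozygous-reference positions are
#' implicit and never materialized.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   sorted by chromosome then position; class `sim_founder`.
#' @export
simulate_founder <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$genome_size_haploid <= 0) stop("zero-length genome")
  set.seed(derive_seed(cfg, 1L))
  out <- lapply(names(cfg$chromosome_lengths), function(ch) {
    len <- cfg$chromosome_lengths[[ch]]
    n <- stats::rpois(1, cfg$founder_het_density * len)
    n <- min(n, len)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n) - 1L)
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
    data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.data.frame(out))   # all chromosomes drew zero sites
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
  class(out) <- c("sim_founder", "data.frame")
  out
}

# geometric tract length with given mean (support >= 1)
rtract_len <- function(n, mean_len) {
  if (mean_len <= 1) return(rep(1L, n))
  stats::rgeom(n, prob = 1 / mean_len) + 1L
}

new_truth <- function() {
  data.frame(event_kind = character(), chrom = character(),
             start = integer(), end = integer(), generation = integer(),
             samples = character(), stringsAsFactors = FALSE)
}

add_event <- function(truth, kind, chrom, start, end, generation, samples = "") {
  rbind(truth, data.frame(event_kind = kind, chrom = chrom,
                          start = as.integer(start), end = as.integer(end),
                          generation = as.integer(generation),
                          samples = samples, stringsAsFactors = FALSE))
}

# set het sites within [start, end) on `chrom` to homozygous
# (unphased representation: the surviving allele is drawn per site)
loh_apply <- function(geno, sites, chrom, start, end) {
  idx <- which(sites$chrom == chrom & sites$pos >= start & sites$pos < end &
                 geno == 1L)
  if (length(idx)) geno[idx] <- sample(c(0L, 2L), length(idx), replace = TRUE)
  geno
}

#' Propagate a clonal lineage forward in time
#'
#' Simulates one clonal descent line for `generations` automictic
#' generations. Each generation draws: de novo point mutations with count
#' Poisson(2 * mu * G) placed at previously non-segregating positions
#' (new heterozygotes); gene-conversion tracts with Poisson(conversion_rate)
#' count and geometric lengths that convert short runs to homozygosity; and,
#' per chromosome, Poisson(crossover_rate) crossovers at uniform positions,
#' each of which (with probability 1/2, the central-fusion segregation odds)
#' renders all loci distal to the crossover homozygous — a contiguous
#' segmental copy-neutral loss of heterozygosity. Every realized event is
#' logged with exact coordinates in the truth ledger.
#'
#' @param founder output of [simulate_founder()].
#' @param generations non-negative integer.
#' @param cfg a [sim_config()].
#' @param forced_events optional data.frame(kind, chrom, start, end) of
#'   events to plant deterministically at generation 1 (kinds:
#'   `de_novo_snp` with end = start + 1, `gene_conversion_loh`,
#'   `segmental_loh`, `segmental_deletion`). Used to build cohorts with
#'   exactly known truth.
#' @return list with `genomes` (one genotype vector per generation, coded
#'   0/1/2 over the final site registry), `sites` (the registry: chrom,
#'   pos 0-based, ref, alt), and `truth` (the event ledger).
#' @export
propagate_lineage <- function(founder, generations, cfg, forced_events = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (generations < 0) stop("generations must be >= 0")
  set.seed(derive_seed(cfg, 2L))
  sites <- as.data.frame(founder)
  geno <- rep(1L, nrow(sites))
  truth <- new_truth()
  genomes <- vector("list", generations)
  chroms <- names(cfg$chromosome_lengths)

  for (gen in seq_len(max(generations, 0))) {
    ## forced events, generation 1 only
    if (gen == 1 && !is.null(forced_events) && nrow(forced_events)) {
      for (i in seq_len(nrow(forced_events))) {
        ev <- forced_events[i, ]
        if (ev$kind == "de_novo_snp") {
          ref <- sample(BASES, 1)
          alt <- sample(setdiff(BASES, ref), 1)
          hit <- which(sites$chrom == ev$chrom & sites$pos == ev$start)
          if (length(hit)) {        # position already segregating: overwrite
            geno[hit] <- 1L
          } else {
            sites <- rbind(sites, data.frame(chrom = ev$chrom,
                                             pos = as.integer(ev$start),
                                             ref = ref, alt = alt,
                                             stringsAsFactors = FALSE))
            geno <- c(geno, 1L)
          }
          truth <- add_event(truth, "de_novo_snp", ev$chrom,
                             ev$start, ev$start + 1, gen)
        } else if (ev$kind %in% c("gene_conversion_loh", "segmental_loh",
                                  "segmental_deletion")) {
          geno <- loh_apply(geno, sites, ev$chrom, ev$start, ev$end)
          truth <- add_event(truth, ev$kind, ev$chrom, ev$start, ev$end, gen)
        } else stop("unknown forced event kind: ", ev$kind)
      }
    }
    ## stochastic de novo mutations: Poisson(2 mu G) across the diploid genome
    n_mut <- stats::rpois(1, 2 * cfg$mu * cfg$genome_size_haploid)
    for (i in seq_len(n_mut)) {
      repeat {
        g <- sample.int(cfg$genome_size_haploid, 1) - 1
        cum <- c(0, cumsum(cfg$chromosome_lengths))
        ci <- findInterval(g, cum, rightmost.closed = FALSE)
        ch <- chroms[ci]
        pos <- as.integer(g - cum[ci])
        if (!any(sites$chrom == ch & sites$pos == pos)) break
      }
      ref <- sample(BASES, 1)
      alt <- sample(setdiff(BASES, ref), 1)
      sites <- rbind(sites, data.frame(chrom = ch, pos = pos, ref = ref,
                                       alt = alt, stringsAsFactors = FALSE))
      geno <- c(geno, 1L)
      truth <- add_event(truth, "de_novo_snp", ch, pos, pos + 1, gen)
    }
    ## gene conversion tracts
    n_conv <- stats::rpois(1, cfg$conversion_rate)
    for (i in seq_len(n_conv)) {
      ch <- sample(chroms, 1, prob = cfg$chromosome_lengths)
      len <- rtract_len(1, cfg$conversion_tract_mean)
      start <- sample.int(max(cfg$chromosome_lengths[[ch]] - len, 1), 1) - 1L
      geno <- loh_apply(geno, sites, ch, start, start + len)
      truth <- add_event(truth, "gene_conversion_loh", ch, start, start + len, gen)
    }
    ## crossovers: each triggers distal LOH with probability 1/2
    for (ch in chroms) {
      n_co <- stats::rpois(1, cfg$crossover_rate)
      for (i in seq_len(n_co)) {
        x <- sample.int(cfg$chromosome_lengths[[ch]], 1) - 1L
        if (stats::runif(1) < 0.5) {
          geno <- loh_apply(geno, sites, ch, x, cfg$chromosome_lengths[[ch]])
          truth <- add_event(truth, "segmental_loh", ch, x,
                             cfg$chromosome_lengths[[ch]], gen)
        }
      }
    }
    genomes[[gen]] <- geno
  }

  ## final registry order; pad earlier genomes (de novo absent => hom ref)
  ord <- order(sites$chrom, sites$pos)
  n_final <- nrow(sites)
  genomes <- lapply(genomes, function(g) {
    g <- c(g, rep(0L, n_final - length(g)))
    g[ord]
  })
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  if (generations == 0) genomes <- list()
  list(genomes = genomes, sites = sites, truth = truth)
}

#' Simulate per-site per-sample read depths
#'
#' Emits negative-binomial depths with mean `mean_depth` outside deletions
#' and `mean_depth / 2` inside hemizygous deletions (copy-number signal:
#' copy-neutral LOH keeps full depth, a deletion halves it). With
#' `depth_dispersion = 0` the emission degenerates to constant depth.
#'
#' @param gm a [genotype_matrix()] (positions 1-based).
#' @param cfg a [sim_config()].
#' @param deletions optional data.frame(chrom, start, end, samples) of
#'   hemizygous deletion intervals (0-based half-open); `samples` is a
#'   comma-separated list of affected sample names ("" = all samples).
#' @return integer depth matrix, sites x samples.
#' @export
simulate_depths <- function(gm, cfg, deletions = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mean_depth <= 0) stop("mean_depth must be positive")
  set.seed(derive_seed(cfg, 3L))
  n_site <- nrow(gm$sites); n_samp <- length(gm$samples)
  mu <- matrix(cfg$mean_depth, n_site, n_samp)
  if (!is.null(deletions) && nrow(deletions)) {
    for (i in seq_len(nrow(deletions))) {
      d <- deletions[i, ]
      in_del <- gm$sites$chrom == d$chrom &
        gm$sites$pos - 1L >= d$start & gm$sites$pos - 1L < d$end
      affected <- if (is.null(d$samples) || d$samples == "") gm$samples else
        strsplit(d$samples, ",")[[1]]
      mu[in_del, match(affected, gm$samples)] <- cfg$mean_depth / 2
    }
  }
  if (cfg$depth_dispersion <= 0) {
    dp <- matrix(as.integer(round(mu)), n_site, n_samp)
  } else {
    dp <- matrix(stats::rnbinom(n_site * n_samp, mu = mu,
                                size = 1 / cfg$depth_dispersion),
                 n_site, n_samp)
  }
  colnames(dp) <- gm$samples
  dp
}

#' Simulate a clonal cohort with reference, focal and outgroup samples
#'
#' Builds the study design in miniature: a founder clonal line, `n_reference`
#' wild-type samples carrying the founder genotype, `n_focal` samples from a
#' derived sub-lineage propagated for `generations` (optionally with exactly
#' planted events), and optionally one diverged outgroup sample. The first
#' two reference samples play the sister-clade role.
#'
#' @inheritParams propagate_lineage
#' @param cfg a [sim_config()].
#' @param n_focal,n_reference,n_outgroup cohort composition (default 2/15/1,
#'   the study's 2 focal + 15 wild-type + 1 outgroup libraries).
#' @param generations generations on the focal branch (default 1).
#' @param outgroup_divergence fraction of founder het sites homozygous in the
#'   outgroup, plus an equal fraction of outgroup-private het sites.
#' @return list with `gm` (genotype_matrix including depths), `roles`
#'   (sample_roles), `truth` (event ledger, samples = focal sample names)
#'   and `deletions` (intervals passed to the depth model).
#' @export
simulate_cohort <- function(cfg, n_focal = 2, n_reference = 15,
                            n_outgroup = 1, generations = 1,
                            forced_events = NULL,
                            outgroup_divergence = 0.05) {
  founder <- simulate_founder(cfg)
  prop <- propagate_lineage(founder, generations, cfg, forced_events)
  sites <- prop$sites
  focal_geno <- if (generations > 0) prop$genomes[[generations]] else
    rep(1L, nrow(sites))
  ## reference samples: founder genotype over the final registry
  founder_key <- paste(founder$chrom, founder$pos)
  is_founder_site <- paste(sites$chrom, sites$pos) %in% founder_key
  ref_geno <- ifelse(is_founder_site, 1L, 0L)

  focal_names <- paste0("QL", seq_len(n_focal))
  ref_names <- paste0("WT", seq_len(n_reference))
  samples <- c(focal_names, ref_names)
  geno <- cbind(matrix(focal_geno, nrow(sites), n_focal),
                matrix(ref_geno, nrow(sites), n_reference))

  out_names <- character()
  if (n_outgroup > 0) {
    set.seed(derive_seed(cfg, 4L))
    out_names <- paste0("OUT", seq_len(n_outgroup))
    for (j in seq_len(n_outgroup)) {
      og <- ref_geno
      het_idx <- which(og == 1L)
      flip <- sample(het_idx, round(outgroup_divergence * length(het_idx)))
      og[flip] <- sample(c(0L, 2L), length(flip), replace = TRUE)
      geno <- cbind(geno, og)
    }
    samples <- c(samples, out_names)
  }
  colnames(geno) <- samples

  truth <- prop$truth
  if (nrow(truth)) truth$samples <- paste(focal_names, collapse = ",")
  deletions <- truth[truth$event_kind == "segmental_deletion", , drop = FALSE]

  gm_sites <- data.frame(chrom = sites$chrom, pos = sites$pos + 1L,
                         ref = sites$ref, alt = sites$alt,
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(gm_sites, geno, samples = samples)
  gm$depth <- simulate_depths(gm, cfg, deletions)
  roles <- sample_roles(focal = focal_names, reference = ref_names,
                        reference_sister = ref_names[seq_len(min(2, n_reference))],
                        outgroup = out_names)
  list(gm = gm, roles = roles, truth = truth, deletions = deletions, cfg = cfg)
}

#' Write a cohort to VCF plus a truth ledger TSV
#'
#' Emits a minimal valid VCF 4.2 with GT and DP per sample (1-based
#' positions, contig headers from the configuration) and the truth ledger as
#' a tab-separated file that round-trips through [read_truth()]. Re-reading
#' the VCF with [read_vcf_matrix()] reproduces the in-memory matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param vcf_path output VCF path.
#' @param truth optional truth ledger data.frame.
#' @param truth_path output TSV path (required when `truth` given).
#' @param contig_lengths optional named vector for ##contig headers.
#' @return invisibly, `vcf_path`.
#' @export
emit_vcf <- function(gm, vcf_path, truth = NULL, truth_path = NULL,
                     contig_lengths = NULL) {
  if (length(gm$samples) == 0) stop("cohort is empty")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$geno + 1L],
                   nrow(gm$geno), ncol(gm$geno))
  gt_str[is.na(gm$geno)] <- "./."
  dp_str <- ifelse(is.na(gm$depth), ".", as.character(gm$depth))
  cells <- matrix(paste(gt_str, dp_str, sep = ":"),
                  nrow(gm$geno), ncol(gm$geno))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonalloh_sim",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                gm$sites$alt, ".", "PASS", ".", "GT:DP",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(truth)) {
    if (is.null(truth_path)) stop("truth_path required when truth is given")
    write_truth(truth, truth_path)
  }
  invisible(vcf_path)
}

#' Write / read the simulation truth ledger
#' @param truth data.frame(event_kind, chrom, start, end, generation, samples)
#' @param path TSV path
#' @return `read_truth` returns the ledger data.frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "character"))
}

#' Simulate the standard validation cohort
#'
#' Builds the package's reference validation scenario: a 20 Mbp genome of
#' five 4 Mbp chromosomes with founder heterozygous-site density 1e-3,
#' 2 focal + 15 reference + 1 outgroup samples, and exactly planted events
#' on the focal branch — 9 de novo SNPs and 19 gene-conversion tracts
#' (500 bp, each anchored on a founder heterozygous site so it leaves a
#' genotypic footprint) scattered over three chromosomes, one 2.25 Mbp
#' segmental copy-neutral LOH on its own chromosome, and one 400 kbp
#' hemizygous-deletion control tract (half depth in focal samples) on
#' another. Event coordinates are chosen deterministically from the
#' seed-determined founder, at least 20 kbp apart, so every planted event
#' maps to exactly one recoverable call.
#'
#' @param seed integer seed.
#' @param n_de_novo,n_conversions event counts (defaults 9 and 19).
#' @param loh_span segmental LOH span in bp (default 2.25e6).
#' @return As [simulate_cohort()], plus `cfg` and the planted `truth`.
#' @export
simulate_validation_cohort <- function(seed = 1L, n_de_novo = 9,
                                       n_conversions = 19,
                                       loh_span = 2.25e6) {
  lens <- c(chrA = 4e6, chrB = 4e6, chrC = 4e6, chrD = 4e6, chrE = 4e6)
  cfg <- sim_config(chromosome_lengths = lens, founder_het_density = 1e-3,
                    mu = 0, crossover_rate = 0, conversion_rate = 0,
                    seed = seed)
  founder <- simulate_founder(cfg)
  short_chroms <- c("chrA", "chrB", "chrC")

  ## de novo positions: early on each chromosome, nudged off founder sites
  dn_chrom <- rep_len(short_chroms, n_de_novo)
  dn_pos <- integer(n_de_novo)
  for (i in seq_len(n_de_novo)) {
    pos <- 1e5 * (1 + (i - 1) %/% length(short_chroms))
    while (any(founder$chrom == dn_chrom[i] & founder$pos == pos))
      pos <- pos + 7
    dn_pos[i] <- pos
  }
  ## conversion anchors: founder het sites >= 1.2 Mbp in, >= 20 kbp apart
  conv <- do.call(rbind, lapply(short_chroms, function(ch) {
    p <- founder$pos[founder$chrom == ch & founder$pos >= 1.2e6 &
                       founder$pos <= 3.8e6]
    keep <- c()
    last <- -Inf
    for (x in p) if (x - last >= 2e4) { keep <- c(keep, x); last <- x }
    data.frame(chrom = ch, anchor = keep, stringsAsFactors = FALSE)
  }))
  conv <- do.call(rbind, lapply(split(conv, conv$chrom), utils::head,
                                ceiling(n_conversions / 3)))
  conv <- conv[seq_len(n_conversions), ]

  forced <- rbind(
    data.frame(kind = "de_novo_snp", chrom = dn_chrom, start = dn_pos,
               end = dn_pos + 1, stringsAsFactors = FALSE),
    data.frame(kind = "gene_conversion_loh", chrom = conv$chrom,
               start = conv$anchor - 200L, end = conv$anchor + 300L,
               stringsAsFactors = FALSE),
    data.frame(kind = "segmental_loh", chrom = "chrE", start = 1.5e6,
               end = 1.5e6 + loh_span, stringsAsFactors = FALSE),
    data.frame(kind = "segmental_deletion", chrom = "chrD", start = 2.0e6,
               end = 2.4e6, stringsAsFactors = FALSE))
  out <- simulate_cohort(cfg, n_focal = 2, n_reference = 15, n_outgroup = 1,
                         generations = 1, forced_events = forced)
  out$cfg <- cfg
  out
}
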