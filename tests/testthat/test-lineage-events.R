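make_roles <- function(n_focal = 2, n_ref = 3) {
  sample_roles(focal = paste0("F", seq_len(n_focal)),
               reference = paste0("R", seq_len(n_ref)))
}

roles_gm <- function(geno, ...) {
  colnames(geno) <- c(paste0("F", 1:2), paste0("R", seq_len(ncol(geno) - 2)))
  toy_gm(geno, ...)
}

test_that("distinguishing sites require focal agreement and full reference difference", {
  # rows: focal disagree / qualifying het / qualifying hom / ref shares focal
  geno <- rbind(c(0L, 1L, 0L, 0L, 0L),
                c(1L, 1L, 0L, 0L, 2L),
                c(2L, 2L, 1L, 1L, 1L),
                c(1L, 1L, 0L, 1L, 0L))
  gm <- roles_gm(geno)
  ds <- find_distinguishing_sites(gm, make_roles())
  expect_equal(ds$pos, c(200L, 300L))
  expect_equal(ds$zygosity, c("het", "hom"))
  expect_error(find_distinguishing_sites(gm, structure(
    list(focal = character(), reference = "R1", reference_sister = "R1",
         outgroup = character()), class = "sample_roles")), "focal")
})

test_that("distinguishing-site calls equal the brute-force scan on random matrices", {
  set.seed(404)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    geno <- matrix(sample(c(0:2, NA), n * 5, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), n, 5)
    gm <- roles_gm(geno)
    ds <- find_distinguishing_sites(gm, make_roles())
    expect_equal(ds$site, which(oracle_distinguishing(geno, 1:2, 3:5)))
  }
})

test_that("event classification follows the merge and span rules", {
  # singleton heterozygous gain at position 500
  s1 <- data.frame(site = 1L, chrom = "chr1", pos = 500L, focal_geno = 1L,
                   zygosity = "het", stringsAsFactors = FALSE)
  e1 <- classify_events(s1)
  expect_equal(e1$kind, "point_mutation_gain_het")
  expect_equal(c(e1$start, e1$end, e1$n_sites), c(499L, 500L, 1L))

  # hom sites at 100, 600, 5000: {100,600} merge (gap 500), {5000} alone
  s2 <- data.frame(site = 1:3, chrom = "chr1", pos = c(100L, 600L, 5000L),
                   focal_geno = 0L, zygosity = "hom", stringsAsFactors = FALSE)
  e2 <- classify_events(s2)
  expect_equal(nrow(e2), 2)
  expect_true(all(e2$kind == "gene_conversion_loh"))
  expect_equal(e2$start, c(99L, 4999L))
  expect_equal(e2$end, c(600L, 5000L))
  expect_equal(sum(e2$n_sites), 3)

  # unsorted input is rejected; empty input allowed
  expect_error(classify_events(s2[c(2, 1, 3), ]), "sorted")
  expect_equal(nrow(classify_events(s2[0, ])), 0)
})

test_that("classification matches the clustering oracle on random site lists", {
  set.seed(405)
  for (rep in 1:200) {
    n <- sample(1:25, 1)
    pos <- sort(sample.int(5e4, n))
    s <- data.frame(site = seq_len(n),
                    chrom = sample(c("c1", "c2"), n, replace = TRUE),
                    pos = pos,
                    focal_geno = sample(c(0L, 1L, 2L), n, replace = TRUE),
                    stringsAsFactors = FALSE)
    s$zygosity <- ifelse(s$focal_geno == 1L, "het", "hom")
    s <- s[order(s$chrom, s$pos), ]
    got <- classify_events(s, merge_gap = 800, segmental_span = 5000)
    want <- oracle_classify(s, merge_gap = 800, segmental_span = 5000)
    want <- want[order(want$chrom, want$start), ]
    rownames(want) <- NULL
    expect_equal(got[, names(want)], want)
    expect_equal(sum(got$n_sites), nrow(s))        # site conservation
    # disjoint within chromosome
    for (ch in unique(got$chrom)) {
      g <- got[got$chrom == ch, ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] >= head(g$end, -1)))
    }
  }
})

test_that("LOH boundaries bracket the true breakpoints in simulation", {
  coh <- simulate_validation_cohort(seed = 12)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  emit_vcf(coh$gm, vcf)
  gm <- hard_filter(read_vcf_matrix(vcf))
  tr <- coh$truth[coh$truth$event_kind == "segmental_loh", ]
  b <- locate_loh_boundaries(gm, coh$roles, "chrE", chrom_length = 4e6)
  # truth breakpoints (1-based) lie between inner and outer bounds
  expect_gte(tr$start + 1, b$outer_start)
  expect_lte(tr$start + 1, b$inner_start)
  expect_gte(tr$end, b$inner_end)
  expect_lte(tr$end, b$outer_end)
  # inner span within 20 kbp of the 2.25 Mbp truth at ~1 kbp site spacing
  expect_lt(abs(b$span - 2.25e6), 2e4)
})

test_that("boundary saturation and degenerate cases behave", {
  # all informative sites focal-hom: run covers the chromosome
  geno <- cbind(F1 = rep(0L, 4), F2 = rep(2L, 4), R1 = rep(1L, 4),
                R2 = rep(1L, 4), R3 = rep(1L, 4))
  gm <- toy_gm(geno)
  roles <- make_roles(2, 3)
  b <- locate_loh_boundaries(gm, roles, "chr1", chrom_length = 1000)
  expect_equal(b$inner_start, 100L)
  expect_equal(b$inner_end, 400L)
  expect_equal(b$outer_start, 1L)
  expect_equal(b$outer_end, 1000L)
  # no homozygous run at all
  gm2 <- toy_gm(cbind(F1 = 1L, F2 = 1L, R1 = 1L, R2 = 1L, R3 = 1L))
  expect_null(locate_loh_boundaries(gm2, roles, "chr1"))
  expect_error(locate_loh_boundaries(gm, roles, "chrX"), "chrX")
})

test_that("copy-number classification separates neutral LOH from deletion", {
  coh <- simulate_validation_cohort(seed = 12)
  nd <- normalize_depth(coh$gm)
  tr <- coh$truth
  seg <- tr[tr$event_kind == "segmental_loh", ]
  del <- tr[tr$event_kind == "segmental_deletion", ]
  cn1 <- check_copy_neutral(nd$norm, coh$gm, coh$roles, seg$chrom,
                            seg$start, seg$end)
  expect_equal(cn1$status, "copy_neutral")
  expect_lt(abs(cn1$ratio - 1), 0.1)
  cn2 <- check_copy_neutral(nd$norm, coh$gm, coh$roles, del$chrom,
                            del$start, del$end)
  expect_equal(cn2$status, "deletion_like")
  expect_lt(abs(cn2$ratio - 0.5), 0.1)
  # identical depth columns give a ratio of exactly 1
  norm_id <- matrix(1, nrow(coh$gm$sites), length(coh$gm$samples),
                    dimnames = list(NULL, coh$gm$samples))
  cn3 <- check_copy_neutral(norm_id, coh$gm, coh$roles, seg$chrom,
                            seg$start, seg$end)
  expect_identical(cn3$ratio, 1)
  expect_error(check_copy_neutral(nd$norm, coh$gm, coh$roles, "chrA",
                                  0, 1), "no retained SNPs")
})

test_that("generation estimate is the de novo count over 2*mu*G", {
  est <- estimate_generations(9)
  expect_equal(est$expected_per_generation, 1.568)
  expect_equal(round(est$expected_per_generation, 1), 1.6)
  expect_equal(est$generations_estimate, 9 / 1.568, tolerance = 1e-12)
  expect_equal(round(est$generations_estimate, 2), 5.74)
  expect_true(est$conf_low < est$generations_estimate &
                est$generations_estimate < est$conf_high)

  e0 <- estimate_generations(0)
  expect_equal(e0$generations_estimate, 0)
  expect_equal(e0$conf_low, 0)
  expect_gt(e0$conf_high, 0)

  # linear in n, inversely linear in mu and G
  expect_equal(estimate_generations(18)$generations_estimate,
               2 * est$generations_estimate)
  expect_equal(estimate_generations(9, mu = 7e-9)$generations_estimate,
               est$generations_estimate / 2)
  expect_equal(estimate_generations(9, genome_size_haploid = 112e6)$generations_estimate,
               est$generations_estimate * 2)
  expect_error(estimate_generations(9, mu = 0), "positive")
})

test_that("per-chromosome summaries report counts and percentages", {
  s <- data.frame(chrom = c(rep("chr13", 364), rep("other", 36)))
  out <- summarize_by_chromosome(s)
  expect_equal(out$pct[out$chrom == "chr13"], 91.0)
  expect_equal(sum(out$n), 400)

  one <- summarize_by_chromosome(data.frame(chrom = rep("c", 5)))
  expect_equal(one$pct, 100)

  ab <- summarize_by_chromosome(data.frame(chrom = c("A", "B", "B", "B")))
  expect_equal(ab$pct[order(ab$chrom)], c(25, 75))
  expect_equal(nrow(summarize_by_chromosome(data.frame(chrom = character()))), 0)
})

test_that("family enrichment matches exact-test behavior and its oracle", {
  sym <- family_variant_enrichment(5, 5, 5, 5)
  expect_equal(sym$p, 1)
  expect_equal(unname(sym$odds_ratio), 1, tolerance = 1e-6)

  cyp <- family_variant_enrichment(22, 24, 48, 176)
  expect_lt(cyp$p, 0.001)
  expect_gt(cyp$odds_ratio, 1)

  expect_equal(family_variant_enrichment(3, 1, 1, 3)$p,
               oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-9)
  expect_error(family_variant_enrichment(0, 0, 0, 0), "all-zero")

  set.seed(406)
  for (rep in 1:200) {
    tab <- sample(0:12, 4, replace = TRUE)
    if (sum(tab) == 0) tab[1] <- 1
    got <- family_variant_enrichment(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got$p, oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})
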