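test_that("founder site counts follow the configured density", {
  # empty case
  cfg0 <- sim_config(c(chr1 = 1e6), founder_het_density = 0, seed = 1)
  expect_equal(nrow(simulate_founder(cfg0)), 0)

  # mean over replicate seeds matches density * genome size (3-SE band)
  counts <- vapply(1:200, function(s) {
    cfg <- sim_config(c(chr1 = 1e6), founder_het_density = 1e-3, seed = s)
    nrow(simulate_founder(cfg))
  }, 0L)
  se <- sqrt(1000 / 200)   # Poisson(1000) counts, 200 replicates
  expect_lt(abs(mean(counts) - 1000), 3 * se)

  # positions within chromosome bounds, strictly increasing per chromosome
  cfg2 <- sim_config(c(a = 5e5, b = 5e5), founder_het_density = 1e-3, seed = 3)
  f <- simulate_founder(cfg2)
  expect_true(all(f$pos >= 0 & f$pos < 5e5))
  for (ch in c("a", "b"))
    expect_true(all(diff(f$pos[f$chrom == ch]) > 0))

  # reproducibility
  expect_identical(simulate_founder(cfg2), simulate_founder(cfg2))
})

test_that("null process leaves the founder untouched", {
  cfg <- sim_config(c(chr1 = 1e6), founder_het_density = 5e-4, mu = 0,
                    crossover_rate = 0, conversion_rate = 0, seed = 11)
  f <- simulate_founder(cfg)
  pr <- propagate_lineage(f, generations = 4, cfg)
  expect_equal(nrow(pr$truth), 0)
  for (g in pr$genomes) expect_true(all(g == 1L))
  expect_equal(nrow(pr$sites), nrow(f))
})

test_that("de novo count per generation has mean 2*mu*G", {
  lambda <- 2 * 3.5e-9 * 224e6   # 1.568
  counts <- vapply(1:1000, function(s) {
    cfg <- sim_config(c(chr1 = 224e6), founder_het_density = 0, mu = 3.5e-9,
                      seed = s)
    f <- simulate_founder(cfg)
    pr <- propagate_lineage(f, 1, cfg)
    sum(pr$truth$event_kind == "de_novo_snp")
  }, 0L)
  se <- sqrt(lambda / 1000)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("forced events are planted at exact coordinates", {
  cfg <- sim_config(c(chr1 = 3.25e6), founder_het_density = 1e-3, mu = 0,
                    crossover_rate = 0, conversion_rate = 0, seed = 5)
  f <- simulate_founder(cfg)
  forced <- data.frame(kind = "segmental_loh", chrom = "chr1",
                       start = 1.0e6, end = 3.25e6)
  pr <- propagate_lineage(f, 1, cfg, forced_events = forced)
  expect_equal(pr$truth$event_kind, "segmental_loh")
  expect_equal(pr$truth$start, 1.0e6)
  expect_equal(pr$truth$end, 3.25e6)
  # brute-force scan: the event is a maximal homozygous run over founder sites
  g <- pr$genomes[[1]]
  distal <- pr$sites$pos >= 1.0e6
  expect_true(all(g[distal] != 1L))
  expect_true(all(g[!distal] == 1L))
})

test_that("stochastic segmental LOH events are maximal homozygous runs", {
  cfg <- sim_config(c(chr1 = 2e6, chr2 = 2e6), founder_het_density = 1e-3,
                    mu = 0, crossover_rate = 1, conversion_rate = 0, seed = 9)
  f <- simulate_founder(cfg)
  pr <- propagate_lineage(f, 2, cfg)
  seg <- pr$truth[pr$truth$event_kind == "segmental_loh", ]
  expect_gt(nrow(seg), 0)   # rate 1/chrom/gen over 2 chrom x 2 gens
  g <- pr$genomes[[length(pr$genomes)]]
  for (i in seq_len(nrow(seg))) {
    inside <- pr$sites$chrom == seg$chrom[i] & pr$sites$pos >= seg$start[i]
    expect_true(all(g[inside] != 1L))
  }
  # the earliest LOH start per chromosome is preceded by a heterozygous site
  for (ch in unique(seg$chrom)) {
    first <- min(seg$start[seg$chrom == ch])
    before <- which(pr$sites$chrom == ch & pr$sites$pos < first)
    if (length(before)) expect_equal(g[max(before)], 1L)
  }
})

test_that("depth emission matches the copy-number model", {
  cfg <- sim_config(c(chr1 = 1e6), founder_het_density = 1e-2,
                    mean_depth = 35, seed = 21)
  f <- simulate_founder(cfg)
  gm <- toy_gm(matrix(1L, nrow(f), 2), pos = f$pos + 1L)
  gm$sites$chrom <- f$chrom
  dp <- simulate_depths(gm, cfg)
  n <- length(dp)
  se <- sqrt((35 + 35^2 * cfg$depth_dispersion) / n)
  expect_lt(abs(mean(dp) - 35), 3 * se)
  expect_true(all(dp >= 0) && all(dp == round(dp)))

  # whole-chromosome hemizygous deletion halves expected depth
  del <- data.frame(chrom = "chr1", start = 0, end = 1e6, samples = "S1")
  dp2 <- simulate_depths(gm, cfg, del)
  expect_lt(abs(mean(dp2[, "S1"]) - 17.5), 4 * se)
  expect_lt(abs(mean(dp2[, "S2"]) - 35), 4 * se)

  # zero dispersion degenerates to constant depth
  cfg0 <- sim_config(c(chr1 = 1e6), founder_het_density = 1e-2,
                     mean_depth = 35, depth_dispersion = 0, seed = 21)
  expect_true(all(simulate_depths(gm, cfg0) == 35))
})

test_that("VCF emission round-trips and is byte-stable under a fixed seed", {
  gm <- toy_gm(rbind(c(0L, 1L), c(1L, 2L), c(2L, 0L)),
               depth = matrix(30L, 3, 2))
  gm$sites$ref <- c("A", "C", "T"); gm$sites$alt <- c("G", "T", "A")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  emit_vcf(gm, vcf)
  lines <- readLines(vcf)
  body <- grep("^[^#]", lines, value = TRUE)
  expect_length(body, 3)
  fields <- strsplit(body[1], "\t")[[1]]
  expect_length(fields, 11)            # 9 fixed columns + 2 samples
  expect_equal(fields[9], "GT:DP")
  expect_equal(fields[10], "0/0:30")

  back <- read_vcf_matrix(vcf)
  expect_equal(back$geno, gm$geno)
  expect_equal(back$depth, gm$depth)
  expect_equal(back$sites, gm$sites)

  # full-cohort determinism: identical seeds give byte-identical files
  coh1 <- simulate_cohort(sim_config(c(chr1 = 2e5), seed = 33), n_reference = 3)
  coh2 <- simulate_cohort(sim_config(c(chr1 = 2e5), seed = 33), n_reference = 3)
  v1 <- withr::local_tempfile(); v2 <- withr::local_tempfile()
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  emit_vcf(coh1$gm, v1, coh1$truth, t1)
  emit_vcf(coh2$gm, v2, coh2$truth, t2)
  expect_identical(unname(tools::md5sum(v1)), unname(tools::md5sum(v2)))
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("truth ledger round-trips through its reader", {
  tr <- data.frame(event_kind = c("de_novo_snp", "segmental_loh"),
                   chrom = c("chr1", "chr2"), start = c(10L, 500L),
                   end = c(11L, 2000L), generation = c(1L, 2L),
                   samples = c("QL1,QL2", "QL1"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  write_truth(tr, path)
  expect_equal(read_truth(path), tr)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(c(chr1 = 0)), "positive")
  expect_error(sim_config(c(chr1 = 1e5), mu = -1), "non-negative")
  cfg <- sim_config(c(chr1 = 1e5), seed = 2)
  expect_equal(cfg$genome_size_haploid, 1e5)
  f <- simulate_founder(cfg)
  expect_error(propagate_lineage(f, -1, cfg), "generations")
})
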