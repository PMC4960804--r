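test_that("generated genomes hit the gap budget and are reproducible", {
  gen0 <- make_genome(c(chr1 = 1e6), gap_fraction = 0, seed = 1)
  expect_equal(length(gen0$gaps), 0L)
  gen <- make_genome(c(chr1 = 1e6, chr2 = 1e6), gap_fraction = 0.1, seed = 2)
  for (cn in c("chr1", "chr2")) {
    gbp <- sum(GenomicRanges::width(
      gen$gaps[GenomicRanges::seqnames(gen$gaps) == cn]))
    expect_lt(abs(gbp - 1e5), 1e3)  # within 1 % of the target
  }
  gen2 <- make_genome(c(chr1 = 1e6, chr2 = 1e6), gap_fraction = 0.1, seed = 2)
  expect_identical(gr_segments(gen2$gaps), gr_segments(gen$gaps))
})

test_that("planted domains respect overlap-fraction constraints", {
  gen <- make_genome(c(chr1 = 2e6, chr2 = 2e6), gap_fraction = 0.05,
                     seed = 3)
  target <- plant_domains(gen, 40, c(1e4, 5e4), seed = 4)
  full <- plant_domains(gen, 50, c(500, 2000), overlap_with = target,
                        overlap_fraction = 1, seed = 5)
  expect_equal(intersect_bp(full, target), total_bp(full))
  none <- plant_domains(gen, 50, c(500, 2000), overlap_with = target,
                        overlap_fraction = 0, seed = 6)
  expect_equal(intersect_bp(none, target), 0)
  half <- plant_domains(gen, 1000, c(500, 2000), overlap_with = target,
                        overlap_fraction = 0.5, seed = 7)
  # per-region accounting (planted regions may overlap one another)
  tm <- merge_intervals(target)
  per_region <- sum(vapply(seq_along(half), function(i)
    intersect_bp(half[i], tm), numeric(1)))
  frac <- per_region / sum(GenomicRanges::width(half))
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
  # no planted base ever falls in a gap
  expect_equal(intersect_bp(half, gen$gaps), 0)
})

test_that("simulated tags follow the planted intensity mixture", {
  gen <- make_genome(c(chr1 = 1e6), gap_fraction = 0, seed = 8)
  # fold 3 over 10 % of the genome: expected in-region read fraction
  # 0.3 / (0.3 + 0.9) = 0.25
  reg <- gr0(gen, "chr1", 0, 1e5)
  S4Vectors::mcols(reg)$fold <- 3
  n <- 2e5
  tg <- simulate_tags(gen, n, reg, seed = 9)
  expect_equal(tg$total_reads, n)
  inreg <- sum(tg$chrom == "chr1" & tg$pos < 1e5)
  p <- 0.25
  expect_lt(abs(inreg / n - p), 3 * sqrt(p * (1 - p) / n))
  # fold 1 everywhere: in-region fraction ~ bp fraction
  tg1 <- simulate_tags(gen, n, NULL, seed = 10)
  in1 <- sum(tg1$pos < 1e5)
  expect_lt(abs(in1 / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # no tag in gaps; determinism
  geng <- make_genome(c(chr1 = 1e6), gap_fraction = 0.2, seed = 11)
  tgg <- simulate_tags(geng, 5e4, NULL, seed = 12)
  sites <- gr0(geng, tgg$chrom, tgg$pos, tgg$pos + 1)
  expect_equal(intersect_bp(sites, geng$gaps), 0)
  tgg2 <- simulate_tags(geng, 5e4, NULL, seed = 12)
  expect_identical(tgg2$pos, tgg$pos)
})

test_that("gene simulation couples planted rates to expression as asked", {
  gen <- make_genome(seed = 13)
  g_inv <- simulate_genes(gen, 2000, coupling = "inverse", seed = 14)
  expect_lt(spearman_rho(g_inv$rate_rs, g_inv$fpkm_rs), -0.5)
  g_no <- simulate_genes(gen, 2000, coupling = "none", seed = 15)
  expect_equal(sd(g_no$rate_rs), 0)  # flat planted rate
  # family mix roughly honored
  expect_gt(mean(g_inv$family == "ZNF"), 0.03)
  expect_lt(mean(g_inv$family == "ZNF"), 0.10)
  expect_true(all(g_inv$tss != g_inv$tes))
})

test_that("methylation simulation plants the hypomethylation delta", {
  gen <- make_genome(c(chr1 = 1e6), gap_fraction = 0, seed = 16)
  hypo <- gr0(gen, "chr1", 2e5, 4e5)
  tr <- simulate_methylation(gen, 500, 80, hypo, 30, noise_sd = 5,
                             seed = 17)
  expect_true(all(tr$pct >= 0 & tr$pct <= 100))
  inside <- tr$pos >= 2e5 & tr$pos < 4e5
  expect_lt(abs(mean(tr$pct[inside]) - 50), 2)
  expect_lt(abs(mean(tr$pct[!inside]) - 80), 2)
  flat <- simulate_methylation(gen, 500, 80, NULL, 0, noise_sd = 0,
                               seed = 18)
  expect_equal(unique(flat$pct), 80)
})

test_that("scenario bundles are readable and byte-reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- list(n_domains = 20, n_late_rep = 10, n_hypometh = 30,
              n_neutral = 40, n_te_subtypes = 3, n_te_per_subtype = 10,
              n_genes = 50, n_reads = 5000, n_tel_reads = 500)
  b1 <- scenario_senescence(d1, seed = 42, config = cfg)
  b2 <- scenario_senescence(d2, seed = 42, config = cfg)
  for (f in names(b1$files)) {
    expect_identical(readLines(b1$files[[f]]), readLines(b2$files[[f]]),
                     label = paste("file", f))
  }
  # every file loads through the package's public readers
  gen <- Genome(read_chrom_sizes(b1$files[["chrom_sizes"]])$chrom,
                gaps = read_bed(b1$files[["chrom_sizes"]] |>
                                  dirname() |> file.path("gaps.bed"),
                                read_chrom_sizes(b1$files[["chrom_sizes"]])))
  expect_s3_class(gen, "Genome")
  expect_gt(length(read_bed(b1$files[["domains"]], gen)), 0)
  expect_gt(read_tags_bed(b1$files[["tags_rs"]], gen)$total_reads, 0)
  expect_gt(nrow(read_gene_table(b1$files[["genes"]], gen)), 0)
  expect_gt(nrow(read_te_table(b1$files[["te"]], gen)), 0)
  expect_gt(length(read_reads(b1$files[["tel_pro_ip"]])), 0)
})
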