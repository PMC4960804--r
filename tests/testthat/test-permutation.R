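test_that("randomized sets match length and chromosome distributions", {
  set.seed(23)
  gen <- make_genome(c(chr1 = 50000, chr2 = 30000), gap_fraction = 0.1,
                     seed = 1)
  B <- gr0(gen, c(rep("chr1", 3), rep("chr2", 2)),
           c(100, 5000, 20000, 100, 9000),
           c(600, 6500, 21000, 1100, 9800))
  rb <- randomize_set(B, gen, seed = 5)
  dfo <- senescape:::.gr0(B); dfr <- senescape:::.gr0(rb)
  expect_identical(dfr$chrom, dfo$chrom)
  expect_identical(dfr$end - dfr$start, dfo$end - dfo$start)
  # no randomized base falls in a gap
  expect_equal(intersect_bp(rb, gen$gaps), 0)
  # determinism under a fixed seed
  expect_identical(gr_segments(randomize_set(B, gen, seed = 5)),
                   gr_segments(rb))
})

test_that("a single admissible placement is deterministic", {
  gaps <- GenomicRanges::GRanges("chrA", IRanges::IRanges(c(1, 801),
                                                          c(300, 1000)))
  gen <- Genome(c(chrA = 1000), gaps = gaps)  # only [300, 800) is free
  B <- gr0(gen, "chrA", 0, 500)  # length 500 == free stretch length
  rb <- randomize_set(B, gen, seed = 99)
  expect_equal(gr_segments(rb),
               data.frame(chrom = "chrA", start = 300, end = 800))
  B2 <- gr0(gen, "chrA", 0, 600)
  expect_error(randomize_set(B2, gen), "cannot be placed")
})

test_that("start positions are uniform over the admissible set", {
  gen <- toy_genome(c(chrA = 10000))
  # 10,000 identical source regions: each is placed independently, so one
  # call yields 10,000 draws from the placement distribution
  B <- gr0(gen, rep("chrA", 10000), rep(0, 10000), rep(100, 10000))
  starts <- senescape:::.gr0(randomize_set(B, gen, seed = 31))$start
  expect_true(min(starts) >= 0)
  expect_true(max(starts) <= 9900)
  cs <- chisq.test(table(cut(starts, breaks = seq(0, 9900, length.out = 21),
                             include.lowest = TRUE)))
  expect_gt(cs$p.value, 0.01)
})

test_that("expected overlap matches the exhaustive-enumeration oracle", {
  gen <- toy_genome(c(chrA = 10000))
  A <- gr0(gen, "chrA", 0, 5000)
  B <- gr0(gen, "chrA", 1000, 1100)
  null_ovs <- enumerate_expected_overlap(gen, "chrA", 100, A)
  expect_equal(length(null_ovs), 9901)
  expect_equal(mean(null_ovs), 50.0)

  plan <- randomization_plan(10000, seed = 37)
  r <- permutation_enrichment(A, B, gen, plan)
  mc_se <- sd(null_ovs) / sqrt(plan$n_permutations)
  expect_lt(abs(r$expected_bp - 50.0), 3 * mc_se)
  expect_equal(r$observed_bp, 100)
})

test_that("planted overlap is called enriched with a calibrated p", {
  gen <- toy_genome(c(chrA = 10000))
  A <- gr0(gen, "chrA", 0, 5000)
  B <- gr0(gen, "chrA", 1000, 1150)  # fully inside A: observed 150
  plan <- randomization_plan(10000, seed = 41)
  r <- permutation_enrichment(A, B, gen, plan)
  null_ovs <- enumerate_expected_overlap(gen, "chrA", 150, A)
  expect_equal(r$observed_bp, 150)
  expect_equal(r$fold, 150 / r$expected_bp)
  expect_equal(abs(r$fold - 150 / mean(null_ovs)) < 0.1, TRUE)
  # exact null: P(overlap >= 150) = #starts giving full containment / total
  p_exact <- mean(null_ovs >= 150)
  expect_lt(abs(r$p_enriched - p_exact), 3 * sqrt(p_exact / 10000) + 1e-4)
  expect_lte(r$p_enriched, 0.75)  # sanity: enrichment side
  # add-one estimator never returns 0
  expect_gt(r$p_enriched, 0)
  expect_gt(r$p_depleted, 0)
})

test_that("permutation results are deterministic and seed-sensitive", {
  gen <- make_genome(c(chr1 = 40000), gap_fraction = 0.05, seed = 3)
  A <- plant_domains(gen, 10, c(500, 2000), seed = 4)
  B <- plant_domains(gen, 8, c(200, 1000), seed = 5)
  plan <- randomization_plan(300, seed = 7)
  r1 <- permutation_enrichment(A, B, gen, plan)
  r2 <- permutation_enrichment(A, B, gen, plan)
  expect_identical(r1, r2)
  r3 <- permutation_enrichment(A, B, gen, randomization_plan(300, seed = 8))
  expect_false(identical(r1$expected_bp, r3$expected_bp))
})

test_that("monotonicity: enlarging A never decreases observed overlap", {
  set.seed(43)
  gen <- toy_genome(c(chrA = 8000))
  for (i in 1:20) {
    A <- random_interval_set(gen, 20)
    B <- random_interval_set(gen, 20)
    A_big <- c(A, random_interval_set(gen, 10))
    expect_gte(intersect_bp(A_big, B), intersect_bp(A, B))
  }
})

test_that("non-overlapping randomization respects the flag", {
  gen <- toy_genome(c(chrA = 5000))
  B <- gr0(gen, rep("chrA", 5), seq(0, 2000, by = 500)[1:5],
           seq(0, 2000, by = 500)[1:5] + 400)
  rb <- randomize_set(B, gen, seed = 11, allow_mutual_overlap = FALSE)
  expect_equal(total_bp(rb), 2000)  # merged total = sum iff no overlaps
})

test_that("enrichment matrix is invariant to input ordering", {
  gen <- make_genome(c(chr1 = 30000), gap_fraction = 0, seed = 2)
  As <- list(x = plant_domains(gen, 5, c(500, 1500), seed = 1),
             y = plant_domains(gen, 5, c(500, 1500), seed = 2))
  Bs <- list(u = plant_domains(gen, 5, c(200, 800), seed = 3),
             v = plant_domains(gen, 5, c(200, 800), seed = 4))
  plan <- randomization_plan(100, seed = 9)
  m1 <- enrichment_matrix(As, Bs, gen, plan)
  m2 <- enrichment_matrix(rev(As), rev(Bs), gen, plan)
  key <- function(m) m[order(m$a_name, m$b_name), ]
  expect_equal(key(m1), key(m2), ignore_attr = TRUE)
})

test_that("degenerate saturation: B covering everything gives fold 1", {
  gen <- make_genome(c(chr1 = 20000), gap_fraction = 0, seed = 6)
  B <- gapfree_regions(gen)  # the whole chromosome: one admissible placement
  A <- gr0(gen, "chr1", 1000, 3000)
  r <- permutation_enrichment(A, B, gen, randomization_plan(50, seed = 1))
  expect_equal(r$fold, 1)
  expect_equal(r$log2_fold, 0)
  expect_equal(r$p_enriched, 1)
})
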