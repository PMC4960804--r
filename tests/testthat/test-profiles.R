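test_that("region windows have exact proportional and flank widths", {
  gen <- toy_genome(c(chrA = 100000))
  w <- region_windows(gr0(gen, "chrA", 20000, 25000), profile_spec())
  expect_equal(nrow(w), 150)
  expect_equal(unique(diff(c(w$start, w$end[150]))), 100)  # 5000/50 = 100
  expect_equal(w$start[1], 20000 - 5000)
  expect_equal(w$end[150], 25000 + 5000)
  expect_equal(w$class, c(rep("flank5", 50), rep("body", 50),
                          rep("flank3", 50)))
  w2 <- region_windows(gr0(gen, "chrA", 20000, 21000), profile_spec())
  expect_equal(w2$end[51] - w2$start[51], 20)  # 1000-bp body -> 20-bp windows
  # minus-strand orientation reverses the index order
  spec <- profile_spec(orient_by_strand = TRUE)
  wm <- region_windows(gr0(gen, "chrA", 20000, 25000), spec, strand = "-")
  expect_equal(wm$index, rev(w$index))
  expect_error(region_windows(gr0(gen, "chrA", 0, 30), profile_spec()),
               "shorter")
})

make_uniform_tags <- function(gen, n, seed, label = "t") {
  set.seed(seed)
  chrom <- sample(names(gen$chrom), n, replace = TRUE,
                  prob = gen$chrom / sum(gen$chrom))
  tag_set(chrom, floor(runif(n, 0, gen$chrom[chrom])),
          sample(c("+", "-"), n, TRUE), gen, label = label)
}

test_that("composite of treatment == control is identically zero", {
  gen <- toy_genome(c(chrA = 200000))
  tg <- make_uniform_tags(gen, 2000, 1)
  regions <- gr0(gen, c("chrA", "chrA"), c(50000, 120000), c(60000, 130000))
  prof <- composite(tg, tg, regions, profile_spec(), gen)
  expect_equal(length(prof$values), 150)
  expect_equal(prof$values, rep(0, 150))
  expect_equal(prof$n_regions_used, 2)
})

test_that("composite window means match the brute-force oracle", {
  gen <- toy_genome(c(chrA = 60000))
  # deterministic step signal: dense fragments over the first half of the
  # region, sparse elsewhere
  pos_t <- c(seq(30000, 30980, by = 7), seq(32000, 33960, by = 90))
  tg <- tag_set(rep("chrA", length(pos_t)), pos_t,
                rep("+", length(pos_t)), gen)
  regions <- gr0(gen, "chrA", 30000, 32000)
  spec <- profile_spec()
  prof <- composite(tg, NULL, regions, spec, gen)
  b <- senescape:::.window_breaks(30000, 32000, spec)
  expected <- vapply(seq_len(150), function(i)
    naive_window_signal(tg, b[i], b[i + 1], "chrA", gen), numeric(1))
  expect_equal(prof$values, expected, tolerance = 1e-9)
})

test_that("flank windows beyond chromosome bounds are dropped per region", {
  gen <- toy_genome(c(chrA = 20000))
  tg <- make_uniform_tags(gen, 500, 2)
  regions <- gr0(gen, c("chrA", "chrA"), c(1000, 10000), c(3000, 12000))
  prof <- composite(tg, NULL, regions, profile_spec(), gen)
  # first region's flank extends to 1000 - 5000 < 0: windows 1..40 invalid
  expect_equal(prof$n_contributing[1:40], rep(1L, 40))
  expect_equal(prof$n_contributing[41:150], rep(2L, 110))
})

test_that("difference composite is antisymmetric and zero on identity", {
  gen <- toy_genome(c(chrA = 100000))
  t1 <- make_uniform_tags(gen, 1000, 3); c1 <- make_uniform_tags(gen, 1000, 4)
  t2 <- make_uniform_tags(gen, 1500, 5); c2 <- make_uniform_tags(gen, 900, 6)
  regions <- gr0(gen, "chrA", 40000, 50000)
  z <- difference_composite(t1, c1, t1, c1, regions, profile_spec(), gen)
  expect_equal(z$values, rep(0, 150))
  d12 <- difference_composite(t1, c1, t2, c2, regions, profile_spec(), gen)
  d21 <- difference_composite(t2, c2, t1, c1, regions, profile_spec(), gen)
  expect_equal(d12$values, -d21$values, tolerance = 1e-12)
})

test_that("strand mirror: reversing coordinates reverses the profile", {
  L <- 50000
  gen <- toy_genome(c(chrA = L))
  set.seed(8)
  n <- 400
  pos <- floor(runif(n, 0, L))
  str <- sample(c("+", "-"), n, TRUE)
  tg <- tag_set(rep("chrA", n), pos, str, gen)
  # mirrored tag set: position L-1-p, strand flipped
  tgm <- tag_set(rep("chrA", n), L - 1 - pos,
                 ifelse(str == "+", "-", "+"), gen)
  spec <- profile_spec(orient_by_strand = TRUE)
  reg <- gr0(gen, "chrA", 20000, 26000, strand = "+")
  regm <- gr0(gen, "chrA", L - 26000, L - 20000, strand = "-")
  p1 <- composite(tg, NULL, reg, spec, gen)
  p2 <- composite(tgm, NULL, regm, spec, gen)
  expect_equal(p2$values, p1$values, tolerance = 1e-12)
})

test_that("methylation composite separates body and flank levels", {
  gen <- toy_genome(c(chrA = 100000))
  reg <- gr0(gen, "chrA", 40000, 45000)
  # CpGs every 20 bp: body at 20 %, elsewhere 80 %
  pos <- seq(30000, 55000, by = 20)
  pct <- ifelse(pos >= 40000 & pos < 45000, 20, 80)
  track <- methylation_track(rep("chrA", length(pos)), pos, pct, gen)
  prof <- methylation_composite(track, reg, profile_spec(), gen)
  expect_equal(prof$values[51:100], rep(20, 50))
  expect_equal(prof$values[c(1:50, 101:150)], rep(80, 100))
  # flat track -> flat profile
  flat <- methylation_track(rep("chrA", length(pos)), pos,
                            rep(80, length(pos)), gen)
  expect_equal(methylation_composite(flat, reg, profile_spec(),
                                     gen)$values, rep(80, 150))
  # empty track -> all-NA values, no error
  empty <- methylation_track(character(0), numeric(0), numeric(0), gen)
  expect_true(all(is.na(methylation_composite(empty, reg, profile_spec(),
                                              gen)$values)))
})

test_that("profile values are independent of region order", {
  gen <- toy_genome(c(chrA = 300000))
  tg <- make_uniform_tags(gen, 3000, 9)
  regions <- gr0(gen, rep("chrA", 3), c(50000, 120000, 200000),
                 c(58000, 135000, 210000))
  p1 <- composite(tg, NULL, regions, profile_spec(), gen)
  p2 <- composite(tg, NULL, rev(regions), profile_spec(), gen)
  expect_equal(p1$values, p2$values)
})

test_that("sahf regions are the late-replicating/H3K9me3 intersection", {
  gen <- toy_genome(c(chrA = 10000))
  lr <- gr0(gen, "chrA", 1000, 5000)
  k9 <- gr0(gen, c("chrA", "chrA"), c(2000, 4500), c(3000, 7000))
  s <- sahf_regions(lr, k9, gen)
  expect_equal(gr_segments(s),
               data.frame(chrom = c("chrA", "chrA"), start = c(2000, 4500),
                          end = c(3000, 5000)))
  expect_equal(length(sahf_regions(gr0(gen, "chrA", 0, 100),
                                   gr0(gen, "chrA", 200, 300), gen)), 0L)
})

test_that("body-window bp-weighted mean equals the whole-body signal", {
  gen <- toy_genome(c(chrA = 80000))
  tg <- make_uniform_tags(gen, 1500, 10)
  reg <- gr0(gen, "chrA", 30000, 35000)  # multiple of 50
  prof <- composite(tg, NULL, reg, profile_spec(), gen)
  whole <- window_signal(tg, reg, gen)
  expect_equal(mean(prof$values[51:100]), whole, tolerance = 1e-12)
})
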