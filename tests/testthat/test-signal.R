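make_big_N <- function(tags, N) { tags$total_reads <- N; tags }

test_that("fragment extension follows strand and clips at bounds", {
  gen <- toy_genome(c(chrA = 100000, tiny = 100))
  tg <- tag_set(c("chrA", "chrA", "tiny"), c(100, 249, 10),
                c("+", "-", "+"), gen)
  fr <- gr_segments(extend_tags(tg, gen))
  fr <- fr[order(fr$chrom, fr$start), ]
  expect_equal(fr$start, c(100, 100, 10))
  expect_equal(fr$end, c(250, 250, 100))
})

test_that("window signal reproduces the hand-computed formula cases", {
  gen <- toy_genome(c(chrA = 100000))
  # 10 fragments fully inside a 1000-bp window, N = 1e6 -> 0.01
  tg <- make_big_N(tag_set(rep("chrA", 10), seq(2000, 2450, by = 50),
                           rep("+", 10), gen), 1e6)
  w <- gr0(gen, "chrA", 2000, 3000)
  expect_equal(window_signal(tg, w, gen), 0.01, tolerance = 1e-12)

  # one fragment with 75 bp inside a 300-bp window -> (0.5/300)/1
  tg1 <- make_big_N(tag_set("chrA", 5000, "+", gen), 1e6)
  w2 <- gr0(gen, "chrA", 5075, 5375)
  expect_equal(window_signal(tg1, w2, gen), (75 / 150 / 300) / 1,
               tolerance = 1e-15)

  # no overlap -> 0
  expect_equal(window_signal(tg1, gr0(gen, "chrA", 90000, 91000), gen), 0)
  expect_error(window_signal(tag_set(character(0), numeric(0),
                                     character(0), gen), w, gen),
               "zero total reads")
})

test_that("window signal matches the brute-force oracle on random data", {
  set.seed(11)
  gen <- toy_genome(c(chrA = 5000, chrB = 3000))
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    chrom <- sample(names(gen$chrom), n, replace = TRUE)
    pos <- floor(runif(n, 0, gen$chrom[chrom]))
    tg <- tag_set(chrom, pos, sample(c("+", "-"), n, TRUE), gen,
                  fragment_length = sample(c(50, 150), 1))
    cn <- sample(names(gen$chrom), 1)
    lo <- sample(0:(gen$chrom[[cn]] - 200), 1)
    hi <- lo + sample(50:200, 1)
    expect_equal(window_signal(tg, gr0(gen, cn, lo, hi), gen),
                 naive_window_signal(tg, lo, hi, cn, gen),
                 tolerance = 1e-12)
  }
})

test_that("per-million invariance and partition additivity hold", {
  set.seed(13)
  gen <- toy_genome(c(chrA = 20000))
  n <- 200
  tg <- tag_set(rep("chrA", n), floor(runif(n, 0, 20000)),
                sample(c("+", "-"), n, TRUE), gen)
  w <- gr0(gen, "chrA", 4000, 6000)
  base <- window_signal(tg, w, gen)
  # integer replication leaves the signal unchanged exactly
  tg3 <- pool_tags(list(tg, tg, tg))
  expect_equal(window_signal(tg3, w, gen), base, tolerance = 1e-14)
  # length-weighted mean over a partition equals the whole-window value
  parts <- gr0(gen, rep("chrA", 4), c(4000, 4500, 5000, 5700),
               c(4500, 5000, 5700, 6000))
  pv <- window_signal(tg, parts, gen)
  wl <- c(500, 500, 700, 300)
  expect_equal(sum(pv * wl) / 2000, base, tolerance = 1e-12)
})

test_that("control subtraction and pooling behave algebraically", {
  set.seed(17)
  gen <- toy_genome(c(chrA = 50000))
  mk <- function(n, seed) {
    set.seed(seed)
    tag_set(rep("chrA", n), floor(runif(n, 0, 50000)),
            sample(c("+", "-"), n, TRUE), gen)
  }
  t1 <- mk(300, 1); t2 <- mk(150, 2)
  w <- gr0(gen, "chrA", 10000, 15000)
  expect_equal(normalized_window_signal(t1, t1, w, gen), 0)
  expect_equal(normalized_window_signal(t1, t2, w, gen),
               window_signal(t1, w, gen) - window_signal(t2, w, gen))
  pooled <- pool_tags(list(t1, t2))
  expect_equal(pooled$total_reads, 450)
  # pooled signal is the read-weighted combination of per-replicate signals
  f1 <- window_signal(t1, w, gen) * t1$total_reads
  f2 <- window_signal(t2, w, gen) * t2$total_reads
  expect_equal(window_signal(pooled, w, gen), (f1 + f2) / 450,
               tolerance = 1e-12)
  t_other <- tag_set("chrA", 5, "+", gen, fragment_length = 100)
  expect_error(pool_tags(list(t1, t_other)), "fragment length")
})

test_that("dedupe keeps one tag per position/strand", {
  gen <- toy_genome(c(chrA = 1000))
  tg <- tag_set(rep("chrA", 4), c(10, 10, 10, 20), c("+", "+", "-", "+"),
                gen)
  expect_equal(dedupe_tags(tg)$total_reads, 3)
})

test_that("tag BED round-trips through read_tags_bed", {
  set.seed(19)
  gen <- toy_genome(c(chrA = 9000, chrB = 4000))
  n <- 100
  chrom <- sample(names(gen$chrom), n, TRUE)
  tg <- tag_set(chrom, floor(runif(n, 0, gen$chrom[chrom])),
                sample(c("+", "-"), n, TRUE), gen)
  p <- withr::local_tempfile(fileext = ".bed")
  write_tags_bed(tg, p)
  back <- read_tags_bed(p, gen)
  expect_equal(back$chrom, tg$chrom)
  expect_equal(back$pos, tg$pos)
  expect_equal(back$strand, tg$strand)
})
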