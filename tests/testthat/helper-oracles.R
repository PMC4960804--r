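# Independent oracles and tiny fixture builders shared across tests.
# The bitmap oracle represents an interval set as a per-base logical vector,
# so set operations reduce to elementwise logic; it is deliberately naive
# and used only on toy genomes (<= tens of kb).

toy_genome <- function(lens = c(chrA = 1000), gaps = NULL) {
  Genome(lens, gaps = gaps)
}

# build a GRanges on `genome` from 0-based half-open triples
gr0 <- function(genome, chrom, start, end, strand = NULL) {
  if (length(chrom) == 0)
    return(senescape:::.gr(data.frame(), genome))
  senescape:::.gr(data.frame(chrom = chrom, start = start, end = end),
                  genome, strand = strand)
}

# per-chromosome logical occupancy vectors
bitmap_from <- function(gr, genome) {
  df <- senescape:::.gr0(gr)
  bm <- lapply(genome$chrom, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    idx <- seq.int(df$start[i] + 1, df$end[i])
    bm[[df$chrom[i]]][idx] <- TRUE
  }
  bm
}

bitmap_total <- function(bm) sum(vapply(bm, sum, numeric(1)))

bitmap_intersect_bp <- function(grA, grB, genome) {
  a <- bitmap_from(grA, genome); b <- bitmap_from(grB, genome)
  sum(mapply(function(x, y) sum(x & y), a, b))
}

bitmap_subtract_bp <- function(grA, grB, genome) {
  a <- bitmap_from(grA, genome); b <- bitmap_from(grB, genome)
  sum(mapply(function(x, y) sum(x & !y), a, b))
}

# bitmap -> merged 0-based intervals, for exact segment-level comparison
bitmap_segments <- function(bm) {
  out <- list()
  for (cn in names(bm)) {
    v <- bm[[cn]]
    if (!any(v)) next
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- c(0, e[-length(e)])
    keep <- r$values
    out[[cn]] <- data.frame(chrom = cn, start = as.numeric(s[keep]),
                            end = as.numeric(e[keep]))
  }
  if (length(out) == 0)
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  else do.call(rbind, out)
}

gr_segments <- function(gr) {
  df <- senescape:::.gr0(gr)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_interval_set <- function(genome, max_n = 50) {
  n <- sample.int(max_n, 1)
  chrom <- sample(names(genome$chrom), n, replace = TRUE)
  L <- genome$chrom[chrom]
  s <- floor(runif(n, 0, L - 1))
  e <- pmin(L, s + 1 + floor(rexp(n, 1 / 50)))
  gr0(genome, chrom, s, e)
}

# brute-force fractional-read window signal from first principles
naive_window_signal <- function(tags, lo, hi, chrom, genome) {
  F <- tags$fragment_length
  f <- 0
  for (i in seq_along(tags$pos)) {
    if (tags$chrom[i] != chrom) next
    if (tags$strand[i] == "+") {
      s <- tags$pos[i]; e <- tags$pos[i] + F
    } else {
      s <- tags$pos[i] - F + 1; e <- tags$pos[i] + 1
    }
    s <- max(s, 0); e <- min(e, genome$chrom[[chrom]])
    f <- f + max(0, min(e, hi) - max(s, lo)) / F
  }
  (f / (hi - lo)) / (tags$total_reads / 1e6)
}

# exhaustive-enumeration expected overlap for one region of length L placed
# uniformly over all admissible starts on a single chromosome
enumerate_expected_overlap <- function(genome, chrom, L, A) {
  m <- genome$stretches[[chrom]]
  adf <- senescape:::.gr0(merge_intervals(A))
  adf <- adf[adf$chrom == chrom, , drop = FALSE]
  ovs <- numeric(0)
  for (k in seq_len(nrow(m))) {
    if (m[k, 2] - m[k, 1] < L) next
    for (s in m[k, 1]:(m[k, 2] - L)) {
      ov <- sum(pmax(0, pmin(adf$end, s + L) - pmax(adf$start, s)))
      ovs <- c(ovs, ov)
    }
  }
  ovs
}

# brute-force mismatch alignment of a read against a repeat unit, all
# phases and both strands
naive_min_mismatch <- function(read, unit = "TTAGGG") {
  u <- nchar(unit)
  len <- nchar(read)
  conc <- strrep(unit, ceiling((len + u) / u))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  best <- Inf
  for (r in c(read, rc)) {
    rch <- strsplit(r, "")[[1]]
    for (off in 0:(u - 1)) {
      ref <- strsplit(substr(conc, off + 1, off + len), "")[[1]]
      best <- min(best, sum(rch != ref))
    }
  }
  best
}
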