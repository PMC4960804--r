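#' Windowed ChIP-seq signal
#'
#' The signal of a window is the total number of fractional reads inside it,
#' divided by the window length, with that quantity divided by the total
#' number of reads in the dataset over one million:
#'
#'   signal = (f / L) / (N / 1e6)
#'
#' where f sums, over all fragment-extended reads, the fraction of each
#' fragment's length falling inside the window, L is the window length in bp
#' and N the dataset's total read count. The result is a per-bp,
#' per-million-reads density: replicating every tag k times leaves it
#' unchanged.
#'
#' @param tags a [tag_set()].
#' @param windows `GRanges` of scoring windows (any number).
#' @param genome a [Genome()].
#' @return numeric vector of signal values, one per window.
#' @examples
#' gen <- Genome(c(chr1 = 1e6))
#' tg <- tag_set(rep("chr1", 10), seq(1000, 1900, 100), rep("+", 10), gen)
#' tg$total_reads <- 1e6  # pretend the dataset has 1M reads
#' @export
window_signal <- function(tags, windows, genome) {
  if (tags$total_reads == 0) stop("tag set has zero total reads")
  w <- .gr0(windows)
  if (any(w$end <= w$start)) stop("window length must be > 0")
  fi <- .fragment_index(tags, genome)
  .signal_from_index(fi, w)
}

.signal_from_index <- function(fi, w) {
  out <- numeric(nrow(w))
  for (cn in unique(w$chrom)) {
    sel <- which(w$chrom == cn)
    bp <- .frag_overlap_bp(fi$idx[[cn]], w$start[sel], w$end[sel])
    f <- bp / fi$fragment_length
    out[sel] <- (f / (w$end[sel] - w$start[sel])) / (fi$total_reads / 1e6)
  }
  out
}

#' Control-subtracted window signal
#'
#' The normalized signal of a window is the treatment signal minus the
#' control signal (histone H4 or input, per experiment design).
#'
#' @param treatment,control [tag_set()]s.
#' @inheritParams window_signal
#' @return numeric vector, may be negative.
#' @export
normalized_window_signal <- function(treatment, control, windows, genome) {
  window_signal(treatment, windows, genome) -
    window_signal(control, windows, genome)
}

#' Control-subtracted signal over arbitrary regions
#'
#' [normalized_window_signal()] with each region as its own window; used for
#' gene bodies and subtelomeric regions.
#'
#' @inheritParams normalized_window_signal
#' @param regions `GRanges` of regions.
#' @export
region_signal <- function(treatment, control, regions, genome) {
  normalized_window_signal(treatment, control, regions, genome)
}

#' Tile a genome into fixed-width windows
#'
#' @param genome a [Genome()].
#' @param width window width in bp; the final window of each chromosome is
#'   truncated at the chromosome end.
#' @return `GRanges` tiling every chromosome.
#' @export
tile_genome <- function(genome, width) {
  stopifnot(width > 0)
  dfs <- lapply(names(genome$chrom), function(cn) {
    L <- genome$chrom[[cn]]
    s <- seq(0, L - 1, by = width)
    data.frame(chrom = cn, start = s, end = pmin(s + width, L))
  })
  .gr(do.call(rbind, dfs), genome)
}
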