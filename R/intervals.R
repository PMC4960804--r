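#' Interval-set algebra
#'
#' Thin genome-aware wrappers around `GenomicRanges` set operations. All
#' per-base-pair statistics operate on the merged (sorted, non-overlapping)
#' form of their inputs so no base is ever counted twice; book-ended
#' intervals (`[0,10)` and `[10,20)`) are joined.
#'
#' @param x,A,B `GRanges` interval sets on the same genome.
#' @param genome a [Genome()]; all sets are checked against it.
#' @name interval-algebra
NULL

#' @describeIn interval-algebra sorted, non-overlapping (merged) form.
#' @export
merge_intervals <- function(x, genome = NULL) {
  if (!is.null(genome)) .check_genome(x, genome)
  GenomicRanges::reduce(GenomicRanges::granges(x), ignore.strand = TRUE)
}

#' @describeIn interval-algebra total base pairs in the merged set.
#' @export
total_bp <- function(x) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(
    GenomicRanges::granges(x), ignore.strand = TRUE))))
}

#' @describeIn interval-algebra base pairs shared by `A` and `B`
#'   (per-bp overlap, symmetric).
#' @export
intersect_bp <- function(A, B, genome = NULL) {
  sum(as.numeric(GenomicRanges::width(intersect_segments(A, B, genome))))
}

#' @describeIn interval-algebra merged set of segments present in both
#'   `A` and `B` (the consensus set of two peak calls).
#' @export
intersect_segments <- function(A, B, genome = NULL) {
  .check_same_genome(A, B, genome)
  GenomicRanges::intersect(GenomicRanges::granges(A),
                           GenomicRanges::granges(B), ignore.strand = TRUE)
}

#' @describeIn interval-algebra merged set of base pairs in `A` not in `B`.
#' @export
subtract_intervals <- function(A, B, genome = NULL) {
  .check_same_genome(A, B, genome)
  GenomicRanges::setdiff(GenomicRanges::granges(A),
                         GenomicRanges::granges(B), ignore.strand = TRUE)
}

.check_same_genome <- function(A, B, genome = NULL) {
  if (!is.null(genome)) {
    .check_genome(A, genome, "set A")
    .check_genome(B, genome, "set B")
    return(invisible(TRUE))
  }
  sa <- GenomeInfoDb::seqlengths(A); sa <- sa[!is.na(sa)]
  sb <- GenomeInfoDb::seqlengths(B); sb <- sb[!is.na(sb)]
  shared <- intersect(names(sa), names(sb))
  if (length(shared) && any(sa[shared] != sb[shared]))
    stop("interval sets are on different genomes")
  invisible(TRUE)
}

#' Summary statistics of a peak set
#'
#' Counts are computed on the merged set, so overlapping or book-ended input
#' records never inflate the peak count or base-pair total.
#'
#' @param x a `GRanges` peak set.
#' @return list with `n_peaks`, `total_bp` and `mean_length` (`NA` for an
#'   empty set).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 201), c(100, 500)))
#' set_stats(gr)
#' @export
set_stats <- function(x) {
  m <- GenomicRanges::reduce(GenomicRanges::granges(x), ignore.strand = TRUE)
  n <- length(m)
  tot <- sum(as.numeric(GenomicRanges::width(m)))
  list(n_peaks = n, total_bp = tot,
       mean_length = if (n > 0) tot / n else NA_real_)
}
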