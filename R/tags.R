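#' Aligned-read tag sets
#'
#' A `TagSet` stores the 5' positions and strands of aligned reads together
#' with the fragment-extension length used for signal computation. Tags are
#' extended to `fragment_length` bp from their 5' end (towards 3'), clipped
#' at chromosome bounds; the unclipped length remains the denominator when a
#' fragment's overlap fraction is computed, so no fragment ever contributes
#' more than one read of mass.
#'
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based 5'-end positions.
#' @param strand character vector of "+"/"-".
#' @param genome a [Genome()].
#' @param fragment_length fragment extension length F in bp (default 150).
#' @param label dataset label used in outputs.
#' @return an object of class `TagSet`.
#' @export
tag_set <- function(chrom, pos, strand, genome, fragment_length = 150,
                    label = "") {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(strand) == n)
  if (fragment_length <= 0) stop("fragment_length must be > 0")
  if (n > 0) {
    if (!all(strand %in% c("+", "-"))) stop("tag strand must be '+' or '-'")
    lens <- genome$chrom[chrom]
    if (anyNA(lens)) stop("tag on unknown chromosome")
    if (any(pos < 0 | pos >= lens)) stop("tag position outside chromosome")
  }
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 strand = as.character(strand),
                 total_reads = n,
                 fragment_length = as.numeric(fragment_length),
                 label = label,
                 chrom_lengths = genome$chrom),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat("TagSet '", x$label, "': ", format(x$total_reads, big.mark = ","),
      " tags, fragment length ", x$fragment_length, " bp\n", sep = "")
  invisible(x)
}

#' Pool replicate tag sets
#'
#' Concatenates the tags of all replicates; the pooled read total is the sum
#' of the replicate totals. All replicates must share the genome and the
#' fragment length.
#'
#' @param replicates list of `TagSet`s.
#' @param label label for the pooled set.
#' @return a pooled `TagSet`.
#' @export
pool_tags <- function(replicates, label = "pooled") {
  stopifnot(length(replicates) >= 1)
  f <- unique(vapply(replicates, `[[`, numeric(1), "fragment_length"))
  if (length(f) != 1L) stop("replicates have different fragment lengths")
  for (r in replicates[-1])
    if (!identical(r$chrom_lengths, replicates[[1]]$chrom_lengths))
      stop("replicates are on different genomes")
  out <- replicates[[1]]
  out$chrom <- unlist(lapply(replicates, `[[`, "chrom"), use.names = FALSE)
  out$pos <- unlist(lapply(replicates, `[[`, "pos"), use.names = FALSE)
  out$strand <- unlist(lapply(replicates, `[[`, "strand"), use.names = FALSE)
  out$total_reads <- length(out$chrom)
  out$label <- label
  out
}

#' Collapse duplicate tags (redundancy threshold of 1)
#'
#' Keeps at most one tag per exact (chromosome, position, strand) triple.
#'
#' @param tags a `TagSet`.
#' @return a deduplicated `TagSet` with updated `total_reads`.
#' @export
dedupe_tags <- function(tags) {
  keep <- !duplicated(paste(tags$chrom, tags$pos, tags$strand))
  tags$chrom <- tags$chrom[keep]
  tags$pos <- tags$pos[keep]
  tags$strand <- tags$strand[keep]
  tags$total_reads <- sum(keep)
  tags
}

#' Extend a tag to its fragment interval
#'
#' A "+" tag at 5' position p becomes `[p, p+F)`; a "-" tag becomes
#' `[p-F+1, p+1)`; both are clipped to chromosome bounds.
#'
#' @param tags a `TagSet`.
#' @param genome a [Genome()].
#' @return `GRanges` of extended (clipped) fragments, one per tag.
#' @export
extend_tags <- function(tags, genome) {
  fr <- .fragment_coords(tags, genome)
  .gr(data.frame(chrom = tags$chrom, start = fr$s, end = fr$e), genome)
}

# 0-based half-open fragment coordinates, clipped to chromosome bounds.
.fragment_coords <- function(tags, genome) {
  F <- tags$fragment_length
  lens <- genome$chrom[tags$chrom]
  plus <- tags$strand == "+"
  s <- ifelse(plus, tags$pos, tags$pos - F + 1)
  e <- ifelse(plus, tags$pos + F, tags$pos + 1)
  list(s = pmax(0, s), e = pmin(lens, e))
}

# Per-chromosome fragment index for fast overlap sums.
# Cum(x) = total fragment bp in (-inf, x) = sum(min(e, x)) - sum(min(s, x)).
.fragment_index <- function(tags, genome) {
  fr <- .fragment_coords(tags, genome)
  idx <- list()
  for (cn in unique(tags$chrom)) {
    sel <- tags$chrom == cn
    s <- sort(fr$s[sel]); e <- sort(fr$e[sel])
    idx[[cn]] <- list(s = s, e = e, ps = cumsum(s), pe = cumsum(e),
                      n = length(s))
  }
  structure(list(idx = idx, total_reads = tags$total_reads,
                 fragment_length = tags$fragment_length, label = tags$label),
            class = "fragment_index")
}

# Sum over fragments of min(v, x), for sorted v with prefix sums pv.
.sum_min <- function(v, pv, n, x) {
  k <- findInterval(x, v)
  c(0, pv)[k + 1] + (n - k) * x
}

# Total fragment-bp overlap with [lo, hi) for one chromosome index entry;
# lo/hi may be real-valued (fractional composite-window boundaries).
.frag_overlap_bp <- function(ci, lo, hi) {
  if (is.null(ci) || ci$n == 0L) return(rep(0, length(lo)))
  cum_hi <- .sum_min(ci$e, ci$pe, ci$n, hi) - .sum_min(ci$s, ci$ps, ci$n, hi)
  cum_lo <- .sum_min(ci$e, ci$pe, ci$n, lo) - .sum_min(ci$s, ci$ps, ci$n, lo)
  cum_hi - cum_lo
}

#' Read a tag set from a 6-column BED file
#'
#' The 5' end of each record is its start (+ strand) or `end - 1` (- strand).
#'
#' @param path BED6 path (strand in column 6).
#' @param genome a [Genome()].
#' @param fragment_length fragment extension length (default 150).
#' @param label dataset label (defaults to the file name).
#' @return a `TagSet`.
#' @export
read_tags_bed <- function(path, genome, fragment_length = 150,
                          label = basename(path)) {
  gr <- read_bed(path, genome, keep_strand = TRUE)
  str <- as.character(GenomicRanges::strand(gr))
  if (length(gr) && any(str == "*"))
    stop("tag BED requires strand in column 6: ", path)
  df <- .gr0(gr)
  pos <- ifelse(str == "+", df$start, df$end - 1)
  tag_set(df$chrom, pos, str, genome, fragment_length = fragment_length,
          label = label)
}

#' Write a tag set as 6-column BED
#'
#' Tags are written as 1-bp intervals at the 5' position, which round-trips
#' exactly through [read_tags_bed()].
#'
#' @param tags a `TagSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tags_bed <- function(tags, path) {
  dt <- data.table::data.table(tags$chrom, as.integer(tags$pos),
                               as.integer(tags$pos + 1), ".", 0L, tags$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  if (nrow(dt) == 0L) file.create(path)
  invisible(path)
}
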