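#' Genome model: chromosome sizes plus assembly gaps
#'
#' A `Genome` holds the named chromosome lengths of an assembly together with
#' the set of unsequenced ("gap") regions that interval randomization and tag
#' simulation must avoid. Gap-free stretches are precomputed per chromosome at
#' construction, since every placement operation needs them.
#'
#' @param chrom_lengths named integer-ish vector of chromosome lengths (bp).
#'   Names are chromosome names and must be unique; lengths must be > 0.
#' @param gaps optional `GRanges` of unsequenced/excluded regions (or `NULL`
#'   for a gap-free genome). Every gap must lie within its chromosome bounds.
#' @return an object of class `Genome` with elements `chrom` (named numeric
#'   lengths), `gaps` (merged `GRanges`) and `stretches` (per-chromosome
#'   two-column matrices of 0-based half-open gap-free intervals).
#' @examples
#' gen <- Genome(c(chr1 = 10000, chr2 = 5000))
#' gapfree_bp(gen)
#' @export
Genome <- function(chrom_lengths, gaps = NULL) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be unique")
  len <- as.numeric(chrom_lengths)
  if (anyNA(len) || any(len <= 0))
    stop("all chromosome lengths must be positive")
  names(len) <- names(chrom_lengths)

  if (is.null(gaps)) {
    gaps <- GenomicRanges::GRanges()
  } else {
    stopifnot(methods::is(gaps, "GRanges"))
    bad <- !(as.character(GenomicRanges::seqnames(gaps)) %in% names(len))
    if (any(bad))
      stop("gap on unknown chromosome: ",
           paste(unique(as.character(GenomicRanges::seqnames(gaps))[bad]),
                 collapse = ", "))
    gl <- len[as.character(GenomicRanges::seqnames(gaps))]
    if (any(GenomicRanges::start(gaps) < 1 | GenomicRanges::end(gaps) > gl))
      stop("gap interval outside chromosome bounds")
    gaps <- GenomicRanges::reduce(gaps)
  }

  g <- structure(list(chrom = len, gaps = gaps), class = "Genome")
  g$stretches <- .gapfree_stretches(g)
  g
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome:", length(x$chrom), "chromosome(s),",
      format(sum(x$chrom), big.mark = ","), "bp,",
      length(x$gaps), "gap(s) (",
      format(sum(GenomicRanges::width(x$gaps)), big.mark = ","), "bp )\n")
  invisible(x)
}

# Per-chromosome gap-free stretches as 0-based half-open [start, end) matrices.
.gapfree_stretches <- function(genome) {
  out <- vector("list", length(genome$chrom))
  names(out) <- names(genome$chrom)
  gd <- .gr0(genome$gaps)
  for (cn in names(genome$chrom)) {
    L <- genome$chrom[[cn]]
    gc <- gd[gd$chrom == cn, , drop = FALSE]
    if (nrow(gc) == 0L) {
      out[[cn]] <- cbind(start = 0, end = L)
      next
    }
    gc <- gc[order(gc$start), , drop = FALSE]
    s <- c(0, gc$end)
    e <- c(gc$start, L)
    keep <- e > s
    out[[cn]] <- cbind(start = s[keep], end = e[keep])
  }
  out
}

#' Total gap-free base pairs of a genome
#' @param genome a [Genome()] object.
#' @return numeric scalar, base pairs outside assembly gaps.
#' @export
gapfree_bp <- function(genome) {
  sum(vapply(genome$stretches, function(m) sum(m[, 2] - m[, 1]), numeric(1)))
}

#' Gap-free regions of a genome as a GRanges
#' @param genome a [Genome()] object.
#' @return `GRanges` of the complement of the gap set, clipped to chromosomes.
#' @export
gapfree_regions <- function(genome) {
  dfs <- lapply(names(genome$stretches), function(cn) {
    m <- genome$stretches[[cn]]
    data.frame(chrom = cn, start = m[, 1], end = m[, 2])
  })
  .gr(do.call(rbind, dfs), genome)
}

#' Read a two-column chrom.sizes table
#'
#' @param path path to a tab/whitespace separated file with columns
#'   chromosome name and length.
#' @param gaps optional `GRanges` of assembly gaps to attach.
#' @return a [Genome()].
#' @export
read_chrom_sizes <- function(path, gaps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("chrom.sizes must have two columns")
  len <- as.numeric(dt[[2L]])
  names(len) <- dt[[1L]]
  Genome(len, gaps = gaps)
}

#' Write a chrom.sizes table
#' @param genome a [Genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  data.table::fwrite(
    data.table::data.table(chrom = names(genome$chrom),
                           length = as.integer(genome$chrom)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---- internal coordinate plumbing ------------------------------------------

# GRanges -> 0-based half-open data.frame(chrom, start, end)
.gr0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges with the genome's seqinfo
.gr <- function(df, genome, strand = NULL) {
  if (nrow(df) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
      strand = if (is.null(strand)) "*" else strand)
  }
  .set_genome(gr, genome)
}

.set_genome <- function(gr, genome) {
  sl <- genome$chrom
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- as.integer(sl)
  gr
}

# Error unless gr's seqlengths agree with the genome (same assembly).
.check_genome <- function(gr, genome, what = "interval set") {
  sl <- GenomeInfoDb::seqlengths(gr)
  sl <- sl[!is.na(sl)]
  tgt <- genome$chrom[names(sl)]
  if (length(sl) && (anyNA(tgt) || any(tgt != sl)))
    stop(what, " does not match the genome (seqlengths differ)")
  bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(genome$chrom))
  if (any(bad))
    stop(what, " uses unknown chromosome(s): ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
               collapse = ", "))
  invisible(TRUE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-stage seed derived from a master seed and a label.
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% (2^31 - 1))
}
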