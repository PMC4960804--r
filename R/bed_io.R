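#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` uses the
#' usual 1-based closed convention. Records are validated against the genome:
#' unknown chromosomes, zero-length intervals and malformed lines are errors
#' that name the offending line.
#'
#' @param path path to a tab-separated BED file with at least 3 columns.
#' @param genome a [Genome()] the records must belong to.
#' @param clip_out_of_bounds if `TRUE`, records extending past chromosome
#'   ends are truncated to the chromosome bounds; if `FALSE` (default) such
#'   records are an error.
#' @param keep_strand if `TRUE` and a 6th column is present, strand is kept.
#' @return an (unmerged) `GRanges` preserving input record order.
#' @export
read_bed <- function(path, genome, clip_out_of_bounds = FALSE,
                     keep_strand = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) return(.gr(data.frame(), genome))
  if (ncol(dt) < 3L) stop("BED file must have at least 3 columns: ", path)
  chrom <- dt[[1L]]
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED record at line ", bad[1L], " of ", path)
  unknown <- which(!(chrom %in% names(genome$chrom)))
  if (length(unknown))
    stop("unknown chromosome '", chrom[unknown[1L]], "' at line ",
         unknown[1L], " of ", path)
  if (any(start < 0))
    stop("negative start at line ", which(start < 0)[1L], " of ", path)
  zl <- which(start >= end)
  if (length(zl))
    stop("zero- or negative-length interval at line ", zl[1L], " of ", path)
  lens <- genome$chrom[chrom]
  oob <- which(end > lens)
  if (length(oob)) {
    if (clip_out_of_bounds) {
      end <- pmin(end, lens)
      start <- pmin(start, end - 1)
    } else {
      stop("interval beyond chromosome end at line ", oob[1L], " of ", path,
           " (use clip_out_of_bounds = TRUE to truncate)")
    }
  }
  strand <- NULL
  if (keep_strand && ncol(dt) >= 6L) {
    strand <- dt[[6L]]
    strand[!(strand %in% c("+", "-"))] <- "*"
  }
  .gr(data.frame(chrom = chrom, start = start, end = end), genome,
      strand = strand)
}

#' Write a GRanges as BED
#'
#' Emits BED3, or BED6 (name ".", score 0) when `strand = TRUE`.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param strand write a 6-column BED carrying strand.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, strand = FALSE) {
  df <- .gr0(gr)
  if (strand) {
    dt <- data.table::data.table(df$chrom, as.integer(df$start),
                                 as.integer(df$end), ".", 0L,
                                 as.character(GenomicRanges::strand(gr)))
  } else {
    dt <- data.table::data.table(df$chrom, as.integer(df$start),
                                 as.integer(df$end))
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  if (nrow(dt) == 0L) file.create(path)
  invisible(path)
}

#' Write tiled signal windows as bedGraph
#'
#' @param windows `GRanges` of non-overlapping windows.
#' @param values numeric signal values, one per window.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, values, path) {
  stopifnot(length(windows) == length(values))
  if (length(windows)) {
    red <- GenomicRanges::reduce(windows)
    if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(windows)))
      stop("bedGraph windows must be non-overlapping")
  }
  df <- .gr0(windows)
  dt <- data.table::data.table(df$chrom, as.integer(df$start),
                               as.integer(df$end), values)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  if (nrow(dt) == 0L) file.create(path)
  invisible(path)
}

#' Read a 4-column bedGraph
#' @param path bedGraph path.
#' @param genome a [Genome()].
#' @return list with `windows` (`GRanges`) and `values` (numeric).
#' @export
read_bedgraph <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    return(list(windows = .gr(data.frame(), genome), values = numeric(0)))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L) stop("bedGraph must have 4 columns")
  gr <- .gr(data.frame(chrom = dt[[1L]], start = as.numeric(dt[[2L]]),
                       end = as.numeric(dt[[3L]])), genome)
  list(windows = gr, values = as.numeric(dt[[4L]]))
}
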