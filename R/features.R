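#' Construct standard genomic feature sets
#'
#' Builds the annotation-derived interval sets used as the columns of the
#' feature-enrichment matrix: gene promoters (the region spanning +/- 2 kb of
#' the transcription start site), gene bodies, CpG islands, CpG island shores
#' (the 2 kb flanking each island, excluding island bp) and shelves (the 2 kb
#' flanking the shores, excluding island and shore bp). All sets are clipped
#' to chromosome bounds and merged.
#'
#' @param genes gene table (`data.frame`) with columns `chrom`, `tss`, `tes`,
#'   `strand` (0-based bp positions; `tss` is the transcription start on the
#'   gene's own strand). May be `NULL` to skip gene-derived sets.
#' @param cpg_islands optional `GRanges` of CpG islands.
#' @param genome a [Genome()].
#' @param promoter_bp half-width of the promoter window (default 2000).
#' @param flank_bp width of each shore/shelf flank (default 2000).
#' @return named list of merged `GRanges`: `promoter`, `gene_body`,
#'   `cpg_island`, `cpg_shore`, `cpg_shelf` (present when inputs allow).
#' @export
build_feature_sets <- function(genes = NULL, cpg_islands = NULL, genome,
                               promoter_bp = 2000, flank_bp = 2000) {
  out <- list()
  if (!is.null(genes)) {
    need <- c("chrom", "tss", "tes", "strand")
    if (!all(need %in% names(genes)))
      stop("gene table must have columns: ", paste(need, collapse = ", "))
    if (anyNA(genes$strand) || !all(genes$strand %in% c("+", "-")))
      stop("gene table has missing or invalid strand")
    lens <- genome$chrom[genes$chrom]
    if (anyNA(lens)) stop("gene on unknown chromosome")
    prom <- data.frame(chrom = genes$chrom,
                       start = pmax(0, genes$tss - promoter_bp),
                       end = pmin(lens, genes$tss + promoter_bp))
    out$promoter <- merge_intervals(.gr(prom, genome))
    body <- data.frame(chrom = genes$chrom,
                       start = pmin(genes$tss, genes$tes),
                       end = pmax(genes$tss, genes$tes))
    out$gene_body <- merge_intervals(.gr(body, genome))
  }
  if (!is.null(cpg_islands)) {
    .check_genome(cpg_islands, genome, "CpG islands")
    isl <- merge_intervals(cpg_islands)
    out$cpg_island <- isl
    shore_raw <- .flank_both(isl, flank_bp, genome)
    out$cpg_shore <- subtract_intervals(shore_raw, isl)
    shelf_raw <- .flank_both(.expand(isl, flank_bp, genome), flank_bp, genome)
    out$cpg_shelf <- subtract_intervals(
      shelf_raw, GenomicRanges::union(isl, out$cpg_shore))
  }
  out
}

# 2 kb (or w bp) on each side of every interval, clipped to bounds, merged.
.flank_both <- function(gr, w, genome) {
  df <- .gr0(gr)
  lens <- genome$chrom[df$chrom]
  up <- data.frame(chrom = df$chrom, start = pmax(0, df$start - w),
                   end = df$start)
  dn <- data.frame(chrom = df$chrom, start = df$end,
                   end = pmin(lens, df$end + w))
  both <- rbind(up[up$end > up$start, ], dn[dn$end > dn$start, ])
  merge_intervals(.gr(both, genome))
}

.expand <- function(gr, w, genome) {
  df <- .gr0(gr)
  lens <- genome$chrom[df$chrom]
  merge_intervals(.gr(data.frame(chrom = df$chrom,
                                 start = pmax(0, df$start - w),
                                 end = pmin(lens, df$end + w)), genome))
}
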