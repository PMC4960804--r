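#' Read a transposable-element annotation table
#'
#' Tab-separated with columns `chrom`, `start`, `end` (0-based half-open),
#' `subtype`, `class` and `order_rank` (1 = most ancient). The evolutionary
#' order is consumed as a precomputed rank; subfamily ages are not
#' re-derived here.
#'
#' @param path TSV path.
#' @param genome a [Genome()].
#' @return `data.frame` of TE records.
#' @export
read_te_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("chrom", "start", "end", "subtype", "order_rank")
  if (!all(need %in% names(dt)))
    stop("TE table must have columns: ", paste(need, collapse = ", "))
  rk <- unique(dt[, c("subtype", "order_rank")])
  if (anyDuplicated(rk$subtype))
    stop("subtype with more than one order_rank")
  if (any(dt$order_rank < 1)) stop("order_rank must be >= 1")
  dt
}

#' TE-subtype enrichment by evolutionary order
#'
#' For each TE subtype, the observed/expected per-bp overlap of the peak set
#' with the subtype's intervals, by matched permutation; output rows are
#' ordered by `order_rank` (ancient to recent). With `offset_normalize`, the
#' minimum of the log2 fold series is added to every value (the offset
#' applied to plotted series), reported in `value_offset`.
#'
#' @param te TE table (see [read_te_table()]).
#' @param peaks `GRanges` peak set (set A of the permutation test).
#' @param genome a [Genome()].
#' @param plan a [randomization_plan()]; each subtype's seed is derived from
#'   the plan seed and the subtype name, so results are independent of input
#'   row order.
#' @param offset_normalize add the series minimum to all log2 fold values.
#' @return `data.frame` ordered by `order_rank` with columns `subtype`,
#'   `te_class`, `order_rank`, `n_intervals`, `observed_bp`, `expected_bp`,
#'   `fold`, `log2_fold`, `p_enriched`, `p_depleted` and (optionally)
#'   `value_offset`.
#' @export
te_order_enrichment <- function(te, peaks, genome,
                                plan = randomization_plan(),
                                offset_normalize = FALSE) {
  subs <- unique(te[, c("subtype", "order_rank")])
  subs <- subs[order(subs$order_rank, subs$subtype), , drop = FALSE]
  rows <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    st <- subs$subtype[i]
    d <- te[te$subtype == st, , drop = FALSE]
    if (nrow(d) == 0) stop("subtype with no intervals: ", st)
    B <- .gr(data.frame(chrom = d$chrom, start = d$start, end = d$end),
             genome)
    p <- plan
    if (!is.null(plan$seed)) p$seed <- .derive_seed(plan$seed, st)
    r <- permutation_enrichment(peaks, B, genome, p)
    rows[[i]] <- data.frame(
      subtype = st,
      te_class = if ("class" %in% names(d)) d$class[1] else NA_character_,
      order_rank = subs$order_rank[i], n_intervals = nrow(d),
      observed_bp = r$observed_bp, expected_bp = r$expected_bp,
      fold = r$fold, log2_fold = r$log2_fold,
      p_enriched = r$p_enriched, p_depleted = r$p_depleted,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (offset_normalize)
    out$value_offset <- out$log2_fold + min(out$log2_fold, na.rm = TRUE)
  out
}
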