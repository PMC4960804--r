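#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `name`, `chrom`, `tss`, `tes`,
#' `strand`, `biotype`, `family` and one `fpkm_<condition>` column per
#' expression condition. `tss`/`tes` are 0-based bp; the gene body is
#' `[min(tss, tes), max(tss, tes))`.
#'
#' @param path TSV path.
#' @param genome a [Genome()] for validation.
#' @return `data.frame` of gene records.
#' @export
read_gene_table <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("gene_id", "chrom", "tss", "tes", "strand")
  if (!all(need %in% names(dt)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (!any(grepl("^fpkm_", names(dt))))
    stop("gene table must have at least one fpkm_<condition> column")
  if (any(dt$tss == dt$tes)) stop("zero-length gene body")
  if (!is.null(genome)) {
    lens <- genome$chrom[dt$chrom]
    if (anyNA(lens)) stop("gene on unknown chromosome")
    if (any(pmax(dt$tss, dt$tes) > lens) || any(pmin(dt$tss, dt$tes) < 0))
      stop("gene body outside chromosome bounds")
  }
  dt
}

#' Gene bodies as a stranded GRanges
#' @param genes gene table.
#' @param genome a [Genome()].
#' @return `GRanges` in gene-table order, named by `gene_id`.
#' @export
gene_bodies <- function(genes, genome) {
  gr <- .gr(data.frame(chrom = genes$chrom,
                       start = pmin(genes$tss, genes$tes),
                       end = pmax(genes$tss, genes$tes)),
            genome, strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}

#' Per-gene body ChIP enrichment
#'
#' Control-subtracted signal over each gene body (treatment minus histone H4
#' by default semantics); a ratio mode divides instead of subtracting.
#'
#' @param genes gene table.
#' @param treatment,control [tag_set()]s.
#' @param genome a [Genome()].
#' @param exclude_families character vector of `family` labels to drop
#'   (e.g. the repeat-derived gene class), or `NULL`.
#' @param mode "subtract" (default) or "ratio".
#' @return `data.frame` with `gene_id`, `family`, `signal`.
#' @export
gene_body_enrichment <- function(genes, treatment, control, genome,
                                 exclude_families = NULL,
                                 mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  if (!is.null(exclude_families) && "family" %in% names(genes))
    genes <- genes[!(genes$family %in% exclude_families), , drop = FALSE]
  if (nrow(genes) == 0) stop("no genes after family filtering")
  gb <- gene_bodies(genes, genome)
  ts <- window_signal(treatment, gb, genome)
  cs <- window_signal(control, gb, genome)
  sig <- if (mode == "subtract") ts - cs else ts / ifelse(cs > 0, cs, NA)
  data.frame(gene_id = genes$gene_id,
             family = if ("family" %in% names(genes)) genes$family
                      else NA_character_,
             signal = sig, stringsAsFactors = FALSE)
}

#' Gene families among the most-enriched gene bodies
#'
#' Sorts genes by decreasing enrichment (ties broken by `gene_id` for
#' determinism), then tabulates the family labels of the `top_n` genes and,
#' for the background, of all genes.
#'
#' @param enrichment output of [gene_body_enrichment()].
#' @param top_n number of top genes to tabulate (default 500).
#' @return list with `top` and `background` family-count tables (sorted
#'   decreasing) and `top_genes`, the ranked `gene_id`s.
#' @export
rank_and_top_families <- function(enrichment, top_n = 500) {
  stopifnot(top_n <= nrow(enrichment))
  o <- order(-enrichment$signal, enrichment$gene_id)
  ranked <- enrichment[o, , drop = FALSE]
  top <- ranked[seq_len(top_n), , drop = FALSE]
  list(top = sort(table(top$family), decreasing = TRUE),
       background = sort(table(enrichment$family), decreasing = TRUE),
       top_genes = top$gene_id)
}

#' Expression quartile assignment
#'
#' Genes with FPKM 0 form the `UN` (unexpressed) class; the remaining genes
#' are sorted by decreasing FPKM and split into four contiguous near-equal
#' groups, `Q1` highest to `Q4` lowest. Boundary ties are broken by
#' `gene_id`.
#'
#' @param genes gene table.
#' @param condition condition name; FPKMs are read from
#'   `fpkm_<condition>`.
#' @return named character vector `gene_id -> label` with labels in
#'   `Q1`..`Q4`, `UN`.
#' @export
expression_quartiles <- function(genes, condition) {
  col <- paste0("fpkm_", condition)
  if (!col %in% names(genes)) stop("no column ", col, " in gene table")
  fpkm <- genes[[col]]
  if (any(fpkm < 0)) stop("negative FPKM")
  lab <- rep(NA_character_, nrow(genes))
  lab[fpkm == 0] <- "UN"
  expr <- which(fpkm > 0)
  if (length(expr)) {
    o <- expr[order(-fpkm[expr], genes$gene_id[expr])]
    m <- length(o)
    sizes <- rep(m %/% 4, 4)
    if (m %% 4 > 0) sizes[seq_len(m %% 4)] <- sizes[seq_len(m %% 4)] + 1
    lab[o] <- rep(paste0("Q", 1:4), times = sizes)
  }
  stats::setNames(lab, genes$gene_id)
}

#' Strand-oriented composite profiles per expression class
#'
#' One gene-body composite (TSS to TES orientation) per quartile label.
#'
#' @param genes gene table.
#' @param assignment output of [expression_quartiles()].
#' @param treatment,control [tag_set()]s.
#' @param spec a [profile_spec()]; strand orientation is forced on.
#' @param genome a [Genome()].
#' @return named list of `composite_profile`s (`Q1`..`Q4`, `UN`); empty
#'   classes are skipped with a warning.
#' @export
quartile_composites <- function(genes, assignment, treatment, control,
                                spec = profile_spec(orient_by_strand = TRUE),
                                genome) {
  spec$orient_by_strand <- TRUE
  gb <- gene_bodies(genes, genome)
  out <- list()
  for (lab in c("Q1", "Q2", "Q3", "Q4", "UN")) {
    ids <- names(assignment)[assignment == lab & !is.na(assignment)]
    if (length(ids) == 0) {
      warning("no genes in class ", lab)
      next
    }
    out[[lab]] <- composite(treatment, control, gb[ids], spec, genome)
  }
  out
}

#' Spearman rank correlation
#'
#' Average ranks are used for ties (`stats::cor`, method "spearman").
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return rho, or `NA` with a warning when either ranking is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("constant ranks; spearman undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Pearson correlation and coefficient of determination
#'
#' @param x,y numeric vectors of equal length (at least 3), non-constant.
#' @return list with `r` and `r_squared`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; pearson undefined")
    return(list(r = NA_real_, r_squared = NA_real_))
  }
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Expression z-score against a reference population
#'
#' The number of standard deviations an expression value lies from the mean
#' of a reference population (sample standard deviation, n - 1).
#'
#' @param value expression value.
#' @param reference numeric vector of reference expression values (>= 2).
#' @return z-score, `NA` with warning when the reference s.d. is zero.
#' @export
expression_zscore <- function(value, reference) {
  stopifnot(length(reference) >= 2)
  s <- stats::sd(reference)
  if (s == 0) {
    warning("zero reference standard deviation; z undefined")
    return(NA_real_)
  }
  (value - mean(reference)) / s
}

#' Signal-change versus baseline-expression table
#'
#' Pass-through long-format table pairing each gene's ChIP signal difference
#' with its baseline FPKM, for scatter plots and correlations.
#'
#' @param gene_ids character vector of gene ids.
#' @param delta_signal per-gene signal difference (e.g. senescent minus
#'   proliferating), aligned with `gene_ids`.
#' @param baseline_fpkm per-gene baseline FPKM, aligned with `gene_ids`.
#' @return `data.frame(gene_id, delta_signal, baseline_fpkm)`.
#' @export
delta_scatter_table <- function(gene_ids, delta_signal, baseline_fpkm) {
  if (length(gene_ids) == 0) stop("empty gene set")
  stopifnot(length(delta_signal) == length(gene_ids),
            length(baseline_fpkm) == length(gene_ids))
  data.frame(gene_id = gene_ids, delta_signal = delta_signal,
             baseline_fpkm = baseline_fpkm, stringsAsFactors = FALSE)
}
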