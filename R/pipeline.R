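#' Validate and complete a run configuration
#'
#' Fills parameter defaults (10,000 permutations, 150-bp fragments, the
#' 50/50/100 composite window layout, mismatch allowance 2, top-500 gene
#' ranking), checks parameter ranges and that every referenced input file
#' exists, and reports all problems together. Unknown keys produce a warning
#' only.
#'
#' @param config named list, typically paths into a [scenario_senescence()]
#'   bundle plus parameter overrides, or a YAML file path (requires the
#'   `yaml` package).
#' @return validated config list with all defaults filled.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    input_dir = NULL, out_dir = NULL, seed = 1,
    n_permutations = 10000, fragment_length = 150,
    n_body_windows = 50, n_flank_windows = 50, flank_window_bp = 100,
    max_mismatch = 2, top_n = 500, offset_normalize = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  errs <- character(0)
  if (is.null(cfg$input_dir)) errs <- c(errs, "input_dir is required")
  else if (!dir.exists(cfg$input_dir))
    errs <- c(errs, paste0("input_dir does not exist: ", cfg$input_dir))
  if (is.null(cfg$out_dir)) errs <- c(errs, "out_dir is required")
  for (p in c("n_permutations", "fragment_length", "n_body_windows",
              "flank_window_bp", "top_n"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 1)
      errs <- c(errs, paste0(p, " must be >= 1"))
  if (!is.numeric(cfg$max_mismatch) || cfg$max_mismatch < 0)
    errs <- c(errs, "max_mismatch must be >= 0")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Run the full downstream analysis on a scenario bundle
#'
#' Chains every stage on the files of a [scenario_senescence()] bundle (or
#' real data laid out the same way): consensus peak statistics, the
#' feature-overlap enrichment matrix, domain and SAHF composite profiles
#' (including the senescent-minus-proliferating difference and percent
#' methylation), telomeric read quantification, TE evolutionary-order
#' enrichment, gene-body enrichment ranking with family tables, expression
#' quartiles with metagene composites, and the signal-change versus
#' expression scatter table with its correlations. All outputs are TSV plus
#' a JSON run manifest; identical inputs and seed reproduce identical
#' outputs.
#'
#' @param config a config list or YAML path accepted by [validate_config()].
#' @return invisibly, a named list of output paths plus in-memory results.
#' @export
run_all <- function(config) {
  cfg <- validate_config(config)
  ind <- cfg$input_dir
  outd <- cfg$out_dir
  dir.create(outd, showWarnings = FALSE, recursive = TRUE)
  ip <- function(x) file.path(ind, x)
  op <- function(x) file.path(outd, x)
  log_lines <- c(sprintf("senescape run, seed %s", cfg$seed),
                 sprintf("parameters: %s",
                         paste(names(cfg), vapply(cfg, function(v)
                           paste(format(v), collapse = ","), ""),
                           collapse = "; ", sep = "=")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  spec_body <- profile_spec(cfg$n_body_windows, cfg$n_flank_windows,
                            cfg$flank_window_bp)
  genome <- stage("load", {
    gaps_gr <- NULL
    gsizes <- read_chrom_sizes(ip("genome.chrom.sizes"))
    if (file.exists(ip("gaps.bed")) && file.size(ip("gaps.bed")) > 0)
      gaps_gr <- read_bed(ip("gaps.bed"), gsizes)
    Genome(gsizes$chrom, gaps = gaps_gr)
  })
  domains <- read_bed(ip("h3k9me3_domains.bed"), genome)
  late_rep <- read_bed(ip("late_replicating.bed"), genome)
  hypometh <- read_bed(ip("hypomethylated.bed"), genome)
  neutral <- read_bed(ip("neutral_control.bed"), genome)
  ab1 <- read_bed(ip("h4k20me3_peaks_ab1.bed"), genome)
  ab2 <- read_bed(ip("h4k20me3_peaks_ab2.bed"), genome)
  tags_rs <- read_tags_bed(ip("tags_rs_h4k20me3.bed"), genome,
                           cfg$fragment_length, "RS_H4K20me3")
  tags_pro <- read_tags_bed(ip("tags_pro_h4k20me3.bed"), genome,
                            cfg$fragment_length, "PRO_H4K20me3")
  h4_rs <- read_tags_bed(ip("tags_rs_h4.bed"), genome,
                         cfg$fragment_length, "RS_H4")
  h4_pro <- read_tags_bed(ip("tags_pro_h4.bed"), genome,
                          cfg$fragment_length, "PRO_H4")
  genes <- read_gene_table(ip("genes.tsv"), genome)
  te <- read_te_table(ip("te.tsv"), genome)

  out <- list()

  # consensus peak set from the two antibody tracks + its summary stats
  consensus <- stage("consensus_peaks", intersect_segments(ab1, ab2, genome))
  st <- set_stats(consensus)
  stats_df <- data.frame(set = c("ab1", "ab2", "consensus"),
                         n_peaks = c(set_stats(ab1)$n_peaks,
                                     set_stats(ab2)$n_peaks, st$n_peaks),
                         total_bp = c(set_stats(ab1)$total_bp,
                                      set_stats(ab2)$total_bp, st$total_bp),
                         mean_length = c(set_stats(ab1)$mean_length,
                                         set_stats(ab2)$mean_length,
                                         st$mean_length))
  data.table::fwrite(stats_df, op("peak_stats.tsv"), sep = "\t")
  out$peak_stats <- stats_df

  plan <- randomization_plan(cfg$n_permutations,
                             seed = .derive_seed(cfg$seed, "enrich"))
  enr <- stage("enrichment_matrix", enrichment_matrix(
    list(consensus_peaks = consensus),
    list(h3k9me3_domains = domains, late_replicating = late_rep,
         hypomethylated = hypometh, neutral_control = neutral),
    genome, plan))
  data.table::fwrite(enr, op("enrichment_matrix.tsv"), sep = "\t")
  out$enrichment <- enr

  # composite profiles over domains and SAHF-like intersected regions
  comp_rs <- stage("composite", composite(tags_rs, h4_rs, domains,
                                          spec_body, genome))
  data.table::fwrite(profile_to_df(comp_rs), op("composite_rs_domains.tsv"),
                     sep = "\t")
  diff_dom <- stage("difference_composite", difference_composite(
    tags_pro, h4_pro, tags_rs, h4_rs, domains, spec_body, genome))
  data.table::fwrite(profile_to_df(diff_dom),
                     op("difference_composite_domains.tsv"), sep = "\t")
  out$difference_composite_domains <- diff_dom
  sahf <- sahf_regions(late_rep, domains, genome)
  diff_prof <- stage("sahf_composite", difference_composite(
    tags_pro, h4_pro, tags_rs, h4_rs, sahf, spec_body, genome))
  data.table::fwrite(profile_to_df(diff_prof),
                     op("difference_composite_sahf.tsv"), sep = "\t")
  out$difference_composite_sahf <- diff_prof

  meth_read <- function(path) {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    methylation_track(dt$chrom, dt$pos, dt$pct, genome)
  }
  mc_pro <- methylation_composite(meth_read(ip("methylation_pro.tsv")),
                                  sahf, spec_body, genome)
  mc_rs <- methylation_composite(meth_read(ip("methylation_rs.tsv")),
                                 sahf, spec_body, genome)
  meth_df <- profile_to_df(mc_rs)
  meth_df$mean_value_pro <- mc_pro$values
  meth_df$difference <- mc_rs$values - mc_pro$values
  names(meth_df)[names(meth_df) == "mean_value"] <- "mean_value_rs"
  data.table::fwrite(meth_df, op("methylation_composite_sahf.tsv"),
                     sep = "\t")
  out$methylation_composite <- meth_df

  # telomere quantification
  tq <- stage("telomere", {
    rows <- list()
    for (cond in c("pro", "rs")) {
      r <- telomere_ratio(read_reads(ip(paste0("tel_", cond, "_ip.fastq"))),
                          read_reads(ip(paste0("tel_", cond,
                                               "_control.fastq"))),
                          max_mismatch = cfg$max_mismatch)
      rows[[cond]] <- data.frame(condition = toupper(cond),
                                 pct_ip = r$pct_ip,
                                 pct_control = r$pct_control,
                                 ratio = r$ratio)
    }
    do.call(rbind, rows)
  })
  data.table::fwrite(tq, op("telomere_quant.tsv"), sep = "\t")
  out$telomere <- tq

  te_plan <- randomization_plan(cfg$n_permutations,
                                seed = .derive_seed(cfg$seed, "te"))
  te_enr <- stage("te_order", te_order_enrichment(
    te, consensus, genome, te_plan,
    offset_normalize = isTRUE(cfg$offset_normalize)))
  data.table::fwrite(te_enr, op("te_order_enrichment.tsv"), sep = "\t")
  out$te_order <- te_enr

  # gene-centric analyses
  gbe <- stage("gene_enrichment", gene_body_enrichment(
    genes, tags_rs, h4_rs, genome))
  data.table::fwrite(gbe, op("gene_body_enrichment.tsv"), sep = "\t")
  fam <- rank_and_top_families(gbe, top_n = min(cfg$top_n, nrow(gbe)))
  fam_df <- data.frame(family = names(fam$top),
                       top_count = as.integer(fam$top),
                       background_count =
                         as.integer(fam$background[names(fam$top)]))
  data.table::fwrite(fam_df, op("top_gene_families.tsv"), sep = "\t")
  out$families <- fam

  qa <- expression_quartiles(genes, "rs")
  data.table::fwrite(data.frame(gene_id = names(qa), quartile = qa),
                     op("expression_quartiles.tsv"), sep = "\t")
  qp <- stage("quartile_composites", quartile_composites(
    genes, qa, tags_rs, h4_rs,
    profile_spec(cfg$n_body_windows, cfg$n_flank_windows,
                 cfg$flank_window_bp, orient_by_strand = TRUE), genome))
  qp_df <- do.call(rbind, lapply(names(qp), function(lab) {
    d <- profile_to_df(qp[[lab]]); d$label <- lab; d
  }))
  data.table::fwrite(qp_df, op("quartile_composites.tsv"), sep = "\t")
  out$quartile_composites <- qp

  gbe_pro <- gene_body_enrichment(genes, tags_pro, h4_pro, genome)
  stopifnot(identical(gbe$gene_id, gbe_pro$gene_id))
  ds <- delta_scatter_table(gbe$gene_id, gbe$signal - gbe_pro$signal,
                            genes$fpkm_pro[match(gbe$gene_id,
                                                 genes$gene_id)])
  data.table::fwrite(ds, op("delta_scatter.tsv"), sep = "\t")
  out$delta_scatter <- ds
  cors <- data.frame(
    statistic = c("spearman_rs_signal_vs_fpkm", "pearson_delta_vs_fpkm",
                  "r_squared_delta_vs_fpkm"),
    value = c(spearman_rho(gbe$signal,
                           genes$fpkm_rs[match(gbe$gene_id, genes$gene_id)]),
              pearson_r(ds$delta_signal, ds$baseline_fpkm)$r,
              pearson_r(ds$delta_signal, ds$baseline_fpkm)$r_squared))
  data.table::fwrite(cors, op("expression_correlations.tsv"), sep = "\t")
  out$correlations <- cors

  manifest <- list(seed = cfg$seed, parameters = cfg[!vapply(cfg, is.null,
                                                             TRUE)],
                   package_version = as.character(
                     utils::packageVersion("senescape")),
                   outputs = list.files(outd, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, op("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, op("run_log.txt"))
  out$out_dir <- outd
  invisible(out)
}
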