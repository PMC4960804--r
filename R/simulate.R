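#' Synthetic genome with assembly gaps
#'
#' Builds a genome whose chromosomes carry randomly placed, non-overlapping
#' gap regions totalling `gap_fraction` of each chromosome (exactly, up to
#' rounding), emulating the unsequenced "gap" track that randomization must
#' avoid.
#'
#' @param lengths named vector of chromosome lengths (default two 5-Mb
#'   chromosomes).
#' @param gap_fraction fraction of each chromosome covered by gaps, in
#'   \[0, 0.5\] (default 0.05).
#' @param n_gaps_per_chrom number of gaps per chromosome (default 5).
#' @param seed RNG seed.
#' @return a [Genome()].
#' @export
make_genome <- function(lengths = c(chr1 = 5e6, chr2 = 5e6),
                        gap_fraction = 0.05, n_gaps_per_chrom = 5,
                        seed = NULL) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 0.5)
  if (gap_fraction == 0) return(Genome(lengths))
  .with_seed(seed, {
    gap_df <- do.call(rbind, lapply(names(lengths), function(cn) {
      L <- lengths[[cn]]
      total <- round(gap_fraction * L)
      k <- max(1L, as.integer(n_gaps_per_chrom))
      # split the gap budget into k parts, then scatter them by drawing the
      # k+1 intervening free spaces from a uniform simplex
      w <- as.vector(stats::rmultinom(1, total, rep(1 / k, k)))
      w <- w[w > 0]
      free <- L - total
      cuts <- sort(stats::runif(length(w), 0, 1))
      sp <- round(c(cuts, 1) * free) - round(c(0, cuts) * free)
      s <- cumsum(sp[-length(sp)]) + c(0, cumsum(w))[seq_along(w)]
      data.frame(chrom = cn, start = s, end = s + w)
    }))
    gaps <- GenomicRanges::GRanges(
      gap_df$chrom, IRanges::IRanges(gap_df$start + 1, gap_df$end))
    Genome(lengths, gaps = gaps)
  })
}

#' Plant a domain set with a controlled overlap fraction
#'
#' Places `n` regions with log-uniform lengths outside assembly gaps. When a
#' target set is given, exactly `round(overlap_fraction * n)` regions are
#' placed fully inside the target (each within a single target interval) and
#' the rest fully outside it, so the planted base-pair overlap fraction
#' closely tracks `overlap_fraction`.
#'
#' @param genome a [Genome()].
#' @param n number of regions.
#' @param length_range two-element vector; lengths are drawn log-uniformly
#'   between the bounds.
#' @param overlap_with optional `GRanges` target set.
#' @param overlap_fraction fraction of regions placed inside the target.
#' @param seed RNG seed.
#' @return unmerged `GRanges` of planted regions.
#' @export
plant_domains <- function(genome, n, length_range = c(5e3, 5e4),
                          overlap_with = NULL, overlap_fraction = 0,
                          seed = NULL) {
  stopifnot(n >= 1, length_range[1] >= 1,
            length_range[2] >= length_range[1],
            overlap_fraction >= 0, overlap_fraction <= 1)
  .with_seed(seed, {
    lens <- round(exp(stats::runif(n, log(length_range[1]),
                                   log(length_range[2]))))
    chroms <- sample(names(genome$chrom), n, replace = TRUE,
                     prob = genome$chrom / sum(genome$chrom))
    if (is.null(overlap_with)) {
      inside <- rep(FALSE, n)
      in_str <- NULL
      out_str <- genome$stretches
    } else {
      .check_genome(overlap_with, genome, "overlap target")
      target <- merge_intervals(overlap_with)
      n_in <- round(overlap_fraction * n)
      inside <- rep(FALSE, n)
      if (n_in > 0) inside[sample.int(n, n_in)] <- TRUE
      in_gr <- intersect_segments(target, gapfree_regions(genome))
      in_str <- .stretches_from_gr(in_gr, genome)
      out_gr <- subtract_intervals(gapfree_regions(genome), target)
      out_str <- .stretches_from_gr(out_gr, genome)
    }
    starts <- numeric(n)
    for (i in seq_len(n)) {
      str_set <- if (inside[i]) in_str else out_str
      placed <- FALSE
      # regions too long for this chromosome's stretches fall back to any
      # chromosome with room, preserving feasibility for skewed targets
      for (cn in c(chroms[i],
                   setdiff(names(genome$chrom), chroms[i]))) {
        m <- str_set[[cn]]
        if (is.null(m) || nrow(m) == 0) next
        adm <- .admissible(m, lens[i])
        if (adm$total <= 0) next
        starts[i] <- .draw_starts(adm, 1L)
        chroms[i] <- cn
        placed <- TRUE
        break
      }
      if (!placed)
        stop("cannot place a ", lens[i], " bp region ",
             if (inside[i]) "inside" else "outside", " the target set")
    }
    .gr(data.frame(chrom = chroms, start = starts, end = starts + lens),
        genome)
  })
}

.stretches_from_gr <- function(gr, genome) {
  df <- .gr0(gr)
  out <- list()
  for (cn in unique(df$chrom)) {
    d <- df[df$chrom == cn, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    out[[cn]] <- cbind(start = d$start, end = d$end)
  }
  out
}

#' Simulate a ChIP tag set with planted fold enrichment
#'
#' Tag 5' positions are drawn from a piecewise-constant intensity: uniform
#' baseline over all gap-free base pairs, multiplied inside each enriched
#' interval by that interval's fold (folds multiply where enriched intervals
#' overlap). Strands are Bernoulli(0.5). Exactly `n_reads` tags are
#' produced.
#'
#' @param genome a [Genome()].
#' @param n_reads number of tags.
#' @param enriched optional `GRanges` with a numeric metadata column `fold`
#'   (> 0) giving the per-interval intensity multiplier.
#' @param fragment_length fragment extension length for the returned set.
#' @param label dataset label.
#' @param seed RNG seed.
#' @return a [tag_set()].
#' @export
simulate_tags <- function(genome, n_reads, enriched = NULL,
                          fragment_length = 150, label = "sim", seed = NULL) {
  stopifnot(n_reads >= 0)
  if (!is.null(enriched)) {
    .check_genome(enriched, genome, "enriched set")
    fold <- S4Vectors::mcols(enriched)$fold
    if (is.null(fold)) stop("enriched GRanges needs a 'fold' column")
    if (any(fold <= 0)) stop("folds must be > 0")
  }
  if (gapfree_bp(genome) <= 0) stop("genome has no gap-free sequence")
  .with_seed(seed, {
    segs <- .intensity_segments(genome, enriched)
    w <- segs$weight * (segs$end - segs$start)
    pick <- sample.int(nrow(segs), n_reads, replace = TRUE, prob = w)
    pos <- floor(segs$start[pick] +
                   stats::runif(n_reads) * (segs$end[pick] - segs$start[pick]))
    pos <- pmin(pos, segs$end[pick] - 1)
    strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
    tag_set(segs$chrom[pick], pos, strand, genome,
            fragment_length = fragment_length, label = label)
  })
}

# Piecewise-constant intensity segments: gap-free stretches cut at every
# enriched-interval boundary; weight = product of folds covering a segment.
.intensity_segments <- function(genome, enriched) {
  edf <- if (is.null(enriched) || length(enriched) == 0) NULL
         else cbind(.gr0(enriched),
                    fold = S4Vectors::mcols(enriched)$fold)
  out <- list()
  for (cn in names(genome$chrom)) {
    m <- genome$stretches[[cn]]
    if (is.null(m) || nrow(m) == 0) next
    br <- sort(unique(c(m[, 1], m[, 2])))
    ec <- NULL
    if (!is.null(edf)) {
      ec <- edf[edf$chrom == cn, , drop = FALSE]
      br <- sort(unique(c(br, ec$start, ec$end)))
    }
    s <- br[-length(br)]; e <- br[-1]
    # keep segments inside gap-free stretches
    mid <- (s + e) / 2
    in_str <- findInterval(mid, m[, 1])
    keep <- in_str > 0 & mid < m[pmax(in_str, 1L), 2]
    s <- s[keep]; e <- e[keep]; mid <- mid[keep]
    wt <- rep(1, length(s))
    if (!is.null(ec) && nrow(ec) > 0) {
      for (j in seq_len(nrow(ec))) {
        hit <- mid >= ec$start[j] & mid < ec$end[j]
        wt[hit] <- wt[hit] * ec$fold[j]
      }
    }
    out[[cn]] <- data.frame(chrom = cn, start = s, end = e, weight = wt)
  }
  do.call(rbind, out)
}

#' Simulate a gene table with expression and planted ChIP coupling
#'
#' Generates `n_genes` gene bodies (log-uniform lengths, placed outside
#' gaps; bodies may overlap, as real genes do), family labels from
#' `family_mix` (including a repeat-derived class for exclusion tests), FPKM
#' values for two conditions, and a planted per-gene ChIP intensity fold for
#' each condition. Under `coupling = "inverse"`, the senescent-condition
#' fold decreases with expression (`1 + (max_fold - 1) / (1 + FPKM)`), so
#' unexpressed and lowly expressed genes gain the most signal; the
#' proliferating condition is flat. Under `coupling = "none"` both are flat.
#'
#' @param genome a [Genome()].
#' @param n_genes number of genes (default 2000).
#' @param length_range gene-body length bounds (default 1-10 kb).
#' @param family_mix named probability vector of family labels; remaining
#'   mass goes to "other".
#' @param zero_fraction fraction of genes with FPKM 0 (default 0.2).
#' @param coupling "inverse" or "none".
#' @param max_fold maximum planted fold at FPKM 0 (default 10).
#' @param seed RNG seed.
#' @return `data.frame` gene table with `fpkm_pro`, `fpkm_rs` and planted
#'   columns `rate_pro`, `rate_rs`.
#' @export
simulate_genes <- function(genome, n_genes = 2000,
                           length_range = c(1e3, 1e4),
                           family_mix = c(ZNF = 0.06, olfactory = 0.05,
                                          protocadherin = 0.02, USP = 0.02,
                                          repeat_class = 0.05),
                           zero_fraction = 0.2,
                           coupling = c("inverse", "none"),
                           max_fold = 10, seed = NULL) {
  coupling <- match.arg(coupling)
  stopifnot(sum(family_mix) <= 1, zero_fraction >= 0, zero_fraction < 1)
  .with_seed(seed, {
    bodies <- plant_domains(genome, n_genes, length_range = length_range)
    df <- .gr0(bodies)
    strand <- ifelse(stats::runif(n_genes) < 0.5, "+", "-")
    tss <- ifelse(strand == "+", df$start, df$end)
    tes <- ifelse(strand == "+", df$end, df$start)
    fams <- c(names(family_mix), "other")
    probs <- c(family_mix, other = 1 - sum(family_mix))
    family <- sample(fams, n_genes, replace = TRUE, prob = probs)
    fpkm_pro <- ifelse(stats::runif(n_genes) < zero_fraction, 0,
                       stats::rlnorm(n_genes, log(5), 1.2))
    fpkm_rs <- fpkm_pro * stats::rlnorm(n_genes, 0, 0.2)
    rate_pro <- rep(1, n_genes)
    rate_rs <- if (coupling == "inverse")
      1 + (max_fold - 1) / (1 + fpkm_rs) else rep(1, n_genes)
    data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
               name = sprintf("gene%04d", seq_len(n_genes)),
               chrom = df$chrom, tss = tss, tes = tes, strand = strand,
               biotype = "protein_coding", family = family,
               fpkm_pro = fpkm_pro, fpkm_rs = fpkm_rs,
               rate_pro = rate_pro, rate_rs = rate_rs,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a per-CpG methylation track
#'
#' CpG sites with geometric spacing; percent methylation is `baseline_pct`
#' outside the hypomethylated regions and `baseline_pct - delta_pct` inside,
#' plus Gaussian noise clamped to \[0, 100\].
#'
#' @param genome a [Genome()].
#' @param mean_spacing mean CpG spacing in bp (default 500).
#' @param baseline_pct baseline percent methylation (default 80).
#' @param hypo_regions optional `GRanges` of hypomethylated regions.
#' @param delta_pct methylation loss inside `hypo_regions` (default 30).
#' @param noise_sd Gaussian noise s.d. in percent (default 5).
#' @param seed RNG seed.
#' @return a [methylation_track()].
#' @export
simulate_methylation <- function(genome, mean_spacing = 500,
                                 baseline_pct = 80, hypo_regions = NULL,
                                 delta_pct = 30, noise_sd = 5, seed = NULL) {
  stopifnot(baseline_pct >= 0, baseline_pct <= 100,
            baseline_pct - delta_pct >= 0)
  .with_seed(seed, {
    chroms <- character(0); pos <- numeric(0)
    for (cn in names(genome$chrom)) {
      m <- genome$stretches[[cn]]
      for (k in seq_len(nrow(m))) {
        span <- m[k, 2] - m[k, 1]
        n_exp <- stats::rpois(1, span / mean_spacing)
        if (n_exp == 0) next
        p <- sort(floor(stats::runif(n_exp, m[k, 1], m[k, 2])))
        p <- unique(pmin(p, m[k, 2] - 1))
        chroms <- c(chroms, rep(cn, length(p)))
        pos <- c(pos, p)
      }
    }
    pct <- rep(baseline_pct, length(pos))
    if (!is.null(hypo_regions) && length(hypo_regions) > 0) {
      sites <- .gr(data.frame(chrom = chroms, start = pos, end = pos + 1),
                   genome)
      hit <- IRanges::overlapsAny(sites, hypo_regions, ignore.strand = TRUE)
      pct[hit] <- pct[hit] - delta_pct
    }
    pct <- pmin(100, pmax(0, pct + stats::rnorm(length(pct), 0, noise_sd)))
    methylation_track(chroms, pos, pct, genome)
  })
}

#' Simulate reads containing a planted telomeric fraction
#'
#' Exactly `round(n * fraction)` reads are TTAGGG-phase repeats (random
#' phase, random strand) with per-base substitution errors at `error_rate`;
#' the remainder are i.i.d. random sequence. Read order is shuffled.
#'
#' @param n number of reads.
#' @param read_length read length in nt (default 72).
#' @param fraction planted telomeric fraction in \[0, 1\].
#' @param error_rate per-base substitution probability for planted reads.
#' @param unit repeat unit (default "TTAGGG").
#' @param seed RNG seed.
#' @return character vector of `n` read sequences.
#' @export
simulate_reads_with_telomere_fraction <- function(n, read_length = 72,
                                                  fraction, error_rate = 0,
                                                  unit = "TTAGGG",
                                                  seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1, n >= 0)
  .with_seed(seed, {
    n_tel <- round(n * fraction)
    bases <- c("A", "C", "G", "T")
    u <- nchar(unit)
    conc <- strrep(unit, ceiling((read_length + u) / u))
    tel <- character(n_tel)
    if (n_tel > 0) {
      for (i in seq_len(n_tel)) {
        off <- sample.int(u, 1) - 1
        s <- substr(conc, off + 1, off + read_length)
        if (error_rate > 0) {
          ch <- strsplit(s, "")[[1]]
          err <- which(stats::runif(read_length) < error_rate)
          if (length(err))
            ch[err] <- sample(bases, length(err), replace = TRUE)
          s <- paste(ch, collapse = "")
        }
        if (stats::runif(1) < 0.5) s <- .revcomp(s)
        tel[i] <- s
      }
    }
    n_bg <- n - n_tel
    bg <- character(n_bg)
    if (n_bg > 0) {
      mat <- matrix(sample(bases, n_bg * read_length, replace = TRUE),
                    nrow = n_bg)
      bg <- apply(mat, 1, paste, collapse = "")
    }
    out <- c(tel, bg)
    out[sample.int(n)]
  })
}

#' Generate the full senescence study scenario
#'
#' One-command synthetic dataset bundle emulating a two-condition
#' (proliferating "PRO" vs replicative-senescent "RS") heterochromatin
#' study, with ground truth recorded alongside. The bundle contains:
#' heterochromatin (H3K9me3-like) domains over which the RS ChIP track is
#' enriched 3-fold; a late-replicating set overlapping the domains; a
#' hypomethylation-like set planted at 3x the random overlap expectation; a
#' neutral control set placed at random; two antibody peak tracks (jittered
#' domain copies) whose consensus stands in for the called peak set; PRO/RS
#' treatment and histone-H4 control tag sets; a gene table with inverse
#' signal-expression coupling in RS; TE subtypes whose peak overlap
#' increases with evolutionary recency; methylation tracks hypomethylated
#' in domains for RS; and telomere FASTQ files with equal planted telomeric
#' fractions in IP and control.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; all per-stage seeds are derived from it.
#' @param config optional list overriding scenario parameters (see
#'   `scenario_defaults()`).
#' @return list with `files` (named paths), `truth` (planted parameters)
#'   and `genome`.
#' @export
scenario_senescence <- function(out_dir, seed = 1, config = list()) {
  cfg <- utils::modifyList(scenario_defaults(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)

  genome <- make_genome(cfg$chrom_lengths, cfg$gap_fraction,
                        seed = .derive_seed(seed, "genome"))
  domains <- plant_domains(genome, cfg$n_domains, cfg$domain_length_range,
                           seed = .derive_seed(seed, "domains"))
  q <- total_bp(domains) / gapfree_bp(genome)

  late_rep <- plant_domains(genome, cfg$n_late_rep, cfg$late_rep_length_range,
                            overlap_with = domains,
                            overlap_fraction = cfg$late_rep_overlap,
                            seed = .derive_seed(seed, "late_rep"))
  hypometh <- plant_domains(genome, cfg$n_hypometh,
                            cfg$hypometh_length_range,
                            overlap_with = domains,
                            overlap_fraction = min(1, cfg$planted_fold * q),
                            seed = .derive_seed(seed, "hypometh"))
  neutral <- plant_domains(genome, cfg$n_neutral, cfg$neutral_length_range,
                           seed = .derive_seed(seed, "neutral"))

  # two antibody peak tracks: domain copies with jittered edges
  jitter_set <- function(gr, s) {
    df <- .gr0(gr)
    .with_seed(s, {
      lens <- genome$chrom[df$chrom]
      j1 <- round(stats::runif(nrow(df), -cfg$peak_jitter, cfg$peak_jitter))
      j2 <- round(stats::runif(nrow(df), -cfg$peak_jitter, cfg$peak_jitter))
      st <- pmax(0, df$start + j1)
      en <- pmin(lens, df$end + j2)
      keep <- en > st
      .gr(data.frame(chrom = df$chrom[keep], start = st[keep],
                     end = en[keep]), genome)
    })
  }
  peaks_ab1 <- jitter_set(domains, .derive_seed(seed, "ab1"))
  peaks_ab2 <- jitter_set(domains, .derive_seed(seed, "ab2"))

  # TE subtypes: overlap fraction with domains rises with recency rank
  te_rows <- list()
  te_fracs <- numeric(cfg$n_te_subtypes)
  for (k in seq_len(cfg$n_te_subtypes)) {
    frac <- cfg$te_min_frac +
      (cfg$te_max_frac - cfg$te_min_frac) * (k - 1) /
        max(1, cfg$n_te_subtypes - 1)
    te_fracs[k] <- frac
    gr <- plant_domains(genome, cfg$n_te_per_subtype,
                        cfg$te_length_range, overlap_with = domains,
                        overlap_fraction = frac,
                        seed = .derive_seed(seed, paste0("te", k)))
    d <- .gr0(gr)
    te_rows[[k]] <- data.frame(
      chrom = d$chrom, start = d$start, end = d$end,
      subtype = sprintf("TE%02d", k),
      class = c("LINE", "SINE", "LTR", "DNA")[(k - 1) %% 4 + 1],
      order_rank = k, stringsAsFactors = FALSE)
  }
  te <- do.call(rbind, te_rows)

  genes <- simulate_genes(genome, cfg$n_genes,
                          length_range = cfg$gene_length_range,
                          coupling = cfg$gene_coupling,
                          max_fold = cfg$gene_max_fold,
                          seed = .derive_seed(seed, "genes"))

  gb <- gene_bodies(genes, genome)
  rs_enriched <- c(
    {
      g <- merge_intervals(domains)
      S4Vectors::mcols(g)$fold <- cfg$planted_fold
      g
    },
    {
      g2 <- GenomicRanges::granges(gb)
      S4Vectors::mcols(g2)$fold <- genes$rate_rs
      g2
    })
  pro_enriched <- {
    g2 <- GenomicRanges::granges(gb)
    S4Vectors::mcols(g2)$fold <- genes$rate_pro
    g2
  }
  tags_rs <- simulate_tags(genome, cfg$n_reads, rs_enriched,
                           cfg$fragment_length, label = "RS_H4K20me3",
                           seed = .derive_seed(seed, "tags_rs"))
  tags_pro <- simulate_tags(genome, cfg$n_reads, pro_enriched,
                            cfg$fragment_length, label = "PRO_H4K20me3",
                            seed = .derive_seed(seed, "tags_pro"))
  h4_rs <- simulate_tags(genome, cfg$n_reads, NULL, cfg$fragment_length,
                         label = "RS_H4", seed = .derive_seed(seed, "h4_rs"))
  h4_pro <- simulate_tags(genome, cfg$n_reads, NULL, cfg$fragment_length,
                          label = "PRO_H4",
                          seed = .derive_seed(seed, "h4_pro"))

  meth_pro <- simulate_methylation(genome, cfg$cpg_spacing,
                                   cfg$meth_baseline, NULL, 0,
                                   cfg$meth_noise_sd,
                                   seed = .derive_seed(seed, "meth_pro"))
  meth_rs <- simulate_methylation(genome, cfg$cpg_spacing,
                                  cfg$meth_baseline, merge_intervals(domains),
                                  cfg$meth_delta, cfg$meth_noise_sd,
                                  seed = .derive_seed(seed, "meth_rs"))

  tel <- list()
  for (ds in c("pro_ip", "pro_control", "rs_ip", "rs_control")) {
    tel[[ds]] <- simulate_reads_with_telomere_fraction(
      cfg$n_tel_reads, cfg$tel_read_length, cfg$tel_fraction,
      cfg$tel_error_rate, seed = .derive_seed(seed, paste0("tel_", ds)))
  }

  files <- c(
    chrom_sizes = write_chrom_sizes(genome, fp("genome.chrom.sizes")),
    gaps = write_bed(genome$gaps, fp("gaps.bed")),
    domains = write_bed(domains, fp("h3k9me3_domains.bed")),
    late_replicating = write_bed(late_rep, fp("late_replicating.bed")),
    hypomethylated = write_bed(hypometh, fp("hypomethylated.bed")),
    neutral = write_bed(neutral, fp("neutral_control.bed")),
    peaks_ab1 = write_bed(peaks_ab1, fp("h4k20me3_peaks_ab1.bed")),
    peaks_ab2 = write_bed(peaks_ab2, fp("h4k20me3_peaks_ab2.bed")),
    tags_rs = write_tags_bed(tags_rs, fp("tags_rs_h4k20me3.bed")),
    tags_pro = write_tags_bed(tags_pro, fp("tags_pro_h4k20me3.bed")),
    tags_h4_rs = write_tags_bed(h4_rs, fp("tags_rs_h4.bed")),
    tags_h4_pro = write_tags_bed(h4_pro, fp("tags_pro_h4.bed")),
    genes = fp("genes.tsv"),
    te = fp("te.tsv"),
    meth_pro = fp("methylation_pro.tsv"),
    meth_rs = fp("methylation_rs.tsv"),
    tel_pro_ip = write_reads_fastq(tel$pro_ip, fp("tel_pro_ip.fastq")),
    tel_pro_control = write_reads_fastq(tel$pro_control,
                                        fp("tel_pro_control.fastq")),
    tel_rs_ip = write_reads_fastq(tel$rs_ip, fp("tel_rs_ip.fastq")),
    tel_rs_control = write_reads_fastq(tel$rs_control,
                                       fp("tel_rs_control.fastq")),
    truth = fp("truth.json"))
  data.table::fwrite(genes, fp("genes.tsv"), sep = "\t")
  data.table::fwrite(te, fp("te.tsv"), sep = "\t")
  for (nm in c("pro", "rs")) {
    tr <- if (nm == "pro") meth_pro else meth_rs
    data.table::fwrite(data.table::data.table(chrom = tr$chrom,
                                              pos = as.integer(tr$pos),
                                              pct = tr$pct),
                       fp(paste0("methylation_", nm, ".tsv")), sep = "\t")
  }
  truth <- list(seed = seed, config = cfg,
                domain_coverage_fraction = q,
                planted_fold = cfg$planted_fold,
                hypometh_overlap_fraction = min(1, cfg$planted_fold * q),
                te_overlap_fractions = te_fracs,
                tel_fraction = cfg$tel_fraction,
                gene_coupling = cfg$gene_coupling)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  list(files = files, truth = truth, genome = genome)
}

#' Default scenario parameters
#'
#' Desk-scale study conditions: two 5-Mb chromosomes with 5 % gaps, 150
#' planted heterochromatin domains of 5-50 kb, 3-fold planted RS enrichment,
#' 3e5 tags per track, 2000 genes with inverse signal-expression coupling,
#' 10 TE subtypes with overlap rising by recency, and 2 % telomeric read
#' fractions equal across datasets.
#'
#' @return named list of scenario parameters.
#' @export
scenario_defaults <- function() {
  list(chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
       gap_fraction = 0.05,
       n_domains = 150, domain_length_range = c(5e3, 5e4),
       planted_fold = 3,
       n_late_rep = 100, late_rep_length_range = c(5e3, 3e4),
       late_rep_overlap = 0.7,
       n_hypometh = 200, hypometh_length_range = c(500, 1500),
       n_neutral = 2000, neutral_length_range = c(500, 2000),
       peak_jitter = 500,
       n_te_subtypes = 10, n_te_per_subtype = 150,
       te_length_range = c(300, 3000),
       te_min_frac = 0.05, te_max_frac = 0.9,
       n_genes = 2000, gene_length_range = c(500, 3000),
       gene_coupling = "inverse", gene_max_fold = 5,
       n_reads = 3e5, fragment_length = 150,
       cpg_spacing = 500, meth_baseline = 80, meth_delta = 30,
       meth_noise_sd = 5,
       n_tel_reads = 20000, tel_read_length = 72, tel_fraction = 0.02,
       tel_error_rate = 0.005)
}
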