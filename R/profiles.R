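#' Composite-profile window specification
#'
#' A composite ("metadomain"/metagene) profile rescales every region to
#' `n_body_windows` equal windows (each covering 1/`n_body_windows` of the
#' region, 2 % by default) and adds `n_flank_windows` fixed-width windows of
#' `flank_window_bp` on each side for genomic context: 150 windows in total
#' by default.
#'
#' @param n_body_windows number of scaled body windows (default 50).
#' @param n_flank_windows number of fixed-width flank windows per side
#'   (default 50).
#' @param flank_window_bp width of each flank window in bp (default 100).
#' @param orient_by_strand reverse window order for minus-strand regions, so
#'   profiles read 5' to 3' (used for gene bodies, not for domains).
#' @return a `profile_spec` list.
#' @export
profile_spec <- function(n_body_windows = 50, n_flank_windows = 50,
                         flank_window_bp = 100, orient_by_strand = FALSE) {
  stopifnot(n_body_windows > 0, n_flank_windows >= 0, flank_window_bp > 0)
  structure(list(n_body_windows = as.integer(n_body_windows),
                 n_flank_windows = as.integer(n_flank_windows),
                 flank_window_bp = as.numeric(flank_window_bp),
                 orient_by_strand = isTRUE(orient_by_strand)),
            class = "profile_spec")
}

.n_windows <- function(spec) spec$n_body_windows + 2L * spec$n_flank_windows

#' Window boundaries of one region's composite profile
#'
#' Body-window boundaries are proportional (`start + i * L / n_body`) and may
#' be fractional; signal is accumulated by fractional overlap, so the exact
#' 1/n-per-window semantics hold for any region length.
#'
#' @param region single-row `GRanges`.
#' @param spec a [profile_spec()].
#' @param strand "+"/"-"; with `orient_by_strand`, minus-strand window order
#'   is reversed.
#' @return `data.frame` with columns `chrom`, `start`, `end` (possibly
#'   fractional), `class` (`flank5`/`body`/`flank3`) and `index` (1-based,
#'   already in oriented order).
#' @export
region_windows <- function(region, spec = profile_spec(), strand = "+") {
  stopifnot(length(region) == 1L)
  df <- .gr0(region)
  L <- df$end - df$start
  if (L < spec$n_body_windows)
    stop("region shorter than the number of body windows")
  b <- .window_breaks(df$start, df$end, spec)
  cls <- .window_classes(spec)
  idx <- seq_len(.n_windows(spec))
  if (spec$orient_by_strand && strand == "-") idx <- rev(idx)
  data.frame(chrom = df$chrom, start = b[-length(b)], end = b[-1],
             class = cls, index = idx, stringsAsFactors = FALSE)
}

.window_breaks <- function(s, e, spec) {
  nf <- spec$n_flank_windows; nb <- spec$n_body_windows
  fb <- spec$flank_window_bp
  L <- e - s
  body <- s + seq_len(nb) * (L / nb)
  body[nb] <- e  # guard against floating-point drift at the region end
  c(s - (nf:0) * fb, body, e + seq_len(nf) * fb)
}

.window_classes <- function(spec) {
  c(rep("flank5", spec$n_flank_windows),
    rep("body", spec$n_body_windows),
    rep("flank3", spec$n_flank_windows))
}

# Shared accumulation loop. `tracks` is a list of list(fi = fragment_index,
# coef = +/-1); each region contributes coef-weighted normalized signal per
# window. Flank windows extending past chromosome bounds are dropped from
# that region's contribution (NA).
.composite_core <- function(tracks, regions, spec, genome, label) {
  df <- .gr0(regions)
  strands <- as.character(GenomicRanges::strand(regions))
  nw <- .n_windows(spec)
  usable <- (df$end - df$start) >= spec$n_body_windows
  n_skipped <- sum(!usable)
  if (n_skipped > 0)
    warning(n_skipped, " region(s) shorter than ", spec$n_body_windows,
            " bp skipped")
  if (!any(usable)) stop("no usable regions for composite profile")
  acc <- numeric(nw)
  cnt <- integer(nw)
  for (i in which(usable)) {
    cn <- df$chrom[i]
    clen <- genome$chrom[[cn]]
    b <- .window_breaks(df$start[i], df$end[i], spec)
    lo <- b[-length(b)]; hi <- b[-1]
    valid <- lo >= 0 & hi <= clen
    vals <- rep(NA_real_, nw)
    if (any(valid)) {
      v <- numeric(sum(valid))
      for (tr in tracks) {
        ci <- tr$fi$idx[[cn]]
        bp <- .frag_overlap_bp(ci, lo[valid], hi[valid])
        f <- bp / tr$fi$fragment_length
        v <- v + tr$coef *
          (f / (hi[valid] - lo[valid])) / (tr$fi$total_reads / 1e6)
      }
      vals[valid] <- v
    }
    if (spec$orient_by_strand && strands[i] == "-") vals <- rev(vals)
    ok <- !is.na(vals)
    acc[ok] <- acc[ok] + vals[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  values <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(values = values, n_regions_used = sum(usable),
                 n_skipped = n_skipped, n_contributing = cnt,
                 window_class = .window_classes(spec),
                 track_label = label, spec = spec),
            class = "composite_profile")
}

#' Composite enrichment profile over a region set
#'
#' The mean control-subtracted signal in each of the 150 windows, averaged
#' over all usable regions.
#'
#' @param treatment,control [tag_set()]s; `control = NULL` gives the raw
#'   (unsubtracted) profile.
#' @param regions `GRanges` of regions (domains, peaks or gene bodies;
#'   strand is honoured when `spec$orient_by_strand`).
#' @param spec a [profile_spec()].
#' @param genome a [Genome()].
#' @return a `composite_profile` with 150 window means.
#' @export
composite <- function(treatment, control = NULL, regions,
                      spec = profile_spec(), genome) {
  if (treatment$total_reads == 0) stop("treatment tag set is empty")
  tracks <- list(list(fi = .fragment_index(treatment, genome), coef = 1))
  if (!is.null(control)) {
    if (control$total_reads == 0) stop("control tag set is empty")
    tracks <- c(tracks,
                list(list(fi = .fragment_index(control, genome), coef = -1)))
  }
  .composite_core(tracks, regions, spec, genome, treatment$label)
}

#' Composite profile of a between-condition difference
#'
#' Per-window mean of `[normalized(condition 2) - normalized(condition 1)]`,
#' e.g. senescent minus proliferating H4K20me3 over SAHF-forming regions.
#'
#' @param treat1,ctrl1 condition-1 treatment and control [tag_set()]s.
#' @param treat2,ctrl2 condition-2 treatment and control [tag_set()]s.
#' @inheritParams composite
#' @return a `composite_profile`.
#' @export
difference_composite <- function(treat1, ctrl1, treat2, ctrl2, regions,
                                 spec = profile_spec(), genome) {
  for (t in list(treat1, ctrl1, treat2, ctrl2))
    if (t$total_reads == 0) stop("all four tag sets must be nonempty")
  tracks <- list(
    list(fi = .fragment_index(treat2, genome), coef = 1),
    list(fi = .fragment_index(ctrl2, genome), coef = -1),
    list(fi = .fragment_index(treat1, genome), coef = -1),
    list(fi = .fragment_index(ctrl1, genome), coef = 1))
  .composite_core(tracks, regions, spec, genome,
                  paste0(treat2$label, "-", treat1$label))
}

#' Per-CpG methylation track
#'
#' @param chrom chromosome names.
#' @param pos 0-based CpG positions.
#' @param pct percentage methylated at each site, in \[0, 100\].
#' @param genome a [Genome()].
#' @return a `methylation_track`.
#' @export
methylation_track <- function(chrom, pos, pct, genome) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(pct))
  if (length(pct) && (any(pct < 0) || any(pct > 100)))
    stop("percent methylation must lie in [0, 100]")
  if (length(pos)) {
    lens <- genome$chrom[chrom]
    if (anyNA(lens) || any(pos < 0 | pos >= lens))
      stop("CpG site outside genome")
  }
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos),
                 pct = as.numeric(pct)), class = "methylation_track")
}

#' Composite percent-methylation profile
#'
#' Per-window mean of the percentage methylation over CpG sites falling in
#' the window, averaged across regions. Windows containing no CpGs in a
#' region contribute nothing to that window's mean; a window empty in every
#' region is `NA`.
#'
#' @param track a [methylation_track()].
#' @param regions `GRanges`.
#' @param spec a [profile_spec()].
#' @param genome a [Genome()].
#' @return a `composite_profile` (values in percent).
#' @export
methylation_composite <- function(track, regions, spec = profile_spec(),
                                  genome) {
  df <- .gr0(regions)
  strands <- as.character(GenomicRanges::strand(regions))
  nw <- .n_windows(spec)
  usable <- (df$end - df$start) >= spec$n_body_windows
  if (sum(!usable) > 0)
    warning(sum(!usable), " region(s) shorter than ", spec$n_body_windows,
            " bp skipped")
  if (!any(usable)) stop("no usable regions for composite profile")
  by_chrom <- list()
  for (cn in unique(track$chrom)) {
    sel <- track$chrom == cn
    o <- order(track$pos[sel])
    p <- track$pos[sel][o]
    by_chrom[[cn]] <- list(pos = p, cum = c(0, cumsum(track$pct[sel][o])))
  }
  acc <- numeric(nw); cnt <- integer(nw)
  for (i in which(usable)) {
    cn <- df$chrom[i]
    clen <- genome$chrom[[cn]]
    b <- .window_breaks(df$start[i], df$end[i], spec)
    lo <- b[-length(b)]; hi <- b[-1]
    valid <- lo >= 0 & hi <= clen
    vals <- rep(NA_real_, nw)
    ch <- by_chrom[[cn]]
    if (!is.null(ch) && any(valid)) {
      k <- findInterval(b, ch$pos, left.open = TRUE)
      nsite <- diff(k)
      psum <- diff(ch$cum[k + 1])
      v <- ifelse(nsite > 0, psum / nsite, NA_real_)
      v[!valid] <- NA_real_
      vals <- v
    }
    if (spec$orient_by_strand && strands[i] == "-") vals <- rev(vals)
    ok <- !is.na(vals)
    acc[ok] <- acc[ok] + vals[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  structure(list(values = ifelse(cnt > 0, acc / cnt, NA_real_),
                 n_regions_used = sum(usable), n_skipped = sum(!usable),
                 n_contributing = cnt, window_class = .window_classes(spec),
                 track_label = "pct_methylated", spec = spec),
            class = "composite_profile")
}

#' SAHF composite substrate regions
#'
#' The intersection of late-replicating regions with H3K9me3 domains — the
#' regions over which senescence-associated heterochromatin composites are
#' computed.
#'
#' @param late_replicating,h3k9me3 `GRanges` sets on the same genome.
#' @param genome optional [Genome()] for validation.
#' @return merged `GRanges` of shared segments.
#' @export
sahf_regions <- function(late_replicating, h3k9me3, genome = NULL) {
  intersect_segments(late_replicating, h3k9me3, genome)
}

#' @export
print.composite_profile <- function(x, ...) {
  cat("composite_profile '", x$track_label, "': ", length(x$values),
      " windows over ", x$n_regions_used, " region(s)",
      if (x$n_skipped > 0) paste0(" (", x$n_skipped, " skipped)"), "\n",
      sep = "")
  invisible(x)
}

#' Composite profile as a data frame
#' @param profile a `composite_profile`.
#' @return `data.frame` with `window_index`, `window_class`, `mean_value`,
#'   `n_contributing_regions`.
#' @export
profile_to_df <- function(profile) {
  data.frame(window_index = seq_along(profile$values),
             window_class = profile$window_class,
             mean_value = profile$values,
             n_contributing_regions = profile$n_contributing,
             stringsAsFactors = FALSE)
}
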