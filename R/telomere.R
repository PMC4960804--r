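#' Telomeric repeat reference
#'
#' A concatemer of the telomeric repeat unit (TTAGGG by default) truncated to
#' a fixed length. Because the reference is periodic, matching a read against
#' it reduces to testing the six phase offsets of the unit on both strands.
#'
#' @param unit repeat unit (default "TTAGGG").
#' @param length reference length in bp (default 1000; must be at least the
#'   read length).
#' @return a `repeat_reference` with the truncated concatemer sequence.
#' @export
repeat_reference <- function(unit = "TTAGGG", length = 1000) {
  stopifnot(nchar(unit) >= 1, length >= nchar(unit))
  seq <- substr(strrep(unit, ceiling(length / nchar(unit))), 1, length)
  structure(list(unit = toupper(unit), length = as.integer(length),
                 sequence = toupper(seq)), class = "repeat_reference")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify reads as telomeric
#'
#' A read is telomeric when its best ungapped end-to-end alignment against
#' the repeat reference — over all phase offsets of the repeat unit and both
#' strands — has at most `max_mismatch` mismatches. `N` bases always count
#' as mismatches.
#'
#' @param reads character vector of read sequences (A/C/G/T/N).
#' @param ref a [repeat_reference()].
#' @param max_mismatch mismatch allowance (default 2, suited to 36-76 nt
#'   reads).
#' @return logical vector, one call per read.
#' @export
is_telomeric <- function(reads, ref = repeat_reference(), max_mismatch = 2) {
  if (length(reads) == 0) return(logical(0))
  reads <- toupper(reads)
  if (any(nchar(reads) == 0)) stop("empty read sequence")
  if (any(nchar(reads) > ref$length))
    stop("read longer than the repeat reference")
  mm <- .min_mismatches(reads, ref)
  mm <= max_mismatch
}

# Minimum mismatch count over all unit phases and both strands, grouped by
# read length so comparisons vectorize as character matrices.
.min_mismatches <- function(reads, ref) {
  u <- nchar(ref$unit)
  out <- rep(NA_real_, length(reads))
  fwd <- reads
  rev <- .revcomp(reads)
  for (len in unique(nchar(reads))) {
    sel <- which(nchar(reads) == len)
    refchars <- strsplit(substr(strrep(ref$unit,
                                       ceiling((len + u) / u)), 1,
                                len + u - 1), "")[[1]]
    best <- rep(Inf, length(sel))
    for (strand_reads in list(fwd[sel], rev[sel])) {
      m <- matrix(unlist(strsplit(strand_reads, "")), nrow = length(sel),
                  ncol = len, byrow = TRUE)
      for (off in 0:(u - 1)) {
        expct <- refchars[(off + 1):(off + len)]
        mm <- rowSums(m != matrix(expct, nrow = length(sel), ncol = len,
                                  byrow = TRUE))
        best <- pmin(best, mm)
      }
    }
    out[sel] <- best
  }
  out
}

#' Percentage of telomeric reads in a dataset
#'
#' @param reads character vector of read sequences.
#' @inheritParams is_telomeric
#' @return percentage in \[0, 100\].
#' @export
pct_telomeric <- function(reads, ref = repeat_reference(), max_mismatch = 2) {
  if (length(reads) == 0) stop("read collection is empty")
  100 * sum(is_telomeric(reads, ref, max_mismatch)) / length(reads)
}

#' Telomere IP/control ratio
#'
#' Ratio of the percentage of telomeric reads in the IP dataset to that in
#' the control (histone H4 or input) dataset.
#'
#' @param ip_reads,control_reads character vectors of read sequences.
#' @inheritParams is_telomeric
#' @return list with `pct_ip`, `pct_control` and `ratio` (`NA` when the
#'   control percentage is zero).
#' @export
telomere_ratio <- function(ip_reads, control_reads, ref = repeat_reference(),
                           max_mismatch = 2) {
  pi <- pct_telomeric(ip_reads, ref, max_mismatch)
  pc <- pct_telomeric(control_reads, ref, max_mismatch)
  if (pc == 0) {
    warning("control has no telomeric reads; ratio undefined")
    ratio <- NA_real_
  } else ratio <- pi / pc
  list(pct_ip = pi, pct_control = pc, ratio = ratio)
}

#' qPCR telomere enrichment
#'
#' Telomeric IP signal normalized to a reference locus's IP signal
#' (beta-globin): `[tel]IP / [reference]IP`.
#'
#' @param tel_ip telomeric IP quantity.
#' @param reference_ip reference-locus IP quantity; must be positive.
#' @return the enrichment ratio.
#' @export
qpcr_enrichment <- function(tel_ip, reference_ip) {
  if (reference_ip <= 0) stop("reference locus IP signal must be positive")
  tel_ip / reference_ip
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is inferred from the extension (`.fq`/`.fastq` vs `.fa`/`.fasta`);
#' qualities are ignored.
#'
#' @param path sequence file path.
#' @return character vector of read sequences.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Write reads as FASTQ
#'
#' Constant qualities ("I") are written; read ids are sequential.
#'
#' @param reads character vector of sequences.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  n <- length(reads)
  lines <- character(4 * n)
  if (n) {
    lines[seq(1, 4 * n, 4)] <- paste0("@read", seq_len(n))
    lines[seq(2, 4 * n, 4)] <- reads
    lines[seq(3, 4 * n, 4)] <- "+"
    lines[seq(4, 4 * n, 4)] <- strrep("I", nchar(reads))
  }
  writeLines(lines, path)
  invisible(path)
}
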