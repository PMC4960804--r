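---
title: "Methods: interval enrichment, windowed signal, and composite profiles for senescent chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval enrichment, windowed signal, and composite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescape)
```

# Scope and data model

`senescape` covers the analysis layer of a senescence chromatin study that
sits *downstream* of read alignment and peak calling: region-set
statistics, windowed signal, permutation enrichment, composite profiles,
telomeric read counting, and integration with expression. Everything is
built on two currencies:

* **Interval sets** are `GRanges` carrying the genome's chromosome lengths
  in their `seqinfo`; BED input/output converts between the file format's
  0-based half-open coordinates and the 1-based convention `GRanges` uses.
  All per-base-pair statistics operate on the merged form of their inputs,
  and book-ended intervals are joined, so peak counts and bp totals are
  deterministic and no base is counted twice.
* **Tag sets** are the 5′ positions and strands of aligned reads, plus a
  fragment-extension length `F` (default 150 bp, the usual size-selected
  ChIP fragment). A `+` tag at `p` becomes the fragment `[p, p + F)`; a
  `-` tag becomes `[p - F + 1, p + 1)`, clipped at chromosome ends. The
  unclipped `F` stays in the denominator of the fractional-read count, so
  a fragment never contributes more than one read of mass.

The `Genome` object also carries the assembly's unsequenced "gap" regions,
because the randomization null (below) must never place a region on
unsequenceable bases.

# Windowed signal

The signal of a window of length $L$ is

$$\mathrm{signal} = \frac{f / L}{N / 10^6}$$

with $N$ the dataset's total mapped read count and $f$ the *fractional
read* count: each extended fragment contributes the fraction of its length
falling inside the window. This reading is the only one under which
partially overlapping reads are "fractional"; it also gives the signal two
exact invariances the tests exploit — replicating every tag $k$ times
leaves the value unchanged, and the signal of a window equals the
length-weighted mean over any partition of it. A *normalized* window
subtracts the control signal (histone H4 for the senescence comparisons,
input otherwise); replicates are pooled before scoring. Subtraction rather
than a ratio is used everywhere one condition is normalized to its
control, including gene bodies, so a single normalization semantics runs
through the package (a ratio mode exists behind a flag in
`gene_body_enrichment()`).

Whether the original windowed statistic extended reads to fragments or
scored raw read intervals is not decidable from tool parameters alone;
fragment extension is the default here and `fragment_length` is settable
everywhere tags enter.

# Observed-to-expected overlap

For region sets $A$ and $B$, the observed statistic is their per-bp
overlap. The null is *matched randomization of B*: each randomized copy
keeps every region's chromosome and length, draws its start uniformly over
all positions where the region fits entirely outside assembly gaps, and
(by default) allows randomized regions to overlap one another — the null
matches length and chromosome composition, nothing else. The expected
overlap is the mean over `n_permutations` (default 10,000) randomized
copies; enrichment is `observed/expected`, reported as log2 fold.

Implementation notes:

* Placement is *exact* uniform sampling over the admissible start set,
  computed from the gap complement, rather than rejection sampling — same
  distribution, deterministic feasibility detection. Rejection is used
  only on the opt-in non-overlapping path.
* Empirical p-values use the add-one estimator $(r+1)/(n+1)$, which never
  returns zero; at 10,000 permutations the strongest reportable claim is
  p < 0.001 in round numbers. Both tails are always computed, because
  depletion (e.g. of promoters and exons from heterochromatin domains) is
  as informative as enrichment.
* Each randomized copy of $B$ is merged before intersection, so the null
  statistic has exactly the same per-bp semantics as the observed one.
* On a single-chromosome toy model the expected overlap is enumerable
  (every admissible start), and the Monte-Carlo estimate is tested to
  agree within three standard errors; under a null $B$ the p-values are
  tested to reject at the nominal 5 % rate within [0.03, 0.07].

`enrichment_matrix()` derives each (A, B) pair's seed from the plan seed
and the pair *names*, so results are invariant to input ordering.

# Composite profiles

A composite profile rescales each region to 50 body windows of $L/50$ bp
(2 % each) and adds 50 fixed 100-bp windows on each side for genomic
context; the 150 per-window means are averaged over the region set. Body
boundaries are kept at fractional coordinates and signal is accumulated by
fractional overlap, so the 2 %-per-window semantics is exact for any
region length. Regions shorter than 50 bp are skipped with a warning;
flank windows running past a chromosome end are dropped from that region's
contribution only. Domain composites (H3K9me3 domains, SAHF regions =
late-replicating ∩ H3K9me3) are unoriented; gene-body composites orient
TSS→TES by strand. Difference composites average
$[\mathrm{norm}_2 - \mathrm{norm}_1]$ per window (senescent minus
proliferating); percent-methylation composites average per-CpG percentages
with CpG-free windows contributing nothing.

One interpretation caveat the synthetic tests make visible: per-million
normalization is compositional. If one condition concentrates a large
share of its reads into enriched territory, its baseline density outside
that territory drops below the other condition's, so difference composites
can sit slightly negative in the flanks while strongly positive over the
body. The pipeline's acceptance check therefore reads the "plateau" as
body mean > 0 *and* body mean above the flank level, not as flanks at
exactly zero.

# Telomeric repeats

Aligning reads to a 1-kb TTAGGG concatemer with a general-purpose aligner
is replaced by a deterministic, equivalent-in-effect criterion: a read is
telomeric when its best ungapped end-to-end alignment over the six phase
offsets of the repeat unit and both strands (the reverse complement is the
CCCTAA phase) has at most `max_mismatch` mismatches (default 2 for
36–76-nt reads; `N` counts as a mismatch). For a purely periodic reference
longer than the read this examines every alignment such an aligner could
report, is reproducible, and is monotone in the threshold. A random 72-nt
read expects ~54 mismatches, so background miscalls are effectively
impossible at the default threshold. Reported statistics are the percent
of telomeric reads per dataset and the IP/control ratio; the qPCR-side
normalization `[tel]IP / [β-globin]IP` is a plain ratio.

# Expression integration

Expression quartiles are computed over expressed genes only (FPKM > 0),
sorted descending and split into four contiguous groups whose sizes differ
by at most one; FPKM = 0 genes form the separate `UN` class. Every sort
that feeds a cutoff (top-500 ranking, quartile edges) breaks ties by
`gene_id`, so outputs are reproducible to the byte. TE subtypes are
consumed with a precomputed evolutionary-order rank (1 = most ancient);
ages are not re-derived. The optional "add the lowest signal to all
signals" offset is applied to the plotted log2 fold series and is off by
default, since the source convention does not pin down which series it
transforms.

# The synthetic-data generator

`scenario_senescence()` generates every input the pipeline consumes, with
the planted truth serialized alongside (`truth.json`). The default
conditions are desk-scale but structured like the real study:

* two 5-Mb chromosomes with 5 % assembly gaps;
* 150 heterochromatin domains of 5–50 kb (log-uniform), covering ~26 % of
  the gap-free genome — senescent heterochromatin domains are large;
* a 3-fold planted senescent-condition enrichment over the domains, and
  3 × 10^5 tags per track;
* a late-replicating set with 70 % of regions planted inside domains, a
  hypomethylation-like set planted at exactly 3× the random overlap
  expectation (fraction `3q` of its regions inside domains, where `q` is
  the realized domain coverage), and 2,000 small neutral regions placed at
  random — the planted and neutral fold recoveries are the package's
  positive and negative controls;
* 2,000 genes of 0.5–3 kb (~28 % genic, so gene bodies do not dominate
  the read-mass budget) with FPKM = 0 for 20 % of genes and, in the
  senescent condition, a planted intensity fold
  $1 + (\mathrm{max\_fold}-1)/(1+\mathrm{FPKM})$ — heterochromatin gain
  concentrated at lowly and unexpressed genes;
* ten TE subtypes whose planted domain-overlap fraction rises linearly
  with recency rank;
* telomeric read files with the *same* 2 % planted fraction in IP and
  control of both conditions, so the expected IP/control ratio is 1 —
  matching the finding that the senescent H4K20me3 gain is not telomeric.

Where a fraction of regions is "planted inside" a target, exactly
`round(fraction × n)` regions are placed fully inside it (and the rest
fully outside), so the per-region planted bp fraction is tight; the
*merged* overlap can sit a few percent lower when planted regions overlap
one another, which is why the planted sets are kept sparse relative to
their targets.

What the generator does **not** emulate: GC or mappability structure
(the matched null does not condition on them, so adding them would change
the tested statistic, not exercise it), read sequences for ChIP tags
(positions suffice), duplicate structure, or realistic quality strings.
Passing the planted-recovery tests therefore demonstrates correctness of
the statistics under the stated sampling model, not robustness to
alignment artefacts in real data.

The dedicated signal–expression recovery experiment uses a larger (two
20-Mb chromosome) genome at the same gene count, because measured per-gene
signal decorrelates when overlapping gene bodies share reads; at ~20 %
genic fraction the planted inverse coupling is recovered with Spearman
ρ ≈ −0.8 at 10^6 reads.

# Numerical choices and degenerate inputs

* Fragment overlap sums are computed from sorted-endpoint prefix sums
  ($\sum_i \min(e_i, x) - \min(s_i, x)$ at window boundaries), exact in
  double precision for bp-scale quantities; profile tests assert agreement
  with a brute-force per-fragment oracle to 10⁻⁹.
* `expected = 0` with `observed > 0` flags an infinite fold with log2
  undefined but still reports p-values; empty sets, zero-length windows,
  zero-read tag sets, and reference loci with zero signal are errors, not
  silent zeros. An all-empty methylation window is `NA`, flagged by its
  contribution count.
* Problem sizes in the tests (10-Mb scenario genome, 10,000 permutations,
  500 calibration replicates at 200 permutations, 10⁶-read gene
  experiments) are chosen so the full suite runs in minutes on one CPU
  while keeping Monte-Carlo error well inside the asserted tolerances.

# Known limitations

No liftover, no UCSC binary formats, no peak calling or differential
binding (those belong to the upstream published tools), no analytic
closed-form null (the permutation is the method), no GC-matched
randomization, and no telomere-length estimation. The command-line front
end is a thin wrapper over the exported functions; scripted R use is the
primary interface.
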