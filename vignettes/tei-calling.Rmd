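---
title: "Calling transposable element insertions from low-coverage long reads"
author: "teicaller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transposable element insertions from low-coverage long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A transposable element (TE) that has moved — or that the reference assembly
simply lacks — shows up in a long-read alignment as sequence present in the
reads but absent from the reference. Around the insertion point, three read
classes appear: reads ending inside the inserted sequence (terminal
soft/hard clip at the junction), reads starting inside it (leading clip),
and reads long enough to span it entirely (a single large in-read `I`
operation). At ~5–10× nanopore coverage each true insertion typically
collects a handful of such reads; the caller's job is to aggregate them,
identify the donor TE, and reject artifacts.

`teicaller` implements this as five stages behind `call_teis()`; each stage
is also exported on its own (`scan_alignments()`, `cluster_breakpoints()`,
`extract_segment_sequences()` / `map_segments()` / `assign_best_te()`,
`build_coverage_model()` / `filter_clusters()`).

## Model and assumptions

* **Reference-guided, insertion-only.** Only sequence gained relative to
  the reference is detected. Deletions, inversions and translocations are
  out of scope; so is reference-free discovery.
* **Evidence is CIGAR-level.** No base-level realignment is performed; the
  aligner's placement of clips and insertions is trusted. This is what
  makes the caller fast and usable at low coverage, and it is why the merge
  window (below) must absorb alignment jitter at target-site duplications.
* **A TEI needs an annotated donor.** Candidate loci whose re-mapped
  segments overlap no annotated TE are discarded as non-TE structural
  variation. The caller is therefore only as complete as its TE BED.
* **Coverage is exchangeable across the genome.** The outlier filter
  compares local read counts against windows sampled genome-wide. Strong
  systematic coverage trends (e.g. severe GC bias) would weaken the
  comparison.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `min_clip` | 1000 (strict >) | bp | smallest terminal clip that counts as evidence; at N50 ~12 kb reads, kb-scale clips separate TE junctions from noisy read ends. Scale down (we use 300) for shorter reads. |
| `min_insertion` | 100 | bp | smallest in-read insertion recorded. Short MITE-scale elements are a few hundred bp; clustering and TE assignment remove spurious small hits downstream. |
| `merge_dist` | 20 (strict <) | bp | single-linkage chaining window for breakpoints. Junction placement jitters by a few bp at target-site duplications. |
| `min_support` | 2 | reads | minimum distinct supporting reads; singletons at low coverage are mostly chimeric reads. |
| `min_overlap` | 50 | bp | smallest segment-to-TE overlap that participates in assignment; keeps 1-bp interval touches from driving calls. |
| `low_q`, `high_q` | 0.01, 0.99 | quantile | two-sided empirical bounds of the coverage filter. |
| `n_intervals`, `window` | 10000, 1000 | –, bp | coverage-model sampling. |
| `flank_bp` | 500 | bp | offset of the flanking coverage windows from the locus. |
| `min_mapq` | 1 | – | drops mapq-0 multi-mappers whose placement is arbitrary while keeping the modest-mapq alignments pericentromeric TEIs rely on. |

## Design choices

**Coordinates.** All internal coordinates are 1-based closed, the
Bioconductor convention of the IRanges/GenomicRanges stack the package is
built on; BED input/output converts at the boundary, and the final report
displays 1-based inclusive positions.

**Secondary vs supplementary alignments.** Secondary records are skipped
(duplicate placements of one read would double-count support).
Supplementary records are kept: a read split across a large insertion is
often represented as primary + supplementary, both carrying informative
clips.

**Joint clip/insertion merging.** Clip and insertion breakpoints are
clustered together, since both are evidence for the same junction; merging
them separately would split support across two half-clusters. Chains are
single-linkage, so a cluster can span more than `merge_dist` end-to-end;
with a 20 bp window and kb-scale separations between real events this has
no practical cost.

**"Best TE" definition.** The annotation hit maximizing total overlap bp
summed over a cluster's placed segments wins, with ties broken by longer TE
and then lexicographic id — favoring full-length donor copies over
fragments, deterministically. One best placement is kept per segment: for
multi-copy TE families all within-family placements are equivalent at the
family level, and multi-placement fan-out would inflate overlap sums.

**Aligner backends.** Segment re-mapping is a contract (segments + genome
in, one best placement per segment out). The production backend shells out
to `minimap2 -x map-ont`. The builtin backend takes fixed-width 15-mer
seeds every 10 bp from each segment and its reverse complement, matches
them exactly against the genome (`Biostrings::matchPDict`), and lets seeds
vote for a placement diagonal; at substitution-level divergence enough
seeds stay exact, and indel-free placements keep all true seeds on one
diagonal. It exists so tests and simulations need no external binary; for
real (indel-rich) nanopore segments use minimap2.

**Coverage filter.** The published description of this step — read counts
"tested to fit" the genome coverage distribution with outlier filtering —
names no statistic, so the package uses assumption-free two-sided empirical
quantile thresholds (type-1 quantiles of the sampled window counts);
nanopore coverage is overdispersed, making parametric fits fragile. Two
numerical details matter:

* The flank statistic is the *mean* of the read counts over two windows of
  the model's window width placed `flank_bp` up- and downstream of the
  locus, not a window containing the junction. Reads sampled from the
  inserted sequence align clipped *at* the junction, so a junction-spanning
  window over-counts by roughly `depth × insert_len / read_len` at every
  true insertion — with 2–3 kb inserts and 6 kb reads that is a ~40%
  inflation, enough to push true events past the upper quantile. The offset
  windows see plain local coverage and are directly comparable to the
  sampled windows; a max over the two would have a fatter upper tail than
  single windows, while collapsed-repeat pile-ups inflate both flanks, so
  the mean still detects them.
* `LOW_COVERAGE` rejects when the flank count falls below
  `max(quantile(low_q), 1)`: with a degenerate all-zero model (empty
  alignment file) every candidate is still rejected.

Rejections are labelled (`LOW_SUPPORT`, `LOW_COVERAGE`, `HIGH_COVERAGE`)
and written to an audit TSV, so filtered candidates remain inspectable.

**Degenerate inputs.** Empty alignment files produce a header-only report,
not an error. Records violating CIGAR/sequence accounting are rejected at
ingestion (htslib already refuses them in SAM; the package re-checks BAM
records). All-clip CIGARs yield no signals. Hard-clipped segments require
the FASTQ; the error lists the missing read ids.

## The simulator, and what passing its tests means

`simulate_mobilome()` emulates the data regime the caller targets, scaled
to desk size: 2 × 500 kb chromosomes; 30 distinct TE copies of 1–3 kb
embedded at annotated positions; 4 planted N-gaps; 20 insertions with 5 bp
target-site duplications planted ≥ 25 kb apart and clear of features; reads
of Normal(6000, 2000) bp truncated at 200 bp — a halved N50-12kb regime
matching the halved element scale — at 8× depth. Read starts are stratified
(one jittered start per ~`genome_len / n_reads` stratum): marginally
uniform, but with sampling gaps bounded far below one read length, so the
emitted data is genuinely uniform-coverage and every junction is sampled at
~depth — i.i.d. starts would leave occasional multi-kb holes that model
sequencing drop-out rather than the even-coverage regime these tests
target. Reverse-strand reads are
emitted reverse-complemented with SAM `SEQ`/CIGAR conventions honored.
Alignments are computed analytically from the planted coordinates: a read
spanning an insertion with ≥ 50 bp (`anchor_bp`) anchors on both sides gets
`M..I..M`; under-anchored or in-insertion read ends fold into terminal soft
clips, mirroring aligner behavior qualitatively. Substitution errors (no
indels) are applied after CIGAR computation, keeping truth alignments exact;
the caller's signals are 100–1000× larger than base-level noise, so indel
noise is not load-bearing for correctness. An optional decoy duplicates all
reads near one extra planted locus 10×, mimicking a collapsed repeat.

What this does *not* emulate: real nanopore error profiles (homopolymer
indels, quality models), chimeric reads, nested or truncated insertions,
segmental duplications, mappability structure, or a real aligner's
breakpoint jitter. Passing the truth-recovery tests therefore demonstrates
the pipeline's bookkeeping (coordinates, strands, clustering, assignment,
filtering) is exact, and its robustness to substitution noise — not
field performance on real data, which additionally depends on the external
aligner and annotation quality.

The test suite checks each stage against independent oracles (a naive
CIGAR walker, an O(n²) single-linkage clusterer, an `N{3,}` regex, a
brute-force overlap summer), property-style invariants (threshold
monotonicity, partition properties, determinism under fixed seeds), and
end-to-end truth recovery at zero and 5% substitution error;
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Problem sizes

The shipped study conditions — 1 Mb of genome at 8× with ~1600 reads,
10,000 coverage windows — run each full simulate-and-call cycle in about a
minute on one CPU. These sizes were chosen as the smallest at which every
failure mode the caller addresses (spanning vs clipped reads, multi-kb
segments, coverage outliers) is well represented; all of them scale
linearly in code and are plain configuration knobs.

## Known limitations

* Genotypes (hom/het) and insertion phasing are not computed.
* The inserted sequence itself is not assembled; donor identity comes from
  segment re-mapping, so a TEI from a family absent in the annotation is
  invisible, and near-identical family members may swap identities.
* Control subtraction and sample comparison match loci by midpoint
  proximity (default tolerance 50 bp, chosen above the 20 bp merge window
  because breakpoint scatter across samples exceeds within-sample jitter);
  they do not require matching TE identity, which is the desired behavior
  for family-level comparisons but can conflate distinct co-located events.
* The command-line front end exposes thresholds as flags over the package
  defaults; a config-file layer was deliberately left out, the R API being
  the primary interface.
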