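# teicaller

Reference-guided detection of **transposable element insertions (TEIs)** and
TE-containing structural variants from **low-coverage long-read alignments**
(Oxford Nanopore scale, ~5–10× depth).

New TE copies that are present in a sequenced individual but absent from the
reference genome leave a characteristic footprint in long-read alignments:
reads that end at the insertion point carry large **soft/hard clips**
(`S`/`H` CIGAR operations), and reads long enough to span the whole event
carry a large **in-read insertion** (`I`). `teicaller` turns that footprint
into annotated insertion calls. It is aimed at plant mobilome work —
e.g. profiling reactivated transposition in hypomethylated mutants, or
flagging TE copies hidden in assembly gaps of the reference — but is
organism-agnostic.

## Method

The caller takes four inputs: a coordinate-sorted BAM of long reads mapped
to the reference, the reference FASTA, the raw-read FASTQ, and a 4-column
BED of annotated TE copies. It then runs five stages:

1. **Signal extraction** — every alignment's CIGAR is scanned for terminal
   clips longer than `min_clip` (default 1000 bp, strict) and insertions of
   at least `min_insertion` (default 100 bp). Each signal records the
   reference breakpoint the unaligned segment attaches to.
2. **Breakpoint clustering** — breakpoints are merged per chromosome by
   single-linkage chaining whenever consecutive positions are less than
   `merge_dist` (default 20 bp) apart; clip and insertion evidence is
   merged jointly. Cluster support counts distinct reads.
3. **Segment re-mapping** — the unaligned segment sequences are sliced from
   the stored alignments (or the raw reads, for hard clips) and mapped back
   to the genome, either with `minimap2` (production backend) or with a
   built-in seed-and-vote exact/near-exact matcher (no external binary).
4. **TE assignment** — segment placements are intersected with the TE
   annotation; per cluster the TE with the largest summed overlap (≥
   `min_overlap`, default 50 bp) wins. Clusters hitting no TE are dropped.
5. **Coverage filtering** — local read counts are tested against an
   empirical genome-coverage distribution sampled from `n_intervals`
   (default 10,000) random windows: candidates with support below
   `min_support`, or flank coverage outside the `[q0.01, q0.99]` empirical
   quantiles, are rejected (`LOW_SUPPORT` / `LOW_COVERAGE` /
   `HIGH_COVERAGE`, the latter removing collapsed-repeat decoys).

The final table reports, per TEI: locus, clipped-read and insertion-read
counts, and the id and coordinates of the assigned donor TE copy.

Downstream utilities cover the typical analysis that follows: assembly-gap
discovery (maximal runs of ≥ 3 `N`s), subtraction of control calls (e.g.
wild-type artifacts) from a mutant call set, windowed between-sample
comparison, and per-TE/per-subfamily tallies.

A **synthetic mobilome simulator** (`simulate_mobilome()`) builds a
reference with embedded TE copies and N-gaps, plants insertions with
target-site duplications into donor genomes, and emits reads whose
reference alignments (CIGARs included) are computed analytically — so the
entire pipeline is testable offline against a known truth set.

## Worked example

Simulate a mobilome and call insertions back:

```r
library(teicaller)

cfg <- sim_config(seed = 42, decoy = TRUE)     # 2 x 500 kb, 20 insertions, 8x
fx  <- simulate_mobilome(cfg, "sim")
res <- call_teis(tei_config(bam = fx$bam, genome = fx$genome,
                            te_bed = fx$te_bed, fastq = fx$fastq,
                            min_clip = 300, backend = "builtin"))
res
evaluate_calls(res$calls, fx$truth)[c("recall", "precision",
                                      "mean_bp_error")]
```

This prints the per-stage counts and the result summary:

```
alignments retained: 1517
breakpoint signals: 285
candidate clusters: 21
TE-assigned clusters: 21
passed coverage filter: 20
tei_result: 20 TEI call(s) from 285 signal(s) in 21 cluster(s); 21 assigned, 20 passed filtering
   chrom  start    end n_clipped_reads n_insertion_reads te_id ...
1   chr1  22557  22558               3                 5 TE010 ...
```

All 20 planted insertions are recovered (`recall` 1, `precision` 1, mean
breakpoint error 0.50 bp), each assigned its true donor TE; the 21st
cluster is the planted collapsed-repeat decoy, rejected by the coverage
filter with reason `HIGH_COVERAGE`. The `min_clip = 300` setting scales the
default clip threshold to the simulator's ~6 kb reads.

A thin command-line front end with the same stages lives at
`inst/scripts/teicaller.R` (subcommands `call`, `simulate`, `gaps`,
`subtract`, `compare`, `tally`).

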