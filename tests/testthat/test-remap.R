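# Segment extraction, re-mapping and best-TE assignment.

test_that("soft-clip and insertion segments are sliced from the stored sequence", {
  seq <- paste0(strrep("A", 400), strrep("C", 300), strrep("G", 400))
  aln <- data.frame(read_id = "r1", flag = 0L, chrom = "chr1", pos = 1000L,
                    mapq = 60L, strand = "+", cigar = "400M300I400M",
                    seq = seq, ref_end = 1799L, stringsAsFactors = FALSE)
  cl <- cluster_breakpoints(scan_alignments(aln, min_clip = 300L,
                                            min_insertion = 100L), 20L)
  segs <- extract_segment_sequences(cl, aln)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$seq, strrep("C", 300))
  expect_match(segs$segment_id, "r1\\|insertion")
})

test_that("hard-clipped segments are recovered from the raw read with strand handling", {
  planted <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = "")
  aligned <- strrep("T", 400)
  # raw read (sequencer orientation) for a minus-strand alignment whose
  # stored orientation is revcomp(raw): raw = revcomp(aligned-part) after
  # the revcomp of the clip, so oriented raw = planted + aligned
  raw <- revcomp(paste0(planted, aligned))
  aln <- data.frame(read_id = "hc", flag = 16L, chrom = "chr1", pos = 5000L,
                    mapq = 60L, strand = "-", cigar = "500H400M",
                    seq = aligned, ref_end = 5399L, stringsAsFactors = FALSE)
  cl <- cluster_breakpoints(scan_alignments(aln, min_clip = 300L), 20L)
  expect_true(cl$signals$hard_clipped)
  segs <- extract_segment_sequences(cl, aln, fastq = c(hc = raw))
  expect_identical(segs$seq, planted)
  # missing read is an error naming the read
  expect_error(extract_segment_sequences(cl, aln, fastq = c(other = "ACGT")),
               "hc")
  expect_error(extract_segment_sequences(cl, aln, fastq = NULL), "FASTQ")
})

test_that("builtin mapper places exact substrings, both strands, drops noise", {
  set.seed(31)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                 collapse = "")))
  g <- as.character(genome[["chr1"]])
  segs <- data.frame(
    segment_id = c("fwd", "rev", "junk"), cluster_id = c(1L, 2L, 3L),
    read_id = c("r1", "r2", "r3"), kind = "insertion",
    seq = c(substr(g, 5001, 7000), revcomp(substr(g, 9001, 10500)),
            paste(rep("ACGT", 100), collapse = "")),
    seg_len = c(2000L, 1500L, 400L), stringsAsFactors = FALSE)
  hits <- suppressMessages(map_segments(segs, genome, backend = "builtin"))
  fwd <- hits[hits$segment_id == "fwd", ]
  expect_equal(c(fwd$start, fwd$end, fwd$strand, fwd$aligned_len),
               c("5001", "7000", "+", "2000"))
  rev <- hits[hits$segment_id == "rev", ]
  expect_equal(c(rev$start, rev$end, rev$strand), c("9001", "10500", "-"))
  expect_false("junk" %in% hits$segment_id)
})

test_that("best TE wins by summed overlap with tie-breaks; non-TE clusters drop out", {
  te_bed <- data.frame(chrom = "chr1", start = c(1000L, 4000L),
                       end = c(3000L, 4400L), te_id = c("TE_A", "TE_B"),
                       stringsAsFactors = FALSE)
  segs <- data.frame(segment_id = c("s1", "s2", "s3"),
                     cluster_id = c(1L, 1L, 2L), read_id = c("r1", "r2", "r3"),
                     kind = "insertion", seq = "", seg_len = 0L,
                     stringsAsFactors = FALSE)
  hits <- data.frame(segment_id = c("s1", "s2", "s3"), chrom = "chr1",
                     start = c(1200L, 4200L, 8000L),
                     end = c(2999L, 4399L, 9000L), strand = "+",
                     aligned_len = c(1800L, 200L, 1001L), score = 1,
                     stringsAsFactors = FALSE)
  asn <- assign_best_te(hits, segs, te_bed)
  expect_equal(nrow(asn), 1L)                 # cluster 2 overlaps no TE
  expect_equal(asn$te_id, "TE_A")             # 1800 bp beats 200 bp
  expect_equal(asn$total_overlap_bp, 1800L)
  expect_equal(asn$n_supporting_segments, 1L)
})

test_that("sub-threshold overlaps cannot drive an assignment", {
  te_bed <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                       te_id = "TE_A", stringsAsFactors = FALSE)
  segs <- data.frame(segment_id = "s1", cluster_id = 1L, read_id = "r1",
                     kind = "insertion", seq = "", seg_len = 0L,
                     stringsAsFactors = FALSE)
  graze <- data.frame(segment_id = "s1", chrom = "chr1", start = 1981L,
                      end = 2500L, strand = "+", aligned_len = 520L,
                      score = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(assign_best_te(graze, segs, te_bed, min_overlap = 50L)),
               0L)                            # 20 bp graze ignored
  expect_equal(nrow(assign_best_te(graze, segs, te_bed, min_overlap = 20L)),
               1L)
})

test_that("assignment overlap sums match a brute-force oracle and ignore record order", {
  set.seed(32)
  for (rep in 1:10) {
    n_te <- sample(3:8, 1)
    te_bed <- data.frame(
      chrom = "chr1", start = seq(1000L, by = 5000L, length.out = n_te),
      te_id = sprintf("TE%02d", 1:n_te), stringsAsFactors = FALSE)
    te_bed$end <- te_bed$start + sample(500:3000, n_te, replace = TRUE)
    n_seg <- sample(2:6, 1)
    hits <- data.frame(
      segment_id = sprintf("s%d", 1:n_seg), chrom = "chr1",
      start = sample(1000:40000, n_seg), strand = "+", score = 1,
      stringsAsFactors = FALSE)
    hits$end <- hits$start + sample(200:2500, n_seg, replace = TRUE)
    hits$aligned_len <- hits$end - hits$start + 1L
    segs <- data.frame(segment_id = hits$segment_id, cluster_id = 1L,
                       read_id = hits$segment_id, kind = "insertion",
                       seq = "", seg_len = 0L, stringsAsFactors = FALSE)
    asn <- assign_best_te(hits, segs, te_bed, min_overlap = 50L)
    # oracle: per TE, summed qualifying overlap over all segments
    sums <- vapply(seq_len(n_te), function(j)
      oracle_overlap_sum(hits$start, hits$end, te_bed$start[j],
                         te_bed$end[j], 50L), integer(1))
    if (all(sums == 0L)) {
      expect_equal(nrow(asn), 0L)
    } else {
      expect_equal(asn$total_overlap_bp, max(sums))
      expect_equal(asn$te_id, te_bed$te_id[which.max(sums)])
      # shuffling the annotation changes nothing
      shuf <- te_bed[sample(n_te), ]
      expect_equal(assign_best_te(hits, segs, shuf)$total_overlap_bp,
                   asn$total_overlap_bp)
    }
  }
})
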