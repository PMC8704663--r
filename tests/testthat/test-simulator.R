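# Synthetic mobilome generator: reference construction, planted events,
# analytic read alignments.

test_that("the reference build is deterministic and internally consistent", {
  s <- fixture_small()
  ref <- s$fx$ref
  ref2 <- simulate_reference(s$cfg)
  expect_identical(ref$genome_chr, ref2$genome_chr)      # same seed, same bytes
  expect_identical(ref$te_bed, ref2$te_bed)
  # every annotated interval carries its TE library sequence
  for (i in seq_len(nrow(ref$te_bed))) {
    b <- ref$te_bed[i, ]
    expect_identical(substr(ref$genome_chr[[b$chrom]], b$start, b$end),
                     unname(ref$te_seqs[b$te_id]))
  }
  # every gap interval is all N, and nothing else overlaps it
  for (i in seq_len(nrow(ref$gaps))) {
    g <- ref$gaps[i, ]
    expect_true(grepl("^N+$", substr(ref$genome_chr[[g$chrom]], g$start,
                                     g$end)))
  }
})

test_that("planted insertions stay clear of gaps and record exact lengths", {
  s <- fixture_small()
  truth <- s$fx$truth
  expect_equal(nrow(truth), s$cfg$n_insertions)
  expect_equal(truth$ins_len, truth$te_len + s$cfg$tsd_len)
  gaps <- s$fx$ref$gaps
  for (i in seq_len(nrow(truth)))
    expect_false(any(gaps$chrom == truth$chrom[i] &
                       gaps$start <= truth$pos[i] &
                       gaps$end >= truth$pos[i]))
  # donor chromosome grows by te_len + tsd_len per event
  ref <- s$fx$ref
  ev1 <- truth[1, ]
  pieces <- teicaller:::donor_pieces(ref$genome_chr[[ev1$chrom]], ev1)
  donor <- teicaller:::donor_sequence(ref$genome_chr[[ev1$chrom]], pieces)
  expect_equal(nchar(donor),
               nchar(ref$genome_chr[[ev1$chrom]]) + ev1$te_len +
                 s$cfg$tsd_len)
  # zero insertions leave the donor equal to the reference
  p0 <- teicaller:::donor_pieces(ref$genome_chr[[1]], truth[0, ])
  expect_identical(teicaller:::donor_sequence(ref$genome_chr[[1]], p0),
                   ref$genome_chr[[1]])
})

test_that("analytic alignments follow the spanning/clipped CIGAR rules", {
  ref_seq <- strrep("A", 10000)
  ev <- data.frame(event_id = "e1", chrom = "c", pos = 5000L, te_id = "T",
                   te_len = 2000L, ins_len = 2000L, tsd_len = 0L,
                   is_decoy = FALSE, ins_seq = strrep("C", 2000),
                   stringsAsFactors = FALSE)
  pieces <- teicaller:::donor_pieces(ref_seq, ev)
  # spanning read: 500 bp flank, whole insertion, 500 bp flank
  a <- teicaller:::align_donor_read(pieces, 4501L, 7500L, 50L)
  expect_equal(a$cigar, "500M2000I500M")
  expect_equal(a$pos, 4501L)
  # read ending inside the insertion: terminal right clip
  b <- teicaller:::align_donor_read(pieces, 4701L, 6400L, 50L)
  expect_equal(b$cigar, "300M1400S")
  expect_equal(b$pos, 4701L)
  # read starting inside the insertion: leading clip, resumes after the event
  d <- teicaller:::align_donor_read(pieces, 6001L, 8000L, 50L)
  expect_equal(d$cigar, "1000S1000M")
  expect_equal(d$pos, 5001L)
  # under-anchored flank folds into the clip
  u <- teicaller:::align_donor_read(pieces, 4981L, 7500L, 50L)
  expect_equal(u$cigar, "2020S500M")
  # read fully inside the insertion is unmapped
  expect_null(teicaller:::align_donor_read(pieces, 5200L, 6800L, 50L))
  # read with no insertion at all is a single match
  m <- teicaller:::align_donor_read(pieces, 1001L, 2000L, 50L)
  expect_equal(m$cigar, "1000M")
})

test_that("emitted alignments pass CIGAR accounting and reach target depth", {
  s <- fixture_small()
  aln <- read_alignments(s$fx$bam)             # rejects violations itself
  expect_gt(nrow(aln), 0L)
  genome_len <- sum(nchar(s$fx$ref$genome_chr))
  emitted <- sum(nchar(read_fastq_seqs(s$fx$fastq)))
  expect_lt(abs(emitted / genome_len - s$cfg$depth) / s$cfg$depth, 0.15)
})

test_that("a minus-strand read's insertion segment recovers the planted sequence", {
  s <- fixture_small()
  fx <- s$fx
  aln <- read_alignments(fx$bam)
  sig <- scan_alignments(aln, min_clip = 300L, min_insertion = 100L)
  ins <- sig[sig$kind == "insertion" & sig$strand == "-", ]
  expect_gt(nrow(ins), 0L)
  hit <- ins[1, ]
  ev <- fx$truth[fx$truth$chrom == hit$chrom &
                   fx$truth$pos == hit$pos, ]
  expect_equal(nrow(ev), 1L)
  stored <- aln$seq[hit$aln_idx]
  segment <- substr(stored, hit$seg_start, hit$seg_end)
  expect_identical(segment, ev$ins_seq)        # exact recovery at zero error
  # and the FASTQ carries its reverse complement within the raw read
  fq <- read_fastq_seqs(fx$fastq)
  expect_true(grepl(revcomp(segment), fq[[hit$read_id]], fixed = TRUE))
})

test_that("simulation output trees are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 77L, n_chroms = 1L, chrom_len = 120000L,
                    n_te_copies = 4L, n_insertions = 2L,
                    read_len_mean = 3000L, read_len_sd = 800L, depth = 4,
                    n_gaps = 1L)
  d1 <- tempfile("det1_"); d2 <- tempfile("det2_")
  simulate_mobilome(cfg, d1)
  simulate_mobilome(cfg, d2)
  for (f in c("genome.fa", "te.bed", "gaps.bed", "s1.sam", "s1.fastq",
              "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
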