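# Assembly gaps, control subtraction, sample comparison, tallies, report.

mk_calls <- function(chrom, start, end = start + 1L,
                     te_id = sprintf("TE%02d", seq_along(start)),
                     sample = "s") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             n_clipped_reads = 3L, n_insertion_reads = 2L, te_id = te_id,
             te_chrom = chrom, te_start = 1L, te_end = 1000L,
             sample = sample, stringsAsFactors = FALSE)
}

test_that("gap finder reports maximal N-runs of at least min_run", {
  g <- find_assembly_gaps(c(chr1 = "ACGTNNNACGT"))
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end, g$n_count), c(5L, 7L, 3L))
  expect_equal(nrow(find_assembly_gaps(c(chr1 = "ACGNNACG"))), 0L)
  b <- find_assembly_gaps(c(chr1 = "NNNNACG"))
  expect_equal(c(b$start, b$end), c(1L, 4L))
  e <- find_assembly_gaps(c(chr1 = "ACGNNNN"))
  expect_equal(c(e$start, e$end), c(4L, 7L))
})

test_that("gap finder matches the regex oracle on random N-salted sequences", {
  set.seed(41)
  for (i in 1:200) {
    s <- random_n_salted()
    got <- find_assembly_gaps(c(chr1 = s))
    want <- oracle_gaps(s)
    expect_equal(got$start, want$start, info = s)
    expect_equal(got$end, want$end, info = s)
    # intervals are disjoint, maximal and all N
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] > got$end[-nrow(got)] + 1L))
    for (j in seq_len(nrow(got)))
      expect_true(grepl("^N+$", substr(s, got$start[j], got$end[j])))
  }
})

test_that("control subtraction removes proximal calls on the same chromosome", {
  calls <- mk_calls("chr1", c(1000L, 5000L))
  ctrl <- mk_calls("chr1", 1010L)
  kept <- subtract_control(calls, ctrl, tolerance_bp = 50L)
  expect_equal(kept$start, 5000L)
  # chromosome mismatch keeps the call
  expect_equal(nrow(subtract_control(mk_calls("chr1", 1000L),
                                     mk_calls("chr2", 1000L), 50L)), 1L)
  # empty control set is the identity
  expect_identical(subtract_control(calls, calls[0, ], 50L), calls)
  # self-subtraction is empty for any call set
  expect_equal(nrow(subtract_control(calls, calls, 50L)), 0L)
})

test_that("gap intersection pads loci and reports the flagged fraction", {
  gaps <- data.frame(chrom = "chr1", start = 90L, end = 120L, n_count = 31L,
                     stringsAsFactors = FALSE)
  r <- intersect_gaps(mk_calls("chr1", 100L, 101L), gaps, pad_bp = 0L)
  expect_true(r$calls$gap_overlap)
  far <- intersect_gaps(mk_calls("chr1", 500L, 501L),
                        data.frame(chrom = "chr1", start = 300L, end = 400L,
                                   n_count = 101L), pad_bp = 50L)
  expect_false(far$calls$gap_overlap)
  near <- intersect_gaps(mk_calls("chr1", 430L, 431L),
                         data.frame(chrom = "chr1", start = 300L, end = 400L,
                                    n_count = 101L), pad_bp = 50L)
  expect_true(near$calls$gap_overlap)
  mix <- intersect_gaps(mk_calls("chr1", c(100L, 5000L, 9000L)), gaps, 100L)
  expect_equal(mix$n_flagged, 1L)
  expect_equal(mix$fraction, 1 / 3)
})

test_that("sample comparison matches greedily, symmetrically, each call once", {
  a <- mk_calls("chr1", c(100L, 130L))
  b <- mk_calls("chr1", 120L)
  r <- compare_samples(a, b, tolerance_bp = 50L)
  expect_equal(r$n_shared, 1L)
  expect_equal(r$shared$idx_a, 2L)            # 130 is nearer to 120 than 100
  expect_equal(r$n_only_a + r$n_shared, nrow(a))
  ident <- compare_samples(a, a, 50L)
  expect_equal(c(ident$n_shared, ident$n_only_a, ident$n_only_b),
               c(2L, 0L, 0L))
  disj <- compare_samples(mk_calls("chr1", c(1L, 2L) * 1000L),
                          mk_calls("chr2", c(1L, 2L, 3L) * 1000L), 50L)
  expect_equal(c(disj$n_shared, disj$n_only_a, disj$n_only_b), c(0L, 2L, 3L))
})

test_that("greedy matching attains the optimum on well-separated instances", {
  set.seed(42)
  for (rep in 1:20) {
    n_a <- sample(1:6, 1); n_b <- sample(1:6, 1)
    # loci live on a coarse grid so candidate matches are unambiguous
    a <- mk_calls("chr1", sample(seq(1000L, 50000L, by = 1000L), n_a))
    b <- mk_calls("chr1", sample(seq(1000L, 50000L, by = 1000L), n_b) +
                    sample(-30:30, n_b, replace = TRUE))
    r <- compare_samples(a, b, tolerance_bp = 50L)
    adj <- outer(a$chrom, b$chrom, "==") &
      abs(outer(locus_mid <- (a$start + a$end) / 2,
                (b$start + b$end) / 2, "-")) <= 50L
    expect_equal(r$n_shared, oracle_max_matching(adj))
    # shared count is symmetric
    expect_equal(compare_samples(b, a, 50L)$n_shared, r$n_shared)
  }
})

test_that("per-TE tallies partition the call set, descending", {
  calls <- mk_calls("chr1", c(1, 2, 3, 4) * 1000L,
                    te_id = c("TE_A", "TE_A", "TE_A", "TE_B"))
  t1 <- tally_by_te(calls)
  expect_equal(t1$te_id, c("TE_A", "TE_B"))
  expect_equal(t1$n_teis, c(3L, 1L))
  expect_equal(sum(t1$n_teis), nrow(calls))
  expect_equal(nrow(tally_by_te(calls[0, ])), 0L)
  sf <- data.frame(te_id = c("TE_A", "TE_B"), subfamily = c("FAM1", "FAM1"),
                   stringsAsFactors = FALSE)
  t2 <- tally_by_te(calls, sf)
  expect_equal(t2$by_subfamily$n_teis, 4L)
})

test_that("the final table has ten columns and round-trips", {
  calls <- mk_calls("chr1", c(2000L, 1000L))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tei_table(calls, p)
  hdr <- strsplit(readLines(p, n = 1L), "\t")[[1]]
  expect_equal(hdr, c("chrom", "tei_start", "tei_end", "n_clipped_reads",
                      "n_insertion_reads", "te_id", "te_chrom", "te_start",
                      "te_end", "sample"))
  back <- read_tei_table(p)
  expect_equal(back, calls[order(calls$start), ], ignore_attr = TRUE)
  write_tei_table(calls[0, ], p)
  expect_equal(length(readLines(p)), 1L)      # header-only for no calls
})
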