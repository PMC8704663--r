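# Shared simulated fixtures, computed once per test run and cached.
# The end-to-end fixture follows the package's reference study conditions:
# 2 chromosomes x 500 kb, 20 planted 1-3 kb insertions with 5 bp TSDs,
# 8x depth, plus one 10x-covered decoy locus; thresholds scaled to the
# short-read regime (min_clip 300).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

e2e_call <- function(fx, sub_label = "s1", ...) {
  conf <- tei_config(bam = fx$bam, genome = fx$genome, te_bed = fx$te_bed,
                     fastq = fx$fastq, sample = sub_label, min_clip = 300L,
                     backend = "builtin", ...)
  suppressMessages(call_teis(conf, quiet = TRUE))
}

# zero-error study conditions with decoy
fixture_e2e <- function() cached("e2e", {
  cfg <- sim_config(seed = 42L, decoy = TRUE)
  fx <- simulate_mobilome(cfg, tempfile("e2e_"))
  res <- e2e_call(fx)
  list(cfg = cfg, fx = fx, res = res,
       ev = evaluate_calls(res$calls, fx$truth))
})

# same conditions at 5% substitution error
fixture_e2e_err <- function() cached("e2e_err", {
  cfg <- sim_config(seed = 42L, decoy = TRUE, sub_error_rate = 0.05)
  fx <- simulate_mobilome(cfg, tempfile("err_"))
  res <- e2e_call(fx)
  list(cfg = cfg, fx = fx, res = res,
       ev = evaluate_calls(res$calls, fx$truth))
})

# control/case pair sharing 10 of the case's 20 planted insertions
fixture_pair <- function() cached("pair", {
  cfg <- sim_config(seed = 101L)
  ref <- simulate_reference(cfg)
  truth <- plant_insertions(ref, cfg)            # 20 events
  shared <- truth[1:10, ]
  dir <- tempfile("pair_"); dir.create(dir)
  run_sample <- function(events, name, seed) {
    sim <- simulate_reads(ref, events, cfg, sample_name = name, seed = seed)
    sam <- file.path(dir, paste0(name, ".sam"))
    fq <- file.path(dir, paste0(name, ".fastq"))
    write_sim_reads(sim, ref, sam, fq)
    sam_to_bam(sam)
  }
  gpath <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ref$genome, gpath)
  bedpath <- file.path(dir, "te.bed")
  write_te_bed(ref$te_bed, bedpath)
  bam_control <- run_sample(shared, "control", cfg$seed + 11L)
  bam_case <- run_sample(truth, "case", cfg$seed + 12L)
  mk <- function(bam, name) suppressMessages(call_teis(tei_config(
    bam = bam, genome = gpath, te_bed = bedpath, sample = name,
    min_clip = 300L, backend = "builtin"), quiet = TRUE))
  list(ref = ref, truth = truth, shared = shared,
       control = mk(bam_control, "control"), case = mk(bam_case, "case"))
})

# small single-chromosome simulation for cheap unit-level checks
fixture_small <- function() cached("small", {
  cfg <- sim_config(seed = 9L, n_chroms = 1L, chrom_len = 200000L,
                    n_te_copies = 5L, te_len_range = c(800L, 1500L),
                    n_insertions = 3L, read_len_mean = 4000L,
                    read_len_sd = 1000L, depth = 8, n_gaps = 2L,
                    gap_len_range = c(3L, 50L))
  fx <- simulate_mobilome(cfg, tempfile("small_"))
  list(cfg = cfg, fx = fx)
})
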