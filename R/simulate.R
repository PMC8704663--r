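# Synthetic mobilome simulator.
#
# Builds a reference genome with embedded TE copies and N-run assembly gaps,
# plants TE insertions (with target-site duplications) into donor genomes,
# and emits reads whose alignments to the *reference* are computed
# analytically: a read spanning a planted insertion with enough anchor on
# both sides carries an M..I..M CIGAR; a read ending inside the insertion a
# terminal soft clip. Every pipeline stage is therefore testable against a
# known truth set with no external aligner or data download.

#' Simulation configuration
#'
#' Defaults emulate, at desk scale, a low-coverage plant nanopore run:
#' ~8x depth, read lengths around 6 kb (a halved N50-12kb regime, suited to
#' 500 kb chromosomes), TE copies of 1-3 kb, 5 bp target-site duplications.
#'
#' @param seed master RNG seed; the reference, planted events and reads are
#'   byte-deterministic under a fixed seed.
#' @param n_chroms,chrom_len genome shape.
#' @param n_te_copies,te_len_range TE library shape (lengths in bp).
#' @param n_insertions number of planted insertions.
#' @param tsd_len target-site duplication length (bp).
#' @param read_len_mean,read_len_sd read length distribution
#'   (Normal, truncated at 200 bp).
#' @param depth target mean coverage (x).
#' @param sub_error_rate per-base substitution probability (indel-free: the
#'   caller's signals are orders of magnitude larger than base-level noise,
#'   and substitutions keep the analytic CIGARs exact).
#' @param n_gaps,gap_len_range planted N-runs.
#' @param decoy plant one collapsed-repeat-like locus: an insertion whose
#'   local reads are duplicated 10x, which the coverage filter must reject.
#' @param anchor_bp minimum flanking match for a spanning read to be emitted
#'   as M..I..M rather than clipped (mirrors aligner behavior).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_chroms = 2L, chrom_len = 500000L,
                       n_te_copies = 30L, te_len_range = c(1000L, 3000L),
                       n_insertions = 20L, tsd_len = 5L,
                       read_len_mean = 6000L, read_len_sd = 2000L,
                       depth = 8, sub_error_rate = 0, n_gaps = 4L,
                       gap_len_range = c(3L, 300L), decoy = FALSE,
                       anchor_bp = 50L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = as.integer(chrom_len),
              n_te_copies = as.integer(n_te_copies),
              te_len_range = as.integer(te_len_range),
              n_insertions = as.integer(n_insertions),
              tsd_len = as.integer(tsd_len),
              read_len_mean = as.integer(read_len_mean),
              read_len_sd = as.integer(read_len_sd), depth = depth,
              sub_error_rate = sub_error_rate, n_gaps = as.integer(n_gaps),
              gap_len_range = as.integer(gap_len_range), decoy = decoy,
              anchor_bp = as.integer(anchor_bp))
  stopifnot(cfg$chrom_len > 0L, cfg$depth > 0,
            cfg$sub_error_rate >= 0, cfg$sub_error_rate < 0.2,
            cfg$read_len_mean > 0L, cfg$tsd_len >= 0L)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# draw positions on [lo, hi] pairwise at least min_dist apart and at least
# min_dist from `avoid` positions; bounded rejection sampling
draw_spaced <- function(n, lo, hi, min_dist, avoid = integer(0L),
                        avoid_dist = min_dist,
                        max_tries = 200L * max(n, 1L)) {
  pos <- integer(0L)
  tries <- 0L
  while (length(pos) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " features with spacing ", min_dist,
           " in [", lo, ", ", hi, "]; configuration infeasible")
    p <- sample.int(hi - lo + 1L, 1L) + lo - 1L
    if (all(abs(pos - p) >= min_dist) && all(abs(avoid - p) >= avoid_dist))
      pos <- c(pos, p)
  }
  sort(pos)
}

#' Simulate a reference genome with TE annotation and assembly gaps
#'
#' I.i.d. random sequence per chromosome; `n_te_copies` distinct TE
#' sequences embedded at annotated, non-overlapping positions; `n_gaps`
#' N-runs planted clear of TEs.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome_chr` (named character), `genome`
#'   ([Biostrings::DNAStringSet]), `te_bed` (chrom/start/end/te_id, 1-based
#'   closed), `te_seqs` (named character), `gaps` (chrom/start/end/n_count),
#'   `config`.
#' @export
simulate_reference <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    genome <- stats::setNames(
      vapply(chroms, function(x) random_dna(cfg$chrom_len), character(1L)),
      chroms)
    te_len <- sample(seq(cfg$te_len_range[1L], cfg$te_len_range[2L]),
                     cfg$n_te_copies, replace = TRUE)
    te_ids <- sprintf("TE%03d", seq_len(cfg$n_te_copies))
    te_seqs <- stats::setNames(vapply(te_len, random_dna, character(1L)),
                               te_ids)
    te_chrom <- sample(chroms, cfg$n_te_copies, replace = TRUE)
    margin <- 5000L
    spacing <- max(te_len) + 2000L
    bed <- list(); placed <- stats::setNames(
      rep(list(integer(0L)), length(chroms)), chroms)
    for (i in seq_len(cfg$n_te_copies)) {
      cn <- te_chrom[i]
      p <- draw_spaced(1L, margin, cfg$chrom_len - margin - te_len[i],
                       spacing, avoid = placed[[cn]])
      placed[[cn]] <- c(placed[[cn]], p)
      substr(genome[[cn]], p, p + te_len[i] - 1L) <- te_seqs[[i]]
      bed[[i]] <- data.frame(chrom = cn, start = p, end = p + te_len[i] - 1L,
                             te_id = te_ids[i], stringsAsFactors = FALSE)
    }
    te_bed <- do.call(rbind, bed)
    te_bed <- te_bed[order(te_bed$chrom, te_bed$start), , drop = FALSE]
    rownames(te_bed) <- NULL
    gaps <- NULL
    if (cfg$n_gaps > 0L) {
      gap_len <- sample(seq(cfg$gap_len_range[1L], cfg$gap_len_range[2L]),
                        cfg$n_gaps, replace = TRUE)
      gap_chrom <- sample(chroms, cfg$n_gaps, replace = TRUE)
      g <- list()
      for (i in seq_len(cfg$n_gaps)) {
        cn <- gap_chrom[i]
        p <- draw_spaced(1L, margin, cfg$chrom_len - margin - gap_len[i],
                         spacing, avoid = placed[[cn]])
        placed[[cn]] <- c(placed[[cn]], p)
        substr(genome[[cn]], p, p + gap_len[i] - 1L) <-
          strrep("N", gap_len[i])
        g[[i]] <- data.frame(chrom = cn, start = p, end = p + gap_len[i] - 1L,
                             n_count = gap_len[i], stringsAsFactors = FALSE)
      }
      gaps <- do.call(rbind, g)
      gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
      rownames(gaps) <- NULL
    } else {
      gaps <- data.frame(chrom = character(), start = integer(),
                         end = integer(), n_count = integer(),
                         stringsAsFactors = FALSE)
    }
    list(genome_chr = genome,
         genome = Biostrings::DNAStringSet(genome),
         te_bed = te_bed, te_seqs = te_seqs, gaps = gaps, config = cfg)
  })
}

#' Plant TE insertions: choose truth events
#'
#' Each event copies a donor TE into a uniformly drawn position clear of
#' annotated TEs, gaps, chromosome ends, and other events, duplicating
#' `tsd_len` reference bases at the junction (so the inserted sequence
#' relative to the reference is TE + TSD and the donor chromosome is
#' `te_len + tsd_len` bp longer per event). Reference coordinates remain
#' valid because detection is reference-guided. When `cfg$decoy` is set one
#' extra event is appended and flagged `is_decoy`; its locus will be
#' over-covered 10x by [simulate_reads()] and must be rejected by the
#' coverage filter, so it is excluded from recall/precision truth.
#'
#' @param ref output of [simulate_reference()].
#' @param cfg a [sim_config()]; defaults to the reference's.
#' @param seed RNG seed (default `cfg$seed + 1`).
#' @return truth data.frame: `event_id`, `chrom`, `pos` (insertion after
#'   this 1-based reference base), `te_id`, `te_len`, `ins_len`, `tsd_len`,
#'   `is_decoy`, `ins_seq`.
#' @export
plant_insertions <- function(ref, cfg = ref$config, seed = cfg$seed + 1L) {
  with_seed(seed, {
    n_total <- cfg$n_insertions + as.integer(isTRUE(cfg$decoy))
    if (n_total == 0L)
      return(data.frame(event_id = character(), chrom = character(),
                        pos = integer(), te_id = character(),
                        te_len = integer(), ins_len = integer(),
                        tsd_len = integer(), is_decoy = logical(),
                        ins_seq = character(), stringsAsFactors = FALSE))
    chroms <- names(ref$genome_chr)
    margin <- max(cfg$read_len_mean + 4L * cfg$read_len_sd, 10000L)
    spacing <- 25000L
    # spread events evenly over chromosomes so the spaced placement stays
    # feasible regardless of seed
    ev_chrom <- sort(rep_len(chroms, n_total))
    pos <- integer(n_total)
    for (cn in unique(ev_chrom)) {
      ix <- which(ev_chrom == cn)
      avoid <- c(ref$te_bed$start[ref$te_bed$chrom == cn],
                 ref$te_bed$end[ref$te_bed$chrom == cn],
                 ref$gaps$start[ref$gaps$chrom == cn],
                 ref$gaps$end[ref$gaps$chrom == cn])
      pos[ix] <- draw_spaced(length(ix), margin, cfg$chrom_len - margin,
                             spacing, avoid = avoid, avoid_dist = 5000L,
                             max_tries = 2000L * length(ix))
    }
    te_id <- sample(names(ref$te_seqs), n_total, replace = TRUE)
    te_len <- nchar(ref$te_seqs[te_id])
    tsd <- vapply(seq_len(n_total), function(i)
      substr(ref$genome_chr[[ev_chrom[i]]], pos[i] - cfg$tsd_len + 1L,
             pos[i]), character(1L))
    truth <- data.frame(
      event_id = sprintf("ev%03d", seq_len(n_total)), chrom = ev_chrom,
      pos = pos, te_id = te_id, te_len = as.integer(te_len),
      ins_len = as.integer(te_len + cfg$tsd_len),
      tsd_len = cfg$tsd_len,
      is_decoy = c(rep(FALSE, cfg$n_insertions),
                   rep(TRUE, n_total - cfg$n_insertions)),
      ins_seq = paste0(ref$te_seqs[te_id], tsd), stringsAsFactors = FALSE)
    truth[order(truth$chrom, truth$pos), , drop = FALSE]
  })
}

# piecewise donor model of one chromosome: alternating reference segments
# and inserted sequences, with donor-coordinate bookkeeping
donor_pieces <- function(ref_seq, events) {
  ref_len <- nchar(ref_seq)
  pieces <- list(); d <- 0L; r <- 1L
  ev <- events[order(events$pos), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]
    pieces[[length(pieces) + 1L]] <-
      list(type = "R", d_start = d + 1L, d_end = d + (p - r + 1L),
           ref_start = r)
    d <- d + (p - r + 1L); r <- p + 1L
    L <- nchar(ev$ins_seq[i])
    pieces[[length(pieces) + 1L]] <-
      list(type = "I", d_start = d + 1L, d_end = d + L, anchor = p,
           seq = ev$ins_seq[i])
    d <- d + L
  }
  pieces[[length(pieces) + 1L]] <-
    list(type = "R", d_start = d + 1L, d_end = d + (ref_len - r + 1L),
         ref_start = r)
  pieces
}

donor_sequence <- function(ref_seq, pieces) {
  paste(vapply(pieces, function(p) {
    if (p$type == "I") p$seq
    else substr(ref_seq, p$ref_start, p$ref_start + (p$d_end - p$d_start))
  }, character(1L)), collapse = "")
}

# analytic alignment of a donor-read [s, e] back to the reference:
# returns NULL (unmapped: read has no anchored reference block) or
# list(pos, cigar)
align_donor_read <- function(pieces, s, e, anchor_bp) {
  blocks <- list()
  for (p in pieces) {
    if (p$d_end < s || p$d_start > e) next
    o_start <- max(s, p$d_start); o_end <- min(e, p$d_end)
    len <- o_end - o_start + 1L
    if (p$type == "R") {
      blocks[[length(blocks) + 1L]] <-
        list(op = "M", len = len,
             ref_start = p$ref_start + (o_start - p$d_start))
    } else {
      blocks[[length(blocks) + 1L]] <- list(op = "I", len = len)
    }
  }
  # fold an under-anchored terminal M into the adjacent clip: an aligner
  # would not anchor fewer than anchor_bp matching bases across an insertion
  is_m <- vapply(blocks, function(b) b$op == "M", logical(1L))
  n <- length(blocks)
  lead_clip <- 0L; trail_clip <- 0L
  repeat {
    if (n >= 1L && !is_m[1L]) {                       # leading I -> S
      lead_clip <- lead_clip + blocks[[1L]]$len
    } else if (n >= 2L && is_m[1L] && !is_m[2L] &&
               blocks[[1L]]$len < anchor_bp) {        # short anchor + I -> S
      lead_clip <- lead_clip + blocks[[1L]]$len
    } else break
    blocks <- blocks[-1L]; is_m <- is_m[-1L]; n <- n - 1L
  }
  repeat {
    if (n >= 1L && !is_m[n]) {
      trail_clip <- trail_clip + blocks[[n]]$len
    } else if (n >= 2L && is_m[n] && !is_m[n - 1L] &&
               blocks[[n]]$len < anchor_bp) {
      trail_clip <- trail_clip + blocks[[n]]$len
    } else break
    blocks <- blocks[-n]; is_m <- is_m[-n]; n <- n - 1L
  }
  if (n == 0L) return(NULL)
  ops <- character(0L)
  if (lead_clip > 0L) ops <- sprintf("%dS", lead_clip)
  for (b in blocks) ops <- c(ops, sprintf("%d%s", b$len, b$op))
  if (trail_clip > 0L) ops <- c(ops, sprintf("%dS", trail_clip))
  list(pos = blocks[[1L]]$ref_start, cigar = paste(ops, collapse = ""))
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, k, replace = TRUE)
  for (j in seq_len(k)) {
    p <- pos[j]
    a <- alt[[ch[p]]]
    if (!is.null(a)) ch[p] <- a[pick[j]]   # leave N and friends alone
  }
  paste(ch, collapse = "")
}

#' Simulate reads from a donor genome with analytic reference alignments
#'
#' Reads are drawn to reach `cfg$depth` mean coverage of the donor, with
#' Normal(`read_len_mean`, `read_len_sd`) lengths truncated at 200 bp.
#' Reverse-strand reads are emitted reverse-complemented in the FASTQ while
#' the alignment rows keep the reference-forward sequence and CIGAR, per SAM
#' conventions. Substitution errors are applied after CIGAR computation.
#' Reads lying entirely within an inserted sequence are unmappable and
#' appear in the FASTQ only. For a decoy event, reads near its locus are
#' duplicated 10x to mimic a collapsed repeat.
#'
#' @param ref output of [simulate_reference()].
#' @param truth output of [plant_insertions()] (any subset of its rows:
#'   samples sharing some events are simulated by subsetting).
#' @param cfg a [sim_config()].
#' @param sample_name label used in read ids.
#' @param seed RNG seed (default `cfg$seed + 2`).
#' @return list with `aln` (mapped reads: `read_id`, `flag`, `chrom`, `pos`,
#'   `mapq`, `strand`, `cigar`, `seq`, `ref_end`), `fastq` (named character,
#'   all reads, read orientation) and `truth`.
#' @export
simulate_reads <- function(ref, truth, cfg = ref$config, sample_name = "s1",
                           seed = cfg$seed + 2L) {
  with_seed(seed, {
    aln_rows <- list(); fq <- list(); counter <- 0L
    for (cn in names(ref$genome_chr)) {
      ev <- truth[truth$chrom == cn, , drop = FALSE]
      pieces <- donor_pieces(ref$genome_chr[[cn]], ev)
      donor <- donor_sequence(ref$genome_chr[[cn]], pieces)
      dlen <- nchar(donor)
      target <- cfg$depth * dlen
      lens <- integer(0L)
      while (sum(lens) < target) {
        batch <- pmax(200L, pmin(dlen, as.integer(round(
          stats::rnorm(200L, cfg$read_len_mean, cfg$read_len_sd)))))
        lens <- c(lens, batch)
      }
      lens <- lens[seq_len(which(cumsum(lens) >= target)[1L])]
      # stratified (jittered) start positions: one start per stratum of
      # ~dlen/n bp keeps the coverage uniform with no multi-kb sampling
      # holes, emulating an even-coverage run; gaps stay far below one
      # read length, so every junction is sampled at ~depth
      n_reads <- length(lens)
      starts <- as.integer(floor((seq_len(n_reads) - stats::runif(n_reads)) *
                                   dlen / n_reads)) + 1L
      starts <- pmin(pmax(1L, starts), dlen - lens + 1L)
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      decoy_pos <- ev$pos[ev$is_decoy]
      for (i in seq_along(lens)) {
        counter <- counter + 1L
        rid <- sprintf("%s_r%06d", sample_name, counter)
        s <- starts[i]; e <- s + lens[i] - 1L
        fwd <- apply_substitutions(substr(donor, s, e), cfg$sub_error_rate)
        a <- align_donor_read(pieces, s, e, cfg$anchor_bp)
        n_copies <- 1L
        if (length(decoy_pos) && !is.null(a)) {
          ref_end <- a$pos + cigar_ref_len(parse_cigar(a$cigar)) - 1L
          if (any(a$pos <= decoy_pos + 2000L & ref_end >= decoy_pos - 2000L))
            n_copies <- 10L
        }
        for (cp in seq_len(n_copies)) {
          id <- if (cp == 1L) rid else sprintf("%s_d%d", rid, cp)
          fq[[id]] <- if (strands[i] == "-") revcomp(fwd) else fwd
          if (!is.null(a)) {
            aln_rows[[length(aln_rows) + 1L]] <- data.frame(
              read_id = id, flag = if (strands[i] == "-") 16L else 0L,
              chrom = cn, pos = a$pos, mapq = 60L, strand = strands[i],
              cigar = a$cigar, seq = fwd, stringsAsFactors = FALSE)
          }
        }
      }
    }
    aln <- do.call(rbind, aln_rows)
    aln <- aln[order(aln$chrom, aln$pos, aln$read_id), , drop = FALSE]
    aln$ref_end <- aln$pos + vapply(aln$cigar, function(cg)
      cigar_ref_len(parse_cigar(cg)), integer(1L)) - 1L
    rownames(aln) <- NULL
    list(aln = aln, fastq = unlist(fq), truth = truth)
  })
}

#' Write a simulated read set as SAM and FASTQ
#'
#' @param sim output of [simulate_reads()].
#' @param ref output of [simulate_reference()].
#' @param sam_path,fastq_path output paths.
#' @export
write_sim_reads <- function(sim, ref, sam_path, fastq_path) {
  lens <- nchar(ref$genome_chr)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  a <- sim$aln
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  a$read_id, a$flag, a$chrom, a$pos, a$mapq, a$cigar,
                  a$seq, strrep("I", nchar(a$seq)))
  writeLines(c(hdr, body), sam_path)
  ids <- names(sim$fastq)
  writeLines(as.vector(rbind(paste0("@", ids), sim$fastq, "+",
                             strrep("I", nchar(sim$fastq)))), fastq_path)
  invisible(c(sam = sam_path, fastq = fastq_path))
}

#' One-shot simulation into a fixture directory
#'
#' Writes `genome.fa`, `te.bed`, `gaps.bed`, `<sample>.sam` (+ sorted,
#' indexed `<sample>.bam`), `<sample>.fastq` and `truth.tsv`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @param sample_name sample label.
#' @return named list of paths plus `truth` and `ref` (invisible inputs for
#'   downstream checks).
#' @export
simulate_mobilome <- function(cfg = sim_config(), dir = tempfile("sim_"),
                              sample_name = "s1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg)
  truth <- plant_insertions(ref, cfg)
  sim <- simulate_reads(ref, truth, cfg, sample_name = sample_name)
  gpath <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(ref$genome, gpath)
  write_te_bed(ref$te_bed, file.path(dir, "te.bed"))
  writeLines(sprintf("%s\t%d\t%d\tgap%d", ref$gaps$chrom,
                     ref$gaps$start - 1L, ref$gaps$end,
                     seq_len(nrow(ref$gaps))),
             file.path(dir, "gaps.bed"))
  sam <- file.path(dir, paste0(sample_name, ".sam"))
  fastq <- file.path(dir, paste0(sample_name, ".fastq"))
  write_sim_reads(sim, ref, sam, fastq)
  bam <- sam_to_bam(sam)
  utils::write.table(
    sim$truth[, c("event_id", "chrom", "pos", "te_id", "te_len", "ins_len",
                  "tsd_len", "is_decoy")],
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(dir = dir, genome = gpath, te_bed = file.path(dir, "te.bed"),
       gaps_bed = file.path(dir, "gaps.bed"), sam = sam, bam = bam,
       fastq = fastq, truth_tsv = file.path(dir, "truth.tsv"),
       truth = sim$truth, ref = ref, sim = sim)
}
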