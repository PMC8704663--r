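# Pipeline steps 3-4: pull the unaligned segment sequences out of the
# stored alignments (or the raw reads, for hard clips), map them back to the
# reference, intersect the placements with the TE annotation and keep the
# best-supported TE per candidate locus.

#' Extract segment sequences for clustered signals
#'
#' Soft-clip and insertion segments are sliced from the stored alignment
#' sequence; hard-clipped segments from the raw read after orienting it to
#' the alignment strand. Segment ids encode (cluster, read, kind, source
#' alignment row) bijectively.
#'
#' @param clustered output of [cluster_breakpoints()].
#' @param aln alignment data.frame the signals were scanned from.
#' @param fastq named character vector from [read_fastq_seqs()]; required
#'   only when hard-clipped signals are present.
#' @return data.frame with `segment_id`, `cluster_id`, `read_id`, `kind`,
#'   `seq`, `seg_len`.
#' @export
extract_segment_sequences <- function(clustered, aln, fastq = NULL) {
  sig <- clustered$signals
  proto <- data.frame(segment_id = character(), cluster_id = integer(),
                      read_id = character(), kind = character(),
                      seq = character(), seg_len = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(proto)
  hard <- sig$hard_clipped
  if (any(hard)) {
    need <- unique(sig$read_id[hard])
    if (is.null(fastq)) stop("hard-clipped signals present but no FASTQ given")
    missing <- setdiff(need, names(fastq))
    if (length(missing))
      stop("read(s) with hard clips absent from FASTQ: ",
           paste(missing, collapse = ", "))
  }
  seqs <- character(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    if (hard[i]) {
      raw <- fastq[[sig$read_id[i]]]
      if (sig$strand[i] == "-") raw <- revcomp(raw)
      src <- raw
    } else {
      src <- aln$seq[sig$aln_idx[i]]
    }
    if (sig$seg_end[i] > nchar(src))
      stop(sprintf("segment [%d,%d] out of range for read %s (length %d)",
                   sig$seg_start[i], sig$seg_end[i], sig$read_id[i],
                   nchar(src)))
    seqs[i] <- substr(src, sig$seg_start[i], sig$seg_end[i])
  }
  data.frame(
    segment_id = sprintf("cl%d|%s|%s|a%d", sig$cluster_id, sig$read_id,
                         sig$kind, sig$aln_idx),
    cluster_id = sig$cluster_id, read_id = sig$read_id, kind = sig$kind,
    seq = seqs, seg_len = sig$seg_len, stringsAsFactors = FALSE)
}

#' Write segments as FASTA
#'
#' @param segments data.frame from [extract_segment_sequences()].
#' @param path output FASTA path.
#' @export
write_segments_fasta <- function(segments, path) {
  x <- Biostrings::DNAStringSet(segments$seq)
  names(x) <- segments$segment_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

hit_proto <- data.frame(segment_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        strand = character(), aligned_len = integer(),
                        score = numeric(), stringsAsFactors = FALSE)

#' Map segment sequences back to the genome
#'
#' Two interchangeable backends behind one contract (segments + genome in,
#' one best placement per segment out):
#'
#' * `"minimap2"` — shells out to the minimap2 long-read aligner
#'   (`-x map-ont`) and parses its PAF output; the production path.
#' * `"builtin"` — a seed-and-vote exact/near-exact matcher: fixed-width
#'   k-mer seeds from each segment are matched exactly against both genome
#'   strands ([Biostrings::matchPDict()]) and vote for a placement diagonal;
#'   the best-voted diagonal gives the placement. Designed for
#'   substitution-level divergence; used by the test-suite and simulator
#'   workflows so no external binary is required.
#' * `"auto"` — minimap2 when on `PATH`, else builtin.
#'
#' Segments with no placement are dropped (count reported via `message()`).
#'
#' @param segments data.frame from [extract_segment_sequences()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param backend `"auto"`, `"builtin"` or `"minimap2"`.
#' @param k seed length for the builtin backend (bp).
#' @param seed_step spacing between seeds (bp).
#' @param min_seed_votes minimum concordant seeds for a builtin placement.
#' @return data.frame with `segment_id`, `chrom`, `start`, `end` (1-based
#'   closed placement), `strand`, `aligned_len`, `score`.
#' @export
map_segments <- function(segments, genome,
                         backend = c("auto", "builtin", "minimap2"),
                         k = 15L, seed_step = 10L, min_seed_votes = 3L) {
  backend <- match.arg(backend)
  if (backend == "auto")
    backend <- if (nzchar(Sys.which("minimap2"))) "minimap2" else "builtin"
  if (nrow(segments) == 0L) return(empty_df(hit_proto))
  hits <- switch(backend,
    builtin = map_segments_builtin(segments, genome, k, seed_step,
                                   min_seed_votes),
    minimap2 = map_segments_minimap2(segments, genome))
  dropped <- sum(!segments$segment_id %in% hits$segment_id)
  if (dropped > 0L)
    message(dropped, " segment(s) had no placement and were dropped")
  hits
}

# Seed-and-vote matcher. Seeds are taken every seed_step bp from the segment
# (forward) and its reverse complement; exact seed matches on the genome vote
# for the diagonal (genome position of segment base 1). Substitution errors
# leave enough clean seeds at the rates the caller tolerates; indel-free
# placements keep all true seeds on one diagonal.
map_segments_builtin <- function(segments, genome, k = 15L, seed_step = 10L,
                                 min_seed_votes = 3L) {
  seed_tab <- list()
  for (i in seq_len(nrow(segments))) {
    for (str in c("+", "-")) {
      s <- if (str == "+") segments$seq[i] else revcomp(segments$seq[i])
      L <- nchar(s)
      if (L < k) next
      offs <- unique(c(seq(1L, L - k + 1L, by = seed_step), L - k + 1L))
      seed_tab[[length(seed_tab) + 1L]] <- data.frame(
        seg = i, strand = str, off = offs,
        kmer = substring(s, offs, offs + k - 1L), stringsAsFactors = FALSE)
    }
  }
  if (length(seed_tab) == 0L) return(empty_df(hit_proto))
  seeds <- do.call(rbind, seed_tab)
  seeds <- seeds[!grepl("[^ACGT]", seeds$kmer), , drop = FALSE]
  if (nrow(seeds) == 0L) return(empty_df(hit_proto))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$kmer))
  votes <- list()
  for (chrom in names(genome)) {
    m <- Biostrings::matchPDict(pd, genome[[chrom]])
    st <- IRanges::start(m)
    n_hit <- lengths(st)
    if (sum(n_hit) == 0L) next
    idx <- rep.int(seq_along(st), n_hit)
    votes[[length(votes) + 1L]] <- data.frame(
      seg = seeds$seg[idx], strand = seeds$strand[idx], chrom = chrom,
      diag = unlist(st, use.names = FALSE) - seeds$off[idx] + 1L,
      stringsAsFactors = FALSE)
  }
  if (length(votes) == 0L) return(empty_df(hit_proto))
  v <- do.call(rbind, votes)
  out <- lapply(split(v, v$seg), function(g) {
    key <- paste(g$chrom, g$strand, g$diag, sep = "\r")
    tab <- sort(table(key), decreasing = TRUE)
    if (tab[1L] < min_seed_votes) return(NULL)
    best <- strsplit(names(tab)[1L], "\r", fixed = TRUE)[[1L]]
    i <- g$seg[1L]
    chrom <- best[1L]; strand <- best[2L]; diag <- as.integer(best[3L])
    L <- nchar(segments$seq[i])
    start <- max(1L, diag)
    end <- min(diag + L - 1L, length(genome[[chrom]]))
    if (end < start) return(NULL)
    data.frame(segment_id = segments$segment_id[i], chrom = chrom,
               start = start, end = end, strand = strand,
               aligned_len = end - start + 1L,
               score = as.numeric(tab[1L]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_df(hit_proto))
  rownames(res) <- NULL
  res
}

# minimap2 backend: write genome + segments to a scratch dir, parse PAF,
# keep the best placement per segment (most matching bases).
map_segments_minimap2 <- function(segments, genome) {
  if (!nzchar(Sys.which("minimap2")))
    stop("minimap2 not found on PATH; use backend = \"builtin\" or install it")
  dir <- tempfile("mm2_"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  gpath <- file.path(dir, "genome.fa")
  spath <- file.path(dir, "segments.fa")
  Biostrings::writeXStringSet(genome, gpath)
  write_segments_fasta(segments, spath)
  paf <- system2("minimap2", c("-x", "map-ont", "--secondary=no", gpath,
                               spath),
                 stdout = TRUE, stderr = FALSE)
  if (length(paf) == 0L) return(empty_df(hit_proto))
  f <- strsplit(paf, "\t", fixed = TRUE)
  rec <- do.call(rbind, lapply(f, function(x) data.frame(
    segment_id = x[1L], strand = x[5L], chrom = x[6L],
    start = as.integer(x[8L]) + 1L, end = as.integer(x[9L]),
    aligned_len = as.integer(x[9L]) - as.integer(x[8L]),
    score = as.numeric(x[10L]), stringsAsFactors = FALSE)))
  keep <- unlist(lapply(split(seq_len(nrow(rec)), rec$segment_id),
                        function(ix) ix[which.max(rec$score[ix])]))
  res <- rec[sort(keep), c("segment_id", "chrom", "start", "end", "strand",
                           "aligned_len", "score")]
  bad <- !res$segment_id %in% segments$segment_id
  if (any(bad)) stop("aligner returned unknown segment id(s)")
  rownames(res) <- NULL
  res
}

#' Assign the best-matching TE to each candidate cluster
#'
#' Segment placements are intersected with the TE annotation; per cluster,
#' candidate TEs are ranked by total overlap (bp) summed over the cluster's
#' placed segments, tie-broken by longer TE and then lexicographic id.
#' Overlaps below `min_overlap` bp do not count, so 1-bp interval touches
#' cannot drive an assignment. Clusters whose segments overlap no TE are
#' excluded (they are not TEIs).
#'
#' @param hits data.frame from [map_segments()].
#' @param segments data.frame from [extract_segment_sequences()] (links
#'   segment ids to clusters).
#' @param te_bed TE annotation from [read_te_bed()].
#' @param min_overlap minimum per-segment overlap in bp to count (default 50).
#' @return data.frame with `cluster_id`, `te_id`, `te_chrom`, `te_start`,
#'   `te_end`, `total_overlap_bp`, `n_supporting_segments`.
#' @export
assign_best_te <- function(hits, segments, te_bed, min_overlap = 50L) {
  proto <- data.frame(cluster_id = integer(), te_id = character(),
                      te_chrom = character(), te_start = integer(),
                      te_end = integer(), total_overlap_bp = integer(),
                      n_supporting_segments = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L || nrow(te_bed) == 0L) return(proto)
  te_bed <- te_bed[order(te_bed$chrom, te_bed$start), , drop = FALSE]
  gr_hit <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$start, hits$end))
  gr_te <- GenomicRanges::GRanges(te_bed$chrom,
                                  IRanges::IRanges(te_bed$start, te_bed$end))
  ov <- GenomicRanges::findOverlaps(gr_hit, gr_te)
  if (length(ov) == 0L) return(proto)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  wid <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_hit)[qh],
                                            IRanges::ranges(gr_te)[sh]))
  keep <- wid >= min_overlap
  if (!any(keep)) return(proto)
  cluster <- segments$cluster_id[match(hits$segment_id[qh[keep]],
                                       segments$segment_id)]
  tab <- data.frame(cluster_id = cluster, te_idx = sh[keep],
                    overlap = wid[keep], stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$cluster_id), function(g) {
    agg <- stats::aggregate(overlap ~ te_idx, data = g, FUN = sum)
    agg$n_seg <- stats::aggregate(overlap ~ te_idx, data = g,
                                  FUN = length)$overlap
    te <- te_bed[agg$te_idx, , drop = FALSE]
    ord <- order(-agg$overlap, -(te$end - te$start + 1L), te$te_id)
    b <- ord[1L]
    data.frame(cluster_id = g$cluster_id[1L], te_id = te$te_id[b],
               te_chrom = te$chrom[b], te_start = te$start[b],
               te_end = te$end[b], total_overlap_bp = agg$overlap[b],
               n_supporting_segments = agg$n_seg[b], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$cluster_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
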