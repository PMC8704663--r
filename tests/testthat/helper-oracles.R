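# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive re-derivation of the contract it checks, kept separate
# from the package's implementation path.

# --- CIGAR-walking oracle -------------------------------------------------
# Walks operations one at a time, accumulating reference and query offsets,
# and reports clip/insertion signals per the caller's contract.
oracle_signals <- function(aln, min_clip = 1000L, min_insertion = 100L) {
  tok <- regmatches(aln$cigar, gregexpr("[0-9]+[MIDNSHP=X]", aln$cigar))[[1]]
  op <- substring(tok, nchar(tok), nchar(tok))
  len <- as.integer(substring(tok, 1, nchar(tok) - 1))
  n <- length(op)
  clip <- op %in% c("S", "H")
  if (all(clip)) return(NULL)
  first_aln <- min(which(!clip)); last_aln <- max(which(!clip))
  ref_span <- sum(len[op %in% c("M", "D", "N", "=", "X")])
  stored_len <- sum(len[op %in% c("M", "I", "S", "=", "X")])
  raw_len <- stored_len + sum(len[op == "H"])
  out <- list()
  lead <- sum(len[seq_len(first_aln - 1)])
  if (first_aln > 1 && lead > min_clip) {
    hard <- any(op[seq_len(first_aln - 1)] == "H")
    out[[length(out) + 1]] <- data.frame(
      kind = "left_clip", pos = aln$pos, seg_start = 1L, seg_end = lead,
      hard_clipped = hard, stringsAsFactors = FALSE)
  }
  trail_ix <- if (last_aln < n) seq(last_aln + 1, n) else integer(0)
  trail <- sum(len[trail_ix])
  if (length(trail_ix) && trail > min_clip) {
    hard <- any(op[trail_ix] == "H")
    top <- if (hard) raw_len else stored_len
    out[[length(out) + 1]] <- data.frame(
      kind = "right_clip", pos = aln$pos + ref_span - 1L,
      seg_start = top - trail + 1L, seg_end = top, hard_clipped = hard,
      stringsAsFactors = FALSE)
  }
  ref_at <- aln$pos - 1L
  q_at <- sum(len[seq_len(first_aln - 1)][op[seq_len(first_aln - 1)] == "S"])
  for (i in seq(first_aln, last_aln)) {
    if (op[i] == "I" && len[i] >= min_insertion)
      out[[length(out) + 1]] <- data.frame(
        kind = "insertion", pos = ref_at, seg_start = q_at + 1L,
        seg_end = q_at + len[i], hard_clipped = FALSE,
        stringsAsFactors = FALSE)
    if (op[i] %in% c("M", "D", "N", "=", "X")) ref_at <- ref_at + len[i]
    if (op[i] %in% c("M", "I", "S", "=", "X")) q_at <- q_at + len[i]
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# canonical string form of a signal set, for exact set comparison
signal_signature <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(character(0))
  sort(sprintf("%s:%d:%d:%d:%d", df$kind, df$pos, df$seg_start, df$seg_end,
               as.integer(df$hard_clipped)))
}

# random valid CIGAR: optional clip group (S, H, or H-then-S), an aligned
# middle alternating match blocks with I/D/N, optional trailing clip group
random_cigar <- function() {
  piece <- function() sprintf("%d%s", sample(2000L, 1L),
                              sample(c("M", "=", "X"), 1L))
  mid <- piece()
  for (k in seq_len(sample(0:4, 1L)))
    mid <- paste0(mid, sprintf("%d%s", sample(2500L, 1L),
                               sample(c("I", "D", "N"), 1L)), piece())
  clip_group <- function() {
    kind <- sample(c("none", "S", "H", "HS"), 1L,
                   prob = c(0.3, 0.35, 0.2, 0.15))
    switch(kind,
           none = "",
           S = sprintf("%dS", sample(3000L, 1L)),
           H = sprintf("%dH", sample(3000L, 1L)),
           HS = sprintf("%dH%dS", sample(1500L, 1L), sample(1500L, 1L)))
  }
  lead <- clip_group()
  trail <- clip_group()
  if (nzchar(trail) && grepl("H", trail) && grepl("S", trail)) {
    # trailing groups are S then H in SAM order
    m <- regmatches(trail, gregexpr("[0-9]+[HS]", trail))[[1]]
    trail <- paste0(rev(m), collapse = "")
  }
  paste0(lead, mid, trail)
}

cigar_aln_row <- function(cigar, chrom = "chr1", pos = 10000L) {
  data.frame(read_id = "r", flag = 0L, chrom = chrom, pos = pos,
             mapq = 60L, strand = "+", cigar = cigar, seq = NA_character_,
             stringsAsFactors = FALSE)
}

# --- O(n^2) single-linkage clustering oracle ------------------------------
# All-pairs adjacency (same chrom, gap < merge_dist), connected components
# by breadth-first search.
oracle_cluster <- function(chrom, pos, merge_dist) {
  n <- length(pos)
  adj <- outer(chrom, chrom, "==") & abs(outer(pos, pos, "-")) < merge_dist
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# partition signature: sorted membership sets, order-free comparison
partition_signature <- function(labels) {
  sort(vapply(split(seq_along(labels), labels),
              function(ix) paste(sort(ix), collapse = ","), character(1)))
}

# --- regex gap oracle -----------------------------------------------------
oracle_gaps <- function(seq, min_run = 3L) {
  m <- gregexpr(sprintf("N{%d,}", min_run), seq)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# random N-salted sequence: random DNA with N runs of assorted lengths
random_n_salted <- function(len = 300L) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (k in seq_len(sample(0:6, 1L))) {
    run <- sample(1:6, 1L)
    at <- sample(len - run, 1L)
    ch[at:(at + run - 1L)] <- "N"
  }
  if (runif(1) < 0.3) ch[1:sample(1:5, 1L)] <- "N"          # boundary runs
  if (runif(1) < 0.3) ch[(len - sample(1:5, 1L) + 1L):len] <- "N"
  paste(ch, collapse = "")
}

# --- brute-force overlap / matching oracles -------------------------------
# summed overlap of [s1,e1] x [s2,e2] interval sets, all pairs
oracle_overlap_sum <- function(a_start, a_end, b_start, b_end, min_overlap) {
  total <- 0L
  for (i in seq_along(a_start)) for (j in seq_along(b_start)) {
    ov <- min(a_end[i], b_end[j]) - max(a_start[i], b_start[j]) + 1L
    if (ov >= min_overlap) total <- total + ov
  }
  total
}

# maximum bipartite matching size by exhaustive recursion (tiny instances)
oracle_max_matching <- function(adj) {
  n_a <- nrow(adj)
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (i > n_a) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used_b, count)
    for (j in which(adj[i, ] & !used_b)) {
      used_b[j] <- TRUE
      recurse(i + 1L, used_b, count + 1L)
      used_b[j] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ncol(adj)), 0L)
  best
}

# --- minimal SAM writer for hand-crafted alignment fixtures ---------------
write_mini_sam <- function(path, records, chrom_lens = c(chr1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lens), chrom_lens))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, mapq, cigar, seq) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s", qname, flag, rname,
          pos, mapq, cigar, seq,
          if (seq == "*") "*" else strrep("I", nchar(seq)))
}
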