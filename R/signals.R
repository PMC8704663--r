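# Pipeline step 1: scan alignments for large clipped ends (S/H) and large
# in-read insertions (I) and record the reference breakpoint each unaligned
# segment attaches to.

SIGNAL_KINDS <- c("left_clip", "right_clip", "insertion")

signal_proto <- data.frame(
  read_id = character(), aln_idx = integer(), kind = character(),
  chrom = character(), pos = integer(), seg_start = integer(),
  seg_end = integer(), seg_len = integer(), strand = character(),
  hard_clipped = logical(), stringsAsFactors = FALSE)

#' Extract breakpoint signals from one alignment record
#'
#' A leading clip (S/H run) longer than `min_clip` yields a `left_clip`
#' signal anchored at the alignment's reference start; a trailing clip
#' a `right_clip` at the reference end; every insertion (I) of at least
#' `min_insertion` bp an `insertion` signal at the reference base preceding
#' it. Clip length comparison is strict (`> min_clip`), matching the
#' pipeline's default of clips exceeding 1000 bp.
#'
#' Segment coordinates (`seg_start`, `seg_end`, 1-based closed) address the
#' stored alignment sequence for soft clips and insertions; when the clip
#' run contains a hard clip (`hard_clipped = TRUE`) they address the raw
#' read oriented to the alignment strand, and the sequence must be recovered
#' from the FASTQ.
#'
#' @param aln one-row data.frame as returned by [read_alignments()].
#' @param min_clip minimum clip length in bp, strict (default 1000).
#' @param min_insertion minimum insertion length in bp, inclusive
#'   (default 100).
#' @return data.frame of signals (possibly 0 rows) with columns `read_id`,
#'   `aln_idx`, `kind`, `chrom`, `pos`, `seg_start`, `seg_end`, `seg_len`,
#'   `strand`, `hard_clipped`.
#' @export
extract_signals <- function(aln, min_clip = 1000L, min_insertion = 100L) {
  ops <- parse_cigar(aln$cigar)
  n <- nrow(ops)
  is_clip <- ops$op %in% c("S", "H")
  lead_n <- sum(cumsum(!is_clip) == 0L)          # leading clip run
  trail_n <- sum(cumsum(rev(!is_clip)) == 0L)    # trailing clip run
  if (all(is_clip)) return(empty_df(signal_proto))
  lead_ops <- ops[seq_len(lead_n), , drop = FALSE]
  trail_ops <- ops[seq(n - trail_n + 1L, length.out = trail_n), , drop = FALSE]
  mid_ops <- ops[seq(lead_n + 1L, n - trail_n), , drop = FALSE]
  qlen <- cigar_query_len(ops)             # stored-sequence length
  lead_len <- sum(lead_ops$len)
  trail_len <- sum(trail_ops$len)
  raw_len <- qlen + sum(ops$len[ops$op == "H"])
  ref_end <- aln$pos + cigar_ref_len(ops) - 1L

  sig <- list()
  add <- function(kind, pos, s, e, hard) {
    data.frame(read_id = aln$read_id, aln_idx = NA_integer_, kind = kind,
               chrom = aln$chrom, pos = as.integer(pos),
               seg_start = as.integer(s), seg_end = as.integer(e),
               seg_len = as.integer(e - s + 1L), strand = aln$strand,
               hard_clipped = hard, stringsAsFactors = FALSE)
  }
  if (lead_len > min_clip) {
    hard <- any(lead_ops$op == "H")
    sig[[length(sig) + 1L]] <- add("left_clip", aln$pos, 1L, lead_len, hard)
  }
  if (trail_len > min_clip) {
    hard <- any(trail_ops$op == "H")
    end_coord <- if (hard) raw_len else qlen
    sig[[length(sig) + 1L]] <-
      add("right_clip", ref_end, end_coord - trail_len + 1L, end_coord, hard)
  }
  # walk the aligned middle for large insertions
  ref_off <- aln$pos - 1L
  q_off <- sum(lead_ops$len[lead_ops$op == "S"])  # stored bases before middle
  for (i in seq_len(nrow(mid_ops))) {
    op <- mid_ops$op[i]; len <- mid_ops$len[i]
    if (op == "I" && len >= min_insertion) {
      sig[[length(sig) + 1L]] <-
        add("insertion", ref_off, q_off + 1L, q_off + len, FALSE)
    }
    if (op %in% REF_OPS) ref_off <- ref_off + len
    if (op %in% QUERY_OPS) q_off <- q_off + len
  }
  if (length(sig) == 0L) return(empty_df(signal_proto))
  do.call(rbind, sig)
}

#' Scan an alignment table for breakpoint signals
#'
#' Applies [extract_signals()] to every record and returns the concatenated
#' signal table, stably ordered by (chrom, pos). `aln_idx` links each signal
#' back to its source row in `aln`.
#'
#' @param aln alignment data.frame from [read_alignments()].
#' @inheritParams extract_signals
#' @return signal data.frame, sorted by (chrom, pos).
#' @export
scan_alignments <- function(aln, min_clip = 1000L, min_insertion = 100L) {
  if (nrow(aln) == 0L) return(empty_df(signal_proto))
  out <- vector("list", nrow(aln))
  for (i in seq_len(nrow(aln))) {
    s <- extract_signals(aln[i, , drop = FALSE], min_clip, min_insertion)
    if (nrow(s)) s$aln_idx <- i
    out[[i]] <- s
  }
  sig <- do.call(rbind, out)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}
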