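# Downstream analyses over finalized TEI calls: assembly-gap discovery,
# control-call subtraction, between-sample comparison, per-TE tallies, and
# the final report table.

#' Find assembly gaps (maximal N-runs) in a genome
#'
#' Returns every maximal run of `N` of length at least `min_run` per
#' chromosome. Runs of ambiguous assembly sequence of three or more Ns mark
#' unassembled regions; insertions called at such positions are usually TE
#' copies hidden from the assembly rather than new transpositions.
#'
#' @param genome named [Biostrings::DNAStringSet] (or named character vector).
#' @param min_run minimum run length in bp (default 3).
#' @return data.frame with `chrom`, `start`, `end` (1-based closed),
#'   `n_count`, sorted by (chrom, start).
#' @export
find_assembly_gaps <- function(genome, min_run = 3L) {
  seqs <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  out <- list()
  for (cn in names(seqs)) {
    ch <- strsplit(seqs[[cn]], "", fixed = TRUE)[[1L]]
    r <- rle(ch == "N")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = starts[keep], end = ends[keep],
        n_count = r$lengths[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_count = integer(),
                      stringsAsFactors = FALSE))
  gaps <- do.call(rbind, out)
  gaps <- gaps[order(gaps$chrom, gaps$start), , drop = FALSE]
  rownames(gaps) <- NULL
  gaps
}

# proximity predicate shared by subtraction and comparison: same chromosome
# and locus midpoints within tolerance_bp
match_matrix <- function(a, b, tolerance_bp) {
  ma <- locus_mid(a); mb <- locus_mid(b)
  outer(a$chrom, b$chrom, "==") &
    abs(outer(ma, mb, "-")) <= tolerance_bp
}

#' Subtract control calls from a call set
#'
#' A call is removed iff some control call on the same chromosome has a locus
#' midpoint within `tolerance_bp`; TE identity is not required to match
#' (the same underlying event can be assigned different family members in
#' different samples). Typical use: subtract the wild-type/control call set
#' (reference-assembly artifacts) from a mutant sample before interpreting
#' new transpositions.
#'
#' @param calls,control_calls TEI call data.frames (columns `chrom`, `start`,
#'   `end`, ...).
#' @param tolerance_bp matching window in bp (default 50).
#' @return the retained rows of `calls`, unchanged.
#' @export
subtract_control <- function(calls, control_calls, tolerance_bp = 50L) {
  if (nrow(calls) == 0L || nrow(control_calls) == 0L) return(calls)
  hit <- rowSums(match_matrix(calls, control_calls, tolerance_bp)) > 0L
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag calls overlapping assembly gaps
#'
#' A call is flagged when its locus, padded by `pad_bp` on each side,
#' intersects a gap interval. Padding matters because an insertion caused by
#' a missing genome segment places its breakpoint at the gap edge, not
#' inside it.
#'
#' @param calls TEI call data.frame.
#' @param gaps gap data.frame from [find_assembly_gaps()].
#' @param pad_bp padding in bp (default 100).
#' @return list with `calls` (input plus logical `gap_overlap` column),
#'   `n_flagged`, and `fraction` flagged.
#' @export
intersect_gaps <- function(calls, gaps, pad_bp = 100L) {
  if (nrow(calls) == 0L) {
    calls$gap_overlap <- logical(0L)
    return(list(calls = calls, n_flagged = 0L, fraction = NaN))
  }
  flag <- logical(nrow(calls))
  if (nrow(gaps) > 0L) {
    gr_call <- GenomicRanges::GRanges(
      calls$chrom, IRanges::IRanges(pmax(1L, calls$start - pad_bp),
                                    calls$end + pad_bp))
    gr_gap <- GenomicRanges::GRanges(
      gaps$chrom, IRanges::IRanges(gaps$start, gaps$end))
    flag <- GenomicRanges::countOverlaps(gr_call, gr_gap) > 0L
  }
  calls$gap_overlap <- flag
  list(calls = calls, n_flagged = sum(flag),
       fraction = sum(flag) / nrow(calls))
}

#' Compare two samples' TEI call sets
#'
#' Symmetric proximity matching with the [subtract_control()] rule; each call
#' is matched at most once, greedily by smallest midpoint distance. Reports
#' the shared calls and those unique to each sample
#' (`|shared| + |only_a| = |calls_a|`).
#'
#' @param calls_a,calls_b TEI call data.frames.
#' @param tolerance_bp matching window in bp (default 50).
#' @return list with `shared` (data.frame of matched index pairs `idx_a`,
#'   `idx_b` and their distance), `only_a`, `only_b` (unmatched rows), and
#'   counts `n_shared`, `n_only_a`, `n_only_b`.
#' @export
compare_samples <- function(calls_a, calls_b, tolerance_bp = 50L) {
  pairs <- data.frame(idx_a = integer(), idx_b = integer(),
                      dist = numeric(), stringsAsFactors = FALSE)
  if (nrow(calls_a) > 0L && nrow(calls_b) > 0L) {
    m <- match_matrix(calls_a, calls_b, tolerance_bp)
    cand <- which(m, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      d <- abs(locus_mid(calls_a)[cand[, 1L]] -
                 locus_mid(calls_b)[cand[, 2L]])
      ord <- order(d, cand[, 1L], cand[, 2L])
      used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
      for (i in ord) {
        ia <- cand[i, 1L]; ib <- cand[i, 2L]
        if (!used_a[ia] && !used_b[ib]) {
          used_a[ia] <- TRUE; used_b[ib] <- TRUE
          pairs <- rbind(pairs, data.frame(idx_a = ia, idx_b = ib,
                                           dist = d[i]))
        }
      }
    }
  }
  only_a <- calls_a[setdiff(seq_len(nrow(calls_a)), pairs$idx_a), ,
                    drop = FALSE]
  only_b <- calls_b[setdiff(seq_len(nrow(calls_b)), pairs$idx_b), ,
                    drop = FALSE]
  list(shared = pairs, only_a = only_a, only_b = only_b,
       n_shared = nrow(pairs), n_only_a = nrow(only_a),
       n_only_b = nrow(only_b))
}

#' Tally TEI calls per donor TE (and optionally per subfamily)
#'
#' @param calls TEI call data.frame with a `te_id` column.
#' @param subfamily_map optional data.frame (`te_id`, `subfamily`) mapping
#'   ids to subfamilies.
#' @return data.frame `te_id`, `n_teis` sorted descending; when
#'   `subfamily_map` is given, also a `by_subfamily` attribute-free second
#'   element in a list: `list(by_te, by_subfamily)`.
#' @export
tally_by_te <- function(calls, subfamily_map = NULL) {
  by_te <- if (nrow(calls) == 0L)
    data.frame(te_id = character(), n_teis = integer(),
               stringsAsFactors = FALSE)
  else {
    t1 <- as.data.frame(table(calls$te_id), stringsAsFactors = FALSE)
    names(t1) <- c("te_id", "n_teis")
    t1[order(-t1$n_teis, t1$te_id), , drop = FALSE]
  }
  rownames(by_te) <- NULL
  if (is.null(subfamily_map)) return(by_te)
  sf <- subfamily_map$subfamily[match(calls$te_id, subfamily_map$te_id)]
  by_sf <- if (nrow(calls) == 0L)
    data.frame(subfamily = character(), n_teis = integer(),
               stringsAsFactors = FALSE)
  else {
    t2 <- as.data.frame(table(ifelse(is.na(sf), "unknown", sf)),
                        stringsAsFactors = FALSE)
    names(t2) <- c("subfamily", "n_teis")
    t2[order(-t2$n_teis, t2$subfamily), , drop = FALSE]
  }
  rownames(by_sf) <- NULL
  list(by_te = by_te, by_subfamily = by_sf)
}

#' Write the final TEI table
#'
#' Tab-separated, ten columns: `chrom`, `tei_start`, `tei_end` (1-based
#' inclusive display coordinates), `n_clipped_reads`, `n_insertion_reads`,
#' `te_id`, `te_chrom`, `te_start`, `te_end`, `sample`. Rows ordered by
#' (chrom, start).
#'
#' @param calls TEI call data.frame.
#' @param path output path.
#' @export
write_tei_table <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, tei_start = calls$start,
                    tei_end = calls$end,
                    n_clipped_reads = calls$n_clipped_reads,
                    n_insertion_reads = calls$n_insertion_reads,
                    te_id = calls$te_id, te_chrom = calls$te_chrom,
                    te_start = calls$te_start, te_end = calls$te_end,
                    sample = calls$sample, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$tei_start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TEI table written by [write_tei_table()]
#'
#' @param path TSV path.
#' @return TEI call data.frame with internal column names (`start`, `end`).
#' @export
read_tei_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character",
                                        te_id = "character",
                                        te_chrom = "character",
                                        sample = "character"))
  names(x)[names(x) == "tei_start"] <- "start"
  names(x)[names(x) == "tei_end"] <- "end"
  x
}
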