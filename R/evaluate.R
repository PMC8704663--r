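# Truth-set evaluation for simulated runs: recall, precision, breakpoint
# accuracy and donor-TE assignment accuracy against planted insertions.

#' Evaluate TEI calls against a simulated truth set
#'
#' Calls are matched to planted (non-decoy) insertions greedily by smallest
#' midpoint distance on the same chromosome within `tolerance_bp`; each call
#' and each event matches at most once. The decoy event, when present, is
#' excluded from the truth: a call at its locus counts as a false positive.
#'
#' @param calls TEI call data.frame from [call_teis()].
#' @param truth truth data.frame from [plant_insertions()].
#' @param tolerance_bp matching window in bp (default 50).
#' @return list with `recall`, `precision`, `mean_bp_error`,
#'   `assignment_accuracy` (fraction of matched calls naming the true donor
#'   TE), `n_true`, `n_calls`, `n_matched`, and the matched pair table.
#' @export
evaluate_calls <- function(calls, truth, tolerance_bp = 50L) {
  tr <- truth[!truth$is_decoy, , drop = FALSE]
  pairs <- data.frame(call = integer(), event = integer(), dist = numeric())
  if (nrow(calls) && nrow(tr)) {
    mids <- locus_mid(calls)
    m <- outer(calls$chrom, tr$chrom, "==") &
      abs(outer(mids, tr$pos, "-")) <= tolerance_bp
    cand <- which(m, arr.ind = TRUE)
    if (nrow(cand)) {
      d <- abs(mids[cand[, 1L]] - tr$pos[cand[, 2L]])
      ord <- order(d, cand[, 1L], cand[, 2L])
      used_c <- logical(nrow(calls)); used_t <- logical(nrow(tr))
      for (i in ord) {
        ic <- cand[i, 1L]; it <- cand[i, 2L]
        if (!used_c[ic] && !used_t[it]) {
          used_c[ic] <- TRUE; used_t[it] <- TRUE
          pairs <- rbind(pairs, data.frame(call = ic, event = it,
                                           dist = d[i]))
        }
      }
    }
  }
  n_matched <- nrow(pairs)
  assign_ok <- if (n_matched)
    mean(calls$te_id[pairs$call] == tr$te_id[pairs$event]) else NaN
  list(recall = if (nrow(tr)) n_matched / nrow(tr) else NaN,
       precision = if (nrow(calls)) n_matched / nrow(calls) else NaN,
       mean_bp_error = if (n_matched) mean(pairs$dist) else NaN,
       assignment_accuracy = assign_ok,
       n_true = nrow(tr), n_calls = nrow(calls), n_matched = n_matched,
       pairs = pairs)
}
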