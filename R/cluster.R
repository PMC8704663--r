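# Pipeline step 2: merge adjacent reference breakpoints of clip and
# insertion signals into candidate TEI loci by single-linkage chaining.

cluster_proto <- data.frame(
  cluster_id = integer(), chrom = character(), start = integer(),
  end = integer(), n_clipped_reads = integer(), n_insertion_reads = integer(),
  support = integer(), stringsAsFactors = FALSE)

#' Cluster breakpoint signals into candidate TEI loci
#'
#' Single-linkage chaining per chromosome: consecutive sorted breakpoints
#' whose gap is strictly less than `merge_dist` join one cluster (positions
#' exactly `merge_dist` apart do not merge). Chains can therefore span more
#' than `merge_dist` end to end. Clip and insertion breakpoints are merged
#' jointly, both being evidence for one insertion locus.
#'
#' @param signals signal data.frame from [scan_alignments()].
#' @param merge_dist maximum gap in bp, strict (default 20).
#' @return list with `signals` (input plus a `cluster_id` column) and
#'   `clusters`, a summary data.frame with one row per cluster: `cluster_id`,
#'   `chrom`, `start`/`end` (min/max member breakpoint), `n_clipped_reads`,
#'   `n_insertion_reads` (distinct reads per evidence class) and `support`
#'   (distinct reads overall). Sorted by (chrom, start).
#' @export
cluster_breakpoints <- function(signals, merge_dist = 20L) {
  if (nrow(signals) == 0L) {
    signals$cluster_id <- integer(0L)
    return(list(signals = signals, clusters = empty_df(cluster_proto)))
  }
  s <- signals[order(signals$chrom, signals$pos), , drop = FALSE]
  new_cluster <- c(TRUE, s$chrom[-1L] != s$chrom[-nrow(s)] |
                     diff(s$pos) >= merge_dist)
  s$cluster_id <- cumsum(new_cluster)
  rownames(s) <- NULL
  cl <- lapply(split(s, s$cluster_id), function(g) {
    cnt <- count_support(g)
    data.frame(cluster_id = g$cluster_id[1L], chrom = g$chrom[1L],
               start = min(g$pos), end = max(g$pos),
               n_clipped_reads = cnt[["n_clipped_reads"]],
               n_insertion_reads = cnt[["n_insertion_reads"]],
               support = cnt[["support"]], stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, cl)
  clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  rownames(clusters) <- NULL
  list(signals = s, clusters = clusters)
}

#' Supporting-read counts for one cluster's signals
#'
#' Counts distinct read ids per evidence class: clipped reads (left or right
#' clip), insertion reads, and overall support. A read contributing both a
#' clip and an insertion is counted once in each class but once in `support`.
#'
#' @param signals signal rows belonging to one cluster.
#' @return named integer vector `n_clipped_reads`, `n_insertion_reads`,
#'   `support`.
#' @export
count_support <- function(signals) {
  stopifnot(nrow(signals) >= 1L)
  clip <- signals$read_id[signals$kind %in% c("left_clip", "right_clip")]
  ins <- signals$read_id[signals$kind == "insertion"]
  c(n_clipped_reads = length(unique(clip)),
    n_insertion_reads = length(unique(ins)),
    support = length(unique(signals$read_id)))
}
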