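# Pipeline step 5: estimate the genome-coverage distribution by random
# interval sampling, then remove candidate loci whose local read counts are
# outliers (too few reads: unsupported; too many: collapsed repeats and
# other multi-copy artifacts).

#' Build an empirical genome-coverage model
#'
#' Draws `n_intervals` windows of `window` bp uniformly over the genome
#' (chromosomes weighted by length) and records, for each, the number of
#' reads whose alignment overlaps the window. The resulting empirical
#' distribution backs the two-sided outlier filter: no parametric form is
#' assumed because long-read coverage is typically overdispersed.
#'
#' @param aln alignment data.frame from [read_alignments()].
#' @param genome_lengths named integer vector of chromosome lengths.
#' @param n_intervals number of sampled windows (default 10000, minimum 100).
#' @param window window width in bp (default 1000).
#' @param seed RNG seed; the model is reproducible bit-for-bit under a fixed
#'   seed.
#' @return object of class `coverage_model` with elements `samples`,
#'   `n_intervals`, `window`, `seed`.
#' @export
build_coverage_model <- function(aln, genome_lengths, n_intervals = 10000L,
                                 window = 1000L, seed = 42L) {
  if (n_intervals < 100L) stop("n_intervals must be at least 100")
  if (any(genome_lengths < window))
    stop("window (", window, " bp) exceeds the shortest chromosome")
  chroms <- names(genome_lengths)
  samples <- with_seed(seed, {
    chr <- sample(chroms, n_intervals, replace = TRUE,
                  prob = as.numeric(genome_lengths))
    start <- vapply(chr, function(cn)
      sample.int(genome_lengths[[cn]] - window + 1L, 1L), integer(1L))
    cov <- integer(n_intervals)
    for (cn in unique(chr)) {
      ix <- which(chr == cn)
      a <- aln[aln$chrom == cn, , drop = FALSE]
      cov[ix] <- IRanges::countOverlaps(
        IRanges::IRanges(start[ix], start[ix] + window - 1L),
        IRanges::IRanges(a$pos, a$ref_end))
    }
    cov
  })
  structure(list(samples = samples, n_intervals = n_intervals,
                 window = window, seed = seed),
            class = "coverage_model")
}

#' Empirical quantile of a coverage model
#'
#' Inverse-ECDF quantile (type 1), monotone in `q`.
#'
#' @param model a `coverage_model`.
#' @param q probability in `[0, 1]` (vectorized).
#' @return numeric quantile(s).
#' @export
coverage_quantile <- function(model, q) {
  stopifnot(inherits(model, "coverage_model"))
  stats::quantile(model$samples, q, type = 1, names = FALSE)
}

#' @export
print.coverage_model <- function(x, ...) {
  cat(sprintf(
    "coverage_model: %d windows of %d bp (seed %d); mean %.2f, q01/q50/q99 = %g/%g/%g\n",
    x$n_intervals, x$window, x$seed, mean(x$samples),
    coverage_quantile(x, 0.01), coverage_quantile(x, 0.5),
    coverage_quantile(x, 0.99)))
  invisible(x)
}

#' Filter candidate clusters against the coverage distribution
#'
#' A cluster is rejected with reason `LOW_SUPPORT` when its supporting-read
#' count is below `min_support`; `LOW_COVERAGE` when the read count over its
#' flanking positions falls below the model's `low_q` quantile (or below 1
#' read); `HIGH_COVERAGE` when it exceeds the `high_q` quantile (collapsed
#' repeats draw reads from many genomic copies). Otherwise `PASS`.
#'
#' The flank statistic is the mean of the read counts over two windows of
#' the model's window width placed `flank_bp` upstream of the locus start
#' and `flank_bp` downstream of its end. The windows deliberately exclude
#' the junction itself: reads sampled from the inserted sequence align
#' clipped at the junction, so any window containing it over-counts by
#' roughly `depth * insert_len / read_len` at every true insertion, whereas
#' the offset windows see plain local coverage and are directly comparable
#' to the model's sampled windows (a max over the two windows would have a
#' fatter upper tail than the single sampled windows; collapsed-repeat
#' pile-ups inflate both flanks, so the mean still detects them).
#'
#' @param clusters cluster summary data.frame from [cluster_breakpoints()].
#' @param aln alignment data.frame the model was built from.
#' @param model a `coverage_model` built from the same alignments.
#' @param min_support minimum supporting reads (default 2).
#' @param low_q,high_q lower/upper quantile bounds (defaults 0.01 / 0.99).
#' @param flank_bp offset of the flanking windows from the locus (default
#'   500).
#' @return data.frame with `cluster_id`, `support`, `flank_total`, `kept`,
#'   `reason`.
#' @export
filter_clusters <- function(clusters, aln, model, min_support = 2L,
                            low_q = 0.01, high_q = 0.99, flank_bp = 500L) {
  proto <- data.frame(cluster_id = integer(), support = integer(),
                      flank_total = integer(), kept = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L) return(proto)
  lo <- coverage_quantile(model, low_q)
  hi <- coverage_quantile(model, high_q)
  w <- model$window
  flank_total <- numeric(nrow(clusters))
  for (cn in unique(clusters$chrom)) {
    ix <- which(clusters$chrom == cn)
    a <- aln[aln$chrom == cn, , drop = FALSE]
    reads <- IRanges::IRanges(a$pos, a$ref_end)
    left <- IRanges::countOverlaps(
      IRanges::IRanges(pmax(1L, clusters$start[ix] - flank_bp - w + 1L),
                       pmax(1L, clusters$start[ix] - flank_bp)), reads)
    right <- IRanges::countOverlaps(
      IRanges::IRanges(clusters$end[ix] + flank_bp,
                       clusters$end[ix] + flank_bp + w - 1L), reads)
    flank_total[ix] <- (left + right) / 2
  }
  reason <- ifelse(clusters$support < min_support, "LOW_SUPPORT",
            ifelse(flank_total < max(lo, 1), "LOW_COVERAGE",
            ifelse(flank_total > hi, "HIGH_COVERAGE", "PASS")))
  data.frame(cluster_id = clusters$cluster_id, support = clusters$support,
             flank_total = flank_total, kept = reason == "PASS",
             reason = reason, stringsAsFactors = FALSE)
}
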