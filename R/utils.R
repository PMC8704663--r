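# Internal helpers shared across the pipeline.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state, so package functions that take
#' a `seed` argument never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Reverse-complement of a nucleotide string
#'
#' @param x character vector of sequences over A, C, G, T, N.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# midpoints of call loci, used by the proximity matcher
locus_mid <- function(calls) (calls$start + calls$end) / 2

# empty data.frame with given column names/prototypes
empty_df <- function(proto) proto[0L, , drop = FALSE]

`%||%` <- function(a, b) if (is.null(a)) b else a
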