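# CIGAR parsing and accounting.
#
# The caller's evidence is read from CIGAR strings directly (large S/H clips
# and large I operations), so the walker lives here rather than being
# delegated: reference-consuming ops are M, D, N, =, X; query-consuming ops
# (relative to the stored alignment sequence) are M, I, S, =, X. Hard clips
# consume neither but are part of the raw read.

CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
REF_OPS <- c("M", "D", "N", "=", "X")
QUERY_OPS <- c("M", "I", "S", "=", "X")

#' Parse a CIGAR string into an operation table
#'
#' @param cigar a single CIGAR string, e.g. `"1500S3000M"`.
#' @return data.frame with columns `op` (character) and `len` (integer),
#'   one row per operation in order.
#' @export
#' @examples
#' parse_cigar("100M2000I100M")
parse_cigar <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  tok <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (length(tok) == 0L || sum(nchar(tok)) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar)
  n <- nchar(tok)
  data.frame(op = substring(tok, n, n),
             len = as.integer(substring(tok, 1L, n - 1L)),
             stringsAsFactors = FALSE)
}

#' Reference and query footprint of a CIGAR
#'
#' `cigar_ref_len()` is the number of reference bases consumed (M, D, N, =, X);
#' `cigar_query_len()` the number of stored-sequence bases consumed
#' (M, I, S, =, X).
#'
#' @param ops operation table from [parse_cigar()].
#' @return integer length in bp.
#' @export
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% REF_OPS])

#' @rdname cigar_ref_len
#' @export
cigar_query_len <- function(ops) sum(ops$len[ops$op %in% QUERY_OPS])

# Validate the CIGAR accounting invariants for one alignment row.
# seq may be NA/"*" (sequence not stored); returns TRUE or a message.
check_cigar_accounting <- function(cigar, seq) {
  ops <- parse_cigar(cigar)
  if (any(ops$len < 1L)) return("zero-length CIGAR operation")
  if (!all(ops$op %in% CIGAR_OPS)) return("unknown CIGAR operation")
  if (!is.na(seq) && seq != "*" && cigar_query_len(ops) != nchar(seq))
    return(sprintf("CIGAR query length %d != stored sequence length %d",
                   cigar_query_len(ops), nchar(seq)))
  TRUE
}
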