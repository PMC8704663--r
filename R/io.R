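# Readers for the four pipeline inputs: TE annotation BED, genome FASTA,
# alignments (BAM/SAM), raw reads (FASTQ).

#' Read a 4-column TE annotation BED file
#'
#' BED coordinates (0-based half-open) are converted to the package's internal
#' 1-based closed convention on input. Records are sorted by (chrom, start);
#' duplicate TE ids are rejected.
#'
#' @param path path to a tab-separated BED file with at least 4 columns:
#'   chrom, start, end, te_id.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based closed),
#'   `te_id`.
#' @export
read_te_bed <- function(path) {
  if (!file.exists(path)) stop("TE BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty TE BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop(sprintf("fewer than 4 columns at line %d of %s", lineno[i], path))
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("non-integer coordinates at line %d of %s", lineno[i], path))
    if (s >= e)
      stop(sprintf("start >= end at line %d of %s", lineno[i], path))
    if (s < 0L)
      stop(sprintf("negative start at line %d of %s", lineno[i], path))
    out[[i]] <- data.frame(chrom = f[1L], start = s + 1L, end = e,
                           te_id = f[4L], stringsAsFactors = FALSE)
  }
  bed <- do.call(rbind, out)
  dup <- unique(bed$te_id[duplicated(bed$te_id)])
  if (length(dup))
    stop("duplicate TE id(s) in annotation: ", paste(dup, collapse = ", "))
  bed[order(bed$chrom, bed$start), , drop = FALSE]
}

#' Write a TE annotation table as 4-column BED
#'
#' Inverse of [read_te_bed()]: internal 1-based closed coordinates are
#' written as 0-based half-open BED.
#'
#' @param bed data.frame with `chrom`, `start`, `end`, `te_id`.
#' @param path output path.
#' @export
write_te_bed <- function(bed, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", bed$chrom, bed$start - 1L, bed$end,
                     bed$te_id), path)
  invisible(path)
}

#' Read a reference genome FASTA
#'
#' Headers are truncated at the first whitespace to form chromosome names;
#' sequences are uppercased. Duplicate names and empty files are errors.
#'
#' @param path FASTA path.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop("empty FASTA file: ", path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate FASTA header(s): ",
         paste(unique(names(g)[duplicated(names(g))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(as.character(g)))
}

#' Read raw reads from FASTQ
#'
#' @param path FASTQ path.
#' @return named character vector of read sequences (names = read ids,
#'   truncated at first whitespace).
#' @export
read_fastq_seqs <- function(path) {
  r <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(r) <- sub("\\s.*$", "", names(r))
  stats::setNames(toupper(as.character(r)), names(r))
}

#' Load alignment records from a BAM/SAM file
#'
#' Unmapped and secondary records are skipped; supplementary records are kept
#' (a read split across a large insertion is often primary + supplementary,
#' both carrying informative clips). Records below `min_mapq` are dropped.
#' Records violating CIGAR accounting (query-consuming operation lengths vs.
#' stored sequence length) are rejected with an error, never passed on.
#'
#' @param path BAM path (a SAM path is converted on the fly via
#'   [Rsamtools::asBam()]).
#' @param min_mapq minimum mapping quality; default 1 excludes mapq-0
#'   multi-mappers whose placements are arbitrary.
#' @param genome optional [Biostrings::DNAStringSet]; when given, alignment
#'   contigs absent from the genome are an error.
#' @return data.frame with one row per retained alignment: `read_id`, `flag`,
#'   `chrom`, `pos` (1-based leftmost reference position), `ref_end`, `mapq`,
#'   `strand`, `cigar`, `seq` (stored sequence, possibly `"*"`).
#' @export
read_alignments <- function(path, min_mapq = 1L, genome = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) path <- sam_to_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  aln <- data.frame(read_id = as.character(b$qname),
                    flag = as.integer(b$flag),
                    chrom = as.character(b$rname),
                    pos = as.integer(b$pos),
                    mapq = as.integer(b$mapq),
                    strand = as.character(b$strand),
                    cigar = as.character(b$cigar),
                    seq = as.character(b$seq),
                    stringsAsFactors = FALSE)
  aln <- aln[is.na(aln$mapq) | aln$mapq >= min_mapq, , drop = FALSE]
  if (nrow(aln)) {
    for (i in seq_len(nrow(aln))) {
      ok <- check_cigar_accounting(aln$cigar[i], aln$seq[i])
      if (!isTRUE(ok))
        stop(sprintf("invalid alignment record for read %s: %s",
                     aln$read_id[i], ok))
    }
    aln$ref_end <- aln$pos + vapply(aln$cigar, function(cg)
      cigar_ref_len(parse_cigar(cg)), integer(1L)) - 1L
  } else {
    aln$ref_end <- integer(0L)
  }
  if (!is.null(genome)) {
    missing_contig <- setdiff(unique(aln$chrom), names(genome))
    if (length(missing_contig))
      stop("alignment contig(s) absent from genome FASTA: ",
           paste(missing_contig, collapse = ", "))
  }
  rownames(aln) <- NULL
  aln
}

#' Convert a SAM file to sorted, indexed BAM
#'
#' @param sam SAM path.
#' @param destination output prefix (default: alongside the SAM).
#' @return path to the BAM file.
#' @export
sam_to_bam <- function(sam, destination = sub("\\.sam$", "", sam,
                                              ignore.case = TRUE)) {
  Rsamtools::asBam(sam, destination, overwrite = TRUE,
                   indexDestination = TRUE)
}
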