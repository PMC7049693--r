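#' Stranded genomic intervals
#'
#' All positional logic in the package runs on 0-based half-open, stranded
#' intervals (BED convention). `genomic_interval()` builds and validates a
#' tibble of such intervals; most pipeline tables simply carry the four
#' columns `chrom`, `start`, `end`, `strand`.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start offsets.
#' @param end Exclusive end offsets; `end > start` is required.
#' @param strand `"+"` or `"-"`; strand is mandatory, unstranded rows are
#'   rejected.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr1", 100, 200, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  ivl <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand)
  )
  validate_intervals(ivl)
  ivl
}

validate_intervals <- function(ivl) {
  if (!all(c("chrom", "start", "end", "strand") %in% names(ivl))) {
    rlang::abort("interval table needs chrom/start/end/strand columns",
      class = "snc_interval_error")
  }
  if (any(is.na(ivl$start)) || any(is.na(ivl$end)) ||
      any(ivl$start < 0) || any(ivl$start >= ivl$end)) {
    rlang::abort("intervals must satisfy 0 <= start < end",
      class = "snc_interval_error")
  }
  if (!all(ivl$strand %in% c("+", "-"))) {
    rlang::abort("strand must be '+' or '-' on every interval",
      class = "snc_interval_error")
  }
  invisible(ivl)
}

# Convert an interval tibble to GRanges (coordinates shift to 1-based).
as_granges <- function(ivl) {
  GenomicRanges::GRanges(
    seqnames = ivl$chrom,
    ranges = IRanges::IRanges(start = ivl$start + 1L, end = ivl$end),
    strand = ivl$strand
  )
}

# Convert GRanges back to a 0-based half-open tibble.
granges_to_tibble <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Number of bases shared by two intervals
#'
#' @param a,b Single-row interval tibbles (or lists with `chrom`, `start`,
#'   `end`, `strand`).
#' @param same_strand_only When `TRUE` (default), intervals on opposite
#'   strands share no bases, mirroring strand-specific intersection.
#' @return Integer count of shared bases; 0 when the chromosomes differ.
#' @examples
#' a <- genomic_interval("chr1", 100, 200, "+")
#' b <- genomic_interval("chr1", 150, 250, "+")
#' overlap_length(a, b)
#' @export
overlap_length <- function(a, b, same_strand_only = TRUE) {
  if (a$chrom != b$chrom) return(0L)
  if (same_strand_only && a$strand != b$strand) return(0L)
  max(0L, min(a$end, b$end) - max(a$start, b$start))
}

# Vectorised overlap widths between parallel interval columns.
overlap_width <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2))
}

#' Reverse complement of a nucleotide sequence
#'
#' Accepts DNA or RNA alphabet (case-insensitive); `U` is treated as `T`, so
#' the result is always DNA. Characters outside `A,C,G,T,U,N` are rejected.
#'
#' @param seq A single nucleotide string.
#' @return The reversed Watson-Crick complement, upper-case DNA.
#' @examples
#' reverse_complement("AAAC")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  s <- gsub("U", "T", s, fixed = TRUE)
  if (grepl("[^ACGTN]", s)) {
    rlang::abort("sequence contains characters outside {A,C,G,T,U,N}",
      class = "snc_alphabet_error")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Fetch the transcribed sequence of an interval from a genome
#'
#' Minus-strand intervals return the reverse complement of the plus-strand
#' sequence, i.e. the sequence as transcribed.
#'
#' @param genome A named [Biostrings::DNAStringSet] keyed by chromosome.
#' @param ivl An interval tibble (one or more rows).
#' @return Character vector of sequences, one per interval row.
#' @export
fetch_sequence <- function(genome, ivl) {
  validate_intervals(ivl)
  vapply(seq_len(nrow(ivl)), function(i) {
    chrom <- ivl$chrom[i]
    if (!chrom %in% names(genome)) {
      rlang::abort(paste0("chromosome not in genome: ", chrom),
        class = "snc_bounds_error")
    }
    chr_len <- length(genome[[chrom]])
    if (ivl$start[i] < 0 || ivl$end[i] > chr_len) {
      rlang::abort(
        sprintf("interval %s:%d-%d out of bounds (length %d)",
          chrom, ivl$start[i], ivl$end[i], chr_len),
        class = "snc_bounds_error"
      )
    }
    s <- as.character(Biostrings::subseq(genome[[chrom]],
      start = ivl$start[i] + 1L, end = ivl$end[i]))
    if (ivl$strand[i] == "-") reverse_complement(s) else s
  }, character(1))
}
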