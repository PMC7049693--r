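#' Read alignment records from a BED6 file
#'
#' Alignments enter the pipeline as BED6 records: `name` carries the read
#' id and `score` the number of genomic hits of the read (1 = uniquely
#' mapped). One file per sequencing dataset.
#'
#' @param path BED6 file.
#' @param dataset_id Dataset label attached to every record.
#' @return A read tibble: `chrom`, `start`, `end`, `strand`, `read_id`,
#'   `dataset_id`, `n_genomic_hits`.
#' @export
read_reads_bed <- function(path, dataset_id) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
    rlang::abort("unstranded BED records are not accepted",
      class = "snc_interval_error")
  }
  out <- granges_to_tibble(gr)
  out$read_id <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("read_%06d", seq_along(gr))
  out$dataset_id <- dataset_id
  out$n_genomic_hits <- if (!is.null(gr$score)) as.integer(gr$score) else 1L
  out
}

#' @rdname read_reads_bed
#' @param reads A read tibble as returned by `read_reads_bed()` or
#'   [simulate_reads()] (one dataset).
#' @export
write_reads_bed <- function(reads, path) {
  bed <- tibble::tibble(
    chrom = reads$chrom, start = reads$start, end = reads$end,
    name = reads$read_id, score = reads$n_genomic_hits, strand = reads$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a gene annotation from GTF
#'
#' GTF input is 1-based inclusive; coordinates are converted to the 0-based
#' half-open convention at this boundary. The `feature` column is taken from
#' the GTF feature field (gene, exon, intron, rDNA_5ETS, rDNA_ITS1, repeat);
#' `gene_id` and `gene_biotype` attributes populate the remaining columns.
#' Unstranded rows are rejected rather than defaulted, because every
#' downstream intersection is strand-specific.
#'
#' @param path GTF file.
#' @return An annotation tibble: `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `biotype`, `feature`.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
    rlang::abort("unstranded annotation rows are rejected",
      class = "snc_interval_error")
  }
  out <- granges_to_tibble(gr)
  out$gene_id <- as.character(gr$gene_id)
  out$biotype <- as.character(gr$gene_biotype)
  out$feature <- as.character(gr$type)
  out
}

#' @rdname read_annotation_gtf
#' @param annotation An annotation tibble.
#' @export
write_annotation_gtf <- function(annotation, path) {
  attrs <- sprintf('gene_id "%s"; gene_biotype "%s";',
    annotation$gene_id, annotation$biotype)
  gtf <- tibble::tibble(
    seqname = annotation$chrom,
    source = "snclust",
    feature = annotation$feature,
    start = annotation$start + 1L,
    end = annotation$end,
    score = ".",
    strand = annotation$strand,
    frame = ".",
    attribute = attrs
  )
  readr::write_tsv(gtf, path, col_names = FALSE, escape = "none")
  invisible(path)
}

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file (0-based half-open intervals with a score).
#' @return A tibble `chrom`, `start`, `end`, `score`.
#' @export
read_conservation_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score)
  )
  out
}

#' @rdname read_conservation_bedgraph
#' @param track A conservation track tibble.
#' @export
write_conservation_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "score")], path,
    col_names = FALSE)
  invisible(path)
}

#' Read or write genome/reference sequences as FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fasta
#' @param seqs A named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a cluster table as BED6 plus a sidecar TSV
#'
#' The BED row carries the cluster id (name) and read count (score); the
#' sidecar TSV holds the full tallies (unique reads, dataset sets, sequence).
#'
#' @param clusters A cluster tibble from [call_clusters()].
#' @param bed_path,tsv_path Output paths (`tsv_path = NULL` skips the
#'   sidecar).
#' @export
write_clusters <- function(clusters, bed_path, tsv_path = NULL) {
  bed <- tibble::tibble(
    chrom = clusters$chrom, start = clusters$start, end = clusters$end,
    name = clusters$cluster_id, score = clusters$read_count,
    strand = clusters$strand
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  if (!is.null(tsv_path)) {
    side <- clusters
    side$datasets_detected <- vapply(side$datasets_detected,
      function(x) paste(sort(x), collapse = ";"), character(1))
    readr::write_tsv(side, tsv_path)
  }
  invisible(bed_path)
}

#' @rdname write_clusters
#' @param tsv_path Path of a sidecar TSV written by `write_clusters()`.
#' @export
read_clusters <- function(tsv_path) {
  x <- readr::read_tsv(tsv_path, show_col_types = FALSE,
    col_types = readr::cols(chrom = "c", datasets_detected = "c"))
  x$datasets_detected <- lapply(x$datasets_detected, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  x
}
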