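#' Per-base read coverage on one chromosome and strand
#'
#' @param reads Read tibble restricted to one chromosome/strand (rows on
#'   other chromosomes or strands are rejected).
#' @param chrom,strand The chromosome and strand covered.
#' @param width Length of the returned vector; defaults to the maximum read
#'   end.
#' @return Numeric vector where position `i` (1-based over genomic offsets
#'   `i - 1`) counts reads overlapping that base; its sum equals the summed
#'   read lengths.
#' @export
coverage_profile <- function(reads, chrom, strand, width = NULL) {
  keep <- reads$chrom == chrom & reads$strand == strand
  if (!all(keep)) {
    rlang::abort("coverage_profile expects reads on a single chromosome/strand",
      class = "snc_interval_error")
  }
  width <- width %||% if (nrow(reads)) max(reads$end) else 0L
  cov <- numeric(width)
  if (nrow(reads)) {
    # difference-array accumulation, equivalent to per-base membership:
    # a read [s, e) increments at 1-based position s+1 and decrements at
    # e+1 (the decrement at width+1 falls off the vector)
    inc <- tabulate(reads$start + 1L, nbins = width)
    dec <- tabulate(pmin(reads$end, width) + 1L,
      nbins = width + 1L)[seq_len(width)]
    cov <- cumsum(as.numeric(inc - dec))
  }
  cov
}

#' Call read clusters from strand-aware alignments
#'
#' Blockbuster-style cluster calling: (i) reads are collapsed into tags
#' (identical chromosome, interval and strand) and tags supported by fewer
#' than `tag_filter` reads are discarded; (ii) surviving tags are chained
#' into per-strand coverage components (contiguously covered regions);
#' (iii) components totalling at least `min_cluster_reads` reads become
#' clusters. The cluster interval spans its member reads; tallies record
#' total reads, uniquely-mapped reads (`n_genomic_hits == 1`) and the
#' datasets contributing member reads. Output ordering is deterministic:
#' (chrom, start, end, strand).
#'
#' No sub-block decomposition is attempted: with full-length, low-jitter
#' coverage the cluster itself is the transcript candidate.
#'
#' @param reads Read tibble (the dataset(s) clusters are called from,
#'   typically the primary non-fragmented datasets).
#' @param genome Optional `DNAStringSet`; when given, each cluster's
#'   transcribed sequence is attached.
#' @param config An [pipeline_config()] object.
#' @return A cluster tibble: `cluster_id`, `chrom`, `start`, `end`,
#'   `strand`, `read_count`, `unique_read_count`, `datasets_detected`
#'   (list-column, initialised to the datasets among member reads),
#'   `sequence`.
#' @export
call_clusters <- function(reads, genome = NULL, config = pipeline_config()) {
  validate_intervals(reads)
  tags <- reads |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      n_unique = sum(.data$n_genomic_hits == 1L),
      datasets = list(unique(.data$dataset_id)),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_reads >= config$tag_filter)

  if (!nrow(tags)) return(empty_clusters())

  gr <- as_granges(tags)
  comp <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(comp)$revmap
  comp_tb <- granges_to_tibble(comp)
  comp_tb$read_count <- vapply(revmap, function(i) sum(tags$n_reads[i]), numeric(1))
  comp_tb$unique_read_count <- vapply(revmap, function(i) sum(tags$n_unique[i]), numeric(1))
  comp_tb$datasets_detected <- lapply(revmap, function(i) {
    sort(unique(unlist(tags$datasets[i])))
  })

  out <- comp_tb |>
    dplyr::filter(.data$read_count >= config$min_cluster_reads) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand)
  if (!nrow(out)) return(empty_clusters())
  out$read_count <- as.integer(out$read_count)
  out$unique_read_count <- as.integer(out$unique_read_count)
  out$cluster_id <- sprintf("cluster_%d", seq_len(nrow(out)))
  out$sequence <- if (!is.null(genome)) fetch_sequence(genome, out) else NA_character_
  dplyr::relocate(out, "cluster_id")
}

empty_clusters <- function() {
  tibble::tibble(
    cluster_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), read_count = integer(0),
    unique_read_count = integer(0), datasets_detected = list(),
    sequence = character(0)
  )
}

#' Determine the datasets a cluster is detected in
#'
#' A dataset counts as "detected" when at least `detect_min_reads` of its
#' reads overlap the cluster interval on the same strand. Antisense reads
#' never count.
#'
#' @param clusters Cluster tibble from [call_clusters()].
#' @param all_reads Read tibble pooling every investigated dataset.
#' @param config An [pipeline_config()] object.
#' @return The cluster tibble with its `datasets_detected` list-column
#'   replaced by the detection result over `all_reads`.
#' @export
detect_in_datasets <- function(clusters, all_reads,
                               config = pipeline_config()) {
  if (!nrow(clusters)) return(clusters)
  hits <- GenomicRanges::findOverlaps(
    as_granges(clusters), as_granges(all_reads), ignore.strand = FALSE
  )
  tally <- tibble::tibble(
    ci = S4Vectors::queryHits(hits),
    dataset = all_reads$dataset_id[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::count(.data$ci, .data$dataset) |>
    dplyr::filter(.data$n >= config$detect_min_reads)
  clusters$datasets_detected <- lapply(seq_len(nrow(clusters)), function(i) {
    sort(tally$dataset[tally$ci == i])
  })
  clusters
}
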