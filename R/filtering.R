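#' Strand-aware overlap join between clusters and annotation
#'
#' A left outer join in the style of strand-specific interval intersection:
#' every cluster is reported, together with each same-strand overlapping
#' annotation entry (or a single all-`NA` row when none overlaps).
#'
#' @param clusters Cluster tibble.
#' @param annotation Annotation tibble (see [read_annotation_gtf()]).
#' @return A tibble with one row per (cluster, overlapping entry) pair:
#'   cluster columns plus `gene_id`, `biotype`, `feature`, `overlap_bp`.
#' @export
annotation_overlap <- function(clusters, annotation) {
  validate_intervals(annotation)
  base <- clusters[, c("cluster_id", "chrom", "start", "end", "strand")]
  if (!nrow(clusters)) {
    return(dplyr::mutate(base, gene_id = character(0), biotype = character(0),
      feature = character(0), overlap_bp = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges(clusters), as_granges(annotation), ignore.strand = FALSE
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  matched <- dplyr::bind_cols(
    base[qi, ],
    annotation[si, c("gene_id", "biotype", "feature")],
    tibble::tibble(overlap_bp = as.integer(overlap_width(
      clusters$start[qi], clusters$end[qi],
      annotation$start[si], annotation$end[si]
    )))
  )
  unmatched <- base[setdiff(seq_len(nrow(clusters)), unique(qi)), ] |>
    dplyr::mutate(gene_id = NA_character_, biotype = NA_character_,
      feature = NA_character_, overlap_bp = NA_integer_)
  dplyr::bind_rows(matched, unmatched) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand, .data$gene_id)
}

# TRUE for clusters counting as previously annotated: same-strand overlap
# with a whitelisted gene entry or with any exon. Gene biotypes listed in
# config$annotated_exclude_biotypes (hosts, the 45S precursor unit) do not
# blacken a cluster at the gene level; their exons still do.
is_annotated <- function(clusters, annotation, config) {
  known <- annotation |>
    dplyr::filter(
      (.data$feature == "gene" &
         !.data$biotype %in% config$annotated_exclude_biotypes) |
        .data$feature == "exon"
    )
  if (!nrow(known) || !nrow(clusters)) return(rep(FALSE, nrow(clusters)))
  hits <- GenomicRanges::findOverlaps(
    as_granges(clusters), as_granges(known), ignore.strand = FALSE
  )
  seq_len(nrow(clusters)) %in% S4Vectors::queryHits(hits)
}

# Other genomic loci carrying the cluster's exact sequence (both strands),
# excluding the cluster's own locus. Used by the multimap exception.
find_identical_loci <- function(cluster, genome) {
  seq <- cluster$sequence
  if (is.na(seq) || !nzchar(seq)) return(NULL)
  out <- list()
  pat <- Biostrings::DNAString(seq)
  rcp <- Biostrings::reverseComplement(pat)
  for (chrom in names(genome)) {
    for (std in c("+", "-")) {
      m <- Biostrings::matchPattern(if (std == "+") pat else rcp, genome[[chrom]])
      if (length(m)) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = chrom, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = std
        )
      }
    }
  }
  if (!length(out)) return(NULL)
  hits <- dplyr::bind_rows(out)
  self <- hits$chrom == cluster$chrom & hits$start == cluster$start &
    hits$end == cluster$end & hits$strand == cluster$strand
  hits[!self, ]
}

#' Apply the novel-transcript filter cascade
#'
#' Implements the selection applied to called clusters: drop clusters
#' overlapping known annotation, outside the 20-500 nt size window, with
#' fewer than 100 uniquely mapped reads, detected in a single dataset,
#' antisense to the 45S pre-rRNA, or representing a fully retained intron.
#' Every discarded cluster reports **all** the filters it fails, enabling a
#' per-filter discard tally.
#'
#' The unique-read filter carries one exception: a low-unique cluster is
#' kept when its multimapped reads align only to loci that are themselves
#' non-annotated candidate clusters of the same run (the ETS/ITS situation,
#' where identical rDNA copies share all reads). Because multimapped reads
#' come from byte-identical gene copies, partner loci are located by exact
#' sequence match against the genome; the exception holds when at least one
#' other copy exists and every copy overlaps a same-strand non-annotated
#' candidate cluster.
#'
#' The retained-intron rule is operationalised as reciprocal overlap of at
#' least `retained_intron_recip` (90%) with an annotated intron and both
#' cluster boundaries within `retained_intron_tol` (5 nt) of the splice
#' sites.
#'
#' @param clusters Cluster tibble with tallies (and `datasets_detected`
#'   refreshed via [detect_in_datasets()] when multiple datasets are
#'   investigated).
#' @param annotation Annotation tibble.
#' @param config An [pipeline_config()] object.
#' @param genome Optional `DNAStringSet`; required for the multimap
#'   exception (without it the exception never applies).
#' @return An object of class `snc_filter_result`: a list with `verdicts`
#'   (tibble `cluster_id`, `kept`, `failed_filters` string plus list-column
#'   `failed_list`) and `kept` (the surviving cluster tibble). `tidy()`
#'   returns the verdicts.
#' @export
filter_cascade <- function(clusters, annotation, config = pipeline_config(),
                           genome = NULL) {
  n <- nrow(clusters)
  ann_genes <- dplyr::filter(annotation, .data$feature == "gene")
  introns <- dplyr::filter(annotation, .data$feature == "intron")

  annotated <- is_annotated(clusters, annotation, config)
  len <- clusters$end - clusters$start
  too_short <- len < config$min_len
  too_long <- len > config$max_len

  low_unique <- clusters$unique_read_count < config$min_unique_reads
  if (any(low_unique)) {
    candidate <- !annotated
    cand_gr <- as_granges(clusters[candidate, , drop = FALSE])
    for (i in which(low_unique)) {
      has_multi <- clusters$read_count[i] > clusters$unique_read_count[i]
      if (!has_multi || is.null(genome)) next
      partners <- find_identical_loci(clusters[i, ], genome)
      if (is.null(partners) || !nrow(partners)) next
      ov <- GenomicRanges::findOverlaps(as_granges(partners), cand_gr,
        ignore.strand = FALSE)
      all_covered <- length(unique(S4Vectors::queryHits(ov))) == nrow(partners)
      if (all_covered) low_unique[i] <- FALSE  # multimap exception
    }
  }

  n_datasets <- vapply(clusters$datasets_detected, function(x) length(unique(x)),
    numeric(1))
  single_dataset <- n_datasets < config$min_datasets

  # antisense of the 45S: positional overlap with an rRNA_45S gene on the
  # opposite strand
  rrna <- dplyr::filter(ann_genes, .data$biotype == "rRNA_45S")
  antisense_45S <- rep(FALSE, n)
  if (nrow(rrna) && n) {
    flipped <- rrna
    flipped$strand <- ifelse(rrna$strand == "+", "-", "+")
    hits <- GenomicRanges::findOverlaps(as_granges(clusters), as_granges(flipped),
      ignore.strand = FALSE)
    antisense_45S[unique(S4Vectors::queryHits(hits))] <- TRUE
  }

  retained_intron <- rep(FALSE, n)
  if (nrow(introns) && n) {
    hits <- GenomicRanges::findOverlaps(as_granges(clusters), as_granges(introns),
      ignore.strand = FALSE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- overlap_width(clusters$start[qi], clusters$end[qi],
      introns$start[si], introns$end[si])
    recip <- ov / pmax(len[qi], introns$end[si] - introns$start[si])
    near <- abs(clusters$start[qi] - introns$start[si]) <= config$retained_intron_tol &
      abs(clusters$end[qi] - introns$end[si]) <= config$retained_intron_tol
    retained_intron[unique(qi[recip >= config$retained_intron_recip & near])] <- TRUE
  }

  fails <- cbind(annotated, too_short, too_long, low_unique, single_dataset,
    antisense_45S, retained_intron)
  colnames(fails) <- FILTER_NAMES
  failed_list <- lapply(seq_len(n), function(i) FILTER_NAMES[fails[i, ]])
  kept <- !vapply(failed_list, function(x) length(x) > 0, logical(1))

  verdicts <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    kept = kept,
    failed_filters = vapply(failed_list, paste, character(1), collapse = ";"),
    failed_list = failed_list
  )
  structure(
    list(verdicts = verdicts, kept = clusters[kept, , drop = FALSE]),
    class = "snc_filter_result"
  )
}

#' @export
tidy.snc_filter_result <- function(x, ...) x$verdicts

#' @export
glance.snc_filter_result <- function(x, ...) {
  tally <- table(factor(unlist(x$verdicts$failed_list), levels = FILTER_NAMES))
  dplyr::bind_cols(
    tibble::tibble(
      n_clusters = nrow(x$verdicts),
      n_kept = sum(x$verdicts$kept),
      n_discarded = sum(!x$verdicts$kept)
    ),
    tibble::as_tibble(as.list(tally))
  )
}

#' @export
print.snc_filter_result <- function(x, ...) {
  cat(sprintf("<snc_filter_result> %d clusters: %d kept, %d discarded\n",
    nrow(x$verdicts), sum(x$verdicts$kept), sum(!x$verdicts$kept)))
  invisible(x)
}
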