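#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Run the full discovery pipeline
#'
#' Chains the stages end-to-end: cluster calling on the primary read set,
#' dataset-detection against all investigated datasets, the filter cascade,
#' evidence collection and biotype classification, and tRNA-fragment
#' mapping.
#'
#' @param primary_reads Read tibble of the dataset(s) clusters are called
#'   from.
#' @param all_reads Read tibble pooling every investigated dataset
#'   (defaults to `primary_reads`).
#' @param genome Named `DNAStringSet`.
#' @param annotation Annotation tibble.
#' @param refs Reference tibble (`id`, `biotype`, `seq`).
#' @param targets Named character vector of guide-search targets (or
#'   `NULL`).
#' @param config An [pipeline_config()] object.
#' @return An object of class `snc_discovery`: list with `clusters`,
#'   `filter` (`snc_filter_result`), `kept`, `evidence`, `biotypes`,
#'   `fragments`, `config`. `tidy()` returns the per-kept-cluster table
#'   (coordinates, tallies, biotype, rationale); `glance()` a one-row
#'   summary; `autoplot()` the biotype distribution.
#' @export
run_discovery <- function(primary_reads, all_reads = primary_reads, genome,
                          annotation, refs, targets = NULL,
                          config = pipeline_config()) {
  clusters <- call_clusters(primary_reads, genome, config)
  clusters <- detect_in_datasets(clusters, all_reads, config)
  flt <- filter_cascade(clusters, annotation, config, genome)
  kept <- flt$kept
  evidence <- if (nrow(kept)) {
    collect_evidence(kept, refs, targets, annotation, config)
  } else NULL
  biotypes <- if (!is.null(evidence)) {
    classify_biotype(evidence, kept, annotation, config)
  } else tibble::tibble(cluster_id = character(0), biotype = character(0),
    rationale = character(0))
  fragments <- map_fragments(biotypes, kept, refs, genome, config)
  structure(list(clusters = clusters, filter = flt, kept = kept,
    evidence = evidence, biotypes = biotypes, fragments = fragments,
    config = config), class = "snc_discovery")
}

#' @export
tidy.snc_discovery <- function(x, ...) {
  x$kept |>
    dplyr::select("cluster_id", "chrom", "start", "end", "strand",
      "read_count", "unique_read_count") |>
    dplyr::left_join(x$biotypes, by = "cluster_id")
}

#' @export
glance.snc_discovery <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_kept = nrow(x$kept),
    n_discarded = nrow(x$clusters) - nrow(x$kept),
    n_trna_family = sum(x$biotypes$biotype %in%
      c("tRNA_like", "pre_tRNA", "tRNA_fragment")),
    n_snorna = sum(x$biotypes$biotype %in% c("snoRNA_CD", "snoRNA_HACA")),
    n_spacer = sum(x$biotypes$biotype %in% c("ITS_RNA", "ETS_RNA")),
    n_unknown = sum(x$biotypes$biotype == "unknown")
  )
}

#' @export
print.snc_discovery <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<snc_discovery> %d clusters -> %d kept (%d tRNA-family, %d snoRNA, %d spacer, %d unknown)\n",
    g$n_clusters, g$n_kept, g$n_trna_family, g$n_snorna, g$n_spacer,
    g$n_unknown))
  invisible(x)
}

#' @export
autoplot.snc_discovery <- function(object, ...) {
  plot_biotype_distribution(object$biotypes)
}
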