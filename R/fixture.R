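#' Designed 12-cluster filter-cascade fixture
#'
#' A hand-designed scenario exercising every branch of the filter cascade
#' on one 20 kb chromosome: 2 annotated clusters, 1 too short, 1 too long,
#' 2 low-unique clusters for which the multimap exception fails (one with
#' a genomically unique sequence, one whose second copy sits in an
#' annotated gene), 1 low-unique cluster rescued by the exception (its
#' identical copy is covered by another candidate cluster), 2
#' single-dataset clusters (one of them the rescued cluster's partner), 1
#' cluster antisense to the 45S unit, 1 fully retained intron and 1 clean
#' cluster. Exactly the clean and the exception clusters survive.
#'
#' @param seed RNG seed for the background sequence (1).
#' @return A list: `clusters`, `annotation`, `genome`, `expected` (tibble
#'   `cluster_id`, `expected_kept`, `expected_filters`).
#' @export
filter_fixture <- function(seed = 1) {
  with_rng_seed(seed, {
    chrom_len <- 20000L
    bg <- rand_dna(chrom_len)
    # identical-copy plants: exception partner pair and annotated-copy pair
    exc_seq <- rand_dna(90)
    lowu2_seq <- rand_dna(80)
    genome <- Biostrings::DNAStringSet(c(fx = bg))
    genome[["fx"]] <- Biostrings::replaceAt(genome[["fx"]],
      IRanges::IRanges(c(9001L, 10001L, 7001L, 8001L),
        c(9090L, 10090L, 7080L, 8080L)),
      Biostrings::DNAStringSet(c(exc_seq, exc_seq, lowu2_seq, lowu2_seq)))

    cl <- function(id, start, end, strand, reads, unique, datasets) {
      tibble::tibble(cluster_id = id, chrom = "fx", start = as.integer(start),
        end = as.integer(end), strand = strand, read_count = as.integer(reads),
        unique_read_count = as.integer(unique),
        datasets_detected = list(datasets))
    }
    clusters <- dplyr::bind_rows(
      cl("fx_ann_trna", 1000, 1072, "+", 200, 200, c("d1", "d2")),
      cl("fx_ann_snrna", 2000, 2120, "+", 200, 200, c("d1", "d2")),
      cl("fx_short", 3000, 3015, "+", 200, 200, c("d1", "d2")),
      cl("fx_long", 4000, 4600, "+", 200, 200, c("d1", "d2")),
      cl("fx_lowu_unique_seq", 6000, 6080, "+", 200, 10, c("d1", "d2")),
      cl("fx_lowu_annot_copy", 7000, 7080, "+", 200, 10, c("d1", "d2")),
      cl("fx_exception", 9000, 9090, "+", 300, 0, c("d1", "d2")),
      cl("fx_single_partner", 10000, 10090, "+", 150, 0, "d1"),
      cl("fx_single", 11000, 11060, "+", 150, 150, "d1"),
      cl("fx_anti45S", 13000, 13100, "-", 150, 150, c("d1", "d2")),
      cl("fx_retained_intron", 17202, 17598, "+", 150, 150, c("d1", "d2")),
      cl("fx_clean", 19000, 19080, "+", 250, 250, c("d1", "d2"))
    )
    clusters$sequence <- fetch_sequence(genome, clusters)

    ann <- function(start, end, strand, gene_id, biotype, feature) {
      tibble::tibble(chrom = "fx", start = as.integer(start),
        end = as.integer(end), strand = strand, gene_id = gene_id,
        biotype = biotype, feature = feature)
    }
    annotation <- dplyr::bind_rows(
      ann(1000, 1072, "+", "fx_gene_tRNA", "tRNA", "gene"),
      ann(2000, 2120, "+", "fx_gene_snRNA_a", "snRNA", "gene"),
      ann(8000, 8080, "+", "fx_gene_snRNA_b", "snRNA", "gene"),
      ann(12000, 16000, "+", "fx_gene_45S", "rRNA_45S", "gene"),
      ann(17000, 18000, "+", "fx_gene_host", "protein_coding", "gene"),
      ann(17000, 17200, "+", "fx_gene_host", "protein_coding", "exon"),
      ann(17200, 17600, "+", "fx_gene_host", "protein_coding", "intron"),
      ann(17600, 17800, "+", "fx_gene_host", "protein_coding", "exon")
    )

    expected <- tibble::tibble(
      cluster_id = clusters$cluster_id,
      expected_kept = clusters$cluster_id %in% c("fx_exception", "fx_clean"),
      expected_filters = c("annotated", "annotated", "too_short", "too_long",
        "low_unique", "low_unique", "", "single_dataset", "single_dataset",
        "antisense_45S", "retained_intron", "")
    )
    list(clusters = clusters, annotation = annotation, genome = genome,
      expected = expected)
  })
}
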