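#' Map a tRNA fragment onto its reference tRNA
#'
#' Aligns a fragment cluster against the tRNA references, picks the best
#' hit (lowest e-value, ties broken by identity then reference id), and
#' expresses the fragment's aligned span as fractions of the reference
#' mature length (`rel_start`/`rel_end`; 0 and 1 are the mature 5' and 3'
#' ends). The genomic locus is then extended so that it is equivalent in
#' length and position to the full reference, and `extension_identity` is
#' the global percent identity of that extended genomic sequence against
#' the full reference: a fragment whose extension stays >= 75% identical is
#' flagged as processed from a (novel) tRNA gene rather than an isolated
#' tRNA-similar locus. Reference coordinates are genomic mature
#' coordinates, without a CCA tail.
#'
#' @param frag_seq Fragment sequence (cluster sequence).
#' @param frag_locus One-row interval tibble of the fragment's genomic
#'   locus (optionally with `cluster_id`).
#' @param refs Reference tibble; only `biotype == "tRNA"` rows are used.
#' @param genome Named `DNAStringSet`.
#' @param config An [pipeline_config()] object.
#' @return A one-row tibble: `cluster_id`, `reference_id`,
#'   `fragment_identity`, `rel_start`, `rel_end`, `extension_identity`,
#'   `positional_class`, `processed_from_novel_trna`.
#' @export
map_fragment <- function(frag_seq, frag_locus, refs, genome,
                         config = pipeline_config()) {
  trna_refs <- dplyr::filter(refs, .data$biotype == "tRNA")
  hits <- homology_search(frag_seq, trna_refs, config)
  if (!nrow(hits)) {
    rlang::abort("no tRNA reference hit for fragment",
      class = "snc_reference_error")
  }
  h <- hits[1, ]
  R <- h$r_len
  if (R < (h$q_end - h$q_start + 1)) {
    rlang::abort("reference shorter than the fragment's aligned span",
      class = "snc_reference_error")
  }
  rel_start <- (h$r_start - 1) / R
  rel_end <- h$r_end / R

  # reference-equivalent extension in transcribed (query) coordinates
  if (h$strand == "+") {
    t1 <- h$q_start - (h$r_start - 1)
    t2 <- h$q_end + (R - h$r_end)
  } else {
    t1 <- h$q_start - (R - h$r_end)
    t2 <- h$q_end + (h$r_start - 1)
  }
  chrom_len <- length(genome[[frag_locus$chrom]])
  if (frag_locus$strand == "+") {
    g1 <- frag_locus$start + (t1 - 1)
    g2 <- frag_locus$start + t2
  } else {
    g1 <- frag_locus$end - t2
    g2 <- frag_locus$end - (t1 - 1)
  }
  g1 <- max(0L, as.integer(g1))
  g2 <- min(chrom_len, as.integer(g2))
  ext_ivl <- genomic_interval(frag_locus$chrom, g1, g2, frag_locus$strand)
  ext_seq <- fetch_sequence(genome, ext_ivl)
  if (h$strand == "-") ext_seq <- reverse_complement(ext_seq)

  ref_seq <- trna_refs$seq[trna_refs$id == h$ref_id][1]
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE)
  gl <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ext_seq),
    subject = Biostrings::DNAString(toupper(gsub("U", "T", ref_seq, fixed = TRUE))),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend
  )
  ext_identity <- aln_identity(gl)

  tibble::tibble(
    cluster_id = frag_locus$cluster_id %||% NA_character_,
    reference_id = h$ref_id,
    fragment_identity = h$identity,
    rel_start = rel_start,
    rel_end = rel_end,
    extension_identity = ext_identity,
    positional_class = positional_class(rel_start, rel_end, config),
    processed_from_novel_trna = ext_identity >= config$extension_identity_min
  )
}

#' Positional class of a tRNA fragment
#'
#' Classifies relative coordinates on the reference mature tRNA into the
#' four positional groups, checked in this fixed order: `five_prime_half`
#' (`rel_start <= 0.1` and `rel_end` in `[0.4, 0.6]`), `three_prime_half`
#' (`rel_end >= 0.9` and `rel_start` in `[0.4, 0.6]`), `near_full`
#' (span >= 0.75), otherwise `internal`. The numeric windows formalise the
#' visual categories used for fragment maps and sit in the configuration.
#'
#' @param rel_start,rel_end Fractions in `[0, 1]`, `rel_start < rel_end`.
#' @param config An [pipeline_config()] object.
#' @return Character vector of class labels.
#' @examples
#' positional_class(0, 0.5)
#' positional_class(0.25, 0.72)
#' @export
positional_class <- function(rel_start, rel_end, config = pipeline_config()) {
  stopifnot(all(rel_start >= 0), all(rel_start < rel_end), all(rel_end <= 1))
  dplyr::case_when(
    rel_start <= config$trf_half_start &
      rel_end >= config$trf_half_lo & rel_end <= config$trf_half_hi ~
      "five_prime_half",
    rel_end >= 1 - config$trf_half_start &
      rel_start >= config$trf_half_lo & rel_start <= config$trf_half_hi ~
      "three_prime_half",
    rel_end - rel_start >= config$trf_near_full ~ "near_full",
    TRUE ~ "internal"
  )
}

#' Map every tRNA-fragment cluster of a biotype table
#'
#' Convenience wrapper running [map_fragment()] on each cluster classified
#' `tRNA_fragment`.
#'
#' @param biotypes Biotype call tibble from [classify_biotype()].
#' @param clusters Cluster tibble (same ids).
#' @param refs Reference tibble.
#' @param genome Named `DNAStringSet`.
#' @param config An [pipeline_config()] object.
#' @return A fragment-mapping tibble, one row per tRNA fragment.
#' @export
map_fragments <- function(biotypes, clusters, refs, genome,
                          config = pipeline_config()) {
  ids <- biotypes$cluster_id[biotypes$biotype == "tRNA_fragment"]
  rows <- lapply(ids, function(id) {
    cl <- clusters[clusters$cluster_id == id, ]
    map_fragment(cl$sequence, cl, refs, genome, config)
  })
  if (!length(rows)) {
    return(tibble::tibble(
      cluster_id = character(0), reference_id = character(0),
      fragment_identity = numeric(0), rel_start = numeric(0),
      rel_end = numeric(0), extension_identity = numeric(0),
      positional_class = character(0), processed_from_novel_trna = logical(0)
    ))
  }
  dplyr::bind_rows(rows)
}
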