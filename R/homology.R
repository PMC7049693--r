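# Local alignment scoring shared by the homology search, tRF mapping and
# ortholog identity: match +1, mismatch -2, affine gaps costing 5 for the
# first gapped base and 2 for each extension.
align_local <- function(query, subject, config) {
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = config$match, mismatch = config$mismatch, baseOnly = TRUE
  )
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = sub_mat,
    gapOpening = config$gap_open,
    gapExtension = config$gap_extend
  )
}

# Percent identity over aligned columns (gaps included in the denominator).
aln_identity <- function(aln) {
  100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# k-mer set of a sequence (character vector, possibly empty).
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Search a query sequence against a reference ncRNA set
#'
#' Seeded local alignment with e-value filtering. A reference is aligned
#' only when it shares an exact `seed_k`-mer (11 by default) with the query
#' in either orientation; seeded pairs are aligned locally (match +1,
#' mismatch -2, affine gaps 5/2) and scored in bits as
#' `S = raw * lambda / ln 2` with `lambda = 0.5`. The expectation value is
#' `E = m * n * 2^-S`, where `m` is the query length and `n` the summed
#' length of the reference set. Hits with `E` above `evalue_max` (0.01) are
#' dropped; survivors are sorted by e-value. The calibration constants are
#' a fixed, documented statistical convention, not a fitted model.
#'
#' @param query A nucleotide string.
#' @param refs Reference tibble with columns `id`, `biotype`, `seq`.
#' @param config An [pipeline_config()] object.
#' @return A tibble of hits: `ref_id`, `ref_biotype`, `q_start`, `q_end`,
#'   `r_start`, `r_end` (1-based alignment spans), `strand` (query
#'   orientation), `identity` (percent over aligned columns), `bits`,
#'   `evalue`, `q_len`, `r_len`.
#' @export
homology_search <- function(query, refs, config = pipeline_config()) {
  if (is.null(refs) || !nrow(refs)) {
    rlang::abort("empty reference set", class = "snc_reference_error")
  }
  query <- toupper(gsub("U", "T", query, fixed = TRUE))
  m <- nchar(query)
  n_total <- sum(nchar(refs$seq))
  k <- config$seed_k
  q_fwd <- kmer_set(query, k)
  q_rev <- kmer_set(reverse_complement(query), k)

  rows <- list()
  for (i in seq_len(nrow(refs))) {
    ref_seq <- toupper(gsub("U", "T", refs$seq[i], fixed = TRUE))
    r_kmers <- kmer_set(ref_seq, k)
    for (std in c("+", "-")) {
      seeds <- if (std == "+") q_fwd else q_rev
      if (!length(seeds) || !any(seeds %in% r_kmers)) next
      qs <- if (std == "+") query else reverse_complement(query)
      aln <- align_local(qs, ref_seq, config)
      raw <- Biostrings::score(aln)
      bits <- raw * config$lambda / log(2)
      evalue <- m * n_total * 2^(-bits)
      if (evalue > config$evalue_max) next
      pr <- Biostrings::pattern(aln)
      sr <- Biostrings::subject(aln)
      q1 <- Biostrings::start(pr); q2 <- Biostrings::end(pr)
      if (std == "-") {
        tmp <- q1
        q1 <- m - q2 + 1L
        q2 <- m - tmp + 1L
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        ref_id = refs$id[i], ref_biotype = refs$biotype[i],
        q_start = q1, q_end = q2,
        r_start = Biostrings::start(sr), r_end = Biostrings::end(sr),
        strand = std, identity = aln_identity(aln),
        n_match = Biostrings::nmatch(aln),
        bits = bits, evalue = evalue,
        q_len = m, r_len = nchar(ref_seq)
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      ref_id = character(0), ref_biotype = character(0),
      q_start = integer(0), q_end = integer(0), r_start = integer(0),
      r_end = integer(0), strand = character(0), identity = numeric(0),
      n_match = integer(0), bits = numeric(0), evalue = numeric(0),
      q_len = integer(0), r_len = integer(0)
    ))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$identity), .data$ref_id)
}

#' Ortholog sequence identity
#'
#' Aligns a cluster sequence against the orthologous region (the equivalent
#' coordinates extended by the ortholog flank) of another species and
#' reports percent identity over the aligned columns. When the species
#' lacks the region (`NA` input) or the best local alignment covers less
#' than half of the cluster, the result is "no equivalent".
#'
#' @param cluster_seq Cluster sequence.
#' @param species_seq Orthologous regional sequence, or `NA` when the
#'   species has no equivalent region.
#' @param config An [pipeline_config()] object.
#' @return A one-row tibble: `identity` (percent, `NA` for no equivalent),
#'   `no_equivalent` flag, `coverage` (aligned fraction of the cluster).
#' @export
ortholog_identity <- function(cluster_seq, species_seq,
                              config = pipeline_config()) {
  if (is.null(species_seq) || length(species_seq) == 0 ||
      is.na(species_seq) || !nzchar(species_seq)) {
    return(tibble::tibble(identity = NA_real_, no_equivalent = TRUE,
      coverage = 0))
  }
  aln <- align_local(cluster_seq, species_seq, config)
  pr <- Biostrings::pattern(aln)
  coverage <- (Biostrings::end(pr) - Biostrings::start(pr) + 1) /
    nchar(cluster_seq)
  if (coverage < 0.5) {
    return(tibble::tibble(identity = NA_real_, no_equivalent = TRUE,
      coverage = coverage))
  }
  tibble::tibble(identity = aln_identity(aln), no_equivalent = FALSE,
    coverage = coverage)
}
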