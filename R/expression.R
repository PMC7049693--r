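#' Mean conservation score over intervals
#'
#' Arithmetic mean of the per-base conservation score over all positions of
#' each interval. Bases missing from the track score 0 but stay in the
#' denominator (the convention for unaligned bases in phastCons-style
#' tracks).
#'
#' @param ivl Interval tibble (one or more rows).
#' @param track Conservation tibble (`chrom`, `start`, `end`, `score`;
#'   0-based half-open rows).
#' @return Numeric vector of means in `[0, 1]`, one per interval row.
#' @export
mean_conservation <- function(ivl, track) {
  validate_intervals(ivl)
  vapply(seq_len(nrow(ivl)), function(i) {
    len <- ivl$end[i] - ivl$start[i]
    rows <- track[track$chrom == ivl$chrom[i] &
      track$end > ivl$start[i] & track$start < ivl$end[i], , drop = FALSE]
    if (!nrow(rows)) return(0)
    ov <- overlap_width(ivl$start[i], ivl$end[i], rows$start, rows$end)
    sum(rows$score * ov) / len
  }, numeric(1))
}

#' Assign reads to features (embedded-gene priority)
#'
#' Each read goes to the smallest same-strand feature that fully contains
#' it — so reads of an intron-embedded gene are never double-counted to the
#' host — and otherwise to the same-strand feature with the largest
#' overlap. Reads overlapping no feature stay unassigned.
#'
#' @param reads Read tibble.
#' @param features Feature tibble: `feature_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return Character vector of `feature_id` per read (`NA` = unassigned).
#' @export
assign_reads <- function(reads, features) {
  out <- rep(NA_character_, nrow(reads))
  if (!nrow(reads) || !nrow(features)) return(out)
  width <- features$end - features$start
  rg <- as_granges(reads)
  fg <- as_granges(features)

  within <- GenomicRanges::findOverlaps(rg, fg, type = "within",
    ignore.strand = FALSE)
  if (length(within)) {
    w <- tibble::tibble(
      ri = S4Vectors::queryHits(within),
      fi = S4Vectors::subjectHits(within)
    ) |>
      dplyr::mutate(width = width[.data$fi],
        fid = features$feature_id[.data$fi]) |>
      dplyr::group_by(.data$ri) |>
      dplyr::arrange(.data$width, .data$fid, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
    out[w$ri] <- w$fid
  }

  rest <- which(is.na(out))
  if (length(rest)) {
    any_ov <- GenomicRanges::findOverlaps(rg[rest], fg, ignore.strand = FALSE)
    if (length(any_ov)) {
      ri <- rest[S4Vectors::queryHits(any_ov)]
      fi <- S4Vectors::subjectHits(any_ov)
      ov <- overlap_width(reads$start[ri], reads$end[ri],
        features$start[fi], features$end[fi])
      a <- tibble::tibble(ri = ri, fi = fi, ov = ov) |>
        dplyr::mutate(width = width[.data$fi],
          fid = features$feature_id[.data$fi]) |>
        dplyr::group_by(.data$ri) |>
        dplyr::arrange(dplyr::desc(.data$ov), .data$width, .data$fid,
          .by_group = TRUE) |>
        dplyr::slice(1) |>
        dplyr::ungroup()
      out[a$ri] <- a$fid
    }
  }
  out
}

#' TPM quantification over genes and kept clusters
#'
#' Counts reads per feature with embedded-gene priority (see
#' [assign_reads()]), splitting multimapped reads as `1/n_genomic_hits`,
#' and converts counts to transcripts per million per dataset:
#' `TPM = 1e6 * (count/length) / sum(count/length)`. Every column of the
#' returned matrix sums to one million.
#'
#' @param reads Read tibble across datasets (column `dataset_id`).
#' @param features Feature tibble: `feature_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return A wide tibble: `feature_id`, then one TPM column per dataset.
#'   Attributes `counts` (matching tibble of fractional counts) and
#'   `n_unassigned` (reads matching no feature, per dataset).
#' @export
tpm_quantify <- function(reads, features) {
  stopifnot(!anyDuplicated(features$feature_id))
  fid <- assign_reads(reads, features)
  w <- 1 / reads$n_genomic_hits
  datasets <- sort(unique(reads$dataset_id))

  counts <- tibble::tibble(
    feature_id = fid, dataset_id = reads$dataset_id, w = w
  ) |>
    dplyr::filter(!is.na(.data$feature_id)) |>
    dplyr::group_by(.data$feature_id, .data$dataset_id) |>
    dplyr::summarise(count = sum(.data$w), .groups = "drop")

  grid <- tidyr::expand_grid(
    feature_id = features$feature_id, dataset_id = datasets
  ) |>
    dplyr::left_join(counts, by = c("feature_id", "dataset_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0)) |>
    dplyr::left_join(
      tibble::tibble(feature_id = features$feature_id,
        len = features$end - features$start),
      by = "feature_id"
    ) |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::mutate(tpm = {
      rate <- .data$count / .data$len
      if (sum(rate) > 0) 1e6 * rate / sum(rate) else rate * 0
    }) |>
    dplyr::ungroup()

  out <- grid |>
    dplyr::select("feature_id", "dataset_id", "tpm") |>
    tidyr::pivot_wider(names_from = "dataset_id", values_from = "tpm")
  out <- out[match(features$feature_id, out$feature_id), ]
  attr(out, "counts") <- grid |>
    dplyr::select("feature_id", "dataset_id", "count") |>
    tidyr::pivot_wider(names_from = "dataset_id", values_from = "count")
  attr(out, "n_unassigned") <- tapply(
    is.na(fid), reads$dataset_id, sum)[datasets]
  out
}

#' Host-gene expression correlation of an embedded cluster
#'
#' Rank (Spearman) correlation of cluster TPM against host-gene TPM across
#' datasets. The expression mode is `host_dependent` when the correlation
#' reaches `host_corr_min` (0.5), `independent` when it is non-positive,
#' `indeterminate` in between. Intergenic clusters (no host) are
#' `independent` by construction.
#'
#' @param expr Wide TPM tibble from [tpm_quantify()].
#' @param cluster_id,host_gene_id Feature ids (host may be `NA`).
#' @param config An [pipeline_config()] object.
#' @return A one-row tibble: `cluster_id`, `host_gene_id`, `correlation`,
#'   `mode`.
#' @export
host_correlation <- function(expr, cluster_id, host_gene_id,
                             config = pipeline_config()) {
  datasets <- setdiff(names(expr), "feature_id")
  if (is.na(host_gene_id) || !nzchar(host_gene_id)) {
    return(tibble::tibble(cluster_id = cluster_id,
      host_gene_id = NA_character_, correlation = NA_real_,
      mode = "independent"))
  }
  if (length(datasets) < 3) {
    rlang::abort("host correlation needs at least 3 datasets",
      class = "snc_expression_error")
  }
  x <- as.numeric(expr[expr$feature_id == cluster_id, datasets])
  y <- as.numeric(expr[expr$feature_id == host_gene_id, datasets])
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  mode <- if (is.na(r)) "indeterminate"
    else if (r >= config$host_corr_min) "host_dependent"
    else if (r <= 0) "independent"
    else "indeterminate"
  tibble::tibble(cluster_id = cluster_id, host_gene_id = host_gene_id,
    correlation = r, mode = mode)
}

#' Depletion response by biotype
#'
#' Per cluster, the pseudo-counted abundance log fold-change
#' `log2(mean KD TPM + 1) - log2(mean control TPM + 1)`, aggregated by
#' biotype with mean, standard deviation and group size. Swapping the
#' control and knockdown matrices negates every fold-change.
#'
#' @param control_expr,kd_expr Wide TPM tibbles (same features; >= 2
#'   replicate columns each).
#' @param biotype_calls Tibble with `cluster_id` (or `feature_id`) and
#'   `biotype`; features absent from it are dropped from the aggregation
#'   but kept in the per-cluster table with `NA` biotype.
#' @return A list of class `snc_depletion`: `per_cluster` tibble
#'   (`feature_id`, `biotype`, `log2fc`) and `per_biotype` tibble
#'   (`biotype`, `mean_log2fc`, `sd_log2fc`, `n`).
#' @export
depletion_response <- function(control_expr, kd_expr, biotype_calls) {
  stopifnot(identical(control_expr$feature_id, kd_expr$feature_id))
  ctrl_cols <- setdiff(names(control_expr), "feature_id")
  kd_cols <- setdiff(names(kd_expr), "feature_id")
  stopifnot(length(ctrl_cols) >= 2, length(kd_cols) >= 2)
  names(biotype_calls)[names(biotype_calls) == "cluster_id"] <- "feature_id"

  per_cluster <- tibble::tibble(
    feature_id = control_expr$feature_id,
    log2fc = log2(rowMeans(kd_expr[, kd_cols]) + 1) -
      log2(rowMeans(control_expr[, ctrl_cols]) + 1)
  ) |>
    dplyr::left_join(biotype_calls[, c("feature_id", "biotype")],
      by = "feature_id") |>
    dplyr::relocate("feature_id", "biotype")

  per_biotype <- per_cluster |>
    dplyr::filter(!is.na(.data$biotype)) |>
    dplyr::group_by(.data$biotype) |>
    dplyr::summarise(
      mean_log2fc = mean(.data$log2fc),
      sd_log2fc = stats::sd(.data$log2fc),
      n = dplyr::n(),
      .groups = "drop"
    )
  structure(list(per_cluster = per_cluster, per_biotype = per_biotype),
    class = "snc_depletion")
}

#' @export
tidy.snc_depletion <- function(x, ...) x$per_cluster

#' @export
glance.snc_depletion <- function(x, ...) {
  tidyr::pivot_wider(x$per_biotype[, c("biotype", "mean_log2fc")],
    names_from = "biotype", values_from = "mean_log2fc")
}

#' @export
print.snc_depletion <- function(x, ...) {
  cat("<snc_depletion> per-biotype mean log2 fold-change:\n")
  print(as.data.frame(x$per_biotype))
  invisible(x)
}
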