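#' Repeat-element overlap of clusters
#'
#' For each cluster, reports the repeat annotation entry with the maximal
#' overlap fraction (cluster length as denominator) when that fraction
#' reaches `repeat_min_frac` (0.5), otherwise "none".
#'
#' @param clusters Cluster tibble.
#' @param annotation Annotation tibble with `feature == "repeat"` entries
#'   (biotypes such as `repeat_Alu`, `repeat_tRNA`, `repeat_NumtS`).
#' @param config An [pipeline_config()] object.
#' @return A tibble `cluster_id`, `repeat_label`, `repeat_frac`.
#' @export
repeat_overlap <- function(clusters, annotation, config = pipeline_config()) {
  out <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    repeat_label = rep("none", nrow(clusters)),
    repeat_frac = rep(0, nrow(clusters))
  )
  reps <- dplyr::filter(annotation, .data$feature == "repeat")
  if (!nrow(reps) || !nrow(clusters)) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(clusters), as_granges(reps),
    ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(out)
  frac <- overlap_width(clusters$start[qi], clusters$end[qi],
    reps$start[si], reps$end[si]) / (clusters$end[qi] - clusters$start[qi])
  best <- tibble::tibble(qi = qi, si = si, frac = frac) |>
    dplyr::group_by(.data$qi) |>
    dplyr::slice_max(.data$frac, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$frac >= config$repeat_min_frac)
  labels <- c(repeat_Alu = "Alu", repeat_tRNA = "tRNA_repeat",
    repeat_NumtS = "NumtS")
  if (nrow(best)) {
    bt <- reps$biotype[best$si]
    lab <- unname(labels[bt])
    lab[is.na(lab)] <- sub("^repeat_", "", bt[is.na(lab)])
    out$repeat_label[best$qi] <- lab
    out$repeat_frac[best$qi] <- best$frac
  }
  out
}

#' Collect classification evidence for candidate clusters
#'
#' Runs the four evidence channels on every cluster: homology search
#' against the reference ncRNA set, the cloverleaf heuristic, the H/ACA
#' architecture heuristic, the C/D box/guide detector (against the supplied
#' target RNAs) and repeat overlap.
#'
#' @param clusters Cluster tibble with sequences.
#' @param refs Reference tibble (`id`, `biotype`, `seq`).
#' @param targets Named character vector of target RNAs for guide search
#'   (or `NULL`).
#' @param annotation Annotation tibble.
#' @param config An [pipeline_config()] object.
#' @return An evidence tibble, one row per cluster, with list-columns
#'   `hits` (all homology hits) and `cd_guide`, flags `folds_as_trna`,
#'   `folds_as_haca`, `has_cd_boxes`, plus `haca_h_start`, `haca_aca_start`,
#'   `repeat_label`, `repeat_frac`.
#' @export
collect_evidence <- function(clusters, refs, targets = NULL,
                             annotation = NULL, config = pipeline_config()) {
  if (!nrow(clusters)) {
    return(tibble::tibble(cluster_id = character(0), length = integer(0),
      hits = list(), folds_as_trna = logical(0), folds_as_haca = logical(0),
      haca_h_start = integer(0), haca_aca_start = integer(0),
      has_cd_boxes = logical(0), cd_guide = list(),
      repeat_label = character(0), repeat_frac = numeric(0)))
  }
  rep_ov <- if (!is.null(annotation)) repeat_overlap(clusters, annotation, config)
    else tibble::tibble(cluster_id = clusters$cluster_id,
      repeat_label = "none", repeat_frac = 0)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    seq <- clusters$sequence[i]
    hits <- homology_search(seq, refs, config)
    clv <- cloverleaf_check(seq, ac_stem_max = config$ac_stem_max)
    haca <- haca_check(seq)
    cd <- cd_check(seq, targets)
    tibble::tibble(
      cluster_id = clusters$cluster_id[i],
      length = clusters$end[i] - clusters$start[i],
      hits = list(hits),
      folds_as_trna = clv$folds_as_trna,
      folds_as_haca = haca$folds_as_haca,
      haca_h_start = if (!is.null(haca$haca_boxes)) haca$haca_boxes$h_start else NA_integer_,
      haca_aca_start = if (!is.null(haca$haca_boxes)) haca$haca_boxes$aca_start else NA_integer_,
      has_cd_boxes = !is.null(cd$cd_boxes),
      cd_guide = list(cd$guide_target)
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::left_join(rep_ov, by = "cluster_id")
}

# Fraction of each cluster lying inside a same-strand annotation feature of
# the given type.
feature_fraction <- function(clusters, annotation, feature) {
  out <- rep(0, nrow(clusters))
  feats <- dplyr::filter(annotation, .data$feature == !!feature)
  if (!nrow(feats) || !nrow(clusters)) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(clusters), as_granges(feats),
    ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(out)
  frac <- overlap_width(clusters$start[qi], clusters$end[qi],
    feats$start[si], feats$end[si]) / (clusters$end[qi] - clusters$start[qi])
  agg <- tapply(frac, qi, max)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Classify candidate clusters into the eight biotype classes
#'
#' Integrates the evidence channels through a fixed, fully logged decision
#' tree (the published analysis states no precedence among conflicting
#' evidence, so this ordering is a committed design choice):
#'
#' 1. location: a cluster lying (>= 50% of its length) within an
#'    `rDNA_5ETS` feature is `ETS_RNA`; within `rDNA_ITS1`, `ITS_RNA`;
#' 2. tRNA homology: with a tRNA reference hit, clusters shorter than
#'    `trf_len_threshold` (65 nt) are `tRNA_fragment`; hits whose query
#'    span extends more than `pre_trna_ext` (5 nt) beyond the reference's
#'    mature ends are `pre_tRNA`; otherwise a cloverleaf fold or >= 80%
#'    full-length identity gives `tRNA_like`, else `tRNA_fragment`;
#' 3. C/D boxes plus a guide give `snoRNA_CD`;
#' 4. an H/ACA fold (or boxes) gives `snoRNA_HACA` (no predicted target is
#'    noted as "orphan" in the rationale);
#' 5. everything else is `unknown` (rationale records any remaining
#'    homology and the repeat label).
#'
#' @param evidence Evidence tibble from [collect_evidence()].
#' @param clusters Cluster tibble (for genomic context).
#' @param annotation Annotation tibble (rDNA spacer features).
#' @param config An [pipeline_config()] object.
#' @return A tibble `cluster_id`, `biotype`, `rationale`.
#' @export
classify_biotype <- function(evidence, clusters, annotation,
                             config = pipeline_config()) {
  stopifnot(identical(evidence$cluster_id, clusters$cluster_id))
  ets_frac <- feature_fraction(clusters, annotation, "rDNA_5ETS")
  its_frac <- feature_fraction(clusters, annotation, "rDNA_ITS1")

  one <- function(i) {
    why <- character(0)
    len <- evidence$length[i]
    if (ets_frac[i] >= 0.5) {
      return(list("ETS_RNA", sprintf("within rDNA 5'ETS feature (%.0f%%)",
        100 * ets_frac[i])))
    }
    if (its_frac[i] >= 0.5) {
      return(list("ITS_RNA", sprintf("within rDNA ITS1 feature (%.0f%%)",
        100 * its_frac[i])))
    }
    hits <- evidence$hits[[i]]
    trna_hits <- hits[hits$ref_biotype == "tRNA", , drop = FALSE]
    if (nrow(trna_hits)) {
      h <- trna_hits[1, ]
      why <- c(why, sprintf(
        "tRNA homology to %s (identity %.1f%%, e-value %.2g)",
        h$ref_id, h$identity, h$evalue))
      if (len < config$trf_len_threshold) {
        return(list("tRNA_fragment",
          c(why, sprintf("length %d < %d nt", len, config$trf_len_threshold))))
      }
      ext5 <- (h$q_start - 1) - (h$r_start - 1)
      ext3 <- (h$q_len - h$q_end) - (h$r_len - h$r_end)
      if (max(ext5, ext3) > config$pre_trna_ext) {
        return(list("pre_tRNA", c(why, sprintf(
          "homology extends %d/%d nt beyond mature reference ends",
          max(0, ext5), max(0, ext3)))))
      }
      full_id <- 100 * h$n_match / h$r_len
      if (evidence$folds_as_trna[i] || full_id >= config$full_len_identity_min) {
        return(list("tRNA_like", c(why,
          if (evidence$folds_as_trna[i]) "cloverleaf fold found"
          else sprintf("full-length identity %.1f%%", full_id))))
      }
      return(list("tRNA_fragment", c(why,
        "no cloverleaf fold and sub-threshold full-length identity")))
    }
    guide <- evidence$cd_guide[[i]]
    if (evidence$has_cd_boxes[i] && !is.null(guide)) {
      return(list("snoRNA_CD", c(why, sprintf(
        "C/D boxes with %d-nt guide against %s (target position %s)",
        guide$guide_len, guide$target_id, guide$target_pos))))
    }
    if (evidence$folds_as_haca[i]) {
      why <- c(why, sprintf("H/ACA architecture (H box at %d, ACA at %d)",
        evidence$haca_h_start[i], evidence$haca_aca_start[i]))
      why <- c(why, "orphan: no rRNA target predicted")
      if (evidence$repeat_label[i] != "none") {
        why <- c(why, sprintf("overlaps %s repeat (%.0f%%)",
          evidence$repeat_label[i], 100 * evidence$repeat_frac[i]))
      }
      return(list("snoRNA_HACA", why))
    }
    if (nrow(hits)) {
      h <- hits[1, ]
      why <- c(why, sprintf("homology to %s (%s) below classification rules",
        h$ref_id, h$ref_biotype))
    } else {
      why <- c(why, "no homology at e-value threshold")
    }
    if (evidence$repeat_label[i] != "none") {
      why <- c(why, sprintf("overlaps %s repeat (%.0f%%)",
        evidence$repeat_label[i], 100 * evidence$repeat_frac[i]))
    }
    list("unknown", why)
  }

  calls <- lapply(seq_len(nrow(evidence)), one)
  tibble::tibble(
    cluster_id = evidence$cluster_id,
    biotype = vapply(calls, function(x) x[[1]], character(1)),
    rationale = vapply(calls, function(x) paste(x[[2]], collapse = "; "),
      character(1))
  )
}
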