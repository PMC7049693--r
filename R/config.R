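#' Pipeline configuration
#'
#' Builds the flat configuration object consumed by every stage of the
#' pipeline. Defaults encode the published analysis settings: clusters need
#' at least 100 reads (`min_cluster_reads`, Blockbuster's minBlockHeight) and
#' identical-read tags at least 50 (`tag_filter`); candidate transcripts must
#' be 20-500 nt long, carry at least 100 uniquely mapped reads (unless the
#' multimap exception applies) and be detected in at least 2 datasets;
#' homology hits are kept at e-value <= 0.01; tRNA-homologous clusters
#' shorter than 65 nt are called fragments; a fragment counts as processed
#' from a novel tRNA when its genomic extension is >= 75% identical to the
#' reference; ortholog sequences are searched within +-300 nt flanks; host
#' dependence calls use a rank correlation threshold of 0.5.
#'
#' @param ... Named overrides for any field listed below.
#'
#' @return A named list of class `snc_config`.
#'
#' @section Fields:
#' \describe{
#'   \item{min_cluster_reads}{minimum reads per cluster (100)}
#'   \item{tag_filter}{minimum reads per identical-read tag (50)}
#'   \item{min_len,max_len}{size selection window in nt (20, 500)}
#'   \item{min_unique_reads}{uniquely-mapped read floor (100)}
#'   \item{min_datasets}{datasets a cluster must be detected in (2)}
#'   \item{detect_min_reads}{overlapping reads needed to call a dataset
#'     "detected" (1)}
#'   \item{evalue_max}{homology e-value ceiling (0.01)}
#'   \item{trf_len_threshold}{tRNA-fragment length rule in nt (65)}
#'   \item{extension_identity_min}{percent identity for
#'     processed-from-novel-tRNA calls (75)}
#'   \item{ortholog_flank}{nt of context fetched around orthologs (300)}
#'   \item{host_corr_min}{rank-correlation threshold for host dependence
#'     (0.5)}
#'   \item{rng_seed}{seed used by CLI entry points (1)}
#'   \item{end_jitter}{maximum read end jitter simulated, nt (2)}
#'   \item{seed_k}{k-mer length seeding the homology search (11)}
#'   \item{match,mismatch,gap_open,gap_extend}{local alignment scoring
#'     (+1, -2, -5 for a length-1 gap via 3+2, -2 per extension)}
#'   \item{lambda}{bit-score calibration constant (0.5)}
#'   \item{annotated_exclude_biotypes}{gene biotypes whose full spans do not
#'     mark a cluster as annotated (protein_coding, rRNA_45S); exonic overlap
#'     always counts}
#'   \item{retained_intron_recip}{reciprocal overlap for the retained-intron
#'     filter (0.9)}
#'   \item{retained_intron_tol}{splice-site boundary tolerance, nt (5)}
#'   \item{repeat_min_frac}{minimal overlap fraction for a repeat label (0.5)}
#'   \item{ac_stem_max}{anticodon stem tolerance in the cloverleaf heuristic,
#'     bp (7; the canonical stem is 5)}
#'   \item{pre_trna_ext}{nt of homology extension beyond mature tRNA ends
#'     that triggers a pre-tRNA call (5)}
#'   \item{full_len_identity_min}{percent identity over the full reference
#'     length accepted as tRNA-like without a fold (80)}
#'   \item{trf_half_start,trf_half_lo,trf_half_hi,trf_near_full}{positional
#'     class windows on relative coordinates (0.1, 0.4, 0.6, 0.75)}
#' }
#'
#' @examples
#' cfg <- pipeline_config(min_cluster_reads = 50)
#' cfg$min_cluster_reads
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_cluster_reads = 100,
    tag_filter = 50,
    min_len = 20,
    max_len = 500,
    min_unique_reads = 100,
    min_datasets = 2,
    detect_min_reads = 1,
    evalue_max = 0.01,
    trf_len_threshold = 65,
    extension_identity_min = 75,
    ortholog_flank = 300,
    host_corr_min = 0.5,
    rng_seed = 1L,
    end_jitter = 2,
    seed_k = 11,
    match = 1,
    mismatch = -2,
    gap_open = 3,
    gap_extend = 2,
    lambda = 0.5,
    annotated_exclude_biotypes = c("protein_coding", "rRNA_45S"),
    retained_intron_recip = 0.9,
    retained_intron_tol = 5,
    repeat_min_frac = 0.5,
    ac_stem_max = 7,
    pre_trna_ext = 5,
    full_len_identity_min = 80,
    trf_half_start = 0.1,
    trf_half_lo = 0.4,
    trf_half_hi = 0.6,
    trf_near_full = 0.75
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      rlang::abort(
        paste0("unknown config field(s): ", paste(bad, collapse = ", ")),
        class = "snc_config_error"
      )
    }
    cfg[names(overrides)] <- overrides
  }
  validate_config(cfg)
  structure(cfg, class = "snc_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_len < cfg$max_len,
    cfg$min_cluster_reads >= 0, cfg$tag_filter >= 0,
    cfg$min_unique_reads >= 0, cfg$min_datasets >= 0,
    cfg$evalue_max > 0, cfg$evalue_max <= 1
  )
  invisible(cfg)
}

#' Read or write a flat key=value configuration file
#'
#' The on-disk format is one `key=value` pair per line; keys mirror
#' [pipeline_config()] field names. Vector-valued fields are comma-separated.
#' Unknown keys are rejected.
#'
#' @param path File path.
#' @param config For `write_config()`, an `snc_config` object.
#' @return `read_config()` returns an `snc_config`.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), character(1))
  defaults <- pipeline_config()
  overrides <- list()
  for (i in seq_along(keys)) {
    key <- keys[[i]]
    if (!key %in% names(defaults)) {
      rlang::abort(paste0("unknown config key: ", key), class = "snc_config_error")
    }
    val <- strsplit(vals[[i]], ",", fixed = TRUE)[[1]]
    val <- trimws(val)
    if (is.numeric(defaults[[key]])) val <- as.numeric(val)
    if (is.integer(defaults[[key]])) val <- as.integer(val)
    overrides[[key]] <- val
  }
  do.call(pipeline_config, overrides)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "snc_config"))
  lines <- vapply(
    names(config),
    function(k) paste0(k, "=", paste(config[[k]], collapse = ",")),
    character(1)
  )
  readr::write_lines(lines, path)
  invisible(path)
}
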