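#' Plot the per-filter discard tally
#'
#' Bar chart of how many discarded clusters fail each filter (a discarded
#' cluster can count towards several bars).
#'
#' @param filter_result An `snc_filter_result` from [filter_cascade()].
#' @return A ggplot object.
#' @export
plot_filter_summary <- function(filter_result) {
  counts <- table(factor(unlist(filter_result$verdicts$failed_list),
    levels = FILTER_NAMES))
  df <- tibble::tibble(filter = names(counts), n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$filter, levels = FILTER_NAMES), y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "discarded clusters",
      title = "Filter cascade: non-optimal features of discarded clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the biotype distribution of classified clusters
#'
#' @param biotypes Biotype call tibble from [classify_biotype()].
#' @return A ggplot object.
#' @export
plot_biotype_distribution <- function(biotypes) {
  df <- dplyr::count(biotypes,
    biotype = factor(.data$biotype, levels = BIOTYPE_CLASSES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$biotype, y = .data$n,
    fill = .data$biotype)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "clusters",
      title = "Biotype classification of kept clusters") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot tRNA-fragment positions on their reference genes
#'
#' One horizontal segment per fragment from `rel_start` to `rel_end`; 0 and
#' 1 mark the mature 5' and 3' reference ends.
#'
#' @param fragments Fragment-mapping tibble from [map_fragments()].
#' @return A ggplot object.
#' @export
plot_trf_positions <- function(fragments) {
  df <- fragments |>
    dplyr::arrange(.data$rel_start, .data$rel_end) |>
    dplyr::mutate(y = dplyr::row_number())
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$rel_start, xend = .data$rel_end, y = .data$y,
      yend = .data$y, colour = .data$positional_class), linewidth = 1.5) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position on reference tRNA (0 = mature 5' end)",
      y = NULL, colour = "class",
      title = "tRNA fragment positions relative to reference genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot depletion response by biotype
#'
#' @param depletion An `snc_depletion` from [depletion_response()].
#' @return A ggplot object.
#' @export
plot_depletion_response <- function(depletion) {
  df <- dplyr::filter(depletion$per_cluster, !is.na(.data$biotype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$biotype, y = .data$log2fc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "log2 fold-change (KD vs control)",
      title = "Depletion response by biotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
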