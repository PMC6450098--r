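#' Plot a windowed G+C track
#'
#' Step plot of per-window G+C fraction along the genome, with the
#' global (length-weighted) mean as a dashed reference line.
#'
#' @param object A `gc_track` from [windowed_gc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_track <- function(object, ...) {
  global <- sum(object$gc_fraction * object$window_length) /
    sum(object$window_length)
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$gc_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = global, linetype = "dashed") +
    ggplot2::labs(x = "genome position (bp)", y = "G+C fraction") +
    ggplot2::theme_minimal()
}

#' Boxplot of transcriptional activity by gene class
#'
#' The silencing comparison figure: RPKM-derived activity per gene,
#' grouped into the LGT direction classes and the vertically inherited
#' reference set, on a log scale.
#'
#' @param activity Tibble with `gene_id`, `activity`.
#' @param groups Tibble with `gene_id`, `group`.
#' @return A ggplot object.
#' @export
plot_activity_by_group <- function(activity, groups) {
  d <- dplyr::inner_join(activity, groups, by = "gene_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$activity + 0.5)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "activity (RPKM, log scale)") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top proteins by emPAI
#'
#' @param proteome Ranked proteome tibble from [rank_proteome()].
#' @param n Number of top-ranked proteins to show (default 20).
#' @return A ggplot object.
#' @export
plot_proteome_ranking <- function(proteome, n = 20) {
  top <- dplyr::slice_head(proteome, n = n)
  id_col <- if ("orf_id" %in% names(top)) "orf_id" else "id"
  top$label <- stats::reorder(top[[id_col]], top$empai)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$empai, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "emPAI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of basic-residue proportions across a proteome
#'
#' Highlights a subset of proteins (e.g. the core histones, which sit in
#' the basic tail of the distribution).
#'
#' @param proteins Tibble with `id`, `sequence`.
#' @param highlight Character vector of protein ids to mark.
#' @param basic_set Residues counted as basic, see [basic_fraction()].
#' @return A ggplot object.
#' @export
plot_basic_fractions <- function(proteins, highlight = character(),
                                 basic_set = c("K", "R", "H")) {
  d <- proteins |>
    dplyr::mutate(
      basic = purrr::map_dbl(.data$sequence, basic_fraction,
                             basic_set = basic_set),
      highlighted = .data$id %in% highlight
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$basic)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(
      data = dplyr::filter(d, .data$highlighted),
      ggplot2::aes(xintercept = .data$basic), colour = "red"
    ) +
    ggplot2::labs(x = "basic residue fraction", y = "proteins") +
    ggplot2::theme_minimal()
}
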