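#' Plot occurrence reduction of a merge
#'
#' Bars of occurrences before merging and merged taxa after, by kingdom.
#'
#' @param object A `diet_merge` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diet_merge <- function(object, ...) {
  red <- occurrence_reduction(object)
  red <- red[red$kingdom != "total", ]
  long <- tidyr::pivot_longer(red, c("n_before", "n_after"),
                              names_to = "stage", values_to = "n")
  long$stage <- factor(long$stage, levels = c("n_before", "n_after"),
                       labels = c("detections", "merged taxa"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kingdom, y = .data$n,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "occurrences", fill = NULL,
                  title = "Cross-marker occurrence reduction") +
    ggplot2::theme_minimal()
}

#' Plot a taxonomic resolution profile
#'
#' @param profile A tibble from [resolution_profile()], optionally with an
#'   extra `method` column to facet by.
#' @return A ggplot.
#' @export
plot_resolution_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, c("n_taxa", "n_occurrences"),
                              names_to = "quantity", values_to = "n")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "deepest assigned rank", y = NULL) +
    ggplot2::theme_minimal()
  if ("method" %in% names(profile)) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$quantity),
                            ggplot2::vars(.data$method), scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y")
  }
}

#' Plot a pairwise overlap matrix
#'
#' @param m A symmetric matrix from [czekanowski_matrix()].
#' @return A ggplot tile map with the index printed in each cell.
#' @export
plot_overlap_matrix <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = \(x)
                          c("method_a", "method_b", "overlap"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method_a, y = .data$method_b,
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$overlap)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Czekanowski") +
    ggplot2::theme_minimal()
}

#' Plot frequency-of-occurrence profiles across methods
#'
#' @param profiles A tibble stacking [frequency_of_occurrence()] outputs
#'   (columns `method`, `taxon`, `foo`).
#' @return A ggplot.
#' @export
plot_frequency_of_occurrence <- function(profiles) {
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$taxon, y = .data$foo,
                                         fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "frequency of occurrence", fill = NULL) +
    ggplot2::theme_minimal()
}
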