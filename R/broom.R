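#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-group table of a multi-marker merge
#'
#' @param x A `diet_merge` object.
#' @param ... Unused.
#' @return A tibble with one row per merged group: `sample_id`, `group_id`,
#'   the representative (most resolved) lineage, its deepest rank and MOTU
#'   label, and the provenance of the absorbed member detections.
#' @export
tidy.diet_merge <- function(x, ...) {
  x$merged
}

#' One-row summary of a multi-marker merge
#'
#' @param x A `diet_merge` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_samples`, `n_markers`, `n_detections`
#'   (occurrences before merging), `n_taxa` (merged groups), `n_redundant`
#'   and `redundancy` (fraction of occurrences absorbed as cross-marker
#'   duplicates), `mean_richness` (mean merged taxa per sample).
#' @export
glance.diet_merge <- function(x, ...) {
  red <- occurrence_reduction(x)
  tot <- red[red$kingdom == "total", ]
  rich <- richness_per_sample(x)
  tibble::tibble(
    n_samples = dplyr::n_distinct(x$detections$sample_id),
    n_markers = dplyr::n_distinct(x$detections$marker_id),
    n_detections = tot$n_before,
    n_taxa = tot$n_after,
    n_redundant = tot$n_removed,
    redundancy = tot$n_removed / max(tot$n_before, 1),
    mean_richness = mean(rich$richness)
  )
}
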