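# Normalise the various inputs (detections tibble / merged tibble /
# diet_merge object) to one table of occurrences: sample_id, lineage, label.
occurrence_table <- function(x) {
  if (inherits(x, "diet_merge")) x <- x$merged
  stopifnot(is.data.frame(x))
  if ("representative_lineage" %in% names(x)) {
    tibble::tibble(sample_id = x$sample_id,
                   lineage = x$representative_lineage,
                   label = dplyr::coalesce(x$representative_label,
                                           x$representative_lineage))
  } else {
    stopifnot(all(c("sample_id", "lineage") %in% names(x)))
    lab <- if ("motu_label" %in% names(x)) {
      dplyr::coalesce(x$motu_label, x$lineage)
    } else {
      x$lineage
    }
    tibble::tibble(sample_id = x$sample_id, lineage = x$lineage, label = lab)
  }
}

# taxon identity at the requested level; NA = does not reach the level
taxon_key <- function(occ, level, sep, ladder) {
  if (identical(level, "taxon")) {
    paste(occ$lineage, occ$label, sep = "::")
  } else {
    truncate_lineage(occ$lineage, level, sep = sep, ladder = ladder)
  }
}

#' Frequency of occurrence per taxon
#'
#' The fraction of samples in which each taxon is detected, at full
#' resolution (`level = "taxon"`, lineage plus MOTU label) or truncated to a
#' rank (e.g. `level = "order"`, where several taxa of one order in a sample
#' count once and detections coarser than the rank are excluded).
#'
#' @param x A detections data frame, merged group table, or `diet_merge`
#'   object.
#' @param level `"taxon"` or a rank name from the ladder.
#' @param method Optional method id recorded in the output (e.g. a marker
#'   name or `"multi-marker"`).
#' @param n_samples Denominator; defaults to the number of distinct samples
#'   in `x`. Supply explicitly when a method analysed samples in which it
#'   detected nothing.
#' @param sep,ladder Lineage conventions.
#' @return A tibble `method`, `taxon`, `n_samples_present`, `foo`.
#' @export
frequency_of_occurrence <- function(x, level = "taxon", method = NA_character_,
                                    n_samples = NULL, sep = ";",
                                    ladder = linnaean_ranks()) {
  if (!identical(level, "taxon") && !level %in% ladder) {
    stop("level must be \"taxon\" or a rank name", call. = FALSE)
  }
  occ <- occurrence_table(x)
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(occ$sample_id)
  if (n_samples == 0) stop("no samples", call. = FALSE)
  occ$taxon <- taxon_key(occ, level, sep, ladder)
  occ |>
    dplyr::filter(!is.na(.data$taxon)) |>
    dplyr::distinct(.data$sample_id, .data$taxon) |>
    dplyr::count(.data$taxon, name = "n_samples_present") |>
    dplyr::mutate(method = method, foo = .data$n_samples_present / n_samples) |>
    dplyr::relocate("method") |>
    dplyr::arrange(.data$taxon)
}

#' Per-sample taxon or rank richness
#'
#' At `level = "taxon"` this counts distinct taxa at their highest available
#' resolution — species-level identifications plus higher-rank MOTUs — which
#' for a merged sample equals its number of merge groups. At a rank it
#' counts distinct truncated lineages (detections coarser than the rank are
#' excluded from the count).
#'
#' @inheritParams frequency_of_occurrence
#' @return A tibble `sample_id`, `richness`.
#' @seealso [richness_summary()] for the mean and standard error.
#' @export
richness_per_sample <- function(x, level = "taxon", sep = ";",
                                ladder = linnaean_ranks()) {
  occ <- occurrence_table(x)
  occ$taxon <- taxon_key(occ, level, sep, ladder)
  occ |>
    dplyr::filter(!is.na(.data$taxon)) |>
    dplyr::distinct(.data$sample_id, .data$taxon) |>
    dplyr::count(.data$sample_id, name = "richness") |>
    dplyr::arrange(.data$sample_id)
}

#' Mean and standard error of per-sample richness
#'
#' @inheritParams richness_per_sample
#' @param n_samples Denominator for the mean; defaults to the number of
#'   samples present in `x`.
#' @return A one-row tibble `level`, `n_samples`, `mean_richness`,
#'   `se_richness` (standard error = sample standard deviation / sqrt(n)).
#' @export
richness_summary <- function(x, level = "taxon", n_samples = NULL, sep = ";",
                             ladder = linnaean_ranks()) {
  r <- richness_per_sample(x, level = level, sep = sep, ladder = ladder)
  counts <- r$richness
  if (!is.null(n_samples)) {
    if (n_samples < nrow(r)) stop("n_samples below observed samples",
                                  call. = FALSE)
    counts <- c(counts, rep(0L, n_samples - nrow(r)))
  }
  n <- length(counts)
  tibble::tibble(level = level, n_samples = n,
                 mean_richness = mean(counts),
                 se_richness = stats::sd(counts) / sqrt(n))
}

#' Czekanowski's niche overlap index
#'
#' `1 - 0.5 * sum(|p_i - q_i|)` over the union of taxa of two
#' frequency-of-occurrence profiles, where by default each profile is first
#' normalised to proportional utilisation (`p_i = foo_i / sum(foo)`), as in
#' the niche-overlap literature. The index is 1 for identical profiles and
#' 0 for profiles with disjoint support.
#'
#' @param a,b Profiles: either tibbles with columns `taxon`, `foo` (as from
#'   [frequency_of_occurrence()]) or named numeric vectors. Taxa missing
#'   from one profile count as zero.
#' @param normalize If `FALSE`, the raw frequency-of-occurrence vectors are
#'   compared instead of proportions.
#' @return The overlap index, a number in \[0, 1\].
#' @export
#' @examples
#' czekanowski(c(a = 0.5, b = 0.5), c(a = 0.5, c = 0.5))
czekanowski <- function(a, b, normalize = TRUE) {
  as_vec <- function(p) {
    if (is.data.frame(p)) {
      stopifnot(all(c("taxon", "foo") %in% names(p)))
      stats::setNames(p$foo, p$taxon)
    } else {
      stopifnot(is.numeric(p), !is.null(names(p)))
      p
    }
  }
  va <- as_vec(a); vb <- as_vec(b)
  taxa <- union(names(va), names(vb))
  pa <- ifelse(taxa %in% names(va), va[taxa], 0)
  pb <- ifelse(taxa %in% names(vb), vb[taxa], 0)
  pa[is.na(pa)] <- 0; pb[is.na(pb)] <- 0
  if (sum(pa) == 0 || sum(pb) == 0) {
    stop("czekanowski is undefined for an all-zero profile", call. = FALSE)
  }
  if (normalize) {
    pa <- pa / sum(pa)
    pb <- pb / sum(pb)
  }
  unname(1 - 0.5 * sum(abs(pa - pb)))
}

#' Pairwise overlap matrix across methods
#'
#' @param profiles A tibble with columns `method`, `taxon`, `foo` stacking
#'   one frequency-of-occurrence profile per method.
#' @inheritParams czekanowski
#' @return A symmetric numeric matrix of Czekanowski indices with unit
#'   diagonal, methods as dimnames.
#' @export
czekanowski_matrix <- function(profiles, normalize = TRUE) {
  stopifnot(is.data.frame(profiles),
            all(c("method", "taxon", "foo") %in% names(profiles)))
  methods <- unique(profiles$method)
  prof <- split(profiles, profiles$method)[methods]
  m <- diag(1, length(methods))
  dimnames(m) <- list(methods, methods)
  if (length(methods) > 1) {
    for (i in seq_along(methods)[-1]) {
      for (j in seq_len(i - 1)) {
        m[i, j] <- m[j, i] <- czekanowski(prof[[i]], prof[[j]],
                                          normalize = normalize)
      }
    }
  }
  m
}

#' Taxonomic resolution profile
#'
#' Distribution of distinct taxa and of occurrences over the deepest
#' assigned rank (how much of the information is at order, family, genus or
#' species level).
#'
#' @inheritParams frequency_of_occurrence
#' @return A tibble `rank` (ordered factor over the ladder), `n_taxa`,
#'   `n_occurrences`.
#' @export
resolution_profile <- function(x, sep = ";", ladder = linnaean_ranks()) {
  occ <- occurrence_table(x)
  occ$rank <- deepest_rank(occ$lineage, sep = sep, ladder = ladder)
  occ$taxon <- taxon_key(occ, "taxon", sep, ladder)
  occ |>
    dplyr::group_by(rank = factor(.data$rank, levels = ladder)) |>
    dplyr::summarise(n_taxa = dplyr::n_distinct(.data$taxon),
                     n_occurrences = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$rank)
}
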