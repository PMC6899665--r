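#' Merge multi-marker detections into a consensus taxa list
#'
#' The central operation of the package. Within each sample, detections of
#' the same ingested item by different markers typically appear at different
#' taxonomic resolutions (one marker reports a Coleoptera, another a
#' Chrysomelidae, a third a Chrysomelidae species). `merge_samples()`
#' partitions each sample's detections into the minimum possible number of
#' groups such that every group (i) contains at most one detection per
#' marker and (ii) has member lineages forming a chain under lineage
#' extension (each coarser lineage a prefix of the finer ones). Each group
#' represents one ingested item; its representative is the most resolved
#' member. Minimising the number of groups is the conservative reading:
#' cross-marker redundancy is collapsed and dietary diversity is never
#' overestimated. MOTU identities are deliberately never linked across
#' samples — the same pair of marker-local MOTUs may merge in one sample
#' and not in another.
#'
#' The partition is found by exact branch-and-bound over detections sorted
#' by decreasing lineage depth; per-sample instances are small (typically
#' well under a dozen detections), so exact search is cheap. Ties among
#' minimum-cardinality partitions are broken deterministically: maximise the
#' summed depth of group representatives, then take the lexicographically
#' smallest sorted list of representative lineages.
#'
#' @param detections A data frame with columns `sample_id`, `marker_id`,
#'   `lineage`, and optionally `motu` and `motu_label`. Within one
#'   (sample, marker) the (lineage, motu) pairs must be distinct.
#' @param sep,ladder Lineage conventions.
#' @return An object of class `diet_merge`; see [tidy.diet_merge()] for the
#'   per-group table and [glance.diet_merge()] for the one-row summary.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   sample_id = "s1",
#'   marker_id = c("18S", "IN16STK", "ZBJ"),
#'   lineage = c(
#'     "Animalia;Arthropoda;Insecta;Coleoptera",
#'     "Animalia;Arthropoda;Insecta;Coleoptera;Chrysomelidae",
#'     "Animalia;Arthropoda;Insecta;Coleoptera;Chrysomelidae;Oulema;Oulema melanopus"
#'   ))
#' merge_samples(d)
merge_samples <- function(detections, sep = ";", ladder = linnaean_ranks()) {
  detections <- check_detections(detections, sep, ladder)
  merged <- detections |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(g, key) {
      merge_one(g, sep = sep, ladder = ladder)
    }) |>
    dplyr::ungroup()
  structure(list(merged = merged, detections = detections,
                 ladder = ladder, sep = sep),
            class = "diet_merge")
}

#' Merge the detections of a single sample
#'
#' Convenience wrapper around the same exact algorithm as [merge_samples()]
#' for a table holding one sample only.
#'
#' @inheritParams merge_samples
#' @return A tibble with one row per merged group.
#' @export
merge_sample <- function(detections, sep = ";", ladder = linnaean_ranks()) {
  detections <- check_detections(detections, sep, ladder)
  if (dplyr::n_distinct(detections$sample_id) > 1) {
    stop("merge_sample() expects detections from a single sample; ",
         "use merge_samples()", call. = FALSE)
  }
  out <- merge_one(detections, sep = sep, ladder = ladder)
  out$sample_id <- detections$sample_id[1]
  dplyr::relocate(out, "sample_id")
}

check_detections <- function(detections, sep, ladder) {
  stopifnot(is.data.frame(detections),
            all(c("sample_id", "marker_id", "lineage") %in% names(detections)))
  detections <- tibble::as_tibble(detections)
  if (!"motu" %in% names(detections)) detections$motu <- NA_integer_
  if (!"motu_label" %in% names(detections)) {
    detections$motu_label <- NA_character_
  }
  if (nrow(detections) == 0) return(detections)
  detections$lineage <- normalize_lineage(detections$lineage, sep, ladder)
  dup <- detections |>
    dplyr::count(.data$sample_id, .data$marker_id, .data$lineage,
                 .data$motu) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate taxa within one sample x marker: ",
         paste0(dup$sample_id[1], "/", dup$marker_id[1], "/",
                dup$lineage[1]), call. = FALSE)
  }
  detections
}

# Exact minimum partition of one sample's detections into marker-disjoint
# chains, by branch-and-bound in decreasing-depth order. Returns the group
# table for that sample.
merge_one <- function(g, sep, ladder) {
  n <- nrow(g)
  empty <- tibble::tibble(
    group_id = integer(), representative_lineage = character(),
    representative_rank = character(), representative_motu = integer(),
    representative_label = character(), n_members = integer(),
    n_markers = integer(), member_markers = character(),
    member_lineages = character(), member_motus = character())
  if (n == 0) return(empty)

  parsed <- parse_lineage(g$lineage, sep = sep, ladder = ladder)
  depth <- lengths(parsed)
  ord <- order(-depth, g$lineage, g$marker_id, g$motu, method = "radix")
  g <- g[ord, , drop = FALSE]
  parsed <- parsed[ord]
  depth <- depth[ord]

  env <- new.env(parent = emptyenv())
  env$best <- NULL
  assign_vec <- integer(n)
  tail_of <- integer(n)      # index of shallowest member per group
  first_of <- integer(n)     # index of first (deepest) member per group
  markers_of <- vector("list", n)

  leaf_key <- function(ngr) {
    reps <- g$lineage[first_of[seq_len(ngr)]]
    list(count = ngr,
         sumdepth = sum(depth[first_of[seq_len(ngr)]]),
         key = paste(sort(reps), collapse = "\r"))
  }
  better <- function(cand, best) {
    if (is.null(best)) return(TRUE)
    if (cand$count != best$count) return(cand$count < best$count)
    if (cand$sumdepth != best$sumdepth) return(cand$sumdepth > best$sumdepth)
    cand$key < best$key
  }

  recurse <- function(i, ngr) {
    if (!is.null(env$best) && ngr > env$best$count) return(invisible())
    if (i > n) {
      cand <- leaf_key(ngr)
      if (better(cand, env$best)) {
        cand$assignment <- assign_vec[seq_len(n)]
        env$best <- cand
      }
      return(invisible())
    }
    for (j in seq_len(ngr)) {
      if (g$marker_id[i] %in% markers_of[[j]]) next
      if (!is_prefix(parsed[[i]], parsed[[tail_of[j]]])) next
      old_tail <- tail_of[j]
      tail_of[j] <<- i
      markers_of[[j]] <<- c(markers_of[[j]], g$marker_id[i])
      assign_vec[i] <<- j
      recurse(i + 1L, ngr)
      tail_of[j] <<- old_tail
      markers_of[[j]] <<- markers_of[[j]][-length(markers_of[[j]])]
    }
    j <- ngr + 1L
    tail_of[j] <<- i
    first_of[j] <<- i
    markers_of[[j]] <<- g$marker_id[i]
    assign_vec[i] <<- j
    recurse(i + 1L, j)
    markers_of[j] <<- list(NULL)
    invisible()
  }
  recurse(1L, 0L)

  asg <- env$best$assignment
  groups <- split(seq_len(n), asg)
  rows <- lapply(groups, function(idx) {
    idx <- idx[order(match(idx, seq_len(n)))]
    rep_i <- idx[1]  # deepest member: processing order is depth-decreasing
    tibble::tibble(
      representative_lineage = g$lineage[rep_i],
      representative_rank = ladder[depth[rep_i]],
      representative_motu = g$motu[rep_i],
      representative_label = g$motu_label[rep_i],
      n_members = length(idx),
      n_markers = dplyr::n_distinct(g$marker_id[idx]),
      member_markers = paste(g$marker_id[idx], collapse = ","),
      member_lineages = paste(g$lineage[idx], collapse = "|"),
      member_motus = paste(ifelse(is.na(g$motu[idx]), "", g$motu[idx]),
                           collapse = ","))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$representative_lineage,
                   out$representative_motu,
                   method = "radix"), , drop = FALSE]
  out$group_id <- seq_len(nrow(out))
  dplyr::relocate(out, "group_id")
}

#' Exhaustive oracle for the per-sample merge
#'
#' Computes the exact minimum number of groups for one sample's detections
#' by enumerating every partition of the detections into blocks and keeping
#' those in which each block is marker-disjoint and pairwise chain-ordered
#' under lineage extension. Intended as an independent verification oracle
#' for [merge_sample()]; refuses instances above `max_n` detections.
#'
#' @inheritParams merge_sample
#' @param max_n Size limit for the enumeration (default 12).
#' @return The minimum group count (integer).
#' @export
merge_oracle <- function(detections, sep = ";", ladder = linnaean_ranks(),
                         max_n = 12L) {
  detections <- check_detections(detections, sep, ladder)
  if (dplyr::n_distinct(detections$sample_id) > 1) {
    stop("merge_oracle() expects a single sample", call. = FALSE)
  }
  n <- nrow(detections)
  if (n == 0) return(0L)
  if (n > max_n) {
    stop("instance too large for exhaustive enumeration (", n, " > ",
         max_n, ")", call. = FALSE)
  }
  parsed <- parse_lineage(detections$lineage, sep = sep, ladder = ladder)
  markers <- detections$marker_id
  chain_ok <- function(i, block) {
    all(vapply(block, function(j) {
      is_prefix(parsed[[i]], parsed[[j]]) || is_prefix(parsed[[j]], parsed[[i]])
    }, logical(1)))
  }
  best <- n
  enumerate <- function(i, blocks) {
    if (i > n) {
      best <<- min(best, length(blocks))
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      if (markers[i] %in% markers[blk]) next
      if (!chain_ok(i, blk)) next
      blocks[[b]] <- c(blk, i)
      enumerate(i + 1L, blocks)
      blocks[[b]] <- blk
    }
    enumerate(i + 1L, c(blocks, list(i)))
    invisible()
  }
  enumerate(1L, list())
  best
}

#' Occurrence-reduction accounting
#'
#' Counts detections before merging and merged groups after, overall and by
#' kingdom, quantifying how much of the information provided by individual
#' markers was redundant across markers.
#'
#' @param x A `diet_merge` object, or a detections data frame (then `merged`
#'   must be supplied).
#' @param merged The merged group table, if `x` is a detections data frame.
#' @param sep Lineage separator.
#' @return A tibble with columns `kingdom` (including a `"total"` row),
#'   `n_before`, `n_after`, `n_removed`.
#' @export
occurrence_reduction <- function(x, merged = NULL, sep = ";") {
  if (inherits(x, "diet_merge")) {
    detections <- x$detections
    merged <- x$merged
    sep <- x$sep
  } else {
    detections <- x
    if (is.null(merged)) {
      stop("supply the merged table or a diet_merge object", call. = FALSE)
    }
    if (inherits(merged, "diet_merge")) merged <- merged$merged
  }
  first_field <- function(s) {
    vapply(strsplit(s, sep, fixed = TRUE), `[[`, character(1), 1)
  }
  before <- dplyr::count(
    tibble::tibble(kingdom = first_field(detections$lineage)),
    .data$kingdom, name = "n_before")
  after <- dplyr::count(
    tibble::tibble(kingdom = first_field(merged$representative_lineage)),
    .data$kingdom, name = "n_after")
  out <- dplyr::full_join(before, after, by = "kingdom") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                \(v) tidyr::replace_na(v, 0L))) |>
    dplyr::arrange(.data$kingdom)
  out <- dplyr::bind_rows(out, tibble::tibble(
    kingdom = "total", n_before = sum(out$n_before),
    n_after = sum(out$n_after)))
  dplyr::mutate(out, n_removed = .data$n_before - .data$n_after)
}

#' @export
print.diet_merge <- function(x, ...) {
  red <- occurrence_reduction(x)
  tot <- red[red$kingdom == "total", ]
  cat("Multi-marker diet merge\n")
  cat("  samples:", dplyr::n_distinct(x$detections$sample_id), "\n")
  cat("  markers:", paste(sort(unique(x$detections$marker_id)),
                          collapse = ", "), "\n")
  cat(sprintf("  occurrences: %d -> %d merged taxa (%d redundant, %.1f%%)\n",
              tot$n_before, tot$n_after, tot$n_removed,
              100 * tot$n_removed / max(tot$n_before, 1)))
  invisible(x)
}
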