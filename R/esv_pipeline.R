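#' Default per-marker configurations
#'
#' One row per marker with its expected fragment-length window (bp), the
#' minimum read total below which a PCR product is considered failed, the
#' per-PCR relative-abundance floor, and the MOTU clustering identity. The
#' default panel is a universal eukaryote 18S fragment, an arthropod 16S
#' fragment (IN16STK), an arthropod COI fragment (ZBJ) and the plant trnL
#' P6 loop, with the windows used for this panel: 94-153 bp (18S), 72-119 bp
#' (IN16STK), 155-159 bp (ZBJ) and 30-93 bp (trnL).
#'
#' @return A tibble with columns `marker`, `min_len`, `max_len`,
#'   `min_pcr_reads`, `rel_abundance_floor`, `motu_identity`.
#' @export
default_marker_configs <- function() {
  tibble::tibble(
    marker = c("18S", "IN16STK", "ZBJ", "trnL"),
    min_len = c(94L, 72L, 155L, 30L),
    max_len = c(153L, 119L, 159L, 93L),
    min_pcr_reads = 100L,
    rel_abundance_floor = 0.01,
    motu_identity = 0.98
  )
}

check_marker_configs <- function(cfg) {
  stopifnot(
    is.data.frame(cfg),
    all(c("marker", "min_len", "max_len") %in% names(cfg)),
    !anyDuplicated(cfg$marker),
    all(cfg$min_len > 0), all(cfg$min_len <= cfg$max_len)
  )
  if (!"min_pcr_reads" %in% names(cfg)) cfg$min_pcr_reads <- 100L
  if (!"rel_abundance_floor" %in% names(cfg)) cfg$rel_abundance_floor <- 0.01
  if (!"motu_identity" %in% names(cfg)) cfg$motu_identity <- 0.98
  stopifnot(all(cfg$rel_abundance_floor >= 0), all(cfg$rel_abundance_floor < 1))
  cfg
}

#' Assemble a long-format ESV table
#'
#' The package represents per-marker ESV count data as one long tibble with
#' columns `marker`, `esv_id`, `sequence`, `sample_id`, `reads`, one row per
#' ESV x PCR product with non-zero reads. This constructor joins a wide
#' count matrix (one column per sample) with an `esv_id` -> `sequence` table
#' and validates the invariants: non-negative counts, uppercase ACGTN
#' sequences, one sequence per ESV id within a marker.
#'
#' @param counts A data frame whose first column is `esv_id` and remaining
#'   columns are per-sample read counts.
#' @param sequences A data frame with columns `esv_id`, `sequence`.
#' @param marker Marker id for the table.
#' @return A long tibble of class `tbl_df`.
#' @export
esv_table <- function(counts, sequences, marker) {
  stopifnot(is.data.frame(counts), is.data.frame(sequences),
            "esv_id" %in% names(counts),
            all(c("esv_id", "sequence") %in% names(sequences)))
  long <- tidyr::pivot_longer(counts, -"esv_id",
                              names_to = "sample_id", values_to = "reads")
  long <- dplyr::filter(long, .data$reads != 0)
  out <- long |>
    dplyr::inner_join(dplyr::select(sequences, "esv_id", "sequence"),
                      by = "esv_id") |>
    dplyr::mutate(marker = marker) |>
    dplyr::select("marker", "esv_id", "sequence", "sample_id", "reads")
  validate_esv_table(out)
}

validate_esv_table <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("marker", "esv_id", "sequence", "sample_id", "reads")
                %in% names(x)))
  if (any(x$reads < 0)) stop("negative read counts", call. = FALSE)
  if (any(grepl("[^ACGTN]", x$sequence))) {
    stop("sequences must be uppercase ACGT (+N)", call. = FALSE)
  }
  nseq <- dplyr::n_distinct(paste(x$marker, x$esv_id, x$sequence))
  nid <- dplyr::n_distinct(paste(x$marker, x$esv_id))
  if (nseq != nid) stop("conflicting sequences for one esv_id", call. = FALSE)
  tibble::as_tibble(x)
}

# -- provenance -------------------------------------------------------------

new_log_entry <- function(stage, marker, record_id, action, reason) {
  tibble::tibble(stage = stage, marker = marker, record_id = record_id,
                 action = action, reason = reason)
}

append_log <- function(x, prev, entries) {
  attr(x, "dietmerge_log") <- dplyr::bind_rows(attr(prev, "dietmerge_log"),
                                               entries)
  attr(x, "dietmerge_stages") <- attr(prev, "dietmerge_stages")
  x
}

mark_stage <- function(x, prev, stage) {
  attr(x, "dietmerge_stages") <- c(attr(prev, "dietmerge_stages"), stage)
  x
}

#' Retrieve the provenance log of a filtered table
#'
#' Every filtering step records, per affected record, the stage, the record
#' id, the action taken and the reason, as a machine-readable tibble.
#'
#' @param x A table returned by one of the pipeline steps.
#' @return A tibble with columns `stage`, `marker`, `record_id`, `action`,
#'   `reason` (empty if nothing was removed).
#' @export
pipeline_log <- function(x) {
  log <- attr(x, "dietmerge_log")
  if (is.null(log)) {
    log <- new_log_entry(character(), character(), character(),
                         character(), character())
  }
  log
}

# -- filtering cascade ------------------------------------------------------

#' Keep ESVs inside the marker's fragment-length window
#'
#' Retains exactly the ESVs whose sequence length lies in the closed
#' interval `[min_len, max_len]` of their marker's configuration; counts of
#' retained ESVs are untouched.
#'
#' @param x A long ESV table (see [esv_table()]).
#' @param configs Per-marker configuration tibble
#'   (default [default_marker_configs()]).
#' @return The filtered table, with removals appended to [pipeline_log()].
#' @export
filter_length <- function(x, configs = default_marker_configs()) {
  x <- validate_esv_table(x)
  configs <- check_marker_configs(configs)
  missing <- setdiff(unique(x$marker), configs$marker)
  if (length(missing) > 0) {
    stop("no configuration for marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- x |>
    dplyr::left_join(dplyr::select(configs, "marker", "min_len", "max_len"),
                     by = "marker") |>
    dplyr::mutate(.len = nchar(.data$sequence),
                  .keep_row = .data$.len >= .data$min_len &
                    .data$.len <= .data$max_len)
  removed <- y |>
    dplyr::filter(!.data$.keep_row) |>
    dplyr::distinct(.data$marker, .data$esv_id, .data$.len)
  out <- y |>
    dplyr::filter(.data$.keep_row) |>
    dplyr::select(-"min_len", -"max_len", -".len", -".keep_row")
  out <- append_log(out, x, new_log_entry(
    "length_filter", removed$marker, removed$esv_id, "removed_esv",
    paste0("length ", removed$.len, " outside window")))
  mark_stage(out, x, "length_filter")
}

#' Remove one-off sequencing-error ESVs
#'
#' Within each marker, an ESV A is removed when some ESV B exists with
#' (i) unit edit distance between their sequences (one substitution,
#' insertion or deletion), (ii) total read count of A strictly lower than
#' that of B, and (iii) A never occurring in a PCR product without B. Such
#' ESVs are interpreted as PCR or sequencing errors of B. Removal is decided
#' against the original table and applied once (single pass, no cascading),
#' so the highest-count ESV of a marker can never be removed.
#'
#' @inheritParams filter_length
#' @return The denoised table.
#' @export
denoise_one_off <- function(x) {
  x <- validate_esv_table(x)
  drop <- x |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_map(function(g, key) {
      seqs <- g |> dplyr::distinct(.data$esv_id, .data$sequence)
      n <- nrow(seqs)
      if (n < 2) return(character(0))
      totals <- g |>
        dplyr::group_by(.data$esv_id) |>
        dplyr::summarise(total = sum(.data$reads)) |>
        (\(t) stats::setNames(t$total, t$esv_id))()
      pres <- split(g$sample_id[g$reads > 0], g$esv_id[g$reads > 0])
      d <- utils::adist(seqs$sequence)
      removed <- character(0)
      for (i in seq_len(n)) {
        a <- seqs$esv_id[i]
        for (j in seq_len(n)) {
          if (i == j || d[i, j] != 1L) next
          b <- seqs$esv_id[j]
          if (totals[a] >= totals[b]) next
          if (all(pres[[a]] %in% pres[[b]])) {
            removed <- c(removed, a)
            break
          }
        }
      }
      tibble::tibble(marker = key$marker, esv_id = removed)
    }) |>
    dplyr::bind_rows()
  out <- dplyr::anti_join(x, drop, by = c("marker", "esv_id"))
  out <- append_log(out, x, new_log_entry(
    "denoise", drop$marker, drop$esv_id, "removed_esv",
    "one base pair from a higher-count ESV it never occurs without"))
  mark_stage(out, x, "denoise")
}

#' Drop failed PCR products
#'
#' PCR products (sample x marker) whose total read count after denoising is
#' below `min_pcr_reads` (default 100) are considered amplification failures
#' and removed, with each failure logged.
#'
#' @inheritParams filter_length
#' @return The table without failed PCR products.
#' @export
drop_failed_pcrs <- function(x, configs = default_marker_configs()) {
  x <- validate_esv_table(x)
  configs <- check_marker_configs(configs)
  totals <- x |>
    dplyr::group_by(.data$marker, .data$sample_id) |>
    dplyr::summarise(total = sum(.data$reads), .groups = "drop") |>
    dplyr::left_join(dplyr::select(configs, "marker", "min_pcr_reads"),
                     by = "marker")
  failed <- dplyr::filter(totals, .data$total < .data$min_pcr_reads)
  out <- dplyr::anti_join(x, failed, by = c("marker", "sample_id"))
  out <- append_log(out, x, new_log_entry(
    "pcr_failure", failed$marker, failed$sample_id, "removed_pcr",
    paste0("total reads ", failed$total, " < ", failed$min_pcr_reads)))
  mark_stage(out, x, "pcr_failure")
}

#' Per-PCR relative-abundance filter
#'
#' Within each PCR product, ESV counts strictly below
#' `rel_abundance_floor` (default 1%) of that PCR's total read count are set
#' to zero; ESVs left with no positive count anywhere are dropped. The floor
#' is computed against the PCR totals of the table as given (i.e. after
#' failed-PCR removal), and the step must be run exactly once: because it
#' redefines the totals it is not idempotent, so a second application
#' raises an error.
#'
#' @inheritParams filter_length
#' @return The filtered table.
#' @export
relative_abundance_filter <- function(x, configs = default_marker_configs()) {
  if ("rel_abundance" %in% attr(x, "dietmerge_stages")) {
    stop("relative_abundance_filter has already been applied to this table",
         call. = FALSE)
  }
  x <- validate_esv_table(x)
  configs <- check_marker_configs(configs)
  y <- x |>
    dplyr::left_join(dplyr::select(configs, "marker", "rel_abundance_floor"),
                     by = "marker") |>
    dplyr::group_by(.data$marker, .data$sample_id) |>
    dplyr::mutate(.total = sum(.data$reads)) |>
    dplyr::ungroup() |>
    dplyr::mutate(.keep_row = .data$reads >= .data$rel_abundance_floor * .data$.total)
  removed <- dplyr::filter(y, !.data$.keep_row)
  out <- y |>
    dplyr::filter(.data$.keep_row) |>
    dplyr::select(-"rel_abundance_floor", -".total", -".keep_row")
  out <- append_log(out, x, new_log_entry(
    "rel_abundance", removed$marker,
    paste0(removed$esv_id, "@", removed$sample_id), "zeroed_count",
    paste0(removed$reads, " reads < floor of PCR total ", removed$.total)))
  mark_stage(out, x, "rel_abundance")
}

# -- taxonomic assignment ---------------------------------------------------

#' Most-inclusive-rank (lowest common ancestor) assignment
#'
#' For each ESV, all database hits within `tolerance` identity percentage
#' points of that ESV's best hit are considered equally plausible, and the
#' ESV is assigned the lineage truncated at the deepest rank on which all of
#' them agree. An ESV whose near-best hits disagree already at the first
#' rank, is left unassigned (`NA` lineage) and flagged.
#'
#' @param hits A data frame with columns `esv_id`, `lineage`,
#'   `pct_identity` (0-100) and optionally `marker`.
#' @param tolerance Identity window in percentage points (default 1).
#' @param sep Lineage field separator.
#' @param ladder Rank ladder.
#' @return A tibble with columns `esv_id` (and `marker` if present in
#'   `hits`), `lineage`, `depth`, `n_hits_used`, `best_identity`.
#' @export
assign_lca <- function(hits, tolerance = 1, sep = ";",
                       ladder = linnaean_ranks()) {
  stopifnot(is.data.frame(hits),
            all(c("esv_id", "lineage", "pct_identity") %in% names(hits)))
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("pct_identity must be within [0, 100]", call. = FALSE)
  }
  keys <- intersect(c("marker", "esv_id"), names(hits))
  hits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, key) {
      best <- max(g$pct_identity)
      used <- g$lineage[g$pct_identity >= best - tolerance]
      anc <- common_prefix(parse_lineage(used, sep = sep, ladder = ladder))
      tibble::tibble(
        lineage = if (length(anc) == 0) NA_character_ else
          paste(anc, collapse = sep),
        depth = length(anc),
        n_hits_used = length(used),
        best_identity = best
      )
    }) |>
    dplyr::ungroup()
}

# -- MOTU clustering --------------------------------------------------------

#' Cluster unresolved ESVs into MOTUs
#'
#' ESVs assigned the same lineage within a marker but not resolved to
#' species level are clustered into molecular operational taxonomic units
#' by single-linkage at a pairwise sequence identity threshold (default
#' 98%). Pairwise identity is `1 - d/L` with `d` the unit-cost edit distance
#' and `L` the longer sequence length. Clusters are numbered from 1 in order
#' of decreasing total read count (ties broken by smallest ESV id), giving
#' labels such as `"Carabidae 1"`. Species-level ESVs pass through with no
#' MOTU label. MOTU labels are local to a marker and must never be matched
#' across markers.
#'
#' @param esvs A data frame with columns `marker`, `esv_id`, `sequence`,
#'   `lineage`, `total_reads`.
#' @param identity Identity threshold as a fraction (default 0.98). May also
#'   be a per-marker tibble with columns `marker`, `motu_identity`.
#' @param sep,ladder Lineage conventions.
#' @return A tibble `marker`, `esv_id`, `lineage`, `motu`, `motu_label`
#'   (`motu` is `NA` for species-level ESVs).
#' @export
cluster_motus <- function(esvs, identity = 0.98, sep = ";",
                          ladder = linnaean_ranks()) {
  stopifnot(is.data.frame(esvs),
            all(c("marker", "esv_id", "sequence", "lineage", "total_reads")
                %in% names(esvs)))
  id_for <- function(marker) {
    if (is.data.frame(identity)) {
      identity$motu_identity[match(marker, identity$marker)]
    } else identity
  }
  esvs <- dplyr::mutate(esvs,
                        depth = lineage_depth(.data$lineage, sep, ladder))
  species_pos <- length(ladder)
  esvs |>
    dplyr::group_by(.data$marker, .data$lineage) |>
    dplyr::group_modify(function(g, key) {
      if (g$depth[1] >= species_pos) {
        return(tibble::tibble(esv_id = g$esv_id, motu = NA_integer_,
                              motu_label = NA_character_))
      }
      thr <- id_for(key$marker)
      n <- nrow(g)
      if (n == 1) {
        comp <- 1L
      } else {
        d <- utils::adist(g$sequence)
        len <- outer(nchar(g$sequence), nchar(g$sequence), pmax)
        adj <- (1 - d / len) >= thr
        gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                                  diag = FALSE)
        comp <- igraph::components(gr)$membership
      }
      ord <- tibble::tibble(comp = comp, reads = g$total_reads,
                            esv_id = g$esv_id) |>
        dplyr::group_by(.data$comp) |>
        dplyr::summarise(reads = sum(.data$reads),
                         first_id = min(.data$esv_id)) |>
        dplyr::arrange(dplyr::desc(.data$reads), .data$first_id)
      motu <- match(comp, ord$comp)
      leaf <- utils::tail(strsplit(key$lineage, sep, fixed = TRUE)[[1]], 1)
      tibble::tibble(esv_id = g$esv_id, motu = motu,
                     motu_label = paste(leaf, motu))
    }) |>
    dplyr::ungroup()
}

# -- exclusion --------------------------------------------------------------

#' Default taxon exclusion policy
#'
#' Detections are kept only when their lineage falls inside an allowed
#' kingdom (vascular plants and animals by default) and under none of the
#' excluded clade prefixes. The defaults exclude non-vascular plants
#' (bryophytes sensu lato), birds, mammals, internal parasites (Nematoda)
#' and the mealworm family Tenebrionidae (likely bait contamination in
#' studies using mealworm-baited traps).
#'
#' @return A list with elements `allowed_kingdoms` and `excluded_clades`
#'   (lineage prefixes).
#' @export
default_exclusion_policy <- function() {
  list(
    allowed_kingdoms = c("Plantae", "Animalia"),
    excluded_clades = c(
      "Plantae;Bryophyta",
      "Plantae;Marchantiophyta",
      "Plantae;Anthocerotophyta",
      "Animalia;Chordata;Aves",
      "Animalia;Chordata;Mammalia",
      "Animalia;Nematoda",
      "Animalia;Arthropoda;Insecta;Coleoptera;Tenebrionidae"
    )
  )
}

#' Remove non-target taxa from a detection table
#'
#' @param detections A data frame with a `lineage` column.
#' @param policy An exclusion policy (see [default_exclusion_policy()]).
#' @param sep,ladder Lineage conventions.
#' @return The detections kept, with removals in [pipeline_log()].
#' @export
exclude_taxa <- function(detections, policy = default_exclusion_policy(),
                         sep = ";", ladder = linnaean_ranks()) {
  stopifnot(is.data.frame(detections), "lineage" %in% names(detections))
  lin <- parse_lineage(detections$lineage, sep = sep, ladder = ladder)
  kingdom <- vapply(lin, `[[`, character(1), 1)
  reason <- rep(NA_character_, nrow(detections))
  reason[!kingdom %in% policy$allowed_kingdoms] <- "kingdom not allowed"
  for (clade in policy$excluded_clades) {
    pref <- parse_lineage(clade, sep = sep, ladder = ladder)[[1]]
    hit <- is.na(reason) &
      vapply(lin, function(v) is_prefix(pref, v), logical(1))
    reason[hit] <- paste0("excluded clade ", clade)
  }
  keep <- is.na(reason)
  marker <- if ("marker_id" %in% names(detections)) {
    detections$marker_id
  } else rep(NA_character_, nrow(detections))
  out <- detections[keep, , drop = FALSE]
  out <- append_log(out, detections, new_log_entry(
    "exclusion", marker[!keep], detections$lineage[!keep],
    "removed_detection", reason[!keep]))
  out <- mark_stage(out, detections, "exclusion")
  tibble::as_tibble(out)
}

# -- detections -------------------------------------------------------------

#' Collapse a filtered ESV table to presence/absence detections
#'
#' One detection per (sample, marker, taxon label) with any positive read
#' count; several ESVs carrying the same label in a sample collapse to a
#' single detection. ESVs without a taxonomic assignment are dropped and
#' logged.
#'
#' @param x A filtered long ESV table.
#' @param taxa A tibble mapping `marker`, `esv_id` to `lineage`, `motu`,
#'   `motu_label` (as produced by [assign_lca()] + [cluster_motus()]).
#' @return A detections tibble: `sample_id`, `marker_id`, `lineage`,
#'   `motu`, `motu_label`.
#' @export
to_detections <- function(x, taxa) {
  x <- validate_esv_table(x)
  stopifnot(all(c("marker", "esv_id", "lineage") %in% names(taxa)))
  if (!"motu" %in% names(taxa)) taxa$motu <- NA_integer_
  if (!"motu_label" %in% names(taxa)) taxa$motu_label <- NA_character_
  joined <- x |>
    dplyr::filter(.data$reads > 0) |>
    dplyr::left_join(
      dplyr::select(taxa, "marker", "esv_id", "lineage", "motu", "motu_label"),
      by = c("marker", "esv_id"))
  unassigned <- joined |>
    dplyr::filter(is.na(.data$lineage)) |>
    dplyr::distinct(.data$marker, .data$esv_id)
  out <- joined |>
    dplyr::filter(!is.na(.data$lineage)) |>
    dplyr::distinct(.data$sample_id, marker_id = .data$marker,
                    .data$lineage, .data$motu, .data$motu_label) |>
    dplyr::arrange(.data$sample_id, .data$marker_id, .data$lineage,
                   .data$motu)
  out <- append_log(out, x, new_log_entry(
    "assignment", unassigned$marker, unassigned$esv_id, "dropped_esv",
    "no taxonomic assignment"))
  mark_stage(out, x, "assignment")
}

#' Run the full per-marker ESV cleaning pipeline
#'
#' Applies, in this fixed order: fragment-length filter, one-off denoising,
#' failed-PCR removal, per-PCR relative-abundance filter, most inclusive
#' rank assignment, MOTU clustering, and non-target taxon exclusion, then
#' collapses to presence/absence detections. The order is enforced; in
#' particular the relative-abundance floor is computed against PCR totals
#' taken after failed-PCR removal.
#'
#' @param x A long ESV table covering one or more markers.
#' @param hits A hit table (`esv_id`, `lineage`, `pct_identity`, optionally
#'   `marker`).
#' @param configs Per-marker configurations.
#' @param policy Exclusion policy.
#' @param lca_tolerance Identity window for [assign_lca()].
#' @param sep,ladder Lineage conventions.
#' @return A list of class `esv_pipeline_result`: `detections` (tibble),
#'   `table` (the filtered ESV table), `assignments`, `taxa`, and `log`
#'   (the provenance tibble).
#' @export
run_esv_pipeline <- function(x, hits, configs = default_marker_configs(),
                             policy = default_exclusion_policy(),
                             lca_tolerance = 1, sep = ";",
                             ladder = linnaean_ranks()) {
  filtered <- x |>
    filter_length(configs) |>
    denoise_one_off() |>
    drop_failed_pcrs(configs) |>
    relative_abundance_filter(configs)

  retained <- dplyr::distinct(filtered, .data$marker, .data$esv_id)
  if ("marker" %in% names(hits)) {
    hits_used <- dplyr::semi_join(hits, retained, by = c("marker", "esv_id"))
  } else {
    hits_used <- dplyr::semi_join(hits, retained, by = "esv_id")
  }
  assignments <- assign_lca(hits_used, tolerance = lca_tolerance,
                            sep = sep, ladder = ladder)
  if (!"marker" %in% names(assignments)) {
    assignments <- dplyr::left_join(assignments, retained, by = "esv_id")
  }

  totals <- filtered |>
    dplyr::group_by(.data$marker, .data$esv_id, .data$sequence) |>
    dplyr::summarise(total_reads = sum(.data$reads), .groups = "drop")
  assigned <- assignments |>
    dplyr::filter(!is.na(.data$lineage)) |>
    dplyr::inner_join(totals, by = c("marker", "esv_id"))
  id_cfg <- dplyr::select(check_marker_configs(configs),
                          "marker", "motu_identity")
  taxa <- cluster_motus(assigned, identity = id_cfg, sep = sep,
                        ladder = ladder) |>
    dplyr::select("marker", "esv_id", "lineage", "motu", "motu_label")

  detections <- to_detections(filtered, taxa)
  detections <- exclude_taxa(detections, policy, sep = sep, ladder = ladder)

  structure(list(
    detections = tibble::as_tibble(as.data.frame(detections)),
    table = filtered,
    assignments = assignments,
    taxa = taxa,
    log = pipeline_log(detections)
  ), class = "esv_pipeline_result")
}

#' @export
print.esv_pipeline_result <- function(x, ...) {
  cat("ESV pipeline result\n")
  cat("  retained ESV records:", nrow(x$table), "\n")
  cat("  detections:", nrow(x$detections), "in",
      dplyr::n_distinct(x$detections$sample_id), "samples\n")
  cat("  log entries:", nrow(x$log), "\n")
  invisible(x)
}
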