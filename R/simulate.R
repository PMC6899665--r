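#' Default synthetic marker panel
#'
#' Describes, per marker and kingdom it amplifies, the per-item detection
#' probability, the fraction of orders the marker is blind to (taxon-level
#' primer bias: some clades are consistently missed, not just randomly
#' dropped), and the taxonomic resolution distribution (the probability
#' that a detected item is reported at order, family, genus or species
#' level). The defaults emulate a panel of one universal eukaryote marker
#' (broad scope, coarse resolution, modest detection), a plant marker (high
#' detection and resolution for plants), and two arthropod markers — one of
#' intermediate bias and one strongly biased but finely resolving, echoing
#' the well-known behaviour of 16S versus ZBJ-type COI primers.
#'
#' @return A tibble `marker`, `kingdom`, `p_detect`, `p_blind`, `p_order`,
#'   `p_family`, `p_genus`, `p_species`.
#' @export
default_marker_panel <- function() {
  tibble::tibble(
    marker = c("18S", "18S", "trnL", "IN16STK", "ZBJ"),
    kingdom = c("Plantae", "Animalia", "Plantae", "Animalia", "Animalia"),
    p_detect = c(0.57, 0.30, 0.90, 0.64, 0.50),
    p_blind = c(0.10, 0.15, 0.05, 0.15, 0.30),
    p_order = c(0.45, 0.50, 0.16, 0.25, 0.20),
    p_family = c(0.36, 0.40, 0.30, 0.44, 0.38),
    p_genus = c(0.11, 0.06, 0.27, 0.15, 0.20),
    p_species = c(0.08, 0.04, 0.27, 0.16, 0.22)
  )
}

#' Synthetic taxa pool
#'
#' A deterministic pool of full seven-rank lineages for two kingdoms, with
#' synthetic taxon names. Orders within a kingdom diverge at the order rank
#' (they share synthetic kingdom/phylum/class names), so lineages from
#' different orders are never prefix-comparable.
#'
#' @param n_orders Named integer vector: orders per kingdom.
#' @param families_per_order,genera_per_family,species_per_genus Pool shape.
#' @param sep Lineage separator.
#' @return A tibble `kingdom`, `order_id`, `lineage` (one row per species).
#' @export
synthetic_taxa_pool <- function(n_orders = c(Plantae = 27, Animalia = 28),
                                families_per_order = 3,
                                genera_per_family = 2,
                                species_per_genus = 2,
                                sep = ";") {
  stems <- list(Plantae = c("Plantae", "Streptophyta", "Magnoliopsida"),
                Animalia = c("Animalia", "Arthropoda", "Insecta"))
  rows <- list()
  for (k in names(n_orders)) {
    stem <- stems[[k]]
    pre <- tolower(substr(k, 1, 1))
    for (o in seq_len(n_orders[[k]])) {
      ord <- sprintf("%sOrder%02d", pre, o)
      for (f in seq_len(families_per_order)) {
        fam <- sprintf("%sFam%02d_%d", pre, o, f)
        for (g in seq_len(genera_per_family)) {
          gen <- sprintf("%sGen%02d_%d_%d", pre, o, f, g)
          for (s in seq_len(species_per_genus)) {
            sp <- sprintf("%s sp%d", gen, s)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              kingdom = k, order_id = ord,
              lineage = paste(c(stem, ord, fam, gen, sp), collapse = sep))
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a multi-marker detection study
#'
#' Draws, per sample and kingdom, a set of ingested items from a shared
#' taxa pool (each sample's items come from distinct orders, so the
#' expected post-merge count is known exactly), then lets each marker in
#' the panel detect each in-scope item independently — unless the item's
#' order falls in the marker's blind set, drawn once per simulation to
#' emulate taxon-level primer bias — and report it at a rank drawn from
#' the marker's resolution distribution. Items reported above species
#' level carry a marker-local MOTU label that is stable across samples
#' (the same underlying species always maps to the same label for a given
#' marker) but never comparable across markers. The truth table records,
#' per sample and kingdom, the number of distinct items detected by at
#' least one marker and the number of raw detections, so the planted
#' cross-marker redundancy is known by construction.
#'
#' @param n_samples Number of faecal samples (default 115).
#' @param panel Marker panel (see [default_marker_panel()]).
#' @param pool Taxa pool (see [synthetic_taxa_pool()]).
#' @param mean_items Named vector: mean ingested items per sample per
#'   kingdom (Poisson).
#' @param seed Integer seed; all randomness flows from it.
#' @param sep Lineage separator.
#' @return A list with elements `detections` (tibble `sample_id`,
#'   `marker_id`, `lineage`, `motu`, `motu_label`), `truth` (tibble
#'   `sample_id`, `kingdom`, `n_items`, `n_detections`) and `pool`.
#' @export
simulate_detections <- function(n_samples = 115,
                                panel = default_marker_panel(),
                                pool = synthetic_taxa_pool(),
                                mean_items = c(Plantae = 5.7, Animalia = 10.2),
                                seed = 1,
                                sep = ";") {
  stopifnot(n_samples > 0, all(panel$p_detect >= 0 & panel$p_detect <= 1))
  set.seed(seed)
  ladder <- linnaean_ranks()
  rank_choices <- c("order", "family", "genus", "species")
  pool <- dplyr::mutate(pool, species_idx = dplyr::row_number())
  orders_by_kingdom <- split(unique(pool[c("kingdom", "order_id")]),
                             unique(pool[c("kingdom", "order_id")])$kingdom)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  # taxon-level primer bias: per (marker, kingdom), a fixed set of orders
  # the marker never amplifies
  if (!"p_blind" %in% names(panel)) panel$p_blind <- 0
  blind <- lapply(seq_len(nrow(panel)), function(m) {
    k_orders <- orders_by_kingdom[[panel$kingdom[m]]]$order_id
    n_blind <- floor(panel$p_blind[m] * length(k_orders))
    if (n_blind > 0) sample(k_orders, n_blind) else character(0)
  })

  det <- list()
  truth <- list()
  for (s in sample_ids) {
    for (k in names(mean_items)) {
      k_orders <- orders_by_kingdom[[k]]$order_id
      n_items <- min(stats::rpois(1, mean_items[[k]]), length(k_orders))
      if (n_items == 0) {
        truth[[length(truth) + 1L]] <- tibble::tibble(
          sample_id = s, kingdom = k, n_items = 0L, n_detections = 0L)
        next
      }
      item_orders <- sample(k_orders, n_items)
      items <- dplyr::bind_rows(lapply(item_orders, function(o) {
        cand <- pool[pool$order_id == o, ]
        cand[sample.int(nrow(cand), 1), ]
      }))
      n_det_items <- 0L
      n_det <- 0L
      for (ii in seq_len(nrow(items))) {
        item <- items[ii, ]
        full <- strsplit(item$lineage, sep, fixed = TRUE)[[1]]
        detected_by_any <- FALSE
        for (m in seq_len(nrow(panel))) {
          if (panel$kingdom[m] != k) next
          if (item$order_id %in% blind[[m]]) next
          if (stats::runif(1) > panel$p_detect[m]) next
          rank <- sample(rank_choices, 1, prob = unlist(
            panel[m, c("p_order", "p_family", "p_genus", "p_species")]))
          depth <- match(rank, ladder)
          lin <- paste(full[seq_len(depth)], collapse = sep)
          if (rank == "species") {
            motu <- NA_integer_
            label <- NA_character_
          } else {
            # stable marker-local MOTU: index of the species within its
            # truncated-lineage sibling set in the pool
            sibs <- pool$species_idx[startsWith(pool$lineage,
                                                paste0(lin, sep)) |
                                       pool$lineage == lin]
            motu <- match(item$species_idx, sort(sibs))
            label <- paste(full[depth], motu)
          }
          det[[length(det) + 1L]] <- tibble::tibble(
            sample_id = s, marker_id = panel$marker[m], lineage = lin,
            motu = motu, motu_label = label)
          detected_by_any <- TRUE
          n_det <- n_det + 1L
        }
        if (detected_by_any) n_det_items <- n_det_items + 1L
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        sample_id = s, kingdom = k, n_items = n_det_items,
        n_detections = n_det)
    }
  }
  list(detections = dplyr::bind_rows(det),
       truth = dplyr::bind_rows(truth),
       pool = pool)
}

# random DNA sequences with pairwise edit distance >= min_dist
random_spaced_sequences <- function(n, len_range, min_dist = 3L,
                                    max_tries = 2000L) {
  seqs <- character(0)
  tries <- 0L
  while (length(seqs) < n && tries < max_tries) {
    tries <- tries + 1L
    len <- sample(seq(len_range[1], len_range[2]), 1)
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    if (length(seqs) == 0 || all(utils::adist(cand, seqs) >= min_dist)) {
      seqs <- c(seqs, cand)
    }
  }
  if (length(seqs) < n) stop("could not place spaced sequences", call. = FALSE)
  seqs
}

substitute_one <- function(seq) {
  pos <- sample(nchar(seq), 1)
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  paste0(substr(seq, 1, pos - 1), new, substr(seq, pos + 1, nchar(seq)))
}

#' Simulate a per-marker ESV experiment with planted errors
#'
#' Generates a single-marker ESV count table whose truth is known: a set of
#' true ESVs (random sequences inside the marker's length window, pairwise
#' edit distance of at least 3), a set of planted one-off error children
#' (one substitution away from their parent, read counts far below both the
#' parent and 1% of each PCR total, present only in PCR products where the
#' parent is present) and, optionally, PCR products forced below the
#' 100-read failure threshold. True ESV counts are drawn high enough that
#' no true ESV ever falls under the relative-abundance floor, so the
#' filtering cascade should recover exactly the true set. A hit table
#' assigns each ESV a lineage from the synthetic pool; a fraction of ESVs
#' receive two near-tied hits from sister species so the most inclusive
#' rank rule is exercised.
#'
#' @param marker Marker id (must appear in `configs`).
#' @param n_samples Number of PCR products with normal read depth.
#' @param n_esvs Number of true ESVs.
#' @param error_rate Fraction of true ESVs given a planted one-off child.
#' @param n_failed_pcrs Extra PCR products forced under the failure
#'   threshold.
#' @param configs Marker configurations (length windows).
#' @param pool Taxa pool for hit lineages.
#' @param seed Integer seed.
#' @return A list: `esv` (long ESV table), `hits`, and `truth` (list with
#'   `true_esvs`, `error_esvs`, `failed_pcrs`).
#' @export
simulate_esv_experiment <- function(marker = "ZBJ", n_samples = 8,
                                    n_esvs = 12, error_rate = 0.5,
                                    n_failed_pcrs = 1,
                                    configs = default_marker_configs(),
                                    pool = synthetic_taxa_pool(),
                                    seed = 1) {
  set.seed(seed)
  cfg <- configs[configs$marker == marker, ]
  if (nrow(cfg) != 1) stop("unknown marker: ", marker, call. = FALSE)
  seqs <- random_spaced_sequences(n_esvs, c(cfg$min_len, cfg$max_len))
  true_ids <- sprintf("%s_esv%03d", marker, seq_len(n_esvs))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  # presence and counts of true ESVs; every PCR holds >= 3 ESVs and every
  # count is >= 800, above 1% of any attainable PCR total
  rows <- list()
  presence <- matrix(FALSE, n_esvs, n_samples,
                     dimnames = list(true_ids, sample_ids))
  for (s in seq_len(n_samples)) {
    present <- which(stats::runif(n_esvs) < 0.7)
    if (length(present) < 3) present <- sample.int(n_esvs, 3)
    presence[present, s] <- TRUE
    rows[[s]] <- tibble::tibble(
      marker = marker, esv_id = true_ids[present],
      sequence = seqs[present], sample_id = sample_ids[s],
      reads = sample(800:5000, length(present), replace = TRUE))
  }
  esv <- dplyr::bind_rows(rows)

  # planted one-off children, co-occurring exactly with their parents
  n_err <- round(error_rate * n_esvs)
  parents <- if (n_err > 0) sample.int(n_esvs, n_err) else integer(0)
  err_ids <- character(0)
  err_rows <- list()
  pcr_totals <- esv |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$reads))
  totals <- stats::setNames(pcr_totals$total, pcr_totals$sample_id)
  for (i in seq_along(parents)) {
    p <- parents[i]
    child_seq <- substitute_one(seqs[p])
    while (any(utils::adist(child_seq, seqs) == 0)) {
      child_seq <- substitute_one(seqs[p])
    }
    cid <- sprintf("%s_err%03d", marker, i)
    err_ids <- c(err_ids, cid)
    in_pcrs <- sample_ids[presence[p, ]]
    err_rows[[i]] <- tibble::tibble(
      marker = marker, esv_id = cid, sequence = child_seq,
      sample_id = in_pcrs,
      reads = pmax(1, round(0.003 * totals[in_pcrs])))
  }
  esv <- dplyr::bind_rows(esv, dplyr::bind_rows(err_rows))

  # forced failed PCRs: a few true ESVs at trace counts
  failed_ids <- character(0)
  if (n_failed_pcrs > 0) {
    failed_ids <- sprintf("F%03d", seq_len(n_failed_pcrs))
    for (f in failed_ids) {
      pick <- sample.int(n_esvs, 3)
      esv <- dplyr::bind_rows(esv, tibble::tibble(
        marker = marker, esv_id = true_ids[pick], sequence = seqs[pick],
        sample_id = f, reads = sample(1:5, 3, replace = TRUE)))
    }
  }

  # hit table: animal lineages for arthropod/universal markers, plants for
  # trnL; ~25% of true ESVs get a second near-tied sister-species hit
  k <- if (marker == "trnL") "Plantae" else "Animalia"
  kpool <- pool[pool$kingdom == k, ]
  hit_rows <- list()
  picks <- sample.int(nrow(kpool), n_esvs)
  for (i in seq_len(n_esvs)) {
    lin <- kpool$lineage[picks[i]]
    best <- round(stats::runif(1, 98, 100), 1)
    hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
      marker = marker, esv_id = true_ids[i], lineage = lin,
      pct_identity = best)
    if (stats::runif(1) < 0.25) {
      genus <- truncate_lineage(lin, "genus")
      sibs <- kpool$lineage[startsWith(kpool$lineage, paste0(genus, ";")) &
                              kpool$lineage != lin]
      if (length(sibs) > 0) {
        hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
          marker = marker, esv_id = true_ids[i], lineage = sibs[1],
          pct_identity = best - round(stats::runif(1, 0, 0.8), 1))
      }
    }
  }
  for (i in seq_along(err_ids)) {
    hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
      marker = marker, esv_id = err_ids[i],
      lineage = kpool$lineage[picks[parents[i]]],
      pct_identity = 97)
  }
  hits <- dplyr::bind_rows(hit_rows)

  list(esv = validate_esv_table(esv),
       hits = hits,
       truth = list(true_esvs = true_ids, error_esvs = err_ids,
                    failed_pcrs = failed_ids))
}
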