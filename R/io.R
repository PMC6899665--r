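# TSV interchange: header row, UTF-8, "#"-prefixed comment lines allowed.

#' Read a detections table
#'
#' @param path Path to a TSV file with columns `sample_id`, `marker_id`,
#'   `lineage` and optionally `motu`, `motu_label`. Lines starting with `#`
#'   are comments.
#' @return A tibble.
#' @export
read_detections <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("sample_id", "marker_id", "lineage")
  if (!all(need %in% names(x))) {
    stop("detections file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x$sample_id <- as.character(x$sample_id)
  x$marker_id <- as.character(x$marker_id)
  if ("motu" %in% names(x)) x$motu <- as.integer(x$motu)
  x
}

#' Write a table as TSV with a provenance comment header
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comment Optional character vector of comment lines (written with
#'   a leading `#`).
#' @return `path`, invisibly.
#' @export
write_tsv_c <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sub("\n$", "", readr::format_tsv(x)), con)
  invisible(path)
}

#' Read a wide per-marker ESV count matrix
#'
#' @param path TSV whose first column is `esv_id` and remaining columns are
#'   per-sample read counts.
#' @param fasta Path to a FASTA file of the ESV sequences (ids matching
#'   `esv_id`).
#' @param marker Marker id.
#' @return A long ESV table (see [esv_table()]).
#' @export
read_esv_counts <- function(path, fasta, marker) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE)
  names(counts)[1] <- "esv_id"
  esv_table(counts, read_esv_fasta(fasta), marker)
}

#' Read ESV sequences from FASTA
#'
#' @param path FASTA path.
#' @return A tibble `esv_id`, `sequence`.
#' @export
read_esv_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    tibble::tibble(esv_id = sub("\\s.*$", "", names(ss)),
                   sequence = as.character(ss))
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    id <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
    grp <- cumsum(idx)
    seqs <- vapply(split(lines[!idx], grp[!idx]), paste, character(1),
                   collapse = "")
    tibble::tibble(esv_id = id, sequence = toupper(unname(seqs)))
  }
}

#' Write ESV sequences to FASTA
#'
#' @param sequences A tibble `esv_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esv_fasta <- function(sequences, path) {
  writeLines(paste0(">", sequences$esv_id, "\n", sequences$sequence), path)
  invisible(path)
}

#' Read a taxonomic hit table
#'
#' @param path TSV with columns `esv_id`, `lineage`, `pct_identity`
#'   (optionally `marker`).
#' @return A tibble.
#' @export
read_hits <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("esv_id", "lineage", "pct_identity")
  if (!all(need %in% names(x))) {
    stop("hit table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds an optional `ladder`, a `markers` block (one entry per
#' marker with `min_len`, `max_len` and optional `min_pcr_reads`,
#' `rel_abundance_floor`, `motu_identity`), an optional `exclusion` block
#' (`allowed_kingdoms`, `excluded_clades`), and optional scalars
#' `lca_tolerance`, `lineage_sep`, `seed`.
#'
#' @param path YAML path.
#' @return A list with elements `ladder`, `configs`, `policy`,
#'   `lca_tolerance`, `sep`, `seed`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  configs <- if (is.null(y$markers)) {
    default_marker_configs()
  } else {
    dplyr::bind_rows(lapply(names(y$markers), function(m) {
      e <- y$markers[[m]]
      tibble::tibble(
        marker = m, min_len = as.integer(e$min_len),
        max_len = as.integer(e$max_len),
        min_pcr_reads = as.integer(e$min_pcr_reads %||% 100L),
        rel_abundance_floor = e$rel_abundance_floor %||% 0.01,
        motu_identity = e$motu_identity %||% 0.98)
    }))
  }
  policy <- default_exclusion_policy()
  if (!is.null(y$exclusion)) {
    if (!is.null(y$exclusion$allowed_kingdoms)) {
      policy$allowed_kingdoms <- unlist(y$exclusion$allowed_kingdoms)
    }
    if (!is.null(y$exclusion$excluded_clades)) {
      policy$excluded_clades <- unlist(y$exclusion$excluded_clades)
    }
  }
  list(ladder = unlist(y$ladder %||% linnaean_ranks()),
       configs = check_marker_configs(configs),
       policy = policy,
       lca_tolerance = y$lca_tolerance %||% 1,
       sep = y$lineage_sep %||% ";",
       seed = as.integer(y$seed %||% 1L))
}
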