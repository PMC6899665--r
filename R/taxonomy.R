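#' The Linnaean rank ladder
#'
#' The fixed, ordered set of taxonomic ranks every lineage in the package is
#' aligned to, from most to least inclusive. Lineages may stop at any rank
#' (truncation), but never skip one: unknown intermediate ranks are filled
#' with deterministic placeholder tokens (see [parse_lineage()]).
#'
#' @return A character vector of rank names.
#' @export
#' @examples
#' linnaean_ranks()
linnaean_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Parse delimited lineage strings
#'
#' Splits lineage strings such as `"Animalia;Arthropoda;Insecta;Coleoptera"`
#' into ordered vectors of taxon names aligned to the rank ladder. Trailing
#' empty fields are ignored (the lineage is simply truncated); an empty field
#' *between* named ranks is a gap and is filled with a placeholder token
#' `unk_<rank>_<childname>` derived from the nearest named rank below it, so
#' that identical gaps always produce identical lineages. Gap filling emits a
#' warning.
#'
#' @param x Character vector of lineage strings.
#' @param sep Field separator, default `";"`.
#' @param ladder Rank ladder, default [linnaean_ranks()].
#' @return A list of character vectors, one per input string.
#' @seealso [format_lineage()], its inverse on valid lineages.
#' @export
#' @examples
#' parse_lineage("Animalia;Arthropoda;Insecta;Coleoptera")
parse_lineage <- function(x, sep = ";", ladder = linnaean_ranks()) {
  stopifnot(is.character(x))
  gap_filled <- FALSE
  out <- lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      stop("empty lineage string", call. = FALSE)
    }
    parts <- trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    while (length(parts) > 0 && !nzchar(parts[length(parts)])) {
      parts <- parts[-length(parts)]
    }
    if (length(parts) == 0) stop("empty lineage string", call. = FALSE)
    if (length(parts) > length(ladder)) {
      stop("lineage deeper than the rank ladder: ", s, call. = FALSE)
    }
    gaps <- which(!nzchar(parts))
    if (length(gaps) > 0) {
      gap_filled <<- TRUE
      for (i in gaps) {
        deeper <- parts[seq(i + 1L, length(parts))]
        child <- deeper[nzchar(deeper) & !startsWith(deeper, "unk_")][1]
        parts[i] <- paste0("unk_", ladder[i], "_", child)
      }
    }
    parts
  })
  if (gap_filled) {
    warning("gap-filled one or more lineages with placeholder tokens",
            call. = FALSE)
  }
  out
}

#' Format lineages back into delimited strings
#'
#' @param x A list of character vectors (as returned by [parse_lineage()]).
#' @param sep Field separator.
#' @return A character vector of lineage strings.
#' @export
format_lineage <- function(x, sep = ";") {
  if (!is.list(x)) x <- list(x)
  vapply(x, paste, character(1), collapse = sep)
}

#' Canonicalise lineage strings
#'
#' Parses and re-formats lineage strings, applying trailing-field trimming
#' and gap filling so that downstream string comparisons are exact.
#'
#' @inheritParams parse_lineage
#' @return A character vector of normalised lineage strings.
#' @export
normalize_lineage <- function(x, sep = ";", ladder = linnaean_ranks()) {
  format_lineage(parse_lineage(x, sep = sep, ladder = ladder), sep = sep)
}

#' Number of assigned ranks in a lineage
#'
#' @inheritParams parse_lineage
#' @return Integer vector of depths.
#' @export
lineage_depth <- function(x, sep = ";", ladder = linnaean_ranks()) {
  lengths(parse_lineage(x, sep = sep, ladder = ladder))
}

#' Deepest assigned rank of a lineage
#'
#' @inheritParams parse_lineage
#' @return Character vector of rank names.
#' @export
deepest_rank <- function(x, sep = ";", ladder = linnaean_ranks()) {
  ladder[lineage_depth(x, sep = sep, ladder = ladder)]
}

# prefix test on parsed lineages (character vectors); equality counts
is_prefix <- function(coarse, fine) {
  nc <- length(coarse)
  nc <= length(fine) && all(coarse == fine[seq_len(nc)])
}

#' Is one lineage an extension of another?
#'
#' `fine` extends `coarse` when every named rank of `coarse` matches the
#' corresponding rank of `fine` — i.e. `coarse` is a prefix of `fine`
#' (equality allowed). Placeholder tokens from gap filling match only
#' themselves. This is the compatibility relation the multi-marker merge
#' reasons over: a detection at order level extends to any detection of a
#' family, genus or species within that order.
#'
#' @param coarse,fine Character vectors of lineage strings (recycled to a
#'   common length).
#' @inheritParams parse_lineage
#' @return Logical vector.
#' @export
#' @examples
#' is_extension("Animalia;Arthropoda;Insecta;Coleoptera",
#'               "Animalia;Arthropoda;Insecta;Coleoptera;Chrysomelidae")
is_extension <- function(coarse, fine, sep = ";", ladder = linnaean_ranks()) {
  n <- max(length(coarse), length(fine))
  coarse <- rep_len(coarse, n)
  fine <- rep_len(fine, n)
  a <- parse_lineage(coarse, sep = sep, ladder = ladder)
  b <- parse_lineage(fine, sep = sep, ladder = ladder)
  mapply(is_prefix, a, b, USE.NAMES = FALSE)
}

#' Deepest rank at which two lineages agree
#'
#' @param a,b Lineage strings (recycled to a common length).
#' @inheritParams parse_lineage
#' @return Character vector of rank names; `NA` where the lineages already
#'   differ at the first rank.
#' @export
deepest_common_rank <- function(a, b, sep = ";", ladder = linnaean_ranks()) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  pa <- parse_lineage(a, sep = sep, ladder = ladder)
  pb <- parse_lineage(b, sep = sep, ladder = ladder)
  k <- mapply(function(x, y) {
    m <- min(length(x), length(y))
    if (m == 0L) return(0L)
    agree <- x[seq_len(m)] == y[seq_len(m)]
    if (!agree[1]) 0L else {
      d <- which(!agree)
      if (length(d) == 0L) m else d[1] - 1L
    }
  }, pa, pb, USE.NAMES = FALSE)
  ifelse(k == 0L, NA_character_, ladder[pmax(k, 1L)])
}

#' Truncate lineages at a given rank
#'
#' @param x Character vector of lineage strings.
#' @param rank A rank name from the ladder.
#' @inheritParams parse_lineage
#' @return Character vector of truncated lineage strings; `NA` where a
#'   lineage does not reach `rank`.
#' @export
truncate_lineage <- function(x, rank, sep = ";", ladder = linnaean_ranks()) {
  pos <- match(rank, ladder)
  if (is.na(pos)) stop("unknown rank: ", rank, call. = FALSE)
  p <- parse_lineage(x, sep = sep, ladder = ladder)
  vapply(p, function(v) {
    if (length(v) < pos) NA_character_ else paste(v[seq_len(pos)], collapse = sep)
  }, character(1))
}

# longest common prefix of a list of parsed lineages
common_prefix <- function(lins) {
  Reduce(function(a, b) {
    m <- min(length(a), length(b))
    if (m == 0L) return(character(0))
    agree <- a[seq_len(m)] == b[seq_len(m)]
    d <- which(!agree)
    k <- if (length(d) == 0L) m else d[1] - 1L
    a[seq_len(k)]
  }, lins)
}
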