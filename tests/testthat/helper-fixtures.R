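# shared fixtures, all built in code

COLEOPTERA <- "Animalia;Arthropoda;Insecta;Coleoptera"
CHRYSOMELIDAE <- paste0(COLEOPTERA, ";Chrysomelidae")
CHRYSO_SP <- paste0(CHRYSOMELIDAE, ";Oulema;Oulema melanopus")
CARABIDAE <- paste0(COLEOPTERA, ";Carabidae")

# one sample where a universal, a 16S and a COI marker see the same beetle
# at increasing resolution
congruent_example <- function() {
  tibble::tibble(
    sample_id = "s1",
    marker_id = c("18S", "IN16STK", "ZBJ"),
    lineage = c(COLEOPTERA, CHRYSOMELIDAE, CHRYSO_SP),
    motu = c(1L, 1L, NA),
    motu_label = c("Coleoptera 1", "Chrysomelidae 1", NA))
}

# same but the family-level detection is a Carabidae, incompatible with the
# Chrysomelidae species
incongruent_example <- function() {
  d <- congruent_example()
  d$lineage[2] <- CARABIDAE
  d$motu_label[2] <- "Carabidae 1"
  d
}

# random single-sample instance over a small shared name pool, heavy in
# prefix collisions; within-marker duplicates removed
random_instance <- function(seed, max_detections = 8, max_markers = 4) {
  set.seed(seed)
  ladder <- linnaean_ranks()
  rand_lineage <- function() {
    depth <- sample(2:7, 1, prob = c(1, 2, 3, 3, 3, 2))
    paste(vapply(seq_len(depth), function(r) {
      paste0(substr(ladder[r], 1, 1), sample(2, 1))
    }, character(1)), collapse = ";")
  }
  n <- sample(2:max_detections, 1)
  d <- tibble::tibble(
    sample_id = "s",
    marker_id = paste0("M", sample(max_markers, n, replace = TRUE)),
    lineage = vapply(seq_len(n), function(i) rand_lineage(), character(1)))
  d$motu <- ifelse(lineage_depth(d$lineage) < 7, sample(2, n, replace = TRUE),
                   NA_integer_)
  dplyr::distinct(d, marker_id, lineage, motu, .keep_all = TRUE)
}

# minimal two-ESV table: B abundant, A a one-off child of B
one_off_pair <- function(a_reads = 5, b_reads = 100, a_alone = FALSE) {
  b_seq <- strrep("ACGT", 25)          # 100 bp
  a_seq <- paste0("T", substr(b_seq, 2, 100))
  rows <- tibble::tibble(
    marker = "ZBJ",
    esv_id = c("B", "B", "A"),
    sequence = c(b_seq, b_seq, a_seq),
    sample_id = c("p1", "p2", "p1"),
    reads = c(b_reads, b_reads, a_reads))
  if (a_alone) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      marker = "ZBJ", esv_id = "A", sequence = a_seq,
      sample_id = "p3", reads = a_reads))
  }
  rows
}

zbj_cfg <- function() {
  tibble::tibble(marker = "ZBJ", min_len = 30L, max_len = 200L,
                 min_pcr_reads = 100L, rel_abundance_floor = 0.01,
                 motu_identity = 0.98)
}
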