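make_esv <- function(esv_id, sequence, sample_id, reads, marker = "ZBJ") {
  tibble::tibble(marker = marker, esv_id = esv_id, sequence = sequence,
                 sample_id = sample_id, reads = reads)
}

test_that("length filter keeps exactly the closed window", {
  cfgs <- default_marker_configs()
  x <- dplyr::bind_rows(
    make_esv("in", strrep("A", 120), "s1", 500, marker = "18S"),
    make_esv("at_min", strrep("A", 94), "s1", 500, marker = "18S"),
    make_esv("short", strrep("A", 93), "s1", 500, marker = "18S"),
    make_esv("zbj_out", strrep("A", 150), "s1", 500, marker = "ZBJ"))
  out <- filter_length(x, cfgs)
  expect_setequal(out$esv_id, c("in", "at_min"))
  log <- pipeline_log(out)
  expect_setequal(log$record_id, c("short", "zbj_out"))
  expect_true(all(log$action == "removed_esv"))
})

test_that("one-off denoising removes co-occurring low-count children", {
  out <- denoise_one_off(one_off_pair())
  expect_setequal(unique(out$esv_id), "B")
  expect_equal(pipeline_log(out)$record_id, "A")
})

test_that("denoising spares distant, independent, or tied ESVs", {
  # three edits apart: both retained
  far <- make_esv(c("A", "B"), c(strrep("ACGT", 25),
                                 paste0("TTT", substr(strrep("ACGT", 25), 4, 100))),
                  c("s1", "s1"), c(5, 100))
  expect_setequal(denoise_one_off(far)$esv_id, c("A", "B"))
  # child occurs alone in one PCR: retained
  alone <- denoise_one_off(one_off_pair(a_alone = TRUE))
  expect_true("A" %in% alone$esv_id)
  # equal totals: strict inequality keeps both
  tied <- denoise_one_off(one_off_pair(a_reads = 200, b_reads = 100))
  expect_setequal(unique(tied$esv_id), c("A", "B"))
})

test_that("denoising never removes a marker's highest-count ESV", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 6
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    }, character(1))
    x <- tidyr::expand_grid(i = seq_len(n), sample_id = c("s1", "s2", "s3")) |>
      dplyr::mutate(marker = "ZBJ", esv_id = paste0("e", i),
                    sequence = seqs[i],
                    reads = sample(0:500, dplyr::n(), replace = TRUE)) |>
      dplyr::filter(reads > 0) |>
      dplyr::select(marker, esv_id, sequence, sample_id, reads)
    top <- x |>
      dplyr::group_by(esv_id) |>
      dplyr::summarise(total = sum(reads)) |>
      dplyr::slice_max(total, n = 1)
    out <- denoise_one_off(x)
    expect_true(all(top$esv_id %in% out$esv_id))
    # idempotence: a second pass removes nothing
    expect_identical(nrow(denoise_one_off(out)), nrow(out))
  }
})

test_that("PCR products under the read threshold fail and are logged", {
  x <- dplyr::bind_rows(
    make_esv("e1", strrep("A", 160), "ok", 100),
    make_esv("e1", strrep("A", 160), "bad", 99))
  out <- drop_failed_pcrs(x, zbj_cfg())
  expect_equal(unique(out$sample_id), "ok")
  log <- pipeline_log(out)
  expect_equal(log$record_id, "bad")
  expect_equal(log$action, "removed_pcr")
  # empty table passes through
  empty <- drop_failed_pcrs(x[0, ], zbj_cfg())
  expect_equal(nrow(empty), 0L)
})

test_that("relative-abundance filter zeroes strictly-below-floor counts", {
  x <- dplyr::bind_rows(
    make_esv("big", strrep("A", 160), "s1", 9801),
    make_esv("at_floor", strrep("C", 160), "s1", 100),
    make_esv("below", strrep("G", 160), "s1", 99))
  out <- relative_abundance_filter(x, zbj_cfg())   # total 10,000
  expect_setequal(out$esv_id, c("big", "at_floor"))
  # a single-ESV PCR is always kept (100% of its own total)
  single <- relative_abundance_filter(
    make_esv("only", strrep("A", 160), "s1", 3), zbj_cfg())
  expect_equal(single$esv_id, "only")
})

test_that("the relative-abundance filter refuses to run twice", {
  x <- make_esv(c("a", "b"), c(strrep("A", 160), strrep("C", 160)),
                "s1", c(1000, 5))
  once <- relative_abundance_filter(x, zbj_cfg())
  expect_error(relative_abundance_filter(once, zbj_cfg()), "already")
})

test_that("length, denoise and PCR filters are idempotent", {
  sim <- simulate_esv_experiment(seed = 11)
  cfgs <- default_marker_configs()
  a <- filter_length(sim$esv, cfgs)
  expect_equal(filter_length(a, cfgs), a, ignore_attr = TRUE)
  b <- drop_failed_pcrs(a, cfgs)
  expect_equal(drop_failed_pcrs(b, cfgs), b, ignore_attr = TRUE)
})

test_that("most-inclusive-rank assignment backs off to agreement", {
  fam <- "Animalia;Arthropoda;Insecta;Coleoptera;Carabidae"
  hits <- tibble::tibble(
    esv_id = c("e1", "e1", "e2", "e3", "e3"),
    lineage = c(paste0(fam, ";GenusA;Species a"),
                paste0(fam, ";GenusB;Species b"),
                CHRYSO_SP,
                paste0(fam, ";GenusA;Species a"),
                paste0(fam, ";GenusB;Species b")),
    pct_identity = c(99, 99, 100, 99, 90))
  out <- assign_lca(hits, tolerance = 1)
  # two species of different genera, same family, both 99% -> family level
  expect_equal(out$lineage[out$esv_id == "e1"], fam)
  # single hit at 100% -> full lineage
  expect_equal(out$lineage[out$esv_id == "e2"], CHRYSO_SP)
  # 90% hit outside the 1-point window is ignored -> full 99% lineage
  expect_equal(out$lineage[out$esv_id == "e3"],
               paste0(fam, ";GenusA;Species a"))
})

test_that("ESVs whose near-best hits disagree at kingdom are flagged", {
  hits <- tibble::tibble(
    esv_id = "e1",
    lineage = c("Plantae;Streptophyta", "Animalia;Arthropoda"),
    pct_identity = c(99, 99))
  out <- assign_lca(hits)
  expect_true(is.na(out$lineage))
  expect_equal(out$depth, 0L)
})

test_that("MOTU clustering is single-linkage at the identity threshold", {
  base <- strrep("ACGTT", 40)  # 200 bp
  mut <- function(s, positions) {
    for (p in positions) {
      substr(s, p, p) <- chartr("ACGT", "CAGT", substr(s, p, p))
    }
    s
  }
  a <- base
  b <- mut(base, c(1, 11, 21))            # 98.5% to a
  c_ <- mut(base, c(1, 11, 21, 31, 41, 51))  # 98.5% to b, 97% to a
  esvs <- tibble::tibble(
    marker = "ZBJ", esv_id = c("a", "b", "c"),
    sequence = c(a, b, c_), lineage = CARABIDAE,
    total_reads = c(300, 200, 100))
  out <- cluster_motus(esvs, identity = 0.98)
  expect_equal(dplyr::n_distinct(out$motu), 1L)   # chain merges via b
  expect_true(all(out$motu_label == "Carabidae 1"))

  # two sequences at 95% stay distinct, numbered by read count
  far <- tibble::tibble(
    marker = "ZBJ", esv_id = c("x", "y"),
    sequence = c(strrep("A", 100),
                 paste0(strrep("C", 5), strrep("A", 95))),
    lineage = CARABIDAE, total_reads = c(10, 500))
  out2 <- cluster_motus(far, identity = 0.98)
  expect_equal(out2$motu[out2$esv_id == "y"], 1L)
  expect_equal(out2$motu[out2$esv_id == "x"], 2L)

  # identical sequences cluster together; species-level ESVs pass through
  same <- tibble::tibble(
    marker = "ZBJ", esv_id = c("p", "q", "sp"),
    sequence = strrep("ACGT", 25),
    lineage = c(CARABIDAE, CARABIDAE, CHRYSO_SP),
    total_reads = c(5, 5, 5))
  out3 <- cluster_motus(same, identity = 0.98)
  expect_equal(out3$motu[out3$esv_id == "p"], out3$motu[out3$esv_id == "q"])
  expect_true(is.na(out3$motu[out3$esv_id == "sp"]))
})

test_that("non-target taxa are excluded with logged reasons", {
  det <- tibble::tibble(
    sample_id = "s1", marker_id = "ZBJ",
    lineage = c("Animalia;Nematoda;Chromadorea",
                "Animalia;Arthropoda;Insecta;Coleoptera;Tenebrionidae",
                CARABIDAE,
                "Fungi;Ascomycota",
                "Plantae;Bryophyta;Bryopsida"))
  out <- exclude_taxa(det)
  expect_equal(out$lineage, CARABIDAE)
  log <- pipeline_log(out)
  expect_equal(nrow(log), 4L)
  expect_true(any(grepl("Nematoda", log$reason)))
  expect_true(any(log$reason == "kingdom not allowed"))
})

test_that("detections are presence/absence per sample, marker and taxon", {
  x <- dplyr::bind_rows(
    make_esv("e1", strrep("A", 160), c("s1", "s2", "s3"), c(10, 20, 30)),
    make_esv("e2", strrep("C", 160), "s1", 40))
  taxa <- tibble::tibble(
    marker = "ZBJ", esv_id = c("e1", "e2"),
    lineage = CARABIDAE, motu = 1L, motu_label = "Carabidae 1")
  out <- to_detections(x, taxa)
  # two ESVs of one MOTU in s1 collapse; presence in 3 samples = 3 rows
  expect_equal(nrow(out), 3L)
  expect_setequal(out$sample_id, c("s1", "s2", "s3"))
})

test_that("the full cascade recovers the planted truth exactly", {
  sim <- simulate_esv_experiment(seed = 5, n_esvs = 10, error_rate = 0.5,
                                 n_failed_pcrs = 1)
  res <- run_esv_pipeline(sim$esv, sim$hits)
  retained <- sort(unique(res$table$esv_id))
  expect_identical(retained, sort(sim$truth$true_esvs))
  failed_logged <- res$log$record_id[res$log$stage == "pcr_failure"]
  expect_setequal(failed_logged, sim$truth$failed_pcrs)
  # with no planted errors the table passes through unharmed
  clean <- simulate_esv_experiment(seed = 6, error_rate = 0,
                                   n_failed_pcrs = 0)
  res2 <- run_esv_pipeline(clean$esv, clean$hits)
  expect_identical(sort(unique(res2$table$esv_id)),
                   sort(clean$truth$true_esvs))
})
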