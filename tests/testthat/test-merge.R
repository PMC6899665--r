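test_that("congruent cross-marker detections collapse to one resolved taxon", {
  out <- merge_sample(congruent_example())
  expect_equal(nrow(out), 1L)
  expect_equal(out$representative_lineage, CHRYSO_SP)
  expect_equal(out$representative_rank, "species")
  expect_equal(out$n_markers, 3L)
  expect_equal(out$member_markers, "ZBJ,IN16STK,18S")
})

test_that("incongruent family detections remain separate taxa", {
  out <- merge_sample(incongruent_example())
  expect_equal(nrow(out), 2L)
  expect_setequal(out$representative_lineage, c(CHRYSO_SP, CARABIDAE))
  # the order-level detection is absorbed by one group only (partition)
  expect_equal(sum(out$n_members), 3L)
})

test_that("single-marker samples and edge cases pass through unchanged", {
  d <- tibble::tibble(sample_id = "s1", marker_id = "ZBJ",
                      lineage = c(CARABIDAE, CHRYSOMELIDAE),
                      motu = c(1L, 1L))
  expect_equal(nrow(merge_sample(d)), 2L)
  expect_equal(nrow(merge_sample(d[1, ])), 1L)
  fit <- merge_samples(d[0, ])
  expect_equal(nrow(tidy(fit)), 0L)
})

test_that("same-marker MOTUs can never co-group", {
  d <- tibble::tibble(
    sample_id = "s1",
    marker_id = c("18S", "18S", "ZBJ"),
    lineage = c(COLEOPTERA, COLEOPTERA, CHRYSO_SP),
    motu = c(1L, 2L, NA))
  out <- merge_sample(d)
  expect_equal(nrow(out), 2L)
  expect_equal(merge_oracle(d), 2L)
})

test_that("equal lineages from different markers merge into one group", {
  d <- tibble::tibble(sample_id = "s1",
                      marker_id = c("IN16STK", "ZBJ"),
                      lineage = CARABIDAE, motu = c(2L, 5L))
  out <- merge_sample(d)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_markers, 2L)
})

test_that("MOTU identities are merged per sample, never across samples", {
  d <- dplyr::bind_rows(
    tibble::tibble(sample_id = "s1", marker_id = c("18S", "IN16STK"),
                   lineage = c(COLEOPTERA, CARABIDAE), motu = c(1L, 1L)),
    tibble::tibble(sample_id = "s2", marker_id = c("18S", "IN16STK"),
                   lineage = c(COLEOPTERA, CHRYSOMELIDAE), motu = c(1L, 1L)))
  out <- tidy(merge_samples(d))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$representative_lineage[out$sample_id == "s1"], CARABIDAE)
  expect_setequal(out$representative_lineage[out$sample_id == "s2"],
                  CHRYSOMELIDAE)
})

test_that("within-marker duplicate taxa are rejected", {
  d <- tibble::tibble(sample_id = "s1", marker_id = "ZBJ",
                      lineage = CARABIDAE, motu = c(1L, 1L))
  expect_error(merge_samples(d), "duplicate")
})

test_that("the merge is invariant to input row order", {
  set.seed(99)
  for (seed in 1:10) {
    d <- random_instance(seed)
    ref <- merge_sample(d)
    perm <- merge_sample(d[sample.int(nrow(d)), ])
    expect_identical(ref, perm)
  }
})

test_that("group counts respect the structural bounds and chain property", {
  for (seed in 101:130) {
    d <- random_instance(seed)
    out <- merge_sample(d)
    expect_lte(nrow(out), nrow(d))
    expect_gte(nrow(out), max(table(d$marker_id)))
    # every member lineage is a prefix of its representative
    for (i in seq_len(nrow(out))) {
      members <- strsplit(out$member_lineages[i], "|", fixed = TRUE)[[1]]
      expect_true(all(is_extension(members, out$representative_lineage[i])))
    }
    # groups partition the detections
    expect_equal(sum(out$n_members), nrow(d))
  }
})

test_that("the exact merge matches the exhaustive oracle", {
  for (seed in 201:350) {
    d <- random_instance(seed)
    expect_equal(nrow(merge_sample(d)), merge_oracle(d),
                 info = paste("seed", seed))
  }
})

test_that("the oracle handles the printed and degenerate cases", {
  expect_equal(merge_oracle(congruent_example()), 1L)
  expect_equal(merge_oracle(incongruent_example()), 2L)
  k <- 5
  d <- tibble::tibble(sample_id = "s", marker_id = paste0("M", 1:k),
                      lineage = CHRYSO_SP)
  expect_equal(merge_oracle(d), 1L)
  big <- tibble::tibble(sample_id = "s", marker_id = paste0("M", 1:13),
                        lineage = CHRYSO_SP)
  expect_error(merge_oracle(big), "too large")
})

test_that("occurrence reduction accounts for detections and groups", {
  # no cross-marker redundancy: before == after
  d <- tibble::tibble(sample_id = "s1", marker_id = "ZBJ",
                      lineage = c(CARABIDAE, CHRYSOMELIDAE), motu = 1:2)
  fit <- merge_samples(d)
  red <- occurrence_reduction(fit)
  expect_equal(red$n_before[red$kingdom == "total"], 2L)
  expect_equal(red$n_after[red$kingdom == "total"], 2L)
  # full duplication across 2 markers: after == before / 2
  d2 <- tidyr::expand_grid(marker_id = c("A", "B"),
                           lineage = c(CARABIDAE, CHRYSO_SP)) |>
    dplyr::mutate(sample_id = "s1",
                  motu = ifelse(lineage == CARABIDAE, 1L, NA_integer_))
  fit2 <- merge_samples(d2)
  red2 <- occurrence_reduction(fit2)
  expect_equal(red2$n_before[red2$kingdom == "total"], 4L)
  expect_equal(red2$n_after[red2$kingdom == "total"], 2L)
  # kingdom split is taken from the representative
  expect_equal(red2$kingdom, c("Animalia", "total"))
})
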