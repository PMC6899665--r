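---
title: "Merging multi-marker metabarcoding detections into a consensus diet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging multi-marker metabarcoding detections into a consensus diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietmerge)
library(dplyr)
```

## The problem

Describing the diet of a trophic generalist (an insectivorous–frugivorous
bird, say) from faecal DNA typically requires several PCR markers: a
universal eukaryote fragment, a plant-specific fragment, and one or more
arthropod fragments. The markers overlap in taxonomic scope but differ in
two ways that matter: *affinity* (a marker may consistently miss whole
clades — the classic example being ZBJ-type COI primers failing on
Formicidae) and *resolution* (one marker resolves an item to order, another
to species). Summing detections across markers therefore double-counts
prey, while any single marker under-counts it. `dietmerge` implements a
per-sample integration that collapses cross-marker redundancy while keeping
the most resolved identification of each item, together with the upstream
ESV-level cleaning that such studies use and the dietary descriptors used
to compare methods.

## Lineages and compatibility

All taxonomy is carried as delimited lineage strings aligned to the fixed
seven-rank Linnaean ladder (`kingdom;phylum;class;order;family;genus;species`).
A lineage may stop at any rank; it may never skip one — internal gaps are
filled with placeholder tokens (`unk_<rank>_<childname>`) that are
deterministic functions of the nearest named child, so identical input rows
always produce identical lineages, and a placeholder matches nothing but
itself. Detections not resolved to species carry a marker-local MOTU label
("Carabidae 1"). Two identifications are *compatible* when one lineage is a
prefix of the other (`is_extension()`): a `Coleoptera` detection is
compatible with a `Chrysomelidae` species, but `Carabidae` is not.

We deliberately represent intermediate ranks the source data skips by
truncation rather than a sparse ladder: the merge logic only ever reasons
over order/family/genus/species, and a dense prefix representation makes
the compatibility test a plain vector comparison. Rank-vocabulary
normalisation between reference databases (BOLD vs NCBI style lineages) is
the caller's responsibility.

## The ESV cleaning cascade

Raw per-marker ESV count tables are cleaned in a fixed order, and the
runner enforces it:

1. **Fragment-length window** per marker (closed interval; defaults
   94–153 bp for 18S, 72–119 for IN16STK, 155–159 for ZBJ, 30–93 for trnL).
2. **One-off denoising**: an ESV is removed when another ESV exists at unit
   edit distance with a strictly higher total read count that it never
   occurs without. We use unit-cost Levenshtein distance (substitutions
   *and* length-changing indels) because several of these markers — trnL in
   particular — are length-variable, so a Hamming-style test would miss
   single-indel errors. The rule is applied in a single pass against the
   original counts, with no cascading: the removal set is decided before
   anything is removed, which makes the step idempotent and guarantees the
   highest-count ESV of a marker always survives.
3. **PCR failure**: PCR products totalling fewer than 100 reads after
   denoising are dropped and logged as failed.
4. **Relative abundance**: within each remaining PCR product, counts
   strictly below 1% of that PCR's total are zeroed. The totals are taken
   *after* failed-PCR removal; because this step redefines its own
   denominator it is not idempotent, and the function refuses to run twice
   on the same table.
5. **Most-inclusive-rank assignment** (`assign_lca()`): all hits within a
   tolerance (default 1 identity percentage point, exposed as a parameter —
   "similar identity levels" has no canonical number) of the ESV's best hit
   are retained and the assignment is truncated at the deepest rank on
   which they all agree.
6. **MOTU clustering** (`cluster_motus()`): ESVs sharing a marker and an
   above-species lineage are clustered by single-linkage at 98% pairwise
   identity (edit distance over the longer length). This replaces the
   visual neighbour-joining delimitation such studies often do by hand; it
   is an approximation, and per-marker MOTU counts may differ slightly
   from a manual delimitation of the same data. Cluster numbering is by
   decreasing total read count with ties broken by ESV id, so labels are
   deterministic.
7. **Exclusion**: detections outside the allowed kingdoms (Plantae,
   Animalia) or under an excluded clade prefix (non-vascular plants, birds,
   mammals, Nematoda, Tenebrionidae by default — the last as probable bait
   contamination) are removed with a logged reason.

Every record-level action lands in a machine-readable provenance log
(`pipeline_log()`), so tests and users can assert *why* a record
disappeared. Negative controls are processed like any other sample and
reported — they are never used to subtract counts.

## The merge model

Within one sample, let each detection be a pair (marker, taxon label). We
formalise "the same ingested item seen by several markers" as a **group**:
a set of detections with at most one member per marker whose lineages form
a chain under prefix extension. The merged diet of the sample is a
partition of its detections into the **minimum number of groups** — the
conservative choice, since every extra group claims an extra prey item.
Each group's representative is its deepest member; the sample's taxon
richness is its group count.

The minimum-cardinality objective is our formalisation of the
merge-the-compatible / split-the-incompatible behaviour in the two
canonical cases:

* `18S: Coleoptera` + `16S: Chrysomelidae` + `COI: Chrysomelidae species`
  → one group, represented by the species;
* `18S: Coleoptera` + `16S: Carabidae` + `COI: Chrysomelidae species`
  → two groups (the Carabidae; the Chrysomelidae species), the order-level
  detection being absorbed by exactly one of them (partition semantics —
  duplicating it into both would inflate occurrence counts).

The solver is an exact branch-and-bound over detections sorted by
decreasing lineage depth: a detection can join an existing group if its
marker is new to that group and its lineage is a prefix of the group's
shallowest member, or open a new group; search is pruned when the running
group count exceeds the best found. Per-sample instances are small (of the
order of ten detections), so exact search costs microseconds and we did
not implement a greedy fast path. Ties among minimum partitions are broken
deterministically — maximise the summed depth of representatives, then
take the lexicographically smallest sorted representative list — because
the underlying biology provides no reason to prefer one equally-deep
absorption over another; which equally sized group absorbs a coarse
detection does not change any reported count. An independent exhaustive
oracle (`merge_oracle()`, plain enumeration of valid partitions with a
pairwise chain test) verifies the solver on thousands of random instances
in the test suite.

Groups are never formed across samples: two markers' MOTUs may merge in
one sample and not in another, and with label identity unverifiable across
PCRs the per-sample scope is the conservative reading.

## Dietary descriptors

* `frequency_of_occurrence()` — per taxon (or per rank truncation), the
  fraction of samples containing it; denominators are per method, and can
  be supplied explicitly for methods that analysed samples in which they
  detected nothing.
* `richness_per_sample()` / `richness_summary()` — species-level taxa plus
  higher-rank MOTUs per sample; for a merged sample this equals its group
  count. Standard error is sd/sqrt(n).
* `czekanowski()` — niche overlap, `1 − ½Σ|p_i − q_i|`. By default
  profiles are normalised to proportional utilisation
  (`p_i = FOO_i / ΣFOO`), the convention of the null-model ecology
  literature; `normalize = FALSE` gives the raw-FOO variant, since either
  reading is defensible and published descriptions are often ambiguous on
  the point.
* `resolution_profile()` — distinct taxa and occurrences per deepest
  assigned rank.

## The simulators

`simulate_detections()` generates a full multi-marker study with known
truth. Its defaults *are* the study conditions the package is validated
under: 115 faecal samples; a panel of 18S (both kingdoms, coarse, modest
detection), trnL (plants, high detection and resolution), IN16STK and ZBJ
(animals, the latter strongly biased but finely resolving); mean ingested
items per sample 5.7 plants and 10.2 animals. Detection probabilities and
resolution distributions were calibrated once from the kind of per-marker
richness ratios and genus/species shares such multi-marker studies report
(e.g. a universal 18S recovering roughly a third of the animal items that
the full panel recovers, a plant marker recovering ~90% of plant items and
resolving half of them to genus or species), and each marker is blind to a
fixed fraction of orders, emulating taxon-level primer bias rather than
mere random dropout. Under these defaults a run produces on the order of
2,200 occurrences merging down to ~1,500 taxa (about 30% cross-marker
redundancy) — the scale a four-marker generalist-diet study reports.

Two constructions make the truth table exact rather than approximate:
items within a sample are drawn from *distinct orders* (so no two distinct
items can ever be prefix-compatible and over-merge), and a marker reports
an item at order level or deeper (never above). The expected merged count
then equals, provably, the number of items detected by at least one
marker. This is also the generator's main departure from real data, where
congeneric prey co-occur in one sample and can be legitimately
over-merged; passing the truth-recovery tests therefore demonstrates
correctness of the algorithm under the model's assumptions, not that real
co-occurring congeners are never collapsed (the method is explicitly
conservative there).

`simulate_esv_experiment()` plants a known ESV truth: true sequences kept
at pairwise edit distance ≥ 3, one-substitution error children at ~0.3% of
their parent's PCR totals occurring only alongside their parents, counts
drawn high enough (≥ 800 reads against PCR totals bounded below 80,000)
that no true ESV can fall under the 1% floor, plus optional PCR products
forced under the 100-read failure threshold. The cascade must recover the
true set exactly — zero false removals, zero surviving errors — and the
suite asserts exactly that.

All randomness flows from a single integer seed; equal seeds give
byte-identical outputs.

## Numerical and degenerate-input choices

* All count thresholds are strict as specified: a PCR with exactly 100
  reads survives, an ESV at exactly 1% survives, equal-total one-off pairs
  are both retained.
* Empty tables pass through every filter; an empty detection set merges to
  an empty partition; `czekanowski()` errors on an all-zero profile rather
  than returning a conventional value.
* String ordering uses radix (C-locale) sorting throughout, so results do
  not depend on the session locale.
* Problem sizes in the shipped tests — 1,000 random oracle-equivalence
  instances of ≤ 8 detections, 115-sample simulated studies, 12-ESV
  planted experiments — were chosen as the smallest sizes at which the
  properties are convincingly exercised.

## Known limitations

* Identity-threshold single-linkage MOTUs are an automated approximation
  of manual tree-based delimitation.
* Secondary ingestion (prey-of-prey DNA) is a property of the data, not
  corrected algorithmically; merged taxa lists inherit it.
* No across-sample MOTU reconciliation, no read-count-weighted merging,
  and no probabilistic assignment of coarse detections — a coarse
  detection joins exactly one compatible group.
* Statistical comparisons beyond the descriptors here (GLMMs, multivariate
  GLMs) are out of scope; the tidy per-sample tables are designed to feed
  straight into `lme4`/`mvabund`-style tooling.
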