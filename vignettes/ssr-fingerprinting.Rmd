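---
title: "SSR fingerprinting and cultivar identification diagrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR fingerprinting and cultivar identification diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrCID)
```

## The problem

Clonal crop cultivars are propagated vegetatively, so every plant of a
cultivar carries the same genome and a single multilocus genotype
fingerprints the variety. Microsatellite (SSR) markers with long core
motifs (3–6 bp repeat units) are the assay of choice: co-dominant, highly
polymorphic, and — because neighbouring alleles differ by a full repeat
unit — easy to score reliably on capillary electrophoresis.

This package covers the analysis side of such a fingerprinting study:
quantifying the discriminating power of markers, choosing a small core
panel, summarising genetic relationships, and organising the panel into a
*cultivar identification diagram* (CID) that identifies a sample with as
few assays as possible. The packaged case study is a panel of 66 elite
Chinese clonal tea (*Camellia sinensis*) cultivars screened with 33
long-core-motif SSR markers, of which six were retained as the core set
(`?tea_fixtures`).

## Data model

A `genotype_table` is a cultivars × markers matrix of genotype calls plus
cultivar metadata. Each call is the unordered multiset of two or three
allele sizes in base pairs (`"268/292"`, `"171/177/183"`); calls are
canonicalized to ascending order on entry, so comparison is multiset
equality and `"292/268"` equals `"268/292"`. Tea is predominantly diploid
with rare triploid cultivars, and the case-study table indeed contains
three-allele calls for two of the 66 cultivars; the data model therefore
admits exactly 2 or 3 alleles per call. A missing or malformed cell is an
*error*, not an `NA` state: fingerprinting tables are small and complete,
and a silent missing-data policy would let transcription mistakes
propagate into identification results.

## Marker statistics

For a locus with allele frequencies $p_i$, `summarize_markers()` reports:

* **MAF** — the major (most frequent) allele frequency;
* **NA, NG** — the numbers of distinct alleles and of distinct genotypes;
* **Ho** — observed heterozygosity, the fraction of individuals with at
  least two distinct alleles in their call;
* **PIC** — polymorphism information content,
  $1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ (the classical
  Botstein-style form used by PowerMarker-type software; several PIC
  conventions exist and this is the one under which the case study's
  published values are internally consistent);
* **PID** — probability of identity,
  $2\bigl(\sum_i p_i^2\bigr)^2 - \sum_i p_i^4$, the probability that two
  random individuals of a Hardy–Weinberg population share a genotype at
  the locus. The package's test suite checks this closed form against an
  independent brute-force enumeration of all genotype pairs.

Allele frequencies count every allele copy of every call — two per diploid
and three per triploid call — so the denominator is the number of allele
observations. This is the only counting rule that uses the complete data
in a mixed-ploidy table; it treats a triploid call simply as three
observed alleles, with no meiotic model attached.

For a panel of independently segregating loci, the probability that two
random individuals match everywhere is the product of per-locus PIDs
(`combined_pid()`). On the published statistics of the tea study's core
panel this gives $2.22 \times 10^{-5}$, and $1.42 \times 10^{-32}$ over
all 33 markers.

### A known internal inconsistency of the case study

Recomputing statistics from the packaged 66 × 6 genotype table does not
reproduce every published per-locus value to the third decimal (e.g.
TM442: published MAF 0.523 and Ho 0.485, direct counts 0.530 and 0.500).
The published table was presumably derived from a scoring run not fully
recoverable from the printed genotypes. The package keeps both sources and
makes the difference visible through `compare_marker_stats()` rather than
silently preferring either; published-value checks in the test suite use
the published statistics table as *input* (products, averages, selection),
and only structural counts (NA, NG, genotype classes) are asserted from
the genotype table itself. Relatedly, the published panel-average PID is
0.198 while the mean of the 33 published per-locus values is 0.192; the
averaging input behind the printed 0.198 is unknown, so the package treats
0.198 as a conventional threshold default, not as a recomputable quantity.

## Core-panel selection

`select_core_markers()` applies the four panel-design criteria of the case
study: PID < 0.198, PIC > 0.5, at most 5 alleles and at most 10 genotypes
per marker. The PID/PIC bounds are strict and the count bounds inclusive,
mirroring the criteria's wording; the distinction matters at the
boundaries (a marker with PID 0.199 and one with 11 genotypes are both
rejected). The default `pid_max = 0.198` is the published panel average —
deliberately *not* a recomputed mean, which (0.192) would wrongly exclude
the top-ranked marker; users may pass `panel_mean_pid()` of their own
table explicitly. Selected markers are returned in descending PID order
with ties broken alphabetically, the order in which the diagram consumes
them.

## Genetic distances and UPGMA

Published fingerprinting studies typically report a "Nei's genetic
distance" UPGMA tree without naming the exact variant or how individuals
(rather than populations) enter the formula. The package makes one
concrete, documented choice: each cultivar is represented by its
within-individual allele shares (1/2, 1/3 or 1 per allele), and the
default metric is Nei's standard distance with shares pooled across loci,
$D = -\ln\bigl(J_{xy} / \sqrt{J_x J_y}\bigr)$. An allele-sharing distance
($1 -$ mean per-locus shared proportion) is available as an alternative;
it is bounded by 1 where the standard distance diverges for pairs sharing
no alleles. Because the published variant is unknowable, no equivalence
with the study's five-cluster tree partition is claimed; the 0.25-height
cut is provided as a demonstration (`cut_tree(upgma(nei_dist(gt)), 0.25)`)
and the tree outputs are validated structurally (ultrametricity, label
partition, Newick round-trip) instead. UPGMA itself is average-linkage
`stats::hclust()`, whose deterministic merge order makes every tree output
byte-reproducible; Newick export follows the ultrametric convention of
half-height branches.

## The identification diagram

`cid()` fits the decision tree: the first marker of the order partitions
all cultivars by genotype; every group with more than one cultivar is
split by the next marker in the *fixed global order*; a cultivar whose
genotype prefix is unique becomes a resolved singleton leaf at that depth.
Two design points deserve comment:

* **Fixed order, highest PID first.** Re-selecting the locally most
  informative marker per group would shorten some paths, but a fixed
  order matching the published construction keeps the diagram readable as
  a laboratory protocol: every sample starts with the same assay, and the
  case study's own worked identifications use the same second marker
  across groups. Counter-intuitively the *descending* PID order starts
  with the least discriminating core marker; the package implements the
  convention as published rather than optimising it. Any order can be
  passed explicitly via `markers`.
* **Unresolved groups are first-class.** Cultivars sharing genotypes at
  every marker end in a flagged multi-cultivar leaf rather than an error
  — the actionable signal that the panel needs another marker. On the tea
  panel no such group exists: all 66 cultivars resolve, 2 of them after a
  single assay and most within 3–4.

`predict()` walks a sample down the tree lazily (only path markers are
needed) and returns `unique`, `ambiguous` (with candidates) or `no_match`
with the consumed path. `add_cultivar()` inserts a new release
incrementally — a collision with a resolved leaf re-splits it by the next
unused markers — and is tested to agree exactly with refitting on the
extended table. Serializations (JSON for persistence, Graphviz DOT and an
indented text form for display) order branches by genotype string, so
repeated runs produce identical bytes.

## The synthetic-population generator

`simulate_genotypes()` draws individuals from specified per-locus allele
frequencies under Hardy–Weinberg random mating, with loci independent and
an optional triploid fraction (triploids draw three independent alleles —
no meiotic model, matching how triploid calls are treated throughout).
It emulates exactly the statistical structure the analytic machinery
assumes, which is what makes it a useful oracle: sampled spectra must
recover the specified frequencies, empirical genotype-match rates must
agree with the analytic PID (checked at $n = 20{,}000$ within four
standard errors, for uniform 2-, 4- and 8-allele and skewed 0.7/0.2/0.1
spectra), and multi-locus match rates must follow the product law. What it
deliberately does **not** emulate: linkage between loci, genotyping error,
null alleles, stutter, or population structure. Passing tests therefore
validate the mathematics and the code paths, not robustness of the method
to real-world scoring artefacts.

## Numerical and degenerate-input choices

* Frequencies and statistics are computed in double precision; values are
  rounded only for display (3 significant digits in printed summaries).
* A monomorphic locus is legal everywhere: PID 1, PIC 0, single genotype
  class, zero distances.
* An empty marker selection is legal and returned with a warning; an
  empty genotype table is an error.
* Genotype equality is exact integer multiset equality — no fragment-size
  binning tolerance; allele sizes are taken as scored.
* Tree tie-breaks are `hclust`'s deterministic merge order; CID branch
  order is lexicographic in the genotype string.

## Problem sizes

The shipped analyses are small by design: the case study is 66 × 6
(pipeline and diagram fit in well under a second), Monte-Carlo validation
of the PID formula uses populations of 10,000–20,000 individuals at 1–3
loci, and the diagram invariants are exercised on 100 simulated tables of
4–12 individuals. All results in this vignette and the README are computed
by the package at run time.

## Limitations

* The PIC/PID formulas assume Hardy–Weinberg proportions when interpreted
  as match probabilities; for clonal germplasm they are used, as in the
  source literature, as conventional informativeness summaries.
* PID is a diploid-genotype quantity; triploid calls contribute to allele
  frequencies but no triploid match model is defined.
* The Nei-distance variant applied to individuals is a documented package
  choice, not a reconstruction of any specific legacy implementation.
* The diagram identifies only cultivars it was built from; genotyping
  error is not modelled (a one-allele scoring slip yields `no_match`, not
  a near-miss).
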