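---
title: "Building whole-genome marker maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building whole-genome marker maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Decades of linkage mapping in crops such as cotton produced thousands of
sequence-tagged DNA markers — RFLP probes and SSR primer pairs — whose
positions are known in centiMorgans on genetic maps but not in base pairs
on a genome assembly. A whole-genome marker map (WGMM) unifies the two
coordinate systems: every marker sequence is placed on the assembly, the
placements are condensed into marker loci, and the loci inherit genetic
positions from a genetic map through colinear "anchor" markers. Once both
coordinates exist for every locus, several downstream analyses fall out of
the same data structure: marker density and coverage statistics,
structural rearrangements visible as disagreements between genetic and
physical order, resistance gene analog (RGA) clusters with their nearest
flanking markers, and the projection of QTL onto physical intervals.

`wgmm` implements that whole pipeline as composable functions over tidy
tables, plus a synthetic-data generator that plants every feature the
pipeline is supposed to find, so each stage can be validated against a
known truth table.

## Pipeline stages and their parameters

### Placing markers

`locate_markers()` reports every exact occurrence of each RFLP probe and
each SSR primer on both strands of the assembly (Aho–Corasick multi-pattern
search through `Biostrings::matchPDict()`). The matcher is deliberately
exact-match only: degenerate homology search is the province of BLAST, and
the pipeline accepts external BLAST tabular files through
`read_blast_hits()` for real data. For synthetic data, which plants
verbatim copies, exactness is sufficient and lets every test compare
against an exhaustive substring scan. A query equal to its own reverse
complement would otherwise be reported once per strand over the same
interval; such double-reports are collapsed so copy numbers are not
inflated.

Hits are filtered by `filter_hits()` at E-value ≤ 1e-10 for marker
sequences and ≤ 50 for the much shorter primers (both bounds inclusive;
internal exact hits carry E-value 0 and always pass).

### Assembling loci

- `assemble_rflp_loci()` merges same-marker hits within 5000 bp into one
  locus (single linkage along the chromosome; the locus spans the
  outermost coordinates). "Distance" throughout the package is the inner
  gap — start of the right interval minus end of the left — with
  overlapping intervals at distance ≤ 0; this is the strictest readable
  sense of a between-feature distance.
- `pair_primer_hits()` combines one forward with one reverse primer hit at
  inner distance ≤ 1000 bp. Orientation must be convergent (opposite
  strands, 3′ ends facing inward): a distance rule alone would accept
  primer configurations that no PCR amplicon could produce. Ambiguous
  configurations are resolved greedily, nearest pair first, each hit used
  at most once, with deterministic tie-breaking by coordinate.
- `dedup_loci()` collapses clustered duplicate copies of one marker lying
  within 1 kb (SSR) or 5 kb (RFLP) to the leftmost representative.
- `copy_number_table()` counts surviving loci per marker, capping the copy
  number at 5 by retaining the five loci with the smallest summed E-value
  (ties to the leftmost coordinate). The cap mirrors the five-copy ceiling
  of published marker-panel accounting; whether such tables mean "exactly
  five", "capped at five", or "more than five excluded" is not decidable
  from the published totals, so the cap is a documented choice and is
  configurable. Markers with zero surviving loci go to a side list so the
  summary's totals equal mapped markers and mapped loci exactly, giving
  the internal identity `n_loci(c) = c × n_markers(c)`.

Percentage columns in the copy-number summary use largest-remainder
rounding to two decimals, the standard table convention under which each
column totals exactly 100.00.

### Anchoring and interpolation

Colinearity between the genetic map and the assembly is decided per
chromosome by `detect_colinear_anchors()`: the maximal-cardinality subset
of map-bearing loci whose cM rank order equals their bp rank order,
computed as a longest non-decreasing subsequence of cM over loci sorted by
bp. This replaces a dedicated synteny tool with the smallest algorithm of
identical intent, and has the advantage of being checkable against an
exhaustive subset search (the test suite does exactly that for n ≤ 12).
Ties are broken deterministically toward smaller bp. Multi-copy markers
participate with every locus; only copies consistent with colinearity
become anchors.

`interpolate_cm()` assigns non-anchor loci the linear interpolation
between flanking anchors,

cM(p) = c1 + (p − b1)/(b2 − b1) × (c2 − c1),

and clamps loci outside the outermost anchors to the terminal anchor's cM
(flag `extrapolated`). Clamping rather than extending the terminal slope
prevents negative or runaway genetic positions at chromosome ends; the
cost is a small downward bias in the extrapolated tails, which is why
interpolation accuracy is assessed over anchor and interpolated loci —
extrapolated loci carry their own flag precisely so users can treat them
separately. Linear interpolation is itself a choice: any monotone scheme
would satisfy the anchoring constraints, and linearity is the one that
adds no assumptions about local recombination rate.

`remove_discrepant()` drops map-bearing loci whose map position differs
from their interpolated position by more than 10 cM — a concrete default
for "strikingly discrepant", aimed at wrong-arm or wrong-chromosome
placements while leaving local ordering noise and genuine modest
rearrangements (which stay below the threshold for spans up to ~3 Mb at
3 cM/Mb) untouched. Configurable via `max_cm_offset`.

### Density and coverage

`window_density()` counts loci in 1-Mb windows at 100-kb steps from 0 to
each chromosome end. A locus belongs to a window iff its start coordinate
lies inside; boundary-straddling loci are thus counted once per
overlapping step-window, as sliding windows require, and a
non-overlapping tiling (step = window) partitions the loci exactly.
`density_summary()` reports kb-per-locus per chromosome and genome-wide,
loci per annotated gene (one decimal), assembly coverage percent (two
decimals), the least-populated window, and the Pearson correlation of
per-chromosome locus counts with chromosome lengths (`cor.test`, t
transform on n − 2 df). The genome-wide kb-per-locus denominator is the
total genome length rather than the assembled length — the convention
that reproduces published density figures from published totals.

### Rearrangements from dotplots

`build_dotpoints()` tabulates one point per (map marker, locus) pair.
Inversions are detected per (map chromosome, physical chromosome) as
maximal runs of ≥ 3 consecutive points (by cM) with strictly decreasing
bp, reported when the physical span of the run's endpoint markers exceeds
1 Mb. Published inversion catalogues were read off dotplots by eye; a
maximal negative-slope run is the smallest faithful formalization of that
practice, and it admits an exhaustive brute-force oracle. By default one
interior violator splits a run (synthetic maps are noise-free); a
`skip_one` mode tolerates a single violator for noisy real maps. The
3-marker minimum is a documented choice — published catalogues do not
state their minimum support.

Translocations: a map chromosome's "home" is the majority physical
chromosome of its points; a run of ≥ 3 consecutive points on one foreign
chromosome is a translocation. A reciprocal translocation therefore
appears as two calls with swapped (map, physical) pairs. Rearrangement
detection runs on all map-bearing loci *before* discrepancy removal:
removal exists to clean the WGMM's cM assignments, and letting it run
first would delete precisely the markers that evidence a rearrangement.

`summarize_rearrangement()` completes calls with the reporting columns of
a genome-variation table: genetic span and its percentage of the source
map, physical span in Mb and its percentage of the chromosome, all to two
decimals, with percentages computed from unrounded spans.

### RGA clusters

Candidate NBS (NB-ARC, PF00931), TIR (PF01582) and LRR-clan domain hits at
E-value ≤ 1 are validated by overlap adjudication: a hit is rejected iff a
hit of a different domain overlaps its envelope (≥ 1 shared residue) with
a strictly lower E-value. A gene is an RGA iff it retains a validated NBS;
the class adds TIR, LRR, and/or CC, where a coiled-coil segment counts
only if it ends before the NBS envelope (the operational reading of
"N-terminal") and overlaps no validated domain. TIR takes precedence over
CC. Coiled-coil prediction itself is consumed as an input table — it is an
external tool's output, not part of the bespoke core.

A cluster is a maximal run of ≥ 2 genes at consecutive order ranks that
are all RGAs — no intervening non-RGA gene, and no maximum bp gap
(configurable), consistent with descriptions of RGA-only clusters down to
two members. `cluster_flanking_markers()` attaches the nearest locus on
each side and the count of loci wholly inside, with a `chromosome_end`
sentinel where no flank exists.

### QTL projection and hotspots

`project_qtl()` delineates each QTL by the two anchors nearest its peak:
greatest cM ≤ peak and smallest cM ≥ peak. A peak exactly at an anchor
widens to the nearest distinct anchors around it; a peak outside the
anchored range clamps to the terminal anchor pair and is flagged.
`find_hotspots()` merges overlapping projected intervals per chromosome by
single linkage (shared bp counts as overlap, so intervals meeting at a
common anchor chain together) and keeps groups with ≥ 3 distinct trait
codes, matching the published "3–7 fiber traits" convention. Hotspots are
presented descriptively in the literature; overlap components are the
minimal formalization consistent with merged published intervals.
Homoeologous source maps are projected independently — merging QTL across
subgenomes is not attempted, and any tetraploid-to-diploid chromosome
correspondence is the user's input, not inferred.

## What the synthetic generator emulates

`simulate_bundle()` produces a complete study with known truth. The
default configuration (`synth_config()`):

| parameter | default | why |
|---|---|---|
| chromosomes | 4 × 12 Mb | several chromosomes at desk scale; large enough for >1 Mb rearrangements |
| markers | 1000 RFLP + 1000 SSR | ≥ 2000, the scale at which copy-number frequencies are testable |
| copy-number weights | .3491/.2157/.1297/.0643/.2412 | the published single-to-five-copy marker frequencies; implied mean 2.63 copies |
| decoy fraction | 5% | markers planted nowhere, exercising the unmapped path |
| probe / primer / amplicon | 60 / 20 / 400 bp | typical probe and primer scales; amplicon safely below the 1 kb pairing rule |
| map scale | 3 cM/Mb | the genome-wide average of a ~2300 cM map over a ~760 Mb genome |
| map fraction | 50% of single-copy markers | a dense consensus map (~85 markers/chromosome, ~0.4 cM anchor spacing) |
| inversions | 3 Mb and 2.5 Mb | two >1 Mb inversions, the size class published catalogues report |
| translocation | reciprocal, 2 Mb arms | the reciprocal arm-exchange pattern known between cotton chromosomes |
| RGA clusters | sizes 3, 7, 2, 4 | spans the published range from two-member clusters to the seven-RGA maximum |
| QTL | 30, three hotspots of 3–5 traits | hotspots of ≥ 3 distinct fiber traits plus scattered background QTL |

Same-chromosome copies of one marker are planted in distinct ~6.2 kb
slots, guaranteeing separations beyond the dedup distances so that truth
copy number equals recoverable copy number *by construction* — this is
what makes the copy-number accounting exactly testable. Inversions are
planted by reflecting cM inside the interval; translocations by
reassigning markers to the acceptor map chromosome beyond its own map,
preserving internal order. Hotspot peaks co-locate within 0.05 cM, an
order of magnitude below the map's anchor spacing, because a "hotspot"
whose peaks straddle several anchor intervals is not physically
co-located at map resolution and would not merge under any faithful
projection.

Coordinates are 1-based fully closed everywhere in memory; the BED-like
WGMM file and the window table are the only 0-based surfaces. A single
seed drives every stage through derived per-stage streams; identical
configurations give byte-identical outputs.

What the generator does **not** emulate: realistic base composition,
repeat families, rDNA arrays, partial-homology marker hits, genotyping
error in the genetic map, or recombination-rate variation (the truth map
is piecewise linear in bp). Consequently, passing recovery tests
demonstrates the correctness of the *rules* — merging, pairing, dedup,
LIS anchoring, run detection, overlap adjudication, interval grouping —
not robustness to the noise of real marker data. For real data the
E-value thresholds, the `skip_one` inversion mode and the discrepancy
cutoff do that work, and external BLAST tables replace the exact matcher.

## Numerical choices and degenerate inputs

- Thresholds quoted from the field are inclusive (`≤`), including the
  primer E-value bound of 50 taken as a raw E-value as printed.
- Percentages print to two decimals, densities to one, matching published
  precision; percentage columns that represent shares of a whole use
  largest-remainder rounding to total 100.00.
- Chromosomes with < 2 map-bearing loci are skipped by anchoring with a
  warning; chromosomes without anchors yield `cM = NA` and flag
  `unanchored`.
- Equal-length chromosomes (as in the synthetic default) make the
  size–count correlation undefined; it is reported as `NA` rather than an
  error when variance is zero on either axis, while direct calls to
  `chrom_size_correlation()` on degenerate input error.
- Zero loci make densities undefined: `density_summary()` errors rather
  than emitting infinities.
- An empty QTL table, an empty rearrangement set, and header-only output
  files are all well-formed empties.

## Problem sizes

The test suite validates each operation against exhaustive brute-force
oracles on at least 100 random small instances (n ≤ 12–15, where
exhaustive search is exact), and runs the full pipeline on the default
48 Mb / 2000-marker study plus a rearrangement-free variant — sizes chosen
so the whole suite completes in a few minutes on one CPU while every
planted feature class is represented several times over.

## Known limitations

- The inversion detector reports maximal descending runs; two planted
  inversions separated by a single colinear marker are reported
  separately, and nested inversions are reported as their net visible
  runs.
- Extrapolated (clamped) cM positions are biased toward the terminal
  anchor; downstream users should prefer `anchor`/`interpolated` loci for
  genetic-distance arithmetic.
- The copy cap discards loci of markers with more than five surviving
  copies; the discarded loci are not currently reported.
- Real BLAST hit tables bring their own search settings (word size,
  identity, coverage); the package applies only the E-value rules and
  does not second-guess upstream alignment parameters.
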