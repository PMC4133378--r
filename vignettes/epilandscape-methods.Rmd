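---
title: "epilandscape: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epilandscape: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`epilandscape` analyses the joint landscape of cytosine DNA methylation
(CG, CHG, CHH contexts) and H3K9me2 in genomes where genes and
transposable elements (TEs) are interleaved. The analysis unit throughout
is the 100 bp non-overlapping window. Three per-window tracks are carried:

* the **weighted methylation level** per context — summed methylated read
  counts divided by summed total read counts over all cytosines of that
  context in the window. This weights sites by their read support; a mean
  of per-site fractions would up-weight shallowly covered sites.
  Windows with zero covered cytosines in a context are **missing** (`NA`),
  never 0%, and are excluded from every downstream mean. Both strands'
  cytosines are pooled per window; symmetric-context collapsing of
  CG/CHG site pairs is deliberately not performed, matching per-cytosine
  extractor output (configurable only by pre-filtering the input).
* the **H3K9me2 read sum** — the number of ChIP reads intersecting the
  window by at least 1 bp. A read spanning a window boundary counts in
  every window it touches (BED-intersect semantics); midpoint assignment
  was rejected because intersection is the field's named convention.
  Counts are raw sums from the (merged, pre-deduplicated) library; a
  counts-per-million switch exists for cross-library comparison but is
  off by default.
* a **location label** (genic / TE / both / other) from ≥ 1 bp overlap
  with the annotation.

Assumptions inherited from the upstream tools: alignment, deduplication
and methylation extraction are done; contexts arrive pre-called (no
genome sequence is consumed anywhere in the package); coordinates are
converted to 0-based half-open intervals at every reader and back at
every writer, so exactly one convention exists internally.

## Significance thresholds

Window-level H3K9me2 significance and the TSS "high H3K9me2" rule are
both mean + k·sd cutoffs over all windows genome-wide with strict `>`.
The **population** standard deviation (denominator n) is used: the
genome-wide windows are the entire population of interest, not a sample.
Defaults k = 1 (windows) and k = 2 (TSS). The "high CHG" TSS rule uses
the empirical top-decile boundary (quantile 0.90, R type-7) of all
defined window CHG levels: this boundary is a property of each dataset
(≈ 88% in a heavily methylated maize-like genome, very different
elsewhere), so the package always recomputes and reports it rather than
fixing a constant.

## Metaprofiles

**Relative-distance profiles** assign each window to its closest element
(distance from the window midpoint; ties go to the leftmost element in
genome order — deterministic, and each window is counted once even when
equidistant to two elements). Retained windows lie inside the element or
within `flank` (default 1000) bp of it. Midpoints inside the element are
rescaled to a 1–1000 axis via `1 + floor(999·(mid − start)/(len − 1))`,
with edge-straddling midpoints clipped into the element first. Flank
distances are measured from the first element base (upstream, negative,
d ∈ [−flank, 0)) and from the first base past the element (downstream,
d ∈ [0, flank)) so the two flanks bin symmetrically. The concatenated
axis is cut into 60 equal bins (20 + 20 + 20), half-open with closed
outer edges.

**Absolute-distance profiles** anchor at the TSS (5′ plot: 2 kb upstream,
3 kb of gene body) or TTS (3′ plot, mirrored). The observation is the bp
offset of a window midpoint from the anchor, sign-flipped for −strand
genes so both axes run 5′→3′ (TSS of a −strand gene is its right-most
base). Offsets beyond a shorter gene's span are dropped, so bin counts
decline with distance into the body; each 5 kb axis is cut into 100 equal
50 bp bins with the top edge closed. Per-bin means pool all gene-window
pairs (one observation per pair); gene-first averaging is available via
the grouping functions but pooled pairs is the default, since with equal
per-gene window counts the two agree and pooling is the simpler estimand.
The gene-body cap uses the gene span (TSS to TTS, introns included), not
the mRNA length.

**Masked profiles** drop windows overlapping a mask set (typically the
genic-TE catalog) from genic bins only; flank bins are untouched.
Exon-only / intron-only restrictions use the same ≥ 1 bp overlap
semantics, so a window straddling an exon-intron junction contributes to
both restricted profiles.

## TE summaries and the genic-TE catalog

Sub-family summaries average each track over the windows overlapping any
member element (window-weighted; element-first averaging via a flag).
A window overlapping elements of two different groups contributes to
both; within one group it counts once. Flank-band summaries use the bands
[start − 1000, start − 900) and [end + 900, end + 1000); a window
qualifies by ≥ 1 bp band overlap, and bands are not clipped against
neighbouring TEs by default (an `exclude_te_overlap` flag drops
windows that sit inside other elements, for clean spreading contrasts).

A TE is catalogued as **genic** when its length strictly exceeds 1000 bp
and its interval is fully contained in a single intron (gene minus exons)
of a gene. Long TEs overlapping genes without single-intron containment
(e.g. spanning an exon boundary) are excluded and counted separately.
Class enrichment compares the TIR/LINE/LTR composition of the catalog
against all TEs.

## Heatmap binning

The CHG × CHH → H3K9me2 heatmap uses windows with data on all three
marks. CHG: ten equal 10-point bins over [0, 100]% with the top edge
closed. CHH: nine bins — [0,1), [1,2), [2,3), [3,4), [4,5), [5,10),
[10,15), [15,20], (20,100] — i.e. 1-point steps to 5%, 5-point steps to
20%, then everything above. The eighth bin is closed at 20 so the edges
partition [0,100] with no gaps (a half-open eighth bin would leave
exactly-20% windows unbinned). Cell values are mean read sums; all 90
cells are always present, empty ones with n = 0 and an undefined mean.

## Expression

RPKM per replicate is `count / (gene_length_kb × library_millions)` with
the library size taken as that replicate's total mapped count; gene
values average replicates. "Not expressed" is RPKM ≤ 0 by default (the
floor is a parameter; no threshold is canonical). Expressed genes are
ranked (ties broken by gene id, so the grouping is deterministic) and cut
into four quartiles whose sizes differ by at most one.

## The synthetic generator

`sim_config()` describes a compact caricature of a repeat-rich genome —
1 Mb over two chromosomes by default, 40 multi-exon genes, five TE
families (two LTR-like: high CG/CHG/H3K9me2, one of them spreading its
marks linearly over 1 kb flanks; two TIR-like: one high-CHH/low-H3K9me2,
one low-CHH; one LINE family), 15% of genes carrying a > 1 kb TE inside
their first intron, planted high-CHG and/or high-H3K9me2 TSS tiles, and
log-normal expression with a 20% silent fraction. Per-cytosine read depth
is Poisson(20) and methylated reads are Binomial(depth, p) with p taken
from the enclosing regime. ChIP reads are 50 bp single-end with additive
Poisson intensity calibrated so the expected read count over an interior
window equals the regime's rate (rates below background are floored at
the background). `sim_config_tss()` is a larger preset (8 Mb, 1000 small
genes, one abundant LTR family) sized for validating TSS classification:
the LTR family occupies ~15% of the genome so the top-decile CHG boundary
falls inside the transposon mode, as it does in real repeat-rich data.

Deliberate idealisations, hence what a green test does *not* establish:

* **Feature coordinates are snapped to the 100 bp window grid.** Planted
  per-window truth is then unambiguous — no window mixes two regimes —
  which is what lets recovery tests use tight (±0.02) tolerances. Real
  boundaries are not grid-aligned; windows straddling them are mixtures,
  and profile bins adjacent to element edges will sit between the two
  regimes on real data. A side effect is that window midpoints occupy
  fixed offsets within the 50 bp profile bins, so alternating bins can be
  empty (n = 0); profile consumers must treat n = 0 bins as absent, and
  the acceptance checks evaluate decay over populated bins.
* Cytosine sites are placed uniformly at configured densities; there is
  no sequence, no context clustering, no conversion-failure noise.
* TEs do not nest (except the designed intronic insertions), have no age
  structure, and "spreading" is a planted linear decay, not a mechanism.
* Expression suppression of TSS-high genes defaults to complete silencing
  (`suppression_multiplier = 0`) — the cleanest planted contrast for the
  crosstab check; partial suppression is a knob.
* Features are spaced ≥ 2.2 kb apart so 1 kb flank analyses see clean
  background; real flanks are crowded.

Determinism: all four generator stages derive independent RNG streams
from the single config seed (`seed`, `seed+1`…, kept far below 2^31), so
equal seeds give byte-identical emitted files.

## Numerical conventions, in one place

* Coordinates: 0-based half-open everywhere internally; GFF3 and
  cytosine-report positions convert at the boundary.
* Missing ≠ zero for every level; means use `na.rm` semantics with
  reported n.
* All histogram/profile/heatmap bins are half-open with closed top edges,
  so no valid value is unbinned.
* Quantiles: R default type 7. Standard deviations for thresholds:
  population (ddof 0). All significance comparisons strict (`>`).
* Nearest-element ties: leftmost by genome order. Expression ties:
  gene-id order.
* Windows with fewer covered cytosines than `min_sites` (default 1) in a
  context are missing in that context.

## Known limitations

* Sub-family means are window-weighted by default; with very uneven
  element lengths, element-first averaging (provided as a flag) can give
  materially different values, and neither is canonically "right".
* The relative-profile scaling maps each element onto 1–1000 by floor
  arithmetic; elements shorter than ~ 2 windows contribute coarse scaled
  positions.
* No statistical testing is attempted anywhere (no DMRs, no peak calls,
  no confidence bands on profiles) — the package computes descriptive
  landscape summaries.
* The CLI reads plain files only; gzipped inputs work wherever
  `data.table::fread` auto-detects them.
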