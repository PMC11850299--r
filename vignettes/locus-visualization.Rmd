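---
title: "Methods: comparative locus maps and the genome-browser mode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative locus maps and the genome-browser mode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how lociview computes what it draws: the analysis
model and its assumptions, the parameters that matter, the numerical and
design choices made where several options were defensible, and what the
synthetic test fixtures do and do not demonstrate about real data.

## The analysis model

### Input model

A *locus* is one annotated nucleotide sequence displayed as one figure
row. Internally all coordinates are 0-based half-open; GenBank and GFF
(1-based inclusive) are converted at the parsing boundary, which keeps the
arithmetic for wrapping and scaling uniform. A feature spanning the origin
of a circular sequence is stored as a single feature with a wrap flag
(occupying `[start, length)` then `[0, end)`) rather than being split,
because the display contract for circular sequences is continuity across
the origin, with no gap. Display windows (*regions*) follow the same
convention; a locus with no explicit region gets one covering the whole
sequence.

CDS translations are taken from the annotation when present, otherwise
computed conceptually with the bacterial/archaeal genetic code (table 11)
with the initiator rule (alternative starts such as TTG and GTG yield
methionine), the trailing stop removed, and internal stops kept with a
warning — truncating would silently misrepresent pseudogenes.

A protein is *hypothetical* when its label matches, case-insensitively,
any of the configured patterns (`hypothetical protein`, `unknown
function`, `uncharacterized` by default). The set is configurable because
annotation tools vary in their wording.

### Homology groups

The built-in clusterer is a deterministic greedy set-cover: proteins are
visited by decreasing length (ties by lexicographic id, mirroring the
longest-sequence-as-representative convention of common clustering
tools); each joins the first existing representative whose global
alignment reaches both thresholds, otherwise it founds a group. The
alignment is Needleman–Wunsch with match 1, mismatch 0, gap open 10, gap
extension 1; *identity* is exact matches divided by all alignment columns
(gap columns included — an unambiguous, testable denominator) and
*coverage* of each sequence is the fraction of its residues aligned to a
residue of the other. Defaults `min_identity = 0.35`,
`min_coverage = 0.7` (both fractions in [0, 1]) mimic settings widely
used for remote-homologue grouping at desk scale.

Greedy clustering is order-dependent near the thresholds; that is
accepted and documented rather than hidden. For inputs whose within-group
identities clear the threshold and whose between-group identities are
essentially zero — the regime the fixtures construct — the result equals
the connected components of the all-pairs threshold graph, and the test
suite checks exactly that equivalence against an independently coded
dynamic-programming oracle. Exact duplicate sequences are pooled before
any alignment and pairs whose length ratio already caps identity or
coverage below threshold are skipped; both shortcuts are loss-free.

Users with an external clusterer (e.g. MMseqs2) can route through the
adapter, which passes user arguments verbatim — the right upstream
parameters are the user's call, not something to guess. A predefined
group table short-circuits clustering entirely.

### Proteome similarity and sequence clustering

The similarity of two loci is the symmetric mean of the two directional
shared-group fractions. The mean-directional form is the default instead
of Jaccard so that a short sequence fully contained in a longer one still
scores high — a phage and its deletion variant should sit together in the
figure. Jaccard is one configuration key away (`similarity`). Empty
proteomes score 0 against everything (diagonal 1), and adding an empty
locus never changes the similarities among the others.

Row order and sequence clusters come from UPGMA (unweighted average
linkage) on `D = 1 − S`. Merge heights are stored as ultrametric node
heights — half the average inter-cluster distance — so the cophenetic
distance of two leaves is exactly the average-linkage distance at which
they join; this makes the exported Newick branch lengths add up
correctly. Ties are broken by the smallest cluster-index pair in creation
order, and leaf orientation puts the subtree containing the
lexicographically smallest label first, so the whole pipeline is
deterministic across runs and platforms. Flat clusters are the maximal
subtrees within cophenetic distance `cluster_cut` (default 0.75 — at
least a quarter of the proteome shared on average); the value mirrors
common pangenome practice and is exposed in the configuration, as the
choice is inherently conventional.

### Gene classes

Within each sequence cluster a group's presence fraction *f* counts the
member loci carrying the group at least once — paralogous extra copies do
not inflate presence, because presence is about distribution across
genomes, not dosage. Classes: conserved if *f* ≥ `conserved_cutoff`
(default 0.75), variable if *f* ≤ `variable_cutoff` (default 0.25),
otherwise intermediate. Singleton clusters carry no variability evidence,
so all their groups are conserved; this also keeps a lone unrelated
sequence grey instead of rainbow-coloured. The cutoffs are conventional
soft-core/cloud style values, not estimates, and are configurable.

## The figure

All geometry is computed in millimetre canvas units by the layout engine
and handed to the renderer unchanged, so every visual invariant is
testable without reading a PDF.

* **Shared scale.** One bp-to-unit scale figure-wide: the longest
  displayed row spans the drawable width, every other row is
  proportionally shorter. Regions of one locus sit left-to-right with a
  fixed 2-unit gap; a wrapping region is continuous across the origin.
* **Arrows.** Strand-aware polygons; the head is capped at the drawn
  length so short genes degrade to triangles; clipped edges are drawn
  flat to signal truncation.
* **Labels.** Hypothetical proteins are unlabelled. Conserved-group
  labels appear only at the first occurrence in reading order (top row
  first, left to right) — the homology ribbons carry the information for
  later occurrences. Placement is greedy and two-tiered: preferred slot
  centred above the feature; on collision the box slides up to half the
  feature width (right, then left); then it is promoted one label height
  up with a thin leader line; if that also collides the label is dropped
  with a warning. Non-overlap holds by construction and is verified
  exhaustively in tests. A `show_label` column in the feature table
  overrides everything.
* **Homology ribbons.** Drawn between vertically *adjacent* rows only;
  chains of ribbons convey longer-range homology without quadratic
  clutter. With paralogues, the nearest pair by x-midpoint is joined.
  Ribbons are straight-edged quadrilaterals beneath the arrows.
* **Category strip.** A coloured line under each categorized ORF using
  the bundled PHROG-style palette (user-overridable); unknown categories
  render in a reserved colour with a warning. Hidden in compact mode.
* **Scale bar.** In compact mode a single bar replaces the per-row axes;
  its length is the largest 1–2–5 × 10^k bp value not exceeding 25% of
  the canvas width (`scalebar_fraction`), labelled in bp or kbp by
  magnitude.
* **Colours.** In the default `variable` highlight mode every variable
  (and intermediate) group gets its own colour and conserved groups share
  one grey; `conserved` mode inverts this. Hues are equally spaced
  (360/n degrees for n coloured groups) with a seed-derived golden-angle
  offset. Equal spacing, rather than pure golden-angle stepping, is used
  because it actually guarantees the pairwise hue separation of at least
  360/(n+1) degrees that the palette promises; golden-angle stepping
  alone can violate it already at n = 3.

### Rendering

The renderer is a small purpose-built PDF 1.4 writer: uncompressed
content streams, base-14 Helvetica text objects (editable downstream in
vector editors), metadata timestamp pinned by configuration. Rendering is
therefore a pure function of layout and style, and identical inputs give
byte-identical files — the reproducibility contract the tests enforce
with a golden file. Label widths are measured from the Adobe font metric
files shipped with R itself, so layout and output always agree. Numeric
output is formatted with fixed three-decimal precision, which at
millimetre scale is far below visual resolution and keeps files
platform-stable.

## Genome-browser mode

One locus, panels stacked top to bottom: category strip, gene map, GC
content, GC skew, then user tracks in input order. GC statistics use
centred windows shrunk at the sequence edges (trailing windows would
phase-shift the profile); windows with only N yield 0 for content, and
windows with no G or C yield 0 for skew. Signal tracks come from bedGraph
(0-based half-open; uncovered bases 0; overlapping intervals resolve
last-wins with a warning, a tolerance for real-world exports), or from
bigWig through a converter adapter.

Smoothing is image-width-aware: with a target density of
`points_per_unit` (default 2 points per canvas unit ≈ 5 points/mm, the
density beyond which extra points add no visible detail), the target
point count is P and the boxcar window is `w = max(1, floor(span / P))`.
The smoothed series is subsampled at block centres, so each retained
point is the mean of one length-w block; with w = 1 the track passes
through unchanged, and for spans that are multiples of w the mean is
preserved exactly. GC tracks are then centred at their mean, positive and
negative relative values get distinct colours, and the raw minimum,
maximum and mean are annotated in the panel corner.

## The synthetic fixtures

`make_locus_set()` builds circular phage-like loci: per block, a set of
core families present in every locus in conserved order, plus cargo genes
drawn per locus from a block-specific pool, separated by random
intergenic spacers. Core proteins are identical across copies by default
so grouping is threshold-independent in tests (a mutation-rate knob makes
near-threshold variants for stress testing); family proteins are random
amino-acid strings, far below any clustering threshold from each other.
The truth table records each feature's family and the class implied by
the realized presence fractions, and with two blocks the blocks share no
families, so proteome similarity between them is zero and cluster
recovery is unambiguous. `make_signal()` writes bedGraph coverage as
Gaussian bumps plus half-normal noise with the analytic profile as truth.

What the fixtures do *not* emulate: realistic gene content or codon
usage, homologues at intermediate divergence (except via the mutation
knob), annotation noise, or disagreeing labels. Passing tests therefore
demonstrate the pipeline's contracts — parsing fidelity, partition and
matrix laws, geometric invariants, exact class recovery when thresholds
bracket the construction — not clustering accuracy on borderline real
proteins.

Test problem sizes are the package's chosen study conditions: 200 random
group-set inputs (≤ 12 loci) for matrix laws; 100 random dissimilarity
matrices (n ≤ 6) against a from-scratch average-linkage oracle and
`stats::hclust`; fixture sets of 4–10 loci with 10 core families over
seeds 1–20 for class recovery; 50 generated figures plus a pathological
50-features-in-10-units case for layout invariants; and one 78-locus,
60-genes-per-locus set exercising the many-genome single-figure case end
to end.

## Numerical choices and degenerate inputs

* Symmetry of a distance matrix is accepted up to 1e-9; merge-height
  comparisons use a 1e-15 guard so exact ties fall to the deterministic
  index rule.
* A 1-locus input yields a single-leaf tree, Newick `"id;"`, one cluster,
  and all-conserved classes.
* Empty protein sequences are an error naming the feature; empty
  proteomes are legal and score 0.
* bedGraph rows for other sequences are skipped with a warning;
  malformed rows error with their line number.
* The label-placement horizontal clearance is 0.4 units; boxes are
  clamped to the drawable area, and a label wider than the canvas is
  dropped.
* GC windows must be odd (centred windows have a unique centre);
  `gc_window = 1` by default, with display resolution handled by the
  adaptive smoother rather than the window.

## Known limitations

* The GenBank reader covers the flat-file subset written by prokaryotic
  annotation tools; compound locations other than simple origin-spanning
  joins collapse to their outer extent with a warning (multi-exon
  eukaryotic models are out of scope).
* Greedy clustering near thresholds is order-dependent by design; for
  publication-grade homology at scale, use the external-clusterer
  adapter and feed the resulting table back in.
* The renderer emits PDF only (no SVG/PNG), one page, base-14 fonts
  without embedding; non-ASCII label characters fall back to a default
  width in layout and may render approximately.
* Per-base track expansion favours simplicity over memory; it is sized
  for phage/plasmid spans (up to a few hundred kb), not whole bacterial
  chromosomes at once.
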