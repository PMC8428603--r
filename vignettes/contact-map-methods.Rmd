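---
title: "Contact maps, annotation tracks and model-quality scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact maps, annotation tracks and model-quality scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conmapr)
```

This vignette is the package's own account of the methods it implements:
the data model, the contact definitions, the comparison statistic, the
figure geometry, and the design decisions taken where conventions in the
field are not fixed.

## Data model

A **contact map** is a sparse symmetric relation over residue pairs of one
sequence. Storage is canonical — each pair once, with `i < j`, sorted — so
symmetry is a structural property rather than an invariant to police.
Canonicalization folds `(j, i)` onto `(i, j)` and collapses duplicates
keeping the **maximum** score: predictors sometimes emit both triangle
orders, and when they disagree the more confident value is the conservative
choice for ranking-based evaluation. Indexing is 1-based throughout and
user-facing intervals are closed, matching the RR and PDB conventions.

A **distogram** attaches to each pair a probability vector over an ordered
set of distance bins. Vectors must be non-negative and sum to 1 within
1e-6; the RMODE 2 reader renormalizes vectors whose sum drifts by at most
0.01 (predictors round their output) and rejects anything worse, so a
distogram object downstream is always exactly normalized. The RMODE 2
format itself does not carry bin edges. The default here is the ten
intervals (0,4], (4,6], …, (18,20], (20,∞) Å, a common choice in
CASP-style pipelines; it is an explicit configuration knob
(`default_distance_bins()`), not an assumption.

Collapsing a distogram to contact scores sums the mass of all bins lying
entirely at or below the threshold: with the default bins and the 8 Å
contact definition, P(contact) = p((0,4]) + p((4,6]) + p((6,8]). The
threshold must coincide with a bin edge; interpolating inside a bin would
manufacture precision the prediction does not contain, so a mismatched
threshold is an error rather than an approximation.

An **annotation track** assigns one categorical state (and optionally a
real value) to every residue. Every state must have a palette entry at
construction time, which keeps rendering total: a scene can never contain
an uncoloured primitive.

## Contact extraction from models

A residue is reduced to one representative atom: Cβ, falling back to Cα
for glycine or when Cβ is absent (the CASP convention), or Cα throughout
if requested. Contact: representative-atom distance ≤ 8 Å. Both cutoff
and scheme are exposed because neither is universal.

Author residue numbering is mapped to 1-based sequence positions so model
maps align with prediction maps. When numbering is strictly increasing the
offset to the first residue is removed and **gaps are preserved as missing
positions** — closing them would silently shift every downstream contact.
Only non-monotonic numbering or insertion codes force sequential
renumbering, with a warning. Alternate locations keep the
highest-occupancy conformer; residues lacking both Cβ and Cα are skipped
with a warning rather than invented.

## Superposition and satisfaction

Given predicted map P and model map M over the same sequence length (and,
when both carry sequences, the same sequence — mismatches are refused, not
aligned), both are filtered to the same minimum separation and partitioned
into matched (P ∩ M), model-only (M \ P) and predicted-only (P \ M). The
three sets are disjoint by construction and their union is the union of
the filtered inputs.

The satisfaction score is the precision of the selected predictions:
filter to separation ≥ `min_sep`, rank by score (ties broken by ascending
`(i, j)` so results are reproducible), keep the best `top_n`, and report
the fraction realized in the model. Defaults are the CASP long-range class
(`min_sep = 23`) and `top_n = floor(L/2)`, the standard top-L/2 evaluation
subset. The denominator is the number actually selected — when fewer than
`top_n` predictions survive the filter, precision is measured over what
exists; when none survive, the score is 0 and flagged `undefined`.

One property worth stating precisely: the *count* of realized predictions
can only fall as `min_sep` rises, but the *ratio* need not be monotone,
because the denominator shrinks too (two predictions, one realized at long
range: 1/2 at `min_sep = 0`, 1/1 at 23). The test-suite asserts the
monotone quantity and deliberately not the ratio.

## Figure geometry

The plot square is `[1, L]²`, residue `i` on x, `j` on y. With one map the
points are drawn symmetrically in both triangles; with two maps the upper
triangle shows one and the lower the other (half-map composition). Contacts
with `|i − j| < min_sep` are blanked (display default 5), freeing the
diagonal band.

Track slot `k ∈ {−4…+4}` occupies the band of diagonal offsets
`d = j − i ∈ [k·w − w/2, k·w + w/2)`, where `w` is the band width in
residue units (default 2). The half-open interval makes the nine bands
pairwise disjoint even at shared edges; slots `+k` and `−k` are mirror
images across the diagonal, so mirroring a track is purely geometric.
Segments are parameterized by the along-diagonal position
`s = (i + j)/2`: a run of identical states over residues `[a, b]` becomes
the quadrilateral `s ∈ [a − ½, b + ½] × d ∈ [k·w − w/2, k·w + w/2]`,
clipped to the plot square (Sutherland–Hodgman); clipped-to-nothing
segments — possible for the outermost slots in the first and last few
residues — are dropped. One segment per maximal run keeps the scene small:
a 9-track figure over 150 residues is a few hundred primitives.

With the defaults, four slots per side consume offsets up to
`4w + w/2 = 9` residues, which exceeds the display blanking of 5; the
builder warns when occupied bands reach into the region where contacts are
drawn, and the shipped demo raises the blanking to 10 instead.

Heatmap mode colours each pair's cell either by contact probability or, for
distograms, by the expected distance `Σ mᵦ pᵦ` with bin midpoints `mᵦ` and
the open last bin counted at its lower edge + 2 Å — a bounded, monotone
stand-in for the mean of an unbounded interval.

## Rendering

Scenes render through ggplot2 with identity colour scales (the scene, not
the renderer, owns all colour decisions), to PNG or SVG via the cairo
devices. SVG output is byte-for-byte deterministic for a fixed scene,
which the test-suite exploits as a golden-file contract. The legend lists
one entry per (track, label) pair and one per point layer.

## The synthetic scenario

`make_membrane_scenario()` generates, from one seed, a consistent bundle
for a 150-residue pseudo-protein with two re-entrant loops (residues
16–42 with helices 16–25/28–42 and a break at 26–27; 105–131 likewise):
FASTA, topology string, ss2, conservation grades, a custom track marking
both loops in purple, a model PDB realizing each loop as two adjacent
antiparallel helices, and a predicted RR file derived from the model's
contacts with a seeded 20% removed (these become model-only on
superposition) and ~30 spurious long-range pairs added (predicted-only).
Scores for true contacts are drawn from U(0.70, 0.99) and for spurious
ones U(0.30, 0.80), emulating a predictor that is confident but imperfect.

What it emulates: file syntax of every supported format, the geometric
contact patterns of helices (the (i, i+3)/(i, i+4) band, inter-helix
contacts), and a non-trivial three-way superposition. What it does not:
real predictor error structure (errors here are independent deletions and
uniform spurious pairs, not the correlated, interface-concentrated errors
of covariance methods), realistic B-factors/occupancies, side-chain
geometry, or sequence–structure consistency beyond residue naming. Tests
passing on this generator therefore validate parsing, algebra and
geometry — not predictive performance on real proteins.

## Problem sizes and tolerances

The property suite runs 1,000 random map-pair superpositions (L ≤ 100)
against a raw set-algebra oracle, 100 random structures (N ≤ 200) against
an all-pairs distance loop plus rigid-motion (tolerance 1e-6) and
cutoff-monotonicity checks, and 500 RR round-trips; scores are written
with 17 significant digits so doubles survive the text round-trip exactly.
These sizes keep the whole suite around two minutes on one core while
leaving no branch of the pair-classification logic unexercised.

## Known limitations

Single chain, single model: inter-chain contacts and ensembles are out of
scope. No sequence alignment: maps over different sequences are refused,
not reconciled. mmCIF input is not supported. The custom-track grammar is
this package's own dialect, documented in `?read_custom_track`; files
written for other tools' custom formats will generally need a one-line
conversion. Rendering is static (PNG/SVG); there is no interactive
zoom/hover layer.
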