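---
title: "Tracing coronary vessels with regional parameter expansion and cover trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing coronary vessels with regional parameter expansion and cover trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiotrace)
```

## The problem and the model

Coronary angiograms show contrast-filled arteries as dark curvilinear
structures on a brighter background whose brightness drifts smoothly
across the frame (tissue shadows, beam inhomogeneity). Two consequences
follow. First, no single intensity threshold separates vessel from
background everywhere, so binarisation must be local. Second, once a
binary mask exists, the clinically interesting quantity is not the mask
itself but the vessel *path* and the *diameter along it* — a stenosis is
a local dip in that profile.

`angiotrace` addresses the two parts with two cooperating procedures.

### Local binarisation: regional parameter expansion

The frame is divided into square tiles (32 px by default; a 512 x 512
frame gives a 16 x 16 grid). A classification stage marks tiles as
vascular or nonvascular. Vessel and background intensities within one
vascular tile are well separated, so an exact two-cluster split of the
tile's intensities yields a trustworthy local threshold: in one dimension
the optimal two-means partition is a cut point in the sorted sample, and
scanning all cuts with prefix sums finds the global within-cluster
sum-of-squares optimum deterministically — there is no Lloyd iteration
and no seed sensitivity. The threshold `delta` is the midpoint of the two
cluster means, which in one dimension is exactly the nearest-centre
boundary. Pixels strictly below `delta` are vessel candidates; ties go to
background (the conservative call, since vessel is the dark class).

The threshold is then *expanded*: within the clipped 3 x 3 block of tiles
around the vascular tile, an 8-connected flood fill starts from the
centre tile's sub-threshold pixels and admits any block pixel below
`delta`. Expansion recovers vessel pixels in neighbouring tiles the
classifier missed, while the connectivity requirement keeps disconnected
dark clutter out. The final mask is the union over all vascular tiles —
a set union, hence independent of tile order.

Two reference strategies exist for comparison and are exposed as
configuration: `single_tile` thresholds every tile of each vascular
block independently with its own per-tile cut (this forces a two-cluster
split even on vessel-free tiles, typically blackening about half of each
such tile — the noisiest strategy by a wide margin), and `merged_block`
pools each block's pixels under one cut (cleaner, but the pooled
threshold picks up any disconnected dark structure in the block). On
phantom batches the mean black-pixel counts order as
`flood_fill <= merged_block <= single_tile`, and flood fill has the
lowest false-positive count — the motivation for making it the default.

### Tile classification is pluggable

The classification stage is an interface, not a fixed model. Three kinds
are built in: a deterministic heuristic (a tile is vascular iff its
two-cluster split is non-degenerate, the cluster centres are at least
`min_contrast = 40` gray levels apart, and the dark fraction lies in
`[0.05, 0.80]`); an oracle that labels from a ground-truth mask (used to
isolate downstream stages in tests); and an external kind that reads any
per-tile label CSV, so a trained patch classifier can be slotted in. The
expansion step deliberately tolerates classification errors: a vascular
tile missed by the classifier is still recovered as long as a neighbour
is labelled and the vessel is connected across the tile border — a
property the test suite exercises by flipping 20 % of vascular labels.

### Path and diameter: the optimal cover tree

A *cover* is a chord across a black region: from an edge pixel, a ray is
walked in one of five directions — right, down, up, down-right, up-right
— and spans the consecutive run of vessel pixels. Its Euclidean length
(span on the axes, span·√2 on the diagonals) estimates the local vessel
diameter where the chord is perpendicular to the vessel. Five directions
rather than three (right, down, down-right) matter on curved segments:
the underside of a U-turn is only reachable by the upward chords, and the
test suite checks that five-direction coverage is never below
three-direction coverage on a U phantom.

Raw shortest chords zigzag on jagged binarisation edges, so consecutive
covers are *chained* under two rules: the orientation change is at most
`max_angle_step` (45°; orientations are undirected — up and down are the
same line), and the length change is bounded by a tolerance. Among the
candidates satisfying both rules the shortest is selected, with
equal-length ties resolved in favour of the previous direction and then a
fixed priority (E, S, N, SE, NE); if no candidate is admissible the
previous direction is preferred when still available, else the shortest
candidate, and the selection is flagged as a fallback. Chaining lowers
the circular variance of cover orientations on jagged edges — the ruled
chain hugs the true cross-section — which the suite verifies against the
rules-off ablation.

Two numerical choices here deserve explanation:

* **Length tolerance.** The default is
  `max(2 px, 0.30 x previous length)`. The relative part must exceed
  `1 - 1/sqrt(2) ≈ 0.293`: that is the length step between an oblique
  axial chord (w·√2) and the true diagonal diameter (w) of the same
  vessel, and with a smaller tolerance the chain could never rotate onto
  a 45° segment. The absolute floor keeps 3-px vessels workable. A
  running-window variant (mean ± 2 sd of the last five lengths) is
  available behind `tolerance_mode = "window"`.
* **Border-truncated rays.** A ray clipped by the image border does not
  witness an edge-to-edge chord, and such stubs (e.g. short upward rays
  near the top border) would otherwise win the shortest-admissible
  contest and derail the chain. Truncated rays are therefore last-resort
  candidates, used only when no unclipped chord exists.

Covers are cast while walking each 4-connected black region's outer
contour (Moore-neighbour tracing, heading down the left edge first from
the region's top-left pixel; inner hole boundaries afterwards in scan
order). Contour order matters: covers cast from the near edge cross the
region and mark the far edge as covered, so the far edge — from which
only oblique chords could be cast — is skipped. Every boundary pixel not
yet under a cover casts one; each region yields one spanning tree whose
edges follow the selection chain.

Trees whose covers contain pixels that touch (8-adjacency, so regions
meeting corner-to-corner count) are merged transitively, connected by one
edge per adjacency so the merged structure stays a tree. The tree with
the longest simple path (node count; ties to the larger tree, then to the
earliest anchor in scan order) is retained as the main vessel; every
region holding none of its covers is erased. This removes guidewires,
catheter fragments and blob noise — and also any genuine vessel
disconnected from the main one, a known and accepted cost of keeping a
single tree (`keep_top_n` in the pipeline configuration relaxes it).

The diameter profile takes one sample per cover along the main tree's
longest path: position is the cover midpoint, diameter its length in
pixels (no physical calibration is attempted). The overlay paints each
cover by the quantile bin of its length over a fixed diverging palette
(thin red to thick blue); quantile bins adapt the colour scale per image.

## The phantom generator

Every quantitative claim in the package is tested against synthetic
phantoms with exact ground truth. A phantom is a 512 x 512 frame (the
native angiogram format here) with, by default: two vessels of base
widths 15 and 9 px entering from the top edge and descending as unit-step
random walks with bounded curvature (heading sd 0.02 rad/step, clamped to
±1 rad of vertical); vessel gray level 70 on nominal background 170; a
random low-order polynomial illumination field of ±40 gray levels; an
optional Gaussian-profile stenosis; additive Gaussian noise (sd 8,
clipped at ±14 so noise alone can never cross the enforced 30-level
minimum vessel/background contrast); three dark distractor disks and one
2-px guidewire-like curve, placed so they never touch a vessel and
excluded from the truth mask. Vessels are stamped as hard disks of radius
width/2 along the centreline with no anti-aliasing, so the truth mask's
perpendicular chord width equals the nominal width to within a pixel, and
all rasters are integer-valued — outputs are bit-reproducible from the
seed across platforms.

These defaults were chosen to span the failure modes that motivate the
method — uneven illumination, low-contrast thin branches, disconnected
devices — at magnitudes a reader of clinical angiograms would call
plausible. What the phantom does *not* emulate: X-ray projection physics,
contrast-agent washout, motion blur, overlapping/crossing vessels, and
textured anatomical background. Passing tests on phantoms therefore
demonstrate the algorithmic properties (noise ordering, width recovery,
rule effects, pruning semantics, determinism), not clinical performance.

## Degenerate inputs and error handling

Constant-intensity samples have no two-cluster structure: the threshold
raises a classed degeneracy error, which the segmentation stage catches
per tile (the tile contributes nothing and is logged) and the heuristic
classifier treats as nonvascular. Empty masks yield empty forests;
selecting a main tree from an empty forest is a no-vessel error, which
the pipeline converts into empty artifacts plus a warning rather than a
crash. Images whose dimensions do not divide by the tile size are
rejected outright — padding would distort the pixel accounting that the
strategy comparison rests on.

## Problem sizes used by the test suite

The suite runs 512 x 512 phantoms where the full-frame pipeline is the
subject (strategy ordering over 20 phantoms, end-to-end reproducibility)
and 256 x 256 or smaller frames where a stage is tested in isolation;
random-mask property checks use up to 64 x 64 masks, bar-width recovery
uses 64–80 px bars of widths 3–25, and stenosis tracking uses a 256 px
frame with a 15 px vessel at severities 0–75 %. The whole suite completes
in about two minutes on one CPU.

## Known limitations

* On smoothly curving vessels whose direction sits between the five cover
  directions, the chain can hold an oblique direction for a stretch
  (each length change staying inside the tolerance), inflating the local
  diameter estimate; profile medians are robust to it, but pointwise
  errors on strongly wandering vessels can be several pixels. The five
  fixed directions bound the perpendicularity error in the best case to
  the 22.5° half-step (about 8 % length inflation).
* Crossing or overlapping vessels are a single black region to the
  tracer and are not disentangled.
* Retaining a single tree removes genuine disconnected vessels; raise
  `keep_top_n` when that is not wanted.
* Diameters are in pixels; no mm calibration is attempted.
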