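---
title: "Models and design choices in tissuecure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in tissuecure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the data model and its invariants, the tracking and event-detection rules,
what the synthetic test bed does and does not emulate, and the numerical
choices a maintainer would want written down. It states no empirical
result that the test suite does not itself compute.

## The label-movie model

A movie is a `T x Y x X` integer array; nonzero values are cell ids, 0 is
background. Two invariants define a usable movie:

* **one region per id** — within a frame, a nonzero label occupies exactly
  one 4-connected region. Cell interiors use 4-connectivity and junction
  tests use 8-connectivity, the natural pairing when 1-pixel-thin junction
  lines separate 4-connected cells;
* **confluence** (optional, on by default) — epithelia are confluent:
  every interior background pixel must either lie on a junction (its 3x3
  neighbourhood holds at least two distinct labels) or hug the image
  border. A hole in the tissue is a violation, reported with its pixel
  count and bounding box.

Segmentation tools disagree about whether neighbouring cells share an
edge ("dense") or are separated by a 1-pixel background skeleton
("junction-gap"). Both are accepted everywhere. Operations detect the
representation per frame — a frame is junction-gap when more than half of
its cells touch background — rather than globally, so a dense frame with
an (erroneous) hole is not mistaken for a skeletonised one. The junction
skeleton (`skeletonize_frame()`) is the canonical bridge: the band of
pixels whose 3x3 neighbourhood sees two or more labels, thinned
(Zhang–Suen) to one pixel. For a junction-gap frame this reproduces the
stored skeleton; for a dense frame it produces the equivalent line.

Two labels are *neighbours* when their regions come within 2 pixels
(Chebyshev). The reach of 2 bridges the 1-pixel gap, making the neighbour
count (`NbNeighbor`) identical across representations.

All public tables use 0-based frame indices and pixel coordinates, in
(y, x) order, matching the conventions of the imaging files the package
reads and writes; centroids are arithmetic means of pixel coordinates.

## Tracking

Frame-to-frame linking minimises, over one-to-one matchings, the cost

    cost(i, j) = d(c_i, c_j)^2 * (1 + w_A * |A_i - A_j| / max(A_i, A_j))

with links forbidden beyond `max_link_distance` and a per-region no-link
alternative priced at `max_link_distance^2` (the classic augmented-matrix
construction, solved exactly with an O(n^3) shortest-augmenting-path
solver). Quadratic distance is standard practice for linear-assignment
tracking; the relative-area factor implements "link only cells of similar
area" in a scale-free way, with `w_A = 1` by default. Among equal-cost
optima the solver is deterministic given the input order; regions are
always processed in label order. The unit suite checks the minimised cost
against exhaustive enumeration on hundreds of random small instances.

**Division hypotheses** run after linking, not inside the assignment. The
field rule — one track disappears, two appear very nearby — has a failure
mode: the assignment usually links the parent onward to one daughter, so
the parent never "disappears". The division pass therefore enumerates
hypotheses (parent; daughter pair) where at least one daughter is an
unmatched start and the other may be the parent's own onward link,
requires every daughter to be at most `division_area_frac = 0.7` of the
parent's area (a true daughter is about half), ranks hypotheses by the
distance between the parent's last centroid and the daughter midpoint
(for a real division the parent sat where its daughters now straddle),
and accepts greedily. The search radius defaults to twice the median cell
diameter of the frame — a scale-free reading of "very nearby".

**Gap closing** joins a track ending at `t` to one starting at
`t' <= t + 1 + max_gap_frames`, with the distance allowance scaled by
`(gap + 1)` and the additional requirement that the two areas differ by
at most 50% — a gap bridges the *same* cell, so a track that ends tiny
(an extrusion) is never stitched to an unrelated start.

**Relinking after an edit** is overlap-based: the corrected label inherits
the track of the frame-neighbour region with the largest pixel-overlap
fraction (relative to the smaller region) when that fraction reaches
`overlap_min = 0.5` — majority overlap uniquely identifies a
continuation — and otherwise opens a fresh track; a successor track
starting right after the edit is relabelled to match. Only tracks
intersecting the edited neighbourhood are modified. Note one deliberate
reading: "local" bounds *which tracks* change, not which rows — adopting
a track id rewrites that track's later rows too.

## Inspection

Suspicion is rule-based and configurable (`flag_config()`): interior
appearance or disappearance (border cells legitimately enter and leave
the field of view and are exempt, as are registered division daughters,
division parents and extrusions), area jumps, positional jumps, internal
gaps, and short tracks. Two details matter:

* an **area jump** must be both relative (ratio above 1.5 — chosen so an
  honest, registered division halving is not suspicious) *and*
  substantive (absolute change at least 10% of the median cell area):
  pure ratios over-fire on small cells where a few pixels of honest
  boundary motion are a large relative change;
* a registered extruding track is exempt from area-jump flags — its
  terminal shrinkage *is* the event;
* a **positional jump** (default threshold 10 px, matching the tracking
  link radius) is the signature of a track-identity swap, which is
  invisible to geometry-only checks.

## Events

Divisions are read off the track table with the same
end-plus-two-nearby-starts rule the tracker uses (so externally imported
tracks work identically), placed in the middle of the two daughters at
their first frame. Extrusions are tracks that end early, away from the
border, not as division parents, with a final area below
`0.25 x` the frame's median cell area — "the apical size decreases when
extruding" made scale-free. The same daughter-area condition
(`<= 0.7 x` parent) applies in the detector: without it, a track that
ends tiny can be claimed as a "division parent" by unrelated nearby
starts, silently deleting an extrusion.

Cross-filtering keeps an event iff an external probability movie exceeds
0.5 anywhere within ±10 px and ±2 frames of it. Filtering is monotone in
the threshold. Fate groups mark terminal tracks only ("Dividing",
"Extruding"); whether a whole lineage should inherit the fate is not
decidable from the sources we follow, and terminal semantics is the
simplest reading.

## Measures

* `area` — pixel count (µm² via `pixel_size`);
* `perimeter` — the larger of the 4-direction Cauchy–Crofton estimate and
  a corrected convex-hull perimeter (hull of the pixel squares minus the
  `4 − π` square-versus-disk offset term). Crofton alone has bounded bias
  on smooth shapes but systematically underestimates axis-aligned
  polygonal boundaries (a 10 x 10 square comes out at 36.8 instead of
  40); the hull term restores polygon lengths for convex cells while
  Crofton dominates for concave ones, since a region's perimeter always
  bounds its hull's. Tests pin the square, disk and regular-hexagon shape
  indices to their closed forms within 5%;
* `shape_index` — `perimeter / sqrt(area)`, the convention of the
  epithelial-jamming literature (not normalised by `2 sqrt(pi)`);
* `orientation` — major-axis angle of the second-moment ellipse, measured
  from the x axis, in `(-pi/2, pi/2]`;
* junctional / cytoplasmic intensity — means over the boundary band of
  width `ring_width = 2` px and over the region eroded by the same band
  (erosion computed from the exact Euclidean distance transform); the
  width is a free choice, exposed as a parameter;
* track features — duration in observed frames, mean per-frame centroid
  displacement, and straightness = net displacement / path length
  (defined as 1 for a zero-length path, so straightness is always in
  [0, 1] with equality only for monotone collinear motion);
* temporal tables report the 0.95 normal-approximation confidence
  half-width `1.96 sd / sqrt(n)` (deterministic, unlike a bootstrap), and
  `NA` when `n < 2`.

`area` and `NbNeighbor` keep those exact column names in every export.

## Evaluation

The four curation metrics compare a movie before and after correction:
pooled skeleton IoU (a single ratio over all frames, not a per-frame
mean — that is what "the binary mask IoU of the exported skeleton movies"
computes), and three signed relative differences with the after-state as
reference: total cell count, mean track duration, mean cell area along
tracks. All four are invariant under label permutation and reach
(1, 0, 0, 0) exactly iff the movies agree up to relabelling. Skeletons
are computed on full frames, without border cropping.

## The synthetic test bed

The simulator generates the regime the curation model assumes, not a
biophysical tissue:

* frame 0 is a power-diagram (additively weighted Voronoi) tessellation of
  Poisson-disk seeds — convex, fat, confluent cells. Weights are the
  handle by which scheduled events steer areas; a weighted-Voronoi cell is
  always convex, so connectivity is guaranteed up to digitisation (rare
  one-pixel slivers are absorbed into the dominant neighbour and the
  affected labels recorded);
* seeds drift by truncated Gaussian steps (`drift_sigma = 0.7` px/frame,
  capped at 2.5 sigma) under an excluded-volume constraint (no two seeds
  closer than half the mean spacing). The drift default is a property of
  the stated world: it keeps honest frame-to-frame fluctuations clearly
  below the default suspicion thresholds, which is precisely the regime in
  which rule-based error flagging is meaningful. At markedly higher drift
  the flags genuinely fire on real dynamics — that is a different tissue,
  not an error of either side. (The default was revised from 1.0
  px/frame when Brownian tail steps proved able to produce rare honest
  area excursions above the flag ratio.);
* a scheduled division grows the cell's area *relative to its neighbours*
  to `pre_division_growth = 1.5` over 5 frames (ramped from the cell's own
  starting ratio), then divides along its long axis (Hertwig's rule). The
  two daughter seeds are created three frames early, still rendering the
  parent's label (mitotic elongation), so the division frame changes
  labels and nothing else; afterwards the inherited footprint is released
  over 4 frames and the sisters are kept area-balanced while they
  separate. All of this exists to make the division frame geometrically
  quiet: neighbours squeezed by growth re-expand smoothly instead of
  snapping back;
* a scheduled extrusion shrinks the apical area geometrically
  (`x 0.6`/frame for 5 frames, chained off the realised trajectory) to a
  near-zero final area, then removes the seed. Extruding cells are drawn
  from the at-most-median-size pool: compaction to near zero inside the
  window is only attainable without pathological per-frame jumps for
  ordinary-size cells;
* events are scheduled at least 2 frames apart and spatially separated
  (about two cell diameters), so steering neighbourhoods never overlap;
* the intensity render is the junction band, Gaussian-blurred, plus
  noise — junction-bright, like an E-cadherin-type marker.

What it does **not** emulate: vertex-model mechanics, realistic lineages,
intercalation, anisotropic flows, imaging artefacts, or any specific
organism's statistics. A green test therefore establishes that the
algorithms are correct *in the regime they define* — resolvable events,
drift below the suspicion scale — not that they are robust to arbitrary
real microscopy.

**Corruption** draws independently per (frame, cell) and injects false
splits (a random chord through the centroid), false merges (absorb the
neighbour with the longest shared boundary), one-frame dropouts, and
track-identity swaps, at 2% each by default. Every injection logs its
parameters and the returned edit script restores the ground truth
bit-exactly — the master property the whole package is tested against.
Exactness imposes real constraints, all enforced by the injector rather
than assumed: merges are only injected between plain equal-weight cells
whose shared boundary is the exact seed bisector (so a nearest-seed split
at the recorded seed positions inverts them), label permutations caused by
earlier swaps are tracked so seed lookups address the right physical cell,
dropout holes are kept 4-disconnected from other background so refilling
floods exactly the lost region, and — when the ground-truth events are
supplied — cells within the probability-filter's spatiotemporal reach of
an event are shielded, so an injected error can never masquerade as a
corroborated event. Each eligible cell is corrupted at most once per
±1-frame window.

## Numerical and interface choices

* Edit scripts are JSON (canonical; seeded splits carry variable-length
  seed lists) with a flat-CSV fallback; replay aborts at the first failing
  operation, reporting its position, with earlier operations applied.
* The correction vocabulary extends the interactive tool-set with
  `fill` (assign a background hole from a seed point) and with explicit
  part labels for `split`: both are required for corruption inverses to be
  expressible, and both are ordinary seed-based local corrections.
* Merged cells keep the smaller id; fresh labels come from a monotone
  counter above the global maximum and are never reused.
* The TIFF codec is deliberately minimal — uncompressed, single-sample,
  strip-organised, both byte orders — because no TIFF-capable R package is
  available in the target environment; it is validated against an
  independent Python reader/writer in the test suite. Anything fancier is
  rejected with a clear error, never guessed at.
* The run configuration file is JSON, mirroring the parameter objects
  (`tracking`, `flags`, `events`, `simulate`, `corrupt`); command-line
  flags win over the file.
* Heatmap exports are plain-text PPM (P3): value-mapped label fills
  without any graphics-device dependency.

## Known limitations

* 3-D (z-stack) label volumes are out of scope; non-confluent movies are
  validated but receive no confluence guarantees.
* `relink_after_edit` resolves competing claims greedily by overlap; a
  pathological edit touching many labels at once may need a full
  `build_tracks()` rebuild.
* The perimeter hybrid assumes cells are convex-ish; for strongly concave
  regions it falls back to Crofton, whose polygon bias then applies.
* The simulator's ground-truth tracks use label = track id; the
  correction operators also handle foreign tables (labels decoupled from
  ids), but identity edits (`swap`, `set_track`) remap movie pixels only
  under the label-equals-id convention.
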