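---
title: "Quantifying single retinal astrocytes and their vascular contacts"
author: "astromorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single retinal astrocytes and their vascular contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astromorph)
```

## The problem

Retinal astrocytes in the nerve fibre and ganglion cell layers tile the inner
retina and mediate neurovascular coupling. When single cells are labelled
through their whole membrane (rather than through cytoskeletal markers such
as GFAP, which cover only about a fifth of the projected cell area), their
morphology turns out to be far richer than the classical stellate picture:
recurring structural motifs (beads, sails, tubes, bristles, pads, end-feet,
membrane holes) contact specific partners — RGC axons, RGC somas, blood
vessels and neighbouring astrocytes — and every cell touches the vasculature
through one of three mutually exclusive connection types (enveloping, mural,
non-enveloping).

`astromorph` implements the complete measurement pipeline for this kind of
data: outline extraction from multi-channel flat-mount stacks, a full- and
convex-hull shape-descriptor set, marker-coverage fractions, vessel
skeletonization with unique-vessel partitioning, per-cell contact statistics
and connection classification, hemispherical retinal coordinates with
eccentricity-trend fits, motif-to-structure association tables, and a 2D
embedding with density clustering over the 20-parameter feature set. Because
single-cell imaging data of this kind is not publicly deposited, the package
ships a synthetic flat-mount generator with analytic ground truth, so every
stage is validated by parameter recovery rather than by eye.

## The synthetic retina and what it does (and does not) emulate

`scene_params()` + `render_flatmount()` build a five-channel Z-stack
(membrane, GFAP-like filament subset, vessels, astrocyte soma,
axon/neuronal) over a branching vessel bed:

* **Vessel bed** — a random tree grown from a field-edge root (default root
  radius 4 µm, 5 branch events, daughter radius ratio 0.75, continuing
  ratio 0.92). At every branch event one daughter *continues* the parent's
  vessel identity and the other starts a *new* unique vessel, so the true
  number of unique vessels is exactly one plus the number of branch events.
  Growth avoids collisions between unrelated branches and drops
  collision-truncated stubs (under 45 px) together with their branch event,
  keeping the rendered bed a tree whose topology matches the recorded truth.
* **Astrocytes** — a radially modulated core polygon plus processes
  (dilated polylines) and planted motifs at the observed length scales:
  bristles at most ~5 µm long (a "smallest bristle" variant spans
  0.7–2.5 µm), sails as polygonal membrane sheets, pads as rounded process
  endings, beads as inflations along thin processes, holes as interior
  voids, end-feet terminating tangent to a vessel, and tubes as sleeves
  that fully enwrap a vessel section. Connection classes are built
  geometrically: enveloping cells are sleeves, mural cells hug a short
  branch-adjacent vessel section with a one-sided band, non-enveloping
  cells abut vessels with their margin or an end-foot. Because every
  observed cell contacts at least one vessel, placement retries until the
  ground-truth contact count is at least one.
* **Soma** — placed at a planted displacement from the convex-hull centroid
  drawn from |N(17.1, 9.1)| µm, the observed soma–centroid separation
  regime, clamped inside the cell.
* **GFAP-like channel** — a filament subset of each cell: the cell skeleton
  dilated inside the mask and trimmed (farthest-from-skeleton pixels first)
  to exactly the target fraction of the cell area, default 21.1%.
* **Acquisition** — 0.5 µm pixels, 0.3 µm Z-steps, five planes with
  per-plane intensity modulation, optional additive Gaussian noise and
  Gaussian blur. There is no point-spread function, no optical sectioning,
  no label chemistry: segmentation difficulty is controlled, not
  photorealistic. Passing recovery tests on these scenes therefore
  demonstrates correctness of the measurement code under controlled
  conditions, not robustness to every real-world imaging artefact.
* **Annotation flags** — each planted motif instance samples its
  contacted-structure flags (axon / RGC soma / astrocyte) from per-motif
  probabilities whose defaults are the observed association-table rates
  (e.g. sails 65/41/6%); tube and end-foot vessel association is
  structural. Scales the association stage is tested against are thus known
  by construction.

Motif size ranges that the source material does not pin down (sails, pads)
are exposed as configuration rather than asserted.

## Ground truth conventions

True shape metrics are computed from a 4× supersampled rasterisation of the
cell polygons, by polygon geometry rather than by the measurement code:
boundary chains are traced, corner-cut smoothed, and measured with the
shoelace formula and an exhaustive pairwise hull search for the Feret
diameter (deliberately *not* the rotating-calipers routine under test). Two
conventions matter:

* **Perimeter scale.** A traced 8-connected chain at acquisition resolution
  is corner-cut once (diagonal steps keep their Euclidean weight), which
  removes most of the ~5% staircase bias of raw chain codes; a digitized
  disk of radius 40 px then measures within ~0.5% of 2πR and its
  circularity is ≥ 0.95. The supersampled truth chain is corner-cut three
  times so that truth and measurement smooth the boundary at the same
  *physical* scale (~1 acquisition pixel); with mismatched scales the truth
  resolves sub-pixel wiggle the measurement cannot see and the comparison
  acquires a systematic offset.
* **Solidity.** Both numerator and denominator are pixel counts: the region
  count over the count of the rasterised convex hull (hull of
  boundary-pixel centres, union with the filled region). This keeps the
  estimator unbiased across resolutions; hulls built on pixel *corners*
  would inflate the denominator by a half-pixel margin whose relative size
  depends on resolution. The Feret diameter, by contrast, uses pixel
  corners, which makes a 30×40 px rectangle measure exactly 50 px across
  its diagonal.

## Measurement pipeline

The outline stage mirrors the standard particle-analysis workflow:
standard-deviation Z-projection, global Otsu threshold (the reference
macro's automatic threshold is unspecified; the method is configurable),
8-connected particle extraction with a 3 µm² lower bound, hole detection as
interior 4-connected background (the standard duality), and XOR composition
of selected outline and hole ROIs into the final complex cell outline. ROI
selection is interactive in the original workflow; `select_regions_at()`
automates it by seeding at a cell's hull centroid.

The GFAP channel is binarised with the Phansalkar local threshold (radius
15 px; k = 0.25, r = 0.5, p = 2, q = 10 — the published constants, since
only the radius is stated in the source workflow), computed over a circular
window with mirror-padded borders on the min–max normalised image, with the
population standard deviation. A pixel is foreground iff
`v > m (1 + p e^{-q m} + k (s/r - 1))`. A constant image is degenerate under
min–max normalisation and comes back all-background.

Shape metrics follow the particle-analysis definitions: circularity
`4π A / P²` (capped at 1), roundness `4A / (π major²)`, solidity
`A / A_hull`, moment-matched ellipse axes rescaled so the ellipse area
equals the region area (with the 1/12 px² pixel-cover term; collinear
regions report a zero minor axis with a warning), an intensity-weighted
centre of mass next to the geometric hull centroid, and marker coverage as
the marker fraction inside the outline.

## Vessels, unique identity and connection classes

Vessel masks are thinned to a medial-axis skeleton (Zhang–Suen, with
residual 2×2 blocks broken and junction spurs shorter than ~3 local radii
pruned), noded with distance-transform radii, and partitioned into *unique
vessels*: at every degree-3 branch node the two most collinear incident
segments continue one vessel and the third starts a new one (a
radius-similarity pairing is available as an alternative). At degree-4+
nodes — coincident branch events — only genuinely collinear pairs
(|cos θ| ≥ cos 30°) merge beyond the first continuing pair, so each extra
daughter keeps its own identity. Cyclic components fall back to one vessel
per inter-branch segment with a warning. On trees this reproduces the
counting identity *unique vessels = 1 + branch events* exactly.

Contacts are counted where the cell mask dilated by 1 px meets the vessel
mask; intersection pixels attribute to the unique vessel of their nearest
centreline node, and only unique vessels count. Contact diameters are twice
the node radius over the contact-supporting nodes.

The three-way connection classification operationalises a visual judgement,
so its thresholds are explicit configuration: the *wrap* statistic is the
occupied fraction of 10° angular bins of cell pixels within two radii of a
centreline node, normalised for the angular cone blocked by the tube itself
(a blocked run counts as wrapped only when the cell occupies both flanks);
per contacted vessel the 80th-percentile node wrap is taken (a wrapped tube
section need not span the whole vessel), nodes adjacent to junctions are
excluded (their cross-sections are ill-defined), and the cell's statistic is
the maximum over vessels. The *on-vessel mass fraction* is the fraction of
cell pixels within `max(2 px, min(local radius, 3 µm))` of the vessel
surface. A cell is enveloping iff wrap ≥ 300° and mass fraction ≥ 0.5, mural
iff wrap ≥ 120° with the same mass condition, otherwise non-enveloping; the
classes are exhaustive and mutually exclusive, and a vessel-free cell is
non-enveloping with a warning. On planted geometry (sleeves, one-sided
junction bands, end-foot-only cells) the classifier recovers the intended
class; borderline blends of these archetypes can land on either side of a
threshold, which is the nature of a thresholded reading of a continuous
quantity.

## Retinal coordinates

The full elastic flat-mount reconstruction used to build native retinal
coordinates from relief-cut tissue is an external tool and out of scope
here. `map_to_sphere()` uses an azimuthal-equidistant model: latitude is
linear in the normalised radial distance from the ONH (ONH at −π/2, rim at
0), longitude is measured so that dorsal is always π/2 and zero is temporal
for left eyes and nasal for right eyes. The dissection rim angle
(φ0 = 22°) is carried in the configuration for provenance but unused by the
simplified model, whose downstream consumers need only latitude and
longitude. Right eyes mirror into common left-eye space by λ → π − λ
(dorsal fixed, latitude unchanged, involutive on the mirror).
`eccentricity_trend()` fits an ordinary least-squares quadratic in latitude
and labels the curvature sign, treating |a| below 10⁻⁶ of the value scale
as flat so that noise cannot masquerade as curvature. The synthetic
eccentricity cohort plants a mid-retina maximum (curvature −800 µm²/rad²
around latitude −π/4 on a 2000 µm² base with σ = 400 µm² noise, n = 500) —
a "slight negative curvature" regime in which the quadratic sign is
recoverable but not trivially so.

## Association statistics and the embedding

`motif_structure_probabilities()` reports p(structure | motif) as exact
instance counts in percent (no smoothing), so `p·n/100` is always an
integer; contacts are non-exclusive, so rows may sum past 100%. The error
column is not defined in the source material; the default is the binomial
standard error of the mean flagged proportion, with the Wilson 95%
half-width as an alternative, and the method used is recorded on the
result. Both instance-level (default) and cell-level denominators are
supported.

The 20-parameter feature matrix keeps the canonical column order (FO
area/perimeter/axes/circularity/Feret/roundness/solidity, CVH
area/perimeter/Feret, latitude and longitude in radians, GFAP coverage,
centroid-to-vessel and centroid-to-centre-of-mass distances, mean/min/max
contacted vessel diameter, unique-contact count). Features are z-scored
before embedding — with µm², radians and percentages in one matrix an
unscaled metric is meaningless — and the scaling choice is recorded in the
metadata. The embedding stage is pluggable by design (the package's own
contract: swapping the reducer or the clusterer leaves all upstream outputs
unchanged): the default reducer is principal components, and the density
clusterer is an in-package HDBSCAN (mutual-reachability distances, minimum
spanning tree, condensed tree, excess-of-mass selection) with
min_samples = 3 and min_cluster_size = 10 and noise labelled −1; k-means is
the alternative backend. Neighbourhood-graph parameters (n_neighbors = 15)
are carried in the configuration and metadata. A fully degenerate feature
matrix (duplicated rows) embeds to co-located points in a single cluster.
No attempt is made to reproduce any particular published embedding geometry
— such embeddings are stochastic and data-dependent; what is tested is
recovery of planted population structure (adjusted Rand index against
generator labels).

`correlation_dendrogram()` clusters the parameters themselves: Pearson
correlations, distance 1 − |r|, average linkage, with zero-variance columns
excluded under a warning and a Newick export of the leaf order.

## Numerical choices and degenerate inputs

* 8-connected foreground with 4-connected holes avoids the classical
  connectivity paradox; components are labelled through a 4-connected pass
  merged across diagonal adjacencies.
* `compose_outline()` on a disconnected XOR result keeps the largest
  component with a warning; an empty selection is an error, as is a
  selection with no non-hole region.
* A single-pixel outline reports the pixel diagonal as both Feret values.
* Distances to vessels subtract half a pixel from the centre-to-centre
  distance transform (clamped at zero) to approximate the mask edge.
* Sub-resolution holes in vessel masks (under 300 px) are filled before
  thinning; they are rasterisation slivers, two orders of magnitude below
  genuine capillary loops at this resolution.
* All randomness is seeded; scene rendering, pipeline runs and the
  embedding are byte-reproducible under a fixed configuration, and the run
  manifest contains a configuration hash and stage counts but no
  timestamps.

## Problem sizes

The bundled tests and the acceptance script run on deliberately compact
problems chosen as the package's own validation sizes: 100 generated cells
for shape recovery, 50 blobs for the caliper oracle, a 64×64 image for the
Phansalkar oracle, 100 random vessel trees for the counting identity,
two 6-cell scenes for contact recovery, 100 Monte-Carlo replicates at
n = 500 for the trend test, and 6–10-cell scenes at 448–512 px for
end-to-end runs. Statistical conclusions at study scale (thousands of
cells) use the cohort generators, which sample the planted regimes directly
without rendering images.

## Known limitations

* The scene is quasi-2D: a planar geometry replicated across few Z-planes.
  Depth-dependent effects (axial PSF, layer separation between astrocytes
  and deeper vasculature) are not modelled, which is why straddled-vessel
  projections must be avoided by construction rather than resolved in z.
* The connection classifier reads a 3D wrapping judgement from a 2D
  projection; its thresholds (300°/120°/0.5 and the 3 µm on-vessel band)
  are explicit, configurable operationalisations, not measured constants.
* The elastic flat-mount reconstruction is replaced by the
  azimuthal-equidistant model; latitudes are comparable within a dataset
  mapped the same way but are not identical to elastically reconstructed
  ones.
* Real immunolabel variability (patchy GFAP, antibody penetration
  gradients) is reduced to a single area-fraction parameter.
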