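---
title: "Quantifying long-range axonal projections of cortical L2/3 neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying long-range axonal projections of cortical L2/3 neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(projquant)
```

## The analysis problem

Single-neuron tracing of cortical projection neurons yields a rooted tree
of 3D sample points per cell, reconstructed section by section and
assembled into one dataset. For layer 2/3 pyramidal neurons of the whisker
barrel cortex (wS1), the scientific questions are quantitative: how much
axonal cable does each neuron place in each long-range target region, which
targets exceed a meaningful threshold, is a given neuron a wS2-projecting
(S2p) or a wM1/2-projecting (M1p) cell, and where — across animals — are
the density hotspots of the population projection centred?

`projquant` implements that chain: SWC I/O and serial-section stitching,
morphometry, bregma-frame region assignment, per-neuron projection
profiles, the thresholded projection matrix, projection-class labels,
cross-animal hotspot centers, and a synthetic-data generator that produces
inputs with exactly known ground truth so every stage can be tested without
any external download.

## Coordinate frames and units

All internal coordinates are millimetres. Three frames are carried on
reconstructions: `bregma` (ml signed, midline 0, left hemisphere negative;
ap positive anterior to Bregma; dv depth from the pia, increasing
ventrally), `injection` (ml/ap offsets from the injection site) and
`section` (per-section local coordinates before stitching). The frames are
related by a rigid translation, `bregma = site + offset`, and the packaged
reference table of hotspot centers carries both column pairs; applying the
transform to the offset columns reproduces the printed bregma columns
within the rounding of the printed means (the test suite asserts 0.015 mm,
and exactness at 0.005 mm for the six pairs that round without loss).

SWC files default to micrometres (the NeuroMorpho/Neurolucida convention)
with a `# UNITS` header override; radii are kept in micrometres as in the
format.

## The region model

The deposited coordinates constrain the *centers* of the projection zones
far better than their boundaries, so regions are modelled as axis-aligned
domains around those centers: cortical columns spanning the full cortical
depth (default 0–2 mm), and a subcortical box for the dorsolateral
striatum (dv 1.5–3.5 mm, ap 0.30–1.70 mm posterior to Bregma). Default
in-plane half-extents are 0.4 mm, with three informed exceptions: wS1 is
sized to the barrel field (1.0 × 1.0 mm), wM1/2 is elongated
antero-posteriorly (half-extent 0.85 mm, matching the reported ~1.98 to
~0.36 mm anterior span of that projection), and TeA is elongated to its
reported ~1.50–2.20 mm posterior span (half-extent 0.35 mm). Every extent
is configuration — `region_model()` accepts arbitrary tables — because any
fixed boundary choice is the dominant uncertainty when comparing per-region
cable lengths against published values.

Overlaps are resolved by explicit priority, with wS1 given the lowest
priority among cortical regions: the dysgranular hotspots (AM, CM, PM) and
the posterolateral zones abut or overlap the barrel field, and where they
do, the more specific region wins. Contralateral cable (ml > 0 for a
left-hemisphere model) falls in no region and accrues to `elsewhere`,
mirroring the common practice of excluding incompletely labelled callosal
axon from regional tallies.

Segment-to-region assignment is analytic: each edge is clipped against
every region's slab interval, split at the boundary crossings, and each
piece accrues to the region owning its midpoint under the priority rule.
Total length is conserved by construction; the tests verify agreement with
a 1 µm dense-resampling oracle and exact conservation on random chains.

## Branching versus passing axon

Target regions receive arborizing collaterals; fibers of passage merely
cross. The literature distinguishes the two qualitatively (an axon that
"does not appear to branch" in a region is not a projection to it) but
gives no formal rule, so the package fixes one: within a region, the
intra-region cable decomposes into connected pieces of the axonal tree; a
piece containing at least one axonal branch point (a node with two or more
axonal children) inside the region counts as *branching* axon, and
otherwise as *passing*. Both tallies are reported per region — users who
prefer a total-cable reading can sum them. Edge pieces that cross a region
without either endpoint node inside it cannot contain a branch node and are
always passing.

Profiles satisfy, and their constructor enforces, the conservation
invariant: branching + passing + elsewhere = total axonal cable to 1e-9
relative.

## Thresholded matrix, classes, core fraction

The projection matrix classifies each (neuron, region) pair by branching
axon length with strict thresholds: `dark` above 10 mm, `light` above 1 mm,
`none` otherwise; boundary values fall to the lower class, and
monotonicity (more cable never demotes a class) is property-tested. The
S2p/M1p label compares only wS2 and wM1/2 branching cable — the criterion
used when a retrogradely labelled neuron turns out to project predominantly
to the other target — with exact ties (including both zero) left
`unclassified`. The core fraction is the share of branching axon in
wS1 + wS2 + wM1/2. Group summaries use the sample (n−1) SD and flag it
`NA` for single-member groups.

## Serial-section stitching

Tracings arrive as per-section fragments. The stitcher offsets each
fragment's depth by section index × thickness (0.080 mm for single-cell
material, 0.100 mm for viral material), inverts the per-section in-plane
shift recorded in the manifest, and joins cut endpoints: a fragment root
lying on a section face is connected under the nearest node on the matching
face of the adjacent section within the merge tolerance (default 5 µm).
Nearest wins among multiple candidates; an exact distance tie is an error
rather than a silent choice, and endpoints with no partner inside the
tolerance are reported (`projquant_unmerged_error` carries the endpoint
table) instead of being joined. Registration is rigid per-section in-plane
translation only — the provenance of real alignment offsets is outside the
package's scope, so they are inputs via the manifest, not estimated.

Because cut points are inserted exactly on section planes, sectioning
conserves cable to floating-point precision, and a split-then-stitch round
trip recovers total cable and branch-point counts exactly when the jitter
is recorded; the acceptance suite checks 20 random neurons at 80 µm with
±20 µm jitter against a 0.5% band.

## Hotspot-center estimation

Density volumes hold cable length per voxel (default 0.05 mm isotropic),
filled by analytic clipping of segments against the grid (mass conserved to
1e-6 relative, out-of-bounds cable counted and warned). Centers are
estimated on depth-collapsed (horizontal) maps, since the reference
coordinates are ml/ap only.

`find_hotspot_center()` implements the basic estimator: Gaussian-smooth
(default σ 0.1 mm), then the density-weighted centroid of pixels at or
above 50% of the window peak. Both parameters are configurable; with two
equal blobs in one window the centroid is documented to fall midway
(narrow the window, or pass `connected = TRUE` to keep only the peak's
connected support).

`aggregate_centers()` — the cross-animal procedure — has to cope with
eleven interacting hotspots whose positions scatter between animals, and
three refinements proved necessary in planted-recovery simulations:

1. **Nominal seeds.** The search for each region starts from a nominal
   center supplied via `seeds` (defaulting to the region-box centers). The
   striatal box center, for instance, sits ~0.4 mm from the striatal
   density peak, so seeding at box geometry misassigns.
2. **Joint matching.** Per animal, all local maxima of the smoothed map
   are detected once and matched to the region seeds one-to-one,
   minimizing the total squared *Mahalanobis* distance under each seed's
   scatter SDs (floored at 0.05 mm). This is the MAP assignment under a
   Gaussian scatter model; it matters because scatter is strongly
   anisotropic (the AM hotspot wanders ±0.35 mm in ap but only ±0.09 mm in
   ml, so Euclidean matching crosses AM with its neighbours). Matches are
   restricted to each region's search window, which widens to 3 scatter
   SDs beyond the region box when SDs are supplied.
3. **Bounded fallback.** When a region's blob merges into a neighbour's at
   the smoothing resolution it has no maximum of its own; the seed then
   falls back to the most plausible shared maximum if the match is within
   ~5 combined SDs, else the animal is dropped for that region (a region
   with no signal in any animal is omitted with a warning). The final
   per-animal center is the 50%-support centroid around the matched
   maximum, restricted to pixels nearer that maximum than any other — a
   watershed-style cut that stops a close neighbour's shoulder from
   dragging the centroid.

Smoothing bandwidth should not exceed the spatial scale of the structure
being localized: the synthetic volumes plant compact hotspot cores
(σ 0.05 mm), so the recovery analyses smooth at 0.05 mm; the 0.1 mm
default is kept for image-derived densities, whose speckle calls for more
smoothing. Because averaging is linear, the bregma-frame and
injection-frame means differ exactly by the injection-site coordinates,
which the tests assert to 1e-12.

## The synthetic generator

The generator emulates the statistical structure of the study material —
not its biophysics. A neuron spec fixes: soma in wS1 at 200–250 µm depth;
total dendritic length (default 8.1 mm) on a given number of stems
(default 8, one written as apical) with a given number of branch nodes
(default 64), all hit exactly by construction; local wS1 axon (default
41.7 mm); and a list of collaterals, each placing an exact cable length
strictly inside its target region — arborized (branching) or as an
unbranched fiber (passing). Arbors are fixed-step random walks confined to
a box verified, point by point with the containment oracle, to be owned by
the target region; the generator fails loudly rather than return a wrong
ground truth.

Collateral trunks descend from the soma through a shaft column (grid-picked
so the column is wS1 territory down to the cortical floor and unclaimed
below it), run along a deep fiber corridor 0.5 mm below every modelled
region, and rise into each target from below. Trunk geometry is irrelevant
to every measured quantity as long as it avoids other regions, which the
construction guarantees; the wS1 plumbing is deducted from the local-axon
budget so planted wS1 cable is exact, and everything below the cortex
lands in `elsewhere`. The ground-truth profile is assembled from this
bookkeeping, never by running the analyzer — the generator/analyzer
agreement (to 1e-6 mm and better) is the pipeline's central
cross-validation.

Cohorts draw per-region lengths from zero-inflated truncated normals, the
distribution family suggested by cell-by-cell target matrices in which
most neurons have exactly zero cable in most secondary targets but
occasional large projections. Default class parameters follow the study
conditions: 6 S2p and 9 M1p neurons; S2p with wS2 cable 12.2 ± 7.4 mm and
never any wM1/2 cable; M1p with wM1/2 cable 20.8 ± 11.7 mm and wS2 cable
1.6 ± 2.7 mm present in a minority of cells; occasional striatal, TeA, CM,
PM and PL projections at rates reflecting how often individual
reconstructed neurons showed them (e.g. one strongly striatum-projecting
cell per group). Draws below 0.05 mm of planted cable are treated as no
projection — below any measurable interest and below the feasibility of
planting an arbor. Dendritic and local-axon parameters use the reported
group means and SDs. Because an M1p-labelled draw can legitimately come
out with more wS2 than wM1/2 cable, the planted class labels returned for
validation are computed from the planted profiles by the same rule the
classifier uses; classification accuracy is therefore a statement about
the pipeline, not about the sampler.

What the generator does **not** emulate — tortuosity, radius taper,
laminar structure of local axon, callosal projections, tissue shrinkage,
tracing errors other than in-plane section jitter — bounds what passing
tests show: they validate the measurement chain on geometrically clean
trees, not robustness to tracing noise in real material.

## Numerical choices and degenerate inputs

- Internal unit mm; SWC written in µm at six decimals (1e-9 mm), which the
  round-trip tests rely on.
- Missing radii are written with a 1.0 µm sentinel.
- The root parent sentinel is −1; a soma may be a single point; soma
  nodes must form a connected subgraph containing the root.
- Multifurcations count once as a branch point (nodes, not child pairs).
- Thresholds are strict inequalities; boundary lengths fall to the lower
  class.
- Stitch merge ties at exactly equal distance raise an error; all other
  competition is resolved nearest-first, one partner per endpoint.
- Region-boundary clipping uses closed boxes; a point on a shared face
  belongs to the higher-priority region.
- `core_fraction` on an all-zero profile is an error (`undefined-result`),
  not `NaN`.
- All generators accept integer seeds and restore the caller's RNG state;
  identical seeds give bit-identical output.

## Validation scale

The shipped checks run at desk scale: conservation on a 100-neuron cohort,
planted-truth recovery and classification on the study-sized 6 + 9 cohort,
the split/stitch round trip on 20 neurons, and hotspot recovery on 5
simulated animals at the reference scatter — a few minutes end to end.
These sizes are the package's validation design, chosen to match the
study's own group sizes where they exist.

## Known limitations

- Region boundaries are modelled, not measured; per-region cable lengths
  on real data inherit that choice, and only boundary-independent metrics
  (dendritic morphometry, total axon length) are comparable across
  boundary conventions without care.
- Stitching assumes translation-only section alignment and cannot recover
  rotations or nonlinear deformations.
- Hotspot estimation assumes approximately isotropic, unimodal hotspot
  cores; two blobs closer than about twice the effective smoothing scale
  are unresolvable, and the per-animal estimate then degrades to the
  merged centroid (bounded by the fallback cap).
- Laminar analyses, curved-cortex coordinates and atlas registration are
  out of scope; coordinates are axis-aligned bregma-frame throughout.
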