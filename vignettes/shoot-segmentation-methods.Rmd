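---
title: "Methods: organ-level segmentation of single-shoot point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-level segmentation of single-shoot point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shootseg)
```

## The problem

A 3D point cloud of a potted plant shoot — one stem with attached leaves,
possibly a tassel, ears and the pot — arrives as an unordered set of `x y z`
points with no semantic information. Organ-level phenotyping (leaf length,
ear height, tassel branching) and the construction of training data for
learned point-cloud segmentation both require every point to carry an organ
instance label. Fully automatic segmentation remains unreliable for shoots
with overlapping or wrapped organs, so the practical workflow is
semi-automatic: a user supplies a few unambiguous anchor points (the stem's
bottom and top, optionally organ tips), and the rest is computed.

`shootseg` implements that computational core as a scriptable library plus a
thin command-line driver. A shoot with `n1` ears and `n2` leaves is
partitioned into `N = 3 + n1 + n2` instances; instance 1 is always the stem
and the pot, when present, is instance `N`. The pipeline maintains an exact
partition between the unsegmented set and the instance sets and is finished
when the unsegmented set is empty.

## Stem segmentation

Given user endpoints `s0` (bottom) and `sn` (top) and a radius `r1`, a
median-directed region grower walks a seed point from `s0` toward `sn`. At
each step all points within `r1` of the seed become stem points; the seed
then advances by `r1` along

```
v_k = (alpha * v1 + beta * v) / || alpha * v1 + beta * v ||
```

where `v` is the unit direction to `sn` and `v1` is the renormalised
componentwise median of the unit vectors from the seed to the already-grown
stem points. Growth stops when the seed's projection leaves the segment
`[s0, sn]`. The defaults `alpha = 0.2`, `beta = 0.8` matter: `beta`
dominates so the walk always makes progress toward `sn`, while the `v1` term
acts as a negative feedback on lateral drift — if the seed strays off the
stem axis, the median direction toward the grown points pulls it back. (We
verified the sign experimentally: with `v1` pointing *away* from the grown
points the feedback becomes positive, the seed path spirals away from a
bowed stem, and ~15% of the stem surface is missed.)

`r1` should be chosen generously — about twice the stem's bottom radius —
because sphere coverage must overlap across the whole tapering, possibly
bowed surface. Over-capture of leaf bases is then removed by the median
trim: stem points are binned into `M` equal-length segments along
`sn - s0` (default `M = 10`), a total-least-squares axis is fitted per bin,
and only points strictly closer than the bin's mean point-to-axis distance
are kept. Note the strict mean rule removes roughly half of a clean
cylindrical shell per application — this deliberate under-segmentation is
harmless because trimmed points return to the unsegmented pool and are
re-attached to the stem instance during coarse assignment, which is also why
stem recall should be judged after the full pipeline, not after the trim.

## Shoot alignment

The shoot is moved into its own frame so that "higher" means "greater z":
origin at the centroid of the stem points, Z along the stem's first
principal direction (sign fixed by `sn - s0`), and X/Y the principal
components of all points projected onto the plane normal to Z. PCA signs are
inherently arbitrary; we fix X so the highest shoot point has a nonnegative
first score and take `Y = Z x X`, giving a proper rotation and a
deterministic frame. The frame is fitted from the *trimmed* stem set, after
the median operation, since that set is the cleaner axis sample.

## Coarse segmentation

Points strictly below the lowest stem point are classified as pot. Organ
seeds are then the organ highest points. The detector assumes — as the
interactive workflow does — that the highest points of any two organs are
more than 5 cm apart (`min_sep = 50` mm). A candidate seed must be a z-local
maximum at that scale (no higher point within `min_sep`), which directly
rules out any point overtopped within 5 cm; greedy non-maximum suppression
in descending height then enforces pairwise separation. Seed candidacy
excludes the entire *grown* stem column (not just the trimmed set), because
trimmed-out shell points at the stem apex would otherwise masquerade as
organ maxima. Detected seeds get instance ids from 2 downward in height
order; user-supplied seeds (CLI `--seeds`) bypass detection and are snapped
to the nearest eligible cloud point.

Every remaining point is assigned top-down (descending z, ties by index) to
the instance whose nearest member is closest under the entropic
optimal-transport distance. The transport plan of the participating cloud
onto itself is computed once by Sinkhorn matrix scaling on
`K = exp(-eps * H)`, `H` the pairwise-distance matrix scaled by its maximum,
with uniform masses `1/n`; the OT distance between points is the reciprocal
of the plan mass, `D_s(u, v) = 1 / m_uv`, so a point's nearest instance
member is the member receiving the most mass. Assignment is sequential:
instances grow as the sweep descends, so high points recruit the points
below them — the mechanism that keeps a wrapped leaflet attached to its own
tip rather than to the big leaf around it.

Parameters and numerical choices:

* `eps = 5` (default). Smaller `eps` smooths transport toward dense
  regions; larger `eps` approaches plain Euclidean nearest-instance
  assignment.
* Sinkhorn stops when the scaling vector changes by less than `1e-9`, with
  a 10,000 iteration cap (warning on hitting it). At `eps = 5` convergence
  takes a few dozen iterations; a kernel underflow (only possible at
  extreme `eps`) switches to an equivalent log-domain scaling.
* The plan is quadratic in the participant count, so stem and pot — already
  populated with hundreds of points each — are represented by at most
  `plan_cap = 500` evenly spaced members. All unsegmented points and all
  seeds always participate.
* The Euclidean variant (`method = "euclidean"`) runs the identical
  sequential sweep with Euclidean point-to-member distances.

A property worth stating precisely: the converged plan factorises as
`m_uv = h_u K_uv z_v`, so within a row the OT ranking is
`argmax_v K_uv z_v`. As `eps` grows the `K` factor dominates and the
ranking converges to the Euclidean one, but the density-carrying `z_v`
factor never vanishes at finite `eps`: two instances whose competing
nearest-member distances differ by less than about
`diameter * log(z-ratio) / eps` can still rank differently. At `eps = 200`
on synthetic shoots this amounts to a handful of stem/leaf junction points
per shoot (we observe exact label agreement on most shoots and ~99.6%
agreement on the rest, unchanged by running Sinkhorn to full convergence).
Exact equality with the Euclidean variant at large `eps` should therefore
be expected as a strong tendency, not a theorem.

## Fine segmentation

Coarse results are refined inside a user-chosen region of interest among
`n > 1` instances by minimising

```
E(f) = gamma * sum_p D_p(f(p)) + sum_(p,q) V(f(p), f(q))
```

over the symmetrised k-NN graph (default `k = 10`) of the ROI plus the
per-instance seed sets, with seeds pinned to their labels. `D_p(i)` is the
Euclidean distance from `p` to the nearest point of seed set `i`, and

```
V = (d(p,q) / d')^tau * (a(n_p, n_q) / pi)^phi
```

is charged only when the edge's labels disagree (Potts gating: charged
unconditionally it would be a labeling-independent constant and could not
encourage spatial consistency). `d'` is the largest graph edge, putting the
distance factor in `(0, 1]`; the normal angle is folded to `[0, pi/2]` via
`a = acos(|n_p . n_q|)` since normal orientation is arbitrary, while the
`pi` denominator is kept. Defaults `gamma = tau = phi = 1`. As printed, a
larger fold angle makes a cut *more* expensive, so with `phi >= 1` the
optimiser pushes label boundaries toward creases by cutting edges that are
long relative to `d'` and — among short edges — those with small angle
terms; the crease test in the suite confirms boundary edges carry larger
normal angles than interior ones.

The energy is minimised by alpha-expansion: labels are cycled in id order,
each binary "switch to alpha" subproblem is the exact minimum cut of a
directed graph (all pairwise terms are submodular because `V >= 0` and the
gating is metric), and a move is accepted only when it strictly lowers the
energy. The expansion reaches a local optimum with respect to expansion
moves; on small instances (up to 8 free points, 3 labels) it matched the
exhaustive minimum in all 125 random instances we test. Normals come from
the cloud or are estimated as the least-variance principal direction of
each point's k-neighbourhood. A bulk shortcut, `assign_label_direct()`,
moves an entire ROI into one instance without solving anything.

## Sample-based segmentation

For efficiency the pipeline recommends working below ~15,000 points
(default simplification target 13,000). Voxel simplification keeps, per
occupied voxel, the member point nearest the voxel's point centroid — a
real input point, so labels stay meaningful and the sparse cloud is a
subset of the dense one (which makes k = 1 label transfer exact on the
representatives). After segmenting the sparse cloud, each dense point takes
the majority label of its `k = 5` nearest sparse neighbours; ties go to the
nearest neighbour's label when it is among the tied labels, else to the
smaller id. The voxel edge is chosen by bisection to land at or below the
target count.

## Evaluation

`evaluate_segmentation()` compares two labelings of the same cloud:
per-instance precision/recall/F1 from the confusion matrix; shoot-level
precision and recall as unweighted means over instances; macro-F1 the mean
per-instance F1; micro-F1 the F1 of pooled precision and recall, which for
two partitions over one id set equals overall accuracy (asserted on random
labelings in the suite). Because independently produced labelings number
their instances arbitrarily, `matching = "hungarian"` first maps predicted
ids onto reference ids by maximum-weight bipartite matching on the
confusion matrix; unmatched predicted instances keep fresh ids and
contribute zero precision, so inventing instances is penalised.

## The synthetic generator, and what a green test establishes

`generate_shoot()` produces the ground truth every test relies on: a
tapered, slightly bowed stem (800 mm, 12 to 6 mm radius, 8 mm bow); 4-15
leaves attached at increasing heights with alternate 180-degree phyllotaxy
plus azimuth jitter, each a tapering ribbon on a parabolic height profile
(rising then drooping, so lower leaves peak mid-blade); optional tassel
(central spike plus short steep branches, all tips within the 5 cm
suppression radius of the spike), ear (ellipsoid against the mid stem) and
pot (disk plus wall, with a 40 mm soil clearance below the stem base so a
generous `r1` cannot swallow the rim); 1 mm Gaussian coordinate noise
approximating multi-view-stereo jitter; 250 points per organ (~3,000 per
shoot). Organ highest points are kept pairwise more than 50 mm apart by
construction — the generator refuses geometries violating the separation
assumption rather than silently producing them. Stem endpoints returned to
the pipeline are the lowest and highest stem *samples*, i.e. the points an
annotator would click.

The generator states the world the tests live in; it does not imitate the
failure modes of real scans. Real shoots bring reconstruction noise far
from Gaussian, incomplete surfaces, touching organs that violate the 5 cm
assumption, and senescent drooping leaves below the pot rim. A green suite
therefore establishes that the algorithms are implemented correctly and
behave as designed under their stated assumptions — not that any accuracy
figure transfers to field data. Denoising is explicitly a prerequisite, not
a feature of this package.

## Known limitations

* Single-stem shoots only; tillered plants are handled by choosing one stem
  and seeding each tiller top as an organ.
* Automatic seed detection can miss an organ whose highest point is
  overtopped within 5 cm by a neighbouring organ's blade; the CLI's seed
  file exists precisely for such cases.
* Exact ε-limit equivalence between OT and Euclidean assignment fails for a
  small number of junction points (see above).
* The n x n transport plan bounds practical cloud sizes; the simplify /
  upsample pair is the intended route for dense scans.
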