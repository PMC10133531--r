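---
title: "Geodesic patch descriptors for molecular surface comparison: models and methods"
author: "SurfaceMatch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geodesic patch descriptors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(SurfaceMatch)
```

# The problem

Protein function is carried by the molecular surface: the chemistry and
shape a molecule presents to its binding partners. Two proteins with
unrelated sequences and folds can present near-identical local surface
regions — and hence share function — which sequence alignment and global
structural superposition both miss. SurfaceMatch compares proteins at the
level of *surface patches*: fixed-radius geodesic neighborhoods of a
triangulated molecular surface, encoded into fixed-dimension descriptors by
a geodesic convolutional network trained with a self-supervised contrastive
objective. Descriptor distance then drives region search, interface
similarity scoring, epitope/paratope clustering, and rigid alignment of
matched regions (e.g. to graft an antibody onto a new antigen as a design
template).

# Surface construction and featurization

**Mesh.** The surface is the isovalue-`exp(-2)` level set of a Gaussian
atom density, `f(x) = sum_i exp(-|x - a_i|^2 / (2 w_i^2))` with per-atom
width `w_i = (r_i + probe)/2`, extracted by marching *tetrahedra* on a
regular grid (spacing = `targetEdgeLen`, default 1 Angstrom). With this
calibration a lone atom's surface is exactly the sphere of radius
`r_i + probe`, i.e. the solvent-accessible sphere at the default 1.4
Angstrom probe. Marching tetrahedra was chosen over marching cubes because
its case table has no ambiguous configurations: the output is watertight
and manifold by construction, which the `SurfaceMesh` validity and
`isWatertight()` assert on every build. Only the largest connected
component is kept (interior cavities are dropped). Mesh resolution is
controlled by the grid spacing rather than post-hoc decimation — the
downstream method only needs a smooth featurized manifold, not a specific
triangulation. Faces are wound counter-clockwise seen from outside; vertex
and face indices are 1-based inside R (PLY files on disk use the format's
0-based indices).

**Geometric channels.** Per-vertex principal curvatures come from the
cotangent-Laplacian mean-curvature normal and angle-defect Gaussian
curvature with barycentric vertex areas; `shape_index = (2/pi)
atan((k1+k2)/(k1-k2))` in [-1, 1] (convex sphere +1, cup -1; umbilic points
get `sign(k1)` rather than NaN) and `mean_curvature = (k1+k2)/2` in 1/Angstrom.

**Chemical channels.** `charge` is a screened point-charge sum
`sum q_j/(1+d^2)` over atoms within 8 Angstrom, with a small built-in charge
set (ionizable side-chain termini carry split formal charges, the backbone
amide a small dipole). This is deliberately *not* a Poisson–Boltzmann
potential: the channel is standardized per protein anyway, and a
desk-scale, dependency-free field preserves the sign structure the encoder
consumes. `hydropathy` is the Kyte–Doolittle value of the nearest atom's
residue; `hbond` is +1/-1/0 from the nearest heavy-atom hydrogen-bond
donor/acceptor within 3 Angstrom (nitrogens donate, carbonyl/carboxylate
oxygens accept, hydroxyls are left neutral as they do both; if hydrogens
are present in the input they are kept but no protonation is attempted).
Chemical channels are z-scored per protein — patch-based systems
standardize per surface so that every protein contributes comparably — and
the statistics are recorded in the mesh metadata. `shape_index` is left on
its natural bounded scale and `mean_curvature` in physical units.

# Patches, polar coordinates, and the soft grid

A *patch* is every vertex within geodesic radius 6 Angstrom of a center —
the method's minimum similarity unit. Geodesic distances are Dijkstra
shortest paths on the mesh edge graph; at the default ~1 Angstrom edge
length the graph metric overshoots the true geodesic by under a few percent
(the planar test quantifies the worst case as the axis-vs-diagonal ratio,
about 1.41 on a grid mesh; on the near-uniform triangulations the package
produces it is far smaller), which is negligible against a 6 Angstrom
radius. The angular coordinate theta is the angle of the vertex projected
into the tangent plane at the center, with the zero direction along the
projected edge to the lowest-index neighbor — a deterministic but arbitrary
origin. We chose tangent-plane projection over unrolling the triangle fan
because it is exactly rigid-motion equivariant, equals the planar angle in
the flat limit, and is cheap for thousands of patches; the origin
arbitrariness is absorbed by the encoder's rotation max-pooling either way.

Patch vertices are projected onto a polar *soft pixel grid* of 5 radial x
16 angular = 80 bins with Gaussian kernels (wrap-around angular
difference); each vertex's weight row is normalized to a probability
distribution, and each bin pools the weighted mean of its vertices'
features. The kernel widths default to half a bin spacing. They are stored
on the `SoftGrid` and are configurable, but the trainer holds them fixed:
freezing the front end lets every patch's pooled grid be computed once,
which is what makes CPU training in R practical. This is a re-specification
of the original design, which describes the kernel parameters as learnable.

# The encoder and the contrastive objective

The network is: two per-bin 1x1 linear layers (C -> 32 -> 32 filters,
ReLU), then a full-grid linear layer (80x32 -> 64) evaluated at all 16
discrete angular rotations of the bin grid with element-wise max over
rotations (so the descriptor is invariant to the theta origin, exactly so
for whole-bin shifts), then a linear head to D = 80. All layers are plain
matrix algebra with hand-written backpropagation (verified against
numerical gradients in the test suite) and Adam (lr 1e-3).

Training is self-supervised: on each surface, 100–200 anchor centers are
sampled; a *positive* is a center within 1.5 Angstrom of the anchor
(overlapping patches describe the same local region) and *negatives* are
centers beyond 5 Angstrom (4 per anchor). The loss is the margin hinge

```
L = ||a - p||^2 + sum_n max(0, m - ||a - n||)^2,   m = 5,
```

the margin echoing the 5 Angstrom spatial cutoff. Data are split at the
*structure* level (no surface contributes patches to two splits; violating
this is a hard error), with full-scale default split sizes 2700/100/50
structures and desk-scale sizes in the tests (40/4/6 surfaces of 2562
vertices, 100 patches each). Model selection and early stopping use the
validation contrastive loss; we initially used the validation
positive/negative separation, but it saturates within two epochs while the
quantity that matters downstream — the low tail of unrelated-pair
distances, which sets the false-hit rate at the search cutoff — keeps
improving with the loss.

`pairwiseDistanceReport()` summarizes a trained model on held-out
structures: the positive and negative distance distributions (bimodal for a
trained model), their overlap coefficient, the ROC-AUC of separating them
by distance, and a suggested threshold at the equal-density crossing — a
data-driven analogue of choosing an operating point from the distance
histogram. The search module's default cutoff stays at the standard
operational value 3.5 regardless.

# Search, grouping, and scores

`findHits()` is an exact all-pairs search: every (query, candidate)
descriptor pair within distance 3.5. `groupHits()` assigns each query
vertex to its best hit (ties to the lowest candidate index), connects best
hits whose query vertices are within 3 Angstrom *and* whose candidate
vertices are within 3 Angstrom (we require connectivity on both surfaces —
the main text does not say which side, and one-sided grouping lets a
contiguous query region match scattered candidate fragments), takes
connected components, discards components with fewer than `minGroupSize`
(default 8, mirroring the minimum patch size; 2 reproduces the bare
singleton-discard rule), and extends surviving groups by all vertices
within geodesic 6 Angstrom. Components are computed over the per-vertex
best hits rather than all hits because the all-hit graph is quadratic in
the number of hits (10^10 adjacency entries at planted-pair scale) while
the best-hit graph is quadratic in vertices; the vertex-assignment rule is
the same either way.

Scores: the *reciprocal-mean* similarity of a group is `ss = 1/(1 + mean
d)` over its correspondences, mapping [0, inf) distances onto (0, 1]
without a singularity (the source phrase "reciprocal means of the
descriptor distances" is ambiguous between `mean(1/d)` and `1/mean(d)`;
we chose the bounded form and do not claim to reproduce any externally quoted value). The *joint* interface score is the exact product
`SS = ss_AB * ss_A'B'` over the two sides of an interface pair. The
*coverage ratio* is the fraction of an interface's vertices covered by any
extended group — the clustering metric; `allVsAll()` builds the symmetric
(mean of both directions) coverage matrix over a set of interfaces and
clusters it by average linkage on 1 - score with a configurable cut.

**Reported matches.** `filterGroups()` keeps a group only when it is
supported by at least one patch-unit's worth of matched centers (the
median patch vertex count of the query mesh, estimated on a seeded vertex
sample). A continuous embedding plus any nonzero chance-match rate always
produces a few small connected hit clusters somewhere on the candidate
surface, and the geodesic extension inflates even a handful of such hits
into a visible blob; a region-level claim backed by less than one patch of
evidence is below the method's resolution and is treated as a descriptor-
space coincidence. This is the package's realization of reporting only
hits "with reasonable scores"; the group-mean score itself does not
discriminate in our synthetic conditions because a genuine region's rim
correspondences are as noisy as chance matches.

# Rigid alignment

`alignRegions()` centers both point sets and minimizes RMSD over rotations
by gradient descent on an axis-angle parameterization (numerical central-
difference gradient; adaptive step size, growing 1.2x on improvement and
halving on failure; 8 restarts including the identity; up to 500 steps),
keeping the best restart and never returning worse than the centroid-only
RMSD. The closed-form Kabsch superposition (`kabschAlign()`) is the
internal oracle: on random correspondence sets with and without 0.2
Angstrom noise the gradient-descent optimum matches it to well under 1e-3
Angstrom. We kept the descent-based optimizer as the primary path because
the procedure is defined as rotational sampling with gradient
descent; the oracle guards its correctness regardless.

`alignGroups()` applies the alignment to every reported group and, by
default, prunes it to rigid consistency: correspondences whose post-
alignment residual exceeds 2 Angstrom (the same closeness criterion the
alignment score uses) are dropped and the group's vertex sets rebuilt and
re-extended. This matters because best-hit connectivity can chain: each
step of the chain satisfies the 3 Angstrom neighbor rule on both surfaces,
yet over many steps the candidate side can drift far from the rigidly
matched region. The alignment is exactly the independent geometric check
that exposes such drift — its role as a second similarity score
that filters weak hits. `graftComplex()`
applies the resulting transform to a bound partner structure and
`clashReport()` counts interatomic contacts below a cutoff as a diagnostic.
The exported `alignmentScore` (fraction of correspondences within 2
Angstrom after alignment, damped by 1/(1+RMSD)) is the package's own summary score for
ranking alignments; no equivalence to any externally defined score is
claimed.

# Synthetic study conditions

All tests run on generated data; the generators are seeded and bitwise
reproducible.

* `makeIcosphere()` / `makeBumpySphere()` — subdivided icosahedra (10*4^s+2
  vertices) with seeded Gaussian bumps and dents (default 12 bumps,
  amplitude up to 1.5 Angstrom, width ~2 Angstrom on a 10 Angstrom sphere,
  subdivision 4 = 2562 vertices, ~0.75 Angstrom edges — fine enough that
  positive centers exist within 1.5 Angstrom).
* `makeCorrelatedFeatures()` — per-vertex Gaussian noise diffused over the
  mesh graph (steps = correlation length / mean edge length, default 3
  Angstrom) and re-standardized: smooth fields whose spatial coherence is
  the property the contrastive objective relies on.
* `makePlantedPair()` — two bumpy spheres sharing one cap (geometry and
  features copied, blended over a 2 Angstrom margin, feature noise
  configurable), the second mesh displaced by a seeded rigid transform
  recorded as ground truth. The default cap radius is 12 Angstrom — twice
  the patch radius — because a query patch is only fully contained in the
  planted region when its center is more than one patch radius inside it;
  a cap smaller than the patch diameter contains no truly matching patch
  and the construct would be vacuous.
* `makeToyPeptide()` — a jittered extended pseudo-backbone written as
  fixed-column PDB text, for end-to-end preprocessing tests.

What the synthetic conditions do *not* emulate: real side-chain chemistry
and its correlations between channels, surface self-similarity of real
folds, crystallographic noise, and the scale of real benchmark datasets
(thousands of structures). Passing tests therefore demonstrate the
correctness and internal consistency of the machinery and its behavior
under controlled similarity, not benchmark performance on real proteins.

# Numerical choices and degenerate inputs

* Isosurface grid values exactly at the isovalue are nudged by 1e-12 to
  avoid degenerate triangles; faces are oriented by the analytic density
  gradient.
* Vertices farther than 10 Angstrom from every atom inherit the globally
  nearest atom's features, with a warning.
* Patches with fewer than 8 vertices raise a "too sparse" error; umbilic
  curvature points get shape index ±1; soft-grid rows are normalized with
  a max-shift to guard underflow.
* Degenerate alignments (fewer than 3 points, collinear or non-finite
  input) are errors; `alignGroups()` maps them to score 0 instead when
  scoring whole group lists.
* An all-equal distance report yields `threshold = NA` with an explanatory
  note rather than a number.

# Problem sizes

The default test and acceptance runs use 50 surfaces of 2562 vertices with
100 patches each (training: 40 surfaces, ~3 minutes per seed on one CPU),
planted pairs at the same resolution, 100 random alignment instances, and
20 meshes of 162 vertices for the exhaustive geodesic oracle. These sizes
were chosen so the complete suite exercises every pipeline stage at
full fidelity while remaining a desk-scale computation.

# Known limitations

* The simplified charge model ranks charge patterns; it does not
  approximate electrostatic potentials quantitatively.
* Dijkstra geodesics overestimate true geodesics by the graph-metric
  factor; heat-method or exact polyhedral geodesics are out of scope.
* The encoder is a small CPU network; no externally trained weights are
  used, and descriptor values are not comparable
  across differently-trained models (descriptor containers carry a model
  hash so searches can refuse mismatched inputs).
* mmCIF input, NMR multi-model handling beyond the first model, glycans,
  ligands, and protonation-state prediction are out of scope.
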