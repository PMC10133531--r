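# SurfaceMatch

Protein function lives on the molecular surface: the local shape and
chemistry a molecule presents to its partners. Proteins with unrelated
sequences and folds can still display near-identical *surface regions* —
a viral protein mimicking a host ligand, two inhibitors sharing a binding
face — and both sequence alignment and global structure superposition miss
this. SurfaceMatch is an R package for finding, scoring, grouping and
rigidly aligning similar surface regions between proteins. It is aimed at
structural bioinformaticians working on interface classification,
epitope/paratope clustering, and surface-guided antibody discovery.

## The method

1. **Surface build.** A watertight triangle mesh is extracted from a
   Gaussian atom-density isosurface (marching tetrahedra; a lone atom
   yields the sphere of radius *r* + probe). Each vertex carries five
   channels: shape index *s* = (2/π)·atan((κ₁+κ₂)/(κ₁−κ₂)) ∈ [−1, 1],
   mean curvature (κ₁+κ₂)/2, a screened partial-charge sum Σ qᵢ/(1+dᵢ²),
   Kyte–Doolittle hydropathy, and a hydrogen-bond donor/acceptor class;
   chemical channels are z-scored per protein.
2. **Patches.** A patch is every vertex within geodesic radius 6 Å of a
   center, in local polar coordinates (ρ = geodesic distance, θ =
   tangent-plane angle), projected onto a 5 × 16 polar *soft pixel grid*
   with Gaussian kernels.
3. **Descriptors.** A geodesic convolutional encoder (per-bin 1×1 filters,
   max-pooling over 16 discrete grid rotations, linear head to D = 80)
   embeds each patch. Training is self-supervised and contrastive: patches
   whose centers lie within 1.5 Å are pulled together, patches beyond 5 Å
   pushed past a margin *m* = 5:

   L = ‖a − p‖² + Σₙ max(0, m − ‖a − n‖)²

4. **Search & scores.** Hits are descriptor pairs with Euclidean distance
   ≤ 3.5; hits are grouped into connected matched regions (both-side
   connectivity, singleton/low-support clusters discarded) and extended
   geodesically. Similarity scores: the reciprocal mean
   ss = 1/(1 + mean d), the joint interface score SS_AB = ss_AB·ss_A′B′,
   and the coverage ratio (fraction of interface vertices covered), which
   drives all-against-all interface clustering.
5. **Alignment.** A matched region is superposed by centroid translation
   plus gradient-descent rotational refinement minimizing RMSD (validated
   against the closed-form Kabsch optimum to < 10⁻³ Å); the transform
   grafts a bound partner (e.g. an antibody) onto the query surface.

Everything runs on synthetic, seeded fixtures generated by the package
itself — bumpy spheres, spatially correlated feature fields, planted
similar-region mesh pairs, toy peptides — so the full pipeline is testable
offline.

## Worked example

```r
library(SurfaceMatch)

pdb   <- makeToyPeptide(3, seed = 1)          # 3-residue synthetic peptide
atoms <- parseStructure(pdb$text)
atoms
#> AtomSet: 15 atoms, 3 residues, chains [A]

mesh <- computeSurfaceMesh(atoms, probeRadius = 1.4, targetEdgeLen = 1.0)
mesh <- computeGeometricFeatures(mesh)
mesh <- computeChemicalFeatures(mesh, atoms)
mesh
#> SurfaceMesh: 1928 vertices, 3852 faces, 5 feature channel(s)
#>   [shape_index, mean_curvature, charge, hydropathy, hbond]
isWatertight(mesh)
#> [1] TRUE

patch <- extractPatch(mesh, center = 100, radius = 6)
patch
#> Patch at vertex 100: 368 vertices, radius 6.0 A, 5 channel(s)
w <- softGridWeights(patch, softGrid())       # 368 x 80 weights, rows sum to 1

# planted-pair ground truth: alignment recovers the hidden rigid offset
pp   <- makePlantedPair(7, noiseSd = 0)
core <- which(maskFlags(pp$coreA))
alignRegions(vertices(pp$meshA)[core, ], vertices(pp$meshB)[core, ], seed = 2)
#> AlignmentResult: RMSD 0.0000 A (centroid-only 8.6136) over 593 points, score 1.000
```

The `AtomSet` line confirms the parser saw all 15 atoms; the mesh line
shows a closed, fully featurized surface; the patch holds 368 vertices
within 6 Å geodesic radius; and the alignment recovers the planted rigid
transform exactly (RMSD 0 against a centroid-only starting RMSD of 8.6 Å).

Training and searching follow the same API (`sampleTrainingPairs()`,
`trainEncoder()`, `embedPatches()`, `findHits()`, `groupHits()`,
`filterGroups()`, `coverageRatioScore()`, `allVsAll()`); see the methods
vignette in `vignettes/` for the model details, defaults, and design
rationale. A command-line interface covering the same pipeline is
installed as `inst/scripts/surfacematch` (subcommands: preprocess, synth,
train, embed, search, align, report).

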