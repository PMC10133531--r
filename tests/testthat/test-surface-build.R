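# Structure parsing, surface meshing, and per-vertex featurization.

test_that("parseStructure reads ATOM records and assigns lookups", {
  line <- "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C"
  a <- parseStructure(line)
  expect_equal(nVertices(a), 1L)
  expect_equal(atomData(a)$residue_name, "ALA")
  expect_equal(atomData(a)$hydropathy, 1.8)   # Kyte-Doolittle ALA
  expect_equal(atomData(a)$radius, 1.7)

  tp <- makeToyPeptide(3, seed = 1)
  atoms <- parseStructure(tp$text)
  expect_equal(nVertices(atoms), tp$nAtoms)
  expect_equal(length(unique(atomData(atoms)$residue_seq)), 3L)

  bad <- sub("11.104", "xx.xxx", line)
  expect_error(parseStructure(bad), "line 1")
  expect_error(parseStructure("REMARK nothing here"), "no atoms")
  expect_error(parseStructure(line, chains = "Z"), "no atoms")
})

test_that("waters and ions are excluded by default, hydrogens kept", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA A   1       1.000   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    sep = "\n")
  a <- parseStructure(txt)
  expect_equal(atomData(a)$element, c("C", "H"))
})

test_that("single-atom surface is a sphere of radius r + probe", {
  as1 <- make_atoms(c(0, 0, 0))
  mesh <- computeSurfaceMesh(as1, probeRadius = 1.4, targetEdgeLen = 0.6)
  expect_true(as.logical(isWatertight(mesh)))
  r <- 1.7 + 1.4
  expect_lt(abs(meshArea(mesh) / (4 * pi * r^2) - 1), 0.1)
  radii <- sqrt(rowSums(vertices(mesh)^2))
  expect_lt(max(abs(radii - r)), 0.25 * r)
  # outward unit normals
  expect_true(all(abs(sqrt(rowSums(meshNormals(mesh)^2)) - 1) < 1e-6))
  expect_true(all(rowSums(meshNormals(mesh) * vertices(mesh)) > 0))
})

test_that("meshing keeps the largest component and is deterministic", {
  two <- make_atoms(rbind(c(0, 0, 0), c(100, 0, 0)))
  mesh <- computeSurfaceMesh(two, 1.4, 0.8)
  expect_true(as.logical(isWatertight(mesh)))
  # encloses exactly one atom: all vertices near one center
  d0 <- sqrt(rowSums(vertices(mesh)^2))
  d1 <- sqrt(rowSums(sweep(vertices(mesh), 2, c(100, 0, 0))^2))
  expect_true(all(d0 < 10) || all(d1 < 10))

  m1 <- computeSurfaceMesh(two, 1.4, 0.8)
  expect_identical(vertices(mesh), vertices(m1))
  expect_identical(faces(mesh), faces(m1))
})

test_that("toy peptide meshes into a watertight surface", {
  atoms <- parseStructure(makeToyPeptide(3, seed = 2)$text)
  mesh <- computeSurfaceMesh(atoms, 1.4, 0.9)
  expect_true(as.logical(isWatertight(mesh)))
  expect_gt(nVertices(mesh), 100)
})

test_that("curvature features: plane, sphere, dent", {
  pm <- computeGeometricFeatures(make_plane_mesh(9))
  H <- featureMatrix(pm)[plane_interior(9), "mean_curvature"]
  expect_true(all(abs(H) < 0.05))

  ico <- computeGeometricFeatures(makeIcosphere(3, 1))
  si <- featureMatrix(ico)[, "shape_index"]
  expect_gt(mean(si), 0.9)
  expect_true(all(si >= -1 & si <= 1))
  expect_gt(mean(featureMatrix(ico)[, "mean_curvature"]), 0.8)  # ~ 1/r = 1

  # a dented sphere: dent bottoms concave (negative shape index), bump
  # apices more convex than dents
  bump <- makeBumpySphere(7, nBumps = 6, amplitude = 2, subdivisions = 3)
  bump <- computeGeometricFeatures(bump)
  disp <- meshMetadata(bump)$displacement
  si <- featureMatrix(bump)[, "shape_index"]
  dent_bottoms <- which(disp < quantile(disp, 0.02))
  apices <- which(disp > quantile(disp, 0.98))
  expect_lt(mean(si[dent_bottoms]), 0)
  expect_gt(mean(si[apices]), mean(si[dent_bottoms]))
})

test_that("shape index is bounded for every tested surface", {
  for (seed in 1:3) {
    m <- computeGeometricFeatures(makeBumpySphere(seed, subdivisions = 3))
    si <- featureMatrix(m)[, "shape_index"]
    expect_true(all(is.finite(si)))
    expect_true(all(si >= -1 & si <= 1))
  }
})

test_that("chemical features follow the weighted-charge and lookup rules", {
  # all charges zero -> raw charge channel identically zero
  neutral <- make_atoms(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 1, 0)))
  mesh0 <- computeSurfaceMesh(neutral, 1.4, 0.8)
  m0 <- computeChemicalFeatures(mesh0, neutral, standardize = FALSE)
  expect_true(all(featureMatrix(m0)[, "charge"] == 0))

  # +1 / -1 charges 20 A apart: sign of the raw field over each atom
  dipole <- make_atoms(rbind(c(0, 0, 0), c(20, 0, 0)), charge = c(1, -1))
  dm <- computeSurfaceMesh(dipole, 1.4, 0.8)
  dm <- computeChemicalFeatures(dm, dipole, standardize = FALSE)
  ch <- featureMatrix(dm)[, "charge"]
  near_pos <- sqrt(rowSums(vertices(dm)^2)) < 5
  near_neg <- sqrt(rowSums(sweep(vertices(dm), 2, c(20, 0, 0))^2)) < 5
  if (any(near_pos)) expect_true(all(ch[near_pos] > 0))
  if (any(near_neg)) expect_true(all(ch[near_neg] < 0))

  # direct evaluation of the weighted-sum formula at one vertex
  v1 <- vertices(dm)[1, ]
  d2 <- colSums((t(atomCoords(dipole)) - v1)^2)
  manual <- sum(ifelse(d2 <= 64, c(1, -1) / (1 + d2), 0))
  expect_equal(ch[1], manual, tolerance = 1e-12)

  # hydropathy is the Kyte-Doolittle value of the nearest atom's residue
  ile <- parseStructure(
    "ATOM      1  CB  ILE A   1       0.000   0.000   0.000  1.00  0.00           C")
  im <- computeChemicalFeatures(computeSurfaceMesh(ile, 1.4, 0.8), ile,
                                standardize = FALSE)
  expect_true(all(featureMatrix(im)[, "hydropathy"] == 4.5))
})

test_that("standardization gives zero mean unit variance per channel", {
  atoms <- parseStructure(makeToyPeptide(4, seed = 5)$text)
  mesh <- computeSurfaceMesh(atoms, 1.4, 0.9)
  mesh <- computeChemicalFeatures(mesh, atoms, standardize = TRUE)
  for (ch in c("charge", "hydropathy", "hbond")) {
    x <- featureMatrix(mesh)[, ch]
    if (sd(x) > 0) {                       # non-constant channel
      expect_lt(abs(mean(x)), 1e-8)
      expect_lt(abs(sd(x) - 1), 1e-6)
    }
    expect_false(is.null(meshMetadata(mesh)$standardization[[ch]]))
  }
})

test_that("defineRegion matches the exhaustive all-pairs oracle", {
  set.seed(11)
  mesh <- makeBumpySphere(9, subdivisions = 3)
  ref <- make_atoms(matrix(rnorm(15, sd = 8), 5, 3))
  mask <- defineRegion(mesh, ref, 3.5)
  D <- as.matrix(dist(rbind(vertices(mesh), atomCoords(ref))))
  n <- nVertices(mesh)
  oracle <- apply(D[seq_len(n), n + 1:5, drop = FALSE], 1, min) <= 3.5
  expect_identical(unname(maskFlags(mask)), unname(oracle))

  expect_true(all(maskFlags(defineRegion(mesh, ref, 1e6))))
  far <- make_atoms(c(1000, 0, 0))
  expect_false(any(maskFlags(defineRegion(mesh, far, 3.5))))
  empty <- new("AtomSet", atoms = atomData(ref)[0, ])
  expect_error(defineRegion(mesh, empty, 3.5), "empty reference")
})

test_that("featurization is equivariant under rigid motion", {
  atoms <- parseStructure(makeToyPeptide(3, seed = 8)$text)
  mesh <- computeSurfaceMesh(atoms, 1.4, 0.9)
  mesh <- computeGeometricFeatures(mesh)
  mesh <- computeChemicalFeatures(mesh, atoms, standardize = FALSE)

  tr <- rigidTransform(SurfaceMatch:::.axis_angle_to_matrix(c(0.3, -1.1, 0.7)),
                       c(5, -3, 12))
  mesh_r <- applyTransform(mesh, tr)       # same mesh, rotated coordinates
  mesh_r@features <- matrix(numeric(0), nVertices(mesh_r), 0)
  mesh_r <- computeGeometricFeatures(mesh_r)
  mesh_r <- computeChemicalFeatures(mesh_r, applyTransform(atoms, tr),
                                    standardize = FALSE)
  expect_lt(max(abs(featureMatrix(mesh_r) - featureMatrix(mesh))), 1e-3)
  expect_lt(max(abs(vertices(mesh_r) - applyTransform(vertices(mesh), tr))),
            1e-9)
})
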