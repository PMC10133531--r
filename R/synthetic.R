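# Synthetic fixtures: parametric meshes with controllable curvature,
# spatially correlated per-vertex fields, planted similar-region mesh pairs,
# and toy peptides. All generators are pure functions of their seed.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# area-weighted vertex normals from face winding
.vertex_normals <- function(vertices, faces) {
  fn <- .row_cross(vertices[faces[, 2], , drop = FALSE] -
                     vertices[faces[, 1], , drop = FALSE],
                   vertices[faces[, 3], , drop = FALSE] -
                     vertices[faces[, 1], , drop = FALSE])
  nrm <- vapply(1:3, function(d)
    as.vector(rowsum_all(faces, fn[, d], nrow(vertices))),
    numeric(nrow(vertices)))
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm / len
}

.new_mesh <- function(vertices, faces, id = "synthetic", metadata = list()) {
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  dimnames(vertices) <- NULL
  new("SurfaceMesh", vertices = vertices, faces = faces,
      normals = .vertex_normals(vertices, faces),
      features = matrix(numeric(0), nrow(vertices), 0),
      vertexToAtom = integer(0),
      metadata = c(list(id = id), metadata))
}

#' Icosphere mesh
#'
#' Recursively subdivided icosahedron projected onto the sphere:
#' 10 * 4^subdivisions + 2 vertices, watertight, outward CCW faces.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius, Angstrom.
#' @param meshId identifier for the mesh metadata.
#' @return a [SurfaceMesh-class] (geometry only).
#' @export
makeIcosphere <- function(subdivisions = 3, radius = 10, meshId = "icosphere") {
  stopifnot(subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(
    1, 12, 6,  1, 6, 2,   1, 2, 8,   1, 8, 11,  1, 11, 12,
    2, 6, 10,  6, 12, 5,  12, 11, 3, 11, 8, 7,  8, 2, 9,
    4, 10, 5,  4, 5, 3,   4, 3, 7,   4, 7, 9,   4, 9, 10,
    5, 10, 6,  3, 5, 12,  7, 3, 11,  9, 7, 8,   10, 9, 2),
    ncol = 3, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    e1 <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    lo <- pmin(e1[, 1], e1[, 2]); hi <- pmax(e1[, 1], e1[, 2])
    key <- paste(lo, hi)
    uk <- !duplicated(key)
    mididx <- nrow(v) + match(key, key[uk])      # midpoint vertex index
    mid <- (v[lo[uk], , drop = FALSE] + v[hi[uk], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- mididx[seq_len(nf)]
    m23 <- mididx[nf + seq_len(nf)]
    m31 <- mididx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  .new_mesh(v * radius, f, meshId,
            metadata = list(radius = radius, subdivisions = subdivisions,
                            unit_dirs_available = TRUE))
}

#' Bumpy sphere: icosphere with seeded Gaussian bumps and dents
#'
#' Radial displacement field r(u) = radius + sum_b amp_b *
#' exp(-arc(u, c_b)^2 / (2 * bumpSd^2)) with seeded random bump centers,
#' widths around `bumpSd` and signed amplitudes up to `amplitude`. Exercises
#' curvature features (bump apices convex, dent bottoms concave).
#'
#' @param seed integer seed; fully determines the mesh.
#' @param nBumps number of bumps/dents.
#' @param amplitude maximum |displacement| in Angstrom; must be < radius/2.
#' @param radius base sphere radius, Angstrom.
#' @param subdivisions icosphere subdivision level.
#' @param bumpSd bump width (arc length), Angstrom.
#' @param meshId identifier for the mesh metadata.
#' @return a [SurfaceMesh-class] (geometry only). The radial displacement
#'   field is stored in the metadata (`displacement`) for region planting.
#' @export
makeBumpySphere <- function(seed, nBumps = 12, amplitude = 1.5, radius = 10,
                            subdivisions = 4, bumpSd = 2.0,
                            meshId = paste0("bumpy_", seed)) {
  stopifnot(amplitude < radius / 2)
  base <- makeIcosphere(subdivisions, 1, meshId)
  u <- vertices(base)                      # unit directions
  disp <- numeric(nrow(u))
  info <- NULL
  if (nBumps > 0 && amplitude > 0) {
    .with_seed(seed, {
      centers <- matrix(rnorm(3 * nBumps), ncol = 3)
      centers <- centers / sqrt(rowSums(centers^2))
      amps <- runif(nBumps, 0.5, 1) * amplitude * sample(c(-1, 1), nBumps, TRUE)
      sds <- runif(nBumps, 0.8, 1.2) * bumpSd
      info <- list(centers = centers, amplitudes = amps, sds = sds)
      for (b in seq_len(nBumps)) {
        arc <- radius * acos(pmin(1, pmax(-1, u %*% centers[b, ])))
        disp <- disp + amps[b] * exp(-arc^2 / (2 * sds[b]^2))
      }
    })
  }
  m <- .new_mesh(u * (radius + disp), faces(base), meshId,
                 metadata = list(radius = radius, subdivisions = subdivisions,
                                 seed = seed, displacement = disp, bumps = info))
  m
}

#' Spatially correlated per-vertex random fields
#'
#' Gaussian white noise per vertex smoothed by iterated neighbor averaging
#' over the mesh graph (discrete heat diffusion), giving fields whose values
#' decorrelate over roughly `correlationLength`; each channel is then
#' re-standardized to zero mean, unit variance. This emulates the smooth
#' chemical fields of real surfaces: nearby vertices have similar features,
#' the property the contrastive objective relies on.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param correlationLength target correlation length, Angstrom; `Inf` gives
#'   constant channels.
#' @param nChannels number of independent channels.
#' @param seed integer seed.
#' @param channelNames optional column names (default field1..fieldK).
#' @return an nVertices x nChannels matrix.
#' @export
makeCorrelatedFeatures <- function(mesh, correlationLength, nChannels, seed,
                                   channelNames = NULL) {
  n <- nVertices(mesh)
  ed <- meshEdges(mesh)
  steps <- if (is.infinite(correlationLength)) Inf
  else max(0L, round(correlationLength / mean(ed$length)))
  x <- .with_seed(seed, matrix(rnorm(n * nChannels), n, nChannels))
  if (is.infinite(steps)) {
    x <- matrix(rep(colMeans(x) * 0, each = n), n, nChannels)  # constant 0
  } else if (steps > 0) {
    deg <- tabulate(c(ed$v1, ed$v2), n)
    for (s in seq_len(steps)) {
      acc <- x * 0
      for (c in seq_len(nChannels)) {
        sums <- numeric(n)
        s1 <- rowsum(x[ed$v2, c], ed$v1)
        sums[as.integer(rownames(s1))] <- s1[, 1]
        s2 <- rowsum(x[ed$v1, c], ed$v2)
        sums[as.integer(rownames(s2))] <-
          sums[as.integer(rownames(s2))] + s2[, 1]
        acc[, c] <- (x[, c] + sums) / (1 + deg)
      }
      x <- acc
    }
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  colnames(x) <- channelNames %||% paste0("field", seq_len(nChannels))
  x
}

#' Planted similar-region mesh pair
#'
#' Two independently bumpy spheres (same icosphere topology) that share one
#' surface cap: inside the cap, the second mesh's radial displacement and
#' chemical-like feature channels are copied from the first (features with
#' additive Gaussian noise of sd `noiseSd`), blended smoothly over a margin
#' at the cap boundary. The second mesh is then moved by a seeded random
#' rigid transform. Geometric channels are recomputed from each final
#' geometry; chemical-like channels are synthetic correlated fields reusing
#' the standard channel names, so planted pairs flow through the full
#' pipeline.
#'
#' The default cap radius (12 Angstrom) is deliberately twice the 6
#' Angstrom patch radius: patches are only fully contained in the planted
#' region when their center lies more than one patch radius inside it, so a
#' cap must exceed the patch diameter to contain any truly matching
#' patches at all.
#'
#' @param seed integer seed.
#' @param regionSize planted cap radius (arc length), Angstrom.
#' @param noiseSd feature noise inside the cap.
#' @param radius,subdivisions,nBumps,amplitude passed to [makeBumpySphere()].
#' @param blendMargin smooth blend width at the cap boundary, Angstrom.
#' @param correlationLength passed to [makeCorrelatedFeatures()].
#' @return a list with meshA, meshB ([SurfaceMesh-class], featurized),
#'   maskA, maskB ([RegionMask-class] over the planted cap), coreA/coreB
#'   (cap minus the blend margin), correspondence (data.frame vertexA,
#'   vertexB), and transform (the [RigidTransform-class] mapping meshB
#'   coordinates onto meshA, i.e. the alignment ground truth).
#' @export
makePlantedPair <- function(seed, regionSize = 12, noiseSd = 0.1, radius = 10,
                            subdivisions = 4, nBumps = 12, amplitude = 1.5,
                            blendMargin = 2, correlationLength = 3) {
  mA <- makeBumpySphere(seed * 2 + 1, nBumps, amplitude, radius, subdivisions,
                        meshId = paste0("plantedA_", seed))
  mB0 <- makeBumpySphere(seed * 2 + 2, nBumps, amplitude, radius, subdivisions,
                         meshId = paste0("plantedB_", seed))
  u <- vertices(makeIcosphere(subdivisions, 1))
  n <- nrow(u)

  sel <- .with_seed(seed * 7 + 3, sample.int(n, 1))
  arc <- radius * acos(pmin(1, pmax(-1, as.vector(u %*% u[sel, ]))))
  w <- .smoothstep((regionSize - arc) / blendMargin)   # 1 core .. 0 outside
  cap <- arc <= regionSize
  core <- arc <= regionSize - blendMargin

  dispA <- meshMetadata(mA)$displacement
  dispB <- meshMetadata(mB0)$displacement
  dispB2 <- (1 - w) * dispB + w * dispA
  vB <- u * (radius + dispB2)
  mB0 <- .new_mesh(vB, faces(mB0), paste0("plantedB_", seed),
                   metadata = c(meshMetadata(mB0)[c("radius", "subdivisions", "seed")],
                                list(displacement = dispB2)))

  chem <- c("charge", "hydropathy", "hbond")
  fA <- makeCorrelatedFeatures(mA, correlationLength, 3, seed * 11 + 5, chem)
  fB <- makeCorrelatedFeatures(mB0, correlationLength, 3, seed * 11 + 6, chem)
  noise <- .with_seed(seed * 11 + 7, matrix(rnorm(n * 3, sd = noiseSd), n, 3))
  fB2 <- (1 - w) * fB + w * (fA + noise)

  mA <- computeGeometricFeatures(mA)
  mB0 <- computeGeometricFeatures(mB0)
  mA@features <- cbind(mA@features, fA)
  mB0@features <- cbind(mB0@features, fB2)

  tr <- .with_seed(seed * 13 + 9, {
    R0 <- .random_rotation()
    t0 <- rnorm(3, sd = 8)
    new("RigidTransform", rotation = R0, translation = t0)
  })
  mB <- applyTransform(mB0, tr)
  validObject(mA); validObject(mB)

  maskA <- new("RegionMask", meshId = meshMetadata(mA)$id, flags = cap,
               cutoff = regionSize)
  maskB <- new("RegionMask", meshId = meshMetadata(mB)$id, flags = cap,
               cutoff = regionSize)
  coreA <- new("RegionMask", meshId = meshMetadata(mA)$id, flags = core,
               cutoff = max(regionSize - blendMargin, 1e-6))
  list(meshA = mA, meshB = mB, maskA = maskA, maskB = maskB,
       coreA = coreA,
       correspondence = data.frame(vertexA = which(cap), vertexB = which(cap)),
       transform = invertTransform(tr))
}

.smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Toy pseudo-peptide PDB text
#'
#' A geometrically plausible, non-self-intersecting extended backbone
#' (N, CA, C, O plus CB except for glycine) with small seeded coordinate
#' jitter, written as standard fixed-column PDB text. Used for end-to-end
#' preprocessing tests without any external structure files.
#'
#' @param nResidues number of residues.
#' @param seed integer seed.
#' @param residueNames residue name cycle (default ALA/ILE/ASP/SER/LYS).
#' @return a list with `text` (PDB lines as one string), `nAtoms`, and
#'   `nResidues`.
#' @export
makeToyPeptide <- function(nResidues = 3, seed = 1,
                           residueNames = c("ALA", "ILE", "ASP", "SER", "LYS")) {
  stopifnot(nResidues >= 1)
  res <- rep_len(residueNames, nResidues)
  .with_seed(seed, {
    rows <- list()
    id <- 0L
    for (i in seq_len(nResidues)) {
      t0 <- (i - 1) * 3.6
      jit <- function() rnorm(3, sd = 0.08)
      atoms <- list(
        N  = c(t0 - 1.20, 0.45 * (-1)^i, 0.10) + jit(),
        CA = c(t0, 0, 0) + jit(),
        C  = c(t0 + 1.25, 0.40 * (-1)^i, 0.05) + jit(),
        O  = c(t0 + 1.35, 1.55 * (-1)^i, 0.25) + jit())
      if (res[i] != "GLY")
        atoms$CB <- c(t0, -0.85 * (-1)^i, 1.25) + jit()
      for (nm in names(atoms)) {
        id <- id + 1L
        rows[[id]] <- data.frame(
          atom_id = id, atom_name = nm, residue_name = res[i],
          chain_id = "A", residue_seq = i, insert = "",
          x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
          element = substr(nm, 1, 1), stringsAsFactors = FALSE)
      }
    }
    a <- do.call(rbind, rows)
    a$radius <- unname(.VDW_RADII[a$element]); a$radius[is.na(a$radius)] <- .VDW_DEFAULT
    a$charge <- 0; a$hydropathy <- 0; a$hbond <- 0
    atoms <- new("AtomSet", atoms = a[, c("atom_id", "element", "x", "y", "z",
                                          "residue_name", "residue_seq", "insert",
                                          "chain_id", "atom_name", "radius",
                                          "charge", "hydropathy", "hbond")])
    list(text = paste(writeAtomsPDB(atoms), collapse = "\n"),
         nAtoms = nrow(a), nResidues = nResidues)
  })
}
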