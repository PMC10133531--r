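# Per-vertex geometric and chemical surface features.

.ensure_feature_cols <- function(mesh, cols) {
  feats <- mesh@features
  n <- nVertices(mesh)
  for (cn in cols) {
    if (!ncol(feats) || !(cn %in% colnames(feats))) {
      feats <- cbind(feats, matrix(0, n, 1, dimnames = list(NULL, cn)))
    }
  }
  feats
}

#' Compute discrete curvature features (shape index, mean curvature)
#'
#' Estimates per-vertex principal curvatures from the cotangent-Laplacian
#' mean-curvature normal and the angle-defect Gaussian curvature
#' (barycentric vertex areas), then fills the `shape_index` and
#' `mean_curvature` channels. Sign convention: an outward-bulging (convex)
#' sphere has positive curvatures, so its shape index is +1. At umbilic
#' points (kappa1 == kappa2) the shape index is sign(kappa1), never NaN.
#'
#' shape_index = (2/pi) * atan((k1 + k2) / (k1 - k2)), k1 >= k2
#' mean_curvature = (k1 + k2) / 2  (1/Angstrom)
#'
#' @param mesh a [SurfaceMesh-class] with valid geometry and normals.
#' @return the mesh with the two geometric channels filled.
#' @export
computeGeometricFeatures <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh); n <- nrow(v)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]

  ang <- function(a, b) {                 # angle between row vectors
    cosv <- rowSums(a * b) /
      pmax(sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)), 1e-300)
    acos(pmin(1, pmax(-1, cosv)))
  }
  a1 <- ang(p2 - p1, p3 - p1)             # angle at corner 1, etc.
  a2 <- ang(p1 - p2, p3 - p2)
  a3 <- ang(p1 - p3, p2 - p3)
  cot <- function(x) cos(x) / pmax(sin(x), 1e-12)

  area_f <- sqrt(rowSums(.row_cross(p2 - p1, p3 - p1)^2)) / 2
  A <- rowsum_all(f, rep(area_f / 3, 1), n)        # barycentric vertex area
  A <- pmax(A, 1e-12)

  # cotangent Laplacian applied to the coordinates: the edge (i,j) opposite
  # corner k receives weight cot(angle_k)
  Lx <- matrix(0, n, 3)
  acc <- function(i, j, w) {
    d <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    for (c in 1:3) {
      s <- rowsum(w * d[, c], i)
      Lx[as.integer(rownames(s)), c] <<- Lx[as.integer(rownames(s)), c] + s[, 1]
    }
  }
  acc(f[, 1], f[, 2], cot(a3)); acc(f[, 2], f[, 1], cot(a3))
  acc(f[, 2], f[, 3], cot(a1)); acc(f[, 3], f[, 2], cot(a1))
  acc(f[, 1], f[, 3], cot(a2)); acc(f[, 3], f[, 1], cot(a2))
  Lx <- Lx / (2 * A)

  nrm <- meshNormals(mesh)
  H <- sqrt(rowSums(Lx^2)) / 2 * sign(rowSums(Lx * (-nrm)))

  asum <- numeric(n)
  for (pair in list(list(f[, 1], a1), list(f[, 2], a2), list(f[, 3], a3))) {
    s <- rowsum(pair[[2]], pair[[1]])
    asum[as.integer(rownames(s))] <- asum[as.integer(rownames(s))] + s[, 1]
  }
  K <- (2 * pi - asum) / A

  disc <- pmax(H^2 - K, 0)
  k1 <- H + sqrt(disc)
  k2 <- H - sqrt(disc)
  denom <- k1 - k2
  si <- numeric(n)
  umb <- denom < 1e-9
  si[!umb] <- (2 / pi) * atan((k1[!umb] + k2[!umb]) / denom[!umb])
  si[umb] <- sign(k1[umb])
  si[si == 0 & umb] <- 1                  # flat umbilic: treat as cap side
  si <- pmin(1, pmax(-1, si))

  feats <- .ensure_feature_cols(mesh, c("shape_index", "mean_curvature"))
  feats[, "shape_index"] <- si
  feats[, "mean_curvature"] <- H
  mesh@features <- feats
  validObject(mesh)
  mesh
}

#' Compute chemical surface features (charge, hydropathy, hbond)
#'
#' Fills three channels from the source atoms: `charge` is a distance-
#' weighted sum of simplified partial charges, sum q_j / (1 + d^2), over
#' atoms within `chargeCutoff` (a Coulomb-like screened field, not a
#' Poisson-Boltzmann potential); `hydropathy` is the Kyte-Doolittle value of
#' the nearest atom's residue; `hbond` is +1/-1/0 from the nearest hydrogen
#' bond donor/acceptor atom within `hbondRange` (0 when none is near).
#' Channels are then standardized to zero mean and unit variance per protein
#' (the statistics are recorded in the mesh metadata) unless
#' `standardize = FALSE`.
#'
#' Vertices farther than 10 Angstrom from every atom still inherit from the
#' globally nearest atom, with a warning.
#'
#' @param mesh a [SurfaceMesh-class] built from `atoms` (or spatially
#'   compatible with them).
#' @param atoms an [AtomSet-class].
#' @param chargeCutoff neighbor cutoff for the charge sum, Angstrom.
#' @param hbondRange maximum vertex-to-donor/acceptor distance, Angstrom.
#' @param standardize z-score the three channels per protein.
#' @return the mesh with chemical channels filled.
#' @export
computeChemicalFeatures <- function(mesh, atoms, chargeCutoff = 8,
                                    hbondRange = 3, standardize = TRUE) {
  a <- atomData(atoms)
  v <- vertices(mesh)
  coords <- atomCoords(atoms)
  n <- nrow(v)

  nearest <- .nearest_atom(v, coords)
  ndist <- sqrt(rowSums((v - coords[nearest, , drop = FALSE])^2))
  if (any(ndist > 10))
    warning(sprintf("%d vertex/vertices with no atom within 10 A; using the globally nearest atom",
                    sum(ndist > 10)))

  charge <- numeric(n)
  chunk <- 2048L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(v[s:e, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * v[s:e, , drop = FALSE] %*% t(coords)
    d2[d2 < 0] <- 0
    w <- 1 / (1 + d2)
    w[d2 > chargeCutoff^2] <- 0
    charge[s:e] <- as.vector(w %*% a$charge)
  }

  hydro <- a$hydropathy[nearest]

  hbond <- numeric(n)
  polar <- which(a$hbond != 0)
  if (length(polar)) {
    np <- .nearest_atom(v, coords[polar, , drop = FALSE])
    pd <- sqrt(rowSums((v - coords[polar[np], , drop = FALSE])^2))
    hbond <- ifelse(pd <= hbondRange, a$hbond[polar[np]], 0)
  }

  feats <- .ensure_feature_cols(mesh, c("charge", "hydropathy", "hbond"))
  feats[, "charge"] <- charge
  feats[, "hydropathy"] <- hydro
  feats[, "hbond"] <- hbond
  mesh@features <- feats
  mesh@vertexToAtom <- nearest
  if (standardize)
    mesh <- standardizeFeatures(mesh, c("charge", "hydropathy", "hbond"))
  validObject(mesh)
  mesh
}

#' Standardize feature channels per protein
#'
#' Z-scores the named channels over this mesh's vertices (zero mean, unit
#' variance); constant channels are left centered but unscaled. The per-
#' channel mean and standard deviation are stored in
#' `meshMetadata(mesh)$standardization` for reproducibility.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param channels channel names to standardize.
#' @return the mesh with standardized channels.
#' @export
standardizeFeatures <- function(mesh, channels) {
  feats <- mesh@features
  stopifnot(all(channels %in% colnames(feats)))
  stats <- meshMetadata(mesh)$standardization
  if (is.null(stats)) stats <- list()
  for (cn in channels) {
    x <- feats[, cn]
    mu <- mean(x)
    sdv <- stats::sd(x)
    if (!is.finite(sdv) || sdv < 1e-12) {
      feats[, cn] <- x - mu
      stats[[cn]] <- c(mean = mu, sd = 1)
    } else {
      feats[, cn] <- (x - mu) / sdv
      stats[[cn]] <- c(mean = mu, sd = sdv)
    }
  }
  mesh@features <- feats
  mesh@metadata$standardization <- stats
  mesh
}

#' Flag the mesh vertices near a set of reference atoms
#'
#' A vertex is flagged iff its minimum Euclidean distance to any reference
#' atom is at most `cutoff`. This is how query regions (3.5 A of interface
#' residues), paratopes (2 A of the CDRs) and epitopes (4.5 A of the
#' antibody) are defined.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param referenceAtoms an [AtomSet-class]; must be nonempty.
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return a [RegionMask-class].
#' @export
defineRegion <- function(mesh, referenceAtoms, cutoff) {
  stopifnot(cutoff > 0)
  if (nVertices(referenceAtoms) == 0L)
    stop("empty reference atom set: supply residue/CDR selections")
  v <- vertices(mesh)
  coords <- atomCoords(referenceAtoms)
  n <- nrow(v)
  flags <- logical(n)
  chunk <- 2048L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(v[s:e, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * v[s:e, , drop = FALSE] %*% t(coords)
    flags[s:e] <- sqrt(pmax(apply(d2, 1, min), 0)) <= cutoff
  }
  new("RegionMask", meshId = as.character(meshMetadata(mesh)$id %||% "mesh"),
      flags = flags, cutoff = cutoff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
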