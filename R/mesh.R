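# Molecular surface construction: sum-of-Gaussians atom density sampled on a
# regular grid, triangulated by marching tetrahedra at a fixed isovalue.
# Marching tetrahedra (each grid cube split into 6 tetrahedra around its main
# diagonal) has no ambiguous cases, so the extracted isosurface is watertight
# and manifold by construction. Grid spacing sets the mesh resolution.

.ISO <- exp(-2)

# 6-tetrahedron decomposition of the unit cube; corners numbered 1..8 as
# (x,y,z) bit pattern +1: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0)
# 5=(0,0,1) 6=(1,0,1) 7=(0,1,1) 8=(1,1,1). All tets share diagonal 1-8.
.TETS <- matrix(c(
  1, 2, 4, 8,
  1, 4, 3, 8,
  1, 3, 7, 8,
  1, 7, 5, 8,
  1, 5, 6, 8,
  1, 6, 2, 8), ncol = 4, byrow = TRUE)

.CUBE_OFFSETS <- cbind(x = c(0, 1, 0, 1, 0, 1, 0, 1),
                       y = c(0, 0, 1, 1, 0, 0, 1, 1),
                       z = c(0, 0, 0, 0, 1, 1, 1, 1))

# Gaussian density of the atom set on an axis-aligned grid. Width per atom
# w_i = (r_i + probe)/2 with isovalue exp(-2), so a lone atom's isosurface
# is the sphere of radius r_i + probe.
.atom_density_grid <- function(coords, radii, probe, spacing, pad = 3) {
  w <- (radii + probe) / 2
  dmax <- (radii + probe) + pad
  lo <- apply(coords - dmax, 2, min)
  hi <- apply(coords + dmax, 2, max)
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  f <- array(0, dim = c(length(gx), length(gy), length(gz)))
  cut2 <- (3.5 * w)^2                       # per-atom support cutoff
  for (i in seq_len(nrow(coords))) {
    r <- 3.5 * w[i]
    ix <- which(gx >= coords[i, 1] - r & gx <= coords[i, 1] + r)
    iy <- which(gy >= coords[i, 2] - r & gy <= coords[i, 2] + r)
    iz <- which(gz >= coords[i, 3] - r & gz <= coords[i, 3] + r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - coords[i, 1])^2
    dy2 <- (gy[iy] - coords[i, 2])^2
    dz2 <- (gz[iz] - coords[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    d2[d2 > cut2[i]] <- Inf
    f[ix, iy, iz] <- f[ix, iy, iz] + exp(-d2 / (2 * w[i]^2))
  }
  list(f = f, gx = gx, gy = gy, gz = gz)
}

.atom_density_gradient <- function(pts, coords, radii, probe) {
  w <- (radii + probe) / 2
  g <- matrix(0, nrow(pts), 3)
  for (i in seq_len(nrow(coords))) {
    d <- sweep(pts, 2, coords[i, ])
    e <- exp(-rowSums(d^2) / (2 * w[i]^2))
    g <- g - d * (e / w[i]^2)
  }
  g
}

# Marching tetrahedra over a scalar grid. Returns a vertex-welded triangle
# mesh of the f = iso surface (orientation fixed later from the gradient).
.marching_tetrahedra <- function(f, gx, gy, gz, iso) {
  dims <- dim(f)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  fv <- as.vector(f)
  fv[fv == iso] <- iso + 1e-12 * max(1, abs(iso))   # avoid exact hits
  idx1 <- function(i, j, k) i + nx * ((j - 1) + ny * (k - 1))

  # candidate cubes: any corner sign differs
  inside <- fv > iso
  ii <- seq_len(nx - 1L); jj <- seq_len(ny - 1L); kk <- seq_len(nz - 1L)
  base <- as.vector(outer(outer(ii, nx * (jj - 1L), "+"), nx * ny * (kk - 1L), "+"))
  corner_off <- .CUBE_OFFSETS[, 1] + nx * .CUBE_OFFSETS[, 2] +
    nx * ny * .CUBE_OFFSETS[, 3]
  cin <- matrix(inside[rep(base, 8) + rep(corner_off, each = length(base))],
                ncol = 8)
  active <- which(rowSums(cin) %in% 1:7)
  if (!length(active)) stop("isosurface failure: no level crossing in the grid")
  base <- base[active]

  # global corner linear indices for active cubes (ncube x 8)
  corn <- outer(base, corner_off, "+")

  edge_a <- integer(0); edge_b <- integer(0)  # grid endpoints per crossing

  tri_rows <- list(); nt <- 0L

  for (t in seq_len(nrow(.TETS))) {
    tc <- corn[, .TETS[t, ], drop = FALSE]           # ncube x 4 global ids
    tin <- matrix(inside[tc], ncol = 4)
    nin <- rowSums(tin)
    # one corner on one side, three on the other: a single triangle
    for (apex_col in 1:4) {
      sel <- which((nin == 1L & tin[, apex_col]) |
                     (nin == 3L & !tin[, apex_col]))
      if (!length(sel)) next
      tcs <- tc[sel, , drop = FALSE]
      n <- length(sel)
      apex <- tcs[, apex_col]
      oth <- tcs[, setdiff(1:4, apex_col), drop = FALSE]
      v0 <- length(edge_a)
      edge_a <- c(edge_a, rep(apex, 3L))
      edge_b <- c(edge_b, oth[, 1], oth[, 2], oth[, 3])
      nt <- nt + 1L
      tri_rows[[nt]] <- cbind(v0 + seq_len(n), v0 + n + seq_len(n),
                              v0 + 2L * n + seq_len(n))
    }
    # two-and-two: a quad split along one diagonal
    two_in <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (p in seq_len(nrow(two_in))) {
      ic <- two_in[p, ]; oc <- setdiff(1:4, ic)
      sel <- which(nin == 2L & tin[, ic[1]] & tin[, ic[2]])
      if (!length(sel)) next
      tcs <- tc[sel, , drop = FALSE]
      n <- length(sel)
      i1 <- tcs[, ic[1]]; i2 <- tcs[, ic[2]]
      o1 <- tcs[, oc[1]]; o2 <- tcs[, oc[2]]
      # quad vertices in cyclic order: (i1,o1) (i1,o2) (i2,o2) (i2,o1)
      v0 <- length(edge_a)
      edge_a <- c(edge_a, i1, i1, i2, i2)
      edge_b <- c(edge_b, o1, o2, o2, o1)
      q1 <- v0 + seq_len(n); q2 <- v0 + n + seq_len(n)
      q3 <- v0 + 2L * n + seq_len(n); q4 <- v0 + 3L * n + seq_len(n)
      nt <- nt + 1L; tri_rows[[nt]] <- cbind(q1, q2, q3)
      nt <- nt + 1L; tri_rows[[nt]] <- cbind(q1, q3, q4)
    }
  }
  tris <- do.call(rbind, tri_rows)

  # weld: one mesh vertex per unique crossed grid edge
  lo <- pmin(edge_a, edge_b); hi <- pmax(edge_a, edge_b)
  key <- as.numeric(lo) * (as.numeric(nx) * ny * nz + 1) + hi  # exact to ~3e7 points
  uid <- match(key, unique(key))
  faces <- matrix(uid[tris], ncol = 3)

  first <- !duplicated(key)
  ua <- lo[first]; ub <- hi[first]
  # linear interpolation along the grid edge
  tpar <- (iso - fv[ua]) / (fv[ub] - fv[ua])
  toXYZ <- function(lin) {
    lin0 <- lin - 1L
    i <- lin0 %% nx; j <- (lin0 %/% nx) %% ny; k <- lin0 %/% (nx * ny)
    cbind(gx[i + 1L], gy[j + 1L], gz[k + 1L])
  }
  pa <- toXYZ(ua); pb <- toXYZ(ub)
  verts <- pa + tpar * (pb - pa)

  # drop degenerate faces (repeated vertex)
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  faces <- faces[!deg, , drop = FALSE]
  list(vertices = verts, faces = faces)
}

.largest_component <- function(vertices, faces) {
  g <- igraph::graph_from_edgelist(
    rbind(faces[, 1:2], faces[, 2:3], faces[, c(1, 3)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  keepv <- which(comp$membership == which.max(comp$csize))
  fkeep <- faces[faces[, 1] %in% keepv & faces[, 2] %in% keepv &
                   faces[, 3] %in% keepv, , drop = FALSE]
  remap <- integer(nrow(vertices)); remap[keepv] <- seq_along(keepv)
  list(vertices = vertices[keepv, , drop = FALSE],
       faces = matrix(remap[fkeep], ncol = 3))
}

# Angle-weighted outward vertex normals; faces are re-wound first so every
# face normal has positive dot product with the outward density gradient.
.orient_and_normals <- function(vertices, faces, coords, radii, probe) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  cen <- (v1 + v2 + v3) / 3
  fn <- .row_cross(v2 - v1, v3 - v1)
  outward <- -.atom_density_gradient(cen, coords, radii, probe)
  flip <- rowSums(fn * outward) < 0
  faces[flip, ] <- faces[flip, c(1, 3, 2)]
  fn[flip, ] <- -fn[flip, ]
  nrm <- vapply(1:3, function(d)
    as.vector(rowsum_all(faces, fn[, d], nrow(vertices))), numeric(nrow(vertices)))
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  list(faces = faces, normals = nrm / len)
}

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# sum `val[f]` into each vertex appearing in any column of `faces`
rowsum_all <- function(faces, val, n) {
  out <- numeric(n)
  for (c in 1:3) {
    s <- rowsum(val, faces[, c])
    out[as.integer(rownames(s))] <- out[as.integer(rownames(s))] + s[, 1]
  }
  out
}

#' Build the molecular surface mesh of an atom set
#'
#' Constructs a closed triangulated surface as the isosurface of a Gaussian
#' atom density: each atom contributes a Gaussian of width (r + probe)/2 and
#' the surface is extracted at isovalue exp(-2) by marching tetrahedra, so a
#' single atom yields (up to discretization) the sphere of radius r + probe.
#' Only the largest connected component is kept; the result is watertight
#' and manifold with outward, counter-clockwise-wound faces. The grid
#' spacing equals `targetEdgeLen`, which controls mesh resolution.
#'
#' @param atoms an [AtomSet-class].
#' @param probeRadius solvent probe radius in Angstrom (default 1.4).
#' @param targetEdgeLen target mesh edge length / grid spacing in Angstrom.
#' @param meshId identifier stored in the mesh metadata.
#' @return a [SurfaceMesh-class] with geometry and normals but no features.
#' @examples
#' atoms <- parseStructure(makeToyPeptide(3, seed = 1)$text)
#' mesh <- computeSurfaceMesh(atoms, probeRadius = 1.4, targetEdgeLen = 1)
#' @export
computeSurfaceMesh <- function(atoms, probeRadius = 1.4, targetEdgeLen = 1.0,
                               meshId = "mesh") {
  stopifnot(probeRadius >= 0, targetEdgeLen > 0)
  a <- atomData(atoms)
  if (!nrow(a)) stop("no atoms")
  coords <- atomCoords(atoms)
  grid <- .atom_density_grid(coords, a$radius, probeRadius, targetEdgeLen)
  mt <- .marching_tetrahedra(grid$f, grid$gx, grid$gy, grid$gz, .ISO)
  mt <- .largest_component(mt$vertices, mt$faces)
  on <- .orient_and_normals(mt$vertices, mt$faces, coords, a$radius, probeRadius)
  v2a <- .nearest_atom(mt$vertices, coords)
  storage.mode(on$faces) <- "integer"
  new("SurfaceMesh",
      vertices = mt$vertices, faces = on$faces, normals = on$normals,
      features = matrix(numeric(0), nrow(mt$vertices), 0),
      vertexToAtom = v2a,
      metadata = list(id = meshId, probe_radius = probeRadius,
                      isovalue = .ISO, target_edge_len = targetEdgeLen,
                      n_atoms = nrow(a)))
}

.nearest_atom <- function(pts, coords, chunk = 2048L) {
  n <- nrow(pts)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(rowSums(pts[s:e, , drop = FALSE]^2), rowSums(coords^2), "+") -
      2 * pts[s:e, , drop = FALSE] %*% t(coords)
    out[s:e] <- max.col(-d2, "first")
  }
  out
}

#' Check that a mesh is watertight and single-component
#'
#' Watertight: every undirected edge is shared by exactly two faces.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return logical scalar, with attributes `n_components` and `boundary_edges`.
#' @export
isWatertight <- function(mesh) {
  f <- faces(mesh)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  ncomp <- igraph::components(g)$no
  ok <- all(tab == 2L) && ncomp == 1L
  structure(ok, n_components = ncomp, boundary_edges = sum(tab != 2L))
}

#' Total surface area of a mesh
#' @param mesh a [SurfaceMesh-class].
#' @return numeric, Angstrom^2.
#' @export
meshArea <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  cr <- .row_cross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                   v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Unique undirected edges of a mesh with their lengths
#' @param mesh a [SurfaceMesh-class].
#' @return data.frame with columns v1, v2, length.
#' @export
meshEdges <- function(mesh) {
  f <- faces(mesh)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(cbind(lo, hi))
  v <- vertices(mesh)
  lo <- lo[keep]; hi <- hi[keep]
  data.frame(v1 = lo, v2 = hi,
             length = sqrt(rowSums((v[lo, , drop = FALSE] -
                                      v[hi, , drop = FALSE])^2)))
}
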