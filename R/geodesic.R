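# Geodesic distances on the mesh edge graph (Dijkstra metric) and
# fixed-radius patch extraction with local polar coordinates.

.mesh_graph <- function(mesh) {
  ed <- meshEdges(mesh)
  g <- igraph::graph_from_edgelist(cbind(ed$v1, ed$v2), directed = FALSE)
  if (igraph::vcount(g) < nVertices(mesh))
    g <- igraph::add_vertices(g, nVertices(mesh) - igraph::vcount(g))
  igraph::E(g)$weight <- ed$length
  g
}

# distance rows for several sources at once (length(sources) x N)
.geodesic_rows <- function(mesh, sources, graph = NULL) {
  g <- graph %||% .mesh_graph(mesh)
  igraph::distances(g, v = sources, algorithm = "dijkstra")
}

#' Geodesic distances from a source vertex
#'
#' Shortest-path distances along the mesh edge graph (Dijkstra), truncated
#' at `maxRadius`. The source is always included with distance 0.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param source vertex index (1-based).
#' @param maxRadius truncation radius, Angstrom (> 0).
#' @return named numeric vector of distances for the vertices within
#'   `maxRadius`; names are vertex indices.
#' @export
geodesicDistances <- function(mesh, source, maxRadius) {
  stopifnot(maxRadius > 0, source >= 1, source <= nVertices(mesh))
  d <- .geodesic_rows(mesh, source)[1, ]
  if (all(is.infinite(d[-source])))
    stop("source vertex is disconnected from the rest of the mesh")
  keep <- which(d <= maxRadius)
  stats::setNames(d[keep], keep)
}

# Tangent-plane basis at a vertex: e1 along the projected edge to the
# lowest-index neighbor (the deterministic zero direction), e2 = n x e1.
.tangent_basis <- function(mesh, center) {
  f <- faces(mesh)
  inc <- f[f[, 1] == center | f[, 2] == center | f[, 3] == center, ,
           drop = FALSE]
  nb <- sort(unique(setdiff(as.vector(inc), center)))
  if (!length(nb)) stop("center vertex has no neighbors")
  n <- meshNormals(mesh)[center, ]
  v <- vertices(mesh)
  for (j in nb) {
    d <- v[j, ] - v[center, ]
    tang <- d - sum(d * n) * n
    if (sqrt(sum(tang^2)) > 1e-8) {
      e1 <- tang / sqrt(sum(tang^2))
      e2 <- c(n[2] * e1[3] - n[3] * e1[2],
              n[3] * e1[1] - n[1] * e1[3],
              n[1] * e1[2] - n[2] * e1[1])
      return(list(e1 = e1, e2 = e2, n = n))
    }
  }
  stop("degenerate tangent plane at center vertex")
}

.patch_from_distances <- function(mesh, center, d, radius, minVertices = 8L) {
  ids <- which(d <= radius)
  if (length(ids) < minVertices)
    stop(sprintf("patch at vertex %d too sparse (%d vertices): mesh resolution too coarse",
                 center, length(ids)))
  b <- .tangent_basis(mesh, center)
  v <- vertices(mesh)
  rel <- sweep(v[ids, , drop = FALSE], 2, v[center, ])
  theta <- atan2(rel %*% b$e2, rel %*% b$e1) %% (2 * pi)
  theta[theta >= 2 * pi] <- 0            # guard the floating-point wrap
  theta[ids == center] <- 0
  feats <- featureMatrix(mesh)
  pf <- if (ncol(feats)) feats[ids, , drop = FALSE]
  else matrix(numeric(0), length(ids), 0)
  new("Patch", center = as.integer(center), vertexIds = as.integer(ids),
      rho = unname(d[ids]), theta = as.vector(theta), features = pf,
      radius = radius)
}

#' Extract a geodesic surface patch
#'
#' All vertices within geodesic `radius` of `center`, with geodesic
#' distance rho and an angular coordinate theta obtained by projecting onto
#' the tangent plane at the center; the zero direction is the projected
#' edge to the lowest-index neighbor (arbitrary but deterministic — the
#' encoder's rotation max-pooling absorbs the ambiguity). The 6 Angstrom
#' default radius is the minimum convolution unit of the method.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param center vertex index.
#' @param radius geodesic patch radius, Angstrom (default 6).
#' @param minVertices patches with fewer member vertices raise a
#'   "too sparse" error (default 8).
#' @return a [Patch-class].
#' @export
extractPatch <- function(mesh, center, radius = 6, minVertices = 8L) {
  stopifnot(center >= 1, center <= nVertices(mesh))
  d <- .geodesic_rows(mesh, center)[1, ]
  .patch_from_distances(mesh, center, d, radius, minVertices)
}

#' Extract many patches sharing one distance computation
#'
#' @param mesh a [SurfaceMesh-class].
#' @param centers integer vector of center vertices.
#' @param radius geodesic patch radius, Angstrom.
#' @param minVertices minimum patch size (see [extractPatch()]).
#' @return a list of [Patch-class], one per center.
#' @export
extractPatches <- function(mesh, centers, radius = 6, minVertices = 8L) {
  g <- .mesh_graph(mesh)
  D <- .geodesic_rows(mesh, centers, graph = g)
  lapply(seq_along(centers), function(i)
    .patch_from_distances(mesh, centers[i], D[i, ], radius, minVertices))
}
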