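# Descriptor-distance search, hit grouping/extension, and the similarity
# scores: reciprocal-mean ss, joint SS_AB, coverage ratio, and the
# all-against-all interface comparison.

#' Find descriptor hits between two surfaces
#'
#' Exact all-pairs search: every (query, candidate) descriptor pair with
#' Euclidean distance at most `cutoff` (the method's operational descriptor
#' cutoff is 3.5).
#'
#' @param queryDescriptors,candidateDescriptors matrices with one
#'   descriptor per row; rownames (if present) are vertex indices.
#' @param cutoff descriptor distance cutoff (default 3.5).
#' @return data.frame with columns `query`, `candidate` (vertex indices)
#'   and `distance`, ordered by query then distance.
#' @export
findHits <- function(queryDescriptors, candidateDescriptors, cutoff = 3.5) {
  q <- as.matrix(queryDescriptors); c <- as.matrix(candidateDescriptors)
  if (ncol(q) != ncol(c))
    stop(sprintf("descriptor dimension mismatch: %d vs %d", ncol(q), ncol(c)))
  qid <- as.integer(rownames(q) %||% seq_len(nrow(q)))
  cid <- as.integer(rownames(c) %||% seq_len(nrow(c)))
  d2 <- outer(rowSums(q^2), rowSums(c^2), "+") - 2 * tcrossprod(q, c)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  out <- data.frame(query = qid[hit[, 1]], candidate = cid[hit[, 2]],
                    distance = sqrt(d2[hit]))
  out[order(out$query, out$distance, out$candidate), , drop = FALSE]
}

#' Group hits into contiguous matched surface regions
#'
#' Each query vertex is represented by its best (lowest-distance) hit, ties
#' broken by lowest candidate index. Two represented vertices are connected
#' when they lie within `neighborRadius` (Euclidean) on the query surface
#' AND their best-hit candidate vertices lie within `neighborRadius` on the
#' candidate surface (connectivity is required on both sides). Connected
#' components define the groups; components with fewer than `minGroupSize`
#' query vertices (singletons in the limiting case) are discarded, and a
#' discarded vertex never reappears through extension. Grouping exists to
#' suppress the false positives that isolated low-descriptor-distance hits
#' produce by statistical fluctuation; the default minimum of 8 supporting
#' centers mirrors the minimum patch size — a matched region with less
#' support is below the method's resolution.
#' A group's candidate region is built from its representative hits; all
#' correspondences of assigned query vertices that point into that region
#' are kept for scoring. Surviving groups are scored by the reciprocal-mean of their
#' correspondence distances and, when `extend = TRUE`, extended by every
#' mesh vertex within geodesic `extensionRadius` of a member vertex (on
#' each surface).
#'
#' @param hits data.frame from [findHits()].
#' @param queryMesh,candidateMesh the two [SurfaceMesh-class] surfaces.
#' @param neighborRadius Euclidean grouping radius, Angstrom (default 3).
#' @param extensionRadius geodesic extension radius, Angstrom (default 6,
#'   one patch unit).
#' @param extend apply the geodesic extension (default TRUE).
#' @param minGroupSize minimum number of query vertices a component needs
#'   to survive (default 8; 2 reproduces the bare singleton-discard rule).
#' @return list of [HitGroup-class], largest first; empty list when there
#'   are no hits.
#' @export
groupHits <- function(hits, queryMesh, candidateMesh, neighborRadius = 3,
                      extensionRadius = 6, extend = TRUE, minGroupSize = 8L) {
  if (is.null(hits) || !nrow(hits)) return(list())
  stopifnot(all(hits$query >= 1), all(hits$query <= nVertices(queryMesh)),
            all(hits$candidate >= 1),
            all(hits$candidate <= nVertices(candidateMesh)))
  # best hit per query vertex (the vertex's representative correspondence)
  ord <- order(hits$query, hits$distance, hits$candidate)
  best <- hits[ord[!duplicated(hits$query[ord])], , drop = FALSE]
  qv <- vertices(queryMesh)[best$query, , drop = FALSE]
  cv <- vertices(candidateMesh)[best$candidate, , drop = FALSE]
  dq <- outer(rowSums(qv^2), rowSums(qv^2), "+") - 2 * tcrossprod(qv)
  dc <- outer(rowSums(cv^2), rowSums(cv^2), "+") - 2 * tcrossprod(cv)
  adj <- (dq <= neighborRadius^2) & (dc <= neighborRadius^2)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  vertex_comp <- stats::setNames(comp, best$query)

  gq <- .mesh_graph(queryMesh)
  gc <- .mesh_graph(candidateMesh)
  groups <- list()
  for (ci in sort(unique(comp))) {
    qs <- best$query[comp == ci]
    if (length(qs) < max(2L, minGroupSize)) next    # below resolution: discarded
    qset <- sort(unique(qs))
    cset <- sort(unique(best$candidate[comp == ci]))
    co <- hits[hits$query %in% qs & hits$candidate %in% cset,
               c("query", "candidate", "distance"), drop = FALSE]
    rownames(co) <- NULL
    if (extend) {
      dq_ext <- .geodesic_rows(queryMesh, qset, graph = gq)
      qset <- sort(unique(c(qset, which(apply(dq_ext <= extensionRadius, 2, any)))))
      dc_ext <- .geodesic_rows(candidateMesh, cset, graph = gc)
      cset <- sort(unique(c(cset, which(apply(dc_ext <= extensionRadius, 2, any)))))
    }
    groups[[length(groups) + 1L]] <-
      new("HitGroup", queryVertices = as.integer(qset),
          candidateVertices = as.integer(cset), correspondences = co,
          ss = 1 / (1 + mean(co$distance)), extended = extend)
  }
  groups[order(-vapply(groups, function(g) length(g@queryVertices), numeric(1)))]
}

#' Filter hit groups to reportable region matches
#'
#' A reported surface-region match must be supported by at least one
#' patch-unit's worth of matched centers: the method's minimum similarity
#' unit is the fixed-radius geodesic patch, so a candidate region backed by
#' fewer matched centers than fit in a single patch is a descriptor-space
#' coincidence rather than a region-level match — exactly the false
#' positives the grouping step exists to suppress. The support threshold is
#' the median patch vertex count of the query mesh (estimated on a seeded
#' vertex sample), so it adapts to mesh resolution and introduces no new
#' constant beyond the patch radius itself.
#'
#' @param groups list of [HitGroup-class] from [groupHits()].
#' @param queryMesh the query [SurfaceMesh-class].
#' @param patchRadius the patch unit, Angstrom (default 6).
#' @param minSupport override the support threshold directly (number of
#'   distinct matched query vertices).
#' @return the surviving groups, largest first.
#' @export
filterGroups <- function(groups, queryMesh, patchRadius = 6,
                         minSupport = NULL) {
  if (!length(groups)) return(groups)
  if (is.null(minSupport)) {
    n <- nVertices(queryMesh)
    probe <- .with_seed(7L, sample.int(n, min(20L, n)))
    D <- .geodesic_rows(queryMesh, probe)
    minSupport <- stats::median(apply(D, 1, function(d)
      sum(d <= patchRadius)))
  }
  support <- vapply(groups, function(g)
    length(unique(g@correspondences$query)), numeric(1))
  groups[support >= minSupport]
}

#' Reciprocal-mean similarity score of a hit group
#'
#' ss = 1 / (1 + mean descriptor distance over the group's
#' correspondences), mapping distances in \[0, Inf) onto (0, 1\]: 1 for a
#' perfect match, strictly decreasing as any correspondence's distance
#' grows.
#'
#' @param group a [HitGroup-class] with at least one correspondence.
#' @return numeric in (0, 1].
#' @export
reciprocalMeanScore <- function(group) {
  co <- group@correspondences
  if (!nrow(co)) stop("empty group: no correspondences to score")
  1 / (1 + mean(co$distance))
}

#' Joint interface similarity score
#'
#' SS_AB = ss_AB * ss_A'B': the product of the similarity score of the two
#' interface sides (A vs B, and their binding partners A' vs B').
#' Symmetric under swapping the roles of the two interfaces.
#'
#' @param ssAB,ssApBp similarity scores in (0, 1].
#' @return their product.
#' @export
jointInterfaceScore <- function(ssAB, ssApBp) {
  stopifnot(ssAB > 0, ssAB <= 1, ssApBp > 0, ssApBp <= 1)
  ssAB * ssApBp
}

#' Coverage ratio of an interface by hit groups
#'
#' The fraction of the interface's vertices covered by any (extended) hit
#' group on the given side: the clustering metric for epitope/paratope
#' comparison. Monotone nondecreasing in the group set.
#'
#' @param interface a [RegionMask-class] (nonempty).
#' @param groups list of [HitGroup-class].
#' @param side which side of the groups covers this interface:
#'   "candidate" (default) or "query".
#' @return numeric in \[0, 1\].
#' @export
coverageRatioScore <- function(interface, groups, side = c("candidate", "query")) {
  side <- match.arg(side)
  iv <- which(maskFlags(interface))
  if (!length(iv)) stop("empty interface mask")
  covered <- unique(unlist(lapply(groups, function(g)
    if (side == "candidate") g@candidateVertices else g@queryVertices)))
  length(intersect(iv, covered)) / length(iv)
}

#' All-against-all interface similarity and clustering
#'
#' For every ordered pair of interfaces, finds descriptor hits from the
#' query interface's patches into the candidate surface, groups and extends
#' them, and scores coverage of the candidate interface; the matrix is then
#' symmetrized by the mean of the two directions. Average-linkage
#' hierarchical clustering on (1 - score) with a configurable cut gives the
#' cluster labels.
#'
#' @param interfaces list of lists, each with elements `mesh`
#'   ([SurfaceMesh-class]), `mask` ([RegionMask-class]) and `descriptors`
#'   (matrix over all mesh vertices, rownames = vertex indices). Names are
#'   used as interface labels.
#' @param cutoff descriptor distance cutoff (default 3.5).
#' @param neighborRadius,extensionRadius grouping parameters, Angstrom.
#' @param clusterCut height at which the dendrogram is cut (on 1 - score;
#'   default 0.5).
#' @return list with `scores` (symmetric matrix), `clusters` (named integer
#'   labels), `hclust` (the dendrogram object), and `order` (heatmap-ready
#'   leaf order).
#' @export
allVsAll <- function(interfaces, cutoff = 3.5, neighborRadius = 3,
                     extensionRadius = 6, clusterCut = 0.5) {
  n <- length(interfaces)
  stopifnot(n >= 1)
  labs <- names(interfaces) %||% paste0("interface", seq_len(n))
  S <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    qi <- interfaces[[i]]; cj <- interfaces[[j]]
    qsel <- which(maskFlags(qi$mask))
    qdesc <- qi$descriptors[as.character(qsel), , drop = FALSE]
    hits <- findHits(qdesc, cj$descriptors, cutoff)
    groups <- groupHits(hits, qi$mesh, cj$mesh, neighborRadius,
                        extensionRadius)
    S[i, j] <- if (length(groups)) coverageRatioScore(cj$mask, groups) else 0
  }
  S <- (S + t(S)) / 2
  if (n == 1)
    return(list(scores = S, clusters = stats::setNames(1L, labs),
                hclust = NULL, order = 1L))
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  cl <- stats::cutree(hc, h = clusterCut)
  list(scores = S, clusters = cl, hclust = hc, order = hc$order)
}
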