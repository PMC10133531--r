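# Rigid alignment: centroid translation plus rotational refinement by
# gradient descent on an axis-angle parameterization of SO(3), minimizing
# RMSD over fixed correspondences. A closed-form Kabsch superposition is
# provided as the internal oracle.

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix, det +1.
#' @param translation length-3 numeric vector, Angstrom.
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = translation)
}

#' Apply a rigid transform
#'
#' Maps every coordinate x to R x + t. Methods exist for plain k x 3
#' matrices, [AtomSet-class] (identities untouched) and
#' [SurfaceMesh-class] (normals rotated, features untouched).
#'
#' @param x the object to transform.
#' @param transform a [RigidTransform-class].
#' @return the transformed object.
#' @export
setGeneric("applyTransform", function(x, transform) standardGeneric("applyTransform"))

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
})

#' @rdname applyTransform
setMethod("applyTransform", "AtomSet", function(x, transform) {
  a <- atomData(x)
  xyz <- applyTransform(unname(as.matrix(a[, c("x", "y", "z")])), transform)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("AtomSet", atoms = a)
})

#' @rdname applyTransform
setMethod("applyTransform", "SurfaceMesh", function(x, transform) {
  x@vertices <- applyTransform(x@vertices, transform)
  if (nrow(x@normals)) x@normals <- x@normals %*% t(transform@rotation)
  x
})

#' Invert a rigid transform
#' @param transform a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.vector(-Rt %*% transform@translation))
}

#' Compose two rigid transforms (`first`, then `second`)
#' @param first,second [RigidTransform-class] objects.
#' @return the composed [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  new("RigidTransform",
      rotation = second@rotation %*% first@rotation,
      translation = as.vector(second@rotation %*% first@translation) +
        second@translation)
}

# Rodrigues: axis-angle 3-vector -> rotation matrix
.axis_angle_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Closed-form optimal rigid superposition (Kabsch)
#'
#' SVD-based least-squares superposition of `candidate` onto `query` under
#' fixed index correspondences; the internal oracle the gradient-descent
#' aligner is validated against.
#'
#' @param query,candidate k x 3 coordinate matrices (k >= 3).
#' @return a list with `transform` ([RigidTransform-class]) and `rmsd`.
#' @export
kabschAlign <- function(query, candidate) {
  .check_points(query, candidate)
  qc <- colMeans(query); cc <- colMeans(candidate)
  Q <- sweep(query, 2, qc); C <- sweep(candidate, 2, cc)
  H <- t(C) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.vector(qc - R %*% cc)
  tr <- new("RigidTransform", rotation = R, translation = t)
  rmsd <- sqrt(mean(rowSums((applyTransform(candidate, tr) - query)^2)))
  list(transform = tr, rmsd = rmsd)
}

.check_points <- function(query, candidate) {
  stopifnot(is.matrix(query), is.matrix(candidate),
            ncol(query) == 3, ncol(candidate) == 3,
            nrow(query) == nrow(candidate))
  if (!all(is.finite(query)) || !all(is.finite(candidate)))
    stop("non-finite coordinates")
  if (nrow(query) < 3) stop("need at least 3 correspondences")
  for (m in list(query, candidate)) {
    cm <- sweep(m, 2, colMeans(m))
    if (sum(svd(cm)$d > 1e-8) < 2) stop("points are collinear or coincident")
  }
  invisible(TRUE)
}

.rmsd_of_rotation <- function(w, Q, C) {
  R <- .axis_angle_to_matrix(w)
  sqrt(mean(rowSums((C %*% t(R) - Q)^2)))
}

#' Rigidly align a candidate region onto a query region
#'
#' Centers both point sets on their centroids, then minimizes RMSD over
#' rotations by gradient descent on an axis-angle parameterization from
#' `nRestarts` seeded random initial rotations (the identity is always one
#' of them), keeping the best final RMSD. The step size adapts (grow on
#' improvement, shrink on failure) so the optimum is polished to well below
#' the 1e-3 Angstrom agreement expected against the closed-form Kabsch
#' superposition. The returned RMSD never exceeds the centroid-only RMSD.
#'
#' @param queryPoints,candidatePoints k x 3 matrices, corresponding by row.
#' @param nRestarts number of random initial rotations (default 8).
#' @param maxSteps gradient-descent iteration cap per restart.
#' @param seed integer seed for the random restarts.
#' @return an [AlignmentResult-class]; its transform maps candidate onto
#'   query coordinates.
#' @export
alignRegions <- function(queryPoints, candidatePoints, nRestarts = 8,
                         maxSteps = 500, seed = 1) {
  .check_points(queryPoints, candidatePoints)
  qc <- colMeans(queryPoints); cc <- colMeans(candidatePoints)
  Q <- sweep(queryPoints, 2, qc); C <- sweep(candidatePoints, 2, cc)

  starts <- .with_seed(seed, {
    c(list(c(0, 0, 0)),
      lapply(seq_len(max(0, nRestarts - 1)), function(i) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ax * runif(1, 0, pi)
      }))
  })

  best_w <- c(0, 0, 0)
  best_f <- .rmsd_of_rotation(best_w, Q, C)
  h <- 1e-5
  for (w0 in starts) {
    w <- w0
    f <- .rmsd_of_rotation(w, Q, C)
    lr <- 0.05
    for (step in seq_len(maxSteps)) {
      g <- vapply(1:3, function(d) {
        e <- numeric(3); e[d] <- h
        (.rmsd_of_rotation(w + e, Q, C) - .rmsd_of_rotation(w - e, Q, C)) / (2 * h)
      }, numeric(1))
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12 || lr < 1e-12) break
      w_new <- w - lr * g
      f_new <- .rmsd_of_rotation(w_new, Q, C)
      if (f_new < f) {
        w <- w_new; f <- f_new; lr <- lr * 1.2
      } else {
        lr <- lr * 0.5
      }
    }
    if (f < best_f) { best_f <- f; best_w <- w }
  }

  R <- .axis_angle_to_matrix(best_w)
  initial_rmsd <- .rmsd_of_rotation(c(0, 0, 0), Q, C)
  if (best_f > initial_rmsd) { R <- diag(3); best_f <- initial_rmsd }
  t <- as.vector(qc - R %*% cc)
  tr <- new("RigidTransform", rotation = R, translation = t)
  aligned <- applyTransform(candidatePoints, tr)
  close_frac <- mean(sqrt(rowSums((aligned - queryPoints)^2)) < 2)
  new("AlignmentResult", transform = tr, rmsd = best_f,
      initialRmsd = initial_rmsd, nPoints = nrow(queryPoints),
      alignmentScore = close_frac / (1 + best_f))
}

#' Extract paired point lists from a hit group
#'
#' One query/candidate coordinate pair per correspondence; query vertices
#' hit by several candidate vertices are collapsed to their lowest-
#' descriptor-distance pair (ties broken by lowest candidate index).
#'
#' @param group a [HitGroup-class] with at least 3 correspondences.
#' @param queryMesh,candidateMesh the two [SurfaceMesh-class] surfaces.
#' @return list with `query` and `candidate` k x 3 matrices and the deduped
#'   `correspondences` data.frame.
#' @export
matchCorrespondences <- function(group, queryMesh, candidateMesh) {
  co <- group@correspondences
  if (nrow(co) < 3) stop("need at least 3 correspondences")
  co <- co[order(co$query, co$distance, co$candidate), , drop = FALSE]
  co <- co[!duplicated(co$query), , drop = FALSE]
  if (nrow(co) < 3) stop("fewer than 3 usable pairs after deduplication")
  list(query = vertices(queryMesh)[co$query, , drop = FALSE],
       candidate = vertices(candidateMesh)[co$candidate, , drop = FALSE],
       correspondences = co)
}

#' Align every hit group and attach a second similarity score
#'
#' Runs [matchCorrespondences()] + [alignRegions()] on each group. The
#' alignment acts as an independent geometric check on a descriptor match:
#' a genuinely similar region superposes rigidly with low RMSD while a
#' spurious descriptor cluster does not, so hit groups can be filtered by
#' `alignmentScore` (degenerate groups — coincident or collinear points —
#' score 0). With `prune = TRUE` (the default) each group is additionally
#' made rigid-consistent: correspondences whose post-alignment residual
#' exceeds `residualCutoff` (2 Angstrom, the same closeness criterion the
#' alignment score uses) are dropped and the group's vertex sets are
#' rebuilt from the surviving hits, re-extended geodesically. This removes
#' chained best-hit stragglers that drift away from the rigidly matched
#' region while connected through intermediate hits.
#'
#' @param groups list of [HitGroup-class].
#' @param queryMesh,candidateMesh the two [SurfaceMesh-class] surfaces.
#' @param minScore drop groups with alignment score below this (default 0:
#'   keep all).
#' @param prune drop rigid-inconsistent correspondences and rebuild the
#'   group (default TRUE).
#' @param residualCutoff post-alignment residual above which a
#'   correspondence is inconsistent, Angstrom.
#' @param extensionRadius geodesic re-extension radius after pruning
#'   (matches [groupHits()]'s default).
#' @param seed,nRestarts,maxSteps passed to [alignRegions()].
#' @return the surviving groups, each with a `list(result, score)` attached
#'   via `attr(group, "alignment")`, sorted by decreasing score.
#' @export
alignGroups <- function(groups, queryMesh, candidateMesh, minScore = 0,
                        prune = TRUE, residualCutoff = 2,
                        extensionRadius = 6, seed = 1, nRestarts = 8,
                        maxSteps = 500) {
  scored <- lapply(groups, function(g) {
    res <- tryCatch({
      mc <- matchCorrespondences(g, queryMesh, candidateMesh)
      alignRegions(mc$query, mc$candidate, nRestarts = nRestarts,
                   maxSteps = maxSteps, seed = seed)
    }, error = function(e) NULL)
    if (!is.null(res) && prune) {
      co <- g@correspondences
      moved <- applyTransform(
        vertices(candidateMesh)[co$candidate, , drop = FALSE], res@transform)
      resid <- sqrt(rowSums((moved -
                               vertices(queryMesh)[co$query, , drop = FALSE])^2))
      kept <- co[resid <= residualCutoff, , drop = FALSE]
      if (nrow(kept) >= 3 && length(unique(kept$query)) >= 2) {
        qset <- sort(unique(kept$query))
        cset <- sort(unique(kept$candidate))
        if (g@extended) {
          dq <- .geodesic_rows(queryMesh, qset)
          qset <- sort(unique(c(qset, which(apply(dq <= extensionRadius, 2,
                                                  any)))))
          dc <- .geodesic_rows(candidateMesh, cset)
          cset <- sort(unique(c(cset, which(apply(dc <= extensionRadius, 2,
                                                  any)))))
        }
        g <- new("HitGroup", queryVertices = as.integer(qset),
                 candidateVertices = as.integer(cset),
                 correspondences = kept, ss = 1 / (1 + mean(kept$distance)),
                 extended = g@extended)
      }
    }
    attr(g, "alignment") <- list(
      result = res, score = if (is.null(res)) 0 else res@alignmentScore)
    g
  })
  sc <- vapply(scored, function(g) attr(g, "alignment")$score, numeric(1))
  scored[order(-sc)][sc[order(-sc)] >= minScore]
}

#' Graft a binding partner onto an aligned surface region
#'
#' Applies the region alignment transform to a partner structure (e.g. the
#' antibody bound to a matched epitope), mapping every atom x -> R x + t
#' while leaving identities untouched. The result can be written as PDB
#' with [writeAtomsPDB()].
#'
#' @param partnerAtoms an [AtomSet-class].
#' @param transform a [RigidTransform-class] (typically from
#'   [alignRegions()]).
#' @return the transformed [AtomSet-class].
#' @export
graftComplex <- function(partnerAtoms, transform) {
  applyTransform(partnerAtoms, transform)
}

#' Count steric clashes between two atom sets
#'
#' @param grafted,target [AtomSet-class] objects.
#' @param clashCutoff interatomic distance below which a pair counts as a
#'   clash, Angstrom (> 0).
#' @return a list with `count` and `pairs` (data.frame grafted_atom,
#'   target_atom, distance).
#' @export
clashReport <- function(grafted, target, clashCutoff = 2.5) {
  stopifnot(clashCutoff > 0)
  g <- atomCoords(grafted); t <- atomCoords(target)
  d2 <- outer(rowSums(g^2), rowSums(t^2), "+") - 2 * g %*% base::t(t)
  d2[d2 < 0] <- 0
  hit <- which(d2 < clashCutoff^2, arr.ind = TRUE)
  pairs <- data.frame(
    grafted_atom = atomData(grafted)$atom_id[hit[, 1]],
    target_atom = atomData(target)$atom_id[hit[, 2]],
    distance = sqrt(d2[hit]))
  list(count = nrow(pairs), pairs = pairs[order(pairs$distance), , drop = FALSE])
}
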