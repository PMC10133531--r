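#' @import methods
#' @importFrom stats sd rnorm runif density approx setNames aggregate
#' @importFrom utils head tail
NULL

#' AtomSet: atoms with coordinates and per-atom surface chemistry
#'
#' One row per atom: identity (element, residue, chain), coordinates in
#' Angstrom, and the derived per-atom quantities used for surface
#' featurization (van der Waals radius, simplified partial charge,
#' Kyte-Doolittle hydropathy of the parent residue, hydrogen-bond class).
#'
#' @slot atoms data.frame with columns atom_id, element, x, y, z,
#'   residue_name, residue_seq, insert, chain_id, atom_name, radius, charge,
#'   hydropathy, hbond (+1 donor, -1 acceptor, 0 neither).
#' @export
setClass("AtomSet", representation(atoms = "data.frame"))

setValidity("AtomSet", function(object) {
  a <- object@atoms
  need <- c("atom_id", "element", "x", "y", "z", "residue_name",
            "residue_seq", "insert", "chain_id", "atom_name", "radius",
            "charge", "hydropathy", "hbond")
  miss <- setdiff(need, names(a))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(a) && !all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite coordinates")
  if (nrow(a) && any(a$radius <= 0)) return("radii must be > 0")
  TRUE
})

#' SurfaceMesh: a featurized molecular surface
#'
#' A watertight single-component triangle mesh with outward unit normals and
#' an N x C per-vertex feature matrix. Feature channels are named; the
#' standard set is shape_index, mean_curvature, charge, hydropathy, hbond.
#' Vertex and face indices are 1-based.
#'
#' @slot vertices N x 3 numeric matrix, Angstrom.
#' @slot faces M x 3 integer matrix, counter-clockwise seen from outside.
#' @slot normals N x 3 outward unit normals.
#' @slot features N x C numeric matrix with named columns (may have 0 columns).
#' @slot vertexToAtom integer vector, nearest source atom per vertex (or
#'   length 0 for synthetic meshes).
#' @slot metadata list: provenance, standardization statistics, mesh id.
#' @export
setClass("SurfaceMesh", representation(
  vertices = "matrix", faces = "matrix", normals = "matrix",
  features = "matrix", vertexToAtom = "integer", metadata = "list"))

setValidity("SurfaceMesh", function(object) {
  n <- nrow(object@vertices)
  if (ncol(object@vertices) != 3L) return("vertices must be N x 3")
  if (ncol(object@faces) != 3L) return("faces must be M x 3")
  if (n == 0L) return("empty mesh")
  f <- object@faces
  if (any(f < 1L) || any(f > n)) return("face index out of range")
  if (!all(is.finite(object@vertices))) return("non-finite vertices")
  if (nrow(object@normals)) {
    if (nrow(object@normals) != n) return("normals dimension mismatch")
    len <- sqrt(rowSums(object@normals^2))
    if (any(abs(len - 1) > 1e-6)) return("normals must be unit length")
  }
  if (ncol(object@features)) {
    if (nrow(object@features) != n) return("features dimension mismatch")
    if (is.null(colnames(object@features))) return("feature channels must be named")
    if (!all(is.finite(object@features))) return("non-finite features")
    if ("shape_index" %in% colnames(object@features)) {
      si <- object@features[, "shape_index"]
      if (any(si < -1 - 1e-9 | si > 1 + 1e-9)) return("shape_index outside [-1, 1]")
    }
  }
  TRUE
})

#' RegionMask: a vertex subset of one mesh
#'
#' Flags the vertices of a mesh lying within `cutoff` Angstrom (Euclidean)
#' of a set of reference atoms: interfaces, epitopes, paratopes, query
#' regions.
#'
#' @slot meshId character mesh identifier.
#' @slot flags logical vector, one per mesh vertex.
#' @slot cutoff numeric, the defining distance in Angstrom.
#' @export
setClass("RegionMask", representation(
  meshId = "character", flags = "logical", cutoff = "numeric"))

setValidity("RegionMask", function(object) {
  if (length(object@cutoff) != 1L || object@cutoff <= 0) return("cutoff must be > 0")
  TRUE
})

#' Patch: a geodesic neighborhood in local polar coordinates
#'
#' All vertices within a fixed geodesic radius of a center vertex, with the
#' geodesic distance rho (Angstrom) and an angular coordinate theta
#' (radians in [0, 2*pi)) per vertex, plus the vertices' feature rows.
#'
#' @slot center integer center vertex index.
#' @slot vertexIds integer member vertex indices (center included).
#' @slot rho numeric geodesic distances, rho[center position] == 0.
#' @slot theta numeric angular coordinates (0 for the center).
#' @slot features |patch| x C matrix.
#' @slot radius numeric patch radius, Angstrom.
#' @export
setClass("Patch", representation(
  center = "integer", vertexIds = "integer", rho = "numeric",
  theta = "numeric", features = "matrix", radius = "numeric"))

setValidity("Patch", function(object) {
  i <- match(object@center, object@vertexIds)
  if (is.na(i)) return("center not among vertexIds")
  if (abs(object@rho[i]) > 1e-12) return("rho at center must be 0")
  if (any(object@rho > object@radius + 1e-9)) return("rho exceeds patch radius")
  if (any(object@theta < 0 | object@theta >= 2 * pi)) return("theta outside [0, 2*pi)")
  TRUE
})

#' SoftGrid: polar soft-pixel grid with Gaussian kernels
#'
#' The local polar binning a patch is projected onto: `nRadial` x `nAngular`
#' bins (default 5 x 16 = 80), each with a Gaussian kernel centered at
#' (rhoBar, thetaBar) of widths (sigmaRho, sigmaTheta). Bin order is
#' radial-major: bin (r, a) has index (r-1)*nAngular + a.
#'
#' @slot nRadial integer number of radial rings.
#' @slot nAngular integer number of angular sectors.
#' @slot rhoBar numeric bin-center radii per bin.
#' @slot thetaBar numeric bin-center angles per bin.
#' @slot sigmaRho numeric radial kernel width, Angstrom.
#' @slot sigmaTheta numeric angular kernel width, radians.
#' @slot patchRadius numeric patch radius the grid spans, Angstrom.
#' @export
setClass("SoftGrid", representation(
  nRadial = "integer", nAngular = "integer", rhoBar = "numeric",
  thetaBar = "numeric", sigmaRho = "numeric", sigmaTheta = "numeric",
  patchRadius = "numeric"))

setValidity("SoftGrid", function(object) {
  nb <- object@nRadial * object@nAngular
  if (length(object@rhoBar) != nb || length(object@thetaBar) != nb)
    return("bin centers must have nRadial * nAngular entries")
  if (object@sigmaRho <= 0 || object@sigmaTheta <= 0) return("sigma must be > 0")
  TRUE
})

#' PairSet: contrastive training pairs for one or more meshes
#'
#' Anchor patch centers with one positive (center within the positive
#' Euclidean cutoff, default 1.5 Angstrom) and several negatives (centers
#' beyond the negative cutoff, default 5 Angstrom) each.
#'
#' @slot pairs data.frame with columns mesh_id, anchor, positive and a list
#'   column negatives (integer vectors).
#' @slot positiveCutoff numeric, Angstrom.
#' @slot negativeCutoff numeric, Angstrom.
#' @slot seed integer seed that produced the sample.
#' @export
setClass("PairSet", representation(
  pairs = "data.frame", positiveCutoff = "numeric",
  negativeCutoff = "numeric", seed = "integer"))

#' DatasetSplit: structure-level train/validation/test partition
#'
#' Identifiers are partitioned at the structure (mesh) level so that no
#' surface contributes patches to more than one split.
#'
#' @slot train,validation,test character vectors of structure ids.
#' @export
setClass("DatasetSplit", representation(
  train = "character", validation = "character", test = "character"))

setValidity("DatasetSplit", function(object) {
  all_ids <- c(object@train, object@validation, object@test)
  if (anyDuplicated(all_ids))
    return("splits must be pairwise disjoint at the structure level")
  TRUE
})

#' SurfaceEncoder: geodesic convolutional patch encoder
#'
#' Two per-bin linear layers over the pooled soft grid, a rotation layer
#' evaluated at K discrete angular rotations of the bin grid with
#' element-wise max-pooling (making the descriptor invariant to the
#' arbitrary theta origin), and a linear head to the descriptor dimension.
#'
#' @slot config list of hyperparameters (see [encoderConfig()]).
#' @slot grid SoftGrid the encoder pools with.
#' @slot params list of weight matrices/vectors.
#' @slot trained logical.
#' @slot log data.frame training log (epoch losses, validation separation).
#' @export
setClass("SurfaceEncoder", representation(
  config = "list", grid = "SoftGrid", params = "list",
  trained = "logical", log = "data.frame"))

#' HitGroup: a matched pair of contiguous surface regions
#'
#' A connected set of descriptor hits between a query and a candidate
#' surface, optionally extended along each surface by a geodesic radius,
#' with the group's correspondences and reciprocal-mean score.
#'
#' @slot queryVertices integer query-side member vertices (extension included
#'   when `extended`).
#' @slot candidateVertices integer candidate-side member vertices.
#' @slot correspondences data.frame columns query, candidate, distance.
#' @slot ss numeric reciprocal-mean similarity in (0, 1].
#' @slot extended logical whether geodesic extension was applied.
#' @export
setClass("HitGroup", representation(
  queryVertices = "integer", candidateVertices = "integer",
  correspondences = "data.frame", ss = "numeric", extended = "logical"))

#' RigidTransform: proper rigid motion x -> R x + t
#'
#' @slot rotation 3 x 3 orthonormal matrix with det +1.
#' @slot translation length-3 numeric, Angstrom.
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation must have det +1")
  if (length(object@translation) != 3L) return("translation must have length 3")
  TRUE
})

#' AlignmentResult: outcome of rigid region alignment
#'
#' @slot transform RigidTransform mapping candidate points onto the query.
#' @slot rmsd numeric final RMSD, Angstrom.
#' @slot initialRmsd numeric centroid-only RMSD before rotation, Angstrom.
#' @slot nPoints integer number of correspondences used.
#' @slot alignmentScore numeric 1/(1+rmsd) times the fraction of
#'   correspondences within 2 Angstrom after alignment.
#' @export
setClass("AlignmentResult", representation(
  transform = "RigidTransform", rmsd = "numeric", initialRmsd = "numeric",
  nPoints = "integer", alignmentScore = "numeric"))

setValidity("AlignmentResult", function(object) {
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@rmsd > object@initialRmsd + 1e-9)
    return("rmsd above centroid-only starting RMSD")
  TRUE
})
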