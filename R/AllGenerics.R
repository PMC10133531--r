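#' Accessors for SurfaceMatch classes
#'
#' `vertices()`, `faces()`, `meshNormals()`, `featureMatrix()`,
#' `vertexToAtom()`, `meshMetadata()` read the slots of a [SurfaceMesh-class];
#' `nVertices()`/`nFaces()` count them; `atomData()` and `atomCoords()` read
#' an [AtomSet-class]; `maskFlags()` reads a [RegionMask-class];
#' `descriptorDim()` reads a [SurfaceEncoder-class].
#'
#' @param x an object of the documented class.
#' @return the slot contents (matrices, data.frames or scalars).
#' @name accessors
#' @aliases vertices faces meshNormals featureMatrix nVertices nFaces
#'   atomData atomCoords maskFlags vertexToAtom meshMetadata descriptorDim
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("meshNormals", function(x) standardGeneric("meshNormals"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("maskFlags", function(x) standardGeneric("maskFlags"))
#' @rdname accessors
#' @export
setGeneric("vertexToAtom", function(x) standardGeneric("vertexToAtom"))
#' @rdname accessors
#' @export
setGeneric("meshMetadata", function(x) standardGeneric("meshMetadata"))
#' @rdname accessors
#' @export
setGeneric("descriptorDim", function(x) standardGeneric("descriptorDim"))

#' @rdname accessors
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("faces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
setMethod("meshNormals", "SurfaceMesh", function(x) x@normals)
#' @rdname accessors
setMethod("featureMatrix", "SurfaceMesh", function(x) x@features)
#' @rdname accessors
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
#' @rdname accessors
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))
#' @rdname accessors
setMethod("vertexToAtom", "SurfaceMesh", function(x) x@vertexToAtom)
#' @rdname accessors
setMethod("meshMetadata", "SurfaceMesh", function(x) x@metadata)
#' @rdname accessors
setMethod("atomData", "AtomSet", function(x) x@atoms)
#' @rdname accessors
setMethod("atomCoords", "AtomSet", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))
#' @rdname accessors
setMethod("nVertices", "AtomSet", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("maskFlags", "RegionMask", function(x) x@flags)
#' @rdname accessors
setMethod("descriptorDim", "SurfaceEncoder", function(x) x@config$descriptorDim)

setMethod("show", "AtomSet", function(object) {
  a <- object@atoms
  cat(sprintf("AtomSet: %d atoms, %d residues, chains [%s]\n",
              nrow(a), length(unique(paste(a$chain_id, a$residue_seq, a$insert))),
              paste(unique(a$chain_id), collapse = ",")))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces, %d feature channel(s)%s\n",
              nrow(object@vertices), nrow(object@faces), ncol(object@features),
              if (ncol(object@features))
                paste0(" [", paste(colnames(object@features), collapse = ", "), "]")
              else ""))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask on '%s': %d / %d vertices flagged (cutoff %.2f A)\n",
              object@meshId, sum(object@flags), length(object@flags),
              object@cutoff))
})

setMethod("show", "Patch", function(object) {
  cat(sprintf("Patch at vertex %d: %d vertices, radius %.1f A, %d channel(s)\n",
              object@center, length(object@vertexIds), object@radius,
              ncol(object@features)))
})

setMethod("show", "SoftGrid", function(object) {
  cat(sprintf("SoftGrid: %d radial x %d angular = %d bins over %.1f A\n",
              object@nRadial, object@nAngular,
              object@nRadial * object@nAngular, object@patchRadius))
})

setMethod("show", "PairSet", function(object) {
  cat(sprintf("PairSet: %d anchors on %d mesh(es), pos < %.1f A, neg > %.1f A\n",
              nrow(object@pairs), length(unique(object@pairs$mesh_id)),
              object@positiveCutoff, object@negativeCutoff))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d validation / %d test structures\n",
              length(object@train), length(object@validation),
              length(object@test)))
})

setMethod("show", "SurfaceEncoder", function(object) {
  cat(sprintf("SurfaceEncoder: D=%d, grid %dx%d, %s\n",
              object@config$descriptorDim, object@config$nRadial,
              object@config$nAngular,
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "HitGroup", function(object) {
  cat(sprintf("HitGroup: %d query / %d candidate vertices, %d correspondences, ss=%.3f%s\n",
              length(object@queryVertices), length(object@candidateVertices),
              nrow(object@correspondences), object@ss,
              if (object@extended) " (extended)" else ""))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.1f deg, translation |t| = %.2f A\n",
              ang * 180 / pi, sqrt(sum(object@translation^2))))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: RMSD %.4f A (centroid-only %.4f) over %d points, score %.3f\n",
              object@rmsd, object@initialRmsd, object@nPoints,
              object@alignmentScore))
})
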