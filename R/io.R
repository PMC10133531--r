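# On-disk artifacts: binary little-endian PLY (per-vertex doubles, so
# round-trips are bitwise), OFF, descriptor containers, model checkpoints,
# transforms, run configs, manifests and structured logs.

.GEOM_PROPS <- c("x", "y", "z", "nx", "ny", "nz")

#' Write a mesh as binary little-endian PLY
#'
#' Vertex properties are x, y, z, nx, ny, nz plus every feature channel,
#' stored as float64 so that write -> read round-trips preserve all values
#' bitwise. Face indices are written 0-based as the PLY format requires.
#' A sidecar JSON (`<path>.json`) records provenance: the mesh metadata
#' (source, probe radius, isovalue, standardization statistics).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output path.
#' @param sidecar write the provenance JSON next to the mesh.
#' @return invisibly, `path`.
#' @export
writeMeshPLY <- function(mesh, path, sidecar = TRUE) {
  v <- vertices(mesh); f <- faces(mesh); nrm <- meshNormals(mesh)
  feats <- featureMatrix(mesh)
  if (!nrow(nrm)) nrm <- matrix(0, nrow(v), 3)
  props <- c(.GEOM_PROPS, colnames(feats))
  mat <- cbind(v, nrm, feats)
  header <- c(
    "ply", "format binary_little_endian 1.0",
    "comment SurfaceMatch featurized molecular surface",
    sprintf("element vertex %d", nrow(v)),
    sprintf("property double %s", props),
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.vector(t(mat)), con, size = 8, endian = "little")
  f0 <- t(f) - 1L
  fraw <- rbind(matrix(as.raw(3L), 1, ncol(f0)),
                matrix(writeBin(as.integer(f0), raw(), size = 4,
                                endian = "little"), 12, ncol(f0)))
  writeBin(as.vector(fraw), con)
  if (sidecar) {
    meta <- meshMetadata(mesh)
    meta$channels <- colnames(feats)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a binary PLY written by [writeMeshPLY()]
#'
#' @param path PLY path.
#' @param requiredChannels feature channels that must be present; a missing
#'   one raises an error naming it.
#' @return a [SurfaceMesh-class] (metadata restored from the sidecar JSON
#'   when present).
#' @export
readMeshPLY <- function(path, requiredChannels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("malformed PLY: missing end_header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply" || !any(grepl("binary_little_endian", header)))
    stop("unsupported PLY: expected binary_little_endian")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  props <- sub("property double ", "", grep("^property double ", header, value = TRUE))
  missing_geom <- setdiff(.GEOM_PROPS, props)
  if (length(missing_geom))
    stop(sprintf("PLY lacks required property '%s'", missing_geom[1]))
  channels <- setdiff(props, .GEOM_PROPS)
  miss <- setdiff(requiredChannels, channels)
  if (length(miss))
    stop(sprintf("PLY lacks required feature channel '%s'", miss[1]))
  mat <- matrix(readBin(con, numeric(), n = nv * length(props), size = 8,
                        endian = "little"), nv, length(props), byrow = TRUE)
  colnames(mat) <- props
  fraw <- matrix(readBin(con, raw(), n = nf * 13L), 13, nf)
  counts <- as.integer(fraw[1, ])
  if (any(counts != 3L)) stop("PLY contains non-triangular faces")
  f <- matrix(readBin(as.vector(fraw[-1, , drop = FALSE]), integer(),
                      n = 3L * nf, size = 4, endian = "little"),
              nf, 3, byrow = TRUE) + 1L
  feats <- mat[, channels, drop = FALSE]
  meta <- list(id = sub("\\.ply$", "", basename(path)))
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta$channels <- NULL
  }
  new("SurfaceMesh", vertices = unname(mat[, c("x", "y", "z")]),
      faces = f, normals = unname(mat[, c("nx", "ny", "nz")]),
      features = feats, vertexToAtom = integer(0), metadata = meta)
}

#' Write mesh geometry as OFF (text)
#' @param mesh a [SurfaceMesh-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMeshOFF <- function(mesh, path) {
  v <- vertices(mesh); f <- faces(mesh)
  lines <- c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
             sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
  writeLines(lines, path)
  invisible(path)
}

.model_hash <- function(model) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(model@params, tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Save / load an encoder checkpoint
#'
#' A single-file archive (RDS) holding the config, grid parameters, weight
#' arrays and training log.
#'
#' @param model a [SurfaceEncoder-class].
#' @param path checkpoint path.
#' @return `writeModel`: invisibly, `path`; `readModel`: the
#'   [SurfaceEncoder-class].
#' @export
writeModel <- function(model, path) {
  saveRDS(list(config = model@config,
               grid = list(nRadial = model@grid@nRadial,
                           nAngular = model@grid@nAngular,
                           patchRadius = model@grid@patchRadius,
                           sigmaRho = model@grid@sigmaRho,
                           sigmaTheta = model@grid@sigmaTheta),
               params = model@params, trained = model@trained,
               log = model@log), path, version = 2)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  x <- readRDS(path)
  g <- softGrid(x$grid$nRadial, x$grid$nAngular, x$grid$patchRadius,
                x$grid$sigmaRho, x$grid$sigmaTheta)
  new("SurfaceEncoder", config = x$config, grid = g, params = x$params,
      trained = x$trained, log = x$log %||% data.frame())
}

#' Write / read a descriptor container
#'
#' One binary container per mesh: center vertex ids, the D-dimensional
#' descriptors, and the hash of the model that produced them, so a search
#' can verify model compatibility.
#'
#' @param descriptors matrix, one descriptor per row, rownames = center
#'   vertex indices.
#' @param path output path.
#' @param model the [SurfaceEncoder-class] that produced them (for the
#'   hash), or a precomputed hash string.
#' @return `writeDescriptors`: invisibly, `path`; `readDescriptors`: a list
#'   with `descriptors` and `modelHash`.
#' @export
writeDescriptors <- function(descriptors, path, model = NULL) {
  hash <- if (is(model, "SurfaceEncoder")) .model_hash(model)
  else as.character(model %||% "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("SMDESC01", con, nchars = 8, eos = NULL)
  writeBin(c(nrow(descriptors), ncol(descriptors), nchar(hash)), con,
           size = 4, endian = "little")
  if (nchar(hash)) writeChar(hash, con, nchars = nchar(hash), eos = NULL)
  ids <- as.integer(rownames(descriptors) %||% seq_len(nrow(descriptors)))
  writeBin(ids, con, size = 4, endian = "little")
  writeBin(as.vector(t(descriptors)), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeDescriptors
#' @export
readDescriptors <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, "SMDESC01")) stop("not a descriptor container")
  hdr <- readBin(con, integer(), 3, size = 4, endian = "little")
  hash <- if (hdr[3] > 0) readChar(con, hdr[3], useBytes = TRUE) else ""
  ids <- readBin(con, integer(), hdr[1], size = 4, endian = "little")
  d <- matrix(readBin(con, numeric(), hdr[1] * hdr[2], size = 8,
                      endian = "little"), hdr[1], hdr[2], byrow = TRUE)
  rownames(d) <- as.character(ids)
  list(descriptors = d, modelHash = hash)
}

#' Serialize / read a rigid transform as a 4x4 homogeneous matrix (JSON)
#' @param transform a [RigidTransform-class].
#' @param path JSON path.
#' @return `writeTransformJSON`: invisibly, `path`; `readTransformJSON`:
#'   the [RigidTransform-class].
#' @export
writeTransformJSON <- function(transform, path) {
  M <- rbind(cbind(transform@rotation, transform@translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = M), path, digits = NA)
  invisible(path)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(path) {
  M <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  new("RigidTransform", rotation = M[1:3, 1:3], translation = M[1:3, 4])
}

#' Layered run configuration
#'
#' Collects the package defaults for every tunable (patch radius 6 A, grid
#' 5 x 16, pair cutoffs 1.5/5 A, descriptor cutoff 3.5, grouping radius
#' 3 A, extension radius 6 A, training hyperparameters, seed), optionally
#' overlaid with a YAML file and then explicit overrides (file < overrides,
#' mirroring file < CLI flags).
#'
#' @param file optional YAML config path.
#' @param overrides named list of values that win over the file.
#' @return a named list.
#' @export
runConfig <- function(file = NULL, overrides = list()) {
  cfg <- list(
    patch_radius = 6, n_radial = 5L, n_angular = 16L,
    positive_cutoff = 1.5, negative_cutoff = 5,
    patches_per_protein = 200L, n_negatives = 4L,
    descriptor_cutoff = 3.5, neighbor_radius = 3, extension_radius = 6,
    probe_radius = 1.4, target_edge_len = 1.0,
    descriptor_dim = 80L, n_rotations = 16L, margin = 5,
    learning_rate = 1e-3, batch_size = 128L, max_epochs = 30L,
    seed = 1L)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    cfg[names(y)] <- y
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Write the fully resolved config next to a run's outputs
#' @param config list from [runConfig()].
#' @param dir output directory.
#' @return invisibly, the file path.
#' @export
writeRunConfig <- function(config, dir) {
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a manifest of produced files with content hashes
#' @param dir output directory; every regular file except the manifest
#'   itself is listed.
#' @return invisibly, the manifest path.
#' @export
writeManifest <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  md5 <- unname(tools::md5sum(file.path(dir, files)))
  jsonlite::write_json(
    data.frame(file = files, md5 = md5, stringsAsFactors = FALSE),
    file.path(dir, "manifest.json"), pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

# timestamped, level-tagged log line to stderr and (optionally) a file
.log_msg <- function(level, msg, logfile = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
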