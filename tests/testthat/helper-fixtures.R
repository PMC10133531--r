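# Shared fixtures and independent oracles, built in code at test time.

# single-atom AtomSet builder
make_atoms <- function(coords, element = "C", residue = "ALA",
                       atom_name = "CA", charge = 0, chain = "A") {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  new("AtomSet", atoms = data.frame(
    atom_id = seq_len(n),
    element = rep_len(element, n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    residue_name = rep_len(residue, n),
    residue_seq = seq_len(n), insert = "",
    chain_id = rep_len(chain, n),
    atom_name = rep_len(atom_name, n),
    radius = 1.7, charge = rep_len(charge, n),
    hydropathy = 0, hbond = 0, stringsAsFactors = FALSE))
}

# regular triangulated plane grid (n x n vertices, spacing h, z = 0)
make_plane_mesh <- function(n = 9, h = 1) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  v <- cbind(g$x * h, g$y * h, 0)
  idx <- function(i, j) j * n + i + 1
  f <- NULL
  for (i in 0:(n - 2)) for (j in 0:(n - 2))
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
               c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  new("SurfaceMesh", vertices = v, faces = f,
      normals = matrix(rep(c(0, 0, 1), nrow(v)), ncol = 3, byrow = TRUE),
      features = matrix(numeric(0), nrow(v), 0),
      vertexToAtom = integer(0), metadata = list(id = "plane"))
}

plane_interior <- function(n = 9) {
  g <- expand.grid(x = seq_len(n) - 1, y = seq_len(n) - 1)
  which(g$x %in% 1:(n - 2) & g$y %in% 1:(n - 2))
}

# independent single-source shortest-path oracle (naive Dijkstra on the
# mesh edge list; no igraph)
dijkstra_oracle <- function(mesh, source) {
  ed <- meshEdges(mesh)
  n <- nVertices(mesh)
  adj <- vector("list", n)
  for (k in seq_len(nrow(ed))) {
    adj[[ed$v1[k]]] <- rbind(adj[[ed$v1[k]]], c(ed$v2[k], ed$length[k]))
    adj[[ed$v2[k]]] <- rbind(adj[[ed$v2[k]]], c(ed$v1[k], ed$length[k]))
  }
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# rank-statistic ROC-AUC oracle: P(negative distance > positive distance)
auc_oracle <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[length(pos) + seq_along(neg)]) -
     length(neg) * (length(neg) + 1) / 2) / (length(pos) * length(neg))
}

# featurized bumpy sphere: the standard 5-channel synthetic surface
featurized_sphere <- function(seed, subdivisions = 4) {
  m <- makeBumpySphere(seed, subdivisions = subdivisions)
  m <- computeGeometricFeatures(m)
  m@features <- cbind(m@features,
                      makeCorrelatedFeatures(m, 3, 3, seed + 1000,
                                             c("charge", "hydropathy", "hbond")))
  m
}

# memoised store for fixtures shared across test files (notably the
# trained encoders, reused between the separation and end-to-end tests)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the acceptance-scale training setup: 50 featurized meshes, 100 patches
# each, structure-level split 40/4/6
acceptance_dataset <- function() {
  fixture("acceptance_dataset", function() {
    meshes <- lapply(1:50, featurized_sphere)
    names(meshes) <- paste0("m", 1:50)
    pairs <- sampleTrainingPairs(meshes, 100L, 4L, seed = 3)
    split <- datasetSplit(train = paste0("m", 1:40),
                          validation = paste0("m", 41:44),
                          test = paste0("m", 45:50))
    list(meshes = meshes, pairs = pairs, split = split)
  })
}

acceptance_model <- function(seed = 1L) {
  fixture(paste0("acceptance_model_", seed), function() {
    ds <- acceptance_dataset()
    trainEncoder(ds$meshes, ds$pairs, ds$split,
                 encoderConfig(nChannels = 5L, seed = seed))
  })
}
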