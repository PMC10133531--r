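# Descriptor search, hit grouping, and the similarity score algebra.

test_that("findHits equals the exhaustive all-pairs oracle", {
  set.seed(21)
  q <- matrix(rnorm(100 * 8), 100); c <- matrix(rnorm(100 * 8), 100)
  hits <- findHits(q, c, cutoff = 3.5)
  D <- as.matrix(dist(rbind(q, c)))[1:100, 101:200]
  oracle <- which(D <= 3.5, arr.ind = TRUE)
  expect_equal(nrow(hits), nrow(oracle))
  key <- function(a, b) paste(a, b)
  expect_setequal(key(hits$query, hits$candidate),
                  key(oracle[, 1], oracle[, 2]))
  expect_equal(hits$distance,
               D[cbind(hits$query, hits$candidate)], tolerance = 1e-9)

  # identical sets: the diagonal (distance 0) is always present
  self <- findHits(q, q, cutoff = 3.5)
  expect_true(all(paste(1:100, 1:100) %in% paste(self$query, self$candidate)))
  # cutoff 0 with all-distinct descriptors: only exact coincidences
  expect_equal(nrow(findHits(q, c, cutoff = 0)), 0L)
  expect_error(findHits(q, c[, 1:5]), "dimension mismatch")
})

test_that("grouping matches a union-find oracle and drops singletons", {
  mesh <- makeIcosphere(3, radius = 10)
  v <- vertices(mesh)
  # construct hits: a tight cluster, a second far cluster, one isolated hit
  seed_v <- 17L
  d <- sqrt(rowSums(sweep(v, 2, v[seed_v, ])^2))
  clusterA <- order(d)[1:8]
  seed2 <- which.max(d)
  d2 <- sqrt(rowSums(sweep(v, 2, v[seed2, ])^2))
  clusterB <- order(d2)[1:8]
  iso <- order(pmin(d, d2), decreasing = TRUE)[1]
  hits <- data.frame(query = c(clusterA, clusterB, iso),
                     candidate = c(clusterA, clusterB, iso),
                     distance = 0.5)
  groups <- groupHits(hits, mesh, mesh, neighborRadius = 3,
                      extensionRadius = 6, extend = FALSE, minGroupSize = 2L)

  # union-find oracle on the query vertices (both sides identical here)
  uf <- seq_len(nrow(hits))
  find <- function(i) { while (uf[i] != i) i <- uf[i]; i }
  for (i in seq_len(nrow(hits))) for (j in seq_len(nrow(hits))) {
    if (sqrt(sum((v[hits$query[i], ] - v[hits$query[j], ])^2)) <= 3)
      uf[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(nrow(hits)), find, integer(1))
  oracle_sizes <- sort(as.vector(table(roots)), decreasing = TRUE)
  oracle_groups <- sum(oracle_sizes >= 2)

  expect_equal(length(groups), oracle_groups)
  expect_setequal(vapply(groups, function(g) length(g@queryVertices),
                         integer(1)),
                  oracle_sizes[oracle_sizes >= 2])
  # the isolated vertex appears in no group
  expect_false(any(vapply(groups, function(g) iso %in% g@queryVertices,
                          logical(1))))
  # each hit vertex belongs to exactly one group
  all_q <- unlist(lapply(groups, function(g) g@queryVertices))
  expect_false(anyDuplicated(all_q) > 0)
})

test_that("extension adds geodesic neighbors but never revives singletons", {
  mesh <- makeIcosphere(3, radius = 10)
  v <- vertices(mesh)
  d <- sqrt(rowSums(sweep(v, 2, v[1L, ])^2))
  cluster <- order(d)[1:6]
  iso <- which.max(d)
  hits <- data.frame(query = c(cluster, iso), candidate = c(cluster, iso),
                     distance = 0.2)
  g0 <- groupHits(hits, mesh, mesh, extend = FALSE, minGroupSize = 2L)
  g1 <- groupHits(hits, mesh, mesh, extend = TRUE, minGroupSize = 2L)
  expect_equal(length(g0), 1L)
  expect_equal(length(g1), 1L)
  expect_gt(length(g1[[1]]@queryVertices), length(g0[[1]]@queryVertices))
  expect_true(all(g0[[1]]@queryVertices %in% g1[[1]]@queryVertices))
  expect_false(iso %in% g1[[1]]@queryVertices)
  # extension respects the geodesic radius
  dmax <- max(vapply(g1[[1]]@queryVertices, function(u)
    min(geodesicDistances(mesh, u, 50)[as.character(cluster)], na.rm = TRUE),
    numeric(1)))
  expect_lte(dmax, 6 + 1e-9)
})

test_that("reciprocal-mean score maps distances onto (0, 1] monotonically", {
  mk <- function(d) new("HitGroup", queryVertices = seq_along(d),
                        candidateVertices = seq_along(d),
                        correspondences = data.frame(
                          query = seq_along(d), candidate = seq_along(d),
                          distance = d),
                        ss = 0, extended = FALSE)
  expect_equal(reciprocalMeanScore(mk(c(0, 0, 0))), 1)
  expect_equal(reciprocalMeanScore(mk(c(1, 1))), 0.5)
  base <- reciprocalMeanScore(mk(c(0.5, 1, 2)))
  for (i in 1:3) {
    d <- c(0.5, 1, 2); d[i] <- d[i] + 0.3
    expect_lt(reciprocalMeanScore(mk(d)), base)
  }
  expect_error(reciprocalMeanScore(mk(numeric(0))), "empty")
})

test_that("joint score is the exact product, symmetric, and bounded", {
  expect_identical(jointInterfaceScore(1, 1), 1)
  expect_identical(jointInterfaceScore(0.8, 0.5), 0.4)
  expect_identical(jointInterfaceScore(0.37, 0.91),
                   jointInterfaceScore(0.91, 0.37))
  for (i in 1:20) {
    s1 <- runif(1); s2 <- runif(1)
    expect_lte(jointInterfaceScore(s1, s2), min(s1, s2))
  }
})

test_that("coverage ratio counts covered interface vertices", {
  flags <- rep(FALSE, 50); flags[1:10] <- TRUE
  mask <- new("RegionMask", meshId = "m", flags = flags, cutoff = 3.5)
  mk <- function(cand) new("HitGroup", queryVertices = 1:2,
                           candidateVertices = as.integer(cand),
                           correspondences = data.frame(
                             query = 1L, candidate = cand[1],
                             distance = 0),
                           ss = 1, extended = TRUE)
  expect_equal(coverageRatioScore(mask, list()), 0)
  expect_equal(coverageRatioScore(mask, list(mk(c(1, 2, 3)))), 0.3)
  expect_equal(coverageRatioScore(mask, list(mk(1:10))), 1)
  expect_equal(coverageRatioScore(mask, list(mk(c(1, 2, 3, 40)))), 0.3)
  # monotone nondecreasing in the group set
  g1 <- list(mk(c(1, 2)))
  g2 <- c(g1, list(mk(c(3, 4))))
  expect_gte(coverageRatioScore(mask, g2), coverageRatioScore(mask, g1))
})

test_that("all-vs-all is symmetric, self-similar, and recovers planted pairs", {
  model <- fixture("small_model", function() {
    meshes <- lapply(31:36, featurized_sphere)
    names(meshes) <- paste0("t", 31:36)
    pairs <- sampleTrainingPairs(meshes, 60L, 4L, seed = 5)
    split <- datasetSplit(train = paste0("t", 31:34),
                          validation = paste0("t", 35:36))
    trainEncoder(meshes, pairs, split,
                 encoderConfig(nChannels = 5L, maxEpochs = 6L, seed = 2))
  })
  pp <- makePlantedPair(909, noiseSd = 0.05)
  third <- featurized_sphere(777)
  mk_int <- function(mesh, mask) list(
    mesh = mesh, mask = mask,
    descriptors = embedPatches(model, mesh))
  ints <- list(
    A = mk_int(pp$meshA, pp$maskA),
    B = mk_int(pp$meshB, pp$maskB),
    C = mk_int(third, new("RegionMask", meshId = "t777",
                          flags = maskFlags(pp$maskA), cutoff = 12)))
  res <- allVsAll(ints, cutoff = 3.5)
  expect_true(isSymmetric(res$scores, tol = 1e-12))
  expect_gte(res$scores["A", "A"], 0.99)           # self-coverage
  # the planted-identical pair outranks both unrelated pairs
  expect_gt(res$scores["A", "B"], res$scores["A", "C"])
  expect_gt(res$scores["A", "B"], res$scores["B", "C"])
  # and clusters together at any cut below its mutual score
  cl <- stats::cutree(res$hclust, h = 1 - res$scores["A", "B"] + 1e-6)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["C"]] == cl[["A"]])
})
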