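# Geodesic distances, patch extraction, soft-grid projection, pair sampling.

test_that("geodesic distances match the brute-force Dijkstra oracle", {
  mesh <- makeBumpySphere(4, subdivisions = 2)   # 162 vertices
  oracle <- dijkstra_oracle(mesh, 5)
  d <- geodesicDistances(mesh, 5, maxRadius = 1e6)
  expect_equal(unname(d[as.character(seq_len(nVertices(mesh)))]),
               oracle, tolerance = 1e-12)
  expect_identical(unname(d["5"]), 0)

  # truncation keeps exactly the in-radius set
  d6 <- geodesicDistances(mesh, 5, maxRadius = 6)
  expect_setequal(names(d6), as.character(which(oracle <= 6)))
})

test_that("a single edge with no shorter path has geodesic length L", {
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0), c(1, -3, 0))
  f <- rbind(c(1, 2, 3), c(2, 1, 4))
  m <- new("SurfaceMesh", vertices = v, faces = f,
           normals = matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE),
           features = matrix(numeric(0), 4, 0), vertexToAtom = integer(0),
           metadata = list(id = "wedge"))
  d <- geodesicDistances(m, 1, 10)
  expect_equal(unname(d["2"]), 2)
})

test_that("geodesic distance dominates Euclidean distance", {
  for (seed in c(2, 6)) {
    mesh <- makeBumpySphere(seed, subdivisions = 3)
    src <- seed * 10L
    d <- geodesicDistances(mesh, src, maxRadius = 1e6)
    eu <- sqrt(rowSums(sweep(vertices(mesh), 2, vertices(mesh)[src, ])^2))
    expect_true(all(d >= eu[as.integer(names(d))] - 1e-9))
  }
})

test_that("patches are monotone in radius and flat patches are Euclidean", {
  mesh <- featurized_sphere(3)
  p4 <- extractPatch(mesh, 100, radius = 4)
  p6 <- extractPatch(mesh, 100, radius = 6)
  expect_true(all(p4@vertexIds %in% p6@vertexIds))
  expect_identical(p6@rho[match(p6@center, p6@vertexIds)], 0)
  expect_equal(p6@radius, 6)                # the method's patch unit

  # flat triangulated grid: graph rho within 2% + one-edge slack of Euclid
  pm <- make_plane_mesh(13, h = 0.5)
  center <- plane_interior(13)[85]
  p <- extractPatch(pm, center, radius = 2.5)
  eu <- sqrt(rowSums(sweep(vertices(pm)[p@vertexIds, , drop = FALSE], 2,
                           vertices(pm)[center, ])^2))
  expect_true(all(p@rho <= eu * 1.45 + 1e-9))  # axis vs diagonal worst case
  expect_true(all(p@rho >= eu - 1e-9))
  # along the grid axes the path is exact
  on_axis <- which(abs(vertices(pm)[p@vertexIds, 2] -
                         vertices(pm)[center, 2]) < 1e-12)
  expect_equal(p@rho[on_axis], eu[on_axis], tolerance = 1e-12)

  expect_error(extractPatch(mesh, 1, radius = 0.2), "too sparse")
})

test_that("theta is deterministic and rotation-equivariant", {
  mesh <- featurized_sphere(5, subdivisions = 3)
  p1 <- extractPatch(mesh, 50, radius = 6)
  p2 <- extractPatch(mesh, 50, radius = 6)
  expect_identical(p1@theta, p2@theta)
  expect_true(all(p1@theta >= 0 & p1@theta < 2 * pi))

  tr <- rigidTransform(SurfaceMatch:::.axis_angle_to_matrix(c(1, 0.5, -0.2)),
                       c(3, 4, 5))
  p3 <- extractPatch(applyTransform(mesh, tr), 50, radius = 6)
  expect_equal(p3@rho, p1@rho, tolerance = 1e-9)
  dth <- (p3@theta - p1@theta) %% (2 * pi)
  dth <- pmin(dth, 2 * pi - dth)
  expect_lt(max(dth), 1e-6)                # co-rotating frame: same theta
})

test_that("soft grid has 80 bins and rows are probability distributions", {
  grid <- softGrid()
  expect_equal(grid@nRadial * grid@nAngular, 80L)   # 5 radial x 16 angular
  mesh <- featurized_sphere(2)
  set.seed(9)
  centers <- sample(nVertices(mesh), 30)
  patches <- extractPatches(mesh, centers, radius = 6)
  for (p in patches) {
    w <- softGridWeights(p, grid)
    expect_equal(ncol(w), 80L)
    expect_true(all(w >= 0))
    expect_lt(max(abs(rowSums(w) - 1)), 1e-6)
  }
})

test_that("a vertex at a bin center takes that bin's weight as sigma -> 0", {
  tight <- softGrid(sigmaRho = 1e-3, sigmaTheta = 1e-3)
  fake <- list(rho = tight@rhoBar[18], theta = tight@thetaBar[18])
  w <- softGridWeights(fake, tight)
  expect_equal(unname(w[1, 18]), 1, tolerance = 1e-12)
})

test_that("pair sampling honors the 1.5 A / 5 A contract deterministically", {
  meshes <- list(s1 = featurized_sphere(11), s2 = featurized_sphere(12))
  ps <- sampleTrainingPairs(meshes, 80L, 4L, seed = 7)
  pp <- ps@pairs
  for (mid in names(meshes)) {
    v <- vertices(meshes[[mid]])
    rows <- pp[pp$mesh_id == mid, ]
    pos_d <- sqrt(rowSums((v[rows$anchor, ] - v[rows$positive, ])^2))
    expect_true(all(pos_d < 1.5))                  # 100% of positives
    neg_d <- unlist(lapply(seq_len(nrow(rows)), function(i)
      sqrt(rowSums(sweep(v[rows$negatives[[i]], , drop = FALSE], 2,
                         v[rows$anchor[i], ])^2))))
    expect_true(all(neg_d > 5))                    # 100% of negatives
  }
  ps2 <- sampleTrainingPairs(meshes, 80L, 4L, seed = 7)
  expect_identical(ps@pairs, ps2@pairs)
  ps3 <- sampleTrainingPairs(meshes, 80L, 4L, seed = 8)
  expect_false(identical(ps@pairs, ps3@pairs))
})

test_that("a mesh too coarse for positives fails with a clear message", {
  coarse <- makeIcosphere(1, radius = 10)          # min spacing ~ 5 A
  expect_error(
    suppressMessages(sampleTrainingPairs(list(c = coarse), 20L, 2L, seed = 1)),
    "too coarse|fewer than")
})
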