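# The encoder: descriptor contracts, loss values, invariances, training.

test_that("contrastive loss reproduces hand-computed values", {
  expect_equal(contrastiveLoss(c(1, 2), c(1, 2),
                               list(c(10, 2), c(1, 22)), margin = 5), 0)
  expect_equal(contrastiveLoss(c(0, 0), c(3, 4)), 25)
  expect_equal(contrastiveLoss(c(0, 0), c(0, 0), list(c(1, 0)), margin = 5),
               16)                        # max(0, 5 - 1)^2
  expect_equal(contrastiveLoss(c(0, 0), c(1, 1), list()), 2)
  # zero iff positives coincide and negatives are >= margin away
  expect_gt(contrastiveLoss(c(0, 0), c(0, 0), list(c(4.9, 0)), 5), 0)
  expect_equal(contrastiveLoss(c(0, 0), c(0, 0), list(c(5, 0)), 5), 0)
})

test_that("descriptors have the configured dimension and invariances", {
  mesh <- featurized_sphere(8)
  enc <- surfaceEncoder(encoderConfig(nChannels = 5L, seed = 4))
  p <- extractPatch(mesh, 120, radius = 6)
  d <- embedPatch(enc, p)
  expect_length(d, 80L)
  expect_true(all(is.finite(d)))
  expect_identical(d, embedPatch(enc, p))  # deterministic

  # vertex permutation leaves the descriptor unchanged
  set.seed(3)
  perm <- sample(length(p@vertexIds))
  pp <- new("Patch", center = p@center, vertexIds = p@vertexIds[perm],
            rho = p@rho[perm], theta = p@theta[perm],
            features = p@features[perm, , drop = FALSE], radius = p@radius)
  expect_lt(max(abs(embedPatch(enc, pp) - d)), 1e-6)

  # shifting theta by one angular bin (2 pi / 16) changes nothing:
  # rotation max-pooling absorbs the theta origin
  shifted <- new("Patch", center = p@center, vertexIds = p@vertexIds,
                 rho = p@rho, theta = (p@theta + 2 * pi / 16) %% (2 * pi),
                 features = p@features, radius = p@radius)
  ds <- embedPatch(enc, shifted)
  expect_lt(max(abs(ds - d)) / max(abs(d)), 1e-5)

  # global rigid motion of the surface
  set.seed(6)
  tr <- rigidTransform(SurfaceMatch:::.random_rotation(), c(2, -4, 1))
  p_rot <- extractPatch(applyTransform(mesh, tr), 120, radius = 6)
  expect_lt(max(abs(embedPatch(enc, p_rot) - d)), 1e-3)

  # channel mismatch is an error
  p_bad <- new("Patch", center = p@center, vertexIds = p@vertexIds,
               rho = p@rho, theta = p@theta,
               features = p@features[, 1:3], radius = p@radius)
  expect_error(embedPatch(enc, p_bad), "channel")
})

test_that("descriptor distance behaves as a metric", {
  mesh <- featurized_sphere(9)
  enc <- surfaceEncoder(encoderConfig(nChannels = 5L, seed = 5))
  D <- embedPatches(enc, mesh, c(10L, 400L, 900L, 1500L))
  dm <- as.matrix(dist(D))
  expect_true(isSymmetric(dm))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(dm[i, k], dm[i, j] + dm[j, k] + 1e-9)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- encoderConfig(nChannels = 3L, nFilters = c(8L, 8L), hiddenDim = 12L,
                       descriptorDim = 16L, seed = 9)
  enc <- surfaceEncoder(cfg)
  perms <- SurfaceMatch:::.rotation_perms(cfg)
  set.seed(12)
  B <- 2L; nneg <- 2L
  X <- matrix(rnorm((2 * B + B * nneg) * 80 * 3), 2 * B + B * nneg)
  lossfn <- function(params) {
    fw <- SurfaceMatch:::.enc_forward(params, cfg, X, perms)
    SurfaceMatch:::.batch_loss_grad(fw$desc, B, nneg, cfg$margin)$loss
  }
  fw <- SurfaceMatch:::.enc_forward(enc@params, cfg, X, perms,
                                    want_cache = TRUE)
  lg <- SurfaceMatch:::.batch_loss_grad(fw$desc, B, nneg, cfg$margin)
  gr <- SurfaceMatch:::.enc_backward(enc@params, cfg, fw, lg$grad, perms)
  # check every entry of the small tensors and a sample of the big one;
  # finite differences are valid here because no rotation maxima are tied
  # at this seed (a tie makes the loss non-smooth and the comparison moot)
  set.seed(41)
  for (nm in names(enc@params)) {
    idx <- seq_along(gr[[nm]])
    if (length(idx) > 300) idx <- sample(idx, 300)
    for (i in idx) {
      h <- 1e-6
      p1 <- enc@params; p1[[nm]][i] <- p1[[nm]][i] + h
      p2 <- enc@params; p2[[nm]][i] <- p2[[nm]][i] - h
      num <- (lossfn(p1) - lossfn(p2)) / (2 * h)
      expect_lt(abs(unname(gr[[nm]][i]) - num), 1e-5)
    }
  }
})

test_that("structure-level split leakage is a hard error", {
  expect_error(datasetSplit(train = c("a", "b"), validation = "b"),
               "disjoint")
  # the class validity itself blocks leaky splits before any training
  expect_error(new("DatasetSplit", train = c("a", "b"), validation = "b",
                   test = character()), "disjoint")
})

test_that("training separates positives from negatives on held-out meshes", {
  meshes <- fixture("train_meshes_small", function() {
    m <- lapply(15:26, featurized_sphere)
    names(m) <- paste0("s", 15:26)
    m
  })
  pairs <- sampleTrainingPairs(meshes, 60L, 4L, seed = 4)
  split <- datasetSplit(train = paste0("s", 15:22),
                        validation = paste0("s", 23:24),
                        test = paste0("s", 25:26))
  model <- trainEncoder(meshes, pairs, split,
                        encoderConfig(nChannels = 5L, maxEpochs = 6L,
                                      seed = 3))
  expect_true(model@trained)
  expect_true(all(c("epoch", "train_loss", "val_pos_mean", "val_neg_mean")
                  %in% names(model@log)))
  rep <- pairwiseDistanceReport(model, meshes[split@test], pairs)
  expect_gt(mean(rep$negative), mean(rep$positive))
  expect_gt(rep$auc, 0.8)
  # the report uses only the supplied (test) meshes' pairs
  expect_length(rep$positive,
                sum(pairs@pairs$mesh_id %in% split@test))
  # AUC agrees with the rank-statistic oracle
  expect_equal(rep$auc, auc_oracle(rep$positive, rep$negative),
               tolerance = 1e-9)

  # an untrained encoder separates the same data strictly worse
  un <- surfaceEncoder(encoderConfig(nChannels = 5L, seed = 30))
  rep0 <- pairwiseDistanceReport(un, meshes[split@test], pairs)
  expect_gt(rep$auc, rep0$auc - 1e-9)
  expect_gt(rep0$overlap, rep$overlap)
})

test_that("checkpoints round-trip through writeModel/readModel", {
  enc <- surfaceEncoder(encoderConfig(nChannels = 5L, seed = 21))
  tf <- tempfile(fileext = ".ckpt")
  writeModel(enc, tf)
  enc2 <- readModel(tf)
  expect_identical(enc@params, enc2@params)
  expect_identical(enc@config, enc2@config)
  mesh <- featurized_sphere(19, subdivisions = 3)
  p <- extractPatch(mesh, 40, radius = 6)
  expect_identical(embedPatch(enc, p), embedPatch(enc2, p))
})
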