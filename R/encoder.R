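# Geodesic convolutional patch encoder with self-supervised contrastive
# training. Architecture: patch features are pooled into the 5 x 16 soft
# polar grid (per-bin Gaussian-weighted means), passed through two per-bin
# 1x1 linear layers with ReLU, then a full-grid linear layer evaluated at K
# discrete angular rotations of the bin grid with element-wise max-pooling
# (descriptor invariant to the arbitrary theta origin), and a linear head
# to the descriptor dimension. All gradients are written out by hand;
# optimization is Adam on minibatches of (anchor, positive, negatives).

#' Encoder hyperparameter configuration
#'
#' Defaults mirror the method's operating point: a 5 x 16 soft grid,
#' 80-dimensional descriptors, max-pooling over 16 discrete rotations, and
#' a contrastive margin of 5 (echoing the 5 Angstrom spatial negative
#' cutoff). The full-scale structure split (2700/100/50) is the default
#' `splitSizes`; desk-scale runs pass smaller numbers.
#'
#' @param nRadial,nAngular soft-grid layout (default 5 x 16).
#' @param nChannels number of feature channels C.
#' @param nFilters integer vector, filters of the two per-bin layers.
#' @param hiddenDim width of the rotation-pooled hidden layer.
#' @param descriptorDim descriptor dimension D (default 80).
#' @param nRotations K rotations max-pooled over; must divide nAngular.
#' @param margin contrastive hinge margin (embedding units, default 5).
#' @param learningRate Adam step size.
#' @param batchSize anchors per minibatch.
#' @param maxEpochs training epoch cap.
#' @param patience early-stopping patience on validation separation.
#' @param patchRadius geodesic patch radius, Angstrom.
#' @param splitSizes default train/test/validation structure counts.
#' @param seed integer seed controlling init and batch order.
#' @return a named list.
#' @export
encoderConfig <- function(nRadial = 5L, nAngular = 16L, nChannels = 5L,
                          nFilters = c(32L, 32L), hiddenDim = 64L,
                          descriptorDim = 80L, nRotations = 16L, margin = 5,
                          learningRate = 1e-3, batchSize = 128L,
                          maxEpochs = 8L, patience = 4L, patchRadius = 6,
                          splitSizes = c(train = 2700L, test = 100L,
                                         validation = 50L),
                          seed = 1L) {
  stopifnot(descriptorDim > 0, nRotations >= 1,
            nAngular %% nRotations == 0, length(nFilters) == 2)
  as.list(environment())
}

#' Construct a dataset split
#' @param train,validation,test character vectors of structure identifiers;
#'   must be pairwise disjoint.
#' @return a [DatasetSplit-class].
#' @export
datasetSplit <- function(train, validation = character(), test = character()) {
  new("DatasetSplit", train = as.character(train),
      validation = as.character(validation), test = as.character(test))
}

.init_params <- function(cfg) {
  nb <- cfg$nRadial * cfg$nAngular
  C <- cfg$nChannels; F1 <- cfg$nFilters[1]; F2 <- cfg$nFilters[2]
  H <- cfg$hiddenDim; D <- cfg$descriptorDim
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  .with_seed(cfg$seed, list(
    W1 = he(C, F1), b1 = numeric(F1),
    W2 = he(F1, F2), b2 = numeric(F2),
    W3 = he(nb * F2, H) / sqrt(nb), b3 = numeric(H),
    W4 = he(H, D), b4 = numeric(D)))
}

#' Create a (untrained) surface patch encoder
#'
#' @param config list from [encoderConfig()].
#' @return a [SurfaceEncoder-class] with seeded random weights.
#' @export
surfaceEncoder <- function(config = encoderConfig()) {
  grid <- softGrid(config$nRadial, config$nAngular, config$patchRadius)
  new("SurfaceEncoder", config = config, grid = grid,
      params = .init_params(config), trained = FALSE,
      log = data.frame())
}

# column permutations of the flattened (bin, filter) layout implementing
# angular rotations of the bin grid
.rotation_perms <- function(cfg) {
  nb <- cfg$nRadial * cfg$nAngular
  F2 <- cfg$nFilters[2]
  step <- cfg$nAngular / cfg$nRotations
  lapply(seq_len(cfg$nRotations) - 1L, function(r) {
    ring <- rep(seq_len(cfg$nRadial) - 1L, each = cfg$nAngular)
    ang <- rep(seq_len(cfg$nAngular) - 1L, times = cfg$nRadial)
    rot <- ring * cfg$nAngular + ((ang + r * step) %% cfg$nAngular) + 1L
    # column (k-1)*F2 + f of the rotated layout reads bin rot[k], filter f
    rep((rot - 1L) * F2, each = F2) + rep(seq_len(F2), times = nb)
  })
}

# pooled grid: per-bin Gaussian-weighted mean of the patch features
.pool_grid <- function(patch, grid) {
  w <- softGridWeights(patch, grid)
  ws <- colSums(w)
  G <- crossprod(w, patch@features)
  G[ws > 1e-8, ] <- G[ws > 1e-8, , drop = FALSE] / ws[ws > 1e-8]
  G[ws <= 1e-8, ] <- 0
  G
}

# Forward pass for B pooled grids. `pooled` is B x (nb*C) with column order
# channel-major (bin fastest). Returns descriptors and the cache needed for
# backprop.
.enc_forward <- function(params, cfg, pooled, perms, want_cache = FALSE) {
  nb <- cfg$nRadial * cfg$nAngular
  C <- cfg$nChannels; F2 <- cfg$nFilters[2]
  B <- nrow(pooled)
  arr <- array(t(pooled), dim = c(nb, C, B))
  X0 <- matrix(aperm(arr, c(1, 3, 2)), B * nb, C)     # rows: patch-major bins
  A1 <- sweep(X0 %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(A1, 0)
  A2 <- sweep(H1 %*% params$W2, 2, params$b2, "+")
  H2 <- pmax(A2, 0)
  arr2 <- array(H2, dim = c(nb, B, F2))
  Xflat <- t(matrix(aperm(arr2, c(3, 1, 2)), F2 * nb, B))  # B x (nb*F2)
  K <- length(perms)
  Zmax <- NULL; amax <- NULL
  for (r in seq_len(K)) {
    Zr <- sweep(Xflat %*% params$W3[perms[[r]], , drop = FALSE], 2,
                params$b3, "+")
    if (is.null(Zmax)) {
      Zmax <- Zr; amax <- matrix(1L, B, ncol(Zr))
    } else {
      upd <- Zr > Zmax
      Zmax[upd] <- Zr[upd]
      amax[upd] <- r
    }
  }
  H3 <- pmax(Zmax, 0)
  desc <- sweep(H3 %*% params$W4, 2, params$b4, "+")
  if (!want_cache) return(list(desc = desc))
  list(desc = desc, X0 = X0, H1 = H1, H2 = H2, A1 = A1, A2 = A2,
       Xflat = Xflat, Zmax = Zmax, amax = amax, H3 = H3)
}

# Backward pass: gradient of the scalar loss wrt all parameters given
# d loss / d descriptors.
.enc_backward <- function(params, cfg, cache, ddesc, perms) {
  nb <- cfg$nRadial * cfg$nAngular
  F2 <- cfg$nFilters[2]
  B <- nrow(ddesc)
  gW4 <- crossprod(cache$H3, ddesc)
  gb4 <- colSums(ddesc)
  dH3 <- ddesc %*% t(params$W4)
  dZ <- dH3 * (cache$Zmax > 0)
  gW3 <- matrix(0, nrow(params$W3), ncol(params$W3))
  gb3 <- colSums(dZ)
  dXflat <- matrix(0, B, nb * F2)
  for (r in seq_along(perms)) {
    M <- dZ * (cache$amax == r)
    if (!any(M != 0)) next
    gW3[perms[[r]], ] <- gW3[perms[[r]], ] + crossprod(cache$Xflat, M)
    dXflat <- dXflat + M %*% t(params$W3[perms[[r]], , drop = FALSE])
  }
  # unflatten: dXflat[i, (k-1)*F2+f] -> dH2[(i-1)*nb+k, f]
  arr <- array(t(dXflat), dim = c(F2, nb, B))
  dH2 <- matrix(aperm(arr, c(2, 3, 1)), B * nb, F2)
  dH2 <- dH2 * (cache$A2 > 0)
  gW2 <- crossprod(cache$H1, dH2)
  gb2 <- colSums(dH2)
  dH1 <- dH2 %*% t(params$W2)
  dH1 <- dH1 * (cache$A1 > 0)
  gW1 <- crossprod(cache$X0, dH1)
  gb1 <- colSums(dH1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4)
}

#' Contrastive margin loss for one (anchor, positive, negatives) tuple
#'
#' loss = ||a - p||^2 + sum_n max(0, margin - ||a - n||)^2. With no
#' negatives only the positive term remains. Zero iff the positive
#' coincides with the anchor and every negative is at least `margin` away.
#'
#' @param anchor,positive numeric descriptor vectors of equal length.
#' @param negatives list of descriptor vectors (possibly empty), or a
#'   matrix with one descriptor per row.
#' @param margin hinge margin (default 5).
#' @return nonnegative scalar.
#' @export
contrastiveLoss <- function(anchor, positive, negatives = list(), margin = 5) {
  if (is.matrix(negatives))
    negatives <- lapply(seq_len(nrow(negatives)), function(i) negatives[i, ])
  stopifnot(length(anchor) == length(positive))
  loss <- sum((anchor - positive)^2)
  for (n in negatives) {
    stopifnot(length(n) == length(anchor))
    loss <- loss + max(0, margin - sqrt(sum((anchor - n)^2)))^2
  }
  loss
}

# loss and descriptor gradients for a batch laid out as
# [anchors; positives; negatives(column-major by anchor)]
.batch_loss_grad <- function(desc, B, nneg, margin) {
  A <- desc[seq_len(B), , drop = FALSE]
  P <- desc[B + seq_len(B), , drop = FALSE]
  dAP <- A - P
  loss <- sum(dAP^2)
  gA <- 2 * dAP
  gP <- -2 * dAP
  gN <- NULL
  if (nneg > 0) {
    N <- desc[2 * B + seq_len(B * nneg), , drop = FALSE]
    Arep <- A[rep(seq_len(B), times = nneg), , drop = FALSE]
    dAN <- Arep - N
    dn <- sqrt(rowSums(dAN^2))
    act <- dn < margin
    loss <- loss + sum((margin - dn[act])^2)
    gN <- matrix(0, B * nneg, ncol(desc))
    if (any(act)) {
      coef <- 2 * (margin - dn[act]) / pmax(dn[act], 1e-9)
      gN[act, ] <- coef * dAN[act, , drop = FALSE]
      gAn <- rowsum(-gN, rep(seq_len(B), times = nneg))
      gA <- gA + gAn
    }
  }
  list(loss = loss / B, grad = rbind(gA, gP, gN) / B)
}

.adam_update <- function(params, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Precompute pooled grids for every patch center a PairSet references.
# Returns, per mesh, a (nCenters x nb*C) matrix plus a center -> row map.
.pool_pairset <- function(meshes, pairs, grid, cfg) {
  out <- list()
  for (mid in intersect(unique(pairs@pairs$mesh_id), names(meshes))) {
    pp <- pairs@pairs[pairs@pairs$mesh_id == mid, , drop = FALSE]
    centers <- sort(unique(c(pp$anchor, pp$positive,
                             unlist(pp$negatives))))
    patches <- extractPatches(meshes[[mid]], centers, radius = grid@patchRadius)
    pooled <- t(vapply(patches, function(p) as.vector(.pool_grid(p, grid)),
                       numeric(cfg$nRadial * cfg$nAngular * cfg$nChannels)))
    out[[mid]] <- list(pooled = pooled,
                       row = stats::setNames(seq_along(centers),
                                             as.character(centers)))
  }
  out
}

# pooled rows for a tuple set: anchors, positives, then negatives
.tuple_matrix <- function(pools, pp, nneg) {
  rows <- function(mid, vid) {
    p <- pools[[mid]]
    p$pooled[p$row[as.character(vid)], , drop = FALSE]
  }
  A <- do.call(rbind, lapply(seq_len(nrow(pp)), function(i)
    rows(pp$mesh_id[i], pp$anchor[i])))
  P <- do.call(rbind, lapply(seq_len(nrow(pp)), function(i)
    rows(pp$mesh_id[i], pp$positive[i])))
  N <- NULL
  if (nneg > 0) {
    # column-major by anchor: negative j of all anchors, j = 1..nneg
    N <- do.call(rbind, lapply(seq_len(nneg), function(j)
      do.call(rbind, lapply(seq_len(nrow(pp)), function(i)
        rows(pp$mesh_id[i], pp$negatives[[i]][j])))))
  }
  rbind(A, P, N)
}

#' Train the patch encoder with the contrastive objective
#'
#' Minibatch Adam on the margin contrastive loss over (anchor, positive,
#' negatives) tuples. Structures are split at the structure level; a
#' structure appearing in two splits is a hard error, and pairs from
#' structures outside the training/validation splits are ignored. Pooled
#' soft-grid inputs are precomputed once per referenced patch. The log
#' records epoch training loss and the validation positive/negative mean
#' embedding distances; training stops early when the validation
#' separation stops improving, and a warning is issued if the validation
#' positive mean does not end below the negative mean.
#'
#' @param meshes named list of featurized [SurfaceMesh-class] objects.
#' @param pairs a [PairSet-class] referencing those mesh names.
#' @param split a [DatasetSplit-class] over the mesh names.
#' @param config list from [encoderConfig()].
#' @param verbose print per-epoch progress.
#' @return a trained [SurfaceEncoder-class] (training log in `@log`).
#' @export
trainEncoder <- function(meshes, pairs, split, config = encoderConfig(),
                         verbose = FALSE) {
  validObject(split)
  ids <- names(meshes)
  stopifnot(!is.null(ids))
  pp_all <- pairs@pairs
  train_pp <- pp_all[pp_all$mesh_id %in% split@train, , drop = FALSE]
  val_pp <- pp_all[pp_all$mesh_id %in% split@validation, , drop = FALSE]
  if (!nrow(train_pp)) stop("no training pairs in the training split")
  nneg <- length(train_pp$negatives[[1]])

  enc <- surfaceEncoder(config)
  cfg <- enc@config
  cfg$nChannels <- as.integer(ncol(featureMatrix(meshes[[train_pp$mesh_id[1]]])))
  if (cfg$nChannels != config$nChannels) {
    enc@config <- cfg
    enc@params <- .init_params(cfg)
  }
  perms <- .rotation_perms(cfg)
  pools <- .pool_pairset(meshes, pairs, enc@grid, cfg)

  params <- enc@params
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  tstep <- 0
  log <- NULL
  best_val <- Inf; best_params <- params; stall <- 0L

  val_stats <- function(params) {
    if (!nrow(val_pp)) return(c(NA_real_, NA_real_, NA_real_))
    Xv <- .tuple_matrix(pools, val_pp, nneg)
    dv <- .enc_forward(params, cfg, Xv, perms)$desc
    Bv <- nrow(val_pp)
    A <- dv[seq_len(Bv), , drop = FALSE]
    P <- dv[Bv + seq_len(Bv), , drop = FALSE]
    N <- dv[2 * Bv + seq_len(Bv * nneg), , drop = FALSE]
    pos <- sqrt(rowSums((A - P)^2))
    neg <- sqrt(rowSums((A[rep(seq_len(Bv), nneg), , drop = FALSE] - N)^2))
    c(mean(pos), mean(neg),
      .batch_loss_grad(dv, Bv, nneg, cfg$margin)$loss)
  }

  .with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample.int(nrow(train_pp))
      ep_loss <- 0; nb_count <- 0L
      for (s in seq(1L, length(ord), by = cfg$batchSize)) {
        bi <- ord[s:min(length(ord), s + cfg$batchSize - 1L)]
        pp <- train_pp[bi, , drop = FALSE]
        X <- .tuple_matrix(pools, pp, nneg)
        fw <- .enc_forward(params, cfg, X, perms, want_cache = TRUE)
        lg <- .batch_loss_grad(fw$desc, nrow(pp), nneg, cfg$margin)
        grads <- .enc_backward(params, cfg, fw, lg$grad, perms)
        tstep <- tstep + 1
        up <- .adam_update(params, grads, state, cfg$learningRate, tstep)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + lg$loss; nb_count <- nb_count + 1L
      }
      vs <- val_stats(params)
      vloss <- if (is.na(vs[3])) ep_loss / nb_count else vs[3]
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = ep_loss / nb_count,
                                   val_pos_mean = vs[1], val_neg_mean = vs[2],
                                   val_loss = vs[3]))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val loss %.4f, val pos %.3f, val neg %.3f",
                        epoch, ep_loss / nb_count, vs[3], vs[1], vs[2]))
      if (vloss < best_val - 1e-6) {
        best_val <- vloss; best_params <- params; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })

  enc@params <- best_params
  enc@trained <- TRUE
  enc@log <- log
  last <- log[nrow(log), ]
  if (!is.na(last$val_pos_mean) && last$val_pos_mean >= last$val_neg_mean)
    warning("training failure: validation positive mean distance >= negative mean")
  enc
}

#' Embed one patch into a descriptor
#'
#' Pools the patch into the encoder's soft grid and runs the network. The
#' result is deterministic given the model state, invariant to the order of
#' the patch's vertices (pooling is order-free), and invariant to shifting
#' theta by whole angular bins (rotation max-pooling).
#'
#' @param model a [SurfaceEncoder-class].
#' @param patch a [Patch-class] with `nChannels` feature columns.
#' @param grid optional [SoftGrid-class] override (defaults to the model's).
#' @return numeric descriptor of length `descriptorDim`.
#' @export
embedPatch <- function(model, patch, grid = NULL) {
  cfg <- model@config
  if (ncol(patch@features) != cfg$nChannels)
    stop(sprintf("patch has %d feature channel(s), model expects %d",
                 ncol(patch@features), cfg$nChannels))
  G <- .pool_grid(patch, grid %||% model@grid)
  perms <- .rotation_perms(cfg)
  as.vector(.enc_forward(model@params, cfg, matrix(as.vector(G), 1), perms)$desc)
}

#' Embed patches at many centers of a mesh
#'
#' @param model a [SurfaceEncoder-class].
#' @param mesh a featurized [SurfaceMesh-class].
#' @param centers integer vertex indices (default: all vertices).
#' @param batchSize forward-pass chunk size.
#' @return a length(centers) x descriptorDim matrix, rownames = centers.
#' @export
embedPatches <- function(model, mesh, centers = seq_len(nVertices(mesh)),
                         batchSize = 512L) {
  cfg <- model@config
  if (ncol(featureMatrix(mesh)) != cfg$nChannels)
    stop(sprintf("mesh has %d feature channel(s), model expects %d",
                 ncol(featureMatrix(mesh)), cfg$nChannels))
  patches <- extractPatches(mesh, centers, radius = model@grid@patchRadius)
  pooled <- t(vapply(patches, function(p) as.vector(.pool_grid(p, model@grid)),
                     numeric(cfg$nRadial * cfg$nAngular * cfg$nChannels)))
  perms <- .rotation_perms(cfg)
  out <- matrix(NA_real_, length(centers), cfg$descriptorDim)
  for (s in seq(1L, length(centers), by = batchSize)) {
    e <- min(length(centers), s + batchSize - 1L)
    out[s:e, ] <- .enc_forward(model@params, cfg,
                               pooled[s:e, , drop = FALSE], perms)$desc
  }
  rownames(out) <- as.character(centers)
  out
}

#' Positive/negative embedding-distance report
#'
#' Embeds the pairs of the given (test) meshes, returns the two empirical
#' distance distributions, their overlap coefficient (integral of the
#' pointwise minimum of the two kernel densities), the ROC-AUC of
#' separating positives from negatives by distance, and a suggested
#' classification threshold at the equal-density crossing between the two
#' modes (NA, with a note, when the distributions are degenerate).
#'
#' @param model a trained [SurfaceEncoder-class].
#' @param meshes named list of featurized [SurfaceMesh-class] (test split).
#' @param pairs a [PairSet-class] on those meshes (e.g. from
#'   [sampleTrainingPairs()]).
#' @return list with `positive`, `negative` (distance vectors), `auc`,
#'   `overlap`, `threshold`, and `note`.
#' @export
pairwiseDistanceReport <- function(model, meshes, pairs) {
  cfg <- model@config
  pp <- pairs@pairs[pairs@pairs$mesh_id %in% names(meshes), , drop = FALSE]
  if (!nrow(pp)) stop("no pairs reference the supplied meshes")
  nneg <- length(pp$negatives[[1]])
  pools <- .pool_pairset(meshes, pairs, model@grid, cfg)
  X <- .tuple_matrix(pools, pp, nneg)
  perms <- .rotation_perms(cfg)
  d <- .enc_forward(model@params, cfg, X, perms)$desc
  B <- nrow(pp)
  A <- d[seq_len(B), , drop = FALSE]
  P <- d[B + seq_len(B), , drop = FALSE]
  N <- d[2 * B + seq_len(B * nneg), , drop = FALSE]
  pos <- sqrt(rowSums((A - P)^2))
  neg <- sqrt(rowSums((A[rep(seq_len(B), nneg), , drop = FALSE] - N)^2))

  note <- NULL; threshold <- NA_real_; overlap <- NA_real_
  if (stats::sd(c(pos, neg)) < 1e-12) {
    note <- "degenerate: all distances equal; threshold undefined"
    overlap <- 1
  } else {
    lim <- range(c(pos, neg))
    grid_x <- seq(lim[1], lim[2], length.out = 512)
    dp <- stats::density(pos, from = lim[1], to = lim[2], n = 512)
    dn <- stats::density(neg, from = lim[1], to = lim[2], n = 512)
    overlap <- sum(pmin(dp$y, dn$y)) * diff(grid_x[1:2])
    lo <- min(mean(pos), mean(neg)); hi <- max(mean(pos), mean(neg))
    inb <- which(dp$x >= lo & dp$x <= hi)
    sgn <- sign(dp$y[inb] - dn$y[inb])
    cross <- which(diff(sgn) != 0)
    if (length(cross)) {
      threshold <- mean(dp$x[inb][cross[1] + 0:1])
    } else {
      threshold <- (mean(pos) + mean(neg)) / 2
      note <- "no equal-density crossing between the modes; midpoint reported"
    }
  }
  resp <- c(rep(0, length(pos)), rep(1, length(neg)))
  auc <- as.numeric(pROC::auc(pROC::roc(response = resp,
                                        predictor = c(pos, neg),
                                        quiet = TRUE, direction = "<")))
  list(positive = pos, negative = neg, auc = auc, overlap = overlap,
       threshold = threshold, note = note)
}
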