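# Self-supervised contrastive pair sampling: anchors with positives whose
# patch centers lie within 1.5 A (Euclidean) and negatives beyond 5 A.

#' Sample contrastive training pairs from surface meshes
#'
#' Draws `patchesPerProtein` anchor centers uniformly without replacement on
#' each mesh; for each anchor, one positive center within `positiveCutoff`
#' (Euclidean center-to-center distance, default 1.5 Angstrom) and
#' `nNegatives` negative centers beyond `negativeCutoff` (default 5
#' Angstrom). Negatives are drawn from the anchor set where possible (so
#' their patches are reused during training) and fall back to arbitrary
#' far vertices. Anchors with no vertex within the positive cutoff are
#' resampled (with a message); the run fails if the mesh is globally too
#' coarse.
#'
#' @param meshes a list of [SurfaceMesh-class] (named, or mesh metadata ids
#'   are used).
#' @param patchesPerProtein anchors per mesh (default 200).
#' @param nNegatives negatives per anchor (default 4).
#' @param positiveCutoff,negativeCutoff Euclidean cutoffs, Angstrom.
#' @param seed integer seed; the sample is reproducible under it.
#' @return a [PairSet-class].
#' @export
sampleTrainingPairs <- function(meshes, patchesPerProtein = 200L,
                                nNegatives = 4L, positiveCutoff = 1.5,
                                negativeCutoff = 5, seed = 1) {
  if (is(meshes, "SurfaceMesh")) meshes <- list(meshes)
  ids <- names(meshes) %||% vapply(meshes, function(m)
    as.character(meshMetadata(m)$id %||% "mesh"), character(1))
  if (is.null(names(meshes))) names(meshes) <- ids
  .with_seed(seed, {
    out <- lapply(seq_along(meshes), function(mi) {
      m <- meshes[[mi]]
      v <- vertices(m)
      n <- nrow(v)
      if (n < patchesPerProtein)
        stop(sprintf("mesh '%s' has %d vertices, fewer than patchesPerProtein = %d",
                     ids[mi], n, patchesPerProtein))
      anchors <- sample.int(n, patchesPerProtein)
      pool <- setdiff(seq_len(n), anchors)
      res <- vector("list", length(anchors))
      n_resampled <- 0L
      for (k in seq_along(anchors)) {
        a <- anchors[k]
        tries <- 0L
        repeat {
          d <- sqrt(colSums((t(v) - v[a, ])^2))
          pos_cand <- which(d < positiveCutoff & seq_len(n) != a)
          if (length(pos_cand)) break
          tries <- tries + 1L
          n_resampled <- n_resampled + 1L
          if (!length(pool) || tries > 50L)
            stop(sprintf("mesh '%s': cannot find positive centers within %.2f A; mesh too coarse",
                         ids[mi], positiveCutoff))
          a <- pool[sample.int(length(pool), 1)]
          pool <- setdiff(pool, a)
        }
        anchors[k] <- a
        pos <- pos_cand[sample.int(length(pos_cand), 1)]
        far_anchors <- anchors[sqrt(colSums((t(v[anchors, , drop = FALSE]) -
                                               v[a, ])^2)) > negativeCutoff]
        negs <- if (length(far_anchors) >= nNegatives)
          sample(far_anchors, nNegatives)
        else {
          far_all <- which(d > negativeCutoff)
          if (length(far_all) < nNegatives)
            stop(sprintf("mesh '%s': fewer than %d vertices beyond %.1f A of anchor %d",
                         ids[mi], nNegatives, negativeCutoff, a))
          c(far_anchors, sample(setdiff(far_all, far_anchors),
                                nNegatives - length(far_anchors)))
        }
        res[[k]] <- list(anchor = a, positive = pos, negatives = as.integer(negs))
      }
      if (n_resampled > 0L)
        message(sprintf("mesh '%s': resampled %d anchor(s) with no positive within %.2f A",
                        ids[mi], n_resampled, positiveCutoff))
      data.frame(mesh_id = ids[mi],
                 anchor = vapply(res, `[[`, integer(1), "anchor"),
                 positive = vapply(res, `[[`, integer(1), "positive"),
                 negatives = I(lapply(res, `[[`, "negatives")))
    })
    new("PairSet", pairs = do.call(rbind, out),
        positiveCutoff = positiveCutoff, negativeCutoff = negativeCutoff,
        seed = as.integer(seed))
  })
}
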