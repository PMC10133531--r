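# The local soft pixel grid: polar bins with Gaussian kernels.

#' Construct a soft polar pixel grid
#'
#' `nRadial` x `nAngular` bins spanning a patch of radius `patchRadius`.
#' Radial bin centers sit at ring midpoints (k - 1/2) * R / nRadial; angular
#' centers at (j - 1) * 2 pi / nAngular. Kernel widths default to half a
#' bin in each direction. The default grid is the method's 5 x 16 = 80-bin
#' layout.
#'
#' @param nRadial number of radial rings (default 5).
#' @param nAngular number of angular sectors (default 16).
#' @param patchRadius patch radius the grid spans, Angstrom (default 6).
#' @param sigmaRho radial Gaussian width, Angstrom (default half the ring
#'   spacing).
#' @param sigmaTheta angular Gaussian width, radians (default half the
#'   sector spacing).
#' @return a [SoftGrid-class].
#' @export
softGrid <- function(nRadial = 5L, nAngular = 16L, patchRadius = 6,
                     sigmaRho = NULL, sigmaTheta = NULL) {
  nRadial <- as.integer(nRadial); nAngular <- as.integer(nAngular)
  stopifnot(nRadial >= 1, nAngular >= 1, patchRadius > 0)
  dr <- patchRadius / nRadial
  dth <- 2 * pi / nAngular
  rc <- (seq_len(nRadial) - 0.5) * dr
  tc <- (seq_len(nAngular) - 1) * dth
  # radial-major order: bin (r, a) -> index (r-1)*nAngular + a
  new("SoftGrid",
      nRadial = nRadial, nAngular = nAngular,
      rhoBar = rep(rc, each = nAngular),
      thetaBar = rep(tc, times = nRadial),
      sigmaRho = sigmaRho %||% (dr / 2),
      sigmaTheta = sigmaTheta %||% (dth / 2),
      patchRadius = patchRadius)
}

#' Soft-grid projection weights for a patch
#'
#' Gaussian kernel weights w(v, k) proportional to
#' exp(-(rho_v - rhoBar_k)^2 / (2 sigma_rho^2)) *
#' exp(-dtheta(theta_v, thetaBar_k)^2 / (2 sigma_theta^2)),
#' with the wrap-around angular difference in \[-pi, pi\]. Each vertex row
#' is normalized to sum 1 (a max-shift in log space guards underflow), so
#' rows are probability distributions over the bins.
#'
#' @param patch a [Patch-class] (or any list-like with `rho` and `theta`).
#' @param grid a [SoftGrid-class].
#' @return a |patch| x (nRadial * nAngular) weight matrix.
#' @export
softGridWeights <- function(patch, grid) {
  rho <- if (is(patch, "Patch")) patch@rho else patch$rho
  theta <- if (is(patch, "Patch")) patch@theta else patch$theta
  dr <- outer(rho, grid@rhoBar, "-")
  dth <- outer(theta, grid@thetaBar, "-")
  dth <- (dth + pi) %% (2 * pi) - pi
  logw <- -dr^2 / (2 * grid@sigmaRho^2) - dth^2 / (2 * grid@sigmaTheta^2)
  logw <- logw - apply(logw, 1, max)
  w <- exp(logw)
  w / rowSums(w)
}

# Pooled grid of a patch: (nBins x C) feature matrix, the encoder's input.
.pool_patch <- function(patch, grid) {
  w <- softGridWeights(patch, grid)
  crossprod(w, patch@features)
}
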