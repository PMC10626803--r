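#' Diffusion tensor field
#'
#' Container for a voxelwise symmetric diffusion tensor and its derived
#' maps. Component planes of `D` are ordered
#' `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s; eigenvalues are sorted
#' descending; the principal eigenvector `e1` is unit length on valid
#' voxels with its largest-magnitude component made positive (the sign
#' of an eigenvector is arbitrary); `fa` lies in `[0, 1]`.
#'
#' Raw tensor components are stored exactly as fitted; negative
#' eigenvalues that noise can induce are clamped to zero only when
#' deriving FA and colour maps, so ROI diffusivity means reflect the fit.
#'
#' @name alps_tensor_field
NULL

new_tensor_field <- function(D, evals, e1, fa, mask, voxel_size,
                             clamped = NULL) {
  structure(list(D = D, evals = evals, e1 = e1, fa = fa, mask = mask,
                 voxel_size = voxel_size,
                 clamped = clamped %||% array(FALSE, dim = dim(mask))),
            class = "alps_tensor_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alps_tensor_field <- function(x, ...) {
  cat("<alps_tensor_field> grid ", paste(dim(x$mask), collapse = "x"),
      " @ ", x$voxel_size, " mm; ", sum(x$mask), "/", length(x$mask),
      " valid voxels; FA range ",
      paste(signif(range(x$fa[x$mask]), 3), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Ordinary (unweighted) least squares on the log signal with design row
#' `(gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` scaled by `-b` and an
#' intercept `log S0`, solved once for all voxels. On noise-free data
#' generated from a true tensor the fit is exact. Voxels whose mean
#' b = 0 signal is not positive are masked invalid; individual
#' non-positive samples (possible under heavy Rician noise) are clamped
#' to `s0_floor_frac` times the voxel's estimated S0 before the log and
#' the voxel is flagged in `$clamped`.
#'
#' @param signal 4D numeric array, last dimension indexing volumes.
#' @param scheme the matching [acquisition_scheme()].
#' @param s0_floor_frac clamping floor for non-positive signals, as a
#'   fraction of the voxel's mean b = 0 signal (default 1e-6).
#' @return An [`alps_tensor_field`].
#' @export
fit_tensor <- function(signal, scheme, s0_floor_frac = 1e-6) {
  if (length(dim(signal)) != 4)
    stop("`signal` must be a 4D array", call. = FALSE)
  nv <- dim(signal)[4]
  if (nv != n_volumes(scheme))
    stop("signal has ", nv, " volumes but the scheme describes ",
         n_volumes(scheme), call. = FALSE)
  dims <- dim(signal)[1:3]
  nvox <- prod(dims)
  S <- matrix(signal, nrow = nvox, ncol = nv)  # voxels x volumes

  b0 <- scheme$bvals == 0
  s0_est <- rowMeans(S[, b0, drop = FALSE])
  mask <- is.finite(s0_est) & s0_est > 0

  clamped <- rep(FALSE, nvox)
  floor_v <- pmax(s0_floor_frac * s0_est, .Machine$double.xmin)
  bad <- S <= 0
  if (any(bad)) {
    clamped <- rowSums(bad) > 0
    S[bad] <- floor_v[row(S)[bad]]
  }

  X <- tensor_design(scheme)
  qx <- qr(X)
  coef <- matrix(NA_real_, 7, nvox)
  coef[, mask] <- qr.coef(qx, t(log(S[mask, , drop = FALSE])))

  D <- array(0, dim = c(dims, 6))
  for (k in 1:6) {
    pl <- rep(NA_real_, nvox); pl[mask] <- coef[k, mask]
    D[, , , k] <- pl
  }

  evals <- matrix(NA_real_, nvox, 3)
  e1 <- matrix(NA_real_, nvox, 3)
  for (i in which(mask)) {
    Dv <- coef[1:6, i]
    M <- matrix(c(Dv[1], Dv[4], Dv[5],
                  Dv[4], Dv[2], Dv[6],
                  Dv[5], Dv[6], Dv[3]), 3, 3)
    ev <- eigen(M, symmetric = TRUE)
    evals[i, ] <- ev$values
    v1 <- ev$vectors[, 1]
    if (v1[which.max(abs(v1))] < 0) v1 <- -v1
    e1[i, ] <- v1
  }

  fa <- rep(0, nvox)
  fa[mask] <- compute_fa(evals[mask, , drop = FALSE])

  new_tensor_field(
    D = D,
    evals = array(evals, dim = c(dims, 3)),
    e1 = array(e1, dim = c(dims, 3)),
    fa = array(fa, dim = dims),
    mask = array(mask, dim = dims),
    voxel_size = attr(signal, "voxel_size") %||% NA_real_,
    clamped = array(clamped, dim = dims))
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))`, the
#' normalised dispersion of the three eigenvalues: 0 for isotropic
#' diffusion, 1 in the stick limit. Negative eigenvalues (a noise
#' artefact) are clamped to zero first; an all-zero tensor has FA 0 by
#' definition. FA is invariant to overall eigenvalue scaling.
#'
#' Because FA is scale invariant, a tensor that is zero up to numerical
#' noise (e.g. fitted from a constant signal) would otherwise inherit an
#' arbitrary FA from rounding error; eigenvalue triples whose largest
#' magnitude falls below `zero_tol` (in mm^2/s, far below any tissue
#' diffusivity) are therefore reported as FA 0.
#'
#' @param evals numeric vector of 3 eigenvalues, or an n x 3 matrix.
#' @param zero_tol absolute eigenvalue magnitude below which the tensor
#'   counts as zero (default 1e-12 mm^2/s).
#' @return numeric FA value(s) in `[0, 1]`.
#' @examples
#' compute_fa(c(1, 1, 1))  # 0
#' compute_fa(c(1, 0, 0))  # 1
#' @export
compute_fa <- function(evals, zero_tol = 1e-12) {
  ev <- if (is.matrix(evals)) evals else matrix(evals, nrow = 1)
  if (ncol(ev) != 3) stop("three eigenvalues required", call. = FALSE)
  zero <- apply(abs(ev), 1, max) < zero_tol
  ev <- pmax(ev, 0)
  lbar <- rowMeans(ev)
  num <- sqrt(rowSums((ev - lbar)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- ifelse(den > 0 & !zero, sqrt(1.5) * num / den, 0)
  fa <- pmin(pmax(fa, 0), 1)
  if (is.matrix(evals)) fa else fa[1]
}

#' Directionally encoded colour FA map
#'
#' Standard red-green-blue orientation coding: each channel is the
#' absolute value of the corresponding principal-eigenvector component
#' scaled by FA (red = x, green = y, blue = z), so projection fibres
#' (z-dominant) appear blue and association fibres (y-dominant) green.
#' Invalid voxels are black.
#'
#' @param field an [`alps_tensor_field`].
#' @return 4D array `dim(field) x 3` of RGB values in `[0, 1]`.
#' @export
color_fa <- function(field) {
  dims <- dim(field$mask)
  rgb <- array(0, dim = c(dims, 3))
  for (c in 1:3) {
    ch <- abs(field$e1[, , , c]) * field$fa
    ch[!field$mask | !is.finite(ch)] <- 0
    rgb[, , , c] <- ch
  }
  rgb
}
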