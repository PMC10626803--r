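#' Phantom configuration for DWI simulation
#'
#' Describes a rectangular-region digital phantom on a regular voxel
#' grid. Each region is an axis-aligned box carrying a diagonal
#' diffusion tensor given by its eigenvalues along the scanner x
#' (right-left), y (anterior-posterior) and z (inferior-superior) axes;
#' voxels outside every box take the background tensor. The geometry
#' emulates the lateral-ventricle-body level used for ALPS measurement:
#' projection-fibre blocks (dominant z diffusivity) medial to
#' association-fibre blocks (dominant y diffusivity) in each hemisphere,
#' with a CSF-like ventricle box between the hemispheres.
#'
#' Boxes use 0-based voxel coordinates and half-open extents
#' `[origin, origin + size)`. Volumes are stored RAS (+x right,
#' +y anterior, +z superior).
#'
#' @param dim integer grid shape (3 axes), default `c(64, 64, 40)`.
#' @param voxel_size isotropic voxel edge in mm (default 2).
#' @param s0 non-diffusion-weighted signal level.
#' @param sigma Rician noise standard deviation, in signal units
#'   (same scale as `s0`); 0 disables noise.
#' @param seed integer RNG seed recorded with the phantom; `NULL` uses
#'   the current RNG state.
#' @param background eigenvalues (mm^2/s, scanner x/y/z) outside all
#'   boxes.
#' @param regions named list of regions, each
#'   `list(origin =, size =, evals =)`; later regions override earlier
#'   ones where boxes overlap. Names containing "proj" must have the z
#'   eigenvalue strictly largest, names containing "assoc" the y
#'   eigenvalue.
#' @param alps_slice 0-based slice index of the ventricle-body level on
#'   which ALPS ROIs are placed.
#' @return An object of class `alps_phantom_config`.
#' @seealso [simulate_phantom()], [default_roi_set()]
#' @export
phantom_config <- function(dim = c(64, 64, 40),
                           voxel_size = 2,
                           s0 = 500,
                           sigma = 0,
                           seed = NULL,
                           background = c(0.8e-3, 0.8e-3, 0.8e-3),
                           regions = default_phantom_regions(dim),
                           alps_slice = 20) {
  cfg <- structure(
    list(dim = as.integer(dim), voxel_size = voxel_size, s0 = s0,
         sigma = sigma, seed = seed, background = background,
         regions = regions, alps_slice = as.integer(alps_slice)),
    class = "alps_phantom_config")
  validate_phantom_config(cfg)
  cfg
}

#' @rdname phantom_config
#' @export
default_phantom_regions <- function(dim = c(64, 64, 40)) {
  # blocks scale with the grid; defaults give 8x8x9-voxel fibre blocks
  # mirrored about the midsagittal plane and a central CSF box
  sc <- dim / c(64, 64, 40)
  box <- function(o, s, ev) list(origin = round(o * sc), size = round(s * sc),
                                 evals = ev)
  proj_ev <- c(1.1e-3, 0.6e-3, 1.6e-3)   # z-dominant, x > y (perivascular)
  assoc_ev <- c(1.1e-3, 1.6e-3, 0.6e-3)  # y-dominant, x > z
  list(
    ventricle   = box(c(28, 24, 14), c(8, 16, 12), c(3e-3, 3e-3, 3e-3)),
    right_proj  = box(c(14, 20, 16), c(8, 8, 9), proj_ev),
    right_assoc = box(c(14, 34, 16), c(8, 8, 9), assoc_ev),
    left_proj   = box(c(42, 20, 16), c(8, 8, 9), proj_ev),
    left_assoc  = box(c(42, 34, 16), c(8, 8, 9), assoc_ev))
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$dim) == 3, all(cfg$dim >= 1),
            cfg$voxel_size > 0, cfg$s0 > 0)
  if (cfg$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (any(cfg$background < 0))
    stop("background eigenvalues must be >= 0", call. = FALSE)
  if (cfg$alps_slice < 0 || cfg$alps_slice >= cfg$dim[3])
    stop("alps_slice outside grid", call. = FALSE)
  for (nm in names(cfg$regions)) {
    r <- cfg$regions[[nm]]
    if (any(r$origin < 0) || any(r$origin + r$size > cfg$dim))
      stop("region '", nm, "' extends outside the grid", call. = FALSE)
    if (any(r$evals < 0))
      stop("region '", nm, "' has a negative eigenvalue", call. = FALSE)
    if (grepl("proj", nm) && !(r$evals[3] > max(r$evals[1:2])))
      stop("projection region '", nm,
           "' must have its z eigenvalue strictly largest", call. = FALSE)
    if (grepl("assoc", nm) && !(r$evals[2] > max(r$evals[c(1, 3)])))
      stop("association region '", nm,
           "' must have its y eigenvalue strictly largest", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.alps_phantom_config <- function(x, ...) {
  cat("<alps_phantom_config> grid ", paste(x$dim, collapse = "x"),
      " @ ", x$voxel_size, " mm, S0 = ", x$s0, ", sigma = ", x$sigma,
      ", regions: ", paste(names(x$regions), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Set the ground-truth ALPS index of a phantom
#'
#' Rescales the x (perivascular) eigenvalue of the projection and
#' association fibre blocks of one or both hemispheres so that the
#' phantom's ground-truth ALPS index equals `alps`. The perpendicular
#' eigenvalues (y of the projection block, z of the association block)
#' are left untouched, so `Dxx = alps * mean(Dyy_proj, Dzz_assoc)`.
#'
#' @param config an `alps_phantom_config` with `left_proj`/`left_assoc`
#'   and/or `right_proj`/`right_assoc` regions.
#' @param alps_left,alps_right target indices (> 0); `NULL` leaves the
#'   hemisphere unchanged.
#' @return The modified config.
#' @export
set_phantom_alps <- function(config, alps_left = NULL, alps_right = NULL) {
  for (hemi in c("left", "right")) {
    a <- if (hemi == "left") alps_left else alps_right
    if (is.null(a)) next
    if (a <= 0) stop("ALPS target must be > 0", call. = FALSE)
    pk <- paste0(hemi, "_proj"); ak <- paste0(hemi, "_assoc")
    if (!all(c(pk, ak) %in% names(config$regions)))
      stop("config lacks ", pk, "/", ak, " regions", call. = FALSE)
    d_perp <- mean(c(config$regions[[pk]]$evals[2],
                     config$regions[[ak]]$evals[3]))
    config$regions[[pk]]$evals[1] <- a * d_perp
    config$regions[[ak]]$evals[1] <- a * d_perp
  }
  validate_phantom_config(config)
  config
}

#' Ground-truth ALPS index of a phantom configuration
#'
#' @param config an `alps_phantom_config`.
#' @return named numeric vector `c(left =, right =)`.
#' @export
phantom_true_alps <- function(config) {
  out <- c(left = NA_real_, right = NA_real_)
  for (hemi in c("left", "right")) {
    pk <- paste0(hemi, "_proj"); ak <- paste0(hemi, "_assoc")
    if (!all(c(pk, ak) %in% names(config$regions))) next
    p <- config$regions[[pk]]$evals; a <- config$regions[[ak]]$evals
    out[hemi] <- compute_alps_index(p[1], a[1], p[2], a[3])
  }
  out
}

# per-voxel diagonal diffusivity arrays (list of Dxx, Dyy, Dzz 3D arrays)
phantom_diffusivities <- function(config) {
  d <- lapply(1:3, function(ax) array(config$background[ax], dim = config$dim))
  for (r in config$regions) {
    ix <- (r$origin[1] + 1):(r$origin[1] + r$size[1])
    iy <- (r$origin[2] + 1):(r$origin[2] + r$size[2])
    iz <- (r$origin[3] + 1):(r$origin[3] + r$size[3])
    for (ax in 1:3) d[[ax]][ix, iy, iz] <- r$evals[ax]
  }
  names(d) <- c("Dxx", "Dyy", "Dzz")
  d
}

# evaluate `code` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a DWI phantom
#'
#' Forward-simulates the mono-exponential tensor signal
#' `S = S0 exp(-b g' D g)` for every voxel and volume of the scheme and
#' optionally corrupts it with Rician noise,
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, sigma^2)` drawn from a
#' single seeded generator stream. The ground-truth tensor field is
#' returned alongside the signal.
#'
#' @param config an [phantom_config()] object.
#' @param scheme an [acquisition_scheme()].
#' @return An object of class `alps_dwi`: list with `signal` (4D array,
#'   one 3D frame per scheme volume), `truth` (the ground-truth
#'   `alps_tensor_field`), `config` and `scheme`.
#' @examples
#' cfg <- phantom_config(dim = c(16, 16, 8), alps_slice = 4,
#'                       regions = default_phantom_regions(c(16, 16, 8)))
#' dwi <- simulate_phantom(cfg, default_scheme())
#' dim(dwi$signal)
#' @export
simulate_phantom <- function(config, scheme) {
  validate_phantom_config(config)
  if (!inherits(scheme, "alps_scheme"))
    stop("`scheme` must be an alps_scheme", call. = FALSE)
  d <- phantom_diffusivities(config)
  nv <- n_volumes(scheme)
  sig <- array(0, dim = c(config$dim, nv))
  g <- scheme$bvecs
  for (v in seq_len(nv)) {
    b <- scheme$bvals[v]
    expo <- b * (g[1, v]^2 * d$Dxx + g[2, v]^2 * d$Dyy + g[3, v]^2 * d$Dzz)
    sig[, , , v] <- config$s0 * exp(-expo)
  }
  if (config$sigma > 0) {
    sig <- with_seed(config$seed, {
      e1 <- array(rnorm(length(sig), 0, config$sigma), dim = dim(sig))
      e2 <- array(rnorm(length(sig), 0, config$sigma), dim = dim(sig))
      sqrt((sig + e1)^2 + e2^2)
    })
  }
  structure(list(signal = sig, truth = ground_truth_field(config),
                 config = config, scheme = scheme),
            class = "alps_dwi")
}

# ground-truth tensor field of a phantom (diagonal tensors by construction)
ground_truth_field <- function(config) {
  d <- phantom_diffusivities(config)
  nvox <- prod(config$dim)
  D <- array(0, dim = c(config$dim, 6))
  D[, , , 1] <- d$Dxx; D[, , , 2] <- d$Dyy; D[, , , 3] <- d$Dzz
  # eigenvalues are the sorted diagonal; e1 is the axis of the largest
  flat <- cbind(as.vector(d$Dxx), as.vector(d$Dyy), as.vector(d$Dzz))
  ord <- t(apply(flat, 1, order, decreasing = TRUE))
  evals <- cbind(flat[cbind(1:nvox, ord[, 1])],
                 flat[cbind(1:nvox, ord[, 2])],
                 flat[cbind(1:nvox, ord[, 3])])
  e1 <- matrix(0, nvox, 3)
  e1[cbind(1:nvox, ord[, 1])] <- 1
  new_tensor_field(
    D = D,
    evals = array(evals, dim = c(config$dim, 3)),
    e1 = array(e1, dim = c(config$dim, 3)),
    fa = array(compute_fa(evals), dim = config$dim),
    mask = array(TRUE, dim = config$dim),
    voxel_size = config$voxel_size)
}
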