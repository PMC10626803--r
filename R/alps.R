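#' The four ALPS regions of interest
#'
#' An ALPS measurement uses four rectangular ROIs at the
#' lateral-ventricle-body level: one over the projection fibres
#' (dominant fibre direction z) and one over the association fibres
#' (dominant direction y) in each hemisphere. Each ROI is a 6 x 6 mm^2
#' in-plane rectangle on a single axial slice; its voxel size is derived
#' from the grid spacing (3 x 3 voxels at 2 mm).
#'
#' Coordinates are 0-based and rectangles half-open
#' `[origin, origin + size)`, with `origin = c(i, j)` in-plane and
#' `slice` the 0-based axial index.
#'
#' @param left_proj,left_assoc,right_proj,right_assoc each a
#'   `list(slice =, origin =)` placing one ROI.
#' @param voxel_size in-plane voxel edge in mm.
#' @param dim optional 3-vector grid shape used for bounds checking.
#' @param size_mm in-plane ROI extent in mm (default `c(6, 6)`).
#' @return An object of class `alps_roi_set`: a named list of the four
#'   ROIs, each with `slice`, `origin`, `size` (voxels) and `size_mm`,
#'   with `voxel_size` and `dim` attributes.
#' @export
roi_set <- function(left_proj, left_assoc, right_proj, right_assoc,
                    voxel_size = 2, dim = NULL, size_mm = c(6, 6)) {
  entries <- list(left_proj = left_proj, left_assoc = left_assoc,
                  right_proj = right_proj, right_assoc = right_assoc)
  size_vox <- round(size_mm / voxel_size)
  if (any(size_vox < 1))
    stop("ROI smaller than one voxel at this voxel size", call. = FALSE)
  entries <- lapply(entries, function(e) {
    list(slice = as.integer(e$slice), origin = as.integer(e$origin),
         size = as.integer(size_vox), size_mm = size_mm)
  })
  rs <- structure(entries, class = "alps_roi_set",
                  voxel_size = voxel_size, grid_dim = dim)
  validate_roi_set(rs)
  rs
}

validate_roi_set <- function(rs) {
  if (!setequal(names(rs),
                c("left_proj", "left_assoc", "right_proj", "right_assoc")))
    stop("a ROI set needs exactly the four entries left/right x proj/assoc",
         call. = FALSE)
  dm <- attr(rs, "grid_dim")
  for (nm in names(rs)) {
    e <- rs[[nm]]
    if (any(e$origin < 0) || e$slice < 0)
      stop("ROI '", nm, "' has negative coordinates", call. = FALSE)
    if (!is.null(dm) &&
        (any(e$origin + e$size > dm[1:2]) || e$slice >= dm[3]))
      stop("ROI '", nm, "' extends outside the volume", call. = FALSE)
  }
  for (hemi in c("left", "right")) {
    a <- rs[[paste0(hemi, "_proj")]]; b <- rs[[paste0(hemi, "_assoc")]]
    if (a$slice == b$slice &&
        all(a$origin < b$origin + b$size) &&
        all(b$origin < a$origin + a$size))
      stop("projection and association ROIs overlap in the ", hemi,
           " hemisphere", call. = FALSE)
  }
  invisible(rs)
}

#' @export
print.alps_roi_set <- function(x, ...) {
  cat("<alps_roi_set> 4 ROIs of ", paste(x[[1]]$size_mm, collapse = "x"),
      " mm^2 (", paste(x[[1]]$size, collapse = "x"), " voxels)\n", sep = "")
  for (nm in names(x))
    cat(sprintf("  %-12s slice %d, origin (%s)\n", nm, x[[nm]]$slice,
                paste(x[[nm]]$origin, collapse = ", ")))
  invisible(x)
}

#' @rdname roi_set
#' @param config an [phantom_config()]; ROIs are centred in the
#'   corresponding fibre blocks on the configured ALPS slice.
#' @export
default_roi_set <- function(config) {
  size_vox <- round(c(6, 6) / config$voxel_size)
  centre <- function(key) {
    r <- config$regions[[key]]
    if (is.null(r)) stop("config lacks region '", key, "'", call. = FALSE)
    list(slice = config$alps_slice,
         origin = r$origin[1:2] + floor((r$size[1:2] - size_vox) / 2))
  }
  roi_set(left_proj = centre("left_proj"), left_assoc = centre("left_assoc"),
          right_proj = centre("right_proj"),
          right_assoc = centre("right_assoc"),
          voxel_size = config$voxel_size, dim = config$dim)
}

# 1-based index ranges of a ROI rectangle
roi_indices <- function(roi) {
  list(i = (roi$origin[1] + 1):(roi$origin[1] + roi$size[1]),
       j = (roi$origin[2] + 1):(roi$origin[2] + roi$size[2]),
       k = roi$slice + 1)
}

#' Mean axis-wise diffusivities inside one ROI
#'
#' Arithmetic mean of the diagonal tensor components Dxx, Dyy and Dzz
#' (scanner axes) over the valid voxels of the ROI rectangle.
#'
#' @param field an [`alps_tensor_field`].
#' @param roi one entry of a [roi_set()].
#' @param key label used in error messages.
#' @return named numeric vector `c(Dxx =, Dyy =, Dzz =)` in mm^2/s.
#' @export
extract_roi_diffusivities <- function(field, roi, key = "roi") {
  dims <- dim(field$mask)
  if (any(roi$origin < 0) || any(roi$origin + roi$size > dims[1:2]) ||
      roi$slice < 0 || roi$slice >= dims[3])
    stop("ROI '", key, "' lies outside the tensor field", call. = FALSE)
  ix <- roi_indices(roi)
  m <- field$mask[ix$i, ix$j, ix$k]
  if (!any(m))
    stop("ROI '", key, "' contains no valid voxel", call. = FALSE)
  vapply(1:3, function(c) {
    v <- field$D[ix$i, ix$j, ix$k, c]
    mean(v[m])
  }, numeric(1)) |> stats::setNames(c("Dxx", "Dyy", "Dzz"))
}

#' DTI-ALPS index
#'
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`: the
#' ratio of the diffusivities along the perivascular (x) direction,
#' perpendicular to both fibre populations, over the diffusivities
#' perpendicular to both the fibres and the perivascular space. The
#' index is dimensionless and scale-invariant; values above 1 indicate
#' preferential diffusion along the perivascular axis.
#'
#' @param dxx_proj,dxx_assoc x-axis diffusivities in the projection- and
#'   association-fibre ROIs.
#' @param dyy_proj y-axis diffusivity of the projection ROI.
#' @param dzz_assoc z-axis diffusivity of the association ROI.
#' @return numeric ALPS index (vectorised over inputs).
#' @examples
#' compute_alps_index(1.0e-3, 1.2e-3, 0.6e-3, 0.7e-3)  # 1.6923
#' @export
compute_alps_index <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc) {
  if (any(c(dyy_proj, dzz_assoc) <= 0))
    stop("degenerate fit: non-positive perpendicular diffusivity",
         call. = FALSE)
  if (any(c(dxx_proj, dxx_assoc) <= 0))
    stop("degenerate fit: non-positive Dxx", call. = FALSE)
  ((dxx_proj + dxx_assoc) / 2) / ((dyy_proj + dzz_assoc) / 2)
}

#' Automated ROI placement check
#'
#' Surrogate for the visual inspection that ALPS ROIs sit on their
#' intended fibre populations ("only blue voxels" in the projection
#' ROIs, "only green" in the association ROIs, on the colour FA map).
#' For each ROI it computes the fraction of valid voxels whose principal
#' eigenvector's dominant absolute component is the expected axis
#' (z for projection, y for association) *and* whose FA reaches
#' `fa_min`; the ROI passes when that fraction is at least
#' `frac_threshold` and all of its voxels are valid.
#'
#' @param field an [`alps_tensor_field`].
#' @param rois an [roi_set()].
#' @param fa_min minimum FA for a voxel to count as fibre (default 0.2).
#' @param frac_threshold minimum passing fraction (default 0.9).
#' @return data.frame with one row per ROI: `roi`, `n_voxels`,
#'   `valid_frac`, `dominant_frac`, `pass`.
#' @export
validate_roi_placement <- function(field, rois, fa_min = 0.2,
                                   frac_threshold = 0.9) {
  expected_axis <- c(left_proj = 3, left_assoc = 2,
                     right_proj = 3, right_assoc = 2)
  rows <- lapply(names(rois), function(nm) {
    ix <- roi_indices(rois[[nm]])
    m <- as.vector(field$mask[ix$i, ix$j, ix$k])
    fa <- as.vector(field$fa[ix$i, ix$j, ix$k])
    ex <- sapply(1:3, function(c)
      as.vector(abs(field$e1[ix$i, ix$j, ix$k, c])))
    ex <- matrix(ex, ncol = 3)
    ex[!is.finite(ex)] <- 0
    dom <- max.col(ex, ties.method = "first")
    ok <- m & fa >= fa_min & dom == expected_axis[[nm]]
    frac <- if (any(m)) sum(ok) / sum(m) else 0
    data.frame(roi = nm, n_voxels = length(m),
               valid_frac = mean(m), dominant_frac = frac,
               pass = frac >= frac_threshold && all(m))
  })
  do.call(rbind, rows)
}

#' Measure left and right ALPS indices from a tensor field
#'
#' Extracts the axis-wise ROI diffusivities, runs the placement QC and
#' computes one ALPS index per hemisphere.
#'
#' @inheritParams validate_roi_placement
#' @param strict if `TRUE`, a ROI failing QC raises an error instead of
#'   being reported with `qc_pass = FALSE`.
#' @return data.frame with one row per hemisphere: `hemisphere`,
#'   `Dxxproj`, `Dyyproj`, `Dxxassoc`, `Dzzassoc`, `alps_index`,
#'   `qc_pass`.
#' @export
measure_alps <- function(field, rois, fa_min = 0.2, frac_threshold = 0.9,
                         strict = FALSE) {
  qc <- validate_roi_placement(field, rois, fa_min, frac_threshold)
  if (strict && !all(qc$pass))
    stop("ROI placement QC failed for: ",
         paste(qc$roi[!qc$pass], collapse = ", "), call. = FALSE)
  rows <- lapply(c("left", "right"), function(hemi) {
    dp <- extract_roi_diffusivities(field, rois[[paste0(hemi, "_proj")]],
                                    paste0(hemi, "_proj"))
    da <- extract_roi_diffusivities(field, rois[[paste0(hemi, "_assoc")]],
                                    paste0(hemi, "_assoc"))
    data.frame(hemisphere = hemi,
               Dxxproj = dp[["Dxx"]], Dyyproj = dp[["Dyy"]],
               Dxxassoc = da[["Dxx"]], Dzzassoc = da[["Dzz"]],
               alps_index = compute_alps_index(dp[["Dxx"]], da[["Dxx"]],
                                               dp[["Dyy"]], da[["Dzz"]]),
               qc_pass = all(qc$pass[grepl(hemi, qc$roi)]))
  })
  do.call(rbind, rows)
}

#' Map a ROI set through an affine transform
#'
#' Stand-in for carrying template-space ROIs into a subject's native
#' grid when an affine between the two is known. The four in-plane
#' corner points of each rectangle are mapped through the affine (in
#' voxel coordinates, homogeneous form); the new origin is the
#' elementwise minimum of the mapped corners rounded to the nearest
#' voxel, the slice is the rounded mapped z, and the rectangle size is
#' re-derived from `size_mm` so the ROI area stays 6 x 6 mm^2.
#'
#' @param rois an [roi_set()].
#' @param affine invertible 4 x 4 matrix acting on 0-based voxel
#'   coordinates.
#' @return the transformed `alps_roi_set`.
#' @export
apply_affine_to_rois <- function(rois, affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4 x 4 matrix", call. = FALSE)
  ent <- lapply(rois, function(e) {
    w <- e$size[1]; h <- e$size[2]
    corners <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h))
    pts <- t(apply(corners, 1, function(cc)
      (affine %*% c(e$origin + cc, e$slice, 1))[1:3]))
    lo <- round(apply(pts, 2, min))
    list(slice = lo[3], origin = lo[1:2])
  })
  out <- roi_set(left_proj = ent$left_proj, left_assoc = ent$left_assoc,
                 right_proj = ent$right_proj, right_assoc = ent$right_assoc,
                 voxel_size = attr(rois, "voxel_size"),
                 dim = attr(rois, "grid_dim"),
                 size_mm = rois[[1]]$size_mm)
  out
}
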