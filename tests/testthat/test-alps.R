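# build a minimal constant tensor field by hand
constant_field <- function(dims, diag_vals, mask = NULL) {
  D <- array(0, dim = c(dims, 6))
  for (k in 1:3) D[, , , k] <- diag_vals[k]
  ord <- order(diag_vals, decreasing = TRUE)
  evals <- array(rep(diag_vals[ord], each = prod(dims)), dim = c(dims, 3))
  e1 <- array(0, dim = c(dims, 3)); e1[, , , ord[1]] <- 1
  alpsim:::new_tensor_field(
    D = D, evals = evals, e1 = e1,
    fa = array(compute_fa(diag_vals), dim = dims),
    mask = mask %||% array(TRUE, dim = dims), voxel_size = 2)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ROI means average the diagonal components over valid voxels", {
  dims <- c(8, 8, 4)
  f <- constant_field(dims, c(1.2e-3, 0.7e-3, 1.5e-3))
  roi <- list(slice = 1, origin = c(2, 2), size = c(3, 3))
  d <- extract_roi_diffusivities(f, roi)
  expect_equal(unname(d), c(1.2e-3, 0.7e-3, 1.5e-3), tolerance = 1e-15)

  # hand mean: Dxx values 1..9 x 1e-4 in a 3x3 patch -> 5e-4
  f$D[3:5, 3:5, 2, 1] <- matrix((1:9) * 1e-4, 3, 3)
  d2 <- extract_roi_diffusivities(f, list(slice = 1, origin = c(2, 2),
                                          size = c(3, 3)))
  expect_equal(d2[["Dxx"]], 5e-4, tolerance = 1e-15)

  # out of bounds and fully-invalid ROIs are rejected by name
  expect_error(extract_roi_diffusivities(f, list(slice = 9, origin = c(2, 2),
                                                 size = c(3, 3)), "left_proj"),
               "left_proj")
  mask <- array(TRUE, dims); mask[3:5, 3:5, 2] <- FALSE
  fm <- constant_field(dims, c(1e-3, 1e-3, 1e-3), mask = mask)
  expect_error(extract_roi_diffusivities(fm, list(slice = 1, origin = c(2, 2),
                                                  size = c(3, 3)), "right_assoc"),
               "right_assoc")
})

test_that("the ALPS index is the ratio of the axis-wise diffusivity means", {
  expect_equal(compute_alps_index(1e-3, 1e-3, 1e-3, 1e-3), 1.0)
  expect_equal(compute_alps_index(1.0e-3, 1.2e-3, 0.6e-3, 0.7e-3),
               1.1 / 0.65, tolerance = 1e-12)
  # dimensionless: common scaling cancels
  expect_equal(compute_alps_index(1.0e-2, 1.2e-2, 0.6e-2, 0.7e-2),
               1.1 / 0.65, tolerance = 1e-12)
  expect_error(compute_alps_index(1e-3, 1e-3, 0, 1e-3), "degenerate")
})

test_that("stored measurement fields recompute the index exactly", {
  out <- run_phantom_pipeline(small_config())
  m <- out$measurement
  recomputed <- ((m$Dxxproj + m$Dxxassoc) / 2) / ((m$Dyyproj + m$Dzzassoc) / 2)
  expect_equal(m$alps_index, recomputed, tolerance = 1e-12)
  expect_true(all(m[c("Dxxproj", "Dyyproj", "Dxxassoc", "Dzzassoc")] > 0))
})

test_that("placement QC accepts on-target ROIs and rejects misplaced ones", {
  cfg <- small_config()
  field <- fit_tensor(simulate_phantom(cfg, default_scheme())$signal,
                      default_scheme())
  rois <- default_roi_set(cfg)
  qc <- validate_roi_placement(field, rois)
  expect_true(all(qc$pass))
  expect_equal(qc$dominant_frac, rep(1, 4))

  # projection ROI deliberately dropped onto the association block
  bad <- rois
  bad$right_proj$origin <- rois$right_assoc$origin
  bad$right_proj$slice <- rois$right_assoc$slice
  bad$right_assoc$origin <- c(24, 24)  # isotropic background
  qc_bad <- validate_roi_placement(field, bad)
  expect_equal(qc_bad$dominant_frac[qc_bad$roi == "right_proj"], 0)
  expect_false(qc_bad$pass[qc_bad$roi == "right_proj"])
  # ROI over isotropic background fails through the FA gate
  expect_false(qc_bad$pass[qc_bad$roi == "right_assoc"])
})

test_that("affine ROI mapping matches per-corner mapping", {
  cfg <- small_config()
  rois <- default_roi_set(cfg)

  expect_equal(apply_affine_to_rois(rois, diag(4)), rois)

  shift <- diag(4); shift[1, 4] <- 2
  shifted <- apply_affine_to_rois(rois, shift)
  for (nm in names(rois))
    expect_equal(shifted[[nm]]$origin, rois[[nm]]$origin + c(2L, 0L))

  # 90 degree rotation about z through the grid centre
  th <- pi / 2; c0 <- (small_dim[1:2]) / 2
  A <- diag(4)
  A[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A[1:2, 4] <- c0 - A[1:2, 1:2] %*% c0
  rotated <- apply_affine_to_rois(rois, A)
  for (nm in names(rois)) {
    e <- rois[[nm]]
    corners <- rbind(c(0, 0), c(e$size[1], 0), c(0, e$size[2]), e$size)
    mapped <- t(apply(corners, 1, function(cc)
      (A %*% c(e$origin + cc, e$slice, 1))[1:3]))
    expect_equal(rotated[[nm]]$origin, round(apply(mapped[, 1:2], 2, min)))
    expect_equal(rotated[[nm]]$slice, round(mapped[1, 3]))
  }

  # mapping far outside the grid is refused
  far <- diag(4); far[1, 4] <- 1000
  expect_error(apply_affine_to_rois(rois, far), "outside")
  expect_error(apply_affine_to_rois(rois, matrix(0, 4, 4)), "invertible")
})

test_that("mirroring the phantom across the midsagittal plane swaps the indices", {
  cfg <- set_phantom_alps(small_config(), alps_left = 1.5, alps_right = 1.9)
  dwi <- simulate_phantom(cfg, default_scheme())
  rois <- default_roi_set(cfg)
  meas <- measure_alps(fit_tensor(dwi$signal, dwi$scheme), rois)

  flipped <- dwi$signal[small_dim[1]:1, , , ]
  mirror <- function(e) list(slice = e$slice,
                             origin = c(small_dim[1] - e$origin[1] - e$size[1],
                                        e$origin[2]))
  rois_m <- roi_set(left_proj = mirror(rois$left_proj),
                    left_assoc = mirror(rois$left_assoc),
                    right_proj = mirror(rois$right_proj),
                    right_assoc = mirror(rois$right_assoc),
                    voxel_size = cfg$voxel_size, dim = small_dim)
  meas_m <- measure_alps(fit_tensor(flipped, dwi$scheme), rois_m)
  expect_equal(meas_m$alps_index[meas_m$hemisphere == "left"],
               meas$alps_index[meas$hemisphere == "left"], tolerance = 1e-12)
  expect_equal(meas_m$alps_index[meas_m$hemisphere == "right"],
               meas$alps_index[meas$hemisphere == "right"], tolerance = 1e-12)
})

test_that("noise-free pipeline reproduces any configured ALPS pair", {
  for (targets in list(c(1.4, 1.9), c(1.77, 1.63))) {
    cfg <- set_phantom_alps(small_config(), alps_left = targets[1],
                            alps_right = targets[2])
    out <- run_phantom_pipeline(cfg)
    expect_equal(out$measurement$alps_index,
                 unname(out$truth[c("left", "right")]), tolerance = 1e-6)
    expect_true(all(out$measurement$qc_pass))
  }
})

test_that("mean recovered ALPS under Rician noise stays within 3 SE of truth", {
  sch <- default_scheme()
  truth <- phantom_true_alps(small_config())[["right"]]
  for (sigma_frac in c(0.005, 0.01, 0.02)) {
    vals <- vapply(1:20, function(r) {
      cfg <- small_config(sigma = sigma_frac * 500, seed = 1000 + r)
      out <- run_phantom_pipeline(cfg, scheme = sch)
      out$measurement$alps_index[out$measurement$hemisphere == "right"]
    }, numeric(1))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - truth), 3 * se + 1e-12)
  }
})
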