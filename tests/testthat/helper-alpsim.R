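# Shared fixtures: a 32x32x16 phantom keeps fibre blocks at 4x4x4
# voxels, large enough to hold the 3x3-voxel (6x6 mm^2) ALPS ROIs.
small_dim <- c(32, 32, 16)

small_config <- function(...) {
  phantom_config(dim = small_dim, alps_slice = 8,
                 regions = default_phantom_regions(small_dim), ...)
}

# the published three-group right-ALPS summary structure
paper_alps_summary <- function() {
  group_summary(c("HC", "EM", "CM"), c(41, 32, 24),
                c(1.63, 1.64, 1.77), c(0.18, 0.17, 0.23))
}

# independent forward model: S = S0 exp(-b g' D g) for a full 3x3 tensor
forward_signal <- function(D, scheme, s0 = 500) {
  quad <- colSums(scheme$bvecs * (D %*% scheme$bvecs))
  s0 * exp(-scheme$bvals * quad)
}

# fit a single voxel's signal vector by OLS (wraps the volume fitter)
fit_single_voxel <- function(sig, scheme) {
  vol <- array(sig, dim = c(1, 1, 1, length(sig)))
  fit_tensor(vol, scheme)
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
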