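#' Diffusion acquisition scheme
#'
#' Bundle b-values and unit gradient directions into a validated
#' acquisition scheme. The scheme has one entry per volume of the 4D
#' acquisition; b = 0 volumes may carry a zero direction vector.
#'
#' A scheme is usable for tensor estimation when it contains at least one
#' b = 0 volume and at least six diffusion-weighted directions that span
#' the space of symmetric tensors, i.e. the 6-column design matrix built
#' from them has full rank.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs 3 x n numeric matrix of gradient directions (columns), or
#'   an n x 3 matrix which is transposed. Directions of b > 0 volumes
#'   must be unit vectors to within 1e-6.
#' @return An object of class `alps_scheme`: a list with elements
#'   `bvals` (numeric) and `bvecs` (3 x n matrix).
#' @examples
#' sch <- acquisition_scheme(c(0, rep(1000, 6)),
#'                           cbind(0, diag(3), (diag(3)[, 1:3] + diag(3)[, c(2, 3, 1)]) / sqrt(2)))
#' n_volumes(sch)
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3 && ncol(bvecs) == 3) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3)
    stop("`bvecs` must be a 3 x n matrix of direction columns", call. = FALSE)
  if (length(bvals) != ncol(bvecs))
    stop("length(bvals) must equal the number of bvec columns", call. = FALSE)
  if (any(bvals < 0)) stop("b-values must be non-negative", call. = FALSE)
  if (!any(bvals == 0))
    stop("scheme must contain at least one b = 0 volume", call. = FALSE)

  dw <- bvals > 0
  if (any(dw)) {
    norms <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-6))
      stop("every b > 0 direction must have unit norm (tolerance 1e-6)",
           call. = FALSE)
  }
  sch <- structure(list(bvals = bvals, bvecs = bvecs), class = "alps_scheme")
  rk <- qr(tensor_design(sch)[dw, 1:6, drop = FALSE])$rank
  if (rk < 6)
    stop("degenerate scheme: diffusion directions span only ", rk,
         " of the 6 tensor dimensions; at least 6 independent ",
         "non-collinear directions are required", call. = FALSE)
  sch
}

#' @export
print.alps_scheme <- function(x, ...) {
  cat("<alps_scheme> ", n_volumes(x), " volumes: ",
      sum(x$bvals == 0), " b=0, ",
      sum(x$bvals > 0), " diffusion-weighted (b = ",
      paste(unique(x$bvals[x$bvals > 0]), collapse = ", "), " s/mm^2)\n",
      sep = "")
  invisible(x)
}

#' @rdname acquisition_scheme
#' @param scheme an `alps_scheme`.
#' @export
n_volumes <- function(scheme) length(scheme$bvals)

#' Default acquisition scheme
#'
#' Six b = 0 volumes followed by 32 diffusion-weighted directions at
#' b = 1000 s/mm^2. The direction set was produced once by electrostatic
#' repulsion on the half-sphere and ships with the package; 32 directions
#' keep simulated fits fast while sampling orientation space evenly
#' (minimum inter-axis angle about 25 degrees).
#'
#' @param n_b0 number of leading b = 0 volumes (default 6).
#' @param b b-value of the diffusion-weighted volumes in s/mm^2.
#' @return An `alps_scheme` with `n_b0 + 32` volumes.
#' @export
default_scheme <- function(n_b0 = 6, b = 1000) {
  stopifnot(n_b0 >= 1, b > 0)
  path <- system.file("extdata", "bvecs32.txt", package = "alpsim",
                      mustWork = TRUE)
  dirs <- matrix(scan(path, quiet = TRUE), nrow = 3, byrow = TRUE)
  acquisition_scheme(c(rep(0, n_b0), rep(b, ncol(dirs))),
                     cbind(matrix(0, 3, n_b0), dirs))
}

#' Design matrix of the log-linear tensor model
#'
#' One row per volume: `(-b gx^2, -b gy^2, -b gz^2, -2b gx gy,
#' -2b gx gz, -2b gy gz, 1)`, so that `X %*% c(Dxx, Dyy, Dzz, Dxy, Dxz,
#' Dyz, log S0)` equals the log of the noise-free signal.
#'
#' @param scheme an `alps_scheme`.
#' @return numeric matrix with `n_volumes(scheme)` rows and 7 columns.
#' @keywords internal
#' @export
tensor_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(-b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ], 1)
}

#' Read and write FSL-dialect bval/bvec files
#'
#' The FSL dialect stores b-values as a single whitespace-separated row
#' and directions as three rows (x, y, z components).
#'
#' @param bval_path,bvec_path paths of the two text files.
#' @return `read_bvals_bvecs()` returns an `alps_scheme`;
#'   `write_bvals_bvecs()` returns the paths invisibly.
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3 * length(bvals))
    stop("bvec file does not hold 3 rows of ", length(bvals), " entries",
         call. = FALSE)
  acquisition_scheme(bvals, matrix(bv, nrow = 3, byrow = TRUE))
}

#' @rdname read_bvals_bvecs
#' @param scheme an `alps_scheme` to serialise.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
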