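#' Write and read DWI volumes with their gradient tables
#'
#' Volumes are written as NIfTI-1 (`.nii.gz`) with an RAS diagonal
#' affine at the phantom voxel size; gradient tables use the FSL
#' dialect (`.bval`: one row of b-values; `.bvec`: three rows of x, y, z
#' components).
#'
#' @param dwi an `alps_dwi` from [simulate_phantom()].
#' @param dir output directory (created if missing).
#' @param prefix file name stem.
#' @return `write_dwi()` returns the three paths invisibly;
#'   `read_dwi()` returns a list with `signal` (4D array, with a
#'   `voxel_size` attribute) and `scheme`.
#' @export
write_dwi <- function(dwi, dir, prefix = "dwi") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nii <- file.path(dir, paste0(prefix, ".nii.gz"))
  write_nifti_map(dwi$signal, nii, dwi$config$voxel_size)
  paths <- write_bvals_bvecs(dwi$scheme,
                             file.path(dir, paste0(prefix, ".bval")),
                             file.path(dir, paste0(prefix, ".bvec")))
  invisible(c(nii, paths))
}

#' @rdname write_dwi
#' @param nii_path,bval_path,bvec_path input paths.
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nii_path)
  signal <- as.array(img)
  attr(signal, "voxel_size") <- RNifti::pixdim(img)[1]
  list(signal = signal, scheme = read_bvals_bvecs(bval_path, bvec_path))
}

#' @rdname write_dwi
#' @param map 3D or 4D numeric array (e.g. FA, colour FA, tensor
#'   components).
#' @param path output `.nii.gz` path.
#' @param voxel_size isotropic spacing in mm.
#' @export
write_nifti_map <- function(map, path, voxel_size = 2) {
  nd <- length(dim(map))
  pd <- c(-1, rep(voxel_size, 3), rep(1, 4))
  img <- RNifti::asNifti(map, reference = list(pixdim = pd))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialise a ROI set as JSON
#'
#' Layout: one object per ROI
#' (`{"left_proj": {"slice": 20, "origin": [16, 22], "size_mm": [6, 6]},
#' ...}`) plus `voxel_size` and `dim` entries.
#'
#' @param rois an [roi_set()].
#' @param path JSON file path.
#' @export
write_roi_set <- function(rois, path) {
  obj <- lapply(rois, function(e)
    list(slice = e$slice, origin = e$origin, size_mm = e$size_mm))
  obj$voxel_size <- attr(rois, "voxel_size")
  obj$dim <- attr(rois, "grid_dim")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- c("left_proj", "left_assoc", "right_proj", "right_assoc")
  missing <- setdiff(keys, names(obj))
  if (length(missing))
    stop("ROI JSON lacks entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  args <- lapply(obj[keys], function(e)
    list(slice = e$slice, origin = e$origin))
  do.call(roi_set, c(args, list(
    voxel_size = obj$voxel_size %||% 2,
    dim = obj$dim,
    size_mm = obj[[keys[1]]]$size_mm %||% c(6, 6))))
}

cohort_csv_columns <- c("subject_id", "group", "age", "sex", "vas",
                        "attack_frequency", "midas", "hit6", "phq9",
                        "gad7", "psqi", "alps_left_true",
                        "alps_right_true", "seed")

#' Cohort and ALPS result tables on disk
#'
#' Plain CSV with header, UTF-8, '.' decimal separator. The cohort
#' schema is the column set produced by [simulate_cohort()]; the ALPS
#' schema is the per-hemisphere measurement row of [measure_alps()]
#' prefixed with `subject_id`.
#'
#' @param table data.frame to write.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  stopifnot(all(cohort_csv_columns %in% names(table)))
  write.csv(table[, cohort_csv_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- read.csv(path)
  missing <- setdiff(cohort_csv_columns, names(tab))
  if (length(missing))
    stop("cohort CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!nrow(tab)) stop("cohort CSV is empty", call. = FALSE)
  tab
}

#' @rdname write_cohort_csv
#' @export
write_alps_csv <- function(table, path) {
  cols <- c("subject_id", "hemisphere", "Dxxproj", "Dyyproj", "Dxxassoc",
            "Dzzassoc", "alps_index", "qc_pass")
  stopifnot(all(cols %in% names(table)))
  write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) file with optional blocks `phantom` (fields of
#' [phantom_config()]), `cohort` (`groups` rows plus `seed`) and
#' `stats` (`alpha`). Unknown keys inside a block are reported by name.
#'
#' @param path YAML file path.
#' @return list with `phantom` (`alps_phantom_config`), `cohort`
#'   (`alps_cohort_spec` or `NULL`) and `stats` options.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_phantom <- c("dim", "voxel_size", "s0", "sigma", "seed",
                     "background", "alps_slice")
  ph <- raw$phantom %||% list()
  bad <- setdiff(names(ph), known_phantom)
  if (length(bad))
    stop("unknown phantom config key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ph$dim <- unlist(ph$dim %||% c(64, 64, 40))
  if (is.null(ph$background)) ph$background <- NULL
  ph$regions <- default_phantom_regions(ph$dim)
  phantom <- do.call(phantom_config, ph)

  cohort <- NULL
  if (!is.null(raw$cohort)) {
    co <- raw$cohort
    bad <- setdiff(names(co), c("groups", "seed"))
    if (length(bad))
      stop("unknown cohort config key: ", paste(bad, collapse = ", "),
           call. = FALSE)
    groups <- do.call(rbind, lapply(co$groups, function(gl) {
      # YAML 1.1 reads a bare `n` key as boolean FALSE; restore it
      names(gl)[names(gl) == "FALSE"] <- "n"
      as.data.frame(gl)
    }))
    cohort <- cohort_spec(groups, template = phantom,
                          seed = co$seed %||% 1)
  }
  stats <- raw$stats %||% list()
  stats$alpha <- stats$alpha %||% 0.05
  if (stats$alpha <= 0 || stats$alpha >= 1)
    stop("stats alpha must lie in (0, 1)", call. = FALSE)
  list(phantom = phantom, cohort = cohort, stats = stats)
}
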