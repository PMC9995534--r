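#' Stacked brain-metric maps for a cohort
#'
#' Holds one metric's masked 3D scalar maps for all subjects on a shared
#' grid: a subjects-by-voxels matrix over the in-mask voxels, the binary
#' mask, and the voxel-to-world affine (0-based voxel indices, NIfTI
#' convention).
#'
#' @param data numeric matrix, subjects x in-mask voxels (column order =
#'   `which(mask)` in R's column-major array order); no missing values.
#' @param mask 3D logical array.
#' @param affine 4x4 voxel-to-world matrix (default: identity spacing).
#' @param metric metric name, e.g. `"gm_intensity"`.
#' @param subjects optional subject ids (rownames are used if absent).
#' @return An object of class `cohort_stack`.
#' @export
cohort_stack <- function(data, mask, affine = diag(4), metric = "metric",
                         subjects = NULL) {
  stopifnot(is.matrix(data), is.logical(mask), length(dim(mask)) == 3L)
  if (ncol(data) != sum(mask))
    stop("data must have one column per in-mask voxel", call. = FALSE)
  if (anyNA(data)) stop("missing values inside mask", call. = FALSE)
  if (is.null(subjects)) subjects <- rownames(data)
  if (is.null(subjects)) subjects <- sprintf("S%03d", seq_len(nrow(data)))
  structure(list(data = data, mask = mask, affine = affine,
                 metric = metric, dim = dim(mask), subjects = subjects),
            class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  cat(sprintf("Cohort stack '%s': %d subjects, %d/%d voxels in mask, grid %s\n",
              x$metric, nrow(x$data), sum(x$mask), prod(x$dim),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Put a masked voxel vector back on the 3D grid
#'
#' @param stack a `cohort_stack` (or a 3D logical mask array).
#' @param values vector over in-mask voxels.
#' @param fill value outside the mask.
#' @return 3D array.
#' @export
as_volume <- function(stack, values, fill = 0) {
  mask <- if (inherits(stack, "cohort_stack")) stack$mask else stack
  stopifnot(length(values) == sum(mask))
  vol <- array(fill, dim(mask))
  vol[mask] <- values
  vol
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti keeping the affine with the array.
#'
#' @param vol 3D array.
#' @param path file path (`.nii` / `.nii.gz`).
#' @param affine 4x4 voxel-to-world matrix.
#' @return `write_volume_nifti()` the path; `read_volume_nifti()` a list
#'   with `data` (array) and `affine`.
#' @export
write_volume_nifti <- function(vol, path, affine = diag(4)) {
  img <- RNifti::asNifti(vol)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Build a cohort stack from per-subject NIfTI files
#'
#' @param paths named character vector of NIfTI files (names = subject ids).
#' @param mask_path NIfTI mask file (nonzero = in mask).
#' @param metric metric name.
#' @return A [cohort_stack()].
#' @export
read_cohort_stack <- function(paths, mask_path, metric = "metric") {
  m <- read_volume_nifti(mask_path)
  mask <- m$data != 0
  rows <- lapply(paths, function(p) {
    v <- read_volume_nifti(p)
    if (!identical(dim(v$data), dim(mask)))
      stop(sprintf("grid mismatch between '%s' and the mask", p), call. = FALSE)
    v$data[mask]
  })
  cohort_stack(do.call(rbind, rows), mask, affine = m$affine, metric = metric,
               subjects = names(paths))
}

#' 0-based voxel indices to world coordinates
#'
#' @param affine 4x4 voxel-to-world matrix.
#' @param ijk matrix (n x 3) or vector of 1-based R array indices.
#' @return n x 3 matrix of world coordinates.
#' @export
vox_to_world <- function(affine, ijk) {
  ijk <- rbind(ijk)
  h <- cbind(ijk - 1, 1) %*% t(affine)  # NIfTI voxel indices are 0-based
  h[, 1:3, drop = FALSE]
}
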