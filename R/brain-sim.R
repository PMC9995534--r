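#' Specification of synthetic brain-metric maps
#'
#' Describes the simulated stand-in for preprocessed structural maps
#' (gray-matter intensity, cerebellar volume, FA skeleton): a grid, a
#' binary analysis mask, a planted region whose voxel values depend
#' linearly on the behavioral symmetry score, nuisance effects for group,
#' sex and total intracranial volume, and spatially smoothed Gaussian
#' noise.
#'
#' @param dim grid shape, three positive integers.
#' @param mask 3D logical array (default: all voxels).
#' @param roi integer matrix (n x 3) of 1-based voxel indices, or a 3D
#'   logical array; must lie inside the mask. Default: a central
#'   3x3x3 block.
#' @param slope planted metric change per unit symmetry score (% point).
#' @param noise_sd SD of the voxelwise Gaussian noise before smoothing.
#' @param fwhm smoothing kernel full width at half maximum, in voxels;
#'   sigma = fwhm / (2 sqrt(2 log 2)). 0 disables smoothing.
#' @param baseline mean metric value.
#' @param effect_group,effect_sex additive nuisance shifts for the old
#'   group and female sex.
#' @param effect_tiv nuisance slope per SD of total intracranial volume.
#' @param seed integer seed.
#' @return An object of class `brain_sim_spec`.
#' @export
brain_sim_spec <- function(dim = c(12L, 12L, 12L), mask = NULL, roi = NULL,
                           slope = 1, noise_sd = 1, fwhm = 2, baseline = 100,
                           effect_group = 0, effect_sex = 0, effect_tiv = 0,
                           seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(mask)) mask <- array(TRUE, dim)
  stopifnot(identical(dim(mask), dim))
  if (is.null(roi)) {
    ctr <- pmax(1L, dim %/% 2L)
    roi <- as.matrix(expand.grid(ctr[1] + (-1:1), ctr[2] + (-1:1),
                                 ctr[3] + (-1:1)))
  }
  if (is.array(roi) && is.logical(roi)) roi <- which(roi, arr.ind = TRUE)
  roi <- unname(as.matrix(roi))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  in_mask <- mask[roi]
  if (!all(in_mask)) stop("planted ROI must lie inside the mask", call. = FALSE)
  structure(list(dim = dim, mask = mask, roi = roi, slope = slope,
                 noise_sd = noise_sd, fwhm = fwhm, baseline = baseline,
                 effect_group = effect_group, effect_sex = effect_sex,
                 effect_tiv = effect_tiv, seed = as.integer(seed)),
            class = "brain_sim_spec")
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Kernel convolution along each axis with a normalised discrete Gaussian
#' (truncated at 3 sigma, zero-padded borders);
#' sigma = fwhm / (2 sqrt(2 log 2)).
#'
#' @param vol 3D array.
#' @param fwhm kernel FWHM in voxel units (0 returns the input).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth_3d <- function(vol, fwhm) {
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(vol)
  conv1 <- function(x) {
    # zero-padded 1D convolution, same length
    n <- length(x)
    xp <- c(numeric(r), x, numeric(r))
    out <- numeric(n)
    for (j in seq_along(k)) out <- out + k[j] * xp[j:(j + n - 1L)]
    out
  }
  for (axis in 1:3) {
    vol <- apply(vol, setdiff(1:3, axis), conv1)
    # apply() puts the worked axis first; rotate back
    vol <- aperm(vol, order(c(axis, setdiff(1:3, axis))))
  }
  stopifnot(identical(dim(vol), d))
  vol
}

#' Simulate a cohort's brain-metric maps with planted association
#'
#' Each subject's volume is
#' `baseline + slope * score * 1[voxel in ROI] + nuisance + smoothed noise`,
#' with nuisance effects for group, sex and standardized TIV, masked to
#' the analysis mask (zero outside).
#'
#' @param spec a [brain_sim_spec()].
#' @param scores numeric vector of per-subject symmetry scores.
#' @param covariates data.frame with one row per subject: columns
#'   `subject`, `group` (`young`/`old`), `sex` (`F`/`M`), `tiv`.
#' @param metric metric name for the stack.
#' @return A list: `stack` (a [cohort_stack()]) and `truth` (data.frame of
#'   subject-level ground truth including the planted slope).
#' @export
#' @examples
#' cov <- data.frame(subject = sprintf("S%02d", 1:8),
#'                   group = rep(c("young", "old"), each = 4),
#'                   sex = rep(c("F", "M"), 4), tiv = rnorm(8, 1500, 100))
#' sim <- simulate_brain_maps(brain_sim_spec(dim = c(8, 8, 8), seed = 5),
#'                            scores = rnorm(8, 20, 10), covariates = cov)
#' sim$stack
simulate_brain_maps <- function(spec, scores, covariates,
                                metric = "gm_intensity") {
  stopifnot(inherits(spec, "brain_sim_spec"))
  n <- length(scores)
  if (nrow(covariates) != n)
    stop("mismatched subject counts between scores and covariates",
         call. = FALSE)
  set.seed(spec$seed)
  roi_vol <- array(FALSE, spec$dim)
  roi_vol[spec$roi] <- TRUE
  tiv_z <- as.numeric(scale(covariates$tiv))
  if (all(is.na(tiv_z))) tiv_z <- rep(0, n)  # constant TIV degenerates
  dat <- matrix(NA_real_, n, sum(spec$mask))
  for (i in seq_len(n)) {
    vol <- array(spec$baseline, spec$dim)
    vol[roi_vol] <- vol[roi_vol] + spec$slope * scores[i]
    vol <- vol + spec$effect_group * (covariates$group[i] == "old") +
      spec$effect_sex * (covariates$sex[i] == "F") +
      spec$effect_tiv * tiv_z[i]
    if (spec$noise_sd > 0) {
      noise <- array(rnorm(prod(spec$dim), 0, spec$noise_sd), spec$dim)
      vol <- vol + gaussian_smooth_3d(noise, spec$fwhm)
    }
    dat[i, ] <- vol[spec$mask]
  }
  rownames(dat) <- covariates$subject
  truth <- data.frame(subject = covariates$subject,
                      group = covariates$group, sex = covariates$sex,
                      tiv = covariates$tiv, score = scores,
                      true_slope = spec$slope, stringsAsFactors = FALSE)
  list(stack = cohort_stack(dat, spec$mask, metric = metric,
                            subjects = covariates$subject),
       truth = truth)
}

#' Write a cohort stack as per-subject NIfTI files plus the shared mask
#'
#' @param stack a [cohort_stack()].
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_cohort_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_path <- file.path(dir, sprintf("%s_mask.nii.gz", stack$metric))
  write_volume_nifti(array(as.numeric(stack$mask), stack$dim), mask_path,
                     stack$affine)
  paths <- vapply(seq_len(nrow(stack$data)), function(i) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", stack$metric,
                                stack$subjects[i]))
    write_volume_nifti(as_volume(stack, stack$data[i, ]), p, stack$affine)
    p
  }, character(1))
  invisible(c(paths, mask = mask_path))
}
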