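#' Permutation-based family-wise-error-corrected TFCE inference
#'
#' Freedman–Lane scheme: the response maps are residualized against the
#' nuisance regressors (the design columns with zero contrast weight),
#' the residual rows are permuted, the full model is refitted, and the
#' resulting t-map is TFCE-enhanced. The null distribution of the
#' image-wide maximum enhanced statistic corrects each voxel:
#' \deqn{p_{FWE}(v) = \frac{1 + \#\{ \max_j \ge TFCE_{obs}(v) \}}{n_{perm} + 1},}
#' where the `+1`s are the unpermuted data counted as one ensemble member,
#' so `p >= 1/(n_perm + 1)` always. With `alternative = "two.sided"`
#' (default) both signs are enhanced and the null maximum is taken over
#' both, controlling the FWE of the two-directional family at the nominal
#' level. The integration step `dh` is fixed from the observed map and
#' reused for every permutation. Permutation indices depend only on
#' `(seed, n, n_perm)`.
#'
#' When every distinguishable permutation can be enumerated (small n),
#' enumeration replaces sampling with a warning.
#'
#' @param stack a [cohort_stack()].
#' @param design a [build_design()] result (or plain matrix).
#' @param contrast score name or numeric contrast vector.
#' @param n_perm number of permutations (the study default is 5000).
#' @param seed integer seed for the permutation stream.
#' @param H,E,dh,connectivity TFCE parameters, see [tfce_enhance()].
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return An object of class `perm_fwe`: list with `p` (FWE-corrected
#'   voxelwise p over in-mask voxels), `tfce_obs` (signed observed
#'   enhanced map, masked vector), `t_obs`, `max_null` (null maxima),
#'   `n_perm`, `df`, `alternative`, `dh`.
#' @export
permutation_fwe <- function(stack, design, contrast, n_perm = 5000L,
                            seed = 1L, H = 2, E = 0.5, dh = NULL,
                            connectivity = 26,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.character(contrast)) {
    stopifnot(inherits(design, "design_matrix"))
    contrast <- design$contrasts[[contrast]]
    if (is.null(contrast)) stop("unknown contrast name", call. = FALSE)
  }
  n <- nrow(X)
  mask <- stack$mask

  obs_fit <- fit_glm(stack, X, contrast)
  t_obs <- obs_fit$t
  vmax <- max(abs(t_obs), 0)
  if (is.null(dh)) dh <- if (vmax > 0) vmax / 100 else 1
  enh <- function(tvec) {
    e <- tfce_enhance(as_volume(mask, tvec), mask, H = H, E = E, dh = dh,
                      connectivity = connectivity)
    e[mask]
  }
  tfce_obs <- enh(t_obs)
  obs_stat <- switch(alternative,
                     two.sided = abs(tfce_obs),
                     greater = tfce_obs,
                     less = -tfce_obs)

  # residualize against nuisance (Freedman-Lane)
  Z <- X[, contrast == 0, drop = FALSE]
  Yr <- if (ncol(Z) > 0) {
    qz <- qr(Z)
    stack$data - qr.fitted(qz, stack$data)
  } else stack$data

  n_distinct <- factorial(n)
  exact <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exact) {
    warning(sprintf(
      "n_perm = %d exceeds the %d distinguishable permutations; enumerating exactly",
      n_perm, n_distinct), call. = FALSE)
    perms <- all_permutations(n)
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
  }

  # lean refit per permutation: shared (X'X)^-1 and contrast variance
  XtX_inv <- chol2inv(chol(crossprod(X)))
  cvar <- as.numeric(t(contrast) %*% XtX_inv %*% contrast)
  df <- n - qr(X)$rank
  ct_XtX_inv <- as.numeric(contrast %*% XtX_inv)
  max_null <- vapply(perms, function(p) {
    Yp <- Yr[p, , drop = FALSE]
    XtY <- crossprod(X, Yp)
    beta <- XtX_inv %*% XtY
    rss <- pmax(colSums(Yp^2) - colSums(beta * XtY), 0)
    se <- sqrt(rss / df * cvar)
    eff <- as.numeric(ct_XtX_inv %*% XtY)
    tv <- ifelse(se > 0, eff / ifelse(se > 0, se, 1), 0)
    ev <- enh(tv)
    switch(alternative,
           two.sided = max(abs(ev)),
           greater = max(ev),
           less = max(-ev))
  }, numeric(1))

  if (exact) {
    # identity permutation is part of the enumerated ensemble
    p <- vapply(obs_stat, function(s) mean(max_null >= s), numeric(1))
  } else {
    p <- vapply(obs_stat, function(s) (1 + sum(max_null >= s)) / (n_perm + 1),
                numeric(1))
  }
  structure(list(p = p, tfce_obs = tfce_obs, t_obs = t_obs,
                 max_null = max_null, n_perm = length(perms), df = obs_fit$df,
                 alternative = alternative, dh = dh,
                 connectivity = connectivity, H = H, E = E),
            class = "perm_fwe")
}

#' @export
print.perm_fwe <- function(x, ...) {
  cat(sprintf("Permutation FWE (%s, %d permutations): min corrected p = %.4g\n",
              x$alternative, x$n_perm, min(x$p)))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub)
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  out
}
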