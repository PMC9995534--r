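#' Voxelwise ordinary-least-squares fit with a contrast t-map
#'
#' Fits the same linear model at every in-mask voxel (response = metric,
#' one OLS solve shared across voxels) and returns the contrast
#' t-statistic map,
#' \deqn{t_v = c^\top \hat\beta_v / \sqrt{\hat\sigma_v^2 \, c^\top (X^\top X)^{-1} c},}
#' with `df = n - rank(X)`. Voxels with (numerically) zero residual
#' variance get `t = 0`; their count is reported via a message.
#'
#' @param stack a [cohort_stack()] (rows aligned with the design).
#' @param design a [build_design()] result, or a plain numeric matrix.
#' @param contrast contrast: a score name (when `design` is a
#'   `design_matrix`) or a numeric vector of length `ncol(X)`.
#' @return An object of class `voxel_glm`: list with `t` (vector over
#'   in-mask voxels), `beta` (p x V), `se`, `df`, `contrast`,
#'   `n_zero_variance`.
#' @export
fit_glm <- function(stack, design, contrast) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (is.character(contrast)) {
    stopifnot(inherits(design, "design_matrix"))
    contrast <- design$contrasts[[contrast]]
    if (is.null(contrast)) stop("unknown contrast name", call. = FALSE)
  }
  Y <- stack$data
  n <- nrow(Y)
  stopifnot(nrow(X) == n, length(contrast) == ncol(X))
  rk <- qr(X)$rank
  if (n <= rk)
    stop("more regressors than subjects: model is unidentifiable", call. = FALSE)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  beta <- XtX_inv %*% crossprod(X, Y)             # p x V
  rownames(beta) <- colnames(X)
  rss <- colSums(Y^2) - colSums(beta * crossprod(X, Y))
  df <- n - rk
  sigma2 <- pmax(rss, 0) / df
  cvar <- as.numeric(t(contrast) %*% XtX_inv %*% contrast)
  se <- sqrt(sigma2 * cvar)
  eff <- as.numeric(contrast %*% beta)
  scale_ref <- mean(abs(Y)) + 1
  zero_var <- se <= .Machine$double.eps^0.75 * scale_ref
  tmap <- ifelse(zero_var, 0, eff / ifelse(zero_var, 1, se))
  nz <- sum(zero_var)
  if (nz > 0)
    message(sprintf("fit_glm: %d voxel(s) with zero residual variance set to t = 0", nz))
  structure(list(t = tmap, beta = beta, se = se, df = df,
                 contrast = contrast, n_zero_variance = nz),
            class = "voxel_glm")
}
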