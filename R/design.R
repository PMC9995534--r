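#' Build a design matrix for the brain-behavior models
#'
#' Two model families are supported, mirroring the two study questions:
#'
#' * **q1** (shared association): intercept, one column per behavioral
#'   symmetry score, group, sex (and TIV when requested). The contrast for
#'   each score puts unit weight on that score's column — clusters where
#'   the metric-score association is shared across groups.
#' * **q2** (group interaction): intercept, group, sex (TIV when
#'   requested), and for every score two group-split slope columns
#'   (`<score>.young`, `<score>.old`). The contrast for a score is the
#'   difference of the two group slopes (+1 young, -1 old; sums to zero).
#'
#' All scores enter every model jointly, so multiplicity across gait
#' parameters is absorbed by the joint fit; FWE correction then handles
#' voxelwise multiplicity.
#'
#' @param scores data.frame with `subject` plus one numeric column per
#'   behavioral score (e.g. from [behavioral_scores()] reshaped wide), or
#'   a numeric matrix with subject rownames.
#' @param covariates data.frame: `subject`, `group` (`young`/`old`),
#'   `sex` (`F`/`M`), and `tiv` when `include_tiv = TRUE`.
#' @param question `"q1"` or `"q2"`.
#' @param include_tiv add total intracranial volume as a nuisance column
#'   (used for the volumetric metrics).
#' @return An object of class `design_matrix`: list with `X` (n x p),
#'   `contrasts` (named list of length-p numeric vectors, one per score),
#'   `question`, `score_names`, `subjects`.
#' @export
#' @examples
#' cov <- data.frame(subject = c("a", "b", "c", "d"),
#'                   group = c("young", "young", "old", "old"),
#'                   sex = c("F", "M", "F", "M"), tiv = c(1.4, 1.6, 1.5, 1.55))
#' sc <- data.frame(subject = cov$subject, CoM = rnorm(4), StepCoM = rnorm(4))
#' d <- build_design(sc, cov, question = "q1")
#' colnames(d$X)
build_design <- function(scores, covariates, question = c("q1", "q2"),
                         include_tiv = FALSE) {
  question <- match.arg(question)
  if (is.matrix(scores))
    scores <- data.frame(subject = rownames(scores), scores,
                         stringsAsFactors = FALSE)
  stopifnot("subject" %in% names(scores))
  score_names <- setdiff(names(scores), "subject")
  if (length(score_names) < 1L)
    stop("at least one behavioral score is required", call. = FALSE)
  need <- c("subject", "group", "sex", if (include_tiv) "tiv")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("covariate table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- merge(covariates, scores, by = "subject", sort = TRUE)
  if (nrow(df) != nrow(scores) || anyNA(df[score_names]))
    stop("covariate table incomplete: every scored subject needs covariates",
         call. = FALSE)
  n <- nrow(df)
  g_old <- as.numeric(df$group == "old")
  s_m <- as.numeric(df$sex == "M")
  nuisance <- cbind(group_old = g_old, sex_M = s_m)
  if (include_tiv) nuisance <- cbind(nuisance, tiv = as.numeric(scale(df$tiv)))

  if (question == "q1") {
    X <- cbind(intercept = rep(1, n), as.matrix(df[score_names]), nuisance)
    contrasts <- lapply(score_names, function(s) {
      cv <- stats::setNames(numeric(ncol(X)), colnames(X)); cv[s] <- 1; cv
    })
  } else {
    slopes <- do.call(cbind, lapply(score_names, function(s) {
      m <- cbind(df[[s]] * (1 - g_old), df[[s]] * g_old)
      colnames(m) <- paste(s, c("young", "old"), sep = ".")
      m
    }))
    X <- cbind(intercept = rep(1, n), slopes, nuisance)
    contrasts <- lapply(score_names, function(s) {
      cv <- stats::setNames(numeric(ncol(X)), colnames(X))
      cv[paste(s, "young", sep = ".")] <- 1
      cv[paste(s, "old", sep = ".")] <- -1
      cv
    })
  }
  names(contrasts) <- score_names
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, contrasts = contrasts, question = question,
                 score_names = score_names, subjects = df$subject),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix (%s): %d subjects x %d regressors [%s]\n",
              x$question, nrow(x$X), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}
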