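#' Percent change from the baseline-slow mean
#'
#' Converts a raw per-step series into a delta series,
#' \eqn{\Delta_k = 100 (x_k - \bar b) / \bar b}, where \eqn{\bar b} is the
#' mean of the parameter over the baseline-slow steps of the same foot.
#'
#' @param values raw per-step values (one foot, one parameter).
#' @param baseline_mean mean of the baseline-slow steps (raw units);
#'   must be nonzero.
#' @param parameter,foot optional labels carried along (and used in error
#'   messages).
#' @return An object of class `delta_series`: list with `delta` (%),
#'   `baseline_mean`, `parameter`, `foot`.
#' @export
#' @examples
#' percent_change(c(10, 12, 11), baseline_mean = 10)$delta
percent_change <- function(values, baseline_mean, parameter = NA_character_,
                           foot = NA_character_) {
  if (!is.finite(baseline_mean) || baseline_mean == 0)
    stop(sprintf("zero baseline mean for parameter '%s', foot '%s': percent change undefined",
                 parameter, foot), call. = FALSE)
  structure(list(delta = 100 * (values - baseline_mean) / baseline_mean,
                 baseline_mean = baseline_mean,
                 parameter = parameter, foot = foot),
            class = "delta_series")
}

#' Between-feet symmetry of the delta series
#'
#' Pairs the k-th step of each foot (within-condition step ordinal;
#' unmatched trailing steps are dropped) and returns the raw difference
#' \eqn{s_k = \Delta_{slow,k} - \Delta_{fast,k}}. Positive values mean the
#' slow stance phase changed more from the slow baseline than the fast
#' stance phase; swapping the inputs negates the series.
#'
#' @param delta_slow,delta_fast [percent_change()] results for the
#'   slow-belt (right) and fast-belt (left) foot; parameters must match.
#' @return An object of class `symmetry_series`: list with `symmetry`
#'   (%), `parameter`, `pairing`.
#' @export
symmetry_series <- function(delta_slow, delta_fast) {
  stopifnot(inherits(delta_slow, "delta_series"),
            inherits(delta_fast, "delta_series"))
  if (!identical(delta_slow$parameter, delta_fast$parameter))
    stop(sprintf("parameter mismatch: '%s' vs '%s'",
                 delta_slow$parameter, delta_fast$parameter), call. = FALSE)
  if (!length(delta_slow$delta) || !length(delta_fast$delta))
    stop("both delta series must be nonempty", call. = FALSE)
  n <- min(length(delta_slow$delta), length(delta_fast$delta))
  structure(list(symmetry = delta_slow$delta[seq_len(n)] -
                   delta_fast$delta[seq_len(n)],
                 parameter = delta_slow$parameter,
                 pairing = "step-ordinal"),
            class = "symmetry_series")
}

#' Plateau detection in an adaptation series
#'
#' The plateau is the mean of the final `n_last` values; the series is
#' considered to have reached plateau at the first index `k` such that the
#' `n_consec` consecutive values starting at `k` all lie within
#' `k_sd` standard deviations (SD of the same final `n_last` values) of
#' the plateau. The scan runs forward from the first step and the first
#' qualifying index wins. If the band SD is zero the criterion collapses
#' to exact equality. If no index qualifies, `reached_plateau` is `FALSE`
#' and `steps_to_plateau` equals the series length.
#'
#' @param values numeric series (or a `symmetry_series`).
#' @param n_last number of final steps defining the plateau (default 50).
#' @param n_consec number of consecutive in-band steps required (default 9).
#' @param k_sd half-width of the band in SD units (default 2).
#' @return An object of class `adaptation_result`: list with
#'   `plateau_value`, `band_sd`, `plateau_step`, `steps_to_plateau`,
#'   `reached_plateau`, `n_last`, `n_consec`, `k_sd`.
#' @export
#' @examples
#' detect_plateau(c(seq(10, 0, length.out = 60), rep(0, 60)))
detect_plateau <- function(values, n_last = 50L, n_consec = 9L, k_sd = 2) {
  if (inherits(values, "symmetry_series")) values <- values$symmetry
  n <- length(values)
  if (n < n_last)
    stop(sprintf("series length %d is shorter than n_last = %d", n, n_last),
         call. = FALSE)
  if (n < n_consec)
    stop(sprintf("series length %d is shorter than n_consec = %d", n, n_consec),
         call. = FALSE)
  tail_vals <- values[(n - n_last + 1L):n]
  plateau <- mean(tail_vals)
  band_sd <- if (n_last > 1L) sd(tail_vals) else 0
  within <- abs(values - plateau) <= k_sd * band_sd
  cs <- c(0L, cumsum(within))
  starts <- seq_len(n - n_consec + 1L)
  ok <- (cs[starts + n_consec] - cs[starts]) == n_consec
  if (any(ok)) {
    k <- which(ok)[1L]
    res <- list(plateau_value = plateau, band_sd = band_sd, plateau_step = k,
                steps_to_plateau = k, reached_plateau = TRUE)
  } else {
    res <- list(plateau_value = plateau, band_sd = band_sd,
                plateau_step = NA_integer_, steps_to_plateau = n,
                reached_plateau = FALSE)
  }
  res$n_last <- n_last; res$n_consec <- n_consec; res$k_sd <- k_sd
  class(res) <- "adaptation_result"
  res
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf("Adaptation plateau: value %.3f (band SD %.3f), %s at step %s\n",
              x$plateau_value, x$band_sd,
              if (x$reached_plateau) "reached" else "not reached",
              if (x$reached_plateau) x$plateau_step else sprintf("- (n=%d)", x$steps_to_plateau)))
  invisible(x)
}

#' Magnitude of the symmetry change at plateau
#'
#' The behavioral score passed to the brain-map models: the plateau value
#' (mean of the final `n_last` symmetry values) of the split-condition
#' symmetry series.
#'
#' @param sym a `symmetry_series` (or numeric series).
#' @param plateau optional precomputed [detect_plateau()] result for the
#'   same series.
#' @param ... passed on to [detect_plateau()].
#' @return Scalar symmetry score (% units).
#' @export
magnitude_at_plateau <- function(sym, plateau = NULL, ...) {
  if (is.null(plateau)) plateau <- detect_plateau(sym, ...)
  stopifnot(inherits(plateau, "adaptation_result"))
  plateau$plateau_value
}

#' Per-subject behavioral scores from tidy step data
#'
#' Runs the full behavioral chain for every subject and gait parameter:
#' baseline-slow mean per foot, split-condition percent change per foot,
#' slow-minus-fast symmetry, plateau detection and magnitude-at-plateau.
#' Only the split condition's symmetry score is produced — that is the
#' score carried into the brain-map models.
#'
#' @param steps tidy step data.frame (subject, condition, foot, parameter,
#'   step, value), e.g. `simulate_step_series(spec)$steps` or data read
#'   from CSV.
#' @param subjects optional covariate table (subject, group, sex, tiv)
#'   merged into the output.
#' @param slow_foot,fast_foot which foot walks on which belt.
#' @param n_last,n_consec,k_sd plateau parameters, see [detect_plateau()].
#' @return data.frame: subject, parameter, magnitude_at_plateau,
#'   steps_to_plateau, reached_plateau (+ covariates when supplied).
#' @export
behavioral_scores <- function(steps, subjects = NULL,
                              slow_foot = "right", fast_foot = "left",
                              n_last = 50L, n_consec = 9L, k_sd = 2) {
  need <- c("subject", "condition", "foot", "parameter", "step", "value")
  if (!all(need %in% names(steps)))
    stop("`steps` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  combos <- unique(steps[, c("subject", "parameter")])
  combos <- combos[order(combos$subject, combos$parameter), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sb <- combos$subject[i]; p <- combos$parameter[i]
    d <- steps[steps$subject == sb & steps$parameter == p, , drop = FALSE]
    deltas <- lapply(c(slow = slow_foot, fast = fast_foot), function(f) {
      bl <- d$value[d$condition == "baseline_slow" & d$foot == f]
      sp <- d[d$condition == "split" & d$foot == f, , drop = FALSE]
      percent_change(sp$value[order(sp$step)], mean(bl),
                     parameter = p, foot = f)
    })
    sym <- symmetry_series(deltas$slow, deltas$fast)
    fit <- detect_plateau(sym, n_last = n_last, n_consec = n_consec, k_sd = k_sd)
    data.frame(subject = sb, parameter = p,
               magnitude_at_plateau = magnitude_at_plateau(sym, fit),
               steps_to_plateau = fit$steps_to_plateau,
               reached_plateau = fit$reached_plateau,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(subjects)) out <- merge(subjects, out, by = "subject",
                                       sort = TRUE)
  out[order(out$subject, out$parameter), , drop = FALSE]
}

#' Write the one-row-per-subject-parameter score table as TSV
#'
#' @param scores output of [behavioral_scores()].
#' @param path TSV path.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
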