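#' Simulate per-step gait-parameter series for a synthetic cohort
#'
#' Draws each subject's true plateau symmetry per gait parameter from the
#' group's Normal distribution, then generates split-condition delta series
#' for each foot as a dual-rate exponential approach to the foot's plateau,
#'
#' \deqn{\Delta_k = p_{foot} \pm (A_{fast} e^{-k/\tau_{fast}} +
#'   A_{slow} e^{-k/\tau_{slow}}) + \epsilon_k,}
#'
#' with \eqn{p_{slow} = +s^*/2}, \eqn{p_{fast} = -s^*/2} (so the
#' slow-minus-fast symmetry plateaus at the drawn value \eqn{s^*}), the
#' transient applied with opposite sign on the two feet, and i.i.d.
#' Gaussian step noise. Baseline-slow series fluctuate around the
#' parameter's raw baseline with no systematic asymmetry. Raw step values
#' are `baseline_raw * (1 + delta/100)` so the downstream percent-change
#' stage recovers the planted deltas.
#'
#' The slow belt drives the right foot and the fast belt the left foot,
#' so "slow stance" steps are right-foot steps.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `belt_cohort`:
#' \describe{
#'   \item{steps}{data.frame with columns subject, group, condition
#'     (`baseline_slow`/`split`), foot (`left`/`right`), parameter, step,
#'     value (raw units).}
#'   \item{subjects}{data.frame: subject, group, sex (`F`/`M`), tiv (ml).}
#'   \item{truth}{data.frame: subject, parameter, true_symmetry (%).}
#'   \item{spec}{the input specification.}
#' }
#' Identical spec (including seed) gives bit-identical output.
#' @export
#' @examples
#' cohort <- simulate_step_series(cohort_spec(n_young = 2, n_old = 1,
#'                                            n_steps_split = 80, seed = 7))
#' head(cohort$steps)
simulate_step_series <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_young + spec$n_old
  subjects <- sprintf("S%03d", seq_len(n))
  group <- c(rep("young", spec$n_young), rep("old", spec$n_old))
  sex <- ifelse(rbinom(n, 1L, spec$sex_prob_f[group]) == 1L, "F", "M")
  # total intracranial volume (ml): sex-shifted normal, a nuisance covariate
  tiv <- rnorm(n, mean = ifelse(sex == "F", 1400, 1550), sd = 110)

  params <- spec$gait_params
  truth <- expand.grid(subject = subjects, parameter = params,
                       stringsAsFactors = FALSE)
  truth <- truth[order(truth$subject, truth$parameter), , drop = FALSE]
  rownames(truth) <- NULL
  g_of <- stats::setNames(group, subjects)
  mu <- ifelse(g_of[truth$subject] == "young",
               spec$sym_mean_young[truth$parameter],
               spec$sym_mean_old[truth$parameter])
  sdv <- ifelse(g_of[truth$subject] == "young",
                spec$sym_sd_young[truth$parameter],
                spec$sym_sd_old[truth$parameter])
  truth$true_symmetry <- rnorm(nrow(truth), mu, sdv)

  ks <- seq_len(spec$n_steps_split)
  transient <- spec$A_fast * exp(-ks / spec$tau_fast) +
    spec$A_slow * exp(-ks / spec$tau_slow)
  kb <- seq_len(spec$n_steps_baseline)

  pieces <- vector("list", n * length(params))
  pc <- 0L
  for (si in seq_len(n)) {
    for (p in params) {
      s_star <- truth$true_symmetry[truth$subject == subjects[si] &
                                      truth$parameter == p]
      b <- spec$baseline_raw[[p]]
      d_slow <- s_star / 2 + transient +
        rnorm(length(ks), 0, spec$step_noise_sd)
      d_fast <- -s_star / 2 - transient +
        rnorm(length(ks), 0, spec$step_noise_sd)
      d_bl_l <- rnorm(length(kb), 0, spec$step_noise_sd)
      d_bl_r <- rnorm(length(kb), 0, spec$step_noise_sd)
      pc <- pc + 1L
      pieces[[pc]] <- data.frame(
        subject = subjects[si], group = group[si],
        condition = rep(c("baseline_slow", "baseline_slow", "split", "split"),
                        times = c(length(kb), length(kb),
                                  length(ks), length(ks))),
        foot = rep(c("left", "right", "left", "right"),
                   times = c(length(kb), length(kb),
                             length(ks), length(ks))),
        parameter = p,
        step = c(kb, kb, ks, ks),
        value = b * (1 + c(d_bl_l, d_bl_r, d_fast, d_slow) / 100),
        stringsAsFactors = FALSE)
    }
  }
  steps <- do.call(rbind, pieces)
  rownames(steps) <- NULL
  out <- list(steps = steps,
              subjects = data.frame(subject = subjects, group = group,
                                    sex = sex, tiv = tiv,
                                    stringsAsFactors = FALSE),
              truth = truth,
              spec = spec)
  class(out) <- "belt_cohort"
  out
}

#' @export
print.belt_cohort <- function(x, ...) {
  cat(sprintf("Synthetic split-belt cohort: %d subjects (%d young, %d old), %d step records\n",
              nrow(x$subjects), sum(x$subjects$group == "young"),
              sum(x$subjects$group == "old"), nrow(x$steps)))
  invisible(x)
}

#' Write cohort artifacts as delimited text
#'
#' Step series go to tidy CSV (subject, group, condition, foot, step,
#' parameter, value), covariates and ground truth to TSV/JSON.
#'
#' @param cohort a `belt_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(steps = file.path(dir, "step_series.csv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write.csv(cohort$steps, paths[["steps"]], row.names = FALSE)
  write.table(cohort$subjects, paths[["covariates"]], sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = cohort$spec$seed, truth = cohort$truth),
    paths[["truth"]], dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
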