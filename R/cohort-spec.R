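#' Specification of a synthetic split-belt cohort
#'
#' Bundles every parameter of the synthetic gait cohort: group sizes, the
#' per-group plateau-symmetry distributions of the four gait parameters,
#' the dual-rate adaptation dynamics, step noise, condition lengths and
#' belt speeds. Defaults reproduce the study conditions of a two-group
#' cohort (31 younger, 19 older adults) whose plateau symmetry
#' means and SDs are, per parameter (younger; older, in % units):
#' CoM -4.6±5.2 / -1.7±6.0, intCoPCoM -63.3±68.1 / 11.4±51.9,
#' StepCoM 29.0±16.0 / 3.2±23.4, StepLength 11.7±8.0 / 16.6±15.0.
#'
#' @param n_young,n_old number of younger / older subjects (>= 1).
#' @param gait_params character vector of gait parameter names.
#' @param sym_mean_young,sym_sd_young,sym_mean_old,sym_sd_old named numeric
#'   vectors (one entry per gait parameter): group mean and SD of the true
#'   plateau symmetry, in percent units.
#' @param A_fast,A_slow amplitudes (%) of the fast and slow adaptation
#'   processes applied to each foot's split-condition delta series.
#' @param tau_fast,tau_slow time constants (steps) of the two processes;
#'   `tau_fast < tau_slow` whenever both amplitudes are nonzero.
#' @param step_noise_sd per-step Gaussian noise SD (%).
#' @param n_steps_split,n_steps_baseline steps per foot in the split and
#'   baseline-slow conditions. The split default (600) corresponds to a
#'   10-minute trial at roughly one step per second per foot.
#' @param belt_speed_slow,belt_speed_fast belt speeds in m/s
#'   (fast must exceed slow; defaults 0.7 and 1.4).
#' @param baseline_raw named numeric vector: raw-unit baseline magnitude of
#'   each parameter (mm, or mm*s for the stance integral); the percent-change
#'   reference. Must be nonzero.
#' @param sex_prob_f probability of female sex per group, named
#'   `young`/`old`; defaults 17/31 and 10/19.
#' @param seed integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_young = 4, n_old = 3, n_steps_split = 120, seed = 1)
#' spec$sym_mean_young[["StepCoM"]]
cohort_spec <- function(n_young = 31L, n_old = 19L,
                        gait_params = c("CoM", "intCoPCoM", "StepCoM", "StepLength"),
                        sym_mean_young = c(CoM = -4.6, intCoPCoM = -63.3,
                                           StepCoM = 29.0, StepLength = 11.7),
                        sym_sd_young = c(CoM = 5.2, intCoPCoM = 68.1,
                                         StepCoM = 16.0, StepLength = 8.0),
                        sym_mean_old = c(CoM = -1.7, intCoPCoM = 11.4,
                                         StepCoM = 3.2, StepLength = 16.6),
                        sym_sd_old = c(CoM = 6.0, intCoPCoM = 51.9,
                                       StepCoM = 23.4, StepLength = 15.0),
                        A_fast = 15, A_slow = 5,
                        tau_fast = 15, tau_slow = 100,
                        step_noise_sd = 3,
                        n_steps_split = 600L, n_steps_baseline = 120L,
                        belt_speed_slow = 0.7, belt_speed_fast = 1.4,
                        baseline_raw = c(CoM = 20, intCoPCoM = 30,
                                         StepCoM = 80, StepLength = 700),
                        sex_prob_f = c(young = 17 / 31, old = 10 / 19),
                        seed = 1L) {
  spec <- list(n_young = as.integer(n_young), n_old = as.integer(n_old),
               gait_params = gait_params,
               sym_mean_young = sym_mean_young, sym_sd_young = sym_sd_young,
               sym_mean_old = sym_mean_old, sym_sd_old = sym_sd_old,
               A_fast = A_fast, A_slow = A_slow,
               tau_fast = tau_fast, tau_slow = tau_slow,
               step_noise_sd = step_noise_sd,
               n_steps_split = as.integer(n_steps_split),
               n_steps_baseline = as.integer(n_steps_baseline),
               belt_speed_slow = belt_speed_slow,
               belt_speed_fast = belt_speed_fast,
               baseline_raw = baseline_raw,
               sex_prob_f = sex_prob_f,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_spec field '%s': %s", field, why), call. = FALSE)
  }
  if (is.na(spec$n_young) || spec$n_young < 1L) fail("n_young", "must be >= 1")
  if (is.na(spec$n_old) || spec$n_old < 1L) fail("n_old", "must be >= 1")
  if (length(spec$gait_params) < 1L) fail("gait_params", "must name at least one parameter")
  for (fld in c("sym_mean_young", "sym_sd_young", "sym_mean_old", "sym_sd_old",
                "baseline_raw")) {
    v <- spec[[fld]]
    if (!all(spec$gait_params %in% names(v)))
      fail(fld, "must be named for every gait parameter")
  }
  if (any(spec$sym_sd_young[spec$gait_params] < 0)) fail("sym_sd_young", "SDs must be >= 0")
  if (any(spec$sym_sd_old[spec$gait_params] < 0)) fail("sym_sd_old", "SDs must be >= 0")
  if (spec$step_noise_sd < 0) fail("step_noise_sd", "must be >= 0")
  if (spec$A_fast != 0 && spec$A_slow != 0 && !(spec$tau_fast < spec$tau_slow))
    fail("tau_fast", "must be < tau_slow when both amplitudes are nonzero")
  if (spec$tau_fast <= 0) fail("tau_fast", "must be > 0")
  if (spec$tau_slow <= 0) fail("tau_slow", "must be > 0")
  if (spec$n_steps_split < 1L) fail("n_steps_split", "must be >= 1")
  if (spec$n_steps_baseline < 1L) fail("n_steps_baseline", "must be >= 1")
  if (!(spec$belt_speed_fast > spec$belt_speed_slow))
    fail("belt_speed_fast", "must exceed belt_speed_slow")
  if (any(abs(spec$baseline_raw[spec$gait_params]) < .Machine$double.eps))
    fail("baseline_raw", "baseline magnitudes must be nonzero")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic split-belt cohort specification\n")
  cat(sprintf("  subjects: %d young + %d old\n", x$n_young, x$n_old))
  cat(sprintf("  parameters: %s\n", paste(x$gait_params, collapse = ", ")))
  cat(sprintf("  split steps/foot: %d, baseline steps/foot: %d\n",
              x$n_steps_split, x$n_steps_baseline))
  cat(sprintf("  belts: slow %.2f m/s, fast %.2f m/s (left fast, right slow)\n",
              x$belt_speed_slow, x$belt_speed_fast))
  cat(sprintf("  adaptation: A_fast %.1f%% (tau %.0f), A_slow %.1f%% (tau %.0f), noise SD %.1f%%\n",
              x$A_fast, x$tau_fast, x$A_slow, x$tau_slow, x$step_noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
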