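#' Simulate a continuous marker trial for one subject and condition
#'
#' Builds marker and center-of-pressure trajectories whose extracted
#' per-step gait parameters reproduce the subject's simulated step series
#' exactly (to numerical precision): heel AP positions are sinusoids
#' peaking at the planted heel-strike times plus a slowly varying
#' step-length drift, hip markers straddle a piecewise-linear CoM track
#' through the per-step CoM targets, and the CoP carries one triangular
#' displacement pulse per single-stance interval whose trapezoidal
#' integral equals the target stance integral. Heel-strike times fall
#' exactly on the sampling grid, so event detection and linear
#' interpolation recover the targets without discretisation error.
#'
#' The fast belt drives the left foot; cadence is condition-dependent
#' (stride period 1.4 s baseline-slow, 1.2 s split, 1.0 s baseline-fast).
#'
#' @param cohort a `belt_cohort` from [simulate_step_series()].
#' @param subject subject id present in the cohort.
#' @param condition condition label present in the cohort's step series.
#' @param fs sampling rate (Hz); stride periods must be integer samples.
#' @param duration_s optional cap on trial length (s); steps that do not
#'   fit are dropped, and fewer than two full strides is an error.
#' @return A list of class `marker_sim`: `trial` (a [gait_trial()]),
#'   `events` (data.frame foot, step, time — ground-truth heel strikes),
#'   `targets` (per-step parameter values the trial encodes).
#' @export
#' @examples
#' cohort <- simulate_step_series(cohort_spec(n_young = 1, n_old = 1,
#'                                            n_steps_split = 20,
#'                                            n_steps_baseline = 10, seed = 2))
#' sim <- simulate_marker_trial(cohort, "S001", "split")
#' sim$trial
simulate_marker_trial <- function(cohort, subject, condition, fs = 100,
                                  duration_s = NULL) {
  stopifnot(inherits(cohort, "belt_cohort"))
  st <- cohort$steps
  if (!subject %in% st$subject)
    stop(sprintf("unknown subject '%s'", subject), call. = FALSE)
  st <- st[st$subject == subject, , drop = FALSE]
  if (!condition %in% st$condition)
    stop(sprintf("unknown condition '%s' for subject '%s'", condition, subject),
         call. = FALSE)
  st <- st[st$condition == condition, , drop = FALSE]

  period_s <- switch(condition, baseline_slow = 1.4, baseline_fast = 1.0, 1.2)
  Ts <- as.integer(round(period_s * fs))      # stride period in samples
  if (Ts %% 4L != 0L)
    stop("stride period must be a multiple of four samples", call. = FALSE)
  half <- Ts %/% 2L
  target_of <- function(foot, param) {
    v <- st$value[st$foot == foot & st$parameter == param]
    v[order(st$step[st$foot == foot & st$parameter == param])]
  }
  n_steps <- length(target_of("left", "CoM"))
  margin <- 40L                                # 0.4 s, under half a stride
  if (!is.null(duration_s)) {
    fit <- floor((duration_s * fs - 2 * margin - Ts) / Ts)  # strides that fit
    if (fit < 2) stop("trial duration too short for one full stride", call. = FALSE)
    n_steps <- min(n_steps, fit)
  }
  if (n_steps < 2L) stop("need at least two steps per foot", call. = FALSE)

  tg <- list()
  for (f in c("left", "right"))
    for (p in c("CoM", "intCoPCoM", "StepCoM", "StepLength"))
      tg[[paste(f, p, sep = ".")]] <- target_of(f, p)[seq_len(n_steps)]

  # lead-in/lead-out shorter than half a stride, so no sinusoid peak falls
  # outside the planned strike sequence
  t0 <- margin
  # right (slow-belt) foot strikes first; one terminator right strike at the
  # end so every left step has a complete single-stance interval
  r_idx <- t0 + (seq_len(n_steps + 1L) - 1L) * Ts
  l_idx <- r_idx[seq_len(n_steps)] + half
  dur <- r_idx[n_steps + 1L] + margin
  idx <- 0:dur
  time <- idx / fs

  # per-foot targets; right terminator repeats the final right step
  rep_last <- function(v) c(v, v[length(v)])
  com_r <- rep_last(tg$right.CoM); com_l <- tg$left.CoM
  sl_r <- rep_last(tg$right.StepLength); sl_l <- tg$left.StepLength
  sc_r <- rep_last(tg$right.StepCoM); sc_l <- tg$left.StepCoM
  int_r <- rep_last(tg$right.intCoPCoM); int_l <- tg$left.intCoPCoM

  ev_idx <- c(r_idx, l_idx)
  ev_foot <- c(rep("right", length(r_idx)), rep("left", length(l_idx)))
  ord <- order(ev_idx)
  ev_idx <- ev_idx[ord]; ev_foot <- ev_foot[ord]
  ev_time <- ev_idx / fs
  ev_com <- numeric(length(ev_idx))
  ev_com[ev_foot == "right"] <- com_r
  ev_com[ev_foot == "left"] <- com_l

  pl <- function(xt, yv) approx(xt, yv, xout = time, rule = 2)$y
  com_track <- pl(ev_time, ev_com)
  hip_half_width <- 80
  hip_l_ml <- com_track + hip_half_width
  hip_r_ml <- com_track - hip_half_width

  heel_r_ml <- pl(r_idx / fs, com_r + sc_r)
  heel_l_ml <- pl(l_idx / fs, com_l + sc_l)

  # heel AP: antiphase sinusoids peaking exactly at each foot's strikes,
  # plus a piecewise-linear drift encoding per-step step length
  amp <- 100
  phase <- 2 * pi * (idx - t0) / Ts
  d_r <- numeric(length(ev_idx)); d_l <- numeric(length(ev_idx))
  d_r[ev_foot == "right"] <- sl_r - 2 * amp
  d_l[ev_foot == "left"] <- sl_l - 2 * amp
  heel_r_ap <- amp * cos(phase) + pl(ev_time, d_r)
  heel_l_ap <- -amp * cos(phase) + pl(ev_time, d_l)

  # CoP: CoM track plus one triangular pulse per single-stance interval;
  # pulse peak 4*I/T makes the trapezoidal integral equal the target I
  ev_int <- numeric(length(ev_idx))
  ev_int[ev_foot == "right"] <- int_r
  ev_int[ev_foot == "left"] <- int_l
  n_ev <- length(ev_idx)
  quarter <- Ts %/% 4L
  Tr <- Ts / fs
  knot_t <- c(ev_time, (ev_idx[-n_ev] + quarter) / fs)
  knot_v <- c(rep(0, n_ev), 4 * ev_int[-n_ev] / Tr)
  ko <- order(knot_t)
  cop_ml <- com_track + pl(knot_t[ko], knot_v[ko])

  trial <- gait_trial(time = time,
                      heel_l_ml = heel_l_ml, heel_l_ap = heel_l_ap,
                      heel_r_ml = heel_r_ml, heel_r_ap = heel_r_ap,
                      hip_l_ml = hip_l_ml, hip_l_ap = rep(0, length(time)),
                      hip_r_ml = hip_r_ml, hip_r_ap = rep(0, length(time)),
                      cop_ml = cop_ml, condition = condition,
                      belt_speed_slow = cohort$spec$belt_speed_slow,
                      belt_speed_fast = cohort$spec$belt_speed_fast,
                      fast_foot = "left")
  events <- data.frame(foot = ev_foot,
                       step = stats::ave(seq_along(ev_foot), ev_foot,
                                         FUN = seq_along),
                       time = ev_time, stringsAsFactors = FALSE)
  targets <- do.call(rbind, lapply(c("left", "right"), function(f) {
    data.frame(foot = f, step = seq_len(n_steps),
               CoM = tg[[paste0(f, ".CoM")]],
               intCoPCoM = tg[[paste0(f, ".intCoPCoM")]],
               StepCoM = tg[[paste0(f, ".StepCoM")]],
               StepLength = tg[[paste0(f, ".StepLength")]],
               stringsAsFactors = FALSE)
  }))
  structure(list(trial = trial, events = events, targets = targets),
            class = "marker_sim")
}
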