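make_simple_trial <- function() {
  # two strides per foot at 100 Hz with analytic trajectories
  t <- seq(0, 6, by = 0.01)
  gait_trial(time = t,
             heel_l_ml = rep(120, length(t)),
             heel_l_ap = -100 * cos(2 * pi * (t - 0.4) / 1.2),
             heel_r_ml = rep(-120, length(t)),
             heel_r_ap = 100 * cos(2 * pi * (t - 0.4) / 1.2),
             hip_l_ml = rep(30, length(t)), hip_l_ap = rep(0, length(t)),
             hip_r_ml = rep(-10, length(t)), hip_r_ap = rep(0, length(t)),
             cop_ml = rep(60, length(t)))
}

test_that("heel strikes are found at the AP maxima and alternate feet", {
  trial <- make_simple_trial()
  ev <- detect_heel_strikes(trial)
  expect_true(all(ev$foot[-1] != ev$foot[-nrow(ev)]))
  # right foot peaks at 0.4 + k*1.2, left at 1.0 + k*1.2
  expect_true(all(abs((ev$time[ev$foot == "right"] - 0.4) %% 1.2) < 1e-9 |
                    abs(((ev$time[ev$foot == "right"] - 0.4) %% 1.2) - 1.2) < 1e-9))
})

test_that("motionless and reversed-time inputs are rejected", {
  trial <- make_simple_trial()
  flat <- trial
  for (nm in names(flat$markers)) flat$markers[[nm]] <- rep(1, length(flat$time))
  expect_error(detect_heel_strikes(flat), "no gait events")
  expect_error(gait_trial(time = rev(seq(0, 1, 0.01)),
                          heel_l_ml = 1:101, heel_l_ap = 1:101,
                          heel_r_ml = 1:101, heel_r_ap = 1:101,
                          hip_l_ml = 1:101, hip_l_ap = 1:101,
                          hip_r_ml = 1:101, hip_r_ap = 1:101),
               "strictly increasing")
})

test_that("CoM is the hip-marker ML midpoint, interpolated linearly", {
  trial <- make_simple_trial()
  ev <- detect_heel_strikes(trial)
  # hips at 30 and -10 -> midpoint 10 everywhere
  expect_equal(compute_com_ml(trial, ev), rep(10, nrow(ev)))
  # linear hip track: off-sample event equals the analytic interpolation
  t <- seq(0, 1, by = 0.01)
  lin <- gait_trial(time = t,
                    heel_l_ml = t, heel_l_ap = t, heel_r_ml = t, heel_r_ap = t,
                    hip_l_ml = 100 + 40 * t, hip_l_ap = t,
                    hip_r_ml = 140 - 20 * t, hip_r_ap = t)
  ev_off <- data.frame(foot = "left", time = 0.123456)
  expect_equal(compute_com_ml(lin, ev_off),
               (100 + 40 * 0.123456 + 140 - 20 * 0.123456) / 2,
               tolerance = 1e-12)
  expect_error(compute_com_ml(lin, data.frame(foot = "left", time = 2)),
               "outside trial range")
})

test_that("stance integral matches rectangle, zero and fine-grid ramp cases", {
  t <- seq(0, 2, by = 0.01)
  base <- function(cop) gait_trial(
    time = t,
    heel_l_ml = t, heel_l_ap = t, heel_r_ml = t, heel_r_ap = t,
    hip_l_ml = rep(0, length(t)), hip_l_ap = t,
    hip_r_ml = rep(0, length(t)), hip_r_ap = t, cop_ml = cop)
  ev <- data.frame(foot = c("left", "right"), time = c(0.2, 0.8))
  # constant 50 mm displacement over 0.6 s -> 30 mm*s
  expect_equal(compute_int_cop_com(base(rep(50, length(t))), ev)[1], 30)
  expect_equal(compute_int_cop_com(base(rep(0, length(t))), ev)[1], 0)
  # linear ramp 0 -> 50 mm between the events
  ramp <- approx(c(0, 0.2, 0.8, 2), c(0, 0, 50, 50), xout = t)$y
  got <- compute_int_cop_com(base(ramp), ev)[1]
  fine <- seq(0.2, 0.8, by = 1e-5)
  ref <- pracma::trapz(fine, approx(t, ramp, xout = fine)$y)
  expect_equal(got, 15, tolerance = 1e-6)
  expect_equal(got, ref, tolerance = 1e-9)
  # the trailing event has no closing contralateral strike
  expect_true(is.na(compute_int_cop_com(base(rep(1, length(t))), ev)[2]))
  nocop <- base(NULL)
  expect_error(compute_int_cop_com(nocop, ev), "missing CoP")
})

test_that("step-CoM and step length follow their defining arithmetic", {
  t <- seq(0, 1, by = 0.01)
  trial <- gait_trial(time = t,
                      heel_l_ml = rep(150, length(t)), heel_l_ap = rep(400, length(t)),
                      heel_r_ml = rep(90, length(t)), heel_r_ap = rep(-300, length(t)),
                      hip_l_ml = rep(140, length(t)), hip_l_ap = rep(0, length(t)),
                      hip_r_ml = rep(100, length(t)), hip_r_ap = rep(0, length(t)))
  ev <- data.frame(foot = "left", time = 0.5)
  expect_equal(compute_step_com(trial, ev), 150 - 120)   # heel - CoM
  expect_equal(compute_step_length(trial, ev), 700)      # leading - trailing
  # heel coinciding with the CoM, and the sign flip when medial
  trial$markers$heel_l_ml <- rep(120, length(t))
  expect_equal(compute_step_com(trial, ev), 0)
  trial$markers$heel_l_ml <- rep(90, length(t))
  expect_equal(compute_step_com(trial, ev), -30)
})

test_that("assembled step records conserve events and stay ordered", {
  cohort <- simulate_step_series(cohort_spec(n_young = 1, n_old = 1,
                                             n_steps_split = 25,
                                             n_steps_baseline = 10, seed = 12))
  sim <- simulate_marker_trial(cohort, "S002", "split")
  ev <- detect_heel_strikes(sim$trial)
  rec <- assemble_step_records(sim$trial, ev)
  expect_equal(nrow(rec), nrow(ev))
  lens <- table(rec$foot)
  expect_lte(abs(diff(as.integer(lens))), 1)
  for (f in c("left", "right")) {
    r <- rec[rec$foot == f, ]
    expect_equal(r$step, seq_len(nrow(r)))
    expect_false(is.unsorted(r$time))
  }
  expect_match(attr(rec, "int_cop_com_reading"), "percent change")
})

test_that("extraction reproduces generator truth on zero-noise trials", {
  cohort <- simulate_step_series(cohort_spec(n_young = 1, n_old = 1,
                                             n_steps_split = 60,
                                             n_steps_baseline = 20,
                                             step_noise_sd = 0, seed = 5))
  for (cond in c("split", "baseline_slow")) {
    sim <- simulate_marker_trial(cohort, "S001", cond)
    ev <- detect_heel_strikes(sim$trial)
    # event times agree with the planted ground truth to the sample
    truth <- sim$events
    expect_equal(nrow(ev), nrow(truth))
    expect_lt(max(abs(ev$time - truth$time)), 0.005)
    rec <- assemble_step_records(sim$trial, ev)
    n <- max(sim$targets$step)
    for (f in c("left", "right")) {
      got <- rec[rec$foot == f, ][seq_len(n), ]
      want <- sim$targets[sim$targets$foot == f, ]
      for (p in c("CoM", "intCoPCoM", "StepCoM", "StepLength")) {
        rel <- abs(got[[p]] - want[[p]]) / pmax(abs(want[[p]]), 1)
        expect_lt(max(rel), 1e-6)
      }
    }
  }
})

test_that("gait trials round-trip through wide CSV", {
  cohort <- simulate_step_series(cohort_spec(n_young = 1, n_old = 1,
                                             n_steps_split = 8,
                                             n_steps_baseline = 5, seed = 2))
  sim <- simulate_marker_trial(cohort, "S001", "split")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_gait_trial_csv(sim$trial, path)
  back <- read_gait_trial_csv(path)
  expect_equal(back$condition, "split")
  expect_equal(back$markers$heel_l_ap, sim$trial$markers$heel_l_ap,
               tolerance = 1e-9)
  expect_equal(back$cop_ml, sim$trial$cop_ml, tolerance = 1e-9)
})
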