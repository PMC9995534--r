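test_that("cohort_spec validates its fields and names the offender", {
  expect_s3_class(cohort_spec(n_young = 2, n_old = 2), "cohort_spec")
  expect_error(cohort_spec(n_young = 0), "n_young")
  expect_error(cohort_spec(sym_sd_young = c(CoM = -1, intCoPCoM = 1,
                                            StepCoM = 1, StepLength = 1)),
               "sym_sd_young")
  expect_error(cohort_spec(tau_fast = 200, tau_slow = 100), "tau_fast")
  expect_error(cohort_spec(belt_speed_fast = 0.5), "belt_speed_fast")
})

test_that("degenerate dynamics give exactly constant split series", {
  spec <- cohort_spec(n_young = 2, n_old = 1, A_fast = 0, A_slow = 0,
                      step_noise_sd = 0, n_steps_split = 60,
                      n_steps_baseline = 20, seed = 4)
  cohort <- simulate_step_series(spec)
  sp <- cohort$steps[cohort$steps$condition == "split", ]
  for (sb in unique(sp$subject))
    for (p in unique(sp$parameter))
      for (f in c("left", "right")) {
        v <- sp$value[sp$subject == sb & sp$parameter == p & sp$foot == f]
        expect_equal(diff(range(v)), 0)
        # the constant is the foot's plateau: baseline * (1 +/- s*/2 / 100)
        s_star <- cohort$truth$true_symmetry[cohort$truth$subject == sb &
                                               cohort$truth$parameter == p]
        b <- spec$baseline_raw[[p]]
        expected <- b * (1 + (if (f == "right") s_star else -s_star) / 2 / 100)
        expect_equal(v[1], expected)
      }
})

test_that("same spec and seed reproduce the cohort bit for bit", {
  spec <- cohort_spec(n_young = 3, n_old = 2, n_steps_split = 80,
                      n_steps_baseline = 30, seed = 99)
  a <- simulate_step_series(spec)
  b <- simulate_step_series(spec)
  expect_identical(a$steps, b$steps)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$truth, b$truth)
})

test_that("drawn plateau symmetries recover the configured distribution", {
  # >= 100 subjects: sample mean/SD within Monte-Carlo error of the spec
  spec <- cohort_spec(n_young = 150, n_old = 1, n_steps_split = 50,
                      n_steps_baseline = 10, seed = 21)
  cohort <- simulate_step_series(spec)
  tr <- cohort$truth[cohort$truth$parameter == "StepCoM" &
                       cohort$truth$subject %in%
                       cohort$subjects$subject[cohort$subjects$group == "young"], ]
  mu <- spec$sym_mean_young[["StepCoM"]]
  sg <- spec$sym_sd_young[["StepCoM"]]
  expect_lt(abs(mean(tr$true_symmetry) - mu), 3 * sg / sqrt(nrow(tr)))
  expect_lt(abs(sd(tr$true_symmetry) - sg), 3 * sg / sqrt(2 * (nrow(tr) - 1)))
})

test_that("brain simulator plants a recoverable linear association", {
  set.seed(8)
  n <- 60
  cov <- data.frame(subject = sprintf("S%03d", 1:n),
                    group = rep(c("young", "old"), length.out = n),
                    sex = rep(c("F", "M"), length.out = n),
                    tiv = rnorm(n, 1500, 100))
  scores <- rnorm(n, 20, 10)
  bs <- brain_sim_spec(dim = c(8, 8, 8), slope = 0.8, noise_sd = 0.5,
                       fwhm = 0, seed = 31)
  sim <- simulate_brain_maps(bs, scores, cov)
  vox <- bs$roi[1, , drop = FALSE]
  lin <- (vox[3] - 1) * 64 + (vox[2] - 1) * 8 + vox[1]
  y <- sim$stack$data[, which(which(sim$stack$mask) == lin)]
  fit <- summary(lm(y ~ scores))$coefficients["scores", ]
  expect_lt(abs(fit["Estimate"] - 0.8), 2 * fit["Std. Error"])
})

test_that("brain simulator edge cases: no signal and determinism", {
  cov <- data.frame(subject = c("a", "b", "c"), group = rep("young", 3),
                    sex = rep("F", 3), tiv = rep(1500, 3))
  bs0 <- brain_sim_spec(dim = c(6, 6, 6), slope = 0, noise_sd = 0, seed = 1)
  sim0 <- simulate_brain_maps(bs0, c(1, 2, 3), cov)
  expect_equal(sim0$stack$data[1, ], sim0$stack$data[2, ])
  expect_equal(sim0$stack$data[2, ], sim0$stack$data[3, ])
  bs <- brain_sim_spec(dim = c(6, 6, 6), slope = 1, noise_sd = 1, seed = 5)
  s1 <- simulate_brain_maps(bs, c(1, 2, 3), cov)
  s2 <- simulate_brain_maps(bs, c(1, 2, 3), cov)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_error(simulate_brain_maps(bs, c(1, 2), cov), "mismatch")
  expect_error(brain_sim_spec(dim = c(6, 6, 6),
                              mask = array(c(FALSE, rep(TRUE, 215)), c(6, 6, 6)),
                              roi = matrix(c(1, 1, 1), 1)),
               "inside the mask")
})

test_that("marker trials are deterministic and refuse too-short durations", {
  cohort <- simulate_step_series(cohort_spec(n_young = 1, n_old = 1,
                                             n_steps_split = 30,
                                             n_steps_baseline = 10, seed = 3))
  a <- simulate_marker_trial(cohort, "S001", "split")
  b <- simulate_marker_trial(cohort, "S001", "split")
  expect_identical(a$trial$markers, b$trial$markers)
  expect_error(simulate_marker_trial(cohort, "nope", "split"), "unknown subject")
  expect_error(simulate_marker_trial(cohort, "S001", "after"), "unknown condition")
  expect_error(simulate_marker_trial(cohort, "S001", "split", duration_s = 2),
               "too short")
})
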