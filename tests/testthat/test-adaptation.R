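test_that("percent change is the plain baseline-relative arithmetic", {
  expect_equal(percent_change(10, 10)$delta, 0)
  expect_equal(percent_change(12, 10)$delta, 20)
  expect_equal(percent_change(c(8, 10, 15), 10)$delta, c(-20, 0, 50))
  # delta of the baseline's own mean is zero by construction
  x <- rnorm(40, 50, 3)
  expect_equal(percent_change(mean(x), mean(x))$delta, 0)
  expect_error(percent_change(5, 0, parameter = "CoM", foot = "left"),
               "zero baseline mean.*CoM.*left")
})

test_that("symmetry is the slow-minus-fast delta difference and antisymmetric", {
  ds <- percent_change(c(12.9, 12.9), 10, parameter = "StepCoM", foot = "right")
  df <- percent_change(c(10, 10), 10, parameter = "StepCoM", foot = "left")
  s <- symmetry_series(ds, df)
  expect_equal(s$symmetry, c(29, 29))
  expect_equal(symmetry_series(df, ds)$symmetry, -s$symmetry)
  expect_equal(symmetry_series(ds, ds)$symmetry, c(0, 0))
  other <- percent_change(c(1, 2), 10, parameter = "CoM", foot = "left")
  expect_error(symmetry_series(ds, other), "parameter mismatch")
  # unequal lengths pair by ordinal and drop the unmatched tail
  long <- percent_change(rep(10, 5), 10, parameter = "StepCoM", foot = "left")
  expect_length(symmetry_series(ds, long)$symmetry, 2)
})

test_that("plateau detection handles constant, short and zero-SD series", {
  res <- detect_plateau(rep(7, 100))
  expect_true(res$reached_plateau)
  expect_equal(res$plateau_step, 1L)
  expect_equal(res$plateau_value, 7)
  expect_equal(res$band_sd, 0)
  expect_error(detect_plateau(rnorm(40)), "shorter than n_last")
  # zero band SD demands exact equality: an early off-plateau value defers
  x <- c(rep(3, 20), rep(7, 80))
  res2 <- detect_plateau(x)
  expect_equal(res2$plateau_step, 21L)
})

test_that("plateau scan agrees with the literal brute-force oracle", {
  set.seed(1234)
  for (i in 1:200) {
    n <- sample(100:600, 1)
    kind <- i %% 4
    x <- switch(as.character(kind),
                "0" = rnorm(n),
                "1" = 10 * exp(-(1:n) / sample(5:80, 1)) + rnorm(n, 0, 0.5),
                "2" = c(seq(10, 0, length.out = n %/% 2),
                        rnorm(n - n %/% 2, 0, 0.1)),
                cumsum(rnorm(n, 0, 0.2)))
    got <- detect_plateau(x)
    ref <- oracle_plateau(x)
    expect_equal(got$plateau_value, ref$plateau)
    if (is.na(ref$step)) {
      expect_false(got$reached_plateau)
      expect_equal(got$steps_to_plateau, n)
    } else {
      expect_equal(got$plateau_step, ref$step)
    }
  }
})

test_that("appending in-band copies of the plateau forces plateau attainment", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(60:200, 1)
    x <- rnorm(n, sd = sample(c(0.5, 1, 5), 1)) +
      sample(c(0, 10), 1) * exp(-(1:n) / 20)
    v <- detect_plateau(x)$plateau_value
    y <- c(x, rep(v, 9))
    expect_true(detect_plateau(y)$reached_plateau)
  }
})

test_that("magnitude at plateau is the plateau of the symmetry series", {
  expect_equal(magnitude_at_plateau(rep(29, 120)), 29)
  expect_equal(magnitude_at_plateau(rep(0, 120)), 0)
  # noisy series around a known truth: last-50 mean within sampling error
  set.seed(9)
  ok <- 0L
  for (i in 1:50) {
    s_star <- runif(1, -40, 40)
    noise_sd <- 2
    sym <- s_star + 15 * exp(-(1:300) / 12) + rnorm(300, 0, noise_sd)
    est <- magnitude_at_plateau(sym)
    if (abs(est - s_star) < 3 * noise_sd / sqrt(50)) ok <- ok + 1L
  }
  expect_gte(ok, 48L)  # 3-sigma bound holds essentially always
})

test_that("behavioral_scores runs the full chain per subject and parameter", {
  spec <- cohort_spec(n_young = 3, n_old = 2, n_steps_split = 600,
                      n_steps_baseline = 40, step_noise_sd = 1, seed = 6)
  cohort <- simulate_step_series(spec)
  sc <- behavioral_scores(cohort$steps, cohort$subjects)
  expect_equal(nrow(sc), 5 * 4)
  expect_setequal(unique(sc$parameter), spec$gait_params)
  m <- merge(sc, cohort$truth, by = c("subject", "parameter"))
  # estimate = last-50 mean of a series whose noise SD is sqrt(2) * step noise
  expect_lt(max(abs(m$magnitude_at_plateau - m$true_symmetry)),
            4 * sqrt(2) * spec$step_noise_sd / sqrt(50))
})
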