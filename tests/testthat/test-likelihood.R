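# Lognormal-error likelihood, anchor-time profiling, variance profiling,
# and maximum-likelihood fitting.

test_that("log_likelihood matches hand-computed normal log-densities", {
  th <- c(r = 0.016, K = 364)
  # one measurement exactly on the curve, unit variance (first observation is
  # day 0 by convention, anchored 150 days after onset)
  v <- growth_solution("logistic", th, t = 0, t0 = -150)
  one <- tibble::tibble(tumour_id = "a", t = 0, volume_cm3 = v)
  expect_equal(
    log_likelihood(one, "logistic", th, t0 = c(a = -150), epsilon = 1),
    -0.5 * log(2 * pi))
  # two points with log residuals +/- 0.1 at epsilon = 0.01
  v2 <- growth_solution("logistic", th, t = c(0, 90), t0 = -50)
  two <- tibble::tibble(tumour_id = "a", t = c(0, 90),
                        volume_cm3 = v2 * exp(c(0.1, -0.1)))
  expect_equal(
    log_likelihood(two, "logistic", th, t0 = c(a = -50), epsilon = 0.01),
    2 * (-0.5 * log(2 * pi * 0.01)) - 1.0)
})

test_that("log_likelihood agrees with a brute-force reimplementation", {
  withr::with_seed(21, {
    for (m in c("exponential", "logistic", "gompertz")) {
      th <- oracle_draw_theta(m)
      cohort <- make_plain_cohort(8, m, th, seed = sample.int(1e6, 1))
      ids <- sort(unique(cohort$tumour_id))
      t0 <- setNames(runif(length(ids), -200, 0), ids)
      eps <- runif(1, 0.01, 0.1)
      expect_equal(
        log_likelihood(cohort, m, th, t0, eps),
        oracle_loglik(cohort, m, th, t0, eps),
        tolerance = 1e-10, label = m)
    }
  })
})

test_that("log_likelihood returns -Inf on out-of-domain curves, not an error", {
  th <- c(r = 0.02, b = 1.5)  # blows up ~283 days after the anchor
  dat <- tibble::tibble(tumour_id = "a", t = c(0, 400),
                        volume_cm3 = c(1, 5))
  expect_identical(
    log_likelihood(dat, "mendelsohn", th, t0 = c(a = 0), epsilon = 0.04),
    -Inf)
})

test_that("profile_t0 recovers the closed-form exponential anchor", {
  r <- 0.02
  withr::with_seed(31, {
    t <- c(0, 85, 190)
    t0_true <- -120
    v <- oracle_solution("exponential", c(r = r), t - t0_true) *
      exp(rnorm(3, 0, 0.2))
    dat <- tibble::tibble(tumour_id = "a", t = t, volume_cm3 = v)
    prof <- profile_t0(dat, "exponential", c(r = r))
    # linear least squares in t0: t0 = mean(t - (log V - log V0)/r)
    closed <- mean(t - (log(v) - log(0.125)) / r)
    expect_equal(prof$t0, closed, tolerance = 1e-3)
  })
  # noise-free series recovers the generating anchor exactly
  t <- c(0, 90, 180)
  v <- oracle_solution("exponential", c(r = r), t + 75)
  dat <- tibble::tibble(tumour_id = "a", t = t, volume_cm3 = v)
  prof <- profile_t0(dat, "exponential", c(r = r))
  expect_equal(prof$t0, -75, tolerance = 1e-3)
  expect_lt(prof$ssq, 1e-12)
})

test_that("profile_t0 on a singleton inverts through the point", {
  th <- c(r = 0.016, K = 364)
  dat <- tibble::tibble(tumour_id = "a", t = 0, volume_cm3 = 42)
  prof <- profile_t0(dat, "logistic", th)
  expect_equal(prof$t0, -time_to_volume("logistic", th, 42),
               tolerance = 1e-3)
  expect_lt(prof$ssq, 1e-10)
  expect_equal(prof$n_obs, 1L, ignore_attr = TRUE)
})

test_that("profile_t0 matches a dense grid search on noisy logistic data", {
  th <- c(r = 0.016, K = 364)
  withr::with_seed(41, {
    for (rep in 1:3) {
      t <- c(0, 95, 185)
      t0_true <- runif(1, -400, 0)
      v <- oracle_solution("logistic", th, t - t0_true) *
        exp(rnorm(3, 0, 0.2))
      dat <- tibble::tibble(tumour_id = "a", t = t, volume_cm3 = v)
      prof <- profile_t0(dat, "logistic", th)
      grid <- oracle_grid_t0(t, v, "logistic", th)
      expect_equal(prof$t0, grid, tolerance = 0.1, ignore_attr = TRUE)
    }
  })
})

test_that("profile_epsilon is the mean squared residual with a floor", {
  expect_equal(profile_epsilon(c(0.1, -0.1)), 0.01)
  expect_equal(profile_epsilon(rep(0, 10)), 1e-8)
  expect_error(profile_epsilon(numeric(0)), "at least one")
  withr::with_seed(51, {
    res <- rnorm(1000, 0, 0.2)
    expect_equal(profile_epsilon(res), 0.04, tolerance = 0.15)
  })
})

test_that("fit_growth recovers exact parameters from noise-free data", {
  cohort <- make_plain_cohort(5, "exponential", c(r = 0.02), seed = 61,
                              epsilon = 0, points = 3)
  fit <- fit_growth(cohort, "exponential",
                    control = fit_control(multistart = 5))
  expect_equal(fit$theta[["r"]], 0.02, tolerance = 1e-6)
  expect_equal(fit$epsilon, 1e-8)  # floored: perfect fit
})

test_that("exponential MLE equals pooled per-tumour log-linear least squares", {
  cohort <- make_plain_cohort(20, "exponential", c(r = 0.018), seed = 71,
                              epsilon = 0.05)
  fit <- fit_growth(cohort, "exponential",
                    control = fit_control(multistart = 5))
  d <- dplyr::mutate(
    dplyr::group_by(cohort, tumour_id), t = t - min(t), y = log(volume_cm3))
  ls <- coef(lm(y ~ 0 + factor(tumour_id) + t, data = d))[["t"]]
  expect_equal(fit$theta[["r"]], ls, tolerance = 1e-6)
})

test_that("likelihood at the optimum dominates the generating parameters", {
  th <- c(r = 0.016, K = 364)
  cohort <- simulate_cohort(
    cohort_config(n_tumours = 25,
                  groups = list(g = cohort_group("logistic", th))),
    seed = 81)
  fit <- fit_growth(cohort, "logistic", control = fit_control(multistart = 5))
  truth_parts <- devilgrowth:::profile_loglik_parts(
    devilgrowth:::prepare_series(cohort), growth_model("logistic"),
    th, 0.125, fit$control)
  expect_gte(fit$loglik, truth_parts$loglik - 1e-8)
})

test_that("changing the anchor volume V0 shifts anchors but not the likelihood", {
  cohort <- simulate_cohort(
    cohort_config(n_tumours = 20,
                  groups = list(g = cohort_group("logistic",
                                                 c(r = 0.016, K = 364)))),
    seed = 91)
  ctl <- fit_control(multistart = 4)
  f1 <- fit_growth(cohort, "logistic", v0 = 0.125, control = ctl)
  # profile likelihood at the same theta is invariant to V0 up to the
  # anchor-time reparameterisation
  ser <- devilgrowth:::prepare_series(cohort)
  p1 <- devilgrowth:::profile_loglik_parts(ser, f1$model, f1$theta, 0.125, ctl)
  p2 <- devilgrowth:::profile_loglik_parts(ser, f1$model, f1$theta, 100, ctl)
  expect_equal(p1$loglik, p2$loglik, tolerance = 1e-6)
  # the V0 = 100 anchor sits later on every curve by the 0.125 -> 100 travel
  # time, so each t0 moves forward by that same constant
  shift <- as.numeric(p2$prof$t0) - as.numeric(p1$prof$t0)
  expected <- time_to_volume("logistic", f1$theta, 100, v0 = 0.125)
  expect_lt(max(abs(shift - expected)), 0.01)
})

test_that("shifting one tumour's clock shifts its anchor and nothing else", {
  cohort <- make_plain_cohort(6, "logistic", c(r = 0.016, K = 364),
                              seed = 101, points = 3)
  ctl <- fit_control(multistart = 3)
  f1 <- fit_growth(cohort, "logistic", control = ctl)
  shifted <- dplyr::mutate(
    cohort, t = ifelse(tumour_id == "P01", t + 137, t),
    day = t)
  # prepare_series re-expresses each tumour relative to its first
  # observation, so a within-tumour translation leaves the fit unchanged
  f2 <- fit_growth(shifted, "logistic", control = ctl)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-6)
})

test_that("noise-free fits leave no systematic residual sign trend", {
  cohort <- make_plain_cohort(8, "logistic", c(r = 0.016, K = 364),
                              seed = 111, epsilon = 0, points = 3)
  fit <- fit_growth(cohort, "logistic", control = fit_control(multistart = 4))
  expect_lt(max(abs(residuals(fit))), 1e-3)
})

test_that("fits fail loudly on insufficient data", {
  tiny <- tibble::tibble(tumour_id = c("a", "b"), t = c(0, 0),
                         volume_cm3 = c(1, 2))
  expect_error(fit_growth(tiny, "logistic"), "k \\+ 2")
  expect_error(
    fit_growth(dplyr::mutate(tiny, volume_cm3 = c(-1, 2)), "logistic"),
    "positive")
})

test_that("min_points filtering drops singleton tumours when asked", {
  cohort <- make_plain_cohort(10, "exponential", c(r = 0.02), seed = 121,
                              points = c(1, 3))
  f <- fit_growth(cohort, "exponential",
                  control = fit_control(multistart = 3, min_points = 2))
  counts <- table(cohort$tumour_id)
  expect_equal(f$n_tumours, sum(counts >= 2))
  expect_equal(f$n_obs, sum(counts[counts >= 2]))
})
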