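# Posterior sampling, credible intervals, and permutation tests.

test_that("credible_interval takes empirical central quantiles", {
  expect_error(credible_interval(rep(5, 50)), "at least 100")
  ci <- credible_interval(rep(5, 200))
  expect_equal(c(ci$lower, ci$estimate, ci$upper), c(5, 5, 5))
  withr::with_seed(171, {
    z <- rnorm(1e5)
    ci95 <- credible_interval(z, 0.95)
    expect_equal(c(ci95$lower, ci95$upper), c(-1.96, 1.96), tolerance = 0.02)
    # level = 0.5 is the interquartile range
    ci50 <- credible_interval(z, 0.5)
    expect_equal(c(ci50$lower, ci50$upper),
                 unname(quantile(z, c(0.25, 0.75))), tolerance = 1e-12)
    # intervals widen with level
    ci99 <- credible_interval(z, 0.99)
    expect_lt(ci99$lower, ci95$lower)
    expect_gt(ci99$upper, ci95$upper)
  })
  expect_error(credible_interval(rnorm(200), level = 1.2), "in \\(0, 1\\)")
})

test_that("the Metropolis sampler reproduces a conjugate normal posterior", {
  # y ~ N(mu, 1), flat prior on mu: posterior is N(ybar, 1/n)
  withr::with_seed(181, y <- rnorm(25, 1.3, 1))
  n <- length(y); ybar <- mean(y); se <- 1 / sqrt(n)
  logpost <- function(u) sum(dnorm(y, u, 1, log = TRUE))
  res <- devilgrowth:::mcmc_sample(
    logpost, init = rep(ybar, 2), lower = -10, upper = 10,
    n_steps = 3000, n_chains = 2, burn_in = 1000, seed = 191)
  draws <- as.numeric(res$draws)
  expect_lt(abs(mean(draws) - ybar), 0.05 * se)
  ci <- credible_interval(draws, 0.95)
  expect_lt(abs(ci$lower - (ybar - 1.96 * se)), 0.15 * se)
  expect_lt(abs(ci$upper - (ybar + 1.96 * se)), 0.15 * se)
})

test_that("a zero-variance pseudo-posterior stays at the mode", {
  # degenerate target: any move away from 0 is rejected
  logpost <- function(u) if (abs(u) < 1e-12) 0 else -Inf
  res <- devilgrowth:::mcmc_sample(logpost, init = 0, lower = -1, upper = 1,
                                   n_steps = 200, n_chains = 2,
                                   burn_in = 50, seed = 201)
  expect_true(all(res$draws == 0))
})

test_that("sample_posterior is seed-reproducible and flags non-convergence", {
  cohort <- simulate_cohort(
    cohort_config(n_tumours = 15,
                  groups = list(g = cohort_group("exponential",
                                                 c(r = 0.016)))),
    seed = 211)
  fit <- fit_growth(cohort, "exponential",
                    control = fit_control(multistart = 3))
  p1 <- sample_posterior(fit, n_steps = 300, n_chains = 2, burn_in = 200,
                         seed = 7)
  p2 <- sample_posterior(fit, n_steps = 300, n_chains = 2, burn_in = 200,
                         seed = 7)
  expect_identical(p1$r, p2$r)
  expect_true(all(attr(p1, "rhat") < 1.2))
  # absurdly short chains from dispersed starts should warn
  expect_warning(
    sample_posterior(fit, n_steps = 60, n_chains = 3, burn_in = 5, seed = 8),
    "R-hat")
})

test_that("posterior credible interval brackets the MLE on clean data", {
  cohort <- simulate_cohort(
    cohort_config(n_tumours = 25,
                  groups = list(g = cohort_group("exponential",
                                                 c(r = 0.016)))),
    seed = 221)
  fit <- fit_growth(cohort, "exponential",
                    control = fit_control(multistart = 3))
  post <- sample_posterior(fit, n_steps = 800, n_chains = 2, burn_in = 400,
                           seed = 9)
  ci <- credible_interval(post)
  expect_lt(ci$lower[ci$parameter == "r"], fit$theta[["r"]])
  expect_gt(ci$upper[ci$parameter == "r"], fit$theta[["r"]])
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
})

test_that("permutation p-values follow the add-one convention", {
  # two wildly different exponential groups: observed beats every permutation
  slow <- make_plain_cohort(6, "exponential", c(r = 0.002), seed = 231,
                            epsilon = 0.005, points = 2,
                            labels = rep("diploid", 6))
  fast <- make_plain_cohort(6, "exponential", c(r = 0.1), seed = 232,
                            epsilon = 0.005, points = 2,
                            labels = rep("tetraploid", 6))
  fast$tumour_id <- sub("P", "Q", fast$tumour_id)
  cohort <- dplyr::bind_rows(slow, fast)
  pt <- permutation_test(cohort, "ploidy", model = "exponential",
                         n_perm = 39, seed = 10,
                         control = fit_control(multistart = 2))
  expect_equal(pt$p_value, 1 / 40)
  expect_length(pt$perms, 39)
})

test_that("permutation p matches exhaustive enumeration on a tiny cohort", {
  th <- c(r = 0.02)
  cohort <- make_plain_cohort(6, "exponential", th, seed = 241,
                              epsilon = 0.05, points = 2,
                              labels = rep(c("diploid", "tetraploid"), 3))
  ctl <- fit_control(multistart = 2)
  # exhaustive: all C(6,3) = 20 balanced relabelings, statistic recomputed
  # through the public fitting API
  ids <- sprintf("P%02d", 1:6)
  combos <- combn(6, 3)
  stat_for <- function(members_a) {
    fa <- fit_growth(cohort[cohort$tumour_id %in% ids[members_a], ],
                     "exponential", control = ctl)
    fb <- fit_growth(cohort[!cohort$tumour_id %in% ids[members_a], ],
                     "exponential", control = ctl)
    abs(fa$theta[["r"]] - fb$theta[["r"]])
  }
  stats <- apply(combos, 2, stat_for)
  obs <- stat_for(which(rep(c(TRUE, FALSE), 3)))
  p_exact <- mean(stats >= obs - 1e-12)
  pt <- permutation_test(cohort, "ploidy", model = "exponential",
                         n_perm = 400, seed = 11, control = ctl)
  expect_equal(pt$observed, obs, tolerance = 1e-6)
  expect_equal(pt$p_value, p_exact, tolerance = 0.08)
})

test_that("permutation results are invariant to relabelling the groups", {
  cohort <- simulate_cohort(cohort_config(n_tumours = 16), seed = 251)
  swapped <- dplyr::mutate(cohort, ploidy = ifelse(ploidy == "diploid",
                                                   "tetraploid", "diploid"))
  ctl <- fit_control(multistart = 2)
  p1 <- permutation_test(cohort, "ploidy", model = "exponential",
                         n_perm = 99, seed = 12, control = ctl)
  p2 <- permutation_test(swapped, "ploidy", model = "exponential",
                         n_perm = 99, seed = 12, control = ctl)
  expect_equal(p1$observed, p2$observed, tolerance = 1e-8)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("permutation tests demand two fit-able groups", {
  cohort <- simulate_cohort(cohort_config(n_tumours = 12), seed = 261)
  expect_error(permutation_test(cohort, "location", model = "exponential"),
               "two known groups")
  one_label <- dplyr::mutate(cohort, ploidy = "diploid")
  expect_error(permutation_test(one_label, "ploidy", model = "exponential"),
               "two known groups")
})
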