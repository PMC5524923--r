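# Posterior sampling for structural growth-law parameters.
#
# The posterior is proportional to exp(profile log-likelihood) x prior, where
# the per-tumour anchor times and the residual variance are profiled out of
# the likelihood exactly as in fitting. Priors are log-uniform over each
# parameter's bounds (uniform for the Mendelsohn exponent b), i.e. flat on
# the optimiser scale, so the target on that scale is the profile
# log-likelihood restricted to a box.

# Generic adaptive random-walk Metropolis sampler on a box.
# logpost: function of the parameter vector; -Inf allowed.
# During burn-in the global proposal scale is tuned toward ~25% acceptance
# and, from the second half of burn-in, proposals use the empirical
# covariance of the chain so far (adaptive Metropolis), which matters for the
# strongly correlated (r, K) posteriors of saturating growth laws.
# Returns draws [iter, chain, par] AFTER burn-in, plus acceptance rates.
mcmc_sample <- function(logpost, init, lower, upper,
                        n_steps = 1000, n_chains = 4, burn_in = 500,
                        init_scale = 0.1, seed = 1L) {
  p <- length(lower)
  if (is.vector(init)) init <- matrix(init, n_chains, p, byrow = TRUE)
  stopifnot(nrow(init) >= n_chains, ncol(init) == p)
  draws <- array(NA_real_, c(n_steps, n_chains, p))
  lps <- matrix(NA_real_, n_steps, n_chains)
  accept <- numeric(n_chains)
  withr::with_seed(seed, {
    for (ch in seq_len(n_chains)) {
      x <- pmin(pmax(init[ch, ], lower), upper)
      lp <- logpost(x)
      if (!is.finite(lp)) {
        # nudge into the interior if the chain starts on a bad point
        x <- (lower + upper) / 2
        lp <- logpost(x)
      }
      scale <- init_scale
      chol_prop <- diag(p)
      cov_based <- FALSE
      hist <- matrix(NA_real_, burn_in + n_steps, p)
      acc_window <- 0L
      n_acc <- 0L
      total <- burn_in + n_steps
      for (s in seq_len(total)) {
        prop <- x + scale * as.numeric(chol_prop %*% rnorm(p))
        lp_new <- if (any(prop < lower | prop > upper)) -Inf else logpost(prop)
        if (is.finite(lp_new) && log(runif(1)) < lp_new - lp) {
          x <- prop; lp <- lp_new
          acc_window <- acc_window + 1L
          if (s > burn_in) n_acc <- n_acc + 1L
        }
        hist[s, ] <- x
        if (s <= burn_in && s %% 50 == 0) {
          # global scale toward ~25% acceptance
          rate <- acc_window / 50
          scale <- scale * exp(pmin(pmax(rate - 0.25, -0.5), 0.5))
          acc_window <- 0L
          # correlated proposals from the chain's own covariance
          if (p > 1 && s >= max(100, burn_in / 2)) {
            cv <- stats::cov(hist[seq_len(s), , drop = FALSE])
            diag(cv) <- diag(cv) + 1e-10
            ch_try <- tryCatch(chol(cv), error = function(e) NULL)
            if (!is.null(ch_try)) {
              chol_prop <- t(ch_try) * (2.38 / sqrt(p))
              if (!cov_based) scale <- 1  # scale now rides on the covariance
              cov_based <- TRUE
            }
          }
        }
        if (s > burn_in) {
          draws[s - burn_in, ch, ] <- x
          lps[s - burn_in, ch] <- lp
        }
      }
      accept[ch] <- n_acc / n_steps
    }
  })
  list(draws = draws, lp = lps, accept = accept)
}

# split-chain potential scale reduction factor for one parameter;
# mat is iterations x chains
rhat_split <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Sample the posterior of a fitted growth law
#'
#' Runs adaptive random-walk Metropolis chains on the structural parameters
#' \eqn{\theta}, targeting the profile likelihood (anchor times and residual
#' variance profiled out, as in [fit_growth()]) under independent log-uniform
#' priors on each parameter's bounds (uniform for the Mendelsohn exponent).
#' Chains start from the MLE with small jitter. Split-chain potential scale
#' reduction factors (R-hat) are reported; values above 1.05 trigger a
#' warning but samples are still returned.
#'
#' @param fit A `growth_fit` from [fit_growth()].
#' @param n_steps Retained iterations per chain (after burn-in).
#' @param n_chains Number of chains.
#' @param burn_in Discarded adaptation iterations per chain.
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @param prior_bounds Optional named list of `c(lower, upper)` overriding the
#'   default prior support per parameter (natural units).
#' @param target `"marginal"` (default) or `"profile"`. Both profile the
#'   per-tumour anchor times; they differ in how the residual variance
#'   \eqn{\varepsilon} enters. `"profile"` plugs in the conditional MLE
#'   \eqn{\hat\varepsilon = SS/n}, which ignores the \eqn{m} degrees of
#'   freedom absorbed by the anchors and makes the target too sharp when
#'   tumours are many and measurements few. `"marginal"` integrates
#'   \eqn{\varepsilon} out under its Jeffreys prior and charges one degree of
#'   freedom per profiled anchor (a Laplace approximation to integrating the
#'   anchors), giving the df-honest target
#'   \eqn{-\tfrac{\nu}{2}\log SS(\theta)} with \eqn{\nu = n - m}; its
#'   credible intervals are approximately calibrated (see the vignette).
#' @return A `growth_posterior` tibble of draws (columns `chain`, `iter`, one
#'   column per parameter on the natural scale, and `lp`), with attributes
#'   `rhat`, `accept`, and `fit`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_tumours = 12), seed = 3)
#' fit <- fit_growth(cohort, "exponential", control = fit_control(multistart = 3))
#' post <- sample_posterior(fit, n_steps = 300, n_chains = 2, burn_in = 150)
#' credible_interval(post)
sample_posterior <- function(fit, n_steps = 1000, n_chains = 4,
                             burn_in = 500, seed = 1L, prior_bounds = NULL,
                             target = c("marginal", "profile")) {
  stopifnot(inherits(fit, "growth_fit"))
  target <- match.arg(target)
  model <- fit$model
  ser <- prepare_series(fit$data, fit$control$min_points)
  bu <- bounds_u(model)
  if (!is.null(prior_bounds)) {
    for (nm in names(prior_bounds)) {
      j <- match(nm, model$params)
      if (is.na(j)) abort(sprintf("Unknown parameter '%s' in prior_bounds.", nm))
      pb <- prior_bounds[[nm]]
      if (model$name == "mendelsohn" && nm == "b") {
        bu$lower[j] <- pb[1]; bu$upper[j] <- pb[2]
      } else {
        bu$lower[j] <- log(pb[1]); bu$upper[j] <- log(pb[2])
      }
    }
  }
  n <- ser$n_obs
  m <- ser$n_tumours
  nu <- n - m
  if (target == "marginal" && nu < 2) {
    warn("Too few residual degrees of freedom for the marginal target; falling back to the profile target.")
    target <- "profile"
  }
  floor_ss <- n * fit$control$epsilon_floor
  logpost <- function(u) {
    th <- u_to_theta(model, u)
    parts <- profile_loglik_parts(ser, model, th, fit$v0, fit$control)
    if (target == "profile") return(parts$loglik)
    -(nu / 2) * log(max(parts$ss, floor_ss))
  }
  u_hat <- theta_to_u(model, fit$theta)
  init <- withr::with_seed(seed + 1L, {
    matrix(rep(u_hat, each = n_chains), n_chains, model$k) +
      matrix(rnorm(n_chains * model$k, 0, 0.05), n_chains, model$k)
  })
  res <- mcmc_sample(logpost, init, bu$lower, bu$upper,
                     n_steps = n_steps, n_chains = n_chains,
                     burn_in = burn_in, seed = seed)
  rhat <- vapply(seq_len(model$k), function(j) {
    rhat_split(matrix(res$draws[, , j], nrow = n_steps, ncol = n_chains))
  }, numeric(1))
  names(rhat) <- model$params
  if (any(rhat > 1.05)) {
    warn(paste0("Chains may not have converged (split R-hat > 1.05): ",
                paste(sprintf("%s = %.3f", names(rhat)[rhat > 1.05],
                              rhat[rhat > 1.05]), collapse = ", ")))
  }
  draws <- do.call(rbind, lapply(seq_len(n_chains), function(ch) {
    um <- matrix(res$draws[, ch, ], nrow = n_steps, ncol = model$k)
    nat <- exp(um)
    if (model$name == "mendelsohn") nat[, 2] <- um[, 2]
    colnames(nat) <- model$params
    tibble::tibble(chain = ch, iter = seq_len(n_steps),
                   tibble::as_tibble(nat), lp = res$lp[, ch])
  }))
  structure(tibble::as_tibble(draws),
            class = c("growth_posterior", class(draws)),
            rhat = rhat, accept = res$accept, model = model$name,
            params = model$params, fit = fit, target = target)
}

#' Central credible interval
#'
#' Equal-tailed interval from empirical posterior quantiles: at level
#' \eqn{1-\alpha}, the \eqn{\alpha/2} and \eqn{1-\alpha/2} quantiles.
#'
#' @param x Posterior draws: a numeric vector or a `growth_posterior`.
#' @param level Interval probability, strictly between 0 and 1.
#' @param ... Passed between methods.
#' @return A tibble with columns `parameter`, `estimate` (posterior median),
#'   `lower`, `upper`, `level`.
#' @export
credible_interval <- function(x, level = 0.95, ...) {
  UseMethod("credible_interval")
}

#' @rdname credible_interval
#' @param parameter Label for the `parameter` column (default method).
#' @export
credible_interval.default <- function(x, level = 0.95, parameter = "x", ...) {
  if (!is.numeric(x)) abort("`x` must be numeric posterior draws.")
  if (length(x) < 100) abort("Need at least 100 posterior draws.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  a <- (1 - level) / 2
  q <- quantile(x, c(a, 0.5, 1 - a), names = FALSE, type = 7)
  tibble::tibble(parameter = parameter, estimate = q[2],
                 lower = q[1], upper = q[3], level = level)
}

#' @rdname credible_interval
#' @export
credible_interval.growth_posterior <- function(x, level = 0.95, ...) {
  params <- attr(x, "params")
  dplyr::bind_rows(lapply(params, function(p) {
    credible_interval.default(x[[p]], level = level, parameter = p)
  }))
}

#' @export
print.growth_posterior <- function(x, ...) {
  cat("<growth_posterior> ", attr(x, "model"), " law, ",
      dplyr::n_distinct(x$chain), " chains x ", max(x$iter),
      " retained draws\n", sep = "")
  rh <- attr(x, "rhat")
  cat("  split R-hat: ",
      paste(sprintf("%s = %.3f", names(rh), rh), collapse = ", "), "\n",
      sep = "")
  print(credible_interval(x), ...)
  invisible(x)
}
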