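# Maximum-likelihood fitting: bounded quasi-Newton over log-scale structural
# parameters, with the per-tumour anchor times and the shared residual
# variance profiled out at every objective evaluation.

#' Control settings for growth-law fitting
#'
#' @param multistart Number of Latin-hypercube starting points for the outer
#'   optimiser (in addition to one data-driven start). `0` uses only the
#'   user-supplied or data-driven start (warm-start refits).
#' @param seed Integer seed controlling start placement; fits are
#'   deterministic given the seed.
#' @param t0_bracket Search window for the latent anchor times, days relative
#'   to each tumour's first observation.
#' @param epsilon_floor Lower bound on the profiled residual variance; guards
#'   noise-free data.
#' @param min_points Minimum measurements a tumour needs to enter the fit.
#'   Single-capture tumours are kept by default: their anchor time absorbs the
#'   single residual, so they only contribute to the AICc sample size.
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence tolerance factor.
#' @param grid_step,t0_tol Grid resolution (days) and golden-section tolerance
#'   for the inner anchor-time profiling.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(multistart = 20, seed = 1L,
                        t0_bracket = c(-3000, 3000),
                        epsilon_floor = 1e-8, min_points = 1,
                        maxit = 200, factr = 1e7,
                        grid_step = 25, t0_tol = 1e-5) {
  stopifnot(multistart >= 0, length(t0_bracket) == 2,
            t0_bracket[1] < t0_bracket[2], epsilon_floor > 0, min_points >= 1)
  structure(
    list(multistart = multistart, seed = as.integer(seed),
         t0_bracket = t0_bracket, epsilon_floor = epsilon_floor,
         min_points = min_points, maxit = maxit, factr = factr,
         grid_step = grid_step, t0_tol = t0_tol),
    class = "fit_control"
  )
}

# transform theta <-> optimiser scale: log for positive parameters, natural
# scale for the Mendelsohn exponent b
theta_to_u <- function(model, theta) {
  u <- log(theta)
  if (model$name == "mendelsohn") u[2] <- theta[2]
  u
}
u_to_theta <- function(model, u) {
  th <- exp(u)
  if (model$name == "mendelsohn") th[2] <- u[2]
  names(th) <- model$params
  th
}
bounds_u <- function(model) {
  b <- model$bounds
  lo <- log(b[, 1]); hi <- log(b[, 2])
  if (model$name == "mendelsohn") { lo[2] <- b[2, 1]; hi[2] <- b[2, 2] }
  list(lower = lo, upper = hi)
}

# pooled within-tumour least-squares slope of log volume on time; the exact
# exponential-law MLE and a serviceable rate guess for every other law
pooled_log_slope <- function(ser) {
  num <- 0; den <- 0
  for (i in seq_along(ser$t)) {
    t <- ser$t[[i]]
    if (length(t) < 2) next
    y <- ser$logv[[i]]
    tc <- t - mean(t); yc <- y - mean(y)
    num <- num + sum(tc * yc)
    den <- den + sum(tc * tc)
  }
  if (den == 0) return(NA_real_)
  num / den
}

# one data-informed start per model
data_start <- function(model, ser) {
  b <- model$bounds
  clamp <- function(x, i) min(max(x, b[i, 1] * 1.0000001), b[i, 2] * 0.9999999)
  r0 <- pooled_log_slope(ser)
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.01
  vmax <- exp(max(unlist(ser$logv)))
  vgm <- exp(mean(unlist(ser$logv)))
  th <- switch(model$name,
    exponential = c(r = r0),
    logistic = c(r = r0, K = 3 * vmax),
    mendelsohn = c(r = r0 * vgm^(1 - 0.8), b = 0.8),
    gompertz = c(r = r0, rho = r0 / 2),
    von_bertalanffy = c(alpha = 2 * r0 * vgm^(1 / 3), beta = r0)
  )
  setNames(vapply(seq_along(th), function(i) clamp(th[i], i), numeric(1)),
           model$params)
}

# Latin-hypercube starts on the optimiser scale
lhs_starts <- function(model, n) {
  bu <- bounds_u(model)
  p <- model$k
  out <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    strata <- (sample.int(n) - runif(n)) / n
    out[, j] <- bu$lower[j] + strata * (bu$upper[j] - bu$lower[j])
  }
  out
}

# profile log-likelihood machinery shared by fitting and posterior sampling
profile_loglik_parts <- function(ser, model, theta, v0, control) {
  prof <- profile_t0_core(ser, model, theta, v0, control$t0_bracket,
                          control$grid_step, control$t0_tol)
  ss <- sum(prof$ssq)
  n <- ser$n_obs
  eps <- max(ss / n, control$epsilon_floor)
  ll <- -0.5 * n * log(2 * pi * eps) - ss / (2 * eps)
  list(prof = prof, ss = ss, epsilon = eps, loglik = ll)
}

#' Fit a growth law by maximum likelihood
#'
#' Maximises the lognormal-error likelihood of [log_likelihood()] over the
#' structural parameters \eqn{\theta} by nested optimisation: an outer bounded
#' quasi-Newton search (multi-started from Latin-hypercube points plus one
#' data-driven point, on the log-parameter scale) with, at every evaluation,
#' each tumour's latent anchor time profiled by 1-D search and the shared
#' residual variance by its closed form.
#'
#' @inheritParams log_likelihood
#' @param control A [fit_control()] list.
#' @param start Optional named starting value for \eqn{\theta} (warm starts);
#'   used alongside the automatic starts, or alone when
#'   `control$multistart = 0`.
#' @return A `growth_fit` object with elements `model`, `theta` (MLE),
#'   `t0` (per-tumour anchor tibble), `epsilon`, `loglik`, `aicc`, `n_obs`,
#'   `n_tumours`, `v0`, `data`, and optimiser diagnostics; supports
#'   [generics::tidy()], [generics::glance()], [generics::augment()] and
#'   [ggplot2::autoplot()].
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_tumours = 15), seed = 42)
#' fit <- fit_growth(cohort, "logistic", control = fit_control(multistart = 4))
#' glance(fit)
fit_growth <- function(data, model = "logistic", v0 = 0.125,
                       control = fit_control(), start = NULL) {
  model <- as_growth_model(model)
  ser <- prepare_series(data, control$min_points)
  fit_core(ser, model, v0, control, start)
}

fit_core <- function(ser, model, v0, control, start = NULL) {
  n <- ser$n_obs
  if (n < model$k + 2) {
    abort(sprintf(
      "Need at least k + 2 = %d observations to fit the %s model with AICc; have %d.",
      model$k + 2, model$name, n))
  }
  bu <- bounds_u(model)
  obj <- function(u) {
    th <- u_to_theta(model, u)
    -profile_loglik_parts(ser, model, th, v0, control)$loglik
  }
  starts <- list()
  if (!is.null(start)) {
    starts <- c(starts, list(theta_to_u(model, validate_theta(model, start))))
  }
  if (control$multistart > 0 || is.null(start)) {
    starts <- c(starts, list(theta_to_u(model, data_start(model, ser))))
  }
  if (control$multistart > 0) {
    lhs <- withr::with_seed(control$seed,
                            lhs_starts(model, control$multistart))
    starts <- c(starts, lapply(seq_len(nrow(lhs)), function(i) lhs[i, ]))
  }
  best <- NULL
  fails <- 0L
  for (u0 in starts) {
    res <- tryCatch(
      optim(u0, obj, method = "L-BFGS-B",
            lower = bu$lower, upper = bu$upper,
            control = list(maxit = control$maxit, factr = control$factr)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) { fails <- fails + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(sprintf("All %d optimisation starts failed for the %s model.",
                  length(starts), model$name))
  }
  theta_hat <- u_to_theta(model, best$par)
  parts <- profile_loglik_parts(ser, model, theta_hat, v0, control)
  t0_tbl <- tibble::tibble(
    tumour_id = ser$ids,
    t0 = as.numeric(parts$prof$t0),
    ssq = as.numeric(parts$prof$ssq),
    n_obs = unname(lengths(ser$t)),
    at_boundary = parts$prof$t0 <= control$t0_bracket[1] + 1e-6 |
      parts$prof$t0 >= control$t0_bracket[2] - 1e-6
  )
  if (any(t0_tbl$at_boundary)) {
    warn(paste0("Anchor-time profile hit the search boundary for tumour(s): ",
                paste(t0_tbl$tumour_id[t0_tbl$at_boundary], collapse = ", ")))
  }
  structure(
    list(
      model = model,
      theta = theta_hat,
      t0 = t0_tbl,
      epsilon = parts$epsilon,
      loglik = parts$loglik,
      aicc = aicc(parts$loglik, model$k, n),
      n_obs = n,
      n_tumours = ser$n_tumours,
      v0 = v0,
      control = control,
      data = ser$data,
      optim = list(convergence = best$convergence, value = best$value,
                   n_starts = length(starts), n_failed = fails)
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$model$label, " law, ", x$n_obs, " measurements on ",
      x$n_tumours, " tumours\n", sep = "")
  est <- paste(sprintf("%s = %.4g", names(x$theta), x$theta), collapse = ", ")
  cat("  theta:   ", est, "\n", sep = "")
  cat(sprintf("  epsilon: %.4g   logLik: %.3f   AICc: %.2f\n",
              x$epsilon, x$loglik, x$aicc))
  invisible(x)
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = object$model$k, nobs = object$n_obs,
            class = "logLik")
}

#' Residuals of a growth-law fit
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return Numeric vector of log-volume residuals, observation order of the
#'   fitted data.
#' @export
residuals.growth_fit <- function(object, ...) {
  aug <- augment(object)
  aug$.resid
}
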