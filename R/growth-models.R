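# Registry of the five classical one-dimensional tumour growth laws.
# Volumes are in cm^3 and time in days throughout; all rate parameters are
# per day, K is in cm^3 and the Mendelsohn exponent b is dimensionless.

.model_registry <- list(
  exponential = list(
    code = 1L, label = "Exponential", params = "r",
    bounds = rbind(r = c(1e-4, 1))
  ),
  logistic = list(
    code = 2L, label = "Logistic", params = c("r", "K"),
    bounds = rbind(r = c(1e-4, 1), K = c(1, 1e5))
  ),
  mendelsohn = list(
    code = 3L, label = "Mendelsohn", params = c("r", "b"),
    bounds = rbind(r = c(1e-4, 1), b = c(0.05, 3))
  ),
  gompertz = list(
    code = 4L, label = "Gompertz", params = c("r", "rho"),
    bounds = rbind(r = c(1e-4, 1), rho = c(1e-4, 1))
  ),
  von_bertalanffy = list(
    code = 5L, label = "von Bertalanffy", params = c("alpha", "beta"),
    bounds = rbind(alpha = c(1e-4, 1), beta = c(1e-4, 1))
  )
)

#' Names of the available growth laws
#'
#' @return Character vector of model names accepted by [growth_model()].
#' @export
#' @examples
#' growth_models()
growth_models <- function() names(.model_registry)

#' Define a tumour growth law
#'
#' Constructs a specification of one of five classical growth laws for tumour
#' volume \eqn{V(t)} (cm\eqn{^3}, days):
#' \describe{
#'   \item{exponential}{\eqn{dV/dt = rV}}
#'   \item{logistic}{\eqn{dV/dt = rV(1 - V/K)}}
#'   \item{mendelsohn}{\eqn{dV/dt = rV^b}, \eqn{b \neq 1}}
#'   \item{gompertz}{\eqn{dV/dt = rV e^{-\rho(t - t_0)}}, anchored at the
#'     per-tumour anchor time \eqn{t_0}}
#'   \item{von_bertalanffy}{\eqn{dV/dt = \alpha V^{2/3} - \beta V}}
#' }
#' Each law has a closed-form solution through the anchor condition
#' \eqn{V(t_0) = V_0}; see [growth_solution()].
#'
#' @param name Model name, one of [growth_models()]. Partial matching is not
#'   performed.
#' @return A `growth_model` object: list with `name`, `label`, ordered
#'   `params`, structural parameter count `k`, and a matrix of default search
#'   `bounds` (natural units).
#' @export
#' @examples
#' growth_model("logistic")
growth_model <- function(name) {
  if (inherits(name, "growth_model")) return(name)
  if (!is.character(name) || length(name) != 1 || !name %in% names(.model_registry)) {
    abort(paste0(
      "`name` must be one of: ", paste(names(.model_registry), collapse = ", ")
    ))
  }
  reg <- .model_registry[[name]]
  structure(
    list(
      name = name, label = reg$label, code = reg$code,
      params = reg$params, k = length(reg$params),
      bounds = reg$bounds
    ),
    class = "growth_model"
  )
}

as_growth_model <- function(x) growth_model(x)

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> ", x$label, "\n", sep = "")
  cat("  parameters (k = ", x$k, "): ", paste(x$params, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# validate and canonicalise a parameter vector for a model; returns a named
# numeric in registry order
validate_theta <- function(model, theta) {
  model <- as_growth_model(model)
  if (!is.numeric(theta) || length(theta) != model$k) {
    abort(sprintf("`theta` for the %s model must be numeric of length %d (%s).",
                  model$name, model$k, paste(model$params, collapse = ", ")))
  }
  if (!is.null(names(theta)) && all(nzchar(names(theta)))) {
    if (!setequal(names(theta), model$params)) {
      abort(sprintf("`theta` names must be {%s}, got {%s}.",
                    paste(model$params, collapse = ", "),
                    paste(names(theta), collapse = ", ")))
    }
    theta <- theta[model$params]
  } else {
    names(theta) <- model$params
  }
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    abort("All growth-law parameters must be finite and strictly positive.")
  }
  if (model$name == "mendelsohn" && theta[["b"]] == 1) {
    abort("Mendelsohn exponent b = 1 degenerates to the exponential law; use that model instead.")
  }
  theta
}

#' Growth rate dV/dt of a growth law
#'
#' Evaluates the right-hand side of the model's differential equation at
#' volume `v`. The Gompertz law is time-inhomogeneous: its rate decays with
#' time since the anchor \eqn{t_0}, supplied as `t_since_anchor`; the other
#' laws ignore that argument.
#'
#' @param model A [growth_model()] or model name.
#' @param theta Named (or registry-ordered) numeric parameter vector.
#' @param v Volume(s), cm\eqn{^3}; must be strictly positive.
#' @param t_since_anchor Days since the anchor time (Gompertz only).
#' @return Numeric vector of growth rates, cm\eqn{^3}/day.
#' @export
#' @examples
#' growth_rate("logistic", c(r = 0.016, K = 364), v = 182)
growth_rate <- function(model, theta, v, t_since_anchor = 0) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("`v` must be strictly positive and finite.")
  }
  switch(model$name,
    exponential = theta[["r"]] * v,
    logistic = theta[["r"]] * v * (1 - v / theta[["K"]]),
    mendelsohn = theta[["r"]] * v^theta[["b"]],
    gompertz = theta[["r"]] * v * exp(-theta[["rho"]] * t_since_anchor),
    von_bertalanffy = theta[["alpha"]] * v^(2 / 3) - theta[["beta"]] * v
  )
}

# internal: log-volume at offsets dt since the anchor; NaN outside the domain
log_solution <- function(model, theta, dt, v0) {
  cpp_log_solution(model$code, as.numeric(theta), as.numeric(dt), log(v0))
}

#' Closed-form solution of a growth law
#'
#' Evaluates the analytic solution \eqn{V(t)} of the model's differential
#' equation through the anchor condition \eqn{V(t_0) = V_0}. The anchor
#' volume \eqn{V_0} (default 0.125 cm\eqn{^3}, i.e. a 0.5 cm cube — roughly
#' the smallest detectable facial tumour) fixes the time origin of every
#' curve; changing it only translates curves in time.
#'
#' @inheritParams growth_rate
#' @param t Time(s), days.
#' @param v0 Anchor volume, cm\eqn{^3} (> 0).
#' @param t0 Anchor time, days.
#' @return Volumes at `t`, cm\eqn{^3}.
#' @details The Mendelsohn law with \eqn{b > 1} blows up in finite time (and
#'   with \eqn{b < 1} is undefined before a finite extinction time); the von
#'   Bertalanffy solution reaches zero volume at a finite past time when
#'   \eqn{V_0 < (\alpha/\beta)^3}. Evaluation outside the valid domain is a
#'   domain error reporting the boundary time.
#' @export
#' @examples
#' growth_solution("logistic", c(r = 0.016, K = 364), t = 300)
growth_solution <- function(model, theta, t, v0 = 0.125, t0 = 0) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  if (!is.numeric(v0) || length(v0) != 1 || !is.finite(v0) || v0 <= 0) {
    abort("`v0` must be a single positive volume (cm^3).")
  }
  if (any(!is.finite(t))) abort("`t` must be finite.")
  ls <- log_solution(model, theta, t - t0, v0)
  bad <- is.nan(ls) | ls == -Inf
  if (any(bad)) {
    bt <- domain_boundary(model, theta, v0)
    abort(sprintf(
      "%s solution undefined at t = %s: valid time domain is %s (days relative to t0 = %g).",
      model$label, paste(signif(t[bad], 6), collapse = ", "),
      bt, t0
    ))
  }
  exp(ls)
}

# human-readable valid (t - t0) domain for the error message
domain_boundary <- function(model, theta, v0) {
  switch(model$name,
    mendelsohn = {
      b <- theta[["b"]]; r <- theta[["r"]]
      if (b > 1) {
        sprintf("(-Inf, %g) [finite-time blow-up]", v0^(1 - b) / ((b - 1) * r))
      } else {
        sprintf("(%g, Inf) [extinction boundary]", -v0^(1 - b) / ((1 - b) * r))
      }
    },
    von_bertalanffy = {
      a <- theta[["alpha"]] / theta[["beta"]]
      if (v0^(1 / 3) < a) {
        sprintf("(%g, Inf) [volume reaches zero]",
                -(3 / theta[["beta"]]) * log(a / (a - v0^(1 / 3))))
      } else "(-Inf, Inf)"
    },
    "(-Inf, Inf)"
  )
}

#' Time for a growth law to reach a target volume
#'
#' Inverts the closed-form solution: returns the number of days after the
#' anchor time at which the curve through \eqn{V(t_0) = V_0} reaches
#' `v_target`. Negative values mean the target is passed before the anchor.
#'
#' @inheritParams growth_solution
#' @param v_target Target volume(s), cm\eqn{^3}; must be reachable by the law
#'   (e.g. below the logistic carrying capacity `K`).
#' @return Days since the anchor time, same length as `v_target`.
#' @export
#' @examples
#' time_to_volume("logistic", c(r = 0.016, K = 364), v_target = 182)
time_to_volume <- function(model, theta, v_target, v0 = 0.125) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  if (any(!is.finite(v_target)) || any(v_target <= 0)) {
    abort("`v_target` must be strictly positive and finite.")
  }
  vapply(v_target, function(v) t2v_one(model, theta, v, v0), numeric(1))
}

t2v_one <- function(model, theta, v, v0) {
  switch(model$name,
    exponential = log(v / v0) / theta[["r"]],
    logistic = {
      K <- theta[["K"]]
      if (v >= K || v0 >= K) {
        abort(sprintf(
          "Target volume %g cm^3 unreachable: at or above the logistic carrying capacity K = %g.",
          v, K))
      }
      log((K / v0 - 1) / (K / v - 1)) / theta[["r"]]
    },
    mendelsohn = {
      b <- theta[["b"]]
      (v^(1 - b) - v0^(1 - b)) / ((1 - b) * theta[["r"]])
    },
    gompertz = {
      r <- theta[["r"]]; rho <- theta[["rho"]]
      arg <- (rho / r) * log(v / v0)
      if (arg >= 1) {
        abort(sprintf(
          "Target volume %g cm^3 unreachable: above the Gompertz asymptote %g cm^3.",
          v, v0 * exp(r / rho)))
      }
      -log1p(-arg) / rho
    },
    von_bertalanffy = {
      a <- theta[["alpha"]] / theta[["beta"]]
      u <- v^(1 / 3); u0 <- v0^(1 / 3)
      if ((u - a) * (u0 - a) <= 0 || (u == a)) {
        abort(sprintf(
          "Target volume %g cm^3 unreachable: on the far side of the von Bertalanffy equilibrium %g cm^3.",
          v, a^3))
      }
      -(3 / theta[["beta"]]) * log((a - u) / (a - u0))
    }
  )
}
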