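# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a growth-law fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return One row per structural parameter: `term`, `estimate`.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' One-row summary of a growth-law fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name, k = x$model$k,
    n_obs = x$n_obs, n_tumours = x$n_tumours,
    epsilon = x$epsilon, logLik = x$loglik, AICc = x$aicc
  )
}

#' Augment measurement data with fitted curve values
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return The fitted data with `.t0` (tumour anchor estimate), `.fitted`
#'   (log fitted volume), `.resid` (log residual), and `.fitted_volume`.
#' @export
augment.growth_fit <- function(x, ...) {
  data <- dplyr::left_join(x$data, x$t0[, c("tumour_id", "t0")],
                           by = "tumour_id")
  pred <- log_solution(x$model, x$theta, data$t - data$t0, x$v0)
  data$.t0 <- data$t0
  data$t0 <- NULL
  data$.fitted <- pred
  data$.resid <- log(data$volume_cm3) - pred
  data$.fitted_volume <- exp(pred)
  data
}

#' Tidy posterior draws into credible intervals
#'
#' @param x A `growth_posterior`.
#' @param level Interval probability.
#' @param ... Unused.
#' @export
tidy.growth_posterior <- function(x, level = 0.95, ...) {
  credible_interval(x, level = level)
}

#' One-row diagnostics of a posterior sample
#'
#' @param x A `growth_posterior`.
#' @param ... Unused.
#' @export
glance.growth_posterior <- function(x, ...) {
  rh <- attr(x, "rhat")
  tibble::tibble(
    model = attr(x, "model"),
    n_chains = dplyr::n_distinct(x$chain),
    n_draws = nrow(x),
    max_rhat = max(rh),
    mean_accept = mean(attr(x, "accept"))
  )
}

#' Tidy a permutation test
#'
#' @param x A `perm_test`.
#' @param ... Unused.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, observed = x$observed,
    p_value = x$p_value, n_perm = x$n_perm,
    group = x$group, model = x$model
  )
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x)
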