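# Lognormal-error likelihood with per-tumour latent anchor times.
#
# Each tumour i carries a latent anchor time t_{i,0} (days, relative to its
# first observation) at which its curve passes the reference volume V0. Given
# structural parameters theta, every t_{i,0} is profiled out by 1-D
# minimisation of that tumour's sum of squared log residuals, and the shared
# residual variance epsilon has the closed-form profile MLE mean(resid^2).

# Normalise a long measurement table into the internal per-tumour structure.
# `data` must have tumour_id, volume_cm3, and t (days since first obs) or day
# (arbitrary origin). Times are re-expressed so each tumour starts at t = 0.
prepare_series <- function(data, min_points = 1) {
  data <- tibble::as_tibble(data)
  need <- c("tumour_id", "volume_cm3")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"t" %in% names(data)) {
    if (!"day" %in% names(data)) {
      abort("Need a `t` (days since first observation) or `day` column.")
    }
    data$t <- data$day
  }
  if (any(!is.finite(data$volume_cm3)) || any(data$volume_cm3 <= 0)) {
    abort("All volumes must be positive and finite (cm^3).")
  }
  data <- dplyr::arrange(data, .data$tumour_id, .data$t)
  data <- dplyr::group_by(data, .data$tumour_id)
  dup <- dplyr::summarise(data, d = anyDuplicated(.data$t) > 0)
  if (any(dup$d)) {
    abort(paste0("Duplicate observation times within tumour(s): ",
                 paste(dup$tumour_id[dup$d], collapse = ", ")))
  }
  data <- dplyr::mutate(data, t = .data$t - min(.data$t))
  data <- dplyr::ungroup(data)
  if (min_points > 1) {
    keep <- dplyr::count(data, .data$tumour_id)
    keep <- keep$tumour_id[keep$n >= min_points]
    data <- dplyr::filter(data, .data$tumour_id %in% keep)
    if (nrow(data) == 0) abort("No tumours left after the min_points filter.")
  }
  split_idx <- split(seq_len(nrow(data)), data$tumour_id)
  ids <- names(split_idx)
  list(
    data = data,
    ids = ids,
    t = lapply(split_idx, function(i) data$t[i]),
    logv = lapply(split_idx, function(i) log(data$volume_cm3[i])),
    n_obs = nrow(data),
    n_tumours = length(ids)
  )
}

#' Log-likelihood of a growth law under lognormal measurement error
#'
#' Computes \eqn{\sum_{i,j} \log N(\log V_{i,j};\, \mu = \log V(t_{i,j};
#' \theta, t_{i,0}),\, \sigma^2 = \varepsilon)}: observed log volumes are
#' normal around the log of the model curve anchored at each tumour's
#' \eqn{t_{i,0}}, with shared variance \eqn{\varepsilon}.
#'
#' @param data Long measurement table: columns `tumour_id`, `volume_cm3`, and
#'   `t` (days since the tumour's first observation) or `day`.
#' @param model A [growth_model()] or model name.
#' @param theta Structural parameter vector for `model`.
#' @param t0 Per-tumour anchor times (days relative to each tumour's first
#'   observation): named numeric keyed by tumour id, or unnamed in tumour id
#'   sort order.
#' @param epsilon Residual variance of log volume (> 0).
#' @param v0 Anchor volume, cm\eqn{^3}.
#' @return A single log-likelihood value; `-Inf` if the model curve is
#'   undefined at any observation (rejected point, not an error).
#' @export
log_likelihood <- function(data, model, theta, t0, epsilon, v0 = 0.125) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("`epsilon` must be a single positive variance.")
  }
  ser <- prepare_series(data)
  if (length(t0) != ser$n_tumours) {
    abort(sprintf("`t0` must have one entry per tumour (%d).", ser$n_tumours))
  }
  if (!is.null(names(t0))) {
    if (!setequal(names(t0), ser$ids)) {
      abort("Names of `t0` must match the tumour ids.")
    }
    t0 <- t0[ser$ids]
  }
  ll <- 0
  for (i in seq_along(ser$ids)) {
    pred <- log_solution(model, theta, ser$t[[i]] - t0[[i]], v0)
    if (any(!is.finite(pred))) return(-Inf)
    ll <- ll + sum(dnorm(ser$logv[[i]], pred, sqrt(epsilon), log = TRUE))
  }
  ll
}

#' Profile the latent anchor time of each tumour
#'
#' For fixed structural parameters, finds for every tumour the anchor time
#' \eqn{\hat t_{i,0}} minimising its sum of squared log residuals — because
#' \eqn{\varepsilon} is shared, this is the conditional maximum-likelihood
#' anchor for any \eqn{\varepsilon}. The search scans a coarse grid over
#' `bracket` and polishes by golden-section.
#'
#' @inheritParams log_likelihood
#' @param bracket Search interval for \eqn{t_0}, days relative to first
#'   observation. The default \eqn{\pm 3000} days comfortably covers a
#'   decade-long epidemic.
#' @return Tibble with one row per tumour: `tumour_id`, `t0` (days), `ssq`
#'   (minimised sum of squared log residuals), `n_obs`, and `at_boundary`.
#' @export
profile_t0 <- function(data, model, theta, v0 = 0.125,
                       bracket = c(-3000, 3000)) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  ser <- prepare_series(data)
  prof <- profile_t0_core(ser, model, theta, v0, bracket)
  tibble::tibble(
    tumour_id = ser$ids,
    t0 = prof$t0,
    ssq = prof$ssq,
    n_obs = lengths(ser$t),
    at_boundary = prof$t0 <= bracket[1] + 1e-6 | prof$t0 >= bracket[2] - 1e-6
  )
}

profile_t0_core <- function(ser, model, theta, v0, bracket,
                            grid_step = 25, tol = 1e-5) {
  cpp_profile_t0(model$code, as.numeric(theta), ser$t, ser$logv, log(v0),
                 bracket[1], bracket[2], grid_step, tol)
}

#' Profile maximum-likelihood estimate of the residual variance
#'
#' The MLE of a shared normal variance given residuals is the mean squared
#' residual; a small floor keeps noise-free (synthetic) fits finite.
#'
#' @param residuals Numeric vector of log-volume residuals.
#' @param floor Lower bound for the returned variance.
#' @return The profiled variance \eqn{\hat\varepsilon}.
#' @export
#' @examples
#' profile_epsilon(c(0.1, -0.1))
profile_epsilon <- function(residuals, floor = 1e-8) {
  if (length(residuals) == 0) abort("Need at least one residual.")
  if (any(!is.finite(residuals))) abort("Residuals must be finite.")
  max(mean(residuals^2), floor)
}
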