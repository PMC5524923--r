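# ggplot2 graphics for cohorts, fits, comparisons and tests.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort's tumour volume trajectories
#'
#' Observed volume against days since each tumour's first capture, one line
#' per tumour, log-scale volume axis.
#'
#' @param data Measurement tibble.
#' @param colour_by Optional covariate column to colour by.
#' @return A ggplot.
#' @export
plot_cohort <- function(data, colour_by = NULL) {
  data <- tibble::as_tibble(data)
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$t, y = .data$volume_cm3, group = .data$tumour_id))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour_by]]),
                                alpha = 0.6) +
      ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]), size = 1)
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 1)
  }
  p + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "days since first capture", y = expression(volume~(cm^3)))
}

#' Plot a fitted growth curve over the aligned tumour series
#'
#' Each tumour's measurements are shifted onto the common curve time axis
#' (days since the tumour reached the reference volume, i.e.
#' \eqn{t - \hat t_{i,0}}) and overlaid on the fitted maximum-likelihood
#' curve.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, ...) {
  aug <- augment(object)
  aug$days_since_v0 <- aug$t - aug$.t0
  grid <- seq(0, max(aug$days_since_v0, 1), length.out = 200)
  curve <- tibble::tibble(
    days_since_v0 = grid,
    volume_cm3 = exp(log_solution(object$model, object$theta, grid, object$v0))
  )
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$days_since_v0,
                                    y = .data$volume_cm3)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$tumour_id),
                       alpha = 0.4, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "red", linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = sprintf("days since tumour reached %g cm^3", object$v0),
      y = expression(volume~(cm^3)),
      title = sprintf("%s fit (AICc %.2f)", object$model$label, object$aicc)
    )
}

#' Plot a Delta-AICc comparison
#'
#' @param object A `growth_aicc` from [compare_growth_models()].
#' @param ... Unused.
#' @return A ggplot tile map of Delta-AICc, best model outlined.
#' @export
autoplot.growth_aicc <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$split, y = .data$model,
                                    fill = .data$delta_aicc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$delta_aicc), "-",
                     sprintf("%.2f", .data$delta_aicc))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Delta-AICc")
}

#' Plot posterior densities
#'
#' @param object A `growth_posterior`.
#' @param ... Unused.
#' @return A ggplot of per-parameter posterior densities by chain.
#' @export
autoplot.growth_posterior <- function(object, ...) {
  params <- attr(object, "params")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              dplyr::all_of(params),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     colour = factor(.data$chain))) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(colour = "chain", x = NULL)
}

#' Plot a permutation null distribution
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot histogram of permutation statistics with the observed
#'   value marked.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$perms),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic,
      title = sprintf("p = %.4g (%d permutations)", object$p_value,
                      object$n_perm)
    )
}
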