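# AICc model selection across growth laws and data splits.

#' Small-sample-corrected Akaike information criterion
#'
#' \deqn{AICc = 2k - 2\ell + \frac{2k(k+1)}{n - k - 1}}
#' where \eqn{\ell} is the maximised log-likelihood, `k` the number of
#' structural model parameters (latent anchor times and the residual variance
#' are profiled nuisances and are not counted), and `n` the number of
#' measurements.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Structural parameter count.
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value (vectorised over its arguments).
#' @export
#' @examples
#' aicc(0, 2, 10)
aicc <- function(loglik, k, n) {
  if (any(!is.finite(loglik))) abort("`loglik` must be finite.")
  if (any(n <= k + 1)) {
    abort("AICc undefined: need n > k + 1 observations.")
  }
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)
}

#' Standard cohort splits
#'
#' The seven data splits used to compare growth between tumour types: all
#' data, by ploidy (diploid/tetraploid, dropping unknown ploidy), by facial
#' location (mucosal/dermal, dropping unknown location), and by host sex.
#'
#' @return Named list of filter criteria consumable by [filter_cohort()].
#' @export
default_splits <- function() {
  list(
    all = list(),
    diploid = list(ploidy = "diploid"),
    tetraploid = list(ploidy = "tetraploid"),
    mucosal = list(location = "mucosal"),
    dermal = list(location = "dermal"),
    female = list(sex = "female"),
    male = list(sex = "male")
  )
}

#' Compare growth laws by AICc across cohort splits
#'
#' Fits every requested growth law to every data split and tabulates AICc and
#' \eqn{\Delta}AICc (difference from the best model in that split, computed
#' with `n` = measurements in the split). Ties for the column minimum are
#' broken toward the model with fewer parameters. A fit failure is recorded
#' as a missing cell, not an error.
#'
#' @inheritParams fit_growth
#' @param models Character vector of growth-law names (default: all five).
#' @param splits Named list of filter criteria as in [default_splits()];
#'   splits matching no tumours are dropped with a warning.
#' @return A tibble of class `growth_aicc`: one row per (split, model) with
#'   `k`, `n_obs`, `n_tumours`, `loglik`, `aicc`, `delta_aicc`, `best`. The
#'   fitted `growth_fit` objects are attached as attribute `"fits"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_tumours = 12), seed = 7)
#' compare_growth_models(cohort,
#'   models = c("exponential", "logistic"),
#'   splits = list(all = list()),
#'   control = fit_control(multistart = 3)
#' )
compare_growth_models <- function(data, models = growth_models(),
                                  splits = default_splits(), v0 = 0.125,
                                  control = fit_control()) {
  data <- tibble::as_tibble(data)
  rows <- list()
  fits <- list()
  for (sp in names(splits)) {
    sub <- tryCatch(
      do.call(filter_cohort, c(list(data), splits[[sp]])),
      error = function(e) NULL
    )
    if (is.null(sub) || nrow(sub) == 0) {
      warn(sprintf("Split '%s' matches no measurements; dropped.", sp))
      next
    }
    for (mn in models) {
      mod <- growth_model(mn)
      fit <- tryCatch(fit_growth(sub, mod, v0 = v0, control = control),
                      error = function(e) NULL)
      fits[[paste(sp, mn, sep = ".")]] <- fit
      rows[[length(rows) + 1L]] <- tibble::tibble(
        split = sp, model = mn, k = mod$k,
        n_obs = if (is.null(fit)) sum(!is.na(sub$volume_cm3)) else fit$n_obs,
        n_tumours = if (is.null(fit)) dplyr::n_distinct(sub$tumour_id) else fit$n_tumours,
        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
        aicc = if (is.null(fit)) NA_real_ else fit$aicc
      )
    }
  }
  if (!length(rows)) abort("No non-degenerate splits to compare.")
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::group_by(tab, .data$split)
  tab <- dplyr::mutate(
    tab,
    delta_aicc = .data$aicc - min(.data$aicc, na.rm = TRUE),
    best = best_flag(.data$aicc, .data$k)
  )
  tab <- dplyr::ungroup(tab)
  tab$split <- factor(tab$split, levels = names(splits))
  tab$model <- factor(tab$model, levels = models)
  tab <- dplyr::arrange(tab, .data$split, .data$model)
  structure(tab, class = c("growth_aicc", class(tab)), fits = fits, v0 = v0)
}

# exactly one best model per split; AICc ties broken toward smaller k
best_flag <- function(aicc, k) {
  out <- rep(FALSE, length(aicc))
  ok <- which(is.finite(aicc))
  if (!length(ok)) return(out)
  mins <- ok[aicc[ok] <= min(aicc[ok]) + 1e-9]
  out[mins[which.min(k[mins])]] <- TRUE
  out
}

#' Wide \eqn{\Delta}AICc table
#'
#' Reshapes a [compare_growth_models()] result into models-by-splits layout
#' (one \eqn{\Delta}AICc column per split).
#'
#' @param x A `growth_aicc` tibble.
#' @param digits Decimal places to round to (default 2); `NULL` for no
#'   rounding.
#' @return A tibble with `model`, `k`, and one column per split.
#' @export
aicc_wide <- function(x, digits = 2) {
  stopifnot(inherits(x, "growth_aicc"))
  tab <- tibble::as_tibble(x)[, c("split", "model", "k", "delta_aicc")]
  if (!is.null(digits)) tab$delta_aicc <- round(tab$delta_aicc, digits)
  tidyr::pivot_wider(tab, names_from = "split", values_from = "delta_aicc")
}

#' @export
print.growth_aicc <- function(x, ...) {
  cat("Delta-AICc by growth law and cohort split",
      " (0 marks the best-supported model per split)\n", sep = "")
  print(aicc_wide(x), ...)
  best <- tibble::as_tibble(x)[x$best, c("split", "model", "aicc", "n_obs")]
  cat("\nBest model per split (absolute AICc):\n")
  print(best, ...)
  invisible(x)
}
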