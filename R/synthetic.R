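# Synthetic cohort generator emulating the statistical structure of
# quarterly capture-mark-recapture tumour monitoring: growth-law
# trajectories, ~90-day capture schedules, lognormal measurement noise, a
# detection floor, and censoring by host mortality as tumours approach their
# maximum volume.

#' Define a covariate group for the cohort generator
#'
#' @param model Growth-law name for the group's true trajectories.
#' @param theta Named true parameter vector for `model`.
#' @param ploidy,location,sex Covariate labels stamped on the group's tumours.
#'   `sex = NA` assigns female/male at random per tumour.
#' @return A list describing the group.
#' @export
cohort_group <- function(model, theta, ploidy = "unknown",
                         location = "unknown", sex = NA) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  list(model = model, theta = theta, ploidy = ploidy, location = location,
       sex = sex)
}

#' Configuration of a synthetic tumour cohort
#'
#' Defaults state the sampling design the generator emulates: 62 tumours
#' captured at ~90-day intervals (SD 15 days of jitter), a geometric-like
#' number of captures per tumour with mean 1.4 (87 measurements on 62
#' animals), tumour onset (time of reaching the 0.125 cm\eqn{^3} reference
#' volume) uniform within 400 days before first capture, lognormal
#' measurement noise with log-scale variance 0.04 (about \eqn{\pm}20\% volume
#' error), observations censored once a tumour exceeds 80\% of its carrying
#' capacity (host mortality), and a 0.125 cm\eqn{^3} detection floor. The two
#' default groups are logistic with \eqn{r = 0.016}/day, \eqn{K = 364}
#' cm\eqn{^3} (diploid-like) and \eqn{r = 0.026}/day, \eqn{K = 172}
#' cm\eqn{^3} (tetraploid-like), mixed equally.
#'
#' @param n_tumours Number of tumours (one host each).
#' @param groups Named list of [cohort_group()]s.
#' @param weights Group sampling probabilities (default equal).
#' @param capture_interval Mean days between captures.
#' @param capture_jitter_sd SD of the capture-gap jitter, days; 0 gives exact
#'   intervals.
#' @param captures_mean Mean captures per tumour; counts are
#'   `1 + Geometric(1/captures_mean)`.
#' @param onset_window Range (days, relative to first scheduled capture) over
#'   which the true anchor time is drawn uniformly.
#' @param epsilon Variance of lognormal measurement noise on the log scale.
#' @param censor_fraction Fraction `c` of the group's carrying capacity above
#'   which observation stops (mortality); only applies to laws with a finite
#'   `K`. `1` disables censoring (and with `detection_floor = 0`, all
#'   filtering).
#' @param detection_floor Volume (cm\eqn{^3}) below which a tumour is not
#'   recorded.
#' @param v0 Reference anchor volume, cm\eqn{^3}.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_tumours = 62,
                          groups = list(
                            diploid = cohort_group(
                              "logistic", c(r = 0.016, K = 364),
                              ploidy = "diploid"),
                            tetraploid = cohort_group(
                              "logistic", c(r = 0.026, K = 172),
                              ploidy = "tetraploid")
                          ),
                          weights = NULL,
                          capture_interval = 90, capture_jitter_sd = 15,
                          captures_mean = 1.4,
                          onset_window = c(-400, 0),
                          epsilon = 0.04, censor_fraction = 0.8,
                          detection_floor = 0.125, v0 = 0.125) {
  stopifnot(n_tumours >= 1, length(groups) >= 1,
            capture_interval > 0, capture_jitter_sd >= 0, captures_mean >= 1,
            length(onset_window) == 2, onset_window[1] <= onset_window[2],
            epsilon >= 0, censor_fraction > 0, censor_fraction <= 1,
            detection_floor >= 0, v0 > 0)
  if (is.null(weights)) weights <- rep(1 / length(groups), length(groups))
  stopifnot(length(weights) == length(groups), all(weights >= 0))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  structure(
    list(n_tumours = n_tumours, groups = groups,
         weights = weights / sum(weights),
         capture_interval = capture_interval,
         capture_jitter_sd = capture_jitter_sd,
         captures_mean = captures_mean, onset_window = onset_window,
         epsilon = epsilon, censor_fraction = censor_fraction,
         detection_floor = detection_floor, v0 = v0),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_tumours, " tumours, ", length(x$groups),
      " group(s)\n", sep = "")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %s (w = %.2f): %s, %s\n", g,
                x$weights[match(g, names(x$groups))], gr$model$name,
                paste(sprintf("%s = %.4g", names(gr$theta), gr$theta),
                      collapse = ", ")))
  }
  cat(sprintf(
    "  captures: mean %.2f per tumour every %g +/- %g days; onset U(%g, %g)\n",
    x$captures_mean, x$capture_interval, x$capture_jitter_sd,
    x$onset_window[1], x$onset_window[2]))
  cat(sprintf("  noise eps = %g; censor at %g*K; floor %g cm^3\n",
              x$epsilon, x$censor_fraction, x$detection_floor))
  invisible(x)
}

#' Capture-day schedule for one tumour
#'
#' Strictly increasing capture days starting at day 0, with gaps
#' `interval` plus Gaussian jitter (truncated below at one day).
#'
#' @param n_captures Number of captures.
#' @param interval Mean gap, days.
#' @param jitter_sd SD of gap jitter, days.
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of capture days, length `n_captures`.
#' @export
#' @examples
#' trapping_schedule(4, jitter_sd = 0)
trapping_schedule <- function(n_captures, interval = 90, jitter_sd = 15,
                              seed = NULL) {
  stopifnot(n_captures >= 1)
  gen <- function() {
    if (n_captures == 1) return(0)
    gaps <- pmax(rnorm(n_captures - 1, interval, jitter_sd), 1)
    c(0, cumsum(gaps))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate one tumour's measurement series
#'
#' Evaluates the true growth curve anchored at `t0` (the day the tumour
#' passes `v0`) on the capture days and multiplies by lognormal noise
#' \eqn{e^\eta}, \eqn{\eta \sim N(0, \varepsilon)}.
#'
#' @inheritParams growth_solution
#' @param t0 True anchor day (same time axis as `capture_days`).
#' @param capture_days Days of capture (see [trapping_schedule()]).
#' @param epsilon Log-scale noise variance; 0 gives noise-free volumes.
#' @param seed Optional seed.
#' @return Tibble with `day`, `t` (days since first capture), `v_true`, and
#'   observed `volume_cm3`.
#' @export
simulate_trajectory <- function(model, theta, t0, capture_days, epsilon,
                                v0 = 0.125, seed = NULL) {
  model <- as_growth_model(model)
  theta <- validate_theta(model, theta)
  stopifnot(epsilon >= 0, all(diff(capture_days) > 0))
  v_true <- growth_solution(model, theta, capture_days, v0 = v0, t0 = t0)
  gen <- function() {
    eta <- if (epsilon > 0) rnorm(length(capture_days), 0, sqrt(epsilon)) else 0
    tibble::tibble(
      day = capture_days,
      t = capture_days - capture_days[1],
      v_true = v_true,
      volume_cm3 = v_true * exp(eta)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a synthetic tumour cohort
#'
#' Draws a cohort under a [cohort_config()]: per tumour, a covariate group, a
#' capture schedule, a uniform onset time, a noisy trajectory, then the
#' observation filters — volumes below the detection floor are dropped, and
#' the first observation exceeding `censor_fraction * K` censors that capture
#' and all later ones (host mortality). Tumours whose observations are all
#' filtered are redrawn (up to 50 attempts) and dropped if still empty.
#' Times are re-expressed relative to each tumour's first retained
#' observation.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return A tibble of measurements (`tumour_id`, `host_id`, `group`, `sex`,
#'   `ploidy`, `location`, `day`, `t`, `volume_cm3`) of class
#'   `synthetic_cohort`. The ground truth is attached as attribute `"truth"`:
#'   a list with the `config` and a per-tumour tibble (`tumour_id`, `group`,
#'   `theta` list-column, true `t0` relative to first retained observation,
#'   and scheduled/retained/censored/below-floor counts).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_tumours = 10), seed = 1)
#' cohort_truth(cohort)$tumours
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  run <- function() {
    rows <- list()
    truth_rows <- list()
    gidx <- sample.int(length(config$groups), config$n_tumours, replace = TRUE,
                       prob = config$weights)
    for (i in seq_len(config$n_tumours)) {
      gr <- config$groups[[gidx[i]]]
      K <- if ("K" %in% names(gr$theta)) gr$theta[["K"]] else Inf
      # censor_fraction = 1 disables mortality censoring entirely (otherwise
      # measurement noise above K would still trigger it)
      threshold <- if (config$censor_fraction >= 1) Inf else
        config$censor_fraction * K
      keep <- logical(0)
      for (attempt in 1:50) {
        n_caps <- 1L + rgeom(1, prob = 1 / config$captures_mean)
        days <- trapping_schedule(n_caps, config$capture_interval,
                                  config$capture_jitter_sd)
        t0 <- runif(1, config$onset_window[1], config$onset_window[2])
        traj <- tryCatch(
          simulate_trajectory(gr$model, gr$theta, t0, days,
                              config$epsilon, v0 = config$v0),
          error = function(e) NULL  # capture fell outside the law's domain
        )
        if (is.null(traj)) { keep <- logical(0); next }
        status <- rep("retained", n_caps)
        status[traj$volume_cm3 < config$detection_floor] <- "below_floor"
        over <- which(traj$volume_cm3 >= threshold & status == "retained")
        if (length(over)) status[over[1]:n_caps] <- "censored"
        keep <- status == "retained"
        if (any(keep)) break
      }
      if (!length(keep) || !any(keep)) next
      id <- sprintf("T%03d", i)
      first_day <- traj$day[keep][1]
      sex_i <- if (is.na(gr$sex)) sample(c("female", "male"), 1) else gr$sex
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tumour_id = id, host_id = sprintf("H%03d", i),
        group = names(config$groups)[gidx[i]],
        sex = sex_i, ploidy = gr$ploidy, location = gr$location,
        day = traj$day[keep] - first_day,
        t = traj$day[keep] - first_day,
        volume_cm3 = traj$volume_cm3[keep]
      )
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        tumour_id = id, group = names(config$groups)[gidx[i]],
        model = gr$model$name, theta = list(gr$theta),
        t0 = t0 - first_day,
        n_scheduled = n_caps, n_retained = sum(keep),
        n_censored = sum(status == "censored"),
        n_below_floor = sum(status == "below_floor")
      )
    }
    if (!length(rows)) abort("Configuration produced no observable tumours.")
    list(data = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth_rows))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out$data,
            class = c("synthetic_cohort", class(out$data)),
            truth = list(config = config, tumours = out$truth, seed = seed))
}

#' Ground truth of a synthetic cohort
#'
#' @param cohort A tibble returned by [simulate_cohort()].
#' @return The `"truth"` attribute: `config`, per-tumour `tumours` tibble,
#'   and the `seed`.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) abort("`cohort` carries no ground-truth attribute.")
  tr
}
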