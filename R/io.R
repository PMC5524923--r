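# Reading, writing and filtering long-format measurement tables.

#' Read a tumour measurement table
#'
#' Reads a long-format CSV with one row per capture event. Required columns:
#' `tumour_id`; a time column, either numeric `day` or ISO-8601 `date`; and a
#' volume, either `volume_cm3` directly or the calliper dimensions
#' `length_cm`, `width_cm`, `depth_cm`. Optional columns `host_id`, `sex`,
#' `ploidy`, `location` default to the tumour id / `"unknown"`.
#'
#' Dimension columns are converted to a volume by the rectangular product
#' \eqn{L \times W \times D} (so a 0.5 cm cube gives the 0.125 cm\eqn{^3}
#' reference volume) or, with `volume_convention = "ellipsoid"`, by
#' \eqn{\pi/6 \cdot LWD}. Dates are converted to days; `t` holds days since
#' each tumour's first observation. Rows with non-positive volumes are
#' dropped with a message.
#'
#' @param path CSV file path.
#' @param volume_convention `"rectangular"` (default) or `"ellipsoid"`.
#' @return A measurement tibble (`tumour_id`, `host_id`, `sex`, `ploidy`,
#'   `location`, `day`, `t`, `volume_cm3`) with the convention recorded in
#'   attribute `"volume_convention"`.
#' @export
read_measurements <- function(path,
                              volume_convention = c("rectangular", "ellipsoid")) {
  volume_convention <- match.arg(volume_convention)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"tumour_id" %in% names(data)) abort("Missing required column `tumour_id`.")

  if ("day" %in% names(data)) {
    data$day <- as.numeric(data$day)
  } else if ("date" %in% names(data)) {
    d <- as.Date(data$date)
    if (any(is.na(d))) abort("Column `date` must be ISO-8601 (YYYY-MM-DD).")
    data$day <- as.numeric(d - min(d))
  } else {
    abort("Need a `day` (numeric) or `date` (ISO-8601) column.")
  }

  dims <- c("length_cm", "width_cm", "depth_cm")
  if (!"volume_cm3" %in% names(data)) {
    if (!all(dims %in% names(data))) {
      abort("Need `volume_cm3` or all of `length_cm`, `width_cm`, `depth_cm`.")
    }
    prod_lwd <- data$length_cm * data$width_cm * data$depth_cm
    data$volume_cm3 <- switch(volume_convention,
      rectangular = prod_lwd,
      ellipsoid = pi / 6 * prod_lwd
    )
  }

  bad <- !is.finite(data$volume_cm3) | data$volume_cm3 <= 0
  if (any(bad)) {
    inform(sprintf(
      "Dropping %d row(s) with non-positive or missing volume (tumour %s).",
      sum(bad), paste(unique(data$tumour_id[bad]), collapse = ", ")))
    data <- data[!bad, ]
  }
  if (nrow(data) == 0) abort("No valid measurements in the file.")

  dup <- duplicated(data[, c("tumour_id", "day")])
  if (any(dup)) {
    abort(sprintf("Duplicate (tumour_id, day) row(s): tumour %s.",
                  paste(unique(data$tumour_id[dup]), collapse = ", ")))
  }

  if (!"host_id" %in% names(data)) data$host_id <- data$tumour_id
  for (cv in c("sex", "ploidy", "location")) {
    if (!cv %in% names(data)) data[[cv]] <- "unknown"
    data[[cv]] <- dplyr::coalesce(as.character(data[[cv]]), "unknown")
  }

  data <- dplyr::arrange(data, .data$tumour_id, .data$day)
  data <- dplyr::group_by(data, .data$tumour_id)
  data <- dplyr::mutate(data, t = .data$day - min(.data$day))
  data <- dplyr::ungroup(data)
  keep <- c("tumour_id", "host_id", "sex", "ploidy", "location",
            "day", "t", "volume_cm3")
  out <- data[, c(keep, setdiff(names(data), keep))]
  attr(out, "volume_convention") <- volume_convention
  out
}

#' Write a cohort to CSV (with optional ground-truth sidecar)
#'
#' Writes the measurement table in the same schema [read_measurements()]
#' reads, so synthetic cohorts round-trip. For a [simulate_cohort()] result
#' the ground truth can be written alongside as JSON.
#'
#' @param data Measurement tibble.
#' @param path Output CSV path.
#' @param truth_path Optional path for a JSON ground-truth sidecar (only
#'   written when `data` carries a truth attribute).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path, truth_path = NULL) {
  cols <- intersect(
    c("tumour_id", "host_id", "group", "sex", "ploidy", "location",
      "day", "t", "volume_cm3"),
    names(data)
  )
  readr::write_csv(tibble::as_tibble(data)[, cols], path, progress = FALSE)
  tr <- attr(data, "truth")
  if (!is.null(truth_path) && !is.null(tr)) {
    tum <- tr$tumours
    tum$theta <- lapply(tum$theta, as.list)
    jsonlite::write_json(
      list(seed = tr$seed,
           config = config_as_list(tr$config),
           tumours = tum),
      truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}

config_as_list <- function(config) {
  g <- lapply(config$groups, function(gr) {
    list(model = gr$model$name, theta = as.list(gr$theta),
         ploidy = gr$ploidy, location = gr$location, sex = gr$sex)
  })
  list(
    n_tumours = config$n_tumours, groups = g, weights = config$weights,
    capture_interval = config$capture_interval,
    capture_jitter_sd = config$capture_jitter_sd,
    captures_mean = config$captures_mean,
    onset_window = config$onset_window, epsilon = config$epsilon,
    censor_fraction = config$censor_fraction,
    detection_floor = config$detection_floor, v0 = config$v0
  )
}

#' Filter a cohort by covariates
#'
#' Keeps measurements matching the given covariate values exactly; because
#' unknown categories are spelled `"unknown"`, a ploidy or location split
#' automatically drops tumours with unknown ploidy or location. No criteria
#' returns the data unchanged.
#'
#' @param data Measurement tibble.
#' @param sex,ploidy,location Values to keep, or `NULL` to not filter.
#' @return The filtered tibble; an empty result is an error naming the
#'   criteria.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_tumours = 10), seed = 2)
#' filter_cohort(cohort, ploidy = "diploid")
filter_cohort <- function(data, sex = NULL, ploidy = NULL, location = NULL) {
  data <- tibble::as_tibble(data)
  crit <- list(sex = sex, ploidy = ploidy, location = location)
  crit <- crit[!vapply(crit, is.null, logical(1))]
  miss <- setdiff(names(crit), names(data))
  if (length(miss)) {
    abort(paste0("Criteria reference missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (nm in names(crit)) data <- data[data[[nm]] %in% crit[[nm]], ]
  if (nrow(data) == 0) {
    abort(paste0(
      "No measurements match the criteria: ",
      paste(sprintf("%s = %s", names(crit),
                    vapply(crit, paste, character(1), collapse = "/")),
            collapse = ", ")))
  }
  data
}
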