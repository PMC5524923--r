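# Independent oracles used across the suite. Everything here is deliberately
# written from the model definitions (differential equations, normal
# densities) without touching the package's solution or profiling code.

# right-hand sides of the five growth laws, straight from their ODEs
oracle_rhs <- function(model, theta, v, dt) {
  switch(model,
    exponential = theta[["r"]] * v,
    logistic = theta[["r"]] * v * (1 - v / theta[["K"]]),
    mendelsohn = theta[["r"]] * v^theta[["b"]],
    gompertz = theta[["r"]] * v * exp(-theta[["rho"]] * dt),
    von_bertalanffy = theta[["alpha"]] * v^(2 / 3) - theta[["beta"]] * v
  )
}

# closed-form solutions rewritten independently (plain R, volume scale)
oracle_solution <- function(model, theta, dt, v0 = 0.125) {
  switch(model,
    exponential = v0 * exp(theta[["r"]] * dt),
    logistic = theta[["K"]] /
      (1 + (theta[["K"]] / v0 - 1) * exp(-theta[["r"]] * dt)),
    mendelsohn = {
      b <- theta[["b"]]
      ((1 - b) * theta[["r"]] * dt + v0^(1 - b))^(1 / (1 - b))
    },
    gompertz = v0 * exp(theta[["r"]] / theta[["rho"]] *
                          (1 - exp(-theta[["rho"]] * dt))),
    von_bertalanffy = {
      a <- theta[["alpha"]] / theta[["beta"]]
      (a - (a - v0^(1 / 3)) * exp(-theta[["beta"]] * dt / 3))^3
    }
  )
}

# Adaptive Cash-Karp RK45 integration of dV/d(dt) = rhs from (0, v0),
# reporting V at the sorted non-negative checkpoints t_out.
oracle_ode_solution <- function(model, theta, t_out, v0 = 0.125,
                                rtol = 1e-10, atol = 1e-12) {
  stopifnot(all(diff(t_out) >= 0), all(t_out >= 0))
  b <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(3 / 10, -9 / 10, 6 / 5),
    c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
    c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
  )
  a <- c(0, 1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
  t <- 0
  v <- v0
  h <- min(1, max(t_out[t_out > 0], 1) / 100)
  out <- numeric(length(t_out))
  oi <- 1
  while (oi <= length(t_out) && t_out[oi] <= t) { out[oi] <- v; oi <- oi + 1 }
  max_steps <- 5e5
  for (step in seq_len(max_steps)) {
    if (oi > length(t_out)) break
    h <- min(h, t_out[length(t_out)] - t)
    k <- numeric(6)
    k[1] <- oracle_rhs(model, theta, v, t)
    ok <- TRUE
    for (s in 2:6) {
      vs <- v + h * sum(b[[s - 1]] * k[seq_len(s - 1)])
      if (!is.finite(vs) || vs <= 0) { ok <- FALSE; break }
      k[s] <- oracle_rhs(model, theta, vs, t + a[s] * h)
    }
    if (ok) {
      v5 <- v + h * sum(c5 * k)
      v4 <- v + h * sum(c4 * k)
      err <- abs(v5 - v4)
      tol <- atol + rtol * max(abs(v), abs(v5))
      ok <- is.finite(v5) && v5 > 0 && err <= tol
    }
    if (!ok) { h <- h / 2; next }
    # accept the step; pick off any checkpoints inside it by dense refinement
    t_new <- t + h
    while (oi <= length(t_out) && t_out[oi] <= t_new + 1e-12) {
      if (abs(t_out[oi] - t_new) <= 1e-12) {
        out[oi] <- v5
      } else {
        out[oi] <- oracle_ode_refine(model, theta, t, v, t_out[oi], rtol, atol)
      }
      oi <- oi + 1
    }
    t <- t_new
    v <- v5
    if (err > 0) h <- h * min(5, 0.9 * (tol / err)^0.2) else h <- h * 5
  }
  stopifnot(oi > length(t_out))
  out
}

# small fixed-step RK4 from (t0, v0) to t_target, used to land exactly on
# checkpoints that fall inside an accepted adaptive step
oracle_ode_refine <- function(model, theta, t0, v0, t_target, rtol, atol) {
  n <- 200
  h <- (t_target - t0) / n
  v <- v0
  t <- t0
  for (i in seq_len(n)) {
    k1 <- oracle_rhs(model, theta, v, t)
    k2 <- oracle_rhs(model, theta, v + h / 2 * k1, t + h / 2)
    k3 <- oracle_rhs(model, theta, v + h / 2 * k2, t + h / 2)
    k4 <- oracle_rhs(model, theta, v + h * k3, t + h)
    v <- v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  v
}

# random parameter draws that keep each law integrable over [0, horizon]
# days from V0 = 0.125 (biologically plausible per-day rates)
oracle_draw_theta <- function(model, horizon = 600) {
  runif_log <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  repeat {
    th <- switch(model,
      exponential = c(r = runif_log(1e-3, 0.03)),
      logistic = c(r = runif_log(1e-3, 0.1), K = runif_log(10, 5000)),
      mendelsohn = {
        b <- if (runif(1) < 0.5) runif(1, 0.3, 0.95) else runif(1, 1.05, 1.6)
        c(r = runif_log(1e-3, 0.03), b = b)
      },
      gompertz = c(r = runif_log(1e-3, 0.1), rho = runif_log(1e-3, 0.05)),
      von_bertalanffy = c(alpha = runif_log(0.01, 0.5),
                          beta = runif_log(0.01, 0.5))
    )
    if (model == "mendelsohn" && th[["b"]] > 1) {
      blow <- 0.125^(1 - th[["b"]]) / ((th[["b"]] - 1) * th[["r"]])
      if (blow < 1.3 * horizon) next
    }
    return(th)
  }
}

# brute-force lognormal-error log-likelihood: scalar loop over measurements,
# normal log-densities assembled by hand
oracle_loglik <- function(data, model, theta, t0, epsilon, v0 = 0.125) {
  ll <- 0
  for (id in sort(unique(data$tumour_id))) {
    sub <- data[data$tumour_id == id, ]
    sub <- sub[order(sub$t), ]
    tt <- sub$t - min(sub$t)
    for (j in seq_len(nrow(sub))) {
      mu <- log(oracle_solution(model, theta, tt[j] - t0[[id]], v0))
      x <- log(sub$volume_cm3[j])
      ll <- ll + (-0.5 * log(2 * pi * epsilon) - (x - mu)^2 / (2 * epsilon))
    }
  }
  ll
}

# dense grid search for one tumour's anchor time
oracle_grid_t0 <- function(t, volume, model, theta, v0 = 0.125,
                           lo = -2000, hi = 2000, step = 0.01) {
  grid <- seq(lo, hi, by = step)
  logv <- log(volume)
  ss <- numeric(length(grid))
  for (j in seq_along(t)) {
    pred <- log(oracle_solution(model, theta, t[j] - grid, v0))
    pred[!is.finite(pred)] <- NA
    contrib <- (logv[j] - pred)^2
    contrib[is.na(contrib)] <- 1e30
    ss <- ss + contrib
  }
  grid[which.min(ss)]
}

# a small noisy test cohort without using the package generator
make_plain_cohort <- function(n_tumours, model, theta, seed, epsilon = 0.04,
                              points = c(1, 2, 3), v0 = 0.125,
                              labels = NULL) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_tumours)) {
      np <- if (length(points) == 1) points else sample(points, 1)
      t <- sort(c(0, cumsum(runif(np - 1, 60, 120))))[seq_len(np)]
      t0 <- runif(1, -300, 0)
      vtrue <- vapply(t, function(tt) oracle_solution(model, theta, tt - t0, v0),
                      numeric(1))
      rows[[i]] <- tibble::tibble(
        tumour_id = sprintf("P%02d", i),
        t = t, day = t,
        volume_cm3 = vtrue * exp(rnorm(np, 0, sqrt(epsilon)))
      )
    }
    out <- dplyr::bind_rows(rows)
    if (!is.null(labels)) {
      lab <- tibble::tibble(tumour_id = sprintf("P%02d", seq_len(n_tumours)),
                            ploidy = labels)
      out <- dplyr::left_join(out, lab, by = "tumour_id")
    }
    out
  })
}
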