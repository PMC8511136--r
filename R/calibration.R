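#' Calibration configuration
#'
#' Bounds, grids and optimizer settings used by the fitting routines.
#' Defaults mirror the published fit bounds: growth rate in
#' `[0.017, 0.14]` day^-1 (doubling times 5-40 days), resistance rate in
#' `[0, 0.1]` day^-1, surviving fraction in `[0, 1]`, and the initial
#' volume within +/-30% of the measured baseline.
#'
#' @param lambda_bounds Growth-rate bounds (day^-1).
#' @param lambda_grid Growth-rate grid for [grid_search_lambda()]; default
#'   `log(2) / DT` for doubling times `DT = 5..40` days in 1-day steps.
#' @param epsilon_bounds Resistance-rate bounds (day^-1).
#' @param epsilon_min_positive Smallest strictly positive `epsilon`
#'   searched. The optimizer works on `log10(epsilon)`; values below this
#'   floor are observationally indistinguishable from zero over study
#'   horizons of a few hundred days.
#' @param S_bounds Surviving-fraction bounds.
#' @param V0_rel_bounds Initial-volume bounds relative to the measured
#'   baseline volume.
#' @param gamma0_bounds Bounds for `gamma0` when it is fitted free (only in
#'   parameter-sharing comparisons; the default model ties `gamma0 =
#'   lambda`).
#' @param n_starts Number of multistart initial points (Latin hypercube
#'   over the box).
#' @param n_starts_refit Starts used when only `(S, epsilon)` are refit
#'   (bootstrap replicates); the point estimate is always included as the
#'   first start.
#' @param objective_floor Denominator floor (cm^3) of the relative
#'   squared-difference objective, guarding near-zero measured volumes.
#' @param score_terms RMSE summary statistics summed into the grid-search
#'   score; the default four-term definition
#'   `mean + median + min + max` is normative, `c("mean","median","max")`
#'   is available as the three-term variant.
#' @param optim_control Control list passed to [stats::optim()]
#'   (`L-BFGS-B`); the extra element `fd_step` sets the finite-difference
#'   step per unit-cube coordinate. The tight defaults play the role of
#'   1e-9 step/optimality tolerances in the original analysis.
#' @param seed Default RNG seed for multistart draws.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lambda_bounds = c(0.017, 0.14),
                       lambda_grid = log(2) / seq(40, 5, by = -1),
                       epsilon_bounds = c(0, 0.1),
                       epsilon_min_positive = 1e-6,
                       S_bounds = c(0, 1),
                       V0_rel_bounds = c(0.7, 1.3),
                       gamma0_bounds = c(0, 0.2),
                       n_starts = 10L,
                       n_starts_refit = 5L,
                       objective_floor = 0.5,
                       score_terms = c("mean", "median", "min", "max"),
                       optim_control = list(maxit = 1000L, factr = 10,
                                            fd_step = 1e-6),
                       seed = 1L) {
  stopifnot(lambda_bounds[1] > 0, diff(lambda_bounds) > 0,
            epsilon_min_positive > 0, objective_floor > 0, n_starts >= 1)
  score_terms <- match.arg(score_terms, c("mean", "median", "min", "max"),
                           several.ok = TRUE)
  structure(list(lambda_bounds = lambda_bounds, lambda_grid = lambda_grid,
                 epsilon_bounds = epsilon_bounds,
                 epsilon_min_positive = epsilon_min_positive,
                 S_bounds = S_bounds, V0_rel_bounds = V0_rel_bounds,
                 gamma0_bounds = gamma0_bounds,
                 n_starts = as.integer(n_starts),
                 n_starts_refit = as.integer(n_starts_refit),
                 objective_floor = objective_floor,
                 score_terms = score_terms,
                 optim_control = optim_control, seed = seed),
            class = "fit_config")
}

#' Root mean squared error between measured and simulated volumes
#'
#' @param measured,simulated Equal-length numeric vectors (cm^3).
#' @return RMSE (cm^3).
#' @export
rmse <- function(measured, simulated) {
  if (length(measured) != length(simulated) || length(measured) < 1)
    stop("measured and simulated must be equal-length, non-empty")
  sqrt(mean((measured - simulated)^2))
}

#' Sum of relative squared differences
#'
#' The fitting objective: `sum(((sim - meas) / max(meas, floor))^2)`. The
#' floor keeps the relative difference defined for zero or near-zero
#' measured volumes.
#'
#' @param measured,simulated Equal-length numeric vectors (cm^3).
#' @param floor Denominator floor (cm^3), `> 0`; default 0.5.
#' @return Dimensionless objective value.
#' @export
relative_sq_objective <- function(measured, simulated, floor = 0.5) {
  if (length(measured) != length(simulated) || length(measured) < 1)
    stop("measured and simulated must be equal-length, non-empty")
  if (floor <= 0) stop("floor must be > 0")
  sum(((simulated - measured) / pmax(measured, floor))^2)
}

#' Predicted total volumes at measurement days
#'
#' Days before `t0` follow untreated exponential growth backwards
#' (`V0 * exp(lambda * (day - t0))`); days at or after `t0` follow the full
#' treated model. The total volume is continuous, so days coinciding with a
#' fraction are unambiguous.
#'
#' @param params A [model_params()].
#' @param fraction_times Sorted fraction days.
#' @param days Measurement days (any order).
#' @return Predicted total volumes (cm^3).
#' @export
predict_volumes <- function(params, fraction_times, days) {
  out <- numeric(length(days))
  pre <- days < params$t0
  if (any(pre))
    out[pre] <- params$V0 * exp(params$lambda * (days[pre] - params$t0))
  if (any(!pre)) {
    events <- .fraction_events(params, fraction_times)
    ord <- days[!pre]
    cmp <- .eval_compartments(events, params, ord)
    out[!pre] <- cmp$V_live + cmp$V_dead
  }
  out
}

# ---- internal constrained multistart optimizer -----------------------------

# Validation-free mirror of predict_volumes() for the optimizer hot loop:
# identical piecewise-analytic arithmetic on bare numerics (z-space
# coordinates are in-bounds by construction, so constructor checks add
# nothing here).
.predict_fast <- function(lambda, S, eps, gamma0, V0, t0, fraction_times,
                          days) {
  grow <- function(vl, g, dt) {
    if (eps < .EPS_LIMIT) vl * exp((lambda - g) * dt)
    else vl * exp(lambda * dt + (g / eps) * expm1(-eps * dt))
  }
  n <- length(fraction_times)
  et <- c(t0, fraction_times)
  g <- gamma0 * exp(-eps * (et - t0))
  vl <- vd <- numeric(n + 1L)
  vl[1L] <- V0
  if (n > 0) for (i in seq_len(n)) {
    dt <- et[i + 1L] - et[i]
    a <- grow(vl[i], g[i], dt)
    b <- vd[i] * exp(-lambda * dt)
    vl[i + 1L] <- S * a
    vd[i + 1L] <- b + (1 - S) * a
  }
  out <- numeric(length(days))
  pre <- days < t0
  if (any(pre)) out[pre] <- V0 * exp(lambda * (days[pre] - t0))
  if (any(!pre)) {
    d <- days[!pre]
    i <- findInterval(d, et)
    dt <- d - et[i]
    out[!pre] <- grow(vl[i], g[i], dt) + vd[i] * exp(-lambda * dt)
  }
  out
}

# natural-parameter list (names S, epsilon, V0, lambda, gamma0, t0) ->
# model_params object
.build_params <- function(p) {
  model_params(lambda = p$lambda, surviving_fraction = p$S,
               epsilon = p$epsilon, gamma0 = p$gamma0, V0 = p$V0,
               t0 = if (is.null(p$t0)) 0 else p$t0)
}

# Map unit-cube coordinates to natural parameters. S and gamma0/lambda are
# linear in their bounds; epsilon is searched on a log10 scale.
.z_to_params <- function(z, free, fixed, baseline, config) {
  p <- fixed
  for (j in seq_along(free)) {
    zj <- min(max(z[j], 0), 1)
    p[[free[j]]] <- switch(free[j],
      S = config$S_bounds[1] + zj * diff(config$S_bounds),
      epsilon = 10^(log10(config$epsilon_min_positive) +
                    zj * (log10(config$epsilon_bounds[2]) -
                          log10(config$epsilon_min_positive))),
      V0 = baseline * (config$V0_rel_bounds[1] + zj * diff(config$V0_rel_bounds)),
      lambda = config$lambda_bounds[1] + zj * diff(config$lambda_bounds),
      gamma0 = config$gamma0_bounds[1] + zj * diff(config$gamma0_bounds),
      stop("unknown free parameter ", free[j]))
  }
  if (is.null(p$gamma0)) p$gamma0 <- p$lambda  # tied unless freed/fixed
  p
}

.params_to_z <- function(p, free, baseline, config) {
  vapply(free, function(nm) {
    z <- switch(nm,
      S = (p[[nm]] - config$S_bounds[1]) / diff(config$S_bounds),
      epsilon = (log10(max(p[[nm]], config$epsilon_min_positive)) -
                 log10(config$epsilon_min_positive)) /
                (log10(config$epsilon_bounds[2]) -
                 log10(config$epsilon_min_positive)),
      V0 = (p[[nm]] / baseline - config$V0_rel_bounds[1]) /
           diff(config$V0_rel_bounds),
      lambda = (p[[nm]] - config$lambda_bounds[1]) / diff(config$lambda_bounds),
      gamma0 = (p[[nm]] - config$gamma0_bounds[1]) / diff(config$gamma0_bounds))
    min(max(z, 0), 1)
  }, numeric(1))
}

# Latin hypercube over [0,1]^d: one stratified draw per start and dimension.
.latin_hypercube <- function(n, d) {
  vapply(seq_len(d), function(j) (sample.int(n) - stats::runif(n)) / n,
         numeric(n))
}

# Constrained multistart local minimization of the relative squared
# objective. `free` names the fitted parameters among
# {S, epsilon, V0, lambda, gamma0}; everything else comes from `fixed`
# (gamma0 absent from both => tied to lambda). `init` optionally supplies a
# first start in natural units; it is never displaced by a start whose
# objective is not strictly better (beyond round-off), which makes refits
# of unperturbed data reproduce the incumbent exactly.
.fit_core <- function(days, volumes, fraction_times, free, fixed, baseline,
                      config, n_starts = config$n_starts, init = NULL,
                      seed = config$seed) {
  d <- length(free)
  denom <- pmax(volumes, config$objective_floor)
  obj <- function(z) {
    p <- .z_to_params(z, free, fixed, baseline, config)
    pred <- .predict_fast(p$lambda, p$S, p$epsilon, p$gamma0, p$V0,
                          if (is.null(p$t0)) 0 else p$t0,
                          fraction_times, days)
    if (!all(is.finite(pred))) return(1e12)
    sum(((pred - volumes) / denom)^2)
  }
  starts <- with_seed(seed, {
    s <- .latin_hypercube(n_starts, d)
    if (!is.null(init)) {
      s[1, ] <- .params_to_z(init, free, baseline, config)
    }
    s
  })
  ctrl <- config$optim_control
  ctrl$ndeps <- rep(if (is.null(ctrl$fd_step)) 1e-6 else ctrl$fd_step, d)
  ctrl$fd_step <- NULL
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[k, ], obj, method = "L-BFGS-B",
                   lower = rep(0, d), upper = rep(1, d),
                   control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    tol <- if (is.null(best)) 0 else max(1e-12, 1e-9 * abs(best$value))
    better <- is.null(best) || fit$value < best$value - tol
    # a converged run that ties the incumbent supersedes a non-converged one
    tie_conv <- !is.null(best) && best$convergence != 0 &&
      fit$convergence == 0 && fit$value <= best$value + tol
    if (better || tie_conv) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  p <- .z_to_params(best$par, free, fixed, baseline, config)
  res <- list(params = .build_params(p), objective = best$value,
              converged = best$convergence == 0)
  if (!is.null(init)) {
    # the incumbent wins ties exactly (no unit-cube round-trip), so a
    # refit of unperturbed data reproduces the point estimates bit for bit
    pi <- fixed
    for (nm in names(init)) pi[[nm]] <- init[[nm]]
    if (is.null(pi$gamma0)) pi$gamma0 <- pi$lambda
    pred <- .predict_fast(pi$lambda, pi$S, pi$epsilon, pi$gamma0, pi$V0,
                          if (is.null(pi$t0)) 0 else pi$t0,
                          fraction_times, days)
    f_init <- sum(((pred - volumes) / denom)^2)
    if (f_init <= best$value + max(1e-12, 1e-9 * abs(best$value))) {
      res <- list(params = .build_params(pi), objective = f_init,
                  converged = TRUE)
    }
  }
  res
}

# Normalize a measurement table to columns day / volume.
.as_measurements <- function(measurements) {
  m <- as.data.frame(measurements)
  if ("volume_cm3" %in% names(m)) m$volume <- m$volume_cm3
  if (!all(c("day", "volume") %in% names(m)))
    stop("measurements need columns day and volume (or volume_cm3)")
  if (any(!is.finite(m$day)) || any(!is.finite(m$volume)) || any(m$volume < 0))
    stop("measurement days must be finite and volumes finite and >= 0")
  m[order(m$day), c("day", "volume")]
}

#' Fit the patient-specific parameters (S, epsilon, V0)
#'
#' Constrained multistart minimization of the relative squared-difference
#' objective over the published fit bounds, with the growth rate fixed by
#' the caller (population grid search) and `gamma0 = lambda`. The initial
#' volume is bounded to +/-30% of the measured baseline (last measurement
#' at day <= 0).
#'
#' @param measurements Data frame with columns `day` (relative to treatment
#'   start) and `volume` or `volume_cm3`; at least one row with `day <= 0`
#'   (baseline) and at least 4 rows in total.
#' @param lambda_growth Fixed growth rate (day^-1).
#' @param fraction_times Radiation fraction days of the delivered schedule
#'   (default the 5-fraction daily course at days 0-4).
#' @param config A [fit_config()].
#' @param seed RNG seed for the multistart draw.
#' @return An object of class `irt_fit`: list with `params`
#'   ([model_params()]), `rmse` (cm^3), `objective`, `converged`,
#'   `n_points`, `baseline_volume`.
#' @export
fit_patient <- function(measurements, lambda_growth = 0.065,
                        fraction_times = 0:4, config = fit_config(),
                        seed = config$seed) {
  m <- .as_measurements(measurements)
  if (nrow(m) < 4)
    stop("at least 4 measurements are required to fit 3 parameters")
  if (all(m$volume == 0)) stop("all measured volumes are zero")
  base_idx <- which(m$day <= 0)
  if (length(base_idx) < 1)
    stop("a pre-treatment (day <= 0) baseline measurement is required")
  baseline <- m$volume[max(base_idx)]
  if (baseline <= 0) stop("baseline volume must be > 0")
  fit <- .fit_core(m$day, m$volume, fraction_times,
                   free = c("S", "epsilon", "V0"),
                   fixed = list(lambda = lambda_growth, t0 = 0),
                   baseline = baseline, config = config, seed = seed)
  pred <- predict_volumes(fit$params, fraction_times, m$day)
  structure(list(params = fit$params, rmse = rmse(m$volume, pred),
                 objective = fit$objective, converged = fit$converged,
                 n_points = nrow(m), baseline_volume = baseline,
                 measurements = m, fraction_times = fraction_times),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf(
    "Model fit: S = %.3f, epsilon = %.3g /day, V0 = %.2f cm^3 (lambda = %.3g)\n",
    x$params$surviving_fraction, x$params$epsilon, x$params$V0,
    x$params$lambda))
  cat(sprintf("  RMSE %.3g cm^3 over %d points; converged: %s\n",
              x$rmse, x$n_points, x$converged))
  invisible(x)
}

#' Population growth-rate grid search
#'
#' For each candidate growth rate, every patient is fitted with that shared
#' `lambda` and the per-patient RMSEs are summarized; the grid score is the
#' sum of the configured summary statistics (default
#' `mean + median + min + max`) and the returned rate minimizes it.
#'
#' @param cohort List of patients, each a list with elements `measurements`
#'   and (optionally) `fraction_times` (default days 0-4).
#' @param lambda_grid Candidate rates (day^-1) within the growth-rate
#'   bounds.
#' @param config A [fit_config()].
#' @param seed RNG seed (per-fit multistart).
#' @return List with `lambda` (the argmin), `table` (one row per grid
#'   point: lambda, the four RMSE summaries, score) and `rmse_matrix`
#'   (patients x grid).
#' @export
grid_search_lambda <- function(cohort, lambda_grid = config$lambda_grid,
                               config = fit_config(), seed = config$seed) {
  if (length(cohort) == 0) stop("cohort must be non-empty")
  if (any(lambda_grid < config$lambda_bounds[1] - 1e-12) ||
      any(lambda_grid > config$lambda_bounds[2] + 1e-12))
    stop("lambda_grid must lie within the growth-rate bounds")
  rm <- vapply(lambda_grid, function(lam) {
    vapply(cohort, function(pat) {
      ft <- if (is.null(pat$fraction_times)) 0:4 else pat$fraction_times
      fit_patient(pat$measurements, lambda_growth = lam,
                  fraction_times = ft, config = config, seed = seed)$rmse
    }, numeric(1))
  }, numeric(length(cohort)))
  rm <- matrix(rm, nrow = length(cohort))
  summ <- data.frame(
    lambda = lambda_grid,
    mean = apply(rm, 2, mean),
    median = apply(rm, 2, stats::median),
    min = apply(rm, 2, min),
    max = apply(rm, 2, max))
  summ$score <- rowSums(summ[, config$score_terms, drop = FALSE])
  list(lambda = lambda_grid[which.min(summ$score)], table = summ,
       rmse_matrix = rm)
}

#' Compare parameter-sharing configurations by AIC
#'
#' Each configuration declares whether the growth rate `lambda` is global
#' (shared, fitted by grid search over `config$lambda_grid`) or
#' patient-specific, and whether `gamma0` is tied to `lambda` or fitted per
#' patient; `S`, `epsilon` and `V0` are always patient-specific. The
#' least-squares AIC `n * log(RSS/n) + 2k` is computed with the absolute
#' residual sum of squares pooled over all patients, `n` the total number
#' of data points and `k` the total number of free parameters.
#'
#' @param cohort As in [grid_search_lambda()].
#' @param sharing_configs List of configurations, each a list with `name`,
#'   `lambda` (`"global"` or `"patient"`) and `gamma0` (`"tied"` or
#'   `"patient"`).
#' @param config A [fit_config()].
#' @param seed RNG seed.
#' @return Data frame (name, k, n, rss, aic) sorted by ascending AIC.
#' @export
aic_compare <- function(cohort, sharing_configs, config = fit_config(),
                        seed = config$seed) {
  if (length(cohort) == 0) stop("cohort must be non-empty")
  if (length(sharing_configs) == 0) stop("no sharing configurations given")
  one_cfg <- function(sc) {
    lam_mode <- match.arg(sc$lambda, c("global", "patient"))
    g0_mode <- match.arg(sc$gamma0, c("tied", "patient"))
    free <- c("S", "epsilon", "V0",
              if (lam_mode == "patient") "lambda",
              if (g0_mode == "patient") "gamma0")
    fit_all <- function(lam) {
      rss <- 0; npts <- 0
      for (pat in cohort) {
        m <- .as_measurements(pat$measurements)
        ft <- if (is.null(pat$fraction_times)) 0:4 else pat$fraction_times
        baseline <- m$volume[max(which(m$day <= 0))]
        fixed <- list(t0 = 0)
        if (lam_mode == "global") fixed$lambda <- lam
        fit <- .fit_core(m$day, m$volume, ft, free, fixed, baseline,
                         config, seed = seed)
        pred <- predict_volumes(fit$params, ft, m$day)
        rss <- rss + sum((m$volume - pred)^2)
        npts <- npts + nrow(m)
      }
      list(rss = rss, n = npts)
    }
    if (lam_mode == "global") {
      fits <- lapply(config$lambda_grid, fit_all)
      best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
      k <- 1L + length(free) * length(cohort)
    } else {
      best <- fit_all(NA)
      k <- length(free) * length(cohort)
    }
    if (k < 1) stop("sharing configuration has zero free parameters")
    data.frame(name = sc$name, k = k, n = best$n, rss = best$rss,
               aic = best$n * log(best$rss / best$n) + 2 * k)
  }
  out <- do.call(rbind, lapply(sharing_configs, one_cfg))
  out[order(out$aic), , drop = FALSE]
}

#' Perturb measured volumes with the contouring-uncertainty noise model
#'
#' Volumes at or above `small_cut` are scaled multiplicatively by
#' `N(1, rel_sd^2)`; smaller volumes are shifted additively by
#' `N(0, small_sd^2)` cm^3 (a floor uncertainty independent of the
#' recorded volume). Negative results are clamped to zero.
#'
#' @param volumes Numeric vector (cm^3).
#' @param rel_sd Relative standard deviation (default 0.2).
#' @param small_cut Threshold (cm^3) below which the absolute noise model
#'   applies (default 2).
#' @param small_sd Absolute standard deviation (cm^3, default 0.5).
#' @return Perturbed, non-negative volumes. Uses the current RNG stream.
#' @export
perturb_volumes <- function(volumes, rel_sd = 0.2, small_cut = 2,
                            small_sd = 0.5) {
  n <- length(volumes)
  big <- volumes >= small_cut
  out <- volumes
  # one draw per point regardless of branch keeps the stream aligned
  z <- stats::rnorm(n)
  out[big] <- volumes[big] * (1 + rel_sd * z[big])
  out[!big] <- volumes[!big] + small_sd * z[!big]
  pmax(out, 0)
}

#' Bootstrap uncertainty of (S, epsilon)
#'
#' Repeats the fit of `S` and `epsilon` on datasets perturbed with
#' [perturb_volumes()] (20% multiplicative noise, 0.5 cm^3 absolute below
#' 2 cm^3), holding `V0` and `lambda` at the point fit. With the noise
#' turned off every replicate reproduces the point estimates exactly, and
#' a fixed seed makes the ensemble bit-reproducible.
#'
#' @param measurements As in [fit_patient()].
#' @param point_fit An `irt_fit` from [fit_patient()].
#' @param fraction_times Fraction days of the fitted schedule.
#' @param n_reps Number of bootstrap replicates (default 50).
#' @param noise_rel_sd,small_volume_cut,small_volume_sd Noise model, see
#'   [perturb_volumes()].
#' @param config A [fit_config()].
#' @param seed RNG seed.
#' @return Object of class `irt_bootstrap`: list with `ensemble` (data
#'   frame replicate / S / epsilon) and the call settings.
#' @export
bootstrap_fit <- function(measurements, point_fit, fraction_times = 0:4,
                          n_reps = 50L, noise_rel_sd = 0.2,
                          small_volume_cut = 2, small_volume_sd = 0.5,
                          config = fit_config(), seed = config$seed) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  m <- .as_measurements(measurements)
  p0 <- point_fit$params
  ens <- with_seed(seed, {
    res <- matrix(NA_real_, n_reps, 2L)
    for (r in seq_len(n_reps)) {
      v <- perturb_volumes(m$volume, noise_rel_sd, small_volume_cut,
                           small_volume_sd)
      fit <- .fit_core(m$day, v, fraction_times,
                       free = c("S", "epsilon"),
                       fixed = list(lambda = p0$lambda, V0 = p0$V0, t0 = p0$t0),
                       baseline = point_fit$baseline_volume, config = config,
                       n_starts = config$n_starts_refit,
                       init = list(S = p0$surviving_fraction,
                                   epsilon = p0$epsilon),
                       seed = seed + r)
      res[r, ] <- c(fit$params$surviving_fraction, fit$params$epsilon)
    }
    res
  })
  structure(list(ensemble = data.frame(replicate = seq_len(n_reps),
                                       S = ens[, 1], epsilon = ens[, 2]),
                 point_fit = point_fit, fraction_times = fraction_times,
                 seed = seed),
            class = "irt_bootstrap")
}

#' Trajectory envelope over a bootstrap ensemble
#'
#' Propagates the point fit and every bootstrap replicate through the
#' model and reports the pointwise minimum/maximum total volume (the
#' uncertainty band of the published figures). The point fit is part of
#' the envelope, so the band always brackets the point trajectory.
#'
#' @param bootstrap An `irt_bootstrap`.
#' @param days Evaluation days.
#' @param fraction_times Fraction schedule (default the one stored with
#'   the bootstrap).
#' @return Data frame (day, V_point, V_min, V_max).
#' @export
bootstrap_envelope <- function(bootstrap, days,
                               fraction_times = bootstrap$fraction_times) {
  p0 <- bootstrap$point_fit$params
  traj <- function(S, eps) {
    p <- model_params(lambda = p0$lambda, surviving_fraction = S,
                      epsilon = eps, gamma0 = p0$gamma0, V0 = p0$V0,
                      t0 = p0$t0)
    predict_volumes(p, fraction_times, days)
  }
  vp <- traj(p0$surviving_fraction, p0$epsilon)
  vm <- mapply(traj, bootstrap$ensemble$S, bootstrap$ensemble$epsilon)
  vm <- cbind(vp, matrix(vm, nrow = length(days)))
  data.frame(day = days, V_point = vp,
             V_min = apply(vm, 1, min), V_max = apply(vm, 1, max))
}

#' Local sensitivity ranking of the patient-specific parameters
#'
#' Each of `S`, `epsilon`, `V0` is perturbed by +/- `perturbation`
#' (clipped to its bounds and flagged when clipping occurs); the score is
#' the larger of the two RMSEs between the perturbed and nominal
#' trajectories at the measurement days, normalized by the nominal mean
#' volume. Parameters are returned in descending sensitivity order.
#'
#' @param params Nominal [model_params()].
#' @param days Measurement days used for trajectory comparison.
#' @param fraction_times Fraction schedule.
#' @param perturbation Relative perturbation (default 0.2).
#' @return Data frame (parameter, score, clipped), most sensitive first.
#' @export
sensitivity_rank <- function(params, days, fraction_times = 0:4,
                             perturbation = 0.2) {
  if (perturbation < 0) stop("perturbation must be >= 0")
  nominal <- predict_volumes(params, fraction_times, days)
  norm <- mean(nominal)
  bounds <- list(S = c(0, 1), epsilon = c(0, 0.1), V0 = c(1e-9, Inf))
  slot <- c(S = "surviving_fraction", epsilon = "epsilon", V0 = "V0")
  one <- function(nm) {
    val <- params[[slot[nm]]]
    clipped <- FALSE
    scores <- vapply(c(1 - perturbation, 1 + perturbation), function(f) {
      v <- val * f
      b <- bounds[[nm]]
      if (v < b[1] || v > b[2]) {
        v <- min(max(v, b[1]), b[2])
        clipped <<- TRUE
      }
      p <- params
      p[[slot[nm]]] <- v
      p <- do.call(model_params, p[c("lambda", "surviving_fraction",
                                     "epsilon", "gamma0", "V0", "t0")])
      rmse(predict_volumes(p, fraction_times, days), nominal) / norm
    }, numeric(1))
    data.frame(parameter = nm, score = max(scores), clipped = clipped)
  }
  out <- do.call(rbind, lapply(c("S", "epsilon", "V0"), one))
  out[order(-out$score), , drop = FALSE]
}
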