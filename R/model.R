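#' Model parameters for the tumor growth-response model
#'
#' Container for the five parameters of the two-compartment model of
#' recurrent high-grade glioma volume dynamics under combined radiotherapy
#' and systemic (bevacizumab + pembrolizumab) treatment:
#' viable volume grows exponentially at rate `lambda` and is killed at a
#' drug-attributable rate `gamma(t) = gamma0 * exp(-epsilon * (t - t0))`
#' that decays as treatment resistance evolves; each radiation fraction
#' instantaneously moves a proportion `1 - surviving_fraction` of the viable
#' volume into a dying compartment that resolves exponentially at rate
#' `lambda`.
#'
#' @param lambda Exponential growth rate of viable tumor (day^-1). Must lie
#'   in the biologically motivated band `[0.017, 0.14]` (doubling times of
#'   roughly 5-40 days).
#' @param surviving_fraction Proportion `S` of viable volume surviving one
#'   radiation fraction, in `[0, 1]`. Treated as a free parameter, not a
#'   function of dose.
#' @param epsilon Resistance-evolution rate (day^-1) at which the drug kill
#'   rate decays, in `[0, 0.1]`.
#' @param gamma0 Initial drug-attributable volume kill rate (day^-1),
#'   `>= 0`. Defaults to `lambda`, the constraint used for all headline
#'   analyses.
#' @param V0 Pre-treatment tumor volume (cm^3), `> 0`.
#' @param t0 Treatment start time (day); day of the first radiation
#'   fraction and of systemic therapy start. Defaults to 0.
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(surviving_fraction = 0.41, epsilon = 9e-5, V0 = 10)
#' p
#' @export
model_params <- function(lambda = 0.065, surviving_fraction, epsilon,
                         gamma0 = lambda, V0, t0 = 0) {
  vals <- c(lambda = lambda, S = surviving_fraction, epsilon = epsilon,
            gamma0 = gamma0, V0 = V0, t0 = t0)
  if (!all(is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (lambda < 0.017 || lambda > 0.14)
    stop("lambda must lie in [0.017, 0.14] day^-1")
  if (surviving_fraction < 0 || surviving_fraction > 1)
    stop("surviving_fraction must lie in [0, 1]")
  if (epsilon < 0 || epsilon > 0.1)
    stop("epsilon must lie in [0, 0.1] day^-1")
  if (gamma0 < 0) stop("gamma0 must be >= 0")
  if (V0 <= 0) stop("V0 must be > 0")
  structure(list(lambda = lambda, surviving_fraction = surviving_fraction,
                 epsilon = epsilon, gamma0 = gamma0, V0 = V0, t0 = t0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Tumor growth-response model parameters\n")
  cat(sprintf("  lambda  = %.4g /day (doubling time %.1f d)\n",
              x$lambda, log(2) / x$lambda))
  cat(sprintf("  S       = %.4g\n", x$surviving_fraction))
  cat(sprintf("  epsilon = %.4g /day\n", x$epsilon))
  cat(sprintf("  gamma0  = %.4g /day\n", x$gamma0))
  cat(sprintf("  V0      = %.4g cm^3 at t0 = %g d\n", x$V0, x$t0))
  invisible(x)
}

#' Tumor state at a time point
#'
#' @param t Time (day).
#' @param V_live Viable tumor volume (cm^3), `>= 0`.
#' @param V_dead Dying tumor volume (cm^3), `>= 0`.
#' @return Object of class `tumor_state`. The observed (total) volume is
#'   `V_live + V_dead`.
#' @export
tumor_state <- function(t, V_live, V_dead = 0) {
  if (!all(is.finite(c(t, V_live, V_dead))))
    stop("tumor state components must be finite")
  if (V_live < 0 || V_dead < 0) stop("compartment volumes must be >= 0")
  structure(list(t = t, V_live = V_live, V_dead = V_dead),
            class = "tumor_state")
}

# threshold below which the epsilon -> 0 analytic limit branch is used
.EPS_LIMIT <- 1e-12

#' Closed-form viable volume between radiation fractions
#'
#' Propagates the viable compartment from a reference state forward in time
#' under exponential growth minus the decaying drug kill rate:
#' `V_l(t) = V_ref * exp(lambda*(t - t_ref) + (gamma_ref/epsilon) *
#' (exp(-epsilon*(t - t_ref)) - 1))`, with the analytic limit
#' `V_ref * exp((lambda - gamma_ref)*(t - t_ref))` for `epsilon -> 0`.
#' `gamma_ref` is the kill rate at `t_ref`, i.e.
#' `gamma0 * exp(-epsilon*(t_ref - t0))` on the global resistance clock.
#'
#' @param V_live_ref Viable volume at the reference time (cm^3).
#' @param gamma_ref Drug kill rate at the reference time (day^-1).
#' @param params A [model_params()] object (supplies `lambda`, `epsilon`).
#' @param t_ref Reference time (day).
#' @param t Target time(s) (day), `>= t_ref`. Vectorized.
#' @return Viable volume(s) at `t` (cm^3).
#' @export
live_volume_analytic <- function(V_live_ref, gamma_ref, params, t_ref, t) {
  if (!all(is.finite(c(V_live_ref, gamma_ref, t_ref, t))))
    stop("non-finite input to live_volume_analytic")
  if (any(t < t_ref)) stop("t must be >= t_ref")
  dt <- t - t_ref
  eps <- params$epsilon
  if (eps < .EPS_LIMIT) {
    V_live_ref * exp((params$lambda - gamma_ref) * dt)
  } else {
    V_live_ref * exp(params$lambda * dt + (gamma_ref / eps) * expm1(-eps * dt))
  }
}

#' Exponential resolution of the dying compartment
#'
#' The dying compartment shrinks at the growth rate `lambda` (cell death on
#' attempted division, mitotic catastrophe), keeping the parameter count
#' minimal: `V_d(t_ref + dt) = V_dead_ref * exp(-lambda * dt)`.
#'
#' @param V_dead_ref Dying volume at the reference time (cm^3).
#' @param lambda Growth/resolution rate (day^-1).
#' @param dt Elapsed time (day), `>= 0`. Vectorized.
#' @return Dying volume(s) after `dt` (cm^3).
#' @export
dead_volume_decay <- function(V_dead_ref, lambda, dt) {
  if (any(dt < 0)) stop("dt must be >= 0")
  V_dead_ref * exp(-lambda * dt)
}

#' Instantaneous effect of one radiation fraction
#'
#' At a fraction delivery a proportion `1 - S` of the viable volume is
#' transferred to the dying compartment; total volume is conserved at the
#' fraction instant and time is unchanged.
#'
#' @param state A [tumor_state()].
#' @param surviving_fraction `S` in `[0, 1]`.
#' @return The post-fraction `tumor_state`.
#' @examples
#' apply_fraction(tumor_state(0, 10, 2), 0.41)  # -> V_live 4.1, V_dead 7.9
#' @export
apply_fraction <- function(state, surviving_fraction) {
  if (surviving_fraction < 0 || surviving_fraction > 1)
    stop("surviving_fraction must lie in [0, 1]")
  tumor_state(state$t,
              surviving_fraction * state$V_live,
              state$V_dead + (1 - surviving_fraction) * state$V_live)
}

# Sequentially propagate the initial state (V0, 0) at t0 through all
# fraction deliveries. Returns post-event states (first row = initial
# state) together with the matching pre-fraction compartments; the drug
# kill rate evolves on the global clock and is never reset by fractions.
.fraction_events <- function(params, fraction_times) {
  n <- length(fraction_times)
  if (n > 0) {
    if (is.unsorted(fraction_times)) stop("fraction_times must be sorted")
    if (any(fraction_times < params$t0)) stop("fraction_times must be >= t0")
  }
  time <- c(params$t0, fraction_times)
  V_live <- V_dead <- pre_live <- pre_dead <- numeric(n + 1L)
  gamma <- params$gamma0 * exp(-params$epsilon * (time - params$t0))
  V_live[1L] <- pre_live[1L] <- params$V0
  V_dead[1L] <- pre_dead[1L] <- 0
  S <- params$surviving_fraction
  if (n > 0) for (i in seq_len(n)) {
    vl <- live_volume_analytic(V_live[i], gamma[i], params, time[i], time[i + 1L])
    vd <- dead_volume_decay(V_dead[i], params$lambda, time[i + 1L] - time[i])
    pre_live[i + 1L] <- vl
    pre_dead[i + 1L] <- vd
    V_live[i + 1L] <- S * vl
    V_dead[i + 1L] <- vd + (1 - S) * vl
  }
  data.frame(time = time, V_live = V_live, V_dead = V_dead, gamma = gamma,
             pre_live = pre_live, pre_dead = pre_dead)
}

# Vectorized evaluation of both compartments at times t >= t0 from a
# .fraction_events table (post-fraction convention at event instants; the
# total volume is continuous so V_total is unambiguous).
.eval_compartments <- function(events, params, t) {
  i <- findInterval(t, events$time)
  if (any(i < 1L)) stop("evaluation times must be >= t0")
  dt <- t - events$time[i]
  g <- events$gamma[i]
  eps <- params$epsilon
  if (eps < .EPS_LIMIT) {
    vl <- events$V_live[i] * exp((params$lambda - g) * dt)
  } else {
    vl <- events$V_live[i] * exp(params$lambda * dt + (g / eps) * expm1(-eps * dt))
  }
  vd <- events$V_dead[i] * exp(-params$lambda * dt)
  list(V_live = vl, V_dead = vd)
}

#' Simulate a full treated tumor volume trajectory
#'
#' Piecewise-analytic propagation of the two-compartment model: between
#' fractions the viable compartment follows [live_volume_analytic()] and the
#' dying compartment [dead_volume_decay()]; at every fraction time
#' [apply_fraction()] is applied with the same `S` (boost fractions
#' included). The drug kill rate decays on the global clock from `t0` and is
#' unaffected by fractions.
#'
#' @param params A [model_params()] object.
#' @param fraction_times Sorted fraction delivery days, all `>= t0`.
#' @param eval_times Strictly increasing evaluation days, all `>= t0`.
#' @return A `tumor_trajectory` data frame with columns `day`,
#'   `V_live_cm3`, `V_dead_cm3`, `V_total_cm3`, `is_fraction_pre`,
#'   `is_fraction_post`. Each fraction contributes a paired pre/post row
#'   exposing the transfer discontinuity; evaluation days coinciding with a
#'   fraction are represented by that pair. The event table and parameters
#'   are kept as attributes for exact downstream evaluation (see
#'   [trajectory_volume()]).
#' @export
simulate_trajectory <- function(params, fraction_times = numeric(),
                                eval_times) {
  if (length(eval_times) == 0) stop("eval_times must be non-empty")
  if (is.unsorted(eval_times, strictly = TRUE))
    stop("eval_times must be strictly increasing")
  if (any(eval_times < params$t0)) stop("eval_times must be >= t0")
  events <- .fraction_events(params, fraction_times)

  keep <- !(eval_times %in% fraction_times)
  te <- eval_times[keep]
  ev_rows <- if (length(te) > 0) {
    cmp <- .eval_compartments(events, params, te)
    data.frame(day = te, V_live_cm3 = cmp$V_live, V_dead_cm3 = cmp$V_dead,
               is_fraction_pre = FALSE, is_fraction_post = FALSE)
  } else NULL
  fr_rows <- if (length(fraction_times) > 0) {
    idx <- seq_len(length(fraction_times)) + 1L
    data.frame(
      day = rep(events$time[idx], each = 2L),
      V_live_cm3 = as.vector(rbind(events$pre_live[idx], events$V_live[idx])),
      V_dead_cm3 = as.vector(rbind(events$pre_dead[idx], events$V_dead[idx])),
      is_fraction_pre = rep(c(TRUE, FALSE), length(idx)),
      is_fraction_post = rep(c(FALSE, TRUE), length(idx)))
  } else NULL
  out <- rbind(ev_rows, fr_rows)
  # stable sort: pre row precedes post row at equal day
  out <- out[order(out$day, out$is_fraction_post), , drop = FALSE]
  rownames(out) <- NULL
  out$V_total_cm3 <- out$V_live_cm3 + out$V_dead_cm3
  out <- out[, c("day", "V_live_cm3", "V_dead_cm3", "V_total_cm3",
                 "is_fraction_pre", "is_fraction_post")]
  structure(out, params = params, events = events,
            fraction_times = fraction_times,
            class = c("tumor_trajectory", "data.frame"))
}

#' Evaluate a simulated trajectory at arbitrary times
#'
#' Exact closed-form evaluation of the total observed volume at any time
#' `>= t0`, using the event table stored in a [simulate_trajectory()]
#' result; no interpolation is involved.
#'
#' @param trajectory A `tumor_trajectory` object.
#' @param t Times (day), vectorized.
#' @return Total volumes `V_live + V_dead` (cm^3).
#' @export
trajectory_volume <- function(trajectory, t) {
  events <- attr(trajectory, "events")
  params <- attr(trajectory, "params")
  if (is.null(events) || is.null(params))
    stop("not a tumor_trajectory with stored events")
  cmp <- .eval_compartments(events, params, t)
  cmp$V_live + cmp$V_dead
}

#' Write a trajectory as delimited text
#'
#' @param trajectory A `tumor_trajectory`.
#' @param path Output file path.
#' @param meta Optional named character vector written as `# key=value`
#'   header comment lines.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, meta = NULL) {
  write_table_with_header(as.data.frame(trajectory), path, meta)
}
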