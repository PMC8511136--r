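#' Radiotherapy schedule
#'
#' @param fraction_times Non-decreasing planned fraction days.
#' @param assessment_interval Days between volumetric assessments
#'   (default 42, the 6-week imaging cadence); assessments start at the
#'   baseline day `t0`.
#' @param boost Logical; deliver a three-fraction boost at detected
#'   progression.
#' @param boost_fractions Number of boost fractions (default 3, on
#'   consecutive days).
#' @param boost_spacing Days between boost fractions (default 1).
#' @param max_boosts Maximum number of boost events (default 1; the
#'   repeat-boost variant is available by raising this).
#' @param progression_factor Progression threshold as a multiple of the
#'   running assessment nadir (default 1.2, i.e. 20% above the minimum).
#' @param horizon Simulation horizon (day), must exceed the last planned
#'   fraction; default 1500 days.
#' @param label Arm label used in outputs.
#' @return Object of class `rt_schedule`.
#' @export
new_schedule <- function(fraction_times, assessment_interval = 42,
                         boost = FALSE, boost_fractions = 3L,
                         boost_spacing = 1, max_boosts = 1L,
                         progression_factor = 1.2, horizon = 1500,
                         label = "custom") {
  if (length(fraction_times) < 1) stop("at least one fraction is required")
  if (is.unsorted(fraction_times)) stop("fraction_times must be non-decreasing")
  if (assessment_interval <= 0) stop("assessment_interval must be > 0")
  if (horizon <= max(fraction_times))
    stop("horizon must exceed the last planned fraction")
  structure(list(fraction_times = fraction_times,
                 assessment_interval = assessment_interval,
                 boost = isTRUE(boost),
                 boost_fractions = as.integer(boost_fractions),
                 boost_spacing = boost_spacing,
                 max_boosts = as.integer(max_boosts),
                 progression_factor = progression_factor,
                 horizon = horizon, label = label),
            class = "rt_schedule")
}

#' @export
print.rt_schedule <- function(x, ...) {
  cat(sprintf("<rt_schedule '%s'> %d fractions at days %s%s; horizon %g d\n",
              x$label, length(x$fraction_times),
              paste(utils::head(x$fraction_times, 8), collapse = ","),
              if (x$boost) " + boost-at-progression" else "", x$horizon))
  invisible(x)
}

#' Hypofractionated stereotactic radiotherapy schedule
#'
#' The trial protocol: `n_fractions` fractions on consecutive days starting
#' at `t0` (default five daily fractions, days 0-4).
#'
#' @param t0 First fraction day (default 0).
#' @param n_fractions Number of daily fractions, `>= 1` (default 5).
#' @param ... Passed to [new_schedule()].
#' @return An `rt_schedule`.
#' @export
make_hfsrt <- function(t0 = 0, n_fractions = 5L, ...) {
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  new_schedule(t0 + seq_len(n_fractions) - 1, label = "HFSRT", ...)
}

#' Intermittent radiotherapy schedule
#'
#' Single fractions delivered every `interval` days:
#' `t0 + k * interval`, `k = 0 .. n_fractions - 1`. The default 42-day
#' interval matches the 6-week imaging cadence; 28, 56 and 70 days (4, 8,
#' 10 weeks) are the other intervals studied.
#'
#' @param t0 First fraction day (default 0).
#' @param interval Inter-fraction interval (days), `> 0` (default 42).
#' @param n_fractions Number of intermittent fractions (default 5).
#' @param boost Deliver the three-fraction boost at progression.
#' @param ... Passed to [new_schedule()].
#' @return An `rt_schedule`.
#' @export
make_irt <- function(t0 = 0, interval = 42, n_fractions = 5L,
                     boost = FALSE, ...) {
  if (interval <= 0) stop("interval must be > 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  new_schedule(t0 + interval * (seq_len(n_fractions) - 1),
               boost = boost,
               label = if (isTRUE(boost)) "iRT+boost" else "iRT", ...)
}

#' Detect progression on a series of assessment volumes
#'
#' Progression is the first assessment at which the volume exceeds the
#' running minimum of all *previous* assessed volumes (baseline included,
#' current excluded) by more than `factor - 1` (default 20%).
#'
#' @param assessments Data frame with columns `day` and `volume` (or
#'   `volume_cm3`), ordered by day; the first row is the baseline.
#' @param factor Threshold multiple of the running nadir (default 1.2).
#' @return The progression day, or `NA` if progression never occurs.
#' @examples
#' detect_progression(data.frame(day = c(0, 42, 84, 126),
#'                               volume = c(10, 9, 8, 9.7)))  # 126
#' @export
detect_progression <- function(assessments, factor = 1.2) {
  a <- .as_measurements(assessments)
  if (nrow(a) == 0) stop("assessments must be non-empty")
  if (nrow(a) >= 2) for (k in 2:nrow(a)) {
    if (a$volume[k] > factor * min(a$volume[1:(k - 1)])) return(a$day[k])
  }
  NA_real_
}

#' Simulate one treatment arm for a patient
#'
#' Runs the model under a schedule's planned fractions with volumetric
#' assessments every `assessment_interval` days starting at `t0`
#' (assessment precedes any same-day fraction, mirroring image-then-treat).
#' If the schedule enables the boost and progression is detected
#' (volume > `progression_factor` x running assessment nadir), three
#' additional daily fractions are inserted starting at the progression
#' assessment day -- after any fraction already scheduled that day -- and
#' the remaining planned fractions are still delivered on schedule.
#'
#' @param params A [model_params()].
#' @param schedule An `rt_schedule`.
#' @param eval_times Optional extra days at which the returned trajectory
#'   is tabulated (defaults to the assessment days).
#' @return Object of class `arm_outcome`: list with `trajectory`
#'   (a [simulate_trajectory()] result over all delivered fractions),
#'   `assessments` (day/volume data frame), `progression_day`,
#'   `boost_start_day`, `fractions_delivered`, `fraction_times`,
#'   `schedule`, `params`.
#' @export
simulate_arm <- function(params, schedule, eval_times = NULL) {
  t0 <- params$t0
  if (any(schedule$fraction_times < t0))
    stop("schedule fractions must not precede t0")
  assess_days <- seq(t0, schedule$horizon, by = schedule$assessment_interval)
  if (schedule$boost && length(assess_days) < 2)
    stop("boost requires at least one post-baseline assessment")
  frac_queue <- schedule$fraction_times[schedule$fraction_times <= schedule$horizon]

  # incremental state propagation (exact closed forms between events)
  lam <- params$lambda; eps <- params$epsilon
  st <- list(t = t0, V_live = params$V0, V_dead = 0)
  gamma_at <- function(t) params$gamma0 * exp(-eps * (t - t0))
  advance <- function(st, t) {
    vl <- live_volume_analytic(st$V_live, gamma_at(st$t), params, st$t, t)
    list(t = t, V_live = vl,
         V_dead = dead_volume_decay(st$V_dead, lam, t - st$t))
  }

  assess_vol <- numeric(0)
  delivered <- numeric(0)
  progression_day <- NA_real_
  boost_start <- NA_real_
  boosts_done <- 0L
  ai <- 1L; fi <- 1L
  repeat {
    next_f <- if (fi <= length(frac_queue)) frac_queue[fi] else Inf
    next_a <- if (ai <= length(assess_days)) assess_days[ai] else Inf
    if (!is.finite(next_f) && !is.finite(next_a)) break
    if (next_a <= next_f) {          # assessment first on shared days
      s <- advance(st, next_a)
      v <- s$V_live + s$V_dead
      progressed <- length(assess_vol) >= 1 &&
        v > schedule$progression_factor * min(assess_vol)
      assess_vol <- c(assess_vol, v)
      if (progressed && is.na(progression_day)) progression_day <- next_a
      if (progressed && schedule$boost && boosts_done < schedule$max_boosts) {
        bdays <- next_a + schedule$boost_spacing *
          (seq_len(schedule$boost_fractions) - 1)
        bdays <- bdays[bdays <= schedule$horizon]
        # scheduled fraction on this day is delivered before the boost
        rest <- if (fi <= length(frac_queue)) frac_queue[fi:length(frac_queue)] else numeric(0)
        frac_queue <- c(frac_queue[seq_len(fi - 1L)], sort(c(rest, bdays)))
        if (length(rest) > 0 && rest[1] == next_a)  # keep scheduled-first order
          frac_queue[fi:(fi + 1L)] <- c(next_a, bdays[1])
        if (is.na(boost_start)) boost_start <- next_a
        boosts_done <- boosts_done + 1L
      }
      ai <- ai + 1L
    } else {                          # fraction delivery
      s <- advance(st, next_f)
      st <- list(t = next_f,
                 V_live = params$surviving_fraction * s$V_live,
                 V_dead = s$V_dead + (1 - params$surviving_fraction) * s$V_live)
      delivered <- c(delivered, next_f)
      fi <- fi + 1L
    }
  }

  te <- sort(unique(c(assess_days, eval_times)))
  traj <- simulate_trajectory(params, delivered, te)
  structure(list(trajectory = traj,
                 assessments = data.frame(day = assess_days,
                                          volume_cm3 = assess_vol),
                 progression_day = progression_day,
                 boost_start_day = boost_start,
                 fractions_delivered = length(delivered),
                 fraction_times = delivered,
                 schedule = schedule, params = params),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome '%s'> %d fractions delivered; progression %s%s\n",
              x$schedule$label, x$fractions_delivered,
              if (is.na(x$progression_day)) "not reached"
              else sprintf("at day %g", x$progression_day),
              if (is.na(x$boost_start_day)) ""
              else sprintf("; boost from day %g", x$boost_start_day)))
  invisible(x)
}

#' Simulate several protocols under identical parameters
#'
#' @param params A [model_params()].
#' @param protocols A (optionally named) list of `rt_schedule`s sharing
#'   the same start day.
#' @param eval_times Optional extra tabulation days, passed through.
#' @return Named list of [simulate_arm()] outcomes (names taken from the
#'   list names or the schedule labels).
#' @export
compare_protocols <- function(params, protocols, eval_times = NULL) {
  if (length(protocols) == 0) stop("protocol set must be non-empty")
  out <- lapply(protocols, simulate_arm, params = params,
                eval_times = eval_times)
  nm <- names(protocols)
  if (is.null(nm) || any(nm == ""))
    nm <- vapply(protocols, `[[`, character(1), "label")
  names(out) <- make.unique(nm)
  out
}
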