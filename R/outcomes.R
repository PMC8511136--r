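#' Time to reach the cutoff volume
#'
#' Scores the simulated time-to-progression `tau`: the first time the
#' total volume reaches `cutoff_volume` (the patient's last recorded
#' volume, taken as the maximum tolerated burden). When no cutoff is
#' available, `fallback_fraction * V(t0)` (default a 20% increase over
#' baseline) is used. The crossing is located on the piecewise-analytic
#' segments by a fine scan plus root bracketing to within 0.01 day;
#' records are censored at the horizon if the threshold is never reached.
#'
#' @param trajectory A `tumor_trajectory` (from [simulate_trajectory()])
#'   or an `arm_outcome` (from [simulate_arm()]).
#' @param cutoff_volume Threshold volume (cm^3), `> 0`; `NULL` to use the
#'   fallback.
#' @param fallback_fraction Multiple of the baseline volume used when
#'   `cutoff_volume` is `NULL` (default 1.2).
#' @param horizon Censoring horizon (day, default 1500).
#' @param patient_id,arm Labels carried into the record.
#' @return A one-row data frame (patient_id, arm, time, event); `event`
#'   is `TRUE` when the cutoff was reached, `FALSE` for censoring at the
#'   horizon.
#' @export
time_to_cutoff <- function(trajectory, cutoff_volume = NULL,
                           fallback_fraction = 1.2, horizon = 1500,
                           patient_id = NA_character_, arm = NA_character_) {
  if (inherits(trajectory, "arm_outcome")) trajectory <- trajectory$trajectory
  events <- attr(trajectory, "events")
  params <- attr(trajectory, "params")
  if (is.null(events)) stop("trajectory lacks the analytic event table")
  v0 <- params$V0
  if (is.null(cutoff_volume)) cutoff_volume <- fallback_fraction * v0
  if (!is.finite(cutoff_volume) || cutoff_volume <= 0)
    stop("cutoff_volume must be > 0 (or NULL to use the fallback)")
  rec <- function(time, event) data.frame(patient_id = patient_id, arm = arm,
                                          time = time, event = event)
  if (v0 >= cutoff_volume) return(rec(0, TRUE))
  bounds <- unique(c(events$time[events$time <= horizon], horizon))
  f <- function(t) trajectory_volume(trajectory, t) - cutoff_volume
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    ts <- unique(c(seq(a, b, by = 0.05), b))
    vs <- f(ts)
    hit <- which(vs >= 0)
    if (length(hit) > 0) {
      i <- hit[1L]
      if (i == 1L) return(rec(ts[1L] - params$t0, TRUE))
      root <- stats::uniroot(f, c(ts[i - 1L], ts[i]), tol = 1e-3)$root
      return(rec(root - params$t0, TRUE))
    }
  }
  rec(horizon - params$t0, FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records Data frame with columns `time` and `event` (logical or
#'   0/1), e.g. rows from [time_to_cutoff()].
#' @return Data frame (time, survival, at_risk) including the initial
#'   point (time 0, survival 1).
#' @export
km_estimate <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no survival records")
  fit <- survival::survfit(
    survival::Surv(records$time, as.integer(records$event)) ~ 1)
  data.frame(time = c(0, fit$time),
             survival = c(1, fit$surv),
             at_risk = c(fit$n, fit$n.risk))
}

#' Two-group logrank test
#'
#' Standard 1-df logrank chi-square between two sets of survival records.
#' If neither group has any event the statistic is 0 and p = 1 (with a
#' warning).
#'
#' @param groupA,groupB Data frames with columns `time` and `event`.
#' @return List with `statistic` (chi-square), `p_value`, `n` per group.
#' @export
logrank_test <- function(groupA, groupB) {
  if (nrow(groupA) == 0 || nrow(groupB) == 0)
    stop("both groups must be non-empty")
  time <- c(groupA$time, groupB$time)
  event <- as.integer(c(groupA$event, groupB$event))
  group <- rep(c("A", "B"), c(nrow(groupA), nrow(groupB)))
  if (sum(event) == 0) {
    warning("no events in either group; logrank undefined, returning p = 1")
    return(list(statistic = 0, p_value = 1,
                n = c(A = nrow(groupA), B = nrow(groupB))))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = c(A = nrow(groupA), B = nrow(groupB)))
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided; the exact null distribution is enumerated for combined
#' sample sizes up to 10 without ties, otherwise the normal approximation
#' with continuity and tie correction is used.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (Mann-Whitney W for `x`) and `p_value`.
#' @export
ranksum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 10) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Equal-length numeric vectors (n >= 3), finite, each with
#'   positive variance.
#' @return List with `rho` and two-sided `p_value` (t distribution,
#'   n - 2 df).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Generalized equivalent uniform dose
#'
#' `gEUD = (sum_i v_i * D_i^a)^(1/a)` over a dose-volume histogram with
#' fractional volumes `v_i` summing to 1. The default Lyman exponent
#' `a = -10` weights the calculation towards the minimum dose.
#'
#' @param dvh Data frame with columns `dose_gy` and `fractional_volume`.
#' @param exponent Lyman exponent `a != 0` (default -10).
#' @return gEUD in Gy.
#' @examples
#' geud(data.frame(dose_gy = c(30, 36), fractional_volume = c(0.5, 0.5)))
#' @export
geud <- function(dvh, exponent = -10) {
  d <- as.data.frame(dvh)
  if (!all(c("dose_gy", "fractional_volume") %in% names(d)))
    stop("dvh needs columns dose_gy and fractional_volume")
  if (exponent == 0) stop("exponent must be non-zero")
  v <- d$fractional_volume
  if (any(v < 0)) stop("fractional volumes must be >= 0")
  if (abs(sum(v) - 1) > 1e-6) stop("fractional volumes must sum to 1")
  if (exponent < 0 && any(d$dose_gy <= 0 & v > 0))
    stop("zero dose with positive volume is undefined for negative exponents")
  doses <- unique(d$dose_gy[v > 0])
  if (length(doses) == 1L) return(doses)  # uniform dose, exact
  sum(v * d$dose_gy^exponent)^(1 / exponent)
}

#' Classify a patient's protocol response group
#'
#' Compares per-arm times to cutoff within a tolerance (default 1 day):
#' Group 1 -- HFSRT is best (boost arm still inferior); Group 2 -- iRT is
#' inferior but the boost compensates; Group 3 -- the boost further
#' prolongs time to progression beyond non-inferior iRT; Group 4 -- iRT
#' alone is best (non-inferior without needing the boost; exact three-way
#' ties fall here).
#'
#' @param tau_hfsrt,tau_irt,tau_boost Times to cutoff (days) under HFSRT,
#'   iRT and iRT+boost, `>= 0` (all-zero ties -- a cutoff at or below
#'   baseline -- fall into Group 4).
#' @param tolerance Equality tolerance in days (default 1).
#' @return Integer group label 1-4.
#' @export
classify_group <- function(tau_hfsrt, tau_irt, tau_boost, tolerance = 1) {
  stopifnot(tau_hfsrt >= 0, tau_irt >= 0, tau_boost >= 0, tolerance >= 0)
  if (tau_boost < tau_hfsrt - tolerance) return(1L)
  if (tau_irt < tau_hfsrt - tolerance) return(2L)
  if (tau_boost > tau_irt + tolerance) return(3L)
  4L
}
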