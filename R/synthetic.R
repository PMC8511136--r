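#' Specification of a synthetic virtual-patient cohort
#'
#' Describes the statistical world the generator emulates: a shared
#' exponential growth rate, patient-specific radiation surviving fraction
#' drawn uniformly over the fitted range, a resistance-decay rate drawn
#' log-uniformly over the four decades spanned by the fitted values,
#' baseline volumes of 1-60 cm^3, one pre-treatment measurement plus 4-10
#' post-treatment measurements at a jittered ~6-week cadence, and 20%
#' multiplicative measurement noise with a 0.5 cm^3 absolute floor below
#' 2 cm^3.
#'
#' @param n_patients Number of patients (default 16, the trial cohort
#'   size).
#' @param lambda Shared growth rate (day^-1, default 0.065).
#' @param S_range Uniform range for the surviving fraction (default the
#'   fitted extremes `[0.07, 0.90]`).
#' @param epsilon_range Range for the resistance rate (day^-1, default
#'   the fitted extremes `[0.05e-4, 202e-4]`).
#' @param epsilon_log_uniform Draw `epsilon` log-uniformly (default) or
#'   uniformly.
#' @param V0_range Uniform range of baseline volumes (cm^3).
#' @param n_post_range Integer range of post-treatment measurement counts.
#' @param assessment_interval Nominal measurement cadence (days).
#' @param interval_jitter_sd SD of Gaussian jitter on each
#'   inter-measurement gap (days); gaps are truncated at `min_interval`.
#' @param min_interval Smallest allowed gap (days).
#' @param noise_rel_sd,small_volume_cut,small_volume_sd Measurement noise
#'   model, see [perturb_volumes()].
#' @param geud_range Uniform range of planned gEUD values (Gy, default
#'   the delivered `[31.3, 37.5]`).
#' @param n_fractions Fractions of the ground-truth (delivered) daily
#'   course (default 5; days `0 .. n-1`).
#' @param treated Generate the series under the delivered course
#'   (default) or untreated exponential growth (growth-rate tests).
#' @param seed Master seed; per-patient sub-seeds are derived from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 16L, lambda = 0.065,
                        S_range = c(0.07, 0.90),
                        epsilon_range = c(0.05e-4, 202e-4),
                        epsilon_log_uniform = TRUE,
                        V0_range = c(1, 60),
                        n_post_range = c(4L, 10L),
                        assessment_interval = 42,
                        interval_jitter_sd = 10,
                        min_interval = 7,
                        noise_rel_sd = 0.2,
                        small_volume_cut = 2,
                        small_volume_sd = 0.5,
                        geud_range = c(31.3, 37.5),
                        n_fractions = 5L,
                        treated = TRUE,
                        seed = 1L) {
  stopifnot(n_patients >= 1, lambda >= 0.017, lambda <= 0.14,
            S_range[1] >= 0, S_range[2] <= 1, diff(S_range) >= 0,
            epsilon_range[1] >= 0, epsilon_range[2] <= 0.1,
            V0_range[1] > 0, diff(V0_range) >= 0,
            n_post_range[1] >= 1, n_post_range[2] >= n_post_range[1],
            assessment_interval > 0, min_interval > 0,
            noise_rel_sd >= 0, small_volume_sd >= 0)
  if (epsilon_log_uniform && epsilon_range[1] <= 0)
    stop("log-uniform epsilon requires a positive lower bound")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Draw one synthetic patient
#'
#' Draws `(S, epsilon, V0)` from the cohort distributions (with
#' `gamma0 = lambda`), simulates the ground-truth trajectory under the
#' delivered daily course, samples it at a jittered ~6-week cadence
#' (baseline at day 0), and applies the measurement noise model. The
#' cutoff volume is the last noisy measurement, mirroring "time to reach
#' the last recorded volume" scoring.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed for this patient (default the spec's master seed).
#' @param id Patient identifier.
#' @return Object of class `synthetic_patient`: list with `id`,
#'   `true_params` ([model_params()]), `measurements` (day/volume_cm3),
#'   `cutoff_volume`, `geud`, `fraction_times`.
#' @export
draw_patient <- function(spec, seed = spec$seed, id = "P01") {
  with_seed(seed, {
    S <- stats::runif(1, spec$S_range[1], spec$S_range[2])
    eps <- if (spec$epsilon_log_uniform) {
      exp(stats::runif(1, log(spec$epsilon_range[1]),
                       log(spec$epsilon_range[2])))
    } else {
      stats::runif(1, spec$epsilon_range[1], spec$epsilon_range[2])
    }
    V0 <- stats::runif(1, spec$V0_range[1], spec$V0_range[2])
    n_post <- sample(seq(spec$n_post_range[1], spec$n_post_range[2]), 1)
    gaps <- pmax(spec$min_interval,
                 stats::rnorm(n_post, spec$assessment_interval,
                              spec$interval_jitter_sd))
    days <- c(0, cumsum(gaps))
    params <- model_params(lambda = spec$lambda, surviving_fraction = S,
                           epsilon = eps, gamma0 = spec$lambda, V0 = V0,
                           t0 = 0)
    ft <- if (spec$treated) seq_len(spec$n_fractions) - 1 else numeric(0)
    truth <- predict_volumes(params, ft, days)
    noisy <- perturb_volumes(truth, spec$noise_rel_sd,
                             spec$small_volume_cut, spec$small_volume_sd)
    geud_gy <- stats::runif(1, spec$geud_range[1], spec$geud_range[2])
    structure(list(id = id, true_params = params,
                   measurements = data.frame(day = days, volume_cm3 = noisy),
                   true_volumes = truth,
                   cutoff_volume = noisy[length(noisy)],
                   geud = geud_gy, fraction_times = ft, seed = seed),
              class = "synthetic_patient")
  })
}

#' Draw a synthetic cohort
#'
#' Independent [draw_patient()] draws with per-patient sub-seeds derived
#' reproducibly from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of `synthetic_patient` objects, class `synthetic_cohort`.
#' @export
draw_cohort <- function(spec) {
  out <- lapply(seq_len(spec$n_patients), function(i) {
    draw_patient(spec, seed = .sub_seed(spec$seed, i),
                 id = sprintf("P%02d", i))
  })
  structure(out, class = "synthetic_cohort")
}

#' Long-format measurement table of a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame (patient_id, day, volume_cm3), the interchange
#'   format read by the fitting pipeline.
#' @export
as_measurement_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$id, day = p$measurements$day,
               volume_cm3 = p$measurements$volume_cm3)
  }))
}

#' Ground-truth parameter table of a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Data frame (patient_id, lambda, S, epsilon, V0,
#'   cutoff_volume_cm3, geud_gy) used by recovery tests and correlation
#'   reports.
#' @export
as_truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$id, lambda = p$true_params$lambda,
               S = p$true_params$surviving_fraction,
               epsilon = p$true_params$epsilon, V0 = p$true_params$V0,
               cutoff_volume_cm3 = p$cutoff_volume, geud_gy = p$geud)
  }))
}
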