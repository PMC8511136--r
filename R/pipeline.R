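# End-to-end pipeline commands. Each stage reads/writes delimited text in
# the configured output directory so stages can be re-run independently;
# every file carries the seed and a config fingerprint in its header.

.protocol_to_schedule <- function(p, horizon) {
  type <- match.arg(p$type, c("hfsrt", "irt"))
  if (type == "hfsrt") {
    make_hfsrt(n_fractions = p$n_fractions, horizon = horizon)
  } else {
    make_irt(interval = p$interval_days, n_fractions = p$n_fractions,
             boost = isTRUE(p$boost), horizon = horizon)
  }
}

#' Generate and write a synthetic cohort (stage: synth)
#'
#' Writes `measurements.csv` (patient_id, day, volume_cm3) and
#' `truth.csv` (generative parameters, cutoff volume, gEUD).
#'
#' @param config Configuration list (see [default_config()]); cohort
#'   settings are taken from `config$cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
cmd_synth <- function(config = default_config(), out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec_args <- config$cohort
  spec <- do.call(cohort_spec, spec_args)
  cohort <- draw_cohort(spec)
  meta <- .run_meta(config)
  paths <- c(
    measurements = file.path(out_dir, "measurements.csv"),
    truth = file.path(out_dir, "truth.csv"))
  write_table_with_header(as_measurement_table(cohort), paths["measurements"],
                          meta)
  write_table_with_header(as_truth_table(cohort), paths["truth"], meta)
  message(sprintf("synth: wrote %d patients (seed %s) to %s",
                  spec$n_patients, config$seed, out_dir))
  invisible(paths)
}

#' Fit the model to a measurement file (stage: fit)
#'
#' Runs the population growth-rate grid search (unless `config$fit$lambda`
#' fixes the rate), fits `(S, epsilon, V0)` per patient and bootstraps
#' `(S, epsilon)`. Writes `fits.csv` and `bootstrap.csv`.
#'
#' @param config Configuration list.
#' @param out_dir Output directory.
#' @param measurements_path Measurement file (default
#'   `<out_dir>/measurements.csv`).
#' @return Named character vector of written paths, invisibly.
#' @export
cmd_fit <- function(config = default_config(), out_dir = config$out_dir,
                    measurements_path = file.path(out_dir, "measurements.csv")) {
  m <- read_measurements(measurements_path)
  ft <- config$fit$fraction_times
  fc <- fit_config(n_starts = config$fit$n_starts, seed = config$seed)
  split_m <- split(m, m$patient_id)
  cohort <- lapply(split_m, function(d)
    list(measurements = data.frame(day = d$day, volume = d$volume_cm3),
         fraction_times = ft))
  lambda <- config$fit$lambda
  grid_table <- NULL
  if (is.null(lambda)) {
    gs <- grid_search_lambda(cohort, lambda_grid = config$fit$lambda_grid,
                             config = fc, seed = config$seed)
    lambda <- gs$lambda
    grid_table <- gs$table
    message(sprintf("fit: grid search selected lambda = %.4g /day", lambda))
  }
  fits <- list(); boots <- list()
  for (pid in names(cohort)) {
    fit <- fit_patient(cohort[[pid]]$measurements, lambda_growth = lambda,
                       fraction_times = ft, config = fc, seed = config$seed)
    bs <- bootstrap_fit(cohort[[pid]]$measurements, fit, fraction_times = ft,
                        n_reps = config$fit$n_bootstrap, config = fc,
                        seed = .sub_seed(config$seed, match(pid, names(cohort))))
    message(sprintf("fit: %s converged=%s rmse=%.3g", pid, fit$converged,
                    fit$rmse))
    fits[[pid]] <- data.frame(
      patient_id = pid, lambda = lambda,
      S = fit$params$surviving_fraction, epsilon = fit$params$epsilon,
      V0 = fit$params$V0, rmse = fit$rmse, objective = fit$objective,
      converged = fit$converged)
    boots[[pid]] <- cbind(patient_id = pid, bs$ensemble)
  }
  meta <- .run_meta(config)
  paths <- c(fits = file.path(out_dir, "fits.csv"),
             bootstrap = file.path(out_dir, "bootstrap.csv"))
  write_table_with_header(do.call(rbind, fits), paths["fits"], meta)
  write_table_with_header(do.call(rbind, boots), paths["bootstrap"], meta)
  if (!is.null(grid_table))
    write_table_with_header(grid_table,
                            file.path(out_dir, "lambda_grid.csv"), meta)
  invisible(paths)
}

#' Simulate the configured protocols per patient (stage: simulate)
#'
#' For every patient and protocol, simulates the arm under the point-fit
#' parameters and under each bootstrap replicate, scores the time to the
#' patient's cutoff volume (last recorded measurement), and writes
#' `survival.csv` with the point `tau`, censoring flag and the bootstrap
#' envelope (min/max `tau`, point included).
#'
#' @param config Configuration list.
#' @param out_dir Output directory holding `fits.csv`, `bootstrap.csv`
#'   and `measurements.csv`.
#' @return Path of the written survival table, invisibly.
#' @export
cmd_simulate <- function(config = default_config(),
                         out_dir = config$out_dir) {
  fits_path <- file.path(out_dir, "fits.csv")
  if (!file.exists(fits_path)) stop("missing fits.csv; run cmd_fit first")
  fits <- utils::read.csv(fits_path, comment.char = "#")
  boots <- utils::read.csv(file.path(out_dir, "bootstrap.csv"),
                           comment.char = "#")
  m <- read_measurements(file.path(out_dir, "measurements.csv"))
  horizon <- config$horizon
  schedules <- lapply(config$protocols, .protocol_to_schedule,
                      horizon = horizon)
  labels <- vapply(config$protocols, `[[`, character(1), "label")
  rows <- list()
  for (i in seq_len(nrow(fits))) {
    pid <- fits$patient_id[i]
    pm <- m[m$patient_id == pid, ]
    cutoff <- pm$volume_cm3[which.max(pm$day)]
    if (!is.finite(cutoff) || cutoff <= 0) cutoff <- NULL
    ens <- boots[boots$patient_id == pid, ]
    mk <- function(S, eps) model_params(
      lambda = fits$lambda[i], surviving_fraction = S, epsilon = eps,
      gamma0 = fits$lambda[i], V0 = fits$V0[i], t0 = 0)
    for (j in seq_along(schedules)) {
      tau_of <- function(S, eps) {
        out <- simulate_arm(mk(S, eps), schedules[[j]])
        time_to_cutoff(out, cutoff, horizon = horizon,
                       patient_id = pid, arm = labels[j])
      }
      point <- tau_of(fits$S[i], fits$epsilon[i])
      taus <- point$time
      if (nrow(ens) > 0) {
        taus <- c(taus, mapply(function(S, eps) tau_of(S, eps)$time,
                               ens$S, ens$epsilon))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, arm = labels[j], tau_days = point$time,
        event = point$event, tau_min = min(taus), tau_max = max(taus))
    }
  }
  out <- do.call(rbind, rows)
  path <- file.path(out_dir, "survival.csv")
  write_table_with_header(out, path, .run_meta(config))
  invisible(path)
}

#' Compare arms: KM curves, logrank, response groups, correlations
#' (stage: compare)
#'
#' Reads `survival.csv` (and `fits.csv` / `truth.csv` when present),
#' writes per-arm Kaplan-Meier tables (`km.csv`), classifies every
#' patient into response groups 1-4, compares `log(epsilon)` and `S`
#' between iRT responders and non-responders by rank-sum, and computes
#' Pearson correlations of `S` with `log(epsilon)` and (when dosimetry is
#' available) with gEUD. The summary is written to `report.json`.
#'
#' @param config Configuration list.
#' @param out_dir Output directory.
#' @return The report list, invisibly.
#' @export
cmd_compare <- function(config = default_config(),
                        out_dir = config$out_dir) {
  surv_path <- file.path(out_dir, "survival.csv")
  if (!file.exists(surv_path))
    stop("missing survival.csv; run cmd_simulate first")
  sv <- utils::read.csv(surv_path, comment.char = "#")
  arms <- unique(sv$arm)
  if (length(arms) < 2) stop("need at least 2 arms to compare")
  km <- do.call(rbind, lapply(arms, function(a) {
    recs <- data.frame(time = sv$tau_days[sv$arm == a],
                       event = sv$event[sv$arm == a])
    cbind(arm = a, km_estimate(recs))
  }))
  write_table_with_header(km, file.path(out_dir, "km.csv"),
                          .run_meta(config))
  pairs <- utils::combn(arms, 2, simplify = FALSE)
  logrank <- lapply(pairs, function(pr) {
    g <- function(a) data.frame(time = sv$tau_days[sv$arm == a],
                                event = sv$event[sv$arm == a])
    lr <- logrank_test(g(pr[1]), g(pr[2]))
    list(arms = pr, statistic = lr$statistic, p_value = lr$p_value)
  })
  cmp <- config$compare
  wide <- stats::reshape(sv[, c("patient_id", "arm", "tau_days")],
                         idvar = "patient_id", timevar = "arm",
                         direction = "wide")
  names(wide) <- sub("^tau_days\\.", "", names(wide))
  groups <- NULL
  responders <- NULL
  if (all(c(cmp$hfsrt_arm, cmp$irt_arm, cmp$boost_arm) %in% names(wide))) {
    groups <- data.frame(
      patient_id = wide$patient_id,
      group = mapply(classify_group, wide[[cmp$hfsrt_arm]],
                     wide[[cmp$irt_arm]], wide[[cmp$boost_arm]],
                     MoreArgs = list(tolerance = cmp$tolerance)))
    responders <- wide[[cmp$irt_arm]] >= wide[[cmp$hfsrt_arm]] - cmp$tolerance
    write_table_with_header(groups, file.path(out_dir, "groups.csv"),
                            .run_meta(config))
  }
  report <- list(seed = config$seed, arms = arms, logrank = logrank)
  fits_path <- file.path(out_dir, "fits.csv")
  if (file.exists(fits_path) && !is.null(groups)) {
    fits <- utils::read.csv(fits_path, comment.char = "#")
    fits <- fits[match(wide$patient_id, fits$patient_id), ]
    if (length(unique(responders)) == 2) {
      report$ranksum_log_epsilon <- ranksum_test(
        log(fits$epsilon[responders]), log(fits$epsilon[!responders]))
      report$ranksum_S <- ranksum_test(fits$S[responders],
                                       fits$S[!responders])
    }
    report$pearson_S_logeps <- tryCatch(
      pearson_corr(fits$S, log(fits$epsilon)), error = function(e) NULL)
    truth_path <- file.path(out_dir, "truth.csv")
    if (file.exists(truth_path)) {
      tr <- utils::read.csv(truth_path, comment.char = "#")
      tr <- tr[match(wide$patient_id, tr$patient_id), ]
      if ("geud_gy" %in% names(tr)) {
        report$pearson_S_geud <- tryCatch(
          pearson_corr(fits$S, tr$geud_gy), error = function(e) NULL)
      }
    }
    report$group_counts <- as.list(table(factor(groups$group,
                                                levels = 1:4)))
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
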