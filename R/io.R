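#' Write a delimited table with a commented metadata header
#'
#' Writes `# key=value` comment lines (always including the package
#' version) followed by a comma-separated table. Files written this way
#' round-trip through [read_measurements()] / [utils::read.csv()] with
#' `comment.char = "#"`.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param meta Named character/numeric vector of header fields.
#' @return `path`, invisibly.
#' @export
write_table_with_header <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("irtsim"))
  meta <- c(version = ver, meta)
  writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a longitudinal tumor-volume measurement table
#'
#' Expects comma-separated columns `patient_id`, `day`, `volume_cm3`;
#' lines starting with `#` are ignored.
#'
#' @param path Input file.
#' @return Data frame with the three columns, days ordered within
#'   patient.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  m <- utils::read.csv(path, comment.char = "#")
  need <- c("patient_id", "day", "volume_cm3")
  if (!all(need %in% names(m)))
    stop("measurement file needs columns: ", paste(need, collapse = ", "))
  if (nrow(m) == 0) stop("measurement file is empty: ", path)
  bad <- which(!is.finite(m$day) | !is.finite(m$volume_cm3) |
                 m$volume_cm3 < 0)
  if (length(bad) > 0)
    stop("unparseable or negative measurement at data row ", bad[1])
  m[order(m$patient_id, m$day), need]
}

#' Read a dose-volume histogram table
#'
#' Two comma-separated columns `dose_gy`, `fractional_volume` (fractions
#' summing to 1), as consumed by [geud()].
#'
#' @param path Input file.
#' @return Data frame (dose_gy, fractional_volume).
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) stop("DVH file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("dose_gy", "fractional_volume") %in% names(d)))
    stop("DVH file needs columns dose_gy, fractional_volume")
  d
}

#' Default pipeline configuration
#'
#' A nested list mirroring the structured-text (JSON) configuration file:
#' cohort generation settings, fit settings (growth-rate handling,
#' bootstrap size), the protocol set (HFSRT, iRT, iRT+boost at the 6-week
#' interval) and global seed/horizon. Day 0 is the first radiation
#' fraction throughout; volumes are cm^3, rates day^-1, doses Gy.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return A configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("irtsim_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    cohort = list(n_patients = 16L, lambda = 0.065, seed = seed),
    fit = list(lambda = NULL,            # NULL -> grid search
               lambda_grid = c(0.03, 0.05, 0.065, 0.08, 0.1),
               n_bootstrap = 50L, n_starts = 10L,
               fraction_times = 0:4),
    protocols = list(
      list(label = "HFSRT", type = "hfsrt", n_fractions = 5L),
      list(label = "iRT", type = "irt", n_fractions = 5L,
           interval_days = 42, boost = FALSE),
      list(label = "iRT+boost", type = "irt", n_fractions = 5L,
           interval_days = 42, boost = TRUE)),
    horizon = 1500,
    compare = list(hfsrt_arm = "HFSRT", irt_arm = "iRT",
                   boost_arm = "iRT+boost", tolerance = 1)
  )
}

#' Load a configuration file
#'
#' Reads a JSON configuration and merges it over [default_config()]
#' (top-level and second-level fields present in the file override the
#' defaults; unknown fields are kept).
#'
#' @param path JSON file path.
#' @return A configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg <- default_config(seed = if (!is.null(user$seed)) user$seed else 1L)
  for (nm in names(user)) {
    if (nm %in% names(cfg) && is.list(cfg[[nm]]) && is.list(user[[nm]]) &&
        nm != "protocols") {
      for (sub in names(user[[nm]])) cfg[[nm]][[sub]] <- user[[nm]][[sub]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

# common header fields for all pipeline outputs; filesystem paths are
# excluded from the fingerprint so reruns elsewhere compare equal
.run_meta <- function(config) {
  cfg <- config[setdiff(names(config), c("out_dir", "paths"))]
  c(seed = config$seed,
    config_hash = .fnv1a(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                          digits = NA, null = "null")))
}
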