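#' @name telemonitoring-io
#' @title Readers and writers for the pipeline's CSV interchange files
#' @description All files are comma-separated UTF-8 with a header row, dot
#'   decimal separator and empty string for missing values; `study_day` is
#'   the canonical 1-based time axis. Readers validate the schema (a
#'   missing required column is a schema error) and report malformed rows
#'   by file line number.
#' @param path file path.
#' @param x the table to write.
NULL

.check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

.check_rows <- function(bad, path, what) {
  if (any(bad)) {
    lines <- which(bad)[1] + 1L  # +1 for the header line
    stop(sprintf("malformed row in '%s' at line %d: %s", path, lines, what),
         call. = FALSE)
  }
}

#' @rdname telemonitoring-io
#' @export
read_daily <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("patient_id", "study_day", "completed",
                      "symptom_score", "spo2", "heart_rate",
                      "salbutamol_use"), path)
  df$completed <- as.logical(df$completed)
  .check_rows(is.na(df$completed), path, "completed must be true/false")
  day <- suppressWarnings(as.integer(df$study_day))
  .check_rows(is.na(day) | day < 1, path,
              "study_day must be a positive integer")
  df$study_day <- day
  .check_rows(df$completed & !is.na(df$spo2) & df$spo2 > 100, path,
              "spo2 must not exceed 100")
  .check_rows(df$completed & !is.na(df$heart_rate) & df$heart_rate <= 0,
              path, "heart_rate must be positive")
  df
}

#' @rdname telemonitoring-io
#' @export
read_patients <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("patient_id", "arm", "age", "sex", "smoking_status",
                      "severity", "site"), path)
  .check_rows(!df$arm %in% c("intervention", "usual_care"), path,
              "arm must be 'intervention' or 'usual_care'")
  df
}

#' @rdname telemonitoring-io
#' @export
read_outcomes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_schema(df, c("patient_id", "sgrqc_0"), path)
  for (col in intersect(c("n_admissions", "gp_contacts", "nurse_contacts",
                          "n_exacerbations"), names(df)))
    .check_rows(!is.na(df[[col]]) & df[[col]] < 0, path,
                paste(col, "must be nonnegative"))
  df
}

#' @rdname telemonitoring-io
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full telemonitoring pipeline
#'
#' Chains the stages simulate -> thresholds -> alerts -> classify ->
#' analyze, writing every artifact to `out_dir` together with a manifest of
#' MD5 checksums, so a rerun with the same configuration and seed produces
#' an identical manifest. Stages can be dropped (e.g. omit `"alerts"`); the
#' analysis stage depends only on the simulation outputs.
#'
#' @param config a named list (or path to a YAML/JSON file) with optional
#'   elements `sim` (arguments to [sim_config()]), `alerting`
#'   (`run_in_days`, `centile_high`, `centile_low`, `min_completed`,
#'   `review_window`), `exacerbation` (`symptom_window`, `washout`) and
#'   `seed`.
#' @param out_dir output directory, created if needed.
#' @param seed overrides `config$seed` when given.
#' @param stages character vector of stages to run.
#' @return invisibly, a list with `status` (0 on success), `manifest` (file
#'   names and checksums) and `estimates` (when the analyze stage ran).
#' @export
run_pipeline <- function(config = list(), out_dir = "telecopd-run",
                         seed = NULL,
                         stages = c("simulate", "thresholds", "alerts",
                                    "classify", "analyze")) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  al <- config$alerting %||% list()
  ex <- config$exacerbation %||% list()
  written <- character()
  add <- function(p) written <<- c(written, p)

  scfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
  coh <- simulate_cohort(scfg)
  if ("simulate" %in% stages) {
    add(write_table_csv(coh$patients, file.path(out_dir, "patients.csv")))
    add(write_table_csv(coh$daily, file.path(out_dir, "daily.csv")))
    add(write_table_csv(coh$outcomes, file.path(out_dir, "outcomes.csv")))
    add(write_table_csv(coh$care_events,
                        file.path(out_dir, "care_events.csv")))
    add(write_table_csv(coh$symptom_reports,
                        file.path(out_dir, "symptom_reports.csv")))
  }

  by_patient <- split(coh$daily, coh$daily$patient_id)
  thresholds <- NULL
  if (any(c("thresholds", "alerts") %in% stages)) {
    thresholds <- lapply(by_patient, function(d)
      compute_run_in_thresholds(
        d, run_in_days = al$run_in_days %||% scfg$run_in_days,
        centile_high = al$centile_high %||% 0.97,
        centile_low = al$centile_low %||% 0.03,
        min_completed = al$min_completed %||% 14))
  }
  if ("thresholds" %in% stages) {
    tj <- file.path(out_dir, "thresholds.json")
    jsonlite::write_json(
      lapply(thresholds, function(t) unclass(t)[c(
        "patient_id", "hr_upper", "symptom_upper", "spo2_lower",
        "n_completed_run_in_days", "defined", "provenance")]),
      tj, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    add(tj)
  }
  if ("alerts" %in% stages) {
    alerts <- do.call(rbind, lapply(names(by_patient), function(id)
      generate_alerts(by_patient[[id]], thresholds[[id]])))
    add(write_table_csv(alerts, file.path(out_dir, "alerts.csv")))
    queue <- build_review_queue(alerts, coh$daily,
                                review_day = scfg$follow_up_days,
                                window = al$review_window %||% 14)
    add(write_table_csv(queue, file.path(out_dir, "review_queue.csv")))
  }

  if ("classify" %in% stages) {
    events <- do.call(rbind, lapply(names(by_patient), function(id) {
      d <- by_patient[[id]]
      ri <- d[d$study_day <= scfg$run_in_days & d$completed, ]
      base_use <- if (nrow(ri)) median(ri$salbutamol_use) else 0
      pid <- d$patient_id[1]
      classify_exacerbations(
        coh$symptom_reports[coh$symptom_reports$patient_id == pid, ,
                            drop = FALSE],
        coh$care_events[coh$care_events$patient_id == pid, , drop = FALSE],
        d, base_use,
        symptom_window = ex$symptom_window %||% 7,
        washout = ex$washout %||% 14)
    }))
    add(write_table_csv(events, file.path(out_dir, "exacerbations.csv")))
    tte <- do.call(rbind, lapply(names(by_patient), function(id) {
      pid <- by_patient[[id]]$patient_id[1]
      fu <- coh$outcomes$followup_days[coh$outcomes$patient_id == pid]
      t <- time_to_first_exacerbation(
        events[events$patient_id == pid, , drop = FALSE], fu)
      data.frame(patient_id = pid, time = t$time, observed = t$observed)
    }))
    add(write_table_csv(tte, file.path(out_dir, "tte.csv")))
  }

  estimates <- NULL
  if ("analyze" %in% stages) {
    primary <- fit_primary_model(coh$outcomes, coh$patients)
    estimates <- outcome_table(
      primary,
      fit_change_outcome(coh$outcomes, coh$patients, "eq5d_change"),
      fit_change_outcome(coh$outcomes, coh$patients, "scl20_change"),
      fit_binary_outcome(coh$outcomes, coh$patients, "any_admission"),
      fit_count_outcome(coh$outcomes, coh$patients, "n_exacerbations"))
    add(write_table_csv(estimates, file.path(out_dir, "estimates.csv")))
  }

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, files = manifest), mpath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(status = 0L, manifest = manifest, estimates = estimates))
}
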