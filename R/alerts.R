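#' Per-patient safety thresholds from the run-in period
#'
#' After an initial run-in of daily monitoring, each patient's own
#' distributions of heart rate, composite symptom score and SpO2 define
#' their personal safety thresholds: the 97th centile of heart rate and of
#' symptom score (alerts fire above) and the 3rd centile of SpO2 (alerts
#' fire below). Centiles use the nearest-rank convention: the
#' `ceiling(p * n)`-th smallest completed observation, with no
#' interpolation.
#'
#' Thresholds are undefined (returned with `defined = FALSE` and a reason,
#' never an error) when fewer than `min_completed` run-in days were
#' completed.
#'
#' @param daily daily records for a single patient (see
#'   [simulate_daily_series()] for the schema).
#' @param run_in_days length of the run-in window, days 1..`run_in_days`.
#' @param centile_high upper centile for heart rate and symptom score.
#' @param centile_low lower centile for SpO2.
#' @param min_completed minimum completed run-in days for thresholds to be
#'   defined.
#' @return an object of class `copd_thresholds`: a list with `patient_id`,
#'   `hr_upper`, `symptom_upper`, `spo2_lower`, `run_in_window`,
#'   `n_completed_run_in_days`, `defined`, `reason`, `provenance`
#'   (`"run_in"`) and `effective_from` (first post-run-in day).
#' @export
compute_run_in_thresholds <- function(daily, run_in_days = 42,
                                      centile_high = 0.97,
                                      centile_low = 0.03,
                                      min_completed = 14) {
  pid <- unique(daily$patient_id)
  if (length(pid) > 1L)
    stop("daily records contain more than one patient_id", call. = FALSE)
  if (nrow(daily) > 0L) {
    if (anyDuplicated(daily$study_day) || is.unsorted(daily$study_day))
      stop("daily study_day indices must be strictly increasing",
           call. = FALSE)
  }
  ri <- daily[daily$study_day <= run_in_days & daily$completed, , drop = FALSE]
  n_comp <- nrow(ri)
  ts <- list(patient_id = if (length(pid)) pid else NA_integer_,
             hr_upper = NA_real_, symptom_upper = NA_real_,
             spo2_lower = NA_real_,
             run_in_window = c(1L, as.integer(run_in_days)),
             n_completed_run_in_days = n_comp,
             defined = FALSE, reason = NULL,
             provenance = "run_in",
             effective_from = as.integer(run_in_days) + 1L)
  if (n_comp < min_completed) {
    ts$reason <- sprintf("only %d completed run-in days (minimum %d)",
                         n_comp, min_completed)
    class(ts) <- "copd_thresholds"
    return(ts)
  }
  ts$hr_upper <- nearest_rank_centile(ri$heart_rate, centile_high)
  ts$symptom_upper <- nearest_rank_centile(ri$symptom_score, centile_high)
  ts$spo2_lower <- nearest_rank_centile(ri$spo2, centile_low)
  ts$defined <- TRUE
  class(ts) <- "copd_thresholds"
  ts
}

#' @export
print.copd_thresholds <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Thresholds undefined for patient %s: %s\n",
                x$patient_id, x$reason))
  } else {
    cat(sprintf("Patient %s thresholds (%s): HR > %.1f, symptoms > %g, SpO2 < %.1f (from day %d)\n",
                x$patient_id, x$provenance, x$hr_upper, x$symptom_upper,
                x$spo2_lower, x$effective_from))
  }
  invisible(x)
}

#' Manually override a patient's safety thresholds
#'
#' Clinicians may revise thresholds, for example after a hospital admission.
#' The override returns a new threshold set with provenance
#' `"manual_override"` and an audit note; the original is not modified.
#'
#' @param thresholds a `copd_thresholds` object.
#' @param hr_upper,symptom_upper,spo2_lower replacement values (unchanged if
#'   omitted).
#' @param effective_from first study day the new thresholds apply to.
#' @param note free-text audit note.
#' @return a new `copd_thresholds` object.
#' @export
override_thresholds <- function(thresholds, hr_upper = NULL,
                                symptom_upper = NULL, spo2_lower = NULL,
                                effective_from = NULL, note = "") {
  stopifnot(inherits(thresholds, "copd_thresholds"))
  ts <- thresholds
  ts$hr_upper <- hr_upper %||% ts$hr_upper
  ts$symptom_upper <- symptom_upper %||% ts$symptom_upper
  ts$spo2_lower <- spo2_lower %||% ts$spo2_lower
  if (!is.na(ts$hr_upper) && !is.na(ts$spo2_lower) &&
      (ts$hr_upper <= 0 || ts$spo2_lower > 100))
    stop("override values out of physiologic range", call. = FALSE)
  ts$effective_from <- as.integer(effective_from %||% ts$effective_from)
  ts$provenance <- "manual_override"
  ts$audit_note <- note
  ts$defined <- !any(is.na(c(ts$hr_upper, ts$symptom_upper, ts$spo2_lower)))
  ts
}

.empty_alerts <- function() {
  data.frame(patient_id = integer(), study_day = integer(),
             parameter = character(), observed = numeric(),
             threshold = numeric(), direction = character())
}

#' Generate daily safety alerts against personal thresholds
#'
#' One alert is produced for every (completed day, parameter) pair on which
#' the observation strictly crosses the patient's threshold: heart rate or
#' symptom score strictly above its 97th-centile threshold, SpO2 strictly
#' below its 3rd-centile threshold. Equality never alerts. Days before the
#' thresholds' `effective_from` day (the run-in) produce no alerts.
#'
#' Thresholds may be a single `copd_thresholds` object or a list of them
#' (e.g. the run-in set plus later [override_thresholds()] revisions); for
#' each day the set with the largest `effective_from` not exceeding that day
#' applies.
#'
#' @param daily daily records for the patient.
#' @param thresholds a `copd_thresholds` object or list of them.
#' @return a data.frame of alerts (`patient_id`, `study_day`, `parameter`,
#'   `observed`, `threshold`, `direction`). If thresholds are undefined, an
#'   empty frame with attribute `no_thresholds = TRUE` and the reason.
#' @export
generate_alerts <- function(daily, thresholds) {
  ts_list <- if (inherits(thresholds, "copd_thresholds")) list(thresholds)
             else thresholds
  stopifnot(all(vapply(ts_list, inherits, TRUE, "copd_thresholds")))
  if (!any(vapply(ts_list, `[[`, TRUE, "defined"))) {
    out <- .empty_alerts()
    attr(out, "no_thresholds") <- TRUE
    attr(out, "reason") <- ts_list[[1]]$reason %||% "thresholds undefined"
    return(out)
  }
  ts_list <- ts_list[vapply(ts_list, `[[`, TRUE, "defined")]
  eff <- vapply(ts_list, `[[`, 1L, "effective_from")
  ord <- order(eff)
  ts_list <- ts_list[ord]; eff <- eff[ord]

  d <- daily[daily$completed & daily$study_day >= eff[1], , drop = FALSE]
  if (nrow(d) == 0L) return(.empty_alerts())
  idx <- findInterval(d$study_day, eff)
  hr_up <- vapply(ts_list, `[[`, 1, "hr_upper")[idx]
  sy_up <- vapply(ts_list, `[[`, 1, "symptom_upper")[idx]
  sp_lo <- vapply(ts_list, `[[`, 1, "spo2_lower")[idx]

  mk <- function(sel, param, obs, thr, dir) {
    if (!any(sel)) return(NULL)
    data.frame(patient_id = d$patient_id[sel], study_day = d$study_day[sel],
               parameter = param, observed = obs[sel], threshold = thr[sel],
               direction = dir)
  }
  out <- rbind(
    mk(!is.na(d$heart_rate) & d$heart_rate > hr_up, "heart_rate",
       d$heart_rate, hr_up, "above"),
    mk(!is.na(d$symptom_score) & d$symptom_score > sy_up, "symptom_score",
       as.numeric(d$symptom_score), sy_up, "above"),
    mk(!is.na(d$spo2) & d$spo2 < sp_lo, "spo2", d$spo2, sp_lo, "below")
  )
  if (is.null(out)) return(.empty_alerts())
  out <- out[order(out$study_day, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clinically important changes: alerts persisting at least two days
#'
#' A change is flagged as clinically important when the same parameter
#' alerts on at least two consecutive observed days. A missing
#' (not-completed) day breaks a run, since no alert can be observed on it:
#' runs are maximal sequences of alert days with consecutive study-day
#' indices.
#'
#' @param alerts output of [generate_alerts()] for one patient.
#' @param daily the patient's daily records (schema reference; runs are
#'   determined by the alert days themselves).
#' @param min_days minimum persistence, in days.
#' @return data.frame with one row per maximal qualifying run:
#'   `patient_id`, `parameter`, `start_day`, `end_day`,
#'   `n_consecutive_days`.
#' @export
detect_important_change <- function(alerts, daily = NULL, min_days = 2) {
  empty <- data.frame(patient_id = integer(), parameter = character(),
                      start_day = integer(), end_day = integer(),
                      n_consecutive_days = integer())
  if (is.null(alerts) || nrow(alerts) == 0L) return(empty)
  out <- lapply(split(alerts, alerts$parameter), function(a) {
    runs <- consecutive_runs(a$study_day)
    runs <- runs[runs$n_days >= min_days, , drop = FALSE]
    if (nrow(runs) == 0L) return(NULL)
    data.frame(patient_id = a$patient_id[1], parameter = a$parameter[1],
               start_day = runs$start_day, end_day = runs$end_day,
               n_consecutive_days = runs$n_days)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$start_day, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prioritized clinician review queue
#'
#' Clinical reviews are prioritized by the number of alerts each patient
#' generated in the trailing two weeks. Patients from whom no data were
#' received in the window are surfaced for review as well: a
#' non-transmitting patient ranks immediately above transmitting patients
#' with the same alert count (in particular, above all zero-alert
#' transmitters). Ties are broken by ascending patient id, so repeated
#' builds are identical.
#'
#' @param alerts alert rows for all patients (as from [generate_alerts()],
#'   row-bound).
#' @param daily daily records for all patients (used to determine
#'   `data_received`).
#' @param review_day the day of the review.
#' @param window trailing window length, days; alerts with
#'   `review_day - window < study_day <= review_day` count.
#' @return data.frame sorted by priority: `patient_id`, `review_day`,
#'   `alert_count_14d`, `data_received`, `rank`.
#' @export
build_review_queue <- function(alerts, daily, review_day, window = 14) {
  ids <- sort(unique(daily$patient_id))
  in_win <- function(day) day > review_day - window & day <= review_day
  counts <- vapply(ids, function(id) {
    if (is.null(alerts) || nrow(alerts) == 0L) return(0L)
    a <- alerts[alerts$patient_id == id, , drop = FALSE]
    sum(in_win(a$study_day))
  }, 0L)
  received <- vapply(ids, function(id) {
    d <- daily[daily$patient_id == id, , drop = FALSE]
    any(d$completed & in_win(d$study_day))
  }, TRUE)
  # non-transmitters get a half-step boost so they sit above transmitting
  # patients with the same count
  key <- counts + ifelse(received, 0, 0.5)
  ord <- order(-key, ids)
  out <- data.frame(patient_id = ids[ord], review_day = review_day,
                    alert_count_14d = counts[ord],
                    data_received = received[ord],
                    rank = seq_along(ids))
  rownames(out) <- NULL
  out
}

#' Monthly mood screening with the GP-notification rule
#'
#' Depression (0-24) and anxiety (0-21) checklist scores are screened
#' monthly; if either equals or exceeds 10, the patient's general
#' practitioner is notified by letter.
#'
#' @param depression_score SCL-20-derived depression score, 0-24.
#' @param anxiety_score SCL-10A-derived anxiety score, 0-21.
#' @param patient_id,month_index optional identifiers carried through.
#' @return a one-row data.frame with `gp_letter_flag`.
#' @export
screen_mood <- function(depression_score, anxiety_score, patient_id = NA,
                        month_index = NA) {
  if (!is.numeric(depression_score) || is.na(depression_score) ||
      depression_score < 0 || depression_score > 24)
    stop("depression_score out of instrument range [0, 24]", call. = FALSE)
  if (!is.numeric(anxiety_score) || is.na(anxiety_score) ||
      anxiety_score < 0 || anxiety_score > 21)
    stop("anxiety_score out of instrument range [0, 21]", call. = FALSE)
  data.frame(patient_id = patient_id, month_index = month_index,
             depression_score = depression_score,
             anxiety_score = anxiety_score,
             gp_letter_flag = depression_score >= 10 | anxiety_score >= 10)
}
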