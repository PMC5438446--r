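#' Construct a validated symptom report
#'
#' The trial's case definition distinguishes major respiratory symptoms
#' (change in sputum, more breathless, chest tightness) from minor ones
#' (feeling unwell, tiredness, raised temperature, a cold).
#'
#' @param patient_id,day identifiers.
#' @param major character vector, subset of `change_in_sputum`,
#'   `more_breathless`, `chest_tight`.
#' @param minor character vector, subset of `unwell`, `tired`,
#'   `temperature`, `cold`.
#' @return a list of class `copd_symptom_report`.
#' @export
symptom_report <- function(patient_id, day, major = character(),
                           minor = character()) {
  majors <- c("change_in_sputum", "more_breathless", "chest_tight")
  minors <- c("unwell", "tired", "temperature", "cold")
  major <- unique(as.character(major)); minor <- unique(as.character(minor))
  if (!all(major %in% majors))
    stop("unknown major symptom: ", paste(setdiff(major, majors),
                                          collapse = ", "), call. = FALSE)
  if (!all(minor %in% minors))
    stop("unknown minor symptom: ", paste(setdiff(minor, minors),
                                          collapse = ", "), call. = FALSE)
  structure(list(patient_id = patient_id, day = as.integer(day),
                 major_symptoms = major, minor_symptoms = minor),
            class = "copd_symptom_report")
}

#' Acute-change symptom rule of the exacerbation case definition
#'
#' A reported symptom set qualifies as an acute change in respiratory
#' symptoms when at least two symptoms are present, at least one of them
#' major.
#'
#' @param report a [symptom_report()].
#' @return `TRUE` or `FALSE`.
#' @export
symptom_rule <- function(report) {
  stopifnot(inherits(report, "copd_symptom_report"))
  n_major <- length(report$major_symptoms)
  n_major + length(report$minor_symptoms) >= 2L && n_major >= 1L
}

#' Sustained increased reliever use (48-hour rule)
#'
#' Detects maximal windows of at least two consecutive completed days on
#' which daily salbutamol use exceeds (strictly) the patient's baseline
#' level, operationalizing "taking more salbutamol for at least 48 h".
#'
#' @param daily the patient's daily records.
#' @param baseline_use baseline daily puffs; by convention the median use
#'   over the patient's completed run-in days (compute and pass it, e.g.
#'   with [median()]).
#' @return data.frame of windows (`start_day`, `end_day`, `n_days`).
#' @export
salbutamol_rule <- function(daily, baseline_use) {
  stopifnot(baseline_use >= 0)
  d <- daily[daily$completed & !is.na(daily$salbutamol_use) &
               daily$salbutamol_use > baseline_use, , drop = FALSE]
  runs <- consecutive_runs(d$study_day)
  runs[runs$n_days >= 2L, , drop = FALSE]
}

#' Classify exacerbation events for one patient
#'
#' Applies the trial's composite case definition. An exacerbation is
#' recorded at a treated care event (antibiotics or oral steroids
#' prescribed, A&E attendance or hospital admission) occurring in the
#' presence of an acute symptom change -- a qualifying [symptom_rule()]
#' report within `symptom_window` days either side -- and additionally at
#' the start of every sustained increased-salbutamol window
#' ([salbutamol_rule()]). Candidate events are merged so that no two
#' recorded events start within `washout` days of each other (earliest
#' first; at equal days a care-event trigger wins).
#'
#' @param reports list of [symptom_report()] objects (or a data.frame with
#'   `day`, `major_symptoms`, `minor_symptoms` as `;`-separated strings).
#' @param care_events data.frame with `day` and `kind`.
#' @param daily the patient's daily records.
#' @param baseline_use baseline salbutamol use (puffs/day).
#' @param symptom_window days either side of a care event within which a
#'   qualifying report must fall.
#' @param washout minimum separation, in days, between recorded event
#'   starts.
#' @return data.frame of events: `patient_id`, `start_day`, `trigger`.
#' @export
classify_exacerbations <- function(reports, care_events, daily,
                                   baseline_use, symptom_window = 7,
                                   washout = 14) {
  if (is.data.frame(reports)) reports <- reports_from_frame(reports)
  qual_days <- vapply(reports, function(r)
    if (symptom_rule(r)) r$day else NA_integer_, 1L)
  qual_days <- qual_days[!is.na(qual_days)]

  cand <- data.frame(start_day = integer(), trigger = character())
  if (!is.null(care_events) && nrow(care_events) > 0L) {
    ok <- vapply(care_events$day, function(d)
      any(abs(qual_days - d) <= symptom_window), TRUE)
    if (any(ok))
      cand <- rbind(cand, data.frame(start_day = care_events$day[ok],
                                     trigger = "care_event_with_symptoms"))
  }
  wins <- salbutamol_rule(daily, baseline_use)
  if (nrow(wins) > 0L)
    cand <- rbind(cand, data.frame(start_day = wins$start_day,
                                   trigger = "salbutamol_48h"))
  if (nrow(cand) == 0L)
    return(data.frame(patient_id = integer(), start_day = integer(),
                      trigger = character()))
  # care-event triggers sort first at equal start days
  cand <- cand[order(cand$start_day, cand$trigger), , drop = FALSE]
  keep <- logical(nrow(cand)); last <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$start_day[i] >= last + washout) {
      keep[i] <- TRUE
      last <- cand$start_day[i]
    }
  }
  pid <- unique(daily$patient_id)
  out <- data.frame(patient_id = if (length(pid)) pid[1] else NA_integer_,
                    start_day = cand$start_day[keep],
                    trigger = cand$trigger[keep])
  rownames(out) <- NULL
  out
}

reports_from_frame <- function(df) {
  split_field <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";")[[1]]
  }
  lapply(seq_len(nrow(df)), function(i)
    symptom_report(df$patient_id[i] %||% NA, df$day[i],
                   split_field(df$major_symptoms[i]),
                   split_field(df$minor_symptoms[i])))
}

#' Time to first exacerbation
#'
#' @param events output of [classify_exacerbations()].
#' @param follow_up_days censoring time.
#' @return list with `time` (days) and `observed` (`FALSE` when censored at
#'   the end of follow-up).
#' @export
time_to_first_exacerbation <- function(events, follow_up_days) {
  if (is.null(events) || nrow(events) == 0L)
    return(list(time = follow_up_days, observed = FALSE))
  list(time = min(events$start_day), observed = TRUE)
}
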