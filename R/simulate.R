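#' Simulate a randomized COPD telemonitoring cohort
#'
#' Generates a complete synthetic trial: patient profiles under 2:1 (or any
#' configured) randomization, a daily telemonitoring series per patient
#' (five-item symptom diary scored 0-3 per item, SpO2, heart rate, reliever
#' use, completion flag), episodic exacerbations with an
#' onset-plateau-recovery deviation ramp, independent daily missingness,
#' administrative censoring at death or withdrawal, and a patient-level
#' 12-month outcome panel (SGRQ-C at 0/6/12 months, EQ-5D / SCL-20 / SCL-10A
#' changes, admissions, exacerbation counts, GP and nurse contacts).
#'
#' Every random draw comes from a per-patient substream derived
#' deterministically from `config$seed` and the patient id, so identical
#' configurations yield byte-identical cohorts, and each patient's data do
#' not depend on cohort size or on `include_daily`.
#'
#' Arm sizes are exact: the intervention arm receives
#' `floor(n * i / (i + c))` patients and the control arm the remainder, so
#' 166 patients under 2:1 allocation split 110/56; only the assignment order
#' is random.
#'
#' @param config a [sim_config()] object.
#' @param include_daily if `FALSE`, skip generation of the daily series
#'   (patient profiles, latent exacerbation episodes and outcomes are still
#'   produced, identically). Useful for outcome-level simulation studies.
#' @return an object of class `copd_cohort`: a list with elements
#'   `patients`, `daily` (NULL when `include_daily = FALSE`), `outcomes`,
#'   `care_events`, `symptom_reports` and `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 30, seed = 7))
#' table(coh$patients$arm)
#' @export
simulate_cohort <- function(config = sim_config(), include_daily = TRUE) {
  config <- validate_sim_config(config)
  n <- config$n_patients
  ar <- config$allocation_ratio
  n_int <- floor(n * ar[1] / sum(ar))
  n_ctrl <- n - n_int

  set.seed(config$seed %% 2147483629)
  arms <- sample(c(rep("intervention", n_int), rep("usual_care", n_ctrl)))

  patients <- .rows_to_df(lapply(seq_len(n), function(i) {
    simulate_patient_profile(i, arms[i], config)
  }))

  episodes <- lapply(seq_len(n), function(i) {
    simulate_episode_starts(patients[i, ], config)
  })
  censoring <- .rows_to_df(lapply(seq_len(n), function(i) {
    simulate_censoring(patients[i, ], config)
  }))

  daily <- NULL
  if (include_daily) {
    daily <- do.call(rbind, lapply(seq_len(n), function(i) {
      simulate_daily_series(patients[i, ], config,
                            episode_starts = episodes[[i]],
                            censor_day = censoring$followup_days[i])
    }))
    rownames(daily) <- NULL
  }

  outcomes <- .rows_to_df(lapply(seq_len(n), function(i) {
    simulate_outcomes(patients[i, ], config, episodes[[i]], censoring[i, ])
  }))

  ce <- lapply(seq_len(n), function(i) {
    simulate_care_trail(patients[i, ], config, episodes[[i]],
                        censoring$followup_days[i])
  })
  care_events <- do.call(rbind, lapply(ce, `[[`, "care_events"))
  symptom_reports <- do.call(rbind, lapply(ce, `[[`, "symptom_reports"))
  rownames(care_events) <- rownames(symptom_reports) <- NULL

  structure(list(patients = patients, daily = daily, outcomes = outcomes,
                 care_events = care_events,
                 symptom_reports = symptom_reports, config = config),
            class = "copd_cohort")
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("COPD telemonitoring cohort: %d patients (%d intervention / %d usual care)\n",
              nrow(x$patients), sum(x$patients$arm == "intervention"),
              sum(x$patients$arm == "usual_care")))
  if (!is.null(x$daily))
    cat(sprintf("  daily records: %d rows over %d days\n", nrow(x$daily),
                x$config$follow_up_days))
  invisible(x)
}

simulate_patient_profile <- function(patient_id, arm, config) {
  set.seed(.patient_seed(config$seed, patient_id, 0L))
  smoking <- sample(names(config$smoking_probs), 1L,
                    prob = config$smoking_probs)
  list(
    patient_id = patient_id,
    arm = arm,
    age = round(rnorm(1, config$age_mean, config$age_sd), 1),
    sex = if (runif(1) < config$prop_male) "male" else "female",
    smoking_status = smoking,
    severity = if (runif(1) < config$severity_prob_moderate) "moderate"
               else "severe_or_very_severe",
    site = paste0("site_", sample.int(config$n_sites, 1L)),
    prior_admission = runif(1) < config$prior_admission_prob,
    prior_rehab = runif(1) < config$prior_rehab_prob,
    live_in_support = runif(1) < config$live_in_support_prob,
    baseline_sgrqc = min(100, max(0, rnorm(1, config$sgrqc_baseline_mean,
                                           config$sgrqc_baseline_sd))),
    hr_baseline = max(40, rnorm(1, config$hr_baseline_mean,
                                config$hr_baseline_sd)),
    spo2_baseline = min(100, rnorm(1, config$spo2_baseline_mean,
                                   config$spo2_baseline_sd)),
    symptom_propensity = min(3, max(0, rnorm(1, config$symptom_propensity_mean,
                                             config$symptom_propensity_sd))),
    salbutamol_baseline = max(0, rnorm(1, config$salbutamol_baseline_mean,
                                       config$salbutamol_baseline_sd))
  )
}

# Latent exacerbation start days for one patient. Episodes are drawn from a
# Poisson process at the arm-specific rate and thinned so that successive
# starts are separated by at least the episode length plus 14 days.
simulate_episode_starts <- function(profile, config) {
  set.seed(.patient_seed(config$seed, profile$patient_id, 1L))
  rate <- config$exacerbation_rate *
    if (profile$arm == "intervention") config$exacerbation_rate_ratio else 1
  ep_len <- config$onset_days + config$plateau_days + config$recovery_days
  n_events <- rpois(1, rate * config$follow_up_days / 365)
  if (n_events == 0L || rate == 0) return(integer())
  last_start <- config$follow_up_days - ep_len
  if (last_start < config$run_in_days + 1L) return(integer())
  starts <- sort(sample(seq.int(config$run_in_days + 1L, last_start),
                        min(n_events, last_start - config$run_in_days),
                        replace = FALSE))
  keep <- integer()
  last <- -Inf
  for (s in starts) {
    if (s >= last + ep_len + 14L) { keep <- c(keep, s); last <- s }
  }
  keep
}

simulate_censoring <- function(profile, config) {
  set.seed(.patient_seed(config$seed, profile$patient_id, 3L))
  u_death <- runif(1); u_wd <- runif(1); u_day <- runif(1)
  death <- u_death < config$death_prob
  withdrawal <- !death && u_wd < config$withdrawal_prob
  day <- if (death || withdrawal)
    as.integer(ceiling(u_day * config$follow_up_days)) else NA_integer_
  list(patient_id = profile$patient_id,
       death = death, withdrawal = withdrawal,
       event_day = day,
       followup_days = if (is.na(day)) config$follow_up_days
                       else as.integer(day))
}

# Patient-level daily missingness probability: Beta-distributed around the
# configured mean so that weekly compliance varies between patients. Must
# be drawn first in substream 2 (before the daily noise).
patient_missing_prob <- function(config) {
  m <- config$missing_prob
  s <- config$missing_prob_sd %||% 0
  if (s <= 0 || m <= 0 || m >= 1) return(m)
  v <- min(s^2, 0.9 * m * (1 - m))  # Beta variance bound
  k <- m * (1 - m) / v - 1
  rbeta(1, m * k, (1 - m) * k)
}

# Deviation multiplier for each day of an episode: linear onset to full
# depth, plateau at 1, then linear decay during recovery.
episode_ramp <- function(config) {
  c(seq_len(config$onset_days) / config$onset_days,
    rep(1, config$plateau_days),
    1 - seq_len(config$recovery_days) / (config$recovery_days + 1))
}

#' Simulate the daily telemonitoring series for one patient
#'
#' Draws the patient's daily diary and physiology around their latent
#' baselines: each of the five diary items (well-being, cough,
#' breathlessness, sputum quantity, sputum colour) is an ordinal 0-3 score
#' obtained by rounding and clamping a latent Gaussian; the composite
#' `symptom_score` is their sum (0-15). During exacerbation episodes all
#' channels are shifted by the configured deviations scaled by the
#' onset-plateau-recovery ramp. Days are independently missing with
#' probability `config$missing_prob`; on a missing (or post-censoring) day
#' all measurement fields are `NA`.
#'
#' @param profile a single row of the `patients` table from
#'   [simulate_cohort()].
#' @param config the [sim_config()] used to generate the profile.
#' @param episode_starts integer start days of exacerbation episodes; if
#'   `NULL`, drawn from the patient's own substream (as
#'   [simulate_cohort()] does).
#' @param censor_day last day of observation (death/withdrawal); defaults to
#'   full follow-up.
#' @return a data.frame with one row per study day.
#' @export
simulate_daily_series <- function(profile, config, episode_starts = NULL,
                                  censor_day = NULL) {
  config <- validate_sim_config(config)
  if (is.null(episode_starts))
    episode_starts <- simulate_episode_starts(profile, config)
  if (is.null(censor_day))
    censor_day <- config$follow_up_days
  n_days <- config$follow_up_days
  ramp <- episode_ramp(config)
  frac <- numeric(n_days)
  for (s in episode_starts) {
    idx <- s + seq_along(ramp) - 1L
    ok <- idx <= n_days
    frac[idx[ok]] <- pmax(frac[idx[ok]], ramp[ok])
  }

  set.seed(.patient_seed(config$seed, profile$patient_id, 2L))
  p_miss <- patient_missing_prob(config)
  completed <- runif(n_days) >= p_miss
  hr <- profile$hr_baseline + config$hr_dev * frac +
    rnorm(n_days, 0, config$hr_noise_sd)
  spo2 <- profile$spo2_baseline + config$spo2_dev * frac +
    rnorm(n_days, 0, config$spo2_noise_sd)
  items <- sapply(1:5, function(k) {
    latent <- profile$symptom_propensity + (config$symptom_dev / 5) * frac +
      rnorm(n_days, 0, config$symptom_noise_sd)
    pmin(3L, pmax(0L, as.integer(round(latent))))
  })
  salb <- pmax(0L, as.integer(round(
    profile$salbutamol_baseline + config$salbutamol_dev * frac +
      rnorm(n_days, 0, config$salbutamol_noise_sd))))

  completed[seq_len(n_days) > censor_day] <- FALSE
  in_ex <- frac > 0 & seq_len(n_days) <= censor_day

  out <- data.frame(
    patient_id = profile$patient_id,
    study_day = seq_len(n_days),
    completed = completed,
    wellbeing = items[, 1], cough = items[, 2], breathless = items[, 3],
    sputum_quantity = items[, 4], sputum_colour = items[, 5],
    symptom_score = as.integer(rowSums(items)),
    spo2 = pmin(100, spo2),
    heart_rate = pmax(20, hr),
    salbutamol_use = salb,
    in_exacerbation = in_ex
  )
  meas <- c("wellbeing", "cough", "breathless", "sputum_quantity",
            "sputum_colour", "symptom_score", "spo2", "heart_rate",
            "salbutamol_use")
  out[!out$completed, meas] <- NA
  out
}

simulate_outcomes <- function(profile, config, episode_starts, censoring) {
  set.seed(.patient_seed(config$seed, profile$patient_id, 4L))
  fu <- censoring$followup_days
  is_int <- profile$arm == "intervention"

  # follow-up SGRQ-C: control-arm level plus baseline tracking, a small
  # severity effect, patient random intercept and visit-level noise
  u <- rnorm(1, 0, config$sgrqc_u_sd)
  base_c <- config$sgrqc_baseline_mean - 0.9 +
    config$sgrqc_baseline_slope *
      (profile$baseline_sgrqc - config$sgrqc_baseline_mean) +
    2 * (profile$severity == "severe_or_very_severe")
  sg6 <- base_c + is_int * config$sgrqc_diff_6m + u +
    rnorm(1, 0, config$sgrqc_resid_sd)
  sg12 <- base_c + is_int * config$sgrqc_diff_12m + u +
    rnorm(1, 0, config$sgrqc_resid_sd)

  eq <- config$eq5d_change_mean_control + is_int * config$eq5d_change_diff +
    rnorm(1, 0, config$eq5d_change_sd)
  s20 <- config$scl20_change_mean_control + is_int * config$scl20_change_diff +
    rnorm(1, 0, config$scl20_change_sd)
  s10 <- config$scl10a_change_mean_control +
    is_int * config$scl10a_change_diff + rnorm(1, 0, config$scl10a_change_sd)

  p_adm <- config$admission_prob_control *
    if (is_int) config$admission_rr else 1
  any_adm <- runif(1) < p_adm
  n_adm <- if (any_adm) 1L + rpois(1, 0.4) else 0L

  gp <- rnbinom(1, mu = config$gp_mean_control *
                  if (is_int) config$gp_ratio else 1, size = config$gp_size)
  nurse <- rnbinom(1, mu = config$nurse_mean_control *
                     if (is_int) config$nurse_ratio else 1,
                   size = config$nurse_size)
  quit_flag <- runif(1) < config$smoking_cessation_prob

  has6 <- fu >= 183L
  has12 <- fu >= config$follow_up_days
  list(
    patient_id = profile$patient_id,
    sgrqc_0 = profile$baseline_sgrqc,
    sgrqc_6 = if (has6) min(100, max(0, sg6)) else NA_real_,
    sgrqc_12 = if (has12) min(100, max(0, sg12)) else NA_real_,
    eq5d_change = if (has12) eq else NA_real_,
    scl20_change = if (has12) s20 else NA_real_,
    scl10a_change = if (has12) s10 else NA_real_,
    n_admissions = n_adm,
    any_admission = any_adm,
    n_exacerbations = sum(episode_starts <= fu),
    gp_contacts = gp,
    nurse_contacts = nurse,
    smoking_cessation = quit_flag,
    death = censoring$death,
    withdrawal_day = if (censoring$withdrawal) censoring$event_day
                     else NA_integer_,
    followup_days = fu
  )
}

# Treated care events and qualifying symptom reports attached to latent
# episodes, for exercising the exacerbation classifier on simulated data.
simulate_care_trail <- function(profile, config, episode_starts, fu) {
  set.seed(.patient_seed(config$seed, profile$patient_id, 5L))
  majors <- c("change_in_sputum", "more_breathless", "chest_tight")
  minors <- c("unwell", "tired", "temperature", "cold")
  ce <- list(); sr <- list()
  for (s in episode_starts[episode_starts <= fu]) {
    if (runif(1) < config$care_event_prob) {
      day <- min(s + config$onset_days, fu)
      kind <- sample(c("antibiotics_prescribed", "oral_steroids_prescribed"),
                     1L)
      ce[[length(ce) + 1L]] <- data.frame(patient_id = profile$patient_id,
                                          day = day, kind = kind)
      sr[[length(sr) + 1L]] <- data.frame(
        patient_id = profile$patient_id, day = day,
        major_symptoms = paste(sample(majors, 1L + rbinom(1, 1, 0.5)),
                               collapse = ";"),
        minor_symptoms = sample(minors, 1L))
    }
  }
  empty_ce <- data.frame(patient_id = integer(), day = integer(),
                         kind = character())
  empty_sr <- data.frame(patient_id = integer(), day = integer(),
                         major_symptoms = character(),
                         minor_symptoms = character())
  list(care_events = if (length(ce)) do.call(rbind, ce) else empty_ce,
       symptom_reports = if (length(sr)) do.call(rbind, sr) else empty_sr)
}
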