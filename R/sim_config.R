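#' Configuration for the synthetic telemonitoring cohort
#'
#' Builds and validates the full parameter set for [simulate_cohort()]. The
#' defaults reproduce the design and baseline characteristics of a 12-month
#' COPD telemonitoring trial: 2:1 randomization, a 42-day run-in, covariate
#' distributions calibrated to the published baseline table (age 69.8 (SD 9.1)
#' years, 61.5% male, smoking status 21% current / 15.5% ex < 2 y / 63.5%
#' ex >= 2 y, 38% moderate disease, baseline SGRQ-C 56.4 (SD 19.7)), and
#' outcome effects equal to the trial's reported estimates (SGRQ-C difference
#' -1.7 at 12 months, EQ-5D change difference 0.076, admission relative risk
#' 0.83) so that the analysis functions can be checked by parameter recovery.
#'
#' @param n_patients number of patients randomized.
#' @param allocation_ratio integer vector `c(intervention, control)`.
#' @param follow_up_days length of follow-up in days.
#' @param run_in_days initial threshold-estimation period in days.
#' @param age_mean,age_sd age distribution (years).
#' @param prop_male probability of male sex.
#' @param smoking_probs named probabilities for `current`, `ex_lt2y`,
#'   `ex_ge2y`; must sum to 1.
#' @param severity_prob_moderate probability of moderate (vs severe or very
#'   severe) airflow limitation.
#' @param prior_admission_prob,prior_rehab_prob,live_in_support_prob
#'   probabilities of the binary subgroup covariates.
#' @param n_sites number of recruiting sites (patients assigned uniformly).
#' @param sgrqc_baseline_mean,sgrqc_baseline_sd baseline SGRQ-C distribution
#'   (points, truncated to 0-100; higher = worse health status).
#' @param hr_baseline_mean,hr_baseline_sd between-patient distribution of
#'   resting heart rate (bpm); `hr_noise_sd` is the day-to-day SD.
#' @param spo2_baseline_mean,spo2_baseline_sd between-patient SpO2 (%);
#'   `spo2_noise_sd` day-to-day SD (values capped at 100).
#' @param symptom_propensity_mean,symptom_propensity_sd between-patient mean
#'   per-item diary score on the 0-3 scale; `symptom_noise_sd` daily SD of
#'   the latent item score before rounding.
#' @param salbutamol_baseline_mean,salbutamol_baseline_sd between-patient
#'   mean reliever use (puffs/day); `salbutamol_noise_sd` daily SD.
#' @param exacerbation_rate control-arm exacerbation rate, events per
#'   patient-year; `exacerbation_rate_ratio` multiplies it in the
#'   intervention arm.
#' @param onset_days,plateau_days,recovery_days shape of an exacerbation
#'   episode: linear onset ramp, full-depth plateau, linear recovery.
#' @param symptom_dev,hr_dev,spo2_dev,salbutamol_dev full-depth deviations
#'   during an episode (symptom-score points, bpm, SpO2 points -- negative
#'   for desaturation -- and puffs/day).
#' @param missing_prob mean probability that a day's diary/oximetry entry
#'   is not completed (independent Bernoulli per day). The default 0.15
#'   corresponds to use on about 5.95 days per week, matching observed
#'   system compliance of about 5.9 days/week.
#' @param missing_prob_sd between-patient SD of the daily missingness
#'   probability (Beta-distributed per patient; 0 = identical for all).
#'   The default reproduces the observed spread of weekly compliance.
#' @param sgrqc_diff_6m,sgrqc_diff_12m intervention-minus-control difference
#'   in follow-up SGRQ-C (points) at 6 and 12 months.
#' @param sgrqc_u_sd,sgrqc_resid_sd patient random-intercept and residual SD
#'   of follow-up SGRQ-C (points).
#' @param sgrqc_baseline_slope regression of follow-up SGRQ-C on baseline.
#' @param eq5d_change_mean_control,eq5d_change_diff,eq5d_change_sd 12-month
#'   change in the EQ-5D index: control mean, intervention effect, SD.
#' @param scl20_change_mean_control,scl20_change_diff,scl20_change_sd
#'   12-month change in the SCL-20 depression score.
#' @param scl10a_change_mean_control,scl10a_change_diff,scl10a_change_sd
#'   12-month change in the SCL-10A anxiety score.
#' @param admission_prob_control probability of at least one hospital
#'   admission in the control arm; `admission_rr` relative risk in the
#'   intervention arm.
#' @param gp_mean_control,gp_ratio,gp_size negative-binomial GP surgery
#'   contacts: control mean, intervention rate ratio, dispersion size.
#' @param nurse_mean_control,nurse_ratio,nurse_size practice-nurse contacts,
#'   same parameterization.
#' @param smoking_cessation_prob probability of reporting not smoking at 12
#'   months.
#' @param death_prob,withdrawal_prob probabilities of death or withdrawal
#'   during follow-up (event day uniform; data censored afterwards).
#' @param care_event_prob probability that a latent exacerbation episode
#'   generates a treated care event (antibiotics/steroids prescription) with
#'   an accompanying qualifying symptom report.
#' @param seed integer root seed; all per-patient substreams derive from it.
#'
#' @return an object of class `copd_sim_config` (a validated named list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 166,
                       allocation_ratio = c(2L, 1L),
                       follow_up_days = 365,
                       run_in_days = 42,
                       age_mean = 69.8, age_sd = 9.1,
                       prop_male = 0.615,
                       smoking_probs = c(current = 0.21, ex_lt2y = 0.155,
                                         ex_ge2y = 0.635),
                       severity_prob_moderate = 0.38,
                       prior_admission_prob = 0.40,
                       prior_rehab_prob = 0.30,
                       live_in_support_prob = 0.60,
                       n_sites = 3,
                       sgrqc_baseline_mean = 56.4, sgrqc_baseline_sd = 19.7,
                       hr_baseline_mean = 80, hr_baseline_sd = 8,
                       hr_noise_sd = 5,
                       spo2_baseline_mean = 93.5, spo2_baseline_sd = 2,
                       spo2_noise_sd = 1.2,
                       symptom_propensity_mean = 0.8,
                       symptom_propensity_sd = 0.3,
                       symptom_noise_sd = 0.5,
                       salbutamol_baseline_mean = 2,
                       salbutamol_baseline_sd = 1,
                       salbutamol_noise_sd = 0.8,
                       exacerbation_rate = 1.5,
                       exacerbation_rate_ratio = 1.2,
                       onset_days = 3, plateau_days = 7, recovery_days = 7,
                       symptom_dev = 4, hr_dev = 12, spo2_dev = -4,
                       salbutamol_dev = 2,
                       missing_prob = 0.15,
                       missing_prob_sd = 0.12,
                       sgrqc_diff_6m = 1.0, sgrqc_diff_12m = -1.7,
                       sgrqc_u_sd = 10, sgrqc_resid_sd = 11,
                       sgrqc_baseline_slope = 0.7,
                       eq5d_change_mean_control = -0.08,
                       eq5d_change_diff = 0.076,
                       eq5d_change_sd = 0.20,
                       scl20_change_mean_control = 0.14,
                       scl20_change_diff = -0.13,
                       scl20_change_sd = 0.50,
                       scl10a_change_mean_control = 0.13,
                       scl10a_change_diff = 0,
                       scl10a_change_sd = 0.50,
                       admission_prob_control = 0.411,
                       admission_rr = 0.83,
                       gp_mean_control = 6.5, gp_ratio = 0.8, gp_size = 2,
                       nurse_mean_control = 3.3, nurse_ratio = 0.6,
                       nurse_size = 1.5,
                       smoking_cessation_prob = 0.83,
                       death_prob = 0.055,
                       withdrawal_prob = 0.07,
                       care_event_prob = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "copd_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid configuration field '%s': %s", field, msg),
         call. = FALSE)
  }
  probs <- c("prop_male", "severity_prob_moderate", "prior_admission_prob",
             "prior_rehab_prob", "live_in_support_prob", "missing_prob",
             "admission_prob_control", "smoking_cessation_prob",
             "death_prob", "withdrawal_prob", "care_event_prob")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(p, "must be a probability in [0, 1]")
  }
  sds <- grep("_sd$", names(cfg), value = TRUE)
  for (s in sds) {
    if (!is.numeric(cfg[[s]]) || any(cfg[[s]] < 0))
      stop_field(s, "standard deviations must be >= 0")
  }
  if (cfg$n_patients < 1) stop_field("n_patients", "must be >= 1")
  ar <- cfg$allocation_ratio
  if (length(ar) != 2L || any(ar != round(ar)) || any(ar <= 0))
    stop_field("allocation_ratio",
               "must be two positive integers (intervention, control)")
  if (cfg$run_in_days >= cfg$follow_up_days)
    stop_field("run_in_days", "run-in must be shorter than follow-up")
  if (abs(sum(cfg$smoking_probs) - 1) > 1e-8)
    stop_field("smoking_probs", "must sum to 1")
  if (cfg$exacerbation_rate < 0)
    stop_field("exacerbation_rate", "must be >= 0")
  if (cfg$exacerbation_rate_ratio <= 0 && cfg$exacerbation_rate > 0)
    stop_field("exacerbation_rate_ratio", "must be > 0")
  if (any(c(cfg$onset_days, cfg$recovery_days) < 1) || cfg$plateau_days < 1)
    stop_field("onset_days", "episode phases must each last >= 1 day")
  if (cfg$spo2_baseline_mean <= 0 || cfg$spo2_baseline_mean > 100)
    stop_field("spo2_baseline_mean", "must lie in (0, 100]")
  cfg$allocation_ratio <- as.integer(ar)
  cfg
}

#' @export
print.copd_sim_config <- function(x, ...) {
  cat(sprintf("COPD telemonitoring simulation config: %d patients (%d:%d), %d-day follow-up, %d-day run-in, seed %d\n",
              x$n_patients, x$allocation_ratio[1], x$allocation_ratio[2],
              x$follow_up_days, x$run_in_days, as.integer(x$seed)))
  invisible(x)
}
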