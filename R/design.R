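#' Sample size for a two-arm comparison of means with unequal allocation
#'
#' Computes the number of patients needed to detect a mean difference
#' `delta` in the primary outcome (SGRQ-C points) between two arms
#' randomized `allocation_ratio[1]:allocation_ratio[2]`, then inflates for
#' loss to follow-up.
#'
#' With `method = "t"` (default) the per-arm sizes are the smallest
#' integers achieving the target power under the noncentral-t distribution
#' of the two-sample t statistic, with the intervention arm held at
#' `ratio` times the control arm. Loss inflation divides the control arm by
#' `1 - loss_fraction`, rounds up, and sets the intervention arm to `ratio`
#' times the inflated control arm, so the allocation ratio is preserved
#' exactly in the recruited total. Under the trial's design inputs (delta
#' 7.3 points, SD 12.7, 90% power, two-sided alpha 0.05, 2:1 allocation,
#' 10% loss) this yields 55 + 110 = 165 patients.
#'
#' `method = "normal"` uses the closed-form normal approximation
#' \eqn{n_c = (1 + 1/r)\,\sigma^2 (z_{1-\alpha/2} + z_{1-\beta})^2 / \delta^2}
#' per control-arm patient.
#'
#' @param delta target mean difference (same units as `sd`); must be
#'   nonzero.
#' @param sd common outcome standard deviation.
#' @param power target power (0-1).
#' @param alpha two-sided significance level.
#' @param allocation_ratio integer vector `c(intervention, control)`.
#' @param loss_fraction anticipated loss to follow-up, in `[0, 1)`.
#' @param method `"t"` (noncentral-t) or `"normal"` (closed form).
#' @return an object of class `copd_sample_size`: list with pre-loss arm
#'   sizes `n_control`, `n_intervention`, inflated sizes
#'   `n_control_recruit`, `n_intervention_recruit`, `total`, the achieved
#'   `power`, and the inputs.
#' @export
sample_size <- function(delta = 7.3, sd = 12.7, power = 0.90, alpha = 0.05,
                        allocation_ratio = c(2L, 1L), loss_fraction = 0.10,
                        method = c("t", "normal")) {
  method <- match.arg(method)
  if (delta == 0) stop("delta must be nonzero: power unattainable",
                       call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)",
                                     call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must be in [0, 1)", call. = FALSE)
  if (length(allocation_ratio) != 2L || any(allocation_ratio <= 0))
    stop("allocation_ratio must be two positive numbers", call. = FALSE)
  r <- allocation_ratio[1] / allocation_ratio[2]
  delta <- abs(delta)

  power_t <- function(nc, ni) {
    df <- nc + ni - 2
    if (df < 1) return(0)
    ncp <- delta / (sd * sqrt(1 / nc + 1 / ni))
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  }

  if (method == "normal") {
    z <- qnorm(1 - alpha / 2) + qnorm(power)
    nc_frac <- (1 + 1 / r) * (sd / delta)^2 * z^2
    n_control <- ceiling(nc_frac)
    n_intervention <- ceiling(r * nc_frac)
  } else {
    n_control <- 2L
    while (power_t(n_control, ceiling(r * n_control)) < power)
      n_control <- n_control + 1L
    n_intervention <- ceiling(r * n_control)
  }
  n_control_recruit <- ceiling(n_control / (1 - loss_fraction))
  n_intervention_recruit <- ceiling(r * n_control_recruit)
  structure(list(
    n_control = n_control, n_intervention = n_intervention,
    n_control_recruit = n_control_recruit,
    n_intervention_recruit = n_intervention_recruit,
    total = n_control_recruit + n_intervention_recruit,
    power = power_t(n_control, n_intervention),
    delta = delta, sd = sd, target_power = power, alpha = alpha,
    allocation_ratio = allocation_ratio, loss_fraction = loss_fraction,
    method = method), class = "copd_sample_size")
}

#' @export
print.copd_sample_size <- function(x, ...) {
  cat(sprintf(
    "Sample size (delta %.2g, SD %.3g, power %.0f%%, alpha %.2g, %g:%g, %.0f%% loss):\n",
    x$delta, x$sd, 100 * x$target_power, x$alpha, x$allocation_ratio[1],
    x$allocation_ratio[2], 100 * x$loss_fraction))
  cat(sprintf("  analysed: %d + %d;  recruit: %d + %d = %d total (achieved power %.3f)\n",
              x$n_intervention, x$n_control, x$n_intervention_recruit,
              x$n_control_recruit, x$total, x$power))
  invisible(x)
}

#' System-usage compliance metrics
#'
#' For each patient, the mean number of days per week the monitoring system
#' was used (7 times the fraction of study days with a completed entry) and
#' the trial's engagement flag: in the study for at least `min_days` days
#' with use on at least `min_rate` of every 7 days on average over that
#' period.
#'
#' @param daily daily records (any number of patients). The days present in
#'   the table define each patient's period in the study; pass records
#'   truncated at withdrawal via `followup`.
#' @param followup optional named vector (names = patient ids) of follow-up
#'   lengths in days; rows beyond a patient's follow-up are ignored.
#' @param min_days minimum days in study for engagement.
#' @param min_rate minimum mean days of use per week for engagement.
#' @return list with `per_patient` (patient_id, days_in_study,
#'   days_used, mean_days_per_week, engaged) and `cohort` (mean and SD of
#'   days per week).
#' @export
compliance_metrics <- function(daily, followup = NULL, min_days = 30,
                               min_rate = 3) {
  per <- do.call(rbind, lapply(split(daily, daily$patient_id), function(d) {
    fu <- if (!is.null(followup)) followup[[as.character(d$patient_id[1])]]
          else max(d$study_day)
    d <- d[d$study_day <= fu, , drop = FALSE]
    n_days <- nrow(d)
    used <- sum(d$completed)
    dpw <- if (n_days > 0) 7 * used / n_days else 0
    data.frame(patient_id = d$patient_id[1], days_in_study = n_days,
               days_used = used, mean_days_per_week = dpw,
               engaged = n_days >= min_days & dpw >= min_rate)
  }))
  rownames(per) <- NULL
  list(per_patient = per,
       cohort = c(mean_days_per_week = mean(per$mean_days_per_week),
                  sd_days_per_week = sd(per$mean_days_per_week),
                  prop_engaged = mean(per$engaged)))
}

#' Unit costs of the intervention and of health-care use
#'
#' @param tablet_cost,oximeter_cost one-off equipment costs per
#'   intervention patient (GBP).
#' @param admission_cost,gp_visit_cost,nurse_visit_cost unit costs of a
#'   hospital admission, a GP appointment and a practice-nurse appointment.
#' @return a validated list of class `copd_cost_inputs`.
#' @export
cost_inputs <- function(tablet_cost = 319, oximeter_cost = 399,
                        admission_cost = 2900, gp_visit_cost = 36,
                        nurse_visit_cost = 11) {
  ci <- list(tablet_cost = tablet_cost, oximeter_cost = oximeter_cost,
             admission_cost = admission_cost, gp_visit_cost = gp_visit_cost,
             nurse_visit_cost = nurse_visit_cost)
  if (any(unlist(ci) < 0)) stop("unit costs must be >= 0", call. = FALSE)
  class(ci) <- "copd_cost_inputs"
  ci
}

#' Per-patient and per-arm cost summary
#'
#' Sums equipment costs (tablet plus oximeter, intervention arm only) and
#' unit-costed health-care use: admissions, GP-surgery contacts and
#' practice-nurse contacts.
#'
#' @param outcomes,patients cohort tables.
#' @param costs a [cost_inputs()] object.
#' @return list with `per_patient` (patient_id, arm, equipment, admissions,
#'   gp, nurse, total) and `per_arm` (n, total and mean cost).
#' @export
cost_summary <- function(outcomes, patients, costs = cost_inputs()) {
  stopifnot(inherits(costs, "copd_cost_inputs"))
  d <- merge(outcomes, patients[, c("patient_id", "arm")],
             by = "patient_id")
  counts <- d[, c("n_admissions", "gp_contacts", "nurse_contacts")]
  if (any(is.na(counts)) || any(counts < 0))
    stop("admission/contact counts must be nonnegative and complete",
         call. = FALSE)
  equipment <- ifelse(d$arm == "intervention",
                      costs$tablet_cost + costs$oximeter_cost, 0)
  per <- data.frame(
    patient_id = d$patient_id, arm = d$arm,
    equipment = equipment,
    admissions = d$n_admissions * costs$admission_cost,
    gp = d$gp_contacts * costs$gp_visit_cost,
    nurse = d$nurse_contacts * costs$nurse_visit_cost)
  per$total <- per$equipment + per$admissions + per$gp + per$nurse
  per_arm <- do.call(rbind, lapply(split(per, per$arm), function(a) {
    data.frame(arm = a$arm[1], n = nrow(a), total_cost = sum(a$total),
               mean_cost = mean(a$total))
  }))
  rownames(per_arm) <- NULL
  list(per_patient = per, per_arm = per_arm)
}

#' Collect effect estimates into a single results table
#'
#' Flattens any mixture of `copd_effect` objects and `copd_primary_fit`
#' results into one machine-readable data.frame mirroring the trial's
#' outcome tables (estimate, CI, p per outcome and timepoint).
#'
#' @param ... `copd_effect` or `copd_primary_fit` objects, or lists of
#'   them.
#' @return a data.frame with one row per estimate (zero rows, with the full
#'   set of columns, when nothing is supplied).
#' @export
outcome_table <- function(...) {
  items <- list(...)
  flat <- list()
  add <- function(x) {
    if (inherits(x, "copd_effect")) flat[[length(flat) + 1L]] <<- x
    else if (inherits(x, "copd_primary_fit")) lapply(x$effects, add)
    else if (is.list(x)) lapply(x, add)
    else stop("outcome_table() accepts effect estimates only",
              call. = FALSE)
    invisible(NULL)
  }
  lapply(items, add)
  if (length(flat) == 0L) {
    return(data.frame(outcome = character(), timepoint = character(),
                      scale = character(), estimate = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      ci_level = numeric(), p_value = numeric(),
                      method = character(), converged = logical(),
                      note = character()))
  }
  out <- do.call(rbind, lapply(flat, as.data.frame))
  rownames(out) <- NULL
  out
}
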