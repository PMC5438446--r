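#' @title Treatment-effect estimate container
#' @description Internal constructor for the uniform effect-estimate record
#'   returned by all fitting functions.
#' @keywords internal
effect_estimate <- function(outcome, scale, estimate, ci_low, ci_high,
                            p_value, timepoint = NA_character_,
                            ci_level = 0.95, method = NA_character_,
                            converged = TRUE, note = NA_character_) {
  structure(list(outcome = outcome, scale = scale, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
                 p_value = p_value, timepoint = timepoint, method = method,
                 converged = converged, note = note),
            class = "copd_effect")
}

#' @export
print.copd_effect <- function(x, ...) {
  cat(sprintf("%s [%s%s]: %.3f (%.0f%% CI %.3f to %.3f), p = %.3g%s\n",
              x$outcome, x$scale,
              if (is.na(x$timepoint)) "" else paste0(", ", x$timepoint),
              x$estimate, 100 * x$ci_level, x$ci_low, x$ci_high, x$p_value,
              if (!x$converged) "  [did not converge]" else ""))
  invisible(x)
}

#' @export
as.data.frame.copd_effect <- function(x, ...) {
  data.frame(outcome = x$outcome, timepoint = x$timepoint, scale = x$scale,
             estimate = x$estimate, ci_low = x$ci_low, ci_high = x$ci_high,
             ci_level = x$ci_level, p_value = x$p_value, method = x$method,
             converged = x$converged, note = x$note)
}

# Merge outcomes with patient covariates and derive analysis variables.
analysis_frame <- function(outcomes, patients) {
  d <- merge(outcomes, patients, by = "patient_id")
  d$arm <- factor(d$arm, levels = c("usual_care", "intervention"))
  if (!is.null(d$smoking_status)) d$current_smoker <- d$smoking_status == "current"
  if (!is.null(d$site)) d$site <- factor(d$site)
  if (!is.null(d$severity))
    d$severity <- factor(d$severity,
                         levels = c("moderate", "severe_or_very_severe"))
  d
}

# Standard adjustment set of the trial's models; terms that are constant in
# the data at hand (e.g. a single site, or one severity level inside a
# severity stratum) are dropped automatically.
covariate_terms <- function(d, baseline = "sgrqc_0", exclude = character()) {
  cand <- c(baseline, "age", "sex", "current_smoker", "severity", "site")
  cand <- setdiff(intersect(cand, names(d)), exclude)
  keep <- vapply(cand, function(v) length(unique(d[[v]])) > 1L, TRUE)
  cand[keep]
}

build_formula <- function(lhs, rhs_terms) {
  as.formula(paste(lhs, "~", paste(rhs_terms, collapse = " + ")))
}

#' Primary analysis: linear mixed-effects model for SGRQ-C
#'
#' Fits the trial's primary model to the SGRQ-C scores at 6 and 12 months:
#' fixed effects for randomized group, time point, baseline SGRQ-C, age
#' (continuous), sex, current smoking, COPD severity (moderate vs
#' severe/very severe) and site, a treatment-by-time interaction, and a
#' patient-specific random intercept. The treatment contrast at each time
#' point (6-month: the group main effect; 12-month: group plus interaction)
#' is reported with a Satterthwaite-df confidence interval and p-value.
#' Missing follow-up scores are handled by the likelihood (no imputation),
#' in keeping with intention-to-treat.
#'
#' @param outcomes,patients tables as produced by [simulate_cohort()] (or
#'   read from file with the same columns).
#' @param conf_level confidence level.
#' @return an object of class `copd_primary_fit`: list with `effects` (the
#'   two `copd_effect` contrasts), `model` (the `lmerModLmerTest` fit) and
#'   `converged`.
#' @export
fit_primary_model <- function(outcomes, patients, conf_level = 0.95) {
  d <- analysis_frame(outcomes, patients)
  long <- rbind(
    data.frame(d, sgrqc = d$sgrqc_6, time = "6mo"),
    data.frame(d, sgrqc = d$sgrqc_12, time = "12mo")
  )
  long <- long[!is.na(long$sgrqc), , drop = FALSE]
  long$time <- factor(long$time, levels = c("6mo", "12mo"))
  if (length(unique(long$patient_id[long$arm == "intervention"])) < 2 ||
      length(unique(long$patient_id[long$arm == "usual_care"])) < 2)
    stop("need at least two patients per arm with post-baseline SGRQ-C",
         call. = FALSE)

  rhs <- c("arm * time", covariate_terms(long), "(1 | patient_id)")
  conv_msgs <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(build_formula("sgrqc", rhs), data = long, REML = TRUE),
    warning = function(w) {
      conv_msgs <<- c(conv_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- length(lme4::getME(fit, "theta")) > 0 &&
    !any(grepl("converge", conv_msgs, ignore.case = TRUE))

  fe <- lme4::fixef(fit)
  contrast_at <- function(timepoint) {
    L <- setNames(numeric(length(fe)), names(fe))
    L["armintervention"] <- 1
    if (timepoint == "12mo") L["armintervention:time12mo"] <- 1
    ct <- lmerTest::contest1D(fit, L, confint = TRUE, level = conf_level)
    effect_estimate(outcome = "sgrqc", scale = "mean_difference",
                    estimate = ct$Estimate, ci_low = ct$lower,
                    ci_high = ct$upper, p_value = ct[["Pr(>|t|)"]],
                    timepoint = timepoint, ci_level = conf_level,
                    method = "linear mixed-effects (Satterthwaite df)",
                    converged = converged,
                    note = if (length(conv_msgs))
                      paste(conv_msgs, collapse = "; ") else NA_character_)
  }
  structure(list(effects = list(`6mo` = contrast_at("6mo"),
                                `12mo` = contrast_at("12mo")),
                 model = fit, converged = converged),
            class = "copd_primary_fit")
}

#' @export
print.copd_primary_fit <- function(x, ...) {
  cat("SGRQ-C mixed-model treatment contrasts (intervention - usual care):\n")
  for (e in x$effects) print(e)
  invisible(x)
}

#' Adjusted mean difference for a change-score outcome
#'
#' Linear-model (ANCOVA-style) comparison of a patient-level change score
#' (EQ-5D index, SCL-20, SCL-10A, lung function) between arms, adjusted for
#' the standard covariate set.
#'
#' @param outcomes,patients cohort tables.
#' @param outcome name of the change column in `outcomes`.
#' @param adjust include the covariate adjustment set.
#' @param conf_level confidence level.
#' @return a `copd_effect` (scale `mean_difference`).
#' @export
fit_change_outcome <- function(outcomes, patients, outcome = "eq5d_change",
                               adjust = TRUE, conf_level = 0.95) {
  d <- analysis_frame(outcomes, patients)
  d <- d[!is.na(d[[outcome]]), , drop = FALSE]
  rhs <- c("arm", if (adjust) covariate_terms(d))
  fit <- stats::lm(build_formula(outcome, rhs), data = d)
  sm <- summary(fit)$coefficients["armintervention", ]
  ci <- stats::confint(fit, "armintervention", level = conf_level)
  effect_estimate(outcome = outcome, scale = "mean_difference",
                  estimate = unname(sm["Estimate"]), ci_low = ci[1],
                  ci_high = ci[2], p_value = unname(sm["Pr(>|t|)"]),
                  timepoint = "12mo", ci_level = conf_level,
                  method = if (adjust) "linear model, adjusted"
                           else "linear model, unadjusted")
}

#' Adjusted relative risk via log-binomial regression
#'
#' Binary outcomes (at least one hospital admission, smoking cessation,
#' death) are analyzed by log-binomial regression adjusting for the
#' standard covariate set, giving an adjusted relative risk with a Wald
#' confidence interval; the treatment-term p-value comes from a
#' likelihood-ratio test, which keeps closer to its nominal size than the
#' Wald test when the adjustment set is sizeable relative to the number of
#' events. When the log-binomial likelihood fails to converge (a known
#' fragility of the log link near fitted risks of 1), the function falls
#' back to a modified Poisson model with robust (sandwich) standard errors
#' and flags the result.
#'
#' @param outcomes,patients cohort tables; `outcomes[[outcome]]` must be
#'   logical or 0/1.
#' @param outcome name of the binary column.
#' @param adjust include covariates (set `FALSE` for the crude risk ratio,
#'   which then equals the contingency-table ratio exactly).
#' @param conf_level confidence level.
#' @return a `copd_effect` (scale `relative_risk`); `method` records
#'   whether the fallback was used.
#' @export
fit_binary_outcome <- function(outcomes, patients,
                               outcome = "any_admission", adjust = TRUE,
                               conf_level = 0.95) {
  d <- analysis_frame(outcomes, patients)
  d$.y <- as.numeric(d[[outcome]])
  d <- d[!is.na(d$.y), , drop = FALSE]
  if (sum(d$.y) == 0)
    return(effect_estimate(outcome, "relative_risk", NA_real_, NA_real_,
                           NA_real_, NA_real_, converged = FALSE,
                           note = "no events in either arm"))
  rhs <- c("arm", if (adjust) covariate_terms(d))
  fml <- build_formula(".y", rhs)
  logbin <- function(f) {
    X <- stats::model.matrix(f, d)
    start <- c(log(max(mean(d$.y), 1e-6)), rep(0, ncol(X) - 1L))
    out <- tryCatch(
      suppressWarnings(glm(f, data = d, family = binomial(link = "log"),
                           start = start,
                           control = stats::glm.control(epsilon = 1e-12,
                                                        maxit = 200))),
      error = function(e) NULL)
    if (!is.null(out) && out$converged &&
        all(out$fitted.values < 1 - 1e-10)) out else NULL
  }
  fit <- logbin(fml)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (!is.null(fit)) {
    b <- coef(fit)["armintervention"]
    se <- sqrt(vcov(fit)["armintervention", "armintervention"])
    # treatment-term p from the likelihood ratio, which holds its size
    # better than the Wald test when the adjustment set is sizeable
    # relative to the event count; Wald p is the backstop
    fit0 <- logbin(build_formula(".y", c(rhs[-1], "1")))
    p <- if (!is.null(fit0))
      stats::pchisq(fit0$deviance - fit$deviance, 1, lower.tail = FALSE)
    else 2 * pnorm(-abs(b / se))
    return(effect_estimate(outcome, "relative_risk", unname(exp(b)),
                           unname(exp(b - z * se)), unname(exp(b + z * se)),
                           unname(p), timepoint = "12mo",
                           ci_level = conf_level,
                           method = if (adjust) "log-binomial, adjusted"
                                    else "log-binomial, unadjusted"))
  }
  # modified Poisson with robust variance
  pfit <- suppressWarnings(glm(fml, data = d, family = poisson(link = "log")))
  vc <- sandwich::vcovHC(pfit, type = "HC0")
  b <- coef(pfit)["armintervention"]
  se <- sqrt(vc["armintervention", "armintervention"])
  p <- 2 * pnorm(-abs(b / se))
  effect_estimate(outcome, "relative_risk", unname(exp(b)),
                  unname(exp(b - z * se)), unname(exp(b + z * se)),
                  unname(p), timepoint = "12mo", ci_level = conf_level,
                  method = "modified Poisson (robust variance) fallback",
                  note = "log-binomial did not converge")
}

#' Adjusted incidence rate ratio for a count outcome
#'
#' Exacerbation (or admission) counts are modelled with a log-link count
#' regression with the log of each patient's follow-up time as offset, so
#' the treatment coefficient is an incidence rate ratio. The default family
#' is negative binomial (to absorb the overdispersion typical of
#' exacerbation counts), with Poisson as an alternative; if the negative
#' binomial fit fails (e.g. no overdispersion), the Poisson fit is used and
#' flagged.
#'
#' @param outcomes,patients cohort tables.
#' @param outcome count column name.
#' @param exposure column with follow-up time (days).
#' @param family `"nbinom"` or `"poisson"`.
#' @param adjust include covariates.
#' @param conf_level confidence level.
#' @return a `copd_effect` (scale `rate_ratio`).
#' @export
fit_count_outcome <- function(outcomes, patients,
                              outcome = "n_exacerbations",
                              exposure = "followup_days",
                              family = c("nbinom", "poisson"),
                              adjust = TRUE, conf_level = 0.95) {
  family <- match.arg(family)
  d <- analysis_frame(outcomes, patients)
  d$.count <- d[[outcome]]
  d$.logexp <- log(d[[exposure]] / 365)
  d <- d[!is.na(d$.count) & is.finite(d$.logexp), , drop = FALSE]
  if (any(d$.count < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (all(d$.count == 0))
    return(effect_estimate(outcome, "rate_ratio", NA_real_, NA_real_,
                           NA_real_, NA_real_, converged = FALSE,
                           note = "all counts zero; rate ratio undefined"))
  rhs <- c("arm", if (adjust) covariate_terms(d), "offset(.logexp)")
  fml <- build_formula(".count", rhs)
  note <- NA_character_
  fit <- NULL
  if (family == "nbinom") {
    fit <- tryCatch(suppressWarnings(MASS::glm.nb(fml, data = d)),
                    error = function(e) NULL)
    if (is.null(fit)) note <- "negative binomial failed; Poisson used"
  }
  method <- if (!is.null(fit)) "negative binomial with offset"
            else "Poisson with offset"
  if (is.null(fit)) fit <- suppressWarnings(glm(fml, data = d, family = poisson()))
  b <- coef(fit)["armintervention"]
  se <- sqrt(vcov(fit)["armintervention", "armintervention"])
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(b / se))
  effect_estimate(outcome, "rate_ratio", unname(exp(b)),
                  unname(exp(b - z * se)), unname(exp(b + z * se)),
                  unname(p), timepoint = "12mo", ci_level = conf_level,
                  method = method, note = note)
}

#' Compare health-care contact counts between arms
#'
#' Summarizes GP-surgery or practice-nurse contact counts as per-arm
#' medians with interquartile ranges and compares arms with a two-sample
#' Wilcoxon rank-sum test (normal approximation, suitable for the heavy
#' ties of count data).
#'
#' @param outcomes,patients cohort tables.
#' @param outcome count column (`"gp_contacts"` or `"nurse_contacts"`).
#' @return list with `summary` (per-arm n, median, q25, q75) and `p_value`.
#' @export
compare_contacts <- function(outcomes, patients, outcome = "gp_contacts") {
  d <- analysis_frame(outcomes, patients)
  x <- d[[outcome]]
  if (any(is.na(x)) || any(x < 0))
    stop("contact counts must be nonnegative and complete", call. = FALSE)
  arms <- split(x, d$arm)
  if (any(lengths(arms) == 0L))
    stop("both arms must be non-empty", call. = FALSE)
  summ <- do.call(rbind, lapply(names(arms), function(a) {
    q <- quantile(arms[[a]], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(arm = a, n = length(arms[[a]]), median = q[2],
               q25 = q[1], q75 = q[3])
  }))
  p <- wilcox.test(arms$intervention, arms$usual_care, exact = FALSE)$p.value
  list(summary = summ, p_value = p)
}

#' Subgroup analysis of the primary outcome
#'
#' Refits the primary SGRQ-C mixed model within each level of a prespecified
#' subgroup variable (COPD severity, smoking status, hospital admission in
#' the previous year, prior pulmonary rehabilitation, live-in support) and
#' reports the stratum-specific 12-month treatment contrasts together with
#' a likelihood-ratio test of the group-by-subgroup interaction, in a
#' forest-plot-ready table.
#'
#' @param outcomes,patients cohort tables.
#' @param subgroup one of `"severity"`, `"smoking"`, `"prior_admission"`,
#'   `"prior_rehab"`, `"live_in_support"`.
#' @return list with `table` (one row per stratum: level, n, estimate, CI,
#'   p) and `interaction_p`.
#' @export
subgroup_analysis <- function(outcomes, patients,
                              subgroup = c("severity", "smoking",
                                           "prior_admission", "prior_rehab",
                                           "live_in_support")) {
  subgroup <- match.arg(subgroup)
  pat <- patients
  pat$.sg <- switch(subgroup,
    severity = pat$severity,
    smoking = ifelse(pat$smoking_status == "current", "current",
                     "not_current"),
    prior_admission = ifelse(pat$prior_admission, "yes", "no"),
    prior_rehab = ifelse(pat$prior_rehab, "yes", "no"),
    live_in_support = ifelse(pat$live_in_support, "yes", "no"))

  rows <- list()
  for (lev in sort(unique(pat$.sg))) {
    sub <- pat[pat$.sg == lev, , drop = FALSE]
    est <- tryCatch(
      fit_primary_model(outcomes[outcomes$patient_id %in% sub$patient_id, ],
                        sub)$effects[["12mo"]],
      error = function(e) NULL)
    if (is.null(est)) {
      warning(sprintf("subgroup '%s' stratum '%s' skipped: too few patients",
                      subgroup, lev), call. = FALSE)
      next
    }
    rows[[lev]] <- data.frame(subgroup = subgroup, level = lev,
                              n = nrow(sub), estimate = est$estimate,
                              ci_low = est$ci_low, ci_high = est$ci_high,
                              p_value = est$p_value)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  # interaction: LRT for an arm x subgroup term added to the primary model,
  # refit by ML
  d <- analysis_frame(outcomes, pat)
  long <- rbind(data.frame(d, sgrqc = d$sgrqc_6, time = "6mo"),
                data.frame(d, sgrqc = d$sgrqc_12, time = "12mo"))
  long <- long[!is.na(long$sgrqc), , drop = FALSE]
  long$time <- factor(long$time, levels = c("6mo", "12mo"))
  excl <- if (subgroup == "severity") "severity"
          else if (subgroup == "smoking") "current_smoker" else character()
  cov <- covariate_terms(long, exclude = excl)
  int_p <- NA_real_
  if (length(unique(long$.sg)) > 1L) {
    f0 <- build_formula("sgrqc", c("arm * time", ".sg", cov,
                                   "(1 | patient_id)"))
    f1 <- build_formula("sgrqc", c("arm * time", ".sg", "arm:.sg", cov,
                                   "(1 | patient_id)"))
    m0 <- suppressWarnings(lme4::lmer(f0, data = long, REML = FALSE))
    m1 <- suppressWarnings(lme4::lmer(f1, data = long, REML = FALSE))
    int_p <- anova(m0, m1)[2, "Pr(>Chisq)"]
  }
  list(table = tab, interaction_p = int_p)
}
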