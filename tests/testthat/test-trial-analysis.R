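make_patients <- function(n, arm) {
  data.frame(patient_id = seq_len(n), arm = arm,
             age = 70, sex = "male", smoking_status = "ex_ge2y",
             severity = "moderate", site = "site_1",
             prior_admission = FALSE, prior_rehab = FALSE,
             live_in_support = FALSE)
}

test_that("noise-free data recover the configured SGRQ-C contrasts exactly", {
  cfg <- sim_config(n_patients = 120, seed = 61, sgrqc_u_sd = 0,
                    sgrqc_resid_sd = 1e-4, sgrqc_diff_6m = 0.99,
                    sgrqc_diff_12m = -1.7, death_prob = 0,
                    withdrawal_prob = 0)
  coh <- simulate_cohort(cfg, include_daily = FALSE)
  fit <- fit_primary_model(coh$outcomes, coh$patients)
  expect_equal(fit$effects[["6mo"]]$estimate, 0.99, tolerance = 1e-3)
  expect_equal(fit$effects[["12mo"]]$estimate, -1.7, tolerance = 1e-3)
})

test_that("primary model demands two patients per arm with follow-up", {
  cfg <- sim_config(n_patients = 4, seed = 1)
  coh <- simulate_cohort(cfg, include_daily = FALSE)
  out <- coh$outcomes
  out$sgrqc_6[coh$patients$arm == "usual_care"] <- NA
  out$sgrqc_12[coh$patients$arm == "usual_care"] <- NA
  expect_error(fit_primary_model(out, coh$patients), "two patients per arm")
})

test_that("crude relative risk equals the contingency-table ratio", {
  set.seed(77)
  for (rep in 1:5) {
    n1 <- 110; n0 <- 56
    pat <- make_patients(n1 + n0, c(rep("intervention", n1),
                                    rep("usual_care", n0)))
    y <- c(rbinom(n1, 1, 0.35), rbinom(n0, 1, 0.4))
    out <- data.frame(patient_id = pat$patient_id, any_admission = y)
    if (sum(y[1:n1]) == 0 || sum(y[-(1:n1)]) == 0) next
    est <- fit_binary_outcome(out, pat, adjust = FALSE)
    crude <- (sum(y[1:n1]) / n1) / (sum(y[-(1:n1)]) / n0)
    expect_equal(est$estimate, crude, tolerance = 1e-8)
  }
})

test_that("equal event proportions give a relative risk of 1", {
  pat <- make_patients(80, rep(c("intervention", "usual_care"), 40))
  y <- rep(c(1, 1, 0, 0), 20)
  out <- data.frame(patient_id = pat$patient_id, any_admission = y)
  est <- fit_binary_outcome(out, pat, adjust = FALSE)
  expect_equal(est$estimate, 1, tolerance = 1e-8)
  none <- fit_binary_outcome(
    data.frame(patient_id = pat$patient_id, any_admission = 0), pat)
  expect_false(none$converged)
})

test_that("rate ratio is invariant to rescaling all follow-up times", {
  set.seed(5)
  pat <- make_patients(150, rep(c("intervention", "intervention",
                                  "usual_care"), 50))
  out <- data.frame(patient_id = pat$patient_id,
                    n_exacerbations = rpois(150, 1.5),
                    followup_days = sample(200:365, 150, TRUE))
  e1 <- fit_count_outcome(out, pat, family = "poisson", adjust = FALSE)
  out2 <- out; out2$followup_days <- out$followup_days * 2
  e2 <- fit_count_outcome(out2, pat, family = "poisson", adjust = FALSE)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)

  zero <- out; zero$n_exacerbations <- 0
  expect_false(fit_count_outcome(zero, pat)$converged)
})

test_that("null count data give a rate ratio near 1 across replicates", {
  set.seed(31)
  est <- replicate(40, {
    pat <- make_patients(180, rep(c("intervention", "intervention",
                                    "usual_care"), 60))
    out <- data.frame(patient_id = pat$patient_id,
                      n_exacerbations = rpois(180, 1.5),
                      followup_days = 365)
    fit_count_outcome(out, pat, adjust = FALSE)$estimate
  })
  expect_lt(abs(mean(log(est))), 2 * sd(log(est)) / sqrt(40))
})

test_that("contact comparison reports exact medians and IQRs", {
  pat <- make_patients(4, c("intervention", "intervention", "usual_care",
                            "usual_care"))
  out <- data.frame(patient_id = 1:4, gp_contacts = c(4, 4, 5, 6))
  cc <- compare_contacts(out, pat)
  expect_equal(cc$summary$median[cc$summary$arm == "intervention"], 4)
  expect_equal(cc$summary$median[cc$summary$arm == "usual_care"], 5.5)

  out2 <- data.frame(patient_id = 1:4, gp_contacts = c(1, 2, 2, 3))
  cc2 <- compare_contacts(out2, pat)
  expect_equal(cc2$summary$median, c(2.5, 1.5))
  expect_error(compare_contacts(out, pat[pat$arm == "usual_care", ]),
               "non-empty")
})

test_that("rank test p-values are roughly uniform under the null", {
  set.seed(92)
  ps <- replicate(150, {
    pat <- make_patients(80, rep(c("intervention", "usual_care"), 40))
    out <- data.frame(patient_id = pat$patient_id,
                      gp_contacts = rpois(80, 5))
    compare_contacts(out, pat)$p_value
  })
  expect_lt(mean(ps < 0.05), 0.11)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("sample size reproduces the trial total and its oracle", {
  ss <- sample_size()
  expect_equal(ss$total, 165)
  expect_equal(ss$n_intervention_recruit, 110)
  expect_equal(ss$n_control_recruit, 55)

  # equal allocation, no loss, normal approximation: closed form per arm
  for (delta in c(5, 7.3, 10)) {
    ss_n <- sample_size(delta = delta, sd = 12.7,
                        allocation_ratio = c(1, 1), loss_fraction = 0,
                        method = "normal")
    expect_equal(ss_n$n_control,
                 oracle_n_per_arm_equal(delta, 12.7, 0.9, 0.05))
  }

  expect_lt(sample_size(delta = 14.6)$total, 165)
  expect_gt(sample_size(sd = 16)$total, 165)
  expect_gt(sample_size(power = 0.95)$total, 165)
  expect_error(sample_size(delta = 0), "delta")
})

test_that("compliance metrics match the trial engagement definition", {
  full <- daily_frame(hr = rep(70, 35))
  cm <- compliance_metrics(full)
  expect_equal(cm$per_patient$mean_days_per_week, 7)
  expect_true(cm$per_patient$engaged)

  two_of_seven <- daily_frame(hr = rep(70, 70))
  two_of_seven$completed <- rep(c(TRUE, TRUE, rep(FALSE, 5)), 10)
  cm2 <- compliance_metrics(two_of_seven)
  expect_equal(cm2$per_patient$mean_days_per_week, 2)
  expect_false(cm2$per_patient$engaged)

  short <- daily_frame(hr = rep(70, 20))
  expect_false(compliance_metrics(short)$per_patient$engaged)

  # weekly counting oracle on arbitrary masks
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(40:200, 1)
    d <- daily_frame(hr = rep(70, n))
    d$completed <- runif(n) > 0.3
    got <- compliance_metrics(d)$per_patient$mean_days_per_week
    weekly <- split(d$completed, (d$study_day - 1) %/% 7)
    want <- 7 * sum(vapply(weekly, sum, 0)) /
      sum(vapply(weekly, length, 0))
    expect_equal(got, want)
  }
})

test_that("cost summary applies the unit prices additively", {
  pat <- make_patients(2, c("intervention", "usual_care"))
  out <- data.frame(patient_id = 1:2, n_admissions = c(1, 0),
                    gp_contacts = c(4, 0), nurse_contacts = c(2, 0))
  cs <- cost_summary(out, pat)
  expect_equal(cs$per_patient$total[1], 319 + 399 + 2900 + 4 * 36 + 2 * 11)
  expect_equal(cs$per_patient$total[2], 0)
  expect_equal(sum(cs$per_arm$total_cost), sum(cs$per_patient$total))

  bad <- out; bad$gp_contacts[1] <- -1
  expect_error(cost_summary(bad, pat), "nonnegative")
})

test_that("outcome table collects every estimate exactly once and round-trips", {
  expect_equal(nrow(outcome_table()), 0)
  expect_true("estimate" %in% names(outcome_table()))

  coh <- simulate_cohort(sim_config(n_patients = 166, seed = 71),
                         include_daily = FALSE)
  prim <- fit_primary_model(coh$outcomes, coh$patients)
  ests <- list(prim,
               fit_change_outcome(coh$outcomes, coh$patients),
               fit_binary_outcome(coh$outcomes, coh$patients),
               fit_count_outcome(coh$outcomes, coh$patients))
  tab <- outcome_table(ests)
  expect_equal(nrow(tab), 5)  # two primary contrasts + three secondary
  expect_equal(anyDuplicated(tab[, c("outcome", "timepoint")]), 0)

  tmp <- tempfile(fileext = ".csv")
  write_table_csv(tab, tmp)
  back <- read.csv(tmp)
  expect_equal(back$estimate, tab$estimate)
  expect_equal(nrow(back), nrow(tab))
})

test_that("subgroup analysis recovers stratum-specific effects", {
  cfg <- sim_config(n_patients = 600, seed = 81, sgrqc_diff_12m = 0,
                    sgrqc_diff_6m = 0, death_prob = 0, withdrawal_prob = 0,
                    sgrqc_u_sd = 2, sgrqc_resid_sd = 2)
  coh <- simulate_cohort(cfg, include_daily = FALSE)
  # inject an effect of -6 points at both timepoints only for patients
  # with prior pulmonary rehabilitation
  sel <- coh$patients$prior_rehab &
    coh$patients$arm == "intervention"
  ids <- coh$patients$patient_id[sel]
  hit <- coh$outcomes$patient_id %in% ids
  coh$outcomes$sgrqc_6[hit] <- coh$outcomes$sgrqc_6[hit] - 6
  coh$outcomes$sgrqc_12[hit] <- coh$outcomes$sgrqc_12[hit] - 6

  sg <- subgroup_analysis(coh$outcomes, coh$patients, "prior_rehab")
  est_yes <- sg$table$estimate[sg$table$level == "yes"]
  est_no <- sg$table$estimate[sg$table$level == "no"]
  expect_lt(abs(est_yes - (-6)), 1)
  expect_lt(abs(est_no), 1)
  expect_lt(sg$interaction_p, 0.01)
})

test_that("a single-stratum subgroup reduces to the primary model", {
  cfg <- sim_config(n_patients = 150, seed = 82, death_prob = 0,
                    withdrawal_prob = 0, live_in_support_prob = 1)
  coh <- simulate_cohort(cfg, include_daily = FALSE)
  prim <- fit_primary_model(coh$outcomes, coh$patients)
  sg <- subgroup_analysis(coh$outcomes, coh$patients, "live_in_support")
  expect_equal(nrow(sg$table), 1)
  expect_equal(sg$table$estimate, prim$effects[["12mo"]]$estimate,
               tolerance = 1e-8)
  expect_true(is.na(sg$interaction_p))
})
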