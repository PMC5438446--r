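test_that("constant run-in distribution gives its own value as threshold", {
  d <- daily_frame(hr = rep(70, 42))
  ts <- compute_run_in_thresholds(d, run_in_days = 42)
  expect_true(ts$defined)
  expect_equal(ts$hr_upper, 70)
  expect_equal(ts$n_completed_run_in_days, 42)
})

test_that("nearest-rank centiles match the sort-and-index oracle", {
  d <- daily_frame(hr = 1:42)
  ts <- compute_run_in_thresholds(d, run_in_days = 42)
  expect_equal(ts$hr_upper, oracle_centile(1:42, 0.97))
  expect_equal(ts$hr_upper, 41)  # ceiling(0.97 * 42) = 41

  set.seed(101)
  for (rep in 1:50) {
    n <- sample(1:200, 1)
    x <- round(runif(n, 50, 120), 1)
    d <- daily_frame(hr = x, spo2 = rev(x), symptoms = sample(0:15, n, TRUE))
    ts <- compute_run_in_thresholds(d, run_in_days = n, min_completed = 1)
    expect_equal(ts$hr_upper, oracle_centile(x, 0.97))
    expect_equal(ts$spo2_lower, oracle_centile(rev(x), 0.03))
    expect_equal(ts$symptom_upper, oracle_centile(d$symptom_score, 0.97))
  }
})

test_that("thresholds are undefined below the minimum completed days", {
  d <- daily_frame(hr = rep(80, 42), completed = c(rep(TRUE, 10),
                                                   rep(FALSE, 32)))
  d$heart_rate[!d$completed] <- NA
  ts <- compute_run_in_thresholds(d, min_completed = 14)
  expect_false(ts$defined)
  expect_match(ts$reason, "10 completed")
  out <- generate_alerts(d, ts)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "no_thresholds"))

  empty <- compute_run_in_thresholds(daily_frame(hr = numeric(0)))
  expect_false(empty$defined)

  bad <- daily_frame(hr = rep(70, 5))
  bad$study_day <- c(1, 2, 2, 3, 4)
  expect_error(compute_run_in_thresholds(bad), "increasing")
})

test_that("alerts require strict crossing and fire per parameter", {
  base <- daily_frame(hr = rep(70, 42), spo2 = rep(95, 42),
                      symptoms = rep(2L, 42))
  extra <- daily_frame(hr = c(70, 71, 80), spo2 = c(95, 95, 90),
                       symptoms = c(2L, 2L, 2L))
  extra$study_day <- 43:45
  d <- rbind(base, extra)
  ts <- compute_run_in_thresholds(d, run_in_days = 42)
  a <- generate_alerts(d, ts)
  # day 43: spo2 == threshold, hr == threshold -> nothing (strict)
  expect_false(43 %in% a$study_day)
  # day 45: hr above and spo2 below -> two alerts on one day
  expect_equal(sum(a$study_day == 45), 2)
  expect_setequal(a$parameter[a$study_day == 45], c("heart_rate", "spo2"))
  # no alerts can originate in the run-in window
  expect_true(all(a$study_day > 42))
})

test_that("alert streams equal the brute-force scan on random series", {
  set.seed(202)
  for (rep in 1:40) {
    d <- random_daily(sample(60:150, 1))
    ts <- compute_run_in_thresholds(d, run_in_days = 42, min_completed = 5)
    if (!ts$defined) next
    a <- generate_alerts(d, ts)
    o <- oracle_alerts(d, list(hr_upper = ts$hr_upper,
                               symptom_upper = ts$symptom_upper,
                               spo2_lower = ts$spo2_lower,
                               effective_from = 43))
    expect_equal(a$study_day, o$study_day)
    expect_equal(a$parameter, o$parameter)
  }
})

test_that("persistence detection finds exactly the maximal >=2-day runs", {
  mk_alerts <- function(days, param = "heart_rate")
    data.frame(patient_id = 1L, study_day = days, parameter = param,
               observed = 1, threshold = 0, direction = "above")
  ic <- detect_important_change(mk_alerts(c(10, 11)))
  expect_equal(nrow(ic), 1)
  expect_equal(ic$n_consecutive_days, 2)

  expect_equal(nrow(detect_important_change(mk_alerts(c(10, 12)))), 0)

  ic <- detect_important_change(mk_alerts(c(5, 6, 7, 20, 21)))
  expect_equal(ic$start_day, c(5, 20))
  expect_equal(ic$n_consecutive_days, c(3, 2))

  # a different parameter does not extend a run
  two <- rbind(mk_alerts(10), mk_alerts(11, "spo2"))
  expect_equal(nrow(detect_important_change(two)), 0)
})

test_that("raising the heart-rate threshold never adds heart-rate alerts", {
  set.seed(303)
  for (rep in 1:20) {
    d <- random_daily(100)
    ts <- compute_run_in_thresholds(d, run_in_days = 42, min_completed = 5)
    if (!ts$defined) next
    n0 <- sum(generate_alerts(d, ts)$parameter == "heart_rate")
    ts2 <- override_thresholds(ts, hr_upper = ts$hr_upper + 5)
    n1 <- sum(generate_alerts(d, ts2)$parameter == "heart_rate")
    expect_lte(n1, n0)
  }
})

test_that("mid-series threshold override matches a two-segment scan", {
  set.seed(404)
  d <- random_daily(120)
  ts <- compute_run_in_thresholds(d, run_in_days = 42, min_completed = 5)
  ts2 <- override_thresholds(ts, hr_upper = ts$hr_upper + 8,
                             spo2_lower = ts$spo2_lower - 1,
                             effective_from = 80, note = "post-admission")
  expect_equal(ts2$provenance, "manual_override")
  expect_equal(ts2$audit_note, "post-admission")
  a <- generate_alerts(d, list(ts, ts2))
  o <- oracle_alerts(d, list(
    list(hr_upper = ts$hr_upper, symptom_upper = ts$symptom_upper,
         spo2_lower = ts$spo2_lower, effective_from = 43),
    list(hr_upper = ts2$hr_upper, symptom_upper = ts2$symptom_upper,
         spo2_lower = ts2$spo2_lower, effective_from = 80)))
  expect_equal(a$study_day, o$study_day)
  expect_equal(a$parameter, o$parameter)

  # identity override leaves the alert stream unchanged
  id_ts <- override_thresholds(ts)
  expect_equal(generate_alerts(d, id_ts)[, 1:3],
               generate_alerts(d, ts)[, 1:3])
})

test_that("review queue ranks by trailing alert count with stable ties", {
  d <- rbind(daily_frame(hr = rep(70, 100), patient_id = 1L),
             daily_frame(hr = rep(70, 100), patient_id = 2L),
             daily_frame(hr = rep(70, 100), patient_id = 3L))
  alerts <- data.frame(
    patient_id = c(1L, 1L, 1L, 2L),
    study_day = c(95, 96, 97, 96),
    parameter = "heart_rate", observed = 1, threshold = 0,
    direction = "above")
  q <- build_review_queue(alerts, d, review_day = 100)
  expect_equal(q$patient_id, c(1L, 2L, 3L))
  expect_equal(q$alert_count_14d, c(3L, 1L, 0L))
  expect_equal(q$rank, 1:3)

  # all quiet: patient-id order
  q0 <- build_review_queue(alerts[0, ], d, review_day = 100)
  expect_equal(q0$patient_id, 1:3)

  # a silent patient outranks zero-alert transmitters but not alerting ones
  d2 <- d
  d2$completed[d2$patient_id == 2L & d2$study_day > 86] <- FALSE
  alerts1 <- alerts[alerts$patient_id == 1L, ]
  q2 <- build_review_queue(alerts1, d2, review_day = 100)
  expect_false(q2$data_received[q2$patient_id == 2L])
  expect_equal(q2$patient_id, c(1L, 2L, 3L))
})

test_that("queue order equals the selection-sort oracle on simulated patients", {
  coh <- simulate_cohort(sim_config(n_patients = 20, follow_up_days = 120,
                                    seed = 31))
  by_p <- split(coh$daily, coh$daily$patient_id)
  alerts <- do.call(rbind, lapply(by_p, function(d) {
    ts <- compute_run_in_thresholds(d, run_in_days = 42)
    generate_alerts(d, ts)
  }))
  for (day in c(60, 90, 120)) {
    q <- build_review_queue(alerts, coh$daily, review_day = day)
    expect_equal(q$patient_id, oracle_queue(alerts, coh$daily, day))
    q_again <- build_review_queue(alerts, coh$daily, review_day = day)
    expect_identical(q, q_again)
  }
})

test_that("mood screening applies the >=10 GP-letter rule with validation", {
  expect_true(screen_mood(10, 0)$gp_letter_flag)
  expect_true(screen_mood(0, 10)$gp_letter_flag)
  expect_false(screen_mood(9, 9)$gp_letter_flag)
  expect_false(screen_mood(0, 0)$gp_letter_flag)
  expect_true(screen_mood(24, 21)$gp_letter_flag)
  expect_error(screen_mood(25, 0), "range")
  expect_error(screen_mood(5, -1), "range")
})
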