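# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: plain loops and sort-and-index
# arithmetic only.

# nearest-rank centile by explicit sort and index
oracle_centile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  k <- ceiling(p * n)
  if (k < 1) k <- 1
  if (k > n) k <- n
  x[k]
}

# exhaustive day-by-day alert scan with piecewise thresholds
# th: list(hr_upper, symptom_upper, spo2_lower, effective_from) or a list
# of such lists (later entries override from their effective_from day)
oracle_alerts <- function(daily, th) {
  if (!is.null(th$hr_upper)) th <- list(th)
  rows <- list()
  for (i in seq_len(nrow(daily))) {
    day <- daily$study_day[i]
    active <- NULL
    for (t in th) if (day >= t$effective_from) active <- t
    if (is.null(active) || !daily$completed[i]) next
    if (!is.na(daily$heart_rate[i]) && daily$heart_rate[i] > active$hr_upper)
      rows[[length(rows) + 1]] <- data.frame(study_day = day,
                                             parameter = "heart_rate")
    if (!is.na(daily$symptom_score[i]) &&
        daily$symptom_score[i] > active$symptom_upper)
      rows[[length(rows) + 1]] <- data.frame(study_day = day,
                                             parameter = "symptom_score")
    if (!is.na(daily$spo2[i]) && daily$spo2[i] < active$spo2_lower)
      rows[[length(rows) + 1]] <- data.frame(study_day = day,
                                             parameter = "spo2")
  }
  if (!length(rows))
    return(data.frame(study_day = integer(), parameter = character()))
  out <- do.call(rbind, rows)
  out[order(out$study_day, out$parameter), , drop = FALSE]
}

# brute-force maximal runs of >= min_len consecutive days
oracle_runs <- function(days, min_len = 2) {
  days <- sort(unique(days))
  out <- list()
  i <- 1
  while (i <= length(days)) {
    j <- i
    while (j + 1 <= length(days) && days[j + 1] == days[j] + 1) j <- j + 1
    if (j - i + 1 >= min_len)
      out[[length(out) + 1]] <- data.frame(start_day = days[i],
                                           end_day = days[j],
                                           n_days = j - i + 1)
    i <- j + 1
  }
  if (!length(out))
    return(data.frame(start_day = integer(), end_day = integer(),
                      n_days = integer()))
  do.call(rbind, out)
}

# brute-force elevated-salbutamol windows (>= 2 consecutive completed days
# strictly above baseline)
oracle_salbutamol <- function(daily, baseline) {
  elev <- daily$study_day[daily$completed & !is.na(daily$salbutamol_use) &
                            daily$salbutamol_use > baseline]
  oracle_runs(elev, 2)
}

# review-queue order by repeated selection of the current best patient
oracle_queue <- function(alerts, daily, review_day, window = 14) {
  ids <- sort(unique(daily$patient_id))
  score <- received <- counts <- numeric(length(ids))
  for (k in seq_along(ids)) {
    a <- alerts[alerts$patient_id == ids[k], , drop = FALSE]
    counts[k] <- sum(a$study_day > review_day - window &
                       a$study_day <= review_day)
    d <- daily[daily$patient_id == ids[k], , drop = FALSE]
    received[k] <- any(d$completed & d$study_day > review_day - window &
                         d$study_day <= review_day)
    score[k] <- counts[k] + if (received[k]) 0 else 0.5
  }
  order_ids <- integer()
  remaining <- seq_along(ids)
  while (length(remaining)) {
    best <- remaining[score[remaining] == max(score[remaining])]
    pick <- best[which.min(ids[best])]
    order_ids <- c(order_ids, ids[pick])
    remaining <- setdiff(remaining, pick)
  }
  order_ids
}

# closed-form normal-approximation sample size per arm (equal allocation)
oracle_n_per_arm_equal <- function(delta, sd, power, alpha) {
  ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * sd^2 / delta^2)
}

# random single-patient daily series for oracle equivalence checks
random_daily <- function(n_days, patient_id = 1L, p_missing = 0.15,
                         symptom_max = 15) {
  completed <- runif(n_days) > p_missing
  d <- data.frame(
    patient_id = patient_id,
    study_day = seq_len(n_days),
    completed = completed,
    symptom_score = sample(0:symptom_max, n_days, replace = TRUE),
    spo2 = round(runif(n_days, 85, 99), 1),
    heart_rate = round(runif(n_days, 55, 115), 1),
    salbutamol_use = rpois(n_days, 2)
  )
  meas <- c("symptom_score", "spo2", "heart_rate", "salbutamol_use")
  d[!completed, meas] <- NA
  d
}

# minimal daily frame from explicit vectors (NA = not completed)
daily_frame <- function(hr = NULL, spo2 = NULL, symptoms = NULL,
                        salbutamol = NULL, completed = NULL,
                        patient_id = 1L) {
  n <- max(length(hr), length(spo2), length(symptoms), length(salbutamol))
  fill <- function(x, default) if (is.null(x)) rep(default, n) else x
  hr <- fill(hr, 70); spo2 <- fill(spo2, 95)
  symptoms <- fill(symptoms, 2L); salbutamol <- fill(salbutamol, 1L)
  if (is.null(completed))
    completed <- !(is.na(hr) & is.na(spo2) & is.na(symptoms) &
                     is.na(salbutamol))
  data.frame(patient_id = rep(patient_id, n), study_day = seq_len(n),
             completed = completed, symptom_score = symptoms, spo2 = spo2,
             heart_rate = hr, salbutamol_use = salbutamol)
}
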