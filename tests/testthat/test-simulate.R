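noise_free <- function(n = 4, ...) {
  sim_config(n_participants = n, artifact_rate = 0, recall_sd = 0,
             recall_bias = c(walking = 1, moderate = 1, vigorous = 1,
                             sitting = 1),
             repeat_prob = 0, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 10)
  a <- generate_cohort(cfg, seed = 1)
  b <- generate_cohort(cfg, seed = 1)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(cfg, seed = 2)
  expect_false(identical(a$observations$bmi, c2$observations$bmi))
  m1 <- generate_cohort(sim_config(n_participants = 2), seed = 3,
                        level = "minute")
  m2 <- generate_cohort(sim_config(n_participants = 2), seed = 3,
                        level = "minute")
  expect_identical(m1$steps, m2$steps)
  expect_identical(m1$ipaq, m2$ipaq)
})

test_that("minute series are structurally valid and bout-classified", {
  set.seed(21)
  out <- generate_minute_series(sim_config(), "P1")
  expect_identical(nrow(out$series), 10080L)
  expect_true(all(out$series$steps >= 0))
  expect_true(all(out$series$minute == rep(0:1439, 7)))
  # truth accounts for every minute
  tr <- out$truth
  expect_equal(tr$true_walking_min + tr$true_moderate_min +
                 tr$true_vigorous_min + tr$true_sedentary_min +
                 tr$true_nonwear_min, 10080)
})

test_that("with artifacts off, nonwear detection finds exactly the generated bouts", {
  cfg <- noise_free(5)
  b <- generate_cohort(cfg, seed = 22, level = "minute")
  iv <- b$steps |> recode_spurious() |> detect_nonwear()
  totals <- tapply(iv$end - iv$start, iv$participant_id, sum)
  expected <- tapply(b$truth$true_nonwear_min, b$truth$participant_id, sum)
  expect_equal(as.numeric(totals[names(expected)]), as.numeric(expected))
})

test_that("full pipeline recovers generator truth exactly when noise is off", {
  cfg <- noise_free(5)
  b <- generate_cohort(cfg, seed = 23, level = "minute")
  days <- process_steps(b$steps)
  scored <- b$ipaq |> clean_ipaq() |> score_ipaq()
  obs <- build_observations(scored, days, meta = b$meta)
  expect_identical(nrow(obs), nrow(b$truth))
  m <- dplyr::inner_join(obs, b$truth, by = c("participant_id", "window_start"))
  expect_equal(m$fitbit_walking_time * 60, m$true_walking_min)
  expect_equal(m$fitbit_moderate_time, m$true_moderate_min)
  expect_equal(m$fitbit_vigorous_time, m$true_vigorous_min)
  expect_equal(m$fitbit_sedentary_time * 60, m$true_sedentary_min)
  expect_equal(m$fitbit_steps_per_day, m$true_steps_per_day)
  expect_equal(m$fitbit_wear_time, m$true_wear_h_day)
  # self-report side: scoring returns the true weekly minutes and MET-h
  expect_equal(m$ipaq_walking_time * 60, m$true_walking_min)
  expect_equal(m$ipaq_moderate_time, m$true_moderate_min)
  expect_equal(m$ipaq_vigorous_time, m$true_vigorous_min)
  expect_equal(m$ipaq_met_hours,
               3.3 * m$true_walking_min / 60 + 4.0 * m$true_moderate_min / 60 +
                 8.0 * m$true_vigorous_min / 60)
  expect_equal(m$ipaq_sedentary_time * 60 / 7, m$true_sitting_min_day)
})

test_that("recall bias factors scale reported activity multiplicatively", {
  cfg <- sim_config(n_participants = 500, recall_sd = 0,
                    recall_bias = c(walking = 1, moderate = 1,
                                    vigorous = 1.5, sitting = 1),
                    repeat_prob = 0)
  co <- generate_cohort(cfg, seed = 24)
  obs <- co$observations
  on <- co$truth$true_vigorous_min > 0
  ratio <- sum(obs$ipaq_vigorous_time[on]) / sum(co$truth$true_vigorous_min[on])
  expect_equal(ratio, 1.5, tolerance = 0.02)
})

test_that("walking under-report is detected by the paired signed-rank test", {
  cfg <- sim_config(n_participants = 200,
                    recall_bias = c(walking = 0.3, moderate = 1.3,
                                    vigorous = 3.0, sitting = 0.45),
                    repeat_prob = 0)
  co <- generate_cohort(cfg, seed = 25)
  obs <- co$observations
  res <- wilcoxon_signed_rank(obs$ipaq_walking_time, obs$fitbit_walking_time)
  expect_lt(res$p.value, 1e-6)
  expect_lt(median(obs$ipaq_walking_time - obs$fitbit_walking_time), 0)
})

test_that("null activity effects leave BMI unassociated with activity", {
  cfg <- sim_config(n_participants = 400,
                    activity_effects = c(sedentary = 0, walking = 0,
                                         moderate = 0, vigorous = 0,
                                         steps_per_day = 0))
  co <- generate_cohort(cfg, seed = 26)
  f <- fit_bmi_model(co$observations, "fitbit_steps_per_day", tier = "base")
  td <- tidy(f)
  i <- td$term == "fitbit_steps_per_day"
  expect_lt(abs(td$estimate[i] / td$std.error[i]), 4)
})

test_that("zero residual noise lets the regression recover effects exactly", {
  cfg <- sim_config(n_participants = 120, bmi_residual_sd = 0,
                    bmi_participant_sd = 0, repeat_prob = 0)
  co <- generate_cohort(cfg, seed = 27)
  d <- co$observations
  d$fitbit_moderate_h <- d$fitbit_moderate_time / 60
  d$fitbit_vigorous_h <- d$fitbit_vigorous_time / 60
  f <- fit_bmi_model(
    d, c("fitbit_sedentary_time", "fitbit_walking_time",
         "fitbit_moderate_h", "fitbit_vigorous_h"),
    adjusters = c("age", "gender", "smoking", "diabetes", "hypertension",
                  "hyperlipidemia"))
  td <- tidy(f)
  est <- setNames(td$estimate, td$term)
  expect_equal(est[["fitbit_sedentary_time"]], 0.08, tolerance = 1e-8)
  expect_equal(est[["fitbit_walking_time"]], -0.18, tolerance = 1e-8)
  expect_equal(est[["fitbit_moderate_h"]], -0.41, tolerance = 1e-8)
  expect_equal(est[["fitbit_vigorous_h"]], -0.84, tolerance = 1e-8)
})

test_that("artifact minutes appear at roughly the configured rate", {
  cfg <- sim_config(n_participants = 10, artifact_rate = 0.01,
                    repeat_prob = 0)
  b <- generate_cohort(cfg, seed = 28, level = "minute")
  rate <- mean(b$steps$steps > 200)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
})

test_that("infeasible daily schedules are refused", {
  day <- tibble::tibble(
    day = 1:7, sleep_min = 600L, extra_nonwear_min = 0L,
    walking_min = 700L, moderate_min = 100L, vigorous_min = 39L,
    sedentary_min = 1L
  )
  expect_error(
    actipair:::build_week_minutes(sim_config(), day, 0L, "P1",
                                  as.Date("2016-05-02")),
    "infeasible")
})

test_that("repeat observations create usable participant clusters", {
  co <- generate_cohort(sim_config(n_participants = 300, repeat_prob = 0.2),
                        seed = 29)
  counts <- table(co$observations$participant_id)
  expect_gt(sum(counts >= 2), 0)
  expect_identical(nrow(co$observations), nrow(co$truth))
})

test_that("cohort bundles write and read back as delimited text", {
  dir <- withr::local_tempdir()
  b <- generate_cohort(sim_config(n_participants = 2, repeat_prob = 0),
                       seed = 30, level = "minute")
  write_cohort(b, dir)
  s <- read_step_minutes(file.path(dir, "steps.csv"))
  expect_identical(nrow(s), nrow(b$steps))
  expect_identical(s$steps, b$steps$steps)
  r <- read_ipaq_responses(file.path(dir, "ipaq.csv"))
  expect_equal(nrow(r), nrow(b$ipaq))
})
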