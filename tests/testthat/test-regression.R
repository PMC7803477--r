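# small clustered data set with a known linear signal
mk_reg_data <- function(n_part = 40, obs_per = 2, beta = -0.5, noise = 1,
                        seed = 1) {
  set.seed(seed)
  id <- rep(sprintf("P%02d", 1:n_part), each = obs_per)
  n <- length(id)
  x <- runif(n, 0, 10)
  u <- rep(rnorm(n_part, 0, 1), each = obs_per)
  tibble::tibble(
    participant_id = id,
    x = x,
    bmi = 25 + beta * x + u * (noise > 0) + rnorm(n, 0, noise)
  )
}

test_that("zero-noise data is recovered exactly with zero SE", {
  d <- mk_reg_data(n_part = 20, obs_per = 1, beta = -0.5, noise = 0)
  d$bmi <- 25 - 0.5 * d$x
  f <- fit_bmi_model(d, "x", adjusters = character())
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "x"], -0.5)
  expect_equal(td$std.error[td$term == "x"], 0, tolerance = 1e-8)
})

test_that("point estimates equal ordinary least squares with singleton clusters", {
  d <- mk_reg_data(n_part = 30, obs_per = 1)
  f <- fit_bmi_model(d, "x", adjusters = character())
  ols <- lm(bmi ~ x, data = d)
  expect_equal(coef(f$model), coef(ols))
  # and cluster-robust SEs collapse to heteroskedasticity-robust HC1
  v_hc1 <- sandwich::vcovHC(ols, type = "HC1")
  expect_equal(unname(f$vcov), unname(v_hc1), tolerance = 1e-8)
})

test_that("cluster-robust covariance equals a first-principles sandwich", {
  d <- mk_reg_data(n_part = 25, obs_per = 3)
  f <- fit_bmi_model(d, "x", adjusters = character())
  v_oracle <- oracle_cluster_vcov(f$model, d$participant_id)
  expect_equal(unname(f$vcov), unname(v_oracle), tolerance = 1e-10)
})

test_that("standardized and natural units share t statistics and p-values", {
  d <- mk_reg_data(n_part = 35, obs_per = 2)
  f_nat <- fit_bmi_model(d, "x", adjusters = character())
  f_std <- fit_bmi_model(d, "x", adjusters = character(),
                         unit_mode = "standardized")
  t_nat <- tidy(f_nat); t_std <- tidy(f_std)
  expect_equal(t_std$statistic, t_nat$statistic, tolerance = 1e-10)
  expect_equal(t_std$p.value, t_nat$p.value, tolerance = 1e-10)
  i <- t_nat$term == "x"
  expect_equal(t_std$estimate[i], t_nat$estimate[i] * sd(d$x))
})

test_that("rank-deficient designs raise an error naming the collinear term", {
  d <- mk_reg_data()
  d$x2 <- d$x
  expect_error(fit_bmi_model(d, c("x", "x2"), adjusters = character()),
               "collinear")
})

test_that("comparing a model with itself gives zero difference, p = 1", {
  d <- mk_reg_data()
  f <- fit_bmi_model(d, "x", adjusters = character())
  res <- compare_coefficients(f, f)
  expect_equal(res$difference, 0)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
})

test_that("stacked-system point estimates reproduce the separate fits", {
  d <- mk_reg_data()
  set.seed(2)
  d$z <- d$x + rnorm(nrow(d), 0, 2)
  fx <- fit_bmi_model(d, "x", adjusters = character())
  fz <- fit_bmi_model(d, "z", adjusters = character())
  res <- compare_coefficients(fx, fz)
  expect_equal(res$fitbit_beta, tidy(fx)$estimate[2])
  expect_equal(res$ipaq_beta, tidy(fz)$estimate[2])
  expect_equal(res$difference, res$fitbit_beta - res$ipaq_beta)
  expect_identical(res$model_mode, "separate")
})

test_that("stacked-system p agrees with a cluster bootstrap oracle", {
  set.seed(3)
  n_part <- 60
  id <- rep(seq_len(n_part), each = 2)
  truth <- rep(rnorm(n_part, 5, 2), each = 2)
  d <- tibble::tibble(
    participant_id = sprintf("P%02d", id),
    dev = truth + rnorm(2 * n_part, 0, 0.5),
    self = truth + rnorm(2 * n_part, 0, 2),
    bmi = 27 - 0.4 * truth + rep(rnorm(n_part, 0, 1), each = 2) +
      rnorm(2 * n_part, 0, 1)
  )
  fd <- fit_bmi_model(d, "dev", adjusters = character())
  fs <- fit_bmi_model(d, "self", adjusters = character())
  res <- compare_coefficients(fd, fs)
  # cluster bootstrap of the coefficient difference
  rows_by_id <- split(seq_len(nrow(d)), d$participant_id)
  boots <- replicate(600, {
    idx <- unlist(rows_by_id[sample(length(rows_by_id), replace = TRUE)])
    db <- d[idx, ]
    coef(lm(bmi ~ dev, db))[["dev"]] - coef(lm(bmi ~ self, db))[["self"]]
  })
  z_boot <- res$difference / sd(boots)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_lt(abs(res$p_value - p_boot), 0.06)
})

test_that("combined-model contrast uses the within-model covariance", {
  d <- mk_reg_data()
  set.seed(4)
  d$z <- d$x + rnorm(nrow(d), 0, 2)
  fc <- fit_bmi_model(d, c("x", "z"), adjusters = character())
  res <- compare_coefficients(fc)
  td <- tidy(fc)
  expect_equal(res$fitbit_beta, td$estimate[td$term == "x"])
  expect_equal(res$ipaq_beta, td$estimate[td$term == "z"])
  expect_identical(res$model_mode, "combined")
  # hand-computed Wald from the stored covariance
  v <- fc$vcov
  dd <- res$difference
  expect_equal(res$wald_statistic, dd^2 / (v[2, 2] + v[3, 3] - 2 * v[2, 3]))
})

test_that("the model battery emits the full 12 + 6 family layout per tier", {
  co <- generate_cohort(sim_config(n_participants = 150), seed = 5)
  b <- fit_model_battery(co$observations)
  g <- glance(b)
  expect_identical(g$n_models, 54L)
  expect_identical(g$n_separate, 36L)
  expect_identical(g$n_combined, 18L)
  counts <- table(b$models$tier, b$models$model_mode)
  expect_true(all(counts == 6L))
  td <- tidy(b)
  expect_identical(nrow(td), 36L * 1L + 18L * 2L)  # 1 activity term per
  # separate model, 2 per combined
  expect_identical(sort(unique(td$measure)),
                   c("active", "moderate", "overall", "sedentary",
                     "vigorous", "walking"))
  # overall runs standardized, the rest natural
  expect_true(all(td$unit_mode[td$measure == "overall"] == "standardized"))
  expect_true(all(td$unit_mode[td$measure != "overall"] == "natural"))
})

test_that("identical analogous predictors break the combined model", {
  co <- generate_cohort(sim_config(n_participants = 80), seed = 6)
  d <- co$observations
  d$ipaq_walking_time <- d$fitbit_walking_time
  expect_error(
    fit_bmi_model(d, c("fitbit_walking_time", "ipaq_walking_time"),
                  tier = "base"),
    "collinear")
})

test_that("sensitivity exclusions filter and re-run; no-op when unflagged", {
  co <- generate_cohort(sim_config(n_participants = 120), seed = 7)
  d <- co$observations
  main <- fit_model_battery(d, tiers = "base")
  sens <- run_sensitivity(d, "mobiletrack", tiers = "base")
  expect_identical(sens$n_excluded, sum(d$data_source == "mobiletrack"))
  expect_identical(glance(sens$battery)$n,
                   nrow(d) - sens$n_excluded)
  # unflagged data: identical results
  d2 <- d; d2$data_source <- "tracker"
  sens2 <- run_sensitivity(d2, "mobiletrack", tiers = "base")
  expect_equal(tidy(sens2$battery), tidy(fit_model_battery(d2, tiers = "base")))
  # everything flagged: explicit error
  d3 <- d; d3$data_source <- "mobiletrack"
  expect_error(run_sensitivity(d3, "mobiletrack"), "every observation")
})

test_that("coefficient comparison holds its nominal size under the null", {
  # two predictors with equal true effects and equal noise: the
  # device-vs-self-report contrast is null, so rejections at 0.05
  # should be near nominal
  set.seed(31)
  reps <- 1000
  n <- 100
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    truth <- rnorm(n, 5, 2)
    d <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      a = truth + rnorm(n),
      b = truth + rnorm(n),
      bmi = 27 - 0.3 * truth + rnorm(n)
    )
    fa <- fit_bmi_model(d, "a", adjusters = character())
    fb <- fit_bmi_model(d, "b", adjusters = character())
    rej[r] <- compare_coefficients(fa, fb)$p_value < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
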