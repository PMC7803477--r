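#' Synthetic cohort generator configuration
#'
#' Parameters of the synthetic free-living cohort: bout-structured minute
#' step traces with overnight nonwear and artifact minutes, recall-biased
#' IPAQ short-form responses, covariates drawn from cohort-like
#' marginals, and a BMI outcome built from configured activity and
#' covariate effects with a participant-level random intercept (so
#' repeated observations are clustered).
#'
#' Activity defaults are calibrated loosely to the study cohort's
#' summary distributions (median around 8600 steps/d with a
#' between-participant SD near 3700; wear time around 17 h/d; moderate
#' activity near 75 min/wk). Recall bias factors default to the observed
#' direction of self-report discrepancy: over-reporting of moderate and
#' vigorous activity, under-reporting of walking and sitting. Activity
#' effects on BMI (kg/m2 per true h/wk) default to the fully adjusted
#' separate-model coefficient scale: sedentary +0.08, walking -0.18,
#' moderate -0.41, vigorous -0.84; the steps/d effect defaults to 0
#' because steps/d is a deterministic combination of the intensity
#' times (enable it, and zero the others, to study the overall-activity
#' association: -1.37 per 3663 steps/d is the matching scale).
#'
#' @param n_participants Cohort size. Default 586.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param walking_min_day Mean true walking minutes/day (walking occurs
#'   daily, between 10 and 180 min/day so a 7-day recall can represent
#'   it).
#' @param moderate_min_active_day,vigorous_min_active_day Mean true
#'   minutes on a moderate-active (10--120) or vigorous-active (10--90)
#'   day.
#' @param moderate_days_probs Probabilities of 2--5 moderate days/week.
#' @param vigorous_days_probs Probabilities of 0--3 vigorous days/week.
#' @param between_sd Lognormal SD of the participant activity multiplier.
#' @param day_sd Lognormal SD of day-to-day activity variation.
#' @param cadence Per-intensity truncated-normal cadence parameters
#'   (steps/min), centred within the classification bins; the walking
#'   entry is the within-minute spread around a participant's own mean
#'   cadence.
#' @param walking_cadence_mean,walking_cadence_sd Between-participant
#'   distribution of mean walking cadence (steps/min), truncated to
#'   \[15, 90\].
#' @param sedentary_step_probs Probabilities of 0--9 steps in a worn
#'   sedentary minute.
#' @param sleep_min_day_mean,sleep_min_day_sd Overnight nonwear block
#'   (minutes), truncated to \[240, 720\].
#' @param extra_nonwear_prob Probability of an additional daytime nonwear
#'   bout (uniform 120--240 min).
#' @param artifact_rate Fraction of minutes replaced by >200-step
#'   artifacts.
#' @param recall_sd Lognormal SD of multiplicative recall error.
#' @param recall_bias Named multiplicative reporting-bias factors for
#'   `walking`, `moderate`, `vigorous`, `sitting`.
#' @param bmi_intercept,bmi_residual_sd,bmi_participant_sd BMI model
#'   intercept (kg/m2), within-participant residual SD and
#'   between-participant random-intercept SD.
#' @param activity_effects Named vector: BMI change per true h/wk of
#'   `sedentary`, `walking`, `moderate`, `vigorous` and per true step/d
#'   (`steps_per_day`).
#' @param covariate_effects Named vector of BMI effects: per year of age
#'   (centred at 50), and additive shifts for female gender, current
#'   smoking, diabetes, hypertension, hyperlipidemia.
#' @param torso_prob,mobiletrack_prob Device wear-location and
#'   data-source probabilities.
#' @param repeat_prob Per-slot probability governing extra observations
#'   (each participant gets `1 + Binomial(2, repeat_prob)` windows).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 586,
                       seed = 20260930,
                       walking_min_day = 140,
                       moderate_min_active_day = 22,
                       moderate_days_probs = c(0.20, 0.35, 0.30, 0.15),
                       vigorous_min_active_day = 15,
                       vigorous_days_probs = c(0.25, 0.30, 0.30, 0.15),
                       between_sd = 0.52,
                       day_sd = 0.20,
                       cadence = list(
                         walking = c(mean = 40, sd = 8),
                         moderate = c(mean = 115, sd = 7),
                         vigorous = c(mean = 160, sd = 12)
                       ),
                       walking_cadence_mean = 40,
                       walking_cadence_sd = 16,
                       sedentary_step_probs = c(0.35, 0.17, 0.12, 0.09,
                                                0.07, 0.06, 0.05, 0.04,
                                                0.03, 0.02),
                       sleep_min_day_mean = 420,
                       sleep_min_day_sd = 45,
                       extra_nonwear_prob = 0.10,
                       artifact_rate = 0.001,
                       recall_sd = 0.6,
                       recall_bias = c(walking = 0.2, moderate = 1.3,
                                       vigorous = 3.0, sitting = 0.45),
                       bmi_intercept = 23.4,
                       bmi_residual_sd = 3.5,
                       bmi_participant_sd = 3.5,
                       activity_effects = c(sedentary = 0.08,
                                            walking = -0.18,
                                            moderate = -0.41,
                                            vigorous = -0.84,
                                            steps_per_day = 0),
                       covariate_effects = c(age = 0.03,
                                             gender_female = -0.5,
                                             smoking_current = 0.8,
                                             diabetes = 1.8,
                                             hypertension = 1.2,
                                             hyperlipidemia = 0.6),
                       torso_prob = 0.285,
                       mobiletrack_prob = 0.055,
                       repeat_prob = 0.095) {
  stopifnot(
    n_participants >= 1,
    abs(sum(vigorous_days_probs) - 1) < 1e-8,
    abs(sum(moderate_days_probs) - 1) < 1e-8,
    abs(sum(sedentary_step_probs) - 1) < 1e-8,
    artifact_rate >= 0, artifact_rate <= 1,
    recall_sd >= 0, all(recall_bias > 0),
    bmi_residual_sd >= 0, bmi_participant_sd >= 0,
    torso_prob >= 0, torso_prob <= 1,
    mobiletrack_prob >= 0, mobiletrack_prob <= 1,
    repeat_prob >= 0, repeat_prob <= 1
  )
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_participants, "participants; artifact rate",
      x$artifact_rate, "; recall sd", x$recall_sd, "\n")
  invisible(x)
}

# mean of N(mu, sd) truncated to [a, b]
tnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

rtnorm <- function(n, mu, sd, a, b) {
  qnorm(runif(n, pnorm((a - mu) / sd), pnorm((b - mu) / sd))) * sd + mu
}

# expected steps in one minute of each class, given the config; the
# walking mean is per participant (their own mean cadence)
class_step_means <- function(cfg, walk_cadence = cfg$walking_cadence_mean) {
  b <- activity_config()$cadence_bins
  list(
    sedentary = sum((0:9) * cfg$sedentary_step_probs),
    walking = tnorm_mean(walk_cadence,
                         cfg$cadence$walking[["sd"]], b$walking[1], b$walking[2]),
    moderate = tnorm_mean(cfg$cadence$moderate[["mean"]],
                          cfg$cadence$moderate[["sd"]], b$moderate[1], b$moderate[2]),
    vigorous = tnorm_mean(cfg$cadence$vigorous[["mean"]],
                          cfg$cadence$vigorous[["sd"]], b$vigorous[1], b$vigorous[2])
  )
}

# split a total into bout lengths within [min_len, max_len] (last bout
# absorbs any short remainder)
chop_bouts <- function(total, min_len, max_len) {
  if (total <= 0) return(integer())
  lens <- integer()
  remaining <- total
  while (remaining > 0) {
    len <- min(remaining, sample(min_len:max_len, 1))
    if (remaining - len < min_len && remaining - len > 0) {
      len <- remaining
    }
    lens <- c(lens, len)
    remaining <- remaining - len
  }
  lens
}

# per-observation truth: daily minute allocations as n x 7 matrices
generate_truth <- function(cfg, n_obs_total, activity_level,
                           walk_cadence = NULL) {
  n <- n_obs_total
  a <- activity_level
  if (is.null(walk_cadence)) {
    walk_cadence <- rtnorm(n, cfg$walking_cadence_mean,
                           cfg$walking_cadence_sd, 15, 90)
  }
  daily <- function() matrix(rlnorm(7L * n, -cfg$day_sd^2 / 2, cfg$day_sd),
                             n, 7)
  # walking happens daily within the range a 7-day recall can represent
  walk <- pmin(pmax(round(cfg$walking_min_day * a * daily()), 10), 180)
  mod_days <- sample(2:5, n, replace = TRUE, prob = cfg$moderate_days_probs)
  on_m <- t(apply(matrix(runif(7L * n), n, 7), 1, rank)) <= mod_days
  mod <- matrix(0, n, 7)
  mmin <- pmin(pmax(round(cfg$moderate_min_active_day * a * daily()), 10), 120)
  mod[on_m] <- mmin[on_m]
  vig_days <- sample(0:3, n, replace = TRUE, prob = cfg$vigorous_days_probs)
  # a random subset of vig_days[i] days of the week is vigorous-active
  on <- t(apply(matrix(runif(7L * n), n, 7), 1, rank)) <= vig_days
  vig <- matrix(0, n, 7)
  vmin <- pmin(pmax(round(cfg$vigorous_min_active_day * a * daily()), 10), 90)
  vig[on] <- vmin[on]
  sleep <- matrix(round(rtnorm(7L * n, cfg$sleep_min_day_mean,
                               cfg$sleep_min_day_sd, 240, 720)), n, 7)
  extra <- matrix(sample(120:240, 7L * n, replace = TRUE) *
                    (runif(7L * n) < cfg$extra_nonwear_prob), n, 7)
  # keep each day feasible: activity + nonwear + 2 boundary minutes <= 1440
  extra[(sleep + extra + walk + mod + vig) > 1436] <- 0
  sed <- 1440 - sleep - extra - walk - mod - vig
  list(walk = walk, mod = mod, vig = vig, sleep = sleep, extra = extra,
       sed = sed, vigorous_days = vig_days, walk_cadence = walk_cadence)
}

# one observation's day-level truth as a 7-row tibble (minute assembly)
day_truth_row <- function(tr, i) {
  tibble(
    day = 1:7,
    sleep_min = tr$sleep[i, ], extra_nonwear_min = tr$extra[i, ],
    walking_min = tr$walk[i, ], moderate_min = tr$mod[i, ],
    vigorous_min = tr$vig[i, ], sedentary_min = tr$sed[i, ]
  )
}

weekly_truth_table <- function(tr, cfg) {
  mu <- class_step_means(cfg, tr$walk_cadence)
  nonwear <- rowSums(tr$sleep) + rowSums(tr$extra)
  steps <- mu$walking * rowSums(tr$walk) +
    mu$moderate * rowSums(tr$mod) +
    mu$vigorous * rowSums(tr$vig) +
    mu$sedentary * rowSums(tr$sed)
  tibble(
    true_walking_min = rowSums(tr$walk),
    true_moderate_min = rowSums(tr$mod),
    true_vigorous_min = rowSums(tr$vig),
    true_sedentary_min = rowSums(tr$sed),
    true_nonwear_min = nonwear,
    true_steps_per_day = steps / 7,
    true_wear_h_day = (10080 - nonwear) / 7 / 60,
    walking_days = rowSums(tr$walk > 0),
    moderate_days = rowSums(tr$mod > 0),
    vigorous_days = tr$vigorous_days,
    true_sitting_min_day = rowSums(tr$sed) / 7
  )
}

#' Generate one participant-week of minute-level steps
#'
#' Assembles 7 x 1440 minutes from an overnight zero-step (nonwear)
#' block, optional daytime nonwear bouts, a sedentary background of
#' 0--9 step minutes, and contiguous activity bouts whose cadences are
#' drawn from truncated normals inside the classification bins.
#' Sedentary minutes touching a nonwear block are forced nonzero so the
#' generated nonwear bouts are exactly the maximal zero runs, keeping
#' the truth ledger consistent with the emitted minutes by
#' construction. Artifact minutes (>200 steps) are then injected at the
#' configured rate. Uses the current RNG state; seed upstream.
#'
#' @param config A [sim_config()].
#' @param participant_id Identifier for the emitted rows.
#' @param window_start First calendar day of the week.
#' @return List with `series` (a minute-series tibble) and `truth`
#'   (one-row weekly truth tibble).
#' @export
generate_minute_series <- function(config, participant_id = "P1",
                                   window_start = as.Date("2016-05-02")) {
  cfg <- config
  tr <- generate_truth(cfg, 1L, activity_level = rlnorm(1, 0, cfg$between_sd))
  build_week_minutes(cfg, day_truth_row(tr, 1), tr$vigorous_days[1],
                     participant_id, window_start, tr$walk_cadence[1])
}

build_week_minutes <- function(cfg, day_truth, vig_days, participant_id,
                               window_start, walk_cadence = NULL) {
  b <- activity_config()$cadence_bins
  if (is.null(walk_cadence)) walk_cadence <- cfg$walking_cadence_mean
  draw_cadence <- function(n, which) {
    p <- cfg$cadence[[which]]
    centre <- if (which == "walking") walk_cadence else p[["mean"]]
    round(rtnorm(n, centre, p[["sd"]], b[[which]][1], b[[which]][2]))
  }
  sed_draw <- function(n) sample(0:9, n, replace = TRUE,
                                 prob = cfg$sedentary_step_probs)
  days <- vector("list", 7)
  for (d in 1:7) {
    row <- day_truth[d, ]
    if (row$sedentary_min < 2) abort("infeasible schedule: bout demand exceeds day length")
    segs <- list()
    for (bt in chop_bouts(row$walking_min, 10, 40)) {
      segs <- c(segs, list(draw_cadence(bt, "walking")))
    }
    for (bt in chop_bouts(row$moderate_min, 5, 15)) {
      segs <- c(segs, list(draw_cadence(bt, "moderate")))
    }
    for (bt in chop_bouts(row$vigorous_min, 10, 30)) {
      segs <- c(segs, list(draw_cadence(bt, "vigorous")))
    }
    if (row$extra_nonwear_min > 0) {
      segs <- c(segs, list(rep(0L, row$extra_nonwear_min)))
    }
    segs <- segs[sample.int(length(segs))]
    n_gap <- length(segs) + 1L
    sed_total <- row$sedentary_min
    if (sed_total < n_gap) abort("infeasible schedule: bout demand exceeds day length")
    gap_len <- as.integer(stats::rmultinom(1, sed_total - n_gap,
                                           rep(1, n_gap))) + 1L
    gaps <- lapply(gap_len, function(len) {
      g <- sed_draw(len)
      g[1] <- max(g[1], sample(1:9, 1))       # shield zero runs at both ends
      g[len] <- max(g[len], sample(1:9, 1))
      g
    })
    pieces <- vector("list", 2 * length(segs) + 2)
    pieces[[1]] <- rep(0L, row$sleep_min)
    for (k in seq_along(segs)) {
      pieces[[2 * k]] <- gaps[[k]]
      pieces[[2 * k + 1]] <- segs[[k]]
    }
    pieces[[2 * length(segs) + 2]] <- gaps[[n_gap]]
    days[[d]] <- as.integer(unlist(pieces))
  }
  steps <- unlist(days)
  stopifnot(length(steps) == 10080L)
  truth <- tibble(
    true_walking_min = sum(day_truth$walking_min),
    true_moderate_min = sum(day_truth$moderate_min),
    true_vigorous_min = sum(day_truth$vigorous_min),
    true_sedentary_min = sum(day_truth$sedentary_min),
    true_nonwear_min = sum(day_truth$sleep_min + day_truth$extra_nonwear_min),
    true_steps_per_day = sum(steps) / 7,      # realised, pre-artifact
    true_wear_h_day = (10080 - sum(day_truth$sleep_min +
                                     day_truth$extra_nonwear_min)) / 7 / 60,
    walking_days = sum(day_truth$walking_min > 0),
    moderate_days = sum(day_truth$moderate_min > 0),
    vigorous_days = vig_days,
    true_sitting_min_day = sum(day_truth$sedentary_min) / 7
  )
  if (cfg$artifact_rate > 0) {
    hit <- runif(10080) < cfg$artifact_rate
    steps[hit] <- sample(201:240, sum(hit), replace = TRUE)
  }
  series <- tibble(
    participant_id = participant_id,
    date = rep(window_start + 0:6, each = 1440L),
    minute = rep(0:1439, times = 7L),
    steps = steps
  )
  list(series = series, truth = truth)
}

#' Generate a recall-biased IPAQ response from truth
#'
#' Reported weekly minutes per intensity are the true weekly minutes
#' times an intensity-specific bias factor times multiplicative
#' lognormal recall noise, then expressed as days/week (the true number
#' of active days) and minutes/day. Sitting minutes/day are treated the
#' same way. Minutes are rounded to whole minutes only when noise or
#' bias is active, so the zero-noise, unit-bias limit reproduces truth
#' exactly. Uses the current RNG state.
#'
#' @param truth One-row-per-observation truth tibble (from the
#'   generator), with `participant_id` and `response_date` context
#'   columns present.
#' @param config A [sim_config()].
#' @return A raw IPAQ response tibble (see [read_ipaq_responses()]).
#' @export
generate_ipaq <- function(truth, config) {
  cfg <- config
  n <- nrow(truth)
  noisy <- cfg$recall_sd > 0 || any(cfg$recall_bias != 1)
  rep_week <- function(true_min, bias) {
    x <- true_min * bias * rlnorm(n, -cfg$recall_sd^2 / 2, cfg$recall_sd)
    x
  }
  per_day <- function(week_min, days) {
    m <- if_else(days > 0, week_min / days, 0)
    if (noisy) round(m) else m
  }
  w <- rep_week(truth$true_walking_min, cfg$recall_bias[["walking"]])
  m <- rep_week(truth$true_moderate_min, cfg$recall_bias[["moderate"]])
  v <- rep_week(truth$true_vigorous_min, cfg$recall_bias[["vigorous"]])
  sit <- truth$true_sitting_min_day * cfg$recall_bias[["sitting"]] *
    rlnorm(n, -cfg$recall_sd^2 / 2, cfg$recall_sd)
  tibble(
    participant_id = truth$participant_id,
    response_date = truth$response_date,
    vigorous_days = if_else(v > 0, truth$vigorous_days, 0L),
    vigorous_min_day = per_day(v, truth$vigorous_days),
    moderate_days = if_else(m > 0, truth$moderate_days, 0L),
    moderate_min_day = per_day(m, truth$moderate_days),
    walking_days = if_else(w > 0, truth$walking_days, 0L),
    walking_min_day = per_day(w, truth$walking_days),
    sitting_min_day = if (noisy) round(sit) else sit
  )
}

generate_covariates <- function(cfg, ids) {
  n <- length(ids)
  tibble(
    participant_id = ids,
    age = round(rtnorm(n, 50, 14, 19, 92)),
    gender = sample(c("female", "male"), n, TRUE, c(0.597, 0.403)),
    education = sample(c("bachelor_plus", "lt_bachelor"), n, TRUE,
                       c(0.754, 0.246)),
    income = sample(c("gt_100k", "50_100k", "lt_50k"), n, TRUE,
                    c(0.54, 0.26, 0.20)),
    race = sample(c("white", "other"), n, TRUE, c(0.867, 0.133)),
    ethnicity = sample(c("non_hispanic", "hispanic"), n, TRUE,
                       c(0.95, 0.05)),
    smoking = sample(c("never", "former", "current"), n, TRUE,
                     c(0.60, 0.30, 0.10)),
    alcohol_wk = stats::rnbinom(n, size = 1.2, mu = 4.5),
    cad = rbinom(n, 1, 0.03),
    diabetes = rbinom(n, 1, 0.05),
    hyperlipidemia = rbinom(n, 1, 0.20),
    hypertension = rbinom(n, 1, 0.25)
  )
}

#' BMI outcome and covariates from truth
#'
#' Covariates are drawn from cohort-like marginals; BMI is the
#' configured intercept plus activity effects applied to *true* weekly
#' activity (hours) and true steps/d, plus covariate effects, plus a
#' participant-level random intercept and observation-level residual.
#' Uses the current RNG state.
#'
#' @param truth Per-observation truth tibble with `participant_id`.
#' @param config A [sim_config()].
#' @param covariates Optional pre-drawn participant covariate tibble.
#' @return List: `bmi` (numeric, one per truth row), `covariates`
#'   (participant-level tibble).
#' @export
generate_outcome_and_covariates <- function(truth, config, covariates = NULL) {
  cfg <- config
  ids <- unique(truth$participant_id)
  if (is.null(covariates)) covariates <- generate_covariates(cfg, ids)
  u <- setNames(rnorm(length(ids), 0, cfg$bmi_participant_sd), ids)
  cv <- covariates[match(truth$participant_id, covariates$participant_id), ]
  ae <- cfg$activity_effects
  ce <- cfg$covariate_effects
  mu <- cfg$bmi_intercept +
    ae[["sedentary"]] * truth$true_sedentary_min / 60 +
    ae[["walking"]] * truth$true_walking_min / 60 +
    ae[["moderate"]] * truth$true_moderate_min / 60 +
    ae[["vigorous"]] * truth$true_vigorous_min / 60 +
    ae[["steps_per_day"]] * truth$true_steps_per_day +
    ce[["age"]] * (cv$age - 50) +
    ce[["gender_female"]] * (cv$gender == "female") +
    ce[["smoking_current"]] * (cv$smoking == "current") +
    ce[["diabetes"]] * cv$diabetes +
    ce[["hypertension"]] * cv$hypertension +
    ce[["hyperlipidemia"]] * cv$hyperlipidemia
  bmi <- mu + u[truth$participant_id] + rnorm(nrow(truth), 0, cfg$bmi_residual_sd)
  list(bmi = as.numeric(bmi), covariates = covariates)
}

#' Generate a full synthetic cohort
#'
#' Deterministic under `seed`. At `level = "weekly"` (the default,
#' suitable for statistical simulation studies) the device measures are
#' the truth-level weekly summaries — justified by the exact round-trip
#' property of the minute-level processing when artifacts are disabled —
#' and the result is an analysis-ready observation table. At
#' `level = "minute"` the full raw input bundle is produced (minute step
#' traces, raw IPAQ responses, anthropometry and covariate tables plus
#' the truth ledger) for end-to-end pipeline runs.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param level `"weekly"` or `"minute"`.
#' @return For `"weekly"`: list with `observations` (analysis-ready
#'   tibble with `fitbit_*`, `ipaq_*`, `bmi`, covariates, metadata) and
#'   `truth`. For `"minute"`: list with `steps`, `ipaq`, `anthropometry`,
#'   `covariates`, `meta`, `truth`.
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed,
                            level = c("weekly", "minute")) {
  level <- match.arg(level)
  cfg <- config
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(cfg$n_participants))
  n_obs <- 1L + rbinom(cfg$n_participants, 2, cfg$repeat_prob)
  a_p <- rlnorm(cfg$n_participants, 0, cfg$between_sd)
  cad_p <- rtnorm(cfg$n_participants, cfg$walking_cadence_mean,
                  cfg$walking_cadence_sd, 15, 90)
  meta <- tibble(
    participant_id = ids,
    device_location = sample(c("wrist", "torso"), cfg$n_participants, TRUE,
                             c(1 - cfg$torso_prob, cfg$torso_prob)),
    data_source = sample(c("tracker", "mobiletrack"), cfg$n_participants,
                         TRUE, c(1 - cfg$mobiletrack_prob, cfg$mobiletrack_prob))
  )
  # observation windows: base date per participant, repeats spaced onward
  obs_idx <- rep(seq_len(cfg$n_participants), n_obs)
  rank <- unlist(lapply(n_obs, seq_len))
  base <- as.Date("2014-01-06") + sample(0:1790, cfg$n_participants, TRUE)
  gaps <- round(runif(length(obs_idx), 30, 200))
  window_start <- base[obs_idx] + ave(gaps, obs_idx, FUN = cumsum) - gaps
  tr <- generate_truth(cfg, length(obs_idx), a_p[obs_idx],
                       walk_cadence = cad_p[obs_idx])
  minute_bundles <- NULL
  if (level == "minute") {
    minute_bundles <- vector("list", length(obs_idx))
    for (i in seq_along(obs_idx)) {
      minute_bundles[[i]] <- build_week_minutes(
        cfg, day_truth_row(tr, i), tr$vigorous_days[i],
        ids[obs_idx[i]], window_start[i], tr$walk_cadence[i])
    }
    truth <- list_rbind(map(minute_bundles, "truth"))
  } else {
    truth <- weekly_truth_table(tr, cfg)
  }
  truth <- bind_cols(
    tibble(participant_id = ids[obs_idx],
           observation_rank = rank,
           window_start = window_start,
           window_end = window_start + 6L,
           response_date = window_start + 7L,
           activity_level = a_p[obs_idx]),
    truth
  ) |> left_join(meta, by = "participant_id")
  ipaq_raw <- generate_ipaq(truth, cfg)
  out <- generate_outcome_and_covariates(truth, cfg)
  truth$bmi_true <- out$bmi
  if (level == "minute") {
    steps <- list_rbind(map(minute_bundles, "series"))
    anthro <- make_anthropometry(truth, out$bmi)
    cov_rec <- out$covariates |>
      left_join(truth |> filter(.data$observation_rank == 1L) |>
                  select("participant_id", "midpoint" = "window_start"),
                by = "participant_id") |>
      mutate(record_date = .data$midpoint + 3L +
               sample(-200:200, dplyr::n(), TRUE)) |>
      select(-"midpoint") |>
      select("participant_id", "record_date", dplyr::everything())
    return(list(steps = steps, ipaq = ipaq_raw, anthropometry = anthro,
                covariates = cov_rec, meta = meta, truth = truth))
  }
  scored <- ipaq_raw |> clean_ipaq() |> score_ipaq()
  obs <- bind_cols(
    truth |> select("participant_id", "window_start", "window_end",
                    "observation_rank", "device_location", "data_source"),
    tibble(
      midpoint = truth$window_start + 3L,
      season = assign_season(truth$window_start + 3L),
      fitbit_steps_per_day = truth$true_steps_per_day,
      fitbit_active_time = (truth$true_walking_min + truth$true_moderate_min +
                              truth$true_vigorous_min) / 60,
      fitbit_sedentary_time = truth$true_sedentary_min / 60,
      fitbit_walking_time = truth$true_walking_min / 60,
      fitbit_moderate_time = truth$true_moderate_min,
      fitbit_vigorous_time = truth$true_vigorous_min,
      fitbit_wear_time = truth$true_wear_h_day,
      ipaq_walking_time = scored$walking_time,
      ipaq_sedentary_time = scored$sedentary_time,
      ipaq_active_time = scored$active_time,
      ipaq_moderate_time = scored$moderate_time,
      ipaq_vigorous_time = scored$vigorous_time,
      ipaq_met_hours = scored$met_hours,
      bmi = out$bmi
    )
  ) |> left_join(out$covariates, by = "participant_id")
  list(observations = obs, truth = truth)
}

make_anthropometry <- function(truth, bmi) {
  ids <- unique(truth$participant_id)
  height <- setNames(rtnorm(length(ids), 1.70, 0.09, 1.45, 2.05), ids)
  h <- height[truth$participant_id]
  n <- nrow(truth)
  report1 <- tibble(
    participant_id = truth$participant_id,
    report_date = truth$window_start + 3L + sample(-60:60, n, TRUE),
    height = round(h, 2),
    weight = round(bmi * h^2, 1),
    bmi_selfreport = NA_real_
  )
  has_self <- runif(n) < 0.5
  report2 <- tibble(
    participant_id = truth$participant_id[has_self],
    report_date = truth$window_start[has_self] + 3L +
      sample(-60:60, sum(has_self), TRUE),
    height = NA_real_,
    weight = NA_real_,
    bmi_selfreport = round(bmi[has_self] + rnorm(sum(has_self), 0, 0.3), 1)
  )
  bind_rows(report1, report2) |>
    arrange(.data$participant_id, .data$report_date)
}

#' Write a synthetic cohort bundle as delimited text
#'
#' Writes the tables of a `level = "minute"` bundle (steps, IPAQ,
#' anthropometry, covariates, metadata, truth ledger) as CSV files in
#' `dir`. The truth ledger is kept in a separate file from the pipeline
#' inputs.
#'
#' @param bundle Result of `generate_cohort(level = "minute")`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  steps <- bundle$steps |>
    mutate(timestamp = sprintf("%sT%02d:%02d:00", .data$date,
                               .data$minute %/% 60, .data$minute %% 60)) |>
    select("participant_id", "timestamp", "steps")
  readr::write_csv(steps, file.path(dir, "steps.csv"))
  readr::write_csv(bundle$ipaq, file.path(dir, "ipaq.csv"))
  readr::write_csv(bundle$anthropometry, file.path(dir, "anthropometry.csv"))
  readr::write_csv(bundle$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(bundle$meta, file.path(dir, "meta.csv"))
  readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
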