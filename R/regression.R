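tier_levels <- c("base", "demographics", "full")

#' Adjustment covariates for a model tier
#'
#' Models at every tier adjust for device wear time, device wear
#' location and season; the `demographics` tier adds age, gender,
#' education, income, race and ethnicity; the `full` tier further adds
#' smoking, alcohol use and clinical flags (coronary artery disease,
#' diabetes, hyperlipidemia, hypertension).
#'
#' @param tier One of `"base"`, `"demographics"`, `"full"`.
#' @return Character vector of covariate column names.
#' @export
tier_covariates <- function(tier = tier_levels) {
  tier <- match.arg(tier)
  base <- c("fitbit_wear_time", "device_location", "season")
  demo <- c("age", "gender", "education", "income", "race", "ethnicity")
  behav <- c("smoking", "alcohol_wk", "cad", "diabetes", "hyperlipidemia",
             "hypertension")
  switch(tier,
         base = base,
         demographics = c(base, demo),
         full = c(base, demo, behav))
}

#' Cluster-robust linear regression of BMI on activity
#'
#' Fits untransformed BMI by least squares on one or more activity
#' predictors plus the tier's adjustment covariates, with a
#' cluster-robust sandwich covariance grouped by participant using the
#' small-sample correction `G/(G-1) * (N-1)/(N-K)`. In standardized
#' mode each activity predictor is divided by its sample standard
#' deviation over the analysis rows, so coefficients are per 1 SD.
#' Confidence intervals use the normal critical value by default
#' (`ci = "normal"`); `ci = "t"` uses a t distribution on G-1 degrees
#' of freedom.
#'
#' @param data Observation-level data frame.
#' @param predictors Character vector of activity predictor columns
#'   (one for a separate model, two analogous measures for a combined
#'   head-to-head model).
#' @param tier Adjustment tier (see [tier_covariates()]).
#' @param unit_mode `"natural"` or `"standardized"`.
#' @param cluster Column identifying the participant cluster.
#' @param outcome Outcome column (default `"bmi"`).
#' @param adjusters Override for the adjustment covariates (`character()`
#'   for an unadjusted fit); default `NULL` uses [tier_covariates()].
#' @param ci `"normal"` or `"t"`.
#' @return Object of class `bmi_fit`; see [tidy.bmi_fit()] and
#'   [glance.bmi_fit()].
#' @export
fit_bmi_model <- function(data, predictors, tier = "base",
                          unit_mode = c("natural", "standardized"),
                          cluster = "participant_id", outcome = "bmi",
                          adjusters = NULL, ci = c("normal", "t")) {
  unit_mode <- match.arg(unit_mode)
  ci <- match.arg(ci)
  tier <- match.arg(tier, tier_levels)
  if (is.null(adjusters)) adjusters <- tier_covariates(tier)
  used <- c(outcome, predictors, adjusters, cluster)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[used]), used, drop = FALSE]
  n <- nrow(d)
  cl <- d[[cluster]]
  g <- length(unique(cl))
  if (g < 2) abort("need at least 2 clusters")
  sds <- NULL
  if (unit_mode == "standardized") {
    sds <- vapply(d[predictors], sd, numeric(1))
    if (any(sds == 0)) abort("cannot standardize a constant predictor")
    for (p in predictors) d[[p]] <- d[[p]] / sds[[p]]
  }
  rhs <- c(predictors, adjusters)
  fml <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", outcome))
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste("rank-deficient design; collinear terms:",
                paste(bad, collapse = ", ")))
  }
  v <- sandwich::vcovCL(fit, cluster = cl, type = "HC1", cadjust = TRUE)
  x <- model.matrix(fit)
  structure(
    list(model = fit, vcov = v, predictors = predictors,
         predictor_terms = sprintf("`%s`", predictors),
         tier = tier, unit_mode = unit_mode, ci = ci,
         n_obs = n, n_clusters = g, cluster = cl,
         X = x, y = d[[outcome]], sds = sds, outcome = outcome),
    class = "bmi_fit"
  )
}

crit_value <- function(object) {
  if (object$ci == "t") stats::qt(0.975, df = object$n_clusters - 1)
  else qnorm(0.975)
}

#' Tidy a cluster-robust BMI fit
#'
#' @param x A `bmi_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` (cluster-robust; 95% CI
#'   `beta +/- 1.96 * SE` under the default normal critical value).
#' @method tidy bmi_fit
#' @export
tidy.bmi_fit <- function(x, ...) {
  b <- coef(x$model)
  se <- sqrt(diag(x$vcov))
  z <- b / se
  crit <- crit_value(x)
  p <- if (x$ci == "t") 2 * pt(-abs(z), df = x$n_clusters - 1) else 2 * pnorm(-abs(z))
  tibble(term = names(b), estimate = unname(b), std.error = unname(se),
         statistic = unname(z), p.value = unname(p),
         conf.low = unname(b - crit * se), conf.high = unname(b + crit * se))
}

#' @rdname tidy.bmi_fit
#' @method glance bmi_fit
#' @export
glance.bmi_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(n = x$n_obs, n_clusters = x$n_clusters, r.squared = s$r.squared,
         tier = x$tier, unit_mode = x$unit_mode)
}

#' @export
print.bmi_fit <- function(x, ...) {
  cat(sprintf("<bmi_fit> %s ~ %s  [tier %s, %s units]\n", x$outcome,
              paste(x$predictors, collapse = " + "), x$tier, x$unit_mode))
  cat(sprintf("  n = %d observations, %d participant clusters\n",
              x$n_obs, x$n_clusters))
  td <- tidy(x)
  print(td[td$term %in% c(x$predictors, x$predictor_terms), ])
  invisible(x)
}

term_index <- function(fit, predictor) {
  nm <- colnames(fit$X)
  i <- which(nm == predictor | nm == sprintf("`%s`", predictor))
  if (length(i) != 1L) abort(paste("predictor term not found:", predictor))
  i
}

#' Wald comparison of device versus self-report coefficients
#'
#' For two separate models fit on the same observations and clusters,
#' the equations are re-estimated jointly as a stacked system (block
#' diagonal design, outcomes duplicated) sharing the participant-level
#' cluster covariance, and the difference of the two activity
#' coefficients is Wald-tested against zero. For a combined model the
#' contrast is tested within the single cluster-robust covariance.
#'
#' @param fit_a A `bmi_fit` for the device measure, or a combined
#'   two-predictor fit if `fit_b` is `NULL`.
#' @param fit_b A `bmi_fit` for the analogous self-report measure, or
#'   `NULL`.
#' @return One-row tibble of class `coef_comparison`: `fitbit_beta`,
#'   `ipaq_beta`, `difference`, `wald_statistic`, `p_value`,
#'   `model_mode`.
#' @export
compare_coefficients <- function(fit_a, fit_b = NULL) {
  if (is.null(fit_b)) {
    if (length(fit_a$predictors) != 2L) {
      abort("combined comparison needs a fit with exactly 2 activity predictors")
    }
    i <- term_index(fit_a, fit_a$predictors[1])
    j <- term_index(fit_a, fit_a$predictors[2])
    b <- coef(fit_a$model)
    diff <- b[[i]] - b[[j]]
    var_d <- fit_a$vcov[i, i] + fit_a$vcov[j, j] - 2 * fit_a$vcov[i, j]
    res <- tibble(fitbit_beta = b[[i]], ipaq_beta = b[[j]],
                  difference = diff,
                  wald_statistic = diff^2 / var_d,
                  p_value = pchisq(diff^2 / var_d, df = 1, lower.tail = FALSE),
                  model_mode = "combined")
    class(res) <- c("coef_comparison", class(res))
    return(res)
  }
  if (fit_a$n_obs != fit_b$n_obs || !identical(fit_a$cluster, fit_b$cluster) ||
      !isTRUE(all.equal(fit_a$y, fit_b$y))) {
    abort("models must be estimated on the same observations and clusters")
  }
  xa <- fit_a$X; xb <- fit_b$X
  colnames(xa) <- paste0("eqA_", colnames(xa))
  colnames(xb) <- paste0("eqB_", colnames(xb))
  xs <- rbind(cbind(xa, matrix(0, nrow(xa), ncol(xb),
                               dimnames = list(NULL, colnames(xb)))),
              cbind(matrix(0, nrow(xb), ncol(xa),
                           dimnames = list(NULL, colnames(xa))), xb))
  ys <- c(fit_a$y, fit_b$y)
  cls <- c(fit_a$cluster, fit_b$cluster)
  sfit <- lm(ys ~ 0 + xs)
  names(sfit$coefficients) <- colnames(xs)
  v <- sandwich::vcovCL(sfit, cluster = cls, type = "HC1", cadjust = TRUE)
  dimnames(v) <- list(colnames(xs), colnames(xs))
  ia <- paste0("eqA_", colnames(fit_a$X)[term_index(fit_a, fit_a$predictors[1])])
  ib <- paste0("eqB_", colnames(fit_b$X)[term_index(fit_b, fit_b$predictors[1])])
  b <- coef(sfit)
  diff <- b[[ia]] - b[[ib]]
  var_d <- v[ia, ia] + v[ib, ib] - 2 * v[ia, ib]
  res <- tibble(fitbit_beta = b[[ia]], ipaq_beta = b[[ib]],
                difference = diff,
                wald_statistic = diff^2 / var_d,
                p_value = pchisq(diff^2 / var_d, df = 1, lower.tail = FALSE),
                model_mode = "separate")
  class(res) <- c("coef_comparison", class(res))
  res
}

battery_measures <- function() {
  tibble(
    measure = c("sedentary", "walking", "moderate", "vigorous",
                "active", "overall"),
    fitbit = c("fitbit_sedentary_time", "fitbit_walking_time",
               "fitbit_moderate_h", "fitbit_vigorous_h",
               "fitbit_active_time", "fitbit_steps_per_day"),
    ipaq = c("ipaq_sedentary_time", "ipaq_walking_time",
             "ipaq_moderate_h", "ipaq_vigorous_h",
             "ipaq_active_time", "ipaq_met_hours"),
    unit_mode = c("natural", "natural", "natural", "natural",
                  "natural", "standardized")
  )
}

#' Fit the full BMI model battery
#'
#' For each of the 6 analogous activity measure pairs (sedentary,
#' walking, moderate and vigorous time, total active time, overall
#' activity) fits, at every adjustment tier, the two separate
#' single-predictor models (12 separate families) and the combined
#' head-to-head model (6 combined families), each with cluster-robust
#' errors, plus the device-versus-self-report Wald comparisons for both
#' constructions. Intensity times are analysed in h/wk in natural
#' units; overall activity (steps/d versus MET-h/wk) is standardized
#' because the scales differ. `unit_mode = "standardized"` standardizes
#' every measure instead.
#'
#' @param data The BMI analysis set (see [make_analysis_sets()]).
#' @param tiers Adjustment tiers to run (default all three).
#' @param unit_mode `"paper"` (natural for intensities, standardized for
#'   overall) or `"standardized"`.
#' @param cluster Participant cluster column.
#' @return Object of class `model_battery`: list with `models` (one row
#'   per measure x tier x model with the `bmi_fit` in a list column) and
#'   `comparisons` (one row per measure x tier x construction).
#' @export
fit_model_battery <- function(data, tiers = tier_levels,
                              unit_mode = c("paper", "standardized"),
                              cluster = "participant_id") {
  unit_mode <- match.arg(unit_mode)
  tiers <- match.arg(tiers, tier_levels, several.ok = TRUE)
  d <- data
  d$fitbit_moderate_h <- d$fitbit_moderate_time / 60
  d$fitbit_vigorous_h <- d$fitbit_vigorous_time / 60
  d$ipaq_moderate_h <- d$ipaq_moderate_time / 60
  d$ipaq_vigorous_h <- d$ipaq_vigorous_time / 60
  spec <- battery_measures()
  if (unit_mode == "standardized") spec$unit_mode <- "standardized"
  models <- list(); comparisons <- list()
  for (tier in tiers) {
    for (m in seq_len(nrow(spec))) {
      um <- spec$unit_mode[m]
      # common complete cases so the separate fits share observations
      need <- c("bmi", spec$fitbit[m], spec$ipaq[m], tier_covariates(tier),
                cluster)
      dm <- d[stats::complete.cases(d[need]), , drop = FALSE]
      ff <- fit_bmi_model(dm, spec$fitbit[m], tier = tier, unit_mode = um,
                          cluster = cluster)
      fi <- fit_bmi_model(dm, spec$ipaq[m], tier = tier, unit_mode = um,
                          cluster = cluster)
      fc <- fit_bmi_model(dm, c(spec$fitbit[m], spec$ipaq[m]), tier = tier,
                          unit_mode = um, cluster = cluster)
      models <- c(models, list(
        tibble(measure = spec$measure[m], tier = tier, unit_mode = um,
               model_mode = c("separate_fitbit", "separate_ipaq", "combined"),
               fit = list(ff, fi, fc))
      ))
      comparisons <- c(comparisons, list(
        bind_cols(tibble(measure = spec$measure[m], tier = tier),
                  bind_rows(compare_coefficients(ff, fi),
                            compare_coefficients(fc)))
      ))
    }
  }
  structure(list(models = list_rbind(models),
                 comparisons = list_rbind(comparisons)),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat(sprintf("<model_battery> %d models (%d measures x %d tiers), %d Wald comparisons\n",
              nrow(x$models), length(unique(x$models$measure)),
              length(unique(x$models$tier)), nrow(x$comparisons)))
  invisible(x)
}

#' Tidy a model battery into a coefficient table
#'
#' One row per activity predictor per model, mirroring the layout of
#' the device-versus-self-report coefficient tables.
#'
#' @param x A `model_battery`.
#' @param ... Unused.
#' @return Tibble with `measure`, `tier`, `model_mode`, `unit_mode`,
#'   `instrument`, `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @method tidy model_battery
#' @export
tidy.model_battery <- function(x, ...) {
  pmap(x$models, function(measure, tier, unit_mode, model_mode, fit) {
    td <- tidy(fit)
    td <- td[td$term %in% c(fit$predictors, fit$predictor_terms), ]
    td$term <- gsub("`", "", td$term)
    td$instrument <- if_else(grepl("^fitbit_", td$term), "fitbit", "ipaq")
    bind_cols(tibble(measure = measure, tier = tier, model_mode = model_mode,
                     unit_mode = unit_mode),
              td[c("instrument", "term", "estimate", "std.error",
                   "conf.low", "conf.high", "p.value")])
  }) |> list_rbind()
}

#' @rdname tidy.model_battery
#' @method glance model_battery
#' @export
glance.model_battery <- function(x, ...) {
  tibble(n_models = nrow(x$models),
         n_separate = sum(grepl("^separate", x$models$model_mode)),
         n_combined = sum(x$models$model_mode == "combined"),
         n_tiers = length(unique(x$models$tier)),
         n = x$models$fit[[1]]$n_obs,
         n_clusters = x$models$fit[[1]]$n_clusters)
}

#' Exclusion sensitivity analysis
#'
#' Excludes observations from the named cohort (the mobile-phone-derived
#' step source, or torso-worn devices) and re-runs the measure agreement
#' correlations and the full model battery on the remainder.
#'
#' @param data The BMI analysis set, with `data_source` and
#'   `device_location` columns.
#' @param exclusion `"mobiletrack"` (drop `data_source == "mobiletrack"`)
#'   or `"torso"` (drop `device_location == "torso"`).
#' @param ... Passed to [fit_model_battery()].
#' @return List: `battery`, `agreement` (rank-1 correlations, if
#'   `observation_rank` is present), `n_excluded`, `fraction_excluded`.
#' @export
run_sensitivity <- function(data, exclusion = c("mobiletrack", "torso"), ...) {
  exclusion <- match.arg(exclusion)
  flag <- switch(exclusion,
                 mobiletrack = data$data_source == "mobiletrack",
                 torso = data$device_location == "torso")
  if (anyNA(flag)) abort("exclusion flag column contains NA")
  keep <- data[!flag, , drop = FALSE]
  if (nrow(keep) == 0L) abort("exclusion removes every observation")
  agreement <- NULL
  if ("observation_rank" %in% names(keep)) {
    first <- keep[keep$observation_rank == 1L, , drop = FALSE]
    agreement <- try(compare_measures(first), silent = TRUE)
    if (inherits(agreement, "try-error")) agreement <- NULL
  }
  list(battery = fit_model_battery(keep, ...),
       agreement = agreement,
       n_excluded = sum(flag),
       fraction_excluded = mean(flag))
}

#' Device versus self-report measure agreement
#'
#' For each analogous measure pair computes the Spearman rank
#' correlation and, for same-unit measures, the Wilcoxon matched-pairs
#' signed-rank test, with per-instrument medians. Overall activity is
#' measured on different scales (steps/d versus MET-h/wk) so only the
#' correlation is reported there.
#'
#' @param data Observation-level data (typically the rank-1 comparative
#'   set).
#' @return Tibble: one row per measure with `spearman_rho`,
#'   `spearman_p`, `wilcoxon_v`, `wilcoxon_p`, `fitbit_median`,
#'   `ipaq_median`, `n`.
#' @export
compare_measures <- function(data) {
  d <- data
  d$fitbit_moderate_h <- d$fitbit_moderate_time / 60
  d$fitbit_vigorous_h <- d$fitbit_vigorous_time / 60
  d$ipaq_moderate_h <- d$ipaq_moderate_time / 60
  d$ipaq_vigorous_h <- d$ipaq_vigorous_time / 60
  spec <- battery_measures()
  pmap(spec, function(measure, fitbit, ipaq, unit_mode) {
    x <- d[[fitbit]]; y <- d[[ipaq]]
    sp <- spearman_cor(x, y)
    same_units <- measure != "overall"
    wl <- if (same_units) wilcoxon_signed_rank(y, x) else NULL
    tibble(measure = measure,
           spearman_rho = sp$estimate, spearman_p = sp$p.value,
           wilcoxon_v = if (same_units) wl$statistic else NA_real_,
           wilcoxon_p = if (same_units) wl$p.value else NA_real_,
           fitbit_median = median(x, na.rm = TRUE),
           ipaq_median = median(y, na.rm = TRUE),
           n = sp$n)
  }) |> list_rbind()
}
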