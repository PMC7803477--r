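#' Season of a date
#'
#' Meteorological mapping by month: Mar--May spring, Jun--Aug summer,
#' Sep--Nov fall, Dec--Feb winter.
#'
#' @param date A `Date` vector (typically the window midpoint).
#' @return Factor with levels spring, summer, fall, winter.
#' @export
assign_season <- function(date) {
  m <- as.integer(format(date, "%m"))
  s <- dplyr::case_when(
    m %in% 3:5 ~ "spring",
    m %in% 6:8 ~ "summer",
    m %in% 9:11 ~ "fall",
    TRUE ~ "winter"
  )
  factor(s, levels = c("spring", "summer", "fall", "winter"))
}

#' Pair IPAQ recall windows with adequate device weeks
#'
#' An activity observation is a 7-day window recalled on the IPAQ for
#' which the same 7 days have adequate device data. The recall window is
#' anchored to the 7 days ending the day before the response date. An
#' observation is emitted only when all 7 window days meet the day-level
#' adequacy rule (all-7 gating by default; see
#' `week_min_adequate_days` in [activity_config()]). Duplicate responses
#' by the same participant on the same date keep the first. Observation
#' rank orders windows by start date within participant.
#'
#' @param ipaq_scored Scored IPAQ tibble from [score_ipaq()].
#' @param day_summaries Day-summary tibble from [summarize_days()].
#' @param meta Optional tibble keyed by `participant_id` with observation
#'   metadata such as `device_location` (wrist/torso) and `data_source`
#'   (tracker/mobiletrack), joined onto the output.
#' @param config An [activity_config()].
#' @return Observation tibble: one row per emitted observation with
#'   `fitbit_*`-prefixed weekly device measures, `ipaq_*`-prefixed
#'   self-report measures, `window_start`, `window_end`, `season`,
#'   `observation_rank`.
#' @export
build_observations <- function(ipaq_scored, day_summaries, meta = NULL,
                               config = activity_config()) {
  resp <- ipaq_scored |>
    filter(.data$valid) |>
    distinct(.data$participant_id, .data$response_date, .keep_all = TRUE)
  day_key <- day_summaries |>
    select("participant_id", "date", "adequate")
  obs <- resp |>
    mutate(window_start = .data$response_date - 7L,
           window_end = .data$response_date - 1L)
  keep <- logical(nrow(obs))
  weeks <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    days <- day_summaries |>
      filter(.data$participant_id == obs$participant_id[i],
             .data$date >= obs$window_start[i],
             .data$date <= obs$window_end[i])
    if (nrow(days) != 7L || sum(days$adequate) < config$week_min_adequate_days) next
    keep[i] <- TRUE
    weeks[[i]] <- summarize_week(days, config)
  }
  obs <- obs[keep, , drop = FALSE]
  if (nrow(obs) == 0L) {
    return(tibble(participant_id = character(), window_start = as.Date(character()),
                  window_end = as.Date(character()), observation_rank = integer()))
  }
  fb <- list_rbind(weeks[keep]) |>
    select(-"participant_id", -"window_start", -"window_end") |>
    rename_with_prefix("fitbit_")
  ip <- obs |>
    select("walking_time", "sedentary_time", "active_time", "moderate_time",
           "vigorous_time", "met_hours") |>
    rename_with_prefix("ipaq_")
  out <- bind_cols(
    obs |> select("participant_id", "response_date", "window_start",
                  "window_end"),
    fb, ip
  ) |>
    mutate(
      midpoint = .data$window_start + 3L,
      season = assign_season(.data$window_start + 3L)
    ) |>
    arrange(.data$participant_id, .data$window_start) |>
    group_by(.data$participant_id) |>
    mutate(observation_rank = row_number()) |>
    ungroup()
  if (!is.null(meta)) {
    out <- left_join(out, mutate(meta, participant_id = as.character(.data$participant_id)),
                     by = "participant_id")
  }
  out
}

rename_with_prefix <- function(df, prefix) {
  names(df) <- paste0(prefix, names(df))
  df
}

#' Attach BMI to observations by proximity rules
#'
#' Weight and self-reported BMI values reported within 90 days of the
#' observation (window midpoint) are averaged; height values within 365
#' days are averaged. When averaged height and weight both exist they
#' give a calculated BMI (`weight / height^2`); the final BMI is the
#' median of the calculated and self-reported values when both exist
#' (the median of two values being their mean), else whichever exists,
#' else `NA`.
#'
#' @param obs Observation tibble from [build_observations()].
#' @param reports Anthropometry tibble: `participant_id`, `report_date`,
#'   and optional `height` (m), `weight` (kg), `bmi_selfreport` (kg/m2).
#'   Nonpositive heights or weights are rejected.
#' @param weight_window,height_window Day windows for the proximity
#'   rules (defaults 90 and 365).
#' @return `obs` with an added `bmi` column.
#' @export
merge_bmi <- function(obs, reports, weight_window = 90, height_window = 365) {
  for (col in c("height", "weight", "bmi_selfreport")) {
    if (!col %in% names(reports)) reports[[col]] <- NA_real_
    if (any(reports[[col]] <= 0, na.rm = TRUE)) {
      abort(paste("nonpositive", col, "in anthropometry reports"))
    }
  }
  reports <- mutate(reports, participant_id = as.character(.data$participant_id))
  obs$bmi <- vapply(seq_len(nrow(obs)), function(i) {
    r <- reports[reports$participant_id == obs$participant_id[i], ]
    dd <- as.numeric(r$report_date - obs$midpoint[i])
    w <- mean(r$weight[abs(dd) <= weight_window], na.rm = TRUE)
    h <- mean(r$height[abs(dd) <= height_window], na.rm = TRUE)
    b_self <- mean(r$bmi_selfreport[abs(dd) <= weight_window], na.rm = TRUE)
    b_calc <- if (is.finite(w) && is.finite(h)) w / h^2 else NA_real_
    if (!is.finite(b_self)) b_self <- NA_real_
    both <- c(b_calc, b_self)
    if (all(is.na(both))) NA_real_ else median(both, na.rm = TRUE)
  }, numeric(1))
  obs
}

#' Attach the closest covariate record to each observation
#'
#' Selects, per observation, the covariate questionnaire record with the
#' smallest absolute distance between its date and the window midpoint,
#' among records within 365 days; equidistant ties go to the earlier
#' record. Observations with no qualifying record get `NA` covariates.
#'
#' @param obs Observation tibble (with `midpoint`).
#' @param records Covariate tibble: `participant_id`, `record_date`, plus
#'   covariate columns.
#' @param window Day window for the proximity rule (default 365).
#' @return `obs` with covariate columns joined.
#' @export
attach_covariates <- function(obs, records, window = 365) {
  records <- mutate(records, participant_id = as.character(.data$participant_id))
  cov_cols <- setdiff(names(records), c("participant_id", "record_date"))
  picked <- map(seq_len(nrow(obs)), function(i) {
    r <- records[records$participant_id == obs$participant_id[i], ]
    dd <- as.numeric(r$record_date - obs$midpoint[i])
    r <- r[abs(dd) <= window, ]
    dd <- dd[abs(dd) <= window]
    if (nrow(r) == 0L) return(tibble(!!!setNames(rep(list(NA), length(cov_cols)),
                                                 cov_cols)))
    # ties toward the earlier record: order by |distance|, then by date
    ord <- order(abs(dd), r$record_date)
    r[ord[1], cov_cols]
  })
  bind_cols(obs, list_rbind(picked))
}

#' Split observations into the comparative and BMI analysis sets
#'
#' The comparative set keeps the first (rank-1) observation per
#' participant. The BMI set keeps all observations with a BMI and
#' complete covariates (participants may contribute several); a rank-1
#' restricted view of the BMI set is also returned for bivariate
#' analyses.
#'
#' @param obs Observation tibble with `bmi` and covariates attached.
#' @param covariate_cols Character vector of columns that must be
#'   complete for the BMI set; defaults to every column after `bmi`
#'   that is not an observation field.
#' @return List with tibbles `comparative`, `bmi`, `bmi_first`.
#' @export
make_analysis_sets <- function(obs, covariate_cols = NULL) {
  if (nrow(obs) == 0L) {
    return(list(comparative = obs, bmi = obs, bmi_first = obs))
  }
  if (is.null(covariate_cols)) {
    known <- c("participant_id", "response_date", "window_start", "window_end",
               "midpoint", "season", "observation_rank", "bmi",
               "device_location", "data_source")
    covariate_cols <- setdiff(names(obs),
                              c(known, grep("^(fitbit|ipaq)_", names(obs),
                                            value = TRUE)))
  }
  comparative <- filter(obs, .data$observation_rank == 1L)
  complete <- !is.na(obs$bmi)
  for (col in covariate_cols) complete <- complete & !is.na(obs[[col]])
  bmi <- obs[complete, , drop = FALSE]
  list(
    comparative = comparative,
    bmi = bmi,
    bmi_first = filter(bmi, .data$observation_rank == 1L)
  )
}
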