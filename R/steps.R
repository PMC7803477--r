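#' Read a minute-level step-count table
#'
#' Reads delimited text with columns `participant_id`, `timestamp`
#' (ISO-8601, minute resolution) and `steps`, and expands it to a complete
#' minute grid: one row per participant per minute from the first to the
#' last calendar day observed, minutes absent from the feed filled with
#' `NA` (missing).
#'
#' @param path Path to a delimited text file (delimiter sniffed by readr).
#' @return A minute-series tibble with columns `participant_id`, `date`,
#'   `minute` (0--1439 from local midnight) and `steps` (integer or `NA`).
#' @export
read_step_minutes <- function(path) {
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "timestamp", "steps")
  if (!all(need %in% names(raw))) {
    abort(paste("step table must have columns:", paste(need, collapse = ", ")))
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC")
  as_minute_series(tibble(
    participant_id = as.character(raw$participant_id),
    date = as.Date(ts, tz = "UTC"),
    minute = as.integer(format(ts, "%H", tz = "UTC")) * 60L +
      as.integer(format(ts, "%M", tz = "UTC")),
    steps = as.integer(raw$steps)
  ))
}

#' Normalise a step table to a complete minute grid
#'
#' Ensures every participant has `date`/`minute` rows covering whole
#' calendar days (a multiple of 1440 minutes), strictly ordered, with
#' absent minutes filled as `NA`. Negative step values are rejected.
#'
#' @param df Tibble with `participant_id`, `date`, `minute`, `steps`.
#' @return The completed, ordered minute-series tibble.
#' @export
as_minute_series <- function(df) {
  stopifnot(all(c("participant_id", "date", "minute", "steps") %in% names(df)))
  if (any(df$steps < 0, na.rm = TRUE)) abort("step counts must be >= 0")
  if (any(df$minute < 0 | df$minute > 1439)) abort("minute must be in 0..1439")
  if (anyDuplicated(df[c("participant_id", "date", "minute")])) {
    abort("duplicate participant/date/minute rows")
  }
  grid <- df |>
    group_by(.data$participant_id) |>
    summarise(first_day = min(.data$date), last_day = max(.data$date),
              .groups = "drop") |>
    mutate(days = map2(.data$first_day, .data$last_day, seq, by = "day")) |>
    select("participant_id", "days") |>
    tidyr::unnest("days") |>
    rename(date = "days") |>
    tidyr::expand_grid(minute = 0:1439)
  grid |>
    left_join(df, by = c("participant_id", "date", "minute")) |>
    arrange(.data$participant_id, .data$date, .data$minute)
}

#' Recode spurious minutes as missing
#'
#' Minutes with more than `config$spurious_steps` steps (default 200) are
#' physiologically implausible device artifacts and are recoded to missing.
#' All other minutes are unchanged; the transform is idempotent.
#'
#' @param series A minute-series tibble (see [as_minute_series()]).
#' @param config An [activity_config()].
#' @return The series with artifact minutes set to `NA`; the number of
#'   recoded minutes is in attribute `n_recoded`.
#' @export
recode_spurious <- function(series, config = activity_config()) {
  bad <- !is.na(series$steps) & series$steps > config$spurious_steps
  series$steps[bad] <- NA_integer_
  attr(series, "n_recoded") <- sum(bad)
  series
}

# maximal runs of TRUE with length >= min_len; returns 0-based half-open
# [start, end) offsets into the logical vector
runs_at_least <- function(flag, min_len) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  tibble(start = (ends - r$lengths)[keep], end = ends[keep])
}

#' Detect nonwear intervals
#'
#' Nonwear time is any maximal run of at least `config$nonwear_min_run`
#' (default 120) contiguous minutes with 0 steps counted. Runs may span
#' midnight; missing minutes break a run (they are not zero-step minutes).
#'
#' @param series A minute-series tibble with spurious minutes already
#'   recoded.
#' @param config An [activity_config()].
#' @return Tibble `participant_id`, `start`, `end`: disjoint, sorted,
#'   half-open minute offsets from each participant's series start
#'   (minute 0 = local midnight of the first day).
#' @export
detect_nonwear <- function(series, config = activity_config()) {
  series |>
    group_by(.data$participant_id) |>
    summarise(
      iv = list(runs_at_least(!is.na(.data$steps) & .data$steps == 0L,
                              config$nonwear_min_run)),
      .groups = "drop"
    ) |>
    tidyr::unnest("iv")
}

# class labels in reporting order
minute_classes <- c("nonwear", "missing", "sedentary", "walking",
                    "moderate", "vigorous")

# per-participant vector classification; steps is the full ordered vector
classify_vector <- function(steps, config) {
  if (any(steps > config$spurious_steps, na.rm = TRUE)) {
    abort("steps > spurious threshold present; run recode_spurious() first")
  }
  nz <- runs_at_least(!is.na(steps) & steps == 0L, config$nonwear_min_run)
  nonwear <- rep(FALSE, length(steps))
  for (i in seq_len(nrow(nz))) nonwear[(nz$start[i] + 1):nz$end[i]] <- TRUE
  if (config$sedentary_rule == "strict_bout") {
    lowr <- runs_at_least(!is.na(steps) & steps >= config$cadence_bins$sedentary[1] &
                            steps <= config$cadence_bins$sedentary[2],
                          config$nonwear_min_run)
    for (i in seq_len(nrow(lowr))) nonwear[(lowr$start[i] + 1):lowr$end[i]] <- TRUE
  }
  b <- config$cadence_bins
  cls <- dplyr::case_when(
    nonwear ~ "nonwear",
    is.na(steps) ~ "missing",
    steps >= b$sedentary[1] & steps <= b$sedentary[2] ~ "sedentary",
    steps >= b$walking[1] & steps <= b$walking[2] ~ "walking",
    steps >= b$moderate[1] & steps <= b$moderate[2] ~ "moderate",
    steps >= b$vigorous[1] & steps <= b$vigorous[2] ~ "vigorous"
  )
  factor(cls, levels = minute_classes)
}

#' Classify each minute by wear status and cadence intensity
#'
#' Minutes inside nonwear intervals are `nonwear`; absent or recoded
#' minutes are `missing`; remaining (worn) minutes are binned by cadence:
#' sedentary 0--9, walking 10--100, moderate 101--130, vigorous 131--200
#' steps/min (closed integer ranges, configurable). With
#' `sedentary_rule = "worn"` (default) any worn minute at 0--9 steps is
#' sedentary regardless of bout length, the 120-minute exclusion applying
#' only to all-zero runs.
#'
#' @inheritParams detect_nonwear
#' @return The series with an added factor column `class`.
#' @export
classify_minutes <- function(series, config = activity_config()) {
  series |>
    group_by(.data$participant_id) |>
    mutate(class = classify_vector(.data$steps, config)) |>
    ungroup()
}

#' Summarise classified minutes by calendar day
#'
#' Wear minutes are worn time only: `1440 - nonwear - missing` by default
#' (recoded artifacts and absent minutes count toward neither wear nor
#' nonwear; set `missing_counts_as_wear` in the config to include them).
#' A day is adequate when wear time is at least
#' `config$adequate_wear_minutes` (default 600 = 10 h).
#'
#' @param series A classified minute series (see [classify_minutes()]).
#' @param config An [activity_config()].
#' @return Tibble with one row per participant-day: `wear_minutes`,
#'   `steps_total`, per-class minute counts, and `adequate`.
#' @export
summarize_days <- function(series, config = activity_config()) {
  if (!"class" %in% names(series)) abort("run classify_minutes() first")
  out <- series |>
    group_by(.data$participant_id, .data$date) |>
    summarise(
      steps_total = sum(.data$steps, na.rm = TRUE),
      nonwear_minutes = sum(.data$class == "nonwear"),
      missing_minutes = sum(.data$class == "missing"),
      sedentary_minutes = sum(.data$class == "sedentary"),
      walking_minutes = sum(.data$class == "walking"),
      moderate_minutes = sum(.data$class == "moderate"),
      vigorous_minutes = sum(.data$class == "vigorous"),
      .groups = "drop"
    )
  wear <- 1440L - out$nonwear_minutes -
    if (config$missing_counts_as_wear) 0L else out$missing_minutes
  out |>
    mutate(wear_minutes = wear,
           adequate = wear >= config$adequate_wear_minutes) |>
    select("participant_id", "date", "wear_minutes", "steps_total",
           dplyr::ends_with("_minutes"), "adequate")
}

#' Summarise one 7-day window into weekly activity measures
#'
#' Expects exactly 7 consecutive day summaries for one participant, all
#' adequate (with the default `week_min_adequate_days = 7`; a lower
#' setting admits weeks with at least that many adequate days and rescales
#' sums from the adequate days to a 7-day week).
#'
#' @param day_summaries A 7-row day-summary tibble (see
#'   [summarize_days()]) for a single participant window.
#' @param config An [activity_config()].
#' @return One-row tibble: `steps_per_day` (mean steps/d), `active_time`,
#'   `sedentary_time`, `walking_time` (h/wk), `moderate_time`,
#'   `vigorous_time` (min/wk), `wear_time` (mean h/d), `n_adequate_days`.
#' @export
summarize_week <- function(day_summaries, config = activity_config()) {
  d <- day_summaries
  if (nrow(d) != 7L) abort("a week needs exactly 7 day summaries")
  if (length(unique(d$participant_id)) != 1L) {
    abort("day summaries must belong to one participant")
  }
  d <- arrange(d, .data$date)
  if (!all(diff(d$date) == 1)) abort("days must be consecutive")
  n_ok <- sum(d$adequate)
  if (n_ok < config$week_min_adequate_days) {
    abort(sprintf("only %d of 7 days adequate (need >= %d)",
                  n_ok, config$week_min_adequate_days))
  }
  use <- if (config$week_min_adequate_days < 7L) d[d$adequate, ] else d
  scale <- 7 / nrow(use)   # 1 unless rescaling is enabled
  tibble(
    participant_id = d$participant_id[1],
    window_start = d$date[1],
    window_end = d$date[7],
    steps_per_day = mean(use$steps_total),
    active_time = scale * sum(use$walking_minutes + use$moderate_minutes +
                                use$vigorous_minutes) / 60,
    sedentary_time = scale * sum(use$sedentary_minutes) / 60,
    walking_time = scale * sum(use$walking_minutes) / 60,
    moderate_time = scale * sum(use$moderate_minutes),
    vigorous_time = scale * sum(use$vigorous_minutes),
    wear_time = mean(use$wear_minutes) / 60,
    n_adequate_days = n_ok
  )
}

#' Process raw minute steps end to end
#'
#' Convenience wrapper: completes the minute grid, recodes spurious
#' minutes, classifies, and summarises by day.
#'
#' @param series A minute-series tibble (or raw `participant_id`, `date`,
#'   `minute`, `steps` rows).
#' @param config An [activity_config()].
#' @return A day-summary tibble (see [summarize_days()]).
#' @export
process_steps <- function(series, config = activity_config()) {
  series |>
    as_minute_series() |>
    recode_spurious(config) |>
    classify_minutes(config) |>
    summarize_days(config)
}
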