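#' Read IPAQ short-form responses
#'
#' Reads delimited text with columns `participant_id`, `response_date`,
#' and per intensity (`vigorous`, `moderate`, `walking`) `\*_days`
#' (days/week, integer 0--7) and `\*_min_day` (minutes/day), plus
#' `sitting_min_day`. Missing/refused entries are `NA`.
#'
#' @param path Path to a delimited text file.
#' @return A raw-response tibble.
#' @export
read_ipaq_responses <- function(path) {
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "response_date",
            "vigorous_days", "vigorous_min_day",
            "moderate_days", "moderate_min_day",
            "walking_days", "walking_min_day", "sitting_min_day")
  if (!all(need %in% names(raw))) {
    abort(paste("IPAQ table must have columns:", paste(need, collapse = ", ")))
  }
  raw |>
    mutate(participant_id = as.character(.data$participant_id),
           response_date = as.Date(.data$response_date)) |>
    as_tibble()
}

ipaq_intensities <- c("walking", "moderate", "vigorous")

#' Clean IPAQ short-form responses
#'
#' Applies the short-form scoring-protocol cleaning rules, in order:
#' (1) daily episodes shorter than `ipaq_min_episode` minutes (default 10)
#' are recoded to 0; (2) minutes/day per intensity are truncated at
#' `ipaq_max_minutes` (default 180); (3) responses whose reported summed
#' activity exceeds `ipaq_max_total` minutes/day (default 960, judged on
#' the values as reported, before truncation) are marked invalid.
#' Days/week outside 0--7 invalidate the response. Every applied rule is
#' recorded in `cleaning_flags`; original values are retained in
#' `\*_raw` columns.
#'
#' @param raw A raw-response tibble (see [read_ipaq_responses()]).
#' @param config An [activity_config()].
#' @return The cleaned tibble with added `valid` (logical) and
#'   `cleaning_flags` (list of character) columns.
#' @export
clean_ipaq <- function(raw, config = activity_config()) {
  out <- raw
  flags <- vector("list", nrow(out))
  for (i in seq_along(flags)) flags[[i]] <- character()
  add_flag <- function(which, flag) {
    for (i in which(which)) flags[[i]] <<- c(flags[[i]], flag)
  }
  total_raw <- rep(0, nrow(out))
  for (int in ipaq_intensities) {
    mcol <- paste0(int, "_min_day")
    dcol <- paste0(int, "_days")
    out[[paste0(mcol, "_raw")]] <- out[[mcol]]
    out[[paste0(dcol, "_raw")]] <- out[[dcol]]
    m <- out[[mcol]]
    total_raw <- total_raw + if_else(is.na(m), 0, m)
    low <- !is.na(m) & m > 0 & m < config$ipaq_min_episode
    m[low] <- 0
    add_flag(low, paste0("min_", config$ipaq_min_episode, ":", int))
    high <- !is.na(m) & m > config$ipaq_max_minutes
    m[high] <- config$ipaq_max_minutes
    add_flag(high, paste0("truncate_", config$ipaq_max_minutes, ":", int))
    out[[mcol]] <- m
    bad_days <- !is.na(out[[dcol]]) &
      (out[[dcol]] < 0 | out[[dcol]] > 7 | out[[dcol]] != round(out[[dcol]]))
    add_flag(bad_days, paste0("bad_days:", int))
  }
  over <- total_raw > config$ipaq_max_total
  add_flag(over, paste0("exceeds_", config$ipaq_max_total))
  invalid <- over | vapply(flags, function(f) any(grepl("^bad_days", f)), TRUE)
  out$valid <- !invalid
  out$cleaning_flags <- flags
  out
}

#' Score cleaned IPAQ responses into weekly measures
#'
#' Weekly minutes per intensity are `days_per_week * minutes_per_day`.
#' Overall activity in MET-h/wk is the MET-weighted sum of weekly hours
#' (defaults: walking 3.3, moderate 4.0, vigorous 8.0). Sitting is asked
#' per day; weekly sedentary time is `7 * sitting_minutes / 60`.
#' Responses marked invalid by [clean_ipaq()] are refused (scored as
#' `NA` with `valid = FALSE`).
#'
#' @param cleaned A cleaned tibble from [clean_ipaq()].
#' @param config An [activity_config()] carrying the MET multipliers.
#' @return Tibble with one row per response: `participant_id`,
#'   `response_date`, `walking_time`, `sedentary_time`, `active_time`
#'   (h/wk), `moderate_time`, `vigorous_time` (min/wk), `met_hours`
#'   (MET-h/wk), `valid`, `cleaning_flags`.
#' @export
score_ipaq <- function(cleaned, config = activity_config()) {
  if (!"valid" %in% names(cleaned)) abort("run clean_ipaq() first")
  mets <- config$met_values
  wk <- function(int) {
    d <- cleaned[[paste0(int, "_days")]]
    m <- cleaned[[paste0(int, "_min_day")]]
    if_else(!is.na(d) & d == 0, 0, d * m)    # 0 days means none that week
  }
  w_min <- wk("walking"); m_min <- wk("moderate"); v_min <- wk("vigorous")
  res <- tibble(
    participant_id = cleaned$participant_id,
    response_date = cleaned$response_date,
    walking_time = w_min / 60,
    sedentary_time = 7 * cleaned$sitting_min_day / 60,
    active_time = (w_min + m_min + v_min) / 60,
    moderate_time = m_min,
    vigorous_time = v_min,
    met_hours = mets[["walking"]] * w_min / 60 +
      mets[["moderate"]] * m_min / 60 +
      mets[["vigorous"]] * v_min / 60,
    valid = cleaned$valid,
    cleaning_flags = cleaned$cleaning_flags
  )
  num <- c("walking_time", "sedentary_time", "active_time",
           "moderate_time", "vigorous_time", "met_hours")
  for (col in num) res[[col]][!res$valid] <- NA_real_
  res
}
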