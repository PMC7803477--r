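#' Processing configuration
#'
#' All thresholds used by the minute-level step processing, the IPAQ
#' cleaning/scoring rules, and the observation-gating rules live in one
#' configuration object so that alternative rules can be swapped in without
#' touching pipeline code.
#'
#' Defaults implement the study rules: spurious-minute recoding above 200
#' steps/min, nonwear as runs of at least 120 contiguous zero-step minutes,
#' day adequacy at 600 minutes (10 h) of wear, cadence bins
#' sedentary 0--9, walking 10--100, moderate 101--130, vigorous 131--200
#' steps/min, and the public IPAQ short-form scoring protocol
#' (10-minute episode floor, 180-minute daily cap per intensity,
#' invalidation above 960 summed minutes/day, MET multipliers 3.3 walking,
#' 4.0 moderate, 8.0 vigorous).
#'
#' @param spurious_steps Minutes with more than this many steps are recoded
#'   to missing (artifact rule). Default 200.
#' @param nonwear_min_run Minimum length, in minutes, of a contiguous
#'   zero-step run counted as nonwear. Default 120.
#' @param adequate_wear_minutes Minimum daily wear minutes for a day to be
#'   adequate. Default 600 (10 hours).
#' @param cadence_bins Named list of closed integer cadence ranges
#'   (steps/min) for `sedentary`, `walking`, `moderate`, `vigorous`.
#' @param sedentary_rule `"worn"` (default): every worn minute with 0--9
#'   steps is sedentary, the 120-minute exclusion applying only to all-zero
#'   (nonwear) runs. `"strict_bout"`: additionally reclassify runs of
#'   at least `nonwear_min_run` minutes at 0--9 steps as nonwear, the
#'   literal low-step bout reading.
#' @param missing_counts_as_wear Should recoded/absent minutes count toward
#'   wear time? Default `FALSE`: a >200-step artifact implies a worn but
#'   unusable minute and is excluded from both wear and nonwear so adequacy
#'   denominators are not inflated.
#' @param ipaq_min_episode Daily minutes below this per intensity are
#'   recoded to 0. Default 10.
#' @param ipaq_max_minutes Daily minutes per intensity are truncated at this
#'   value. Default 180.
#' @param ipaq_max_total Responses whose reported (pre-truncation) summed
#'   activity exceeds this many minutes/day are marked invalid. Default 960.
#' @param met_values Named numeric MET multipliers for `walking`,
#'   `moderate`, `vigorous`. Defaults 3.3, 4.0, 8.0.
#' @param week_min_adequate_days Number of adequate days (out of 7) required
#'   for an observation. Default 7 (all days); when lower, weekly sums are
#'   rescaled from the adequate days to a 7-day week.
#'
#' @return A list of class `activity_config`.
#' @export
#' @examples
#' cfg <- activity_config()
#' cfg$nonwear_min_run
activity_config <- function(spurious_steps = 200L,
                            nonwear_min_run = 120L,
                            adequate_wear_minutes = 600L,
                            cadence_bins = list(
                              sedentary = c(0L, 9L),
                              walking   = c(10L, 100L),
                              moderate  = c(101L, 130L),
                              vigorous  = c(131L, 200L)
                            ),
                            sedentary_rule = c("worn", "strict_bout"),
                            missing_counts_as_wear = FALSE,
                            ipaq_min_episode = 10,
                            ipaq_max_minutes = 180,
                            ipaq_max_total = 960,
                            met_values = c(walking = 3.3, moderate = 4.0,
                                           vigorous = 8.0),
                            week_min_adequate_days = 7L) {
  sedentary_rule <- match.arg(sedentary_rule)
  stopifnot(
    spurious_steps > 0, nonwear_min_run >= 1,
    adequate_wear_minutes >= 0, adequate_wear_minutes <= 1440,
    week_min_adequate_days >= 1, week_min_adequate_days <= 7,
    all(c("sedentary", "walking", "moderate", "vigorous") %in%
          names(cadence_bins)),
    all(c("walking", "moderate", "vigorous") %in% names(met_values)),
    all(met_values >= 0)
  )
  structure(
    list(
      spurious_steps = as.integer(spurious_steps),
      nonwear_min_run = as.integer(nonwear_min_run),
      adequate_wear_minutes = as.integer(adequate_wear_minutes),
      cadence_bins = lapply(cadence_bins, as.integer),
      sedentary_rule = sedentary_rule,
      missing_counts_as_wear = isTRUE(missing_counts_as_wear),
      ipaq_min_episode = ipaq_min_episode,
      ipaq_max_minutes = ipaq_max_minutes,
      ipaq_max_total = ipaq_max_total,
      met_values = met_values,
      week_min_adequate_days = as.integer(week_min_adequate_days)
    ),
    class = "activity_config"
  )
}

#' @export
print.activity_config <- function(x, ...) {
  cat("<activity_config>\n")
  cat("  spurious recode: >", x$spurious_steps, "steps/min -> missing\n")
  cat("  nonwear: >=", x$nonwear_min_run, "contiguous zero minutes\n")
  cat("  adequate day: >=", x$adequate_wear_minutes, "wear minutes\n")
  bins <- vapply(x$cadence_bins, function(b) paste0(b[1], "-", b[2]), "")
  cat("  cadence bins:", paste(names(bins), bins, collapse = ", "), "\n")
  cat("  IPAQ: floor", x$ipaq_min_episode, "min, cap", x$ipaq_max_minutes,
      "min, invalid >", x$ipaq_max_total, "min/day; METs",
      paste(names(x$met_values), x$met_values, collapse = ", "), "\n")
  invisible(x)
}
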