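# Trial segmentation: steady-state trimming, trial speed, speed-category
# assignment, and pooling of the non-ambulation tasks into one class.

WALKING_TASKS <- c("walk_self_selected", "walk_brisk")
NONAMB_TASKS <- c("sitting", "setting_table", "washing_dishes")

#' Speed category levels
#'
#' The ordered ambulation categories: pooled non-ambulation, then walking
#' at 0.41--0.8 m/s (`slow`, limited community ambulation), 0.81--1.2 m/s
#' (`med`), and above 1.2 m/s (`fast`, unlimited community ambulation).
#'
#' @return Character vector `c("nonamb", "slow", "med", "fast")`.
#' @export
speed_categories <- function() c("nonamb", "slow", "med", "fast")

as_speed_category <- function(x) {
  factor(as.character(x), levels = speed_categories(), ordered = TRUE)
}

#' Annotated activity trial
#'
#' One timed activity performed by one participant: a non-ambulation task
#' (sitting, setting the table, washing dishes) or a walking trial at
#' self-selected or brisk speed. Walking trials carry the distance walked;
#' non-ambulation trials must not.
#'
#' @param participant_id Identifier.
#' @param task One of `"sitting"`, `"setting_table"`, `"washing_dishes"`,
#'   `"walk_self_selected"`, `"walk_brisk"`.
#' @param start_s,stop_s Trial start/stop times in seconds,
#'   `stop_s > start_s`.
#' @param distance_m Distance walked in metres; required for walking
#'   tasks, forbidden otherwise.
#' @return An object of class `activity_trial`.
#' @export
activity_trial <- function(participant_id, task, start_s, stop_s,
                           distance_m = NULL) {
  if (!task %in% c(WALKING_TASKS, NONAMB_TASKS))
    stop_speedcuts(sprintf("unknown task label '%s'", task),
                   "invalid_argument")
  check_scalar_number(start_s, "start_s", lower = 0)
  check_scalar_number(stop_s, "stop_s", lower = 0)
  if (stop_s <= start_s)
    stop_speedcuts("stop_s must be after start_s", "invalid_argument")
  walking <- task %in% WALKING_TASKS
  if (walking) {
    if (is.null(distance_m))
      stop_speedcuts("walking trials require distance_m", "invalid_argument")
    check_scalar_number(distance_m, "distance_m", lower = 0)
  } else if (!is.null(distance_m) && !is.na(distance_m)) {
    stop_speedcuts("distance_m is only meaningful for walking tasks",
                   "invalid_argument")
  }
  structure(list(participant_id = participant_id, task = task,
                 start_s = start_s, stop_s = stop_s,
                 distance_m = if (walking) distance_m else NA_real_),
            class = "activity_trial")
}

#' Trim the first and last 15 seconds of a trial's count series
#'
#' The opening and closing 15 s of each activity cover initialization and
#' termination rather than steady-state movement and are disregarded. The
#' returned series covers `[start + 15, stop - 15)`.
#'
#' @param trial An [activity_trial()]; its duration must exceed 30 s.
#' @param series The trial's [count_series()] at a 1-second base epoch,
#'   aligned to the trial start.
#' @return The trimmed [count_series()], 30 base epochs shorter.
#' @export
trim_trial <- function(trial, series) {
  if (!inherits(trial, "activity_trial"))
    stop_speedcuts("`trial` must be an activity_trial", "invalid_argument")
  if (!inherits(series, "count_series"))
    stop_speedcuts("`series` must be a count_series", "invalid_argument")
  if (series$base_epoch_s != 1)
    stop_speedcuts("trimming operates on the 1-second base series",
                   "invalid_argument")
  duration <- trial$stop_s - trial$start_s
  if (duration <= 30)
    stop_speedcuts(sprintf(
      "trial duration %.1f s leaves nothing after trimming 2 x 15 s",
      duration), "trial_too_short")
  n <- length(series)
  if (n <= 30)
    stop_speedcuts("count series too short to trim", "trial_too_short")
  keep <- 16:(n - 15)
  count_series(series$counts_v[keep], series$counts_ap[keep],
               series$counts_ml[keep], placement = series$placement,
               filter_mode = series$filter_mode,
               base_epoch_s = series$base_epoch_s)
}

#' Trial walking speed
#'
#' Speed is the distance walked divided by the time taken to cover it.
#'
#' @param distance_m Distance in metres (non-negative).
#' @param duration_s Positive duration in seconds.
#' @return Speed in m/s.
#' @examples
#' compute_speed(288, 360)  # 0.8 m/s
#' @export
compute_speed <- function(distance_m, duration_s) {
  check_scalar_number(distance_m, "distance_m", lower = 0)
  check_scalar_number(duration_s, "duration_s", lower = 0,
                      strict_lower = TRUE)
  distance_m / duration_s
}

#' Assign walking speeds to ambulation categories
#'
#' Maps speeds to the walking bands: 0.41--0.8 m/s (`slow`, upper bound
#' inclusive), 0.81--1.2 m/s (`med`, upper bound inclusive) and
#' above 1.2 m/s (`fast`). Speeds below 0.41 m/s fall outside the
#' category scheme; such trials are rejected with a
#' `below_minimum_speed` error so callers can exclude them explicitly
#' rather than silently mis-binning them.
#'
#' @param speed_mps Numeric vector of walking speeds in m/s.
#' @return Ordered factor over [speed_categories()] (walking levels only).
#' @examples
#' assign_category(c(0.8, 1.2, 1.21))  # slow, med, fast
#' @export
assign_category <- function(speed_mps) {
  if (!is.numeric(speed_mps) || !all(is.finite(speed_mps)) ||
      any(speed_mps < 0))
    stop_speedcuts("speeds must be finite non-negative numbers",
                   "invalid_argument")
  if (any(speed_mps < 0.41))
    stop_speedcuts(sprintf(
      "walking speed %.2f m/s is below the 0.41 m/s category minimum",
      min(speed_mps)), "below_minimum_speed")
  lab <- ifelse(speed_mps <= 0.8, "slow",
                ifelse(speed_mps <= 1.2, "med", "fast"))
  as_speed_category(lab)
}

#' Pool the non-ambulation tasks into a single category
#'
#' Relabels every row as `nonamb` while preserving the task label for
#' provenance. Rows from walking tasks are rejected.
#'
#' @param rows Epoch-table rows (data frame with a `task` column)
#'   containing only non-ambulation tasks.
#' @return The same rows with `category` set to `nonamb` and `speed_mps`
#'   set to `NA`.
#' @export
pool_nonambulation <- function(rows) {
  if (!is.data.frame(rows) || !"task" %in% names(rows))
    stop_speedcuts("`rows` must be a data frame with a task column",
                   "invalid_argument")
  if (any(rows$task %in% WALKING_TASKS))
    stop_speedcuts("walking rows cannot be pooled into non-ambulation",
                   "invalid_argument")
  if (nrow(rows) > 0 && !all(rows$task %in% NONAMB_TASKS))
    stop_speedcuts("unknown task labels in input", "invalid_argument")
  rows$category <- as_speed_category(rep("nonamb", nrow(rows)))
  rows$speed_mps <- rep(NA_real_, nrow(rows))
  rows
}
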