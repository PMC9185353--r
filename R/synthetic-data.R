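# Synthetic cohort generation. Two paths are provided: a signal-level
# path that synthesizes gait-like tri-axial accelerations and runs them
# through the count engine, and a count-level path that draws per-epoch
# counts directly from class-conditional distributions calibrated to
# published median counts per speed category. Both paths emit the same
# epoch-table schema.

#' Default class-conditional count medians
#'
#' Per placement, axis and epoch length: the median activity count per
#' epoch for each ambulation category that the count-level generator is
#' calibrated to. The 15-s and 1-min values reproduce published medians
#' from a post-stroke calibration cohort (waist/ankle, vertical axis and
#' vector magnitude). Where the non-ambulation median is 0 the generator
#' uses a zero-inflated distribution whose non-zero part has median
#' `tail_median`.
#'
#' @return Data frame with columns `placement`, `axis`, `epoch_length_s`,
#'   `category`, `median`, `tail_median`.
#' @export
default_class_medians <- function() {
  g <- function(placement, axis, epoch, meds, tail)
    data.frame(placement = placement, axis = axis, epoch_length_s = epoch,
               category = speed_categories(), median = meds,
               tail_median = c(tail, NA, NA, NA),
               stringsAsFactors = FALSE)
  rbind(
    g("waist", "vertical", 15, c(0, 338, 423, 555), 20),
    g("waist", "vm",       15, c(0, 519, 759, 1147), 35),
    g("ankle", "vertical", 15, c(0, 912, 1898, 3456), 13),
    g("ankle", "vm",       15, c(0, 1394, 2546, 4045), 25),
    g("waist", "vertical", 60, c(17, 1204, 1628, 2099), NA),
    g("waist", "vm",       60, c(44, 1908, 2758, 4244), NA),
    g("ankle", "vertical", 60, c(14, 3496, 6777, 13178), NA),
    g("ankle", "vm",       60, c(37, 5393, 9660, 15576), NA)
  )
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: its size, sensor placements, epoch
#' length, the class-conditional count medians the count-level generator
#' is calibrated to, the log-scale spread of the count distributions, and
#' the master seed from which all per-participant and per-trial random
#' sub-streams are derived.
#'
#' @param n_participants Number of participants (default 42, echoing the
#'   calibration cohort size).
#' @param placements Subset of `c("waist", "ankle")`.
#' @param epoch_length_s 15 or 60.
#' @param class_medians Data frame as returned by
#'   [default_class_medians()].
#' @param dispersion Log-scale standard deviation of the per-epoch count
#'   distributions (default 0.2, i.e. a within-category coefficient of
#'   variation of about 20%).
#' @param nonamb_zero_prob Zero-inflation probability for non-ambulation
#'   epochs when the configured non-ambulation median is 0 (default 0.6).
#' @param trial_duration_s Walking-trial duration in seconds (default
#'   360, a 6-minute walk).
#' @param sampling_rate_hz Raw-signal sampling rate (default 30; must
#'   exceed twice the 2.5 Hz filter high cut).
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 42,
                       placements = c("waist", "ankle"),
                       epoch_length_s = 15,
                       class_medians = default_class_medians(),
                       dispersion = 0.2,
                       nonamb_zero_prob = 0.6,
                       trial_duration_s = 360,
                       sampling_rate_hz = 30,
                       seed = 1L) {
  check_scalar_number(n_participants, "n_participants", lower = 0)
  if (n_participants != floor(n_participants))
    stop_speedcuts("n_participants must be a whole number",
                   "invalid_argument")
  if (length(placements) < 1 || !all(placements %in% c("waist", "ankle")))
    stop_speedcuts("placements must be a subset of {waist, ankle}",
                   "invalid_argument")
  if (!epoch_length_s %in% c(15, 60))
    stop_speedcuts("epoch_length_s must be 15 or 60", "invalid_argument")
  check_scalar_number(dispersion, "dispersion", lower = 0)
  check_scalar_number(nonamb_zero_prob, "nonamb_zero_prob", lower = 0.5,
                      upper = 1)
  check_scalar_number(trial_duration_s, "trial_duration_s", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 0,
                      strict_lower = TRUE)
  if (sampling_rate_hz <= 2 * 2.5)
    stop_speedcuts("sampling_rate_hz must exceed twice the 2.5 Hz high cut",
                   "invalid_argument")
  check_scalar_number(seed, "seed")
  needed <- c("placement", "axis", "epoch_length_s", "category", "median",
              "tail_median")
  if (!is.data.frame(class_medians) || !all(needed %in% names(class_medians)))
    stop_speedcuts("class_medians is missing required columns",
                   "invalid_argument")
  # ordering invariants per placement/axis stratum at the configured epoch
  cm <- class_medians[class_medians$epoch_length_s == epoch_length_s, ]
  for (pl in placements) {
    for (ax in unique(cm$axis[cm$placement == pl])) {
      s <- cm[cm$placement == pl & cm$axis == ax, ]
      med <- s$median[match(speed_categories(), s$category)]
      if (anyNA(med) || !(med[2] < med[3] && med[3] < med[4]))
        stop_speedcuts(sprintf(
          "class medians must increase slow < med < fast for %s/%s", pl, ax),
          "invalid_argument")
      if (med[1] < 0 || med[1] >= med[2])
        stop_speedcuts(sprintf(
          "non-ambulation median must be below the slow median for %s/%s",
          pl, ax), "invalid_argument")
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 placements = placements,
                 epoch_length_s = epoch_length_s,
                 class_medians = class_medians,
                 dispersion = dispersion,
                 nonamb_zero_prob = nonamb_zero_prob,
                 trial_duration_s = trial_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d participants, %s, %g s epochs, dispersion %g, seed %d\n",
    x$n_participants, paste(x$placements, collapse = "+"),
    x$epoch_length_s, x$dispersion, x$seed))
  invisible(x)
}

lookup_median <- function(config, placement, axis, category) {
  cm <- config$class_medians
  row <- cm[cm$placement == placement & cm$axis == axis &
              cm$epoch_length_s == config$epoch_length_s &
              cm$category == category, ]
  if (nrow(row) != 1L)
    stop_speedcuts(sprintf("no configured median for %s/%s/%s at %g s",
                           placement, axis, category,
                           config$epoch_length_s), "invalid_argument")
  row
}

# Lognormal draws rounded to integer counts; common `z` quantiles let the
# caller couple axes. Zero-inflated variant when the target median is 0.
draw_counts <- function(z, median, tail_median, dispersion,
                        zero_mask = NULL) {
  if (median == 0) {
    stopifnot(!is.null(zero_mask), is.finite(tail_median))
    out <- round(exp(log(tail_median) + dispersion * z))
    out[zero_mask] <- 0
  } else {
    out <- round(exp(log(median) + dispersion * z))
  }
  as.integer(out)
}

#' Simulate a gait-like acceleration signal
#'
#' Produces a quasi-periodic tri-axial walking signal: a fundamental at
#' the cadence (linear in speed) plus a second harmonic, with
#' speed-dependent amplitude, lateral sway at half cadence, zero-mean
#' sensor noise and a 1 g gravity offset on the vertical axis. Ankle
#' amplitudes exceed waist amplitudes at the same speed. This is a
#' minimal waveform that places its energy inside the 0.25--2.5 Hz count
#' passband and makes count output grow with walking speed; it is not a
#' biomechanically faithful model of hemiparetic gait.
#'
#' @param speed_mps Walking speed in m/s, within `[0.2, 2.5]`.
#' @param duration_s Duration in seconds, at least 30 (room for the
#'   15 s + 15 s steady-state trimming).
#' @param placement `"waist"` or `"ankle"`.
#' @param config A [sim_config()] (supplies sampling rate and seed).
#' @param seed Optional seed override; by default a sub-stream is derived
#'   from `config$seed` and the arguments, so identical calls are
#'   reproducible sample by sample.
#' @return An [accel_signal()].
#' @export
simulate_gait_signal <- function(speed_mps, duration_s, placement,
                                 config = sim_config(), seed = NULL) {
  check_scalar_number(speed_mps, "speed_mps", lower = 0, strict_lower = TRUE)
  check_scalar_number(duration_s, "duration_s", lower = 0,
                      strict_lower = TRUE)
  if (speed_mps < 0.2 || speed_mps > 2.5)
    stop_speedcuts("speed_mps must lie within [0.2, 2.5]",
                   "invalid_argument")
  if (duration_s < 30)
    stop_speedcuts("duration_s must be at least 30 s", "invalid_argument")
  if (!placement %in% c("waist", "ankle"))
    stop_speedcuts("placement must be 'waist' or 'ankle'",
                   "invalid_argument")
  if (is.null(seed))
    seed <- derive_seed(config$seed, "gait", placement, speed_mps,
                        duration_s)
  fs <- config$sampling_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  cadence_hz <- 0.6 + 0.55 * speed_mps          # step rate, in-band
  amp <- switch(placement, waist = 0.22, ankle = 0.55) * speed_mps  # g
  with_seed(seed, {
    vertical <- 1 + amp * sin(2 * pi * cadence_hz * t) +
      0.4 * amp * sin(4 * pi * cadence_hz * t + 0.8) +
      rnorm(n, sd = 0.02)
    ap <- 0.6 * amp * sin(2 * pi * cadence_hz * t + pi / 2) +
      0.25 * amp * sin(4 * pi * cadence_hz * t) + rnorm(n, sd = 0.02)
    ml <- 0.35 * amp * sin(pi * cadence_hz * t) + rnorm(n, sd = 0.02)
    accel_signal(vertical, ap, ml, sampling_rate_hz = fs)
  })
}

#' Simulate a non-ambulation acceleration signal
#'
#' Stand-ins for the three pooled non-ambulation tasks: sitting (near
#' stillness), setting the table (slow seated arm movement with
#' occasional reach transients) and washing dishes (slow standing arm and
#' trunk movement with occasional transients). Motion is small and mostly
#' below the count passband or the dead-band, so per-epoch counts are
#' predominantly zero with a modest positive tail -- well below the count
#' level of walking at 0.41 m/s or faster.
#'
#' @param task `"sitting"`, `"setting_table"` or `"washing_dishes"`.
#' @inheritParams simulate_gait_signal
#' @return An [accel_signal()].
#' @export
simulate_nonambulation_signal <- function(task, duration_s,
                                          config = sim_config(),
                                          seed = NULL) {
  if (!task %in% NONAMB_TASKS)
    stop_speedcuts(sprintf("unknown non-ambulation task '%s'", task),
                   "invalid_argument")
  check_scalar_number(duration_s, "duration_s", lower = 0,
                      strict_lower = TRUE)
  if (duration_s < 30)
    stop_speedcuts("duration_s must be at least 30 s", "invalid_argument")
  if (is.null(seed))
    seed <- derive_seed(config$seed, "nonamb", task, duration_s)
  fs <- config$sampling_rate_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    transients <- function(rate_per_min, amp) {
      x <- numeric(n)
      k <- rbinom(1, size = max(1, round(duration_s / 60 * rate_per_min)),
                  prob = 0.8)
      if (k > 0) {
        at <- runif(k, 0, duration_s)
        for (a in at) {
          idx <- which(t >= a & t < a + 0.4)
          x[idx] <- x[idx] + amp * exp(-(t[idx] - a) / 0.12) *
            sin(2 * pi * 1.5 * (t[idx] - a))
        }
      }
      x
    }
    sig <- switch(task,
      sitting = list(
        v = rnorm(n, sd = 0.004),
        ap = 0.012 * sin(2 * pi * 0.03 * t) + rnorm(n, sd = 0.004),
        ml = rnorm(n, sd = 0.004)),
      setting_table = list(
        v = rnorm(n, sd = 0.008),
        ap = 0.03 * sin(2 * pi * 0.3 * t) + transients(3, 0.15) +
          rnorm(n, sd = 0.008),
        ml = 0.02 * sin(2 * pi * 0.25 * t) + rnorm(n, sd = 0.008)),
      washing_dishes = list(
        v = 0.015 * sin(2 * pi * 0.3 * t) + rnorm(n, sd = 0.01),
        ap = 0.035 * sin(2 * pi * 0.2 * t) + transients(4, 0.12) +
          rnorm(n, sd = 0.01),
        ml = 0.02 * sin(2 * pi * 0.15 * t) + rnorm(n, sd = 0.01)))
    accel_signal(1 + sig$v, sig$ap, sig$ml, sampling_rate_hz = fs)
  })
}

#' Draw per-epoch counts directly from a class-conditional distribution
#'
#' Skips the signal stage: counts for one placement/axis/category stratum
#' are drawn from a log-location family (lognormal, rounded to integers)
#' with median equal to the configured class median and log-scale spread
#' `config$dispersion`. When the configured median is 0 (non-ambulation
#' at 15 s epochs) a zero-inflated variant is used: epochs are 0 with
#' probability `config$nonamb_zero_prob`, otherwise lognormal around the
#' stratum's `tail_median`.
#'
#' @param category One of [speed_categories()].
#' @param placement `"waist"` or `"ankle"`.
#' @param axis `"vertical"` or `"vm"`.
#' @param n_epochs Number of epochs to draw (at least 1).
#' @param config A [sim_config()].
#' @param seed Optional seed override; defaults to a sub-stream derived
#'   from `config$seed` and the stratum.
#' @return Integer vector of non-negative counts.
#' @export
sample_counts_direct <- function(category, placement, axis, n_epochs,
                                 config = sim_config(), seed = NULL) {
  if (!category %in% speed_categories())
    stop_speedcuts(sprintf("unknown category '%s'", category),
                   "invalid_argument")
  if (!axis %in% c("vertical", "vm"))
    stop_speedcuts("axis must be 'vertical' or 'vm'", "invalid_argument")
  check_scalar_number(n_epochs, "n_epochs", lower = 1)
  row <- lookup_median(config, placement, axis, category)
  if (is.null(seed))
    seed <- derive_seed(config$seed, "counts", placement, axis, category)
  with_seed(seed, {
    z <- rnorm(n_epochs)
    zero_mask <- if (row$median == 0)
      runif(n_epochs) < config$nonamb_zero_prob
    draw_counts(z, row$median, row$tail_median, config$dispersion,
                zero_mask)
  })
}

epoch_table_prototype <- function() {
  data.frame(participant_id = character(0), placement = character(0),
             filter_mode = character(0), task = character(0),
             category = as_speed_category(character(0)),
             speed_mps = numeric(0), epoch_index = integer(0),
             epoch_length_s = numeric(0), count_v = integer(0),
             count_ap = integer(0), count_ml = integer(0),
             count_vm = integer(0), stringsAsFactors = FALSE)
}

cohort_trials <- function(config) {
  data.frame(task = c(NONAMB_TASKS, WALKING_TASKS),
             duration_s = c(300, 180, 360,
                            config$trial_duration_s,
                            config$trial_duration_s),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic calibration cohort
#'
#' Emulates the layout of a cut-point calibration study: each participant
#' performs three non-ambulation tasks (sitting 5 min, setting the table
#' 3 min, washing dishes 6 min) and two 6-minute walking trials
#' (self-selected and brisk speed, one speed per trial), with sensors at
#' the configured placements. The steady-state trimming rule (first and
#' last 15 s disregarded) is already applied, every retained epoch
#' carries its trial's true category, and non-ambulation tasks are pooled
#' under the `nonamb` label.
#'
#' `level = "count"` (the default) draws per-epoch counts directly from
#' the calibrated class-conditional distributions: the vertical-axis and
#' vector-magnitude counts of an epoch share one lognormal quantile (so
#' the vector magnitude never falls below the vertical count), and the
#' two horizontal axes are back-filled consistently with the Euclidean
#' vector-magnitude convention. `level = "signal"` synthesizes raw
#' accelerations per trial and runs the full count engine; its count
#' scale is not calibrated to the published medians, but its schema is
#' identical.
#'
#' @param config A [sim_config()].
#' @param level `"count"` or `"signal"`.
#' @return An epoch-table data frame with columns `participant_id`,
#'   `placement`, `filter_mode`, `task`, `category`, `speed_mps`,
#'   `epoch_index`, `epoch_length_s`, `count_v`, `count_ap`, `count_ml`,
#'   `count_vm`. Identical `config` gives identical output.
#' @export
generate_cohort <- function(config = sim_config(),
                            level = c("count", "signal")) {
  level <- match.arg(level)
  if (!inherits(config, "sim_config"))
    stop_speedcuts("`config` must be a sim_config", "invalid_argument")
  if (config$n_participants == 0L) return(epoch_table_prototype())
  trials <- cohort_trials(config)
  out <- vector("list", config$n_participants * length(config$placements) *
                  nrow(trials))
  k <- 0L
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%03d", p)
    sp <- with_seed(derive_seed(config$seed, "speeds", p), {
      self <- min(max(rnorm(1, 0.85, 0.25), 0.41), 1.3)
      brisk <- min(max(self + rnorm(1, 0.35, 0.10), 0.45), 2.2)
      c(walk_self_selected = self, walk_brisk = brisk)
    })
    for (placement in config$placements) {
      for (i in seq_len(nrow(trials))) {
        task <- trials$task[i]
        dur <- trials$duration_s[i]
        walking <- task %in% WALKING_TASKS
        speed <- if (walking) unname(sp[task]) else NA_real_
        category <- if (walking) as.character(assign_category(speed))
                    else "nonamb"
        rows <- if (level == "count")
          trial_rows_count(config, p, placement, task, category, dur)
        else
          trial_rows_signal(config, p, placement, task, speed, dur)
        if (is.null(rows) || nrow(rows) == 0L) next
        k <- k + 1L
        out[[k]] <- data.frame(
          participant_id = pid, placement = placement,
          filter_mode = "default", task = task,
          category = as_speed_category(rep(category, nrow(rows))),
          speed_mps = speed, epoch_index = rows$epoch_index,
          epoch_length_s = config$epoch_length_s,
          count_v = rows$count_v, count_ap = rows$count_ap,
          count_ml = rows$count_ml, count_vm = rows$count_vm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(epoch_table_prototype())
  do.call(rbind, out[seq_len(k)])
}

trial_rows_count <- function(config, p, placement, task, category, dur) {
  n_ep <- floor((dur - 30) / config$epoch_length_s)
  if (n_ep < 1) return(NULL)
  med_v <- lookup_median(config, placement, "vertical", category)
  med_vm <- lookup_median(config, placement, "vm", category)
  with_seed(derive_seed(config$seed, "trial", p, placement, task), {
    z <- rnorm(n_ep)
    zero_mask <- if (med_v$median == 0 || med_vm$median == 0)
      runif(n_ep) < config$nonamb_zero_prob
    v <- draw_counts(z, med_v$median, med_v$tail_median,
                     config$dispersion, zero_mask)
    vm <- draw_counts(z, med_vm$median, med_vm$tail_median,
                      config$dispersion, zero_mask)
    vm <- pmax(vm, v)
    horiz <- as.integer(round(sqrt(pmax(as.numeric(vm)^2 -
                                          as.numeric(v)^2, 0) / 2)))
    data.frame(epoch_index = seq_len(n_ep), count_v = v, count_ap = horiz,
               count_ml = horiz, count_vm = vm)
  })
}

trial_rows_signal <- function(config, p, placement, task, speed, dur) {
  seed <- derive_seed(config$seed, "sigtrial", p, placement, task)
  sig <- if (task %in% WALKING_TASKS)
    simulate_gait_signal(speed, dur, placement, config, seed = seed)
  else
    simulate_nonambulation_signal(task, dur, config, seed = seed)
  series <- signal_to_counts(sig, filter_spec(), placement = placement)
  trial <- activity_trial(sprintf("P%03d", p), task, 0, dur,
                          distance_m = if (task %in% WALKING_TASKS)
                            speed * dur else NULL)
  trimmed <- trim_trial(trial, series)
  ep <- aggregate_epochs(trimmed, config$epoch_length_s)
  ep[, c("epoch_index", "count_v", "count_ap", "count_ml", "count_vm")]
}
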