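# Plain-text I/O: cohort tables as CSV, simulation configuration as a
# key-value (YAML) file, and raw tri-axial signals as tabular text.

COHORT_COLUMNS <- c("participant_id", "placement", "filter_mode", "task",
                    "category", "speed_mps", "epoch_index",
                    "epoch_length_s", "count_v", "count_ap", "count_ml",
                    "count_vm")

#' Write an epoch table to CSV
#'
#' @param table Epoch-table data frame (see [generate_cohort()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  missing <- setdiff(COHORT_COLUMNS, names(table))
  if (length(missing) > 0)
    stop_speedcuts(paste("missing cohort columns:",
                         paste(missing, collapse = ", ")),
                   "invalid_argument")
  write.csv(table[, COHORT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an epoch table from CSV
#'
#' @param path CSV file written by [write_cohort()] (or any file with the
#'   same columns).
#' @return Epoch-table data frame with `category` restored as an ordered
#'   factor.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing) > 0)
    stop_speedcuts(paste("missing cohort columns:",
                         paste(missing, collapse = ", ")),
                   "invalid_argument")
  df$category <- as_speed_category(df$category)
  for (col in c("count_v", "count_ap", "count_ml", "count_vm")) {
    if (!is_count_vector(df[[col]]))
      stop_speedcuts(sprintf("column %s must hold non-negative integers",
                             col), "invalid_argument")
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Read a simulation configuration from a key-value file
#'
#' Reads a YAML (or plain `key: value`) file and builds a [sim_config()].
#' All fields are optional; omitted keys take the documented defaults.
#' `placements` may be a list or a comma-separated string. A
#' `class_medians` key may point to a CSV file with the columns of
#' [default_class_medians()].
#'
#' @param path Configuration file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  args <- list()
  for (key in c("n_participants", "epoch_length_s", "dispersion",
                "nonamb_zero_prob", "trial_duration_s",
                "sampling_rate_hz", "seed"))
    if (!is.null(raw[[key]])) args[[key]] <- as.numeric(raw[[key]])
  if (!is.null(raw$placements)) {
    pl <- raw$placements
    if (is.character(pl) && length(pl) == 1L)
      pl <- trimws(strsplit(pl, ",")[[1]])
    args$placements <- unlist(pl)
  }
  if (!is.null(raw$class_medians))
    args$class_medians <- read.csv(raw$class_medians,
                                   stringsAsFactors = FALSE)
  do.call(sim_config, args)
}

#' Read a raw tri-axial acceleration signal from tabular text
#'
#' Expects columns `time_s`, `acc_v_g`, `acc_ap_g`, `acc_ml_g`
#' (comma-separated, header row; comment lines starting with `#` are
#' ignored). The sampling rate is inferred from the median time step
#' unless declared in a header comment of the form
#' `# sampling_rate_hz: 30`. Rates other than 30 Hz are rejected: the
#' count chain is defined at 30 Hz and resampling is out of scope.
#'
#' @param path Input file path.
#' @return An [accel_signal()].
#' @export
read_signal <- function(path) {
  header <- readLines(path, n = 10)
  declared <- grep("^#\\s*sampling_rate_hz\\s*:", header, value = TRUE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("time_s", "acc_v_g", "acc_ap_g", "acc_ml_g")
  if (!all(needed %in% names(df)))
    stop_speedcuts(paste("signal file must have columns:",
                         paste(needed, collapse = ", ")),
                   "invalid_argument")
  fs <- if (length(declared) > 0)
    as.numeric(sub(".*:\\s*", "", declared[1]))
  else 1 / median(diff(df$time_s))
  if (!isTRUE(all.equal(fs, 30, tolerance = 0.01)))
    stop_speedcuts(sprintf(
      "sampling rate %.3g Hz is not supported (30 Hz assumed)", fs),
      "invalid_argument")
  accel_signal(df$acc_v_g, df$acc_ap_g, df$acc_ml_g,
               sampling_rate_hz = 30, t0_s = df$time_s[1])
}
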