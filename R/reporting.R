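# Study-style reporting: per-category count summaries with bootstrap
# intervals, a calibration report (per-category sensitivity/specificity,
# boundary AUC and interval), and deterministic rendering to tabular
# text.

#' Summarize epoch counts per stratum and category
#'
#' One row per placement x filter mode x epoch length x axis x category:
#' number of epochs, exact sample median, and a percentile bootstrap
#' interval for the median. The interval is a clearly labelled bootstrap
#' construct, not an attempt to reproduce any particular published
#' interval.
#'
#' @param table Labelled epoch-table data frame.
#' @param axes Which axes to summarize, subset of
#'   `c("vertical", "vm")`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Seed for the bootstrap (sub-streams are derived per
#'   stratum, so row order does not affect results).
#' @return Data frame with columns `placement`, `filter_mode`,
#'   `epoch_length_s`, `axis`, `category`, `n`, `median`, `interval_low`,
#'   `interval_high`. Strata missing a category are reported only for the
#'   categories present, with a warning.
#' @export
summarize_counts <- function(table, axes = c("vertical", "vm"),
                             n_boot = 2000, conf = 0.95, seed = 1L) {
  if (!is.data.frame(table))
    stop_speedcuts("`table` must be a data frame", "invalid_argument")
  if (!all(axes %in% c("vertical", "vm")))
    stop_speedcuts("axes must be a subset of {vertical, vm}",
                   "invalid_argument")
  check_scalar_number(n_boot, "n_boot", lower = 1)
  check_scalar_number(conf, "conf", lower = 0, upper = 1,
                      strict_lower = TRUE)
  out <- list()
  strata <- unique(table[, c("placement", "filter_mode", "epoch_length_s")])
  for (s in seq_len(nrow(strata))) {
    sub <- table[table$placement == strata$placement[s] &
                   table$filter_mode == strata$filter_mode[s] &
                   table$epoch_length_s == strata$epoch_length_s[s], ]
    missing_cats <- setdiff(speed_categories(),
                            as.character(unique(sub$category)))
    if (length(missing_cats) > 0)
      warning(sprintf("stratum %s/%s/%g s has no epochs for: %s",
                      strata$placement[s], strata$filter_mode[s],
                      strata$epoch_length_s[s],
                      paste(missing_cats, collapse = ", ")),
              call. = FALSE)
    for (ax in axes) {
      col <- if (ax == "vm") "count_vm" else "count_v"
      for (cat in intersect(speed_categories(),
                            as.character(unique(sub$category)))) {
        x <- sub[[col]][sub$category == cat]
        ci <- boot_median_ci(x, n_boot, conf,
                             derive_seed(seed, "boot",
                                         strata$placement[s],
                                         strata$filter_mode[s],
                                         strata$epoch_length_s[s], ax, cat))
        out[[length(out) + 1L]] <- data.frame(
          placement = strata$placement[s],
          filter_mode = strata$filter_mode[s],
          epoch_length_s = strata$epoch_length_s[s],
          axis = ax, category = cat, n = length(x),
          median = median(x), interval_low = ci[1], interval_high = ci[2],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(placement = character(0), filter_mode = character(0),
                      epoch_length_s = numeric(0), axis = character(0),
                      category = character(0), n = integer(0),
                      median = numeric(0), interval_low = numeric(0),
                      interval_high = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

boot_median_ci <- function(x, n_boot, conf, seed) {
  if (length(x) == 1L) return(c(x, x))
  with_seed(seed, {
    meds <- vapply(seq_len(n_boot),
                   function(i) median(sample(x, replace = TRUE)),
                   numeric(1))
    unname(quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  })
}

#' Calibration report for one cut-point table
#'
#' Combines the interval-classification sensitivity/specificity of
#' [category_performance()] with the boundary AUCs and the rendered
#' count intervals, mirroring the layout of a published calibration
#' table (one row per category; the three boundary AUCs are attached to
#' the first three categories, whose upper edges they define).
#'
#' @param table Labelled epoch-table data frame for the stratum.
#' @param cuts A calibrated [cutpoint_table()] (from
#'   [build_cutpoint_table()], so that ROC curves are attached).
#' @return Data frame with columns `placement`, `axis`,
#'   `epoch_length_s`, `category`, `n`, `sensitivity`, `specificity`,
#'   `auc`, `interval`.
#' @export
calibration_report <- function(table, cuts) {
  perf <- category_performance(table, cuts)
  aucs <- if (is.null(cuts$roc)) rep(NA_real_, 3) else boundary_aucs(cuts)
  data.frame(placement = cuts$placement, axis = cuts$axis,
             epoch_length_s = cuts$epoch_length_s,
             category = as.character(perf$category), n = perf$n,
             sensitivity = perf$sensitivity,
             specificity = perf$specificity,
             auc = c(aucs, NA_real_),
             interval = format_cutpoint_intervals(cuts),
             stringsAsFactors = FALSE)
}

#' Render summary, calibration and evaluation tables to text files
#'
#' Writes up to three comma-separated files with deterministic column
#' order and fixed numeric formatting (counts as integers, rates and
#' AUCs with two decimals): `counts_summary.csv` (per-category count
#' summary), `calibration_report.csv` (per-category
#' sensitivity/specificity/AUC/interval) and `cutpoints.csv` (final
#' intervals per placement). Inputs given as `NULL` are skipped; empty
#' inputs produce header-only files. Rendering is a pure function of its
#' inputs: identical inputs give byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param summary Output of [summarize_counts()], or `NULL`.
#' @param calibration Output of [calibration_report()] (possibly several
#'   row-bound together), or `NULL`.
#' @param cutpoints A [cutpoint_table()] or list of them, or `NULL`.
#' @param evaluation A `classification_report` (see [evaluate()]), or
#'   `NULL`; written as `evaluation.csv`.
#' @return Invisibly, the paths of the files written.
#' @export
render_tables <- function(dir, summary = NULL, calibration = NULL,
                          cutpoints = NULL, evaluation = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))
  if (!is.null(summary)) {
    s <- summary
    s$median <- fmt_num(s$median)
    s$interval_low <- fmt_num(s$interval_low)
    s$interval_high <- fmt_num(s$interval_high)
    written <- c(written, write_rendered(s, file.path(dir,
                                                      "counts_summary.csv")))
  }
  if (!is.null(calibration)) {
    cb <- calibration
    cb$sensitivity <- fmt2(cb$sensitivity)
    cb$specificity <- fmt2(cb$specificity)
    cb$auc <- fmt2(cb$auc)
    written <- c(written, write_rendered(cb, file.path(
      dir, "calibration_report.csv")))
  }
  if (!is.null(cutpoints)) {
    if (inherits(cutpoints, "cutpoint_table")) cutpoints <- list(cutpoints)
    rows <- lapply(cutpoints, function(ct)
      data.frame(placement = ct$placement, axis = ct$axis,
                 epoch_length_s = ct$epoch_length_s,
                 category = speed_categories(),
                 interval = format_cutpoint_intervals(ct),
                 stringsAsFactors = FALSE))
    written <- c(written, write_rendered(do.call(rbind, rows),
                                         file.path(dir, "cutpoints.csv")))
  }
  if (!is.null(evaluation)) {
    pc <- evaluation$per_category
    ev <- data.frame(category = as.character(pc$category), n = pc$n,
                     sensitivity = fmt2(pc$sensitivity),
                     specificity = fmt2(pc$specificity),
                     overall_accuracy = fmt2(evaluation$overall_accuracy),
                     stringsAsFactors = FALSE)
    written <- c(written, write_rendered(ev, file.path(dir,
                                                       "evaluation.csv")))
  }
  invisible(written)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "",
         ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
                sprintf("%.1f", x)))
}

write_rendered <- function(df, path) {
  con <- file(path, open = "wb")  # binary: fixed line endings
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    rows <- do.call(paste, c(lapply(df, as.character), sep = ","))
    writeLines(rows, con)
  }
  path
}
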