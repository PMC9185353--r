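# Classification: apply a cut-point table (including the published
# tables shipped with the package) to epoch counts and summarize the
# result as a confusion matrix with per-category sensitivity and
# specificity.

#' Published cut-point tables
#'
#' The recommended vector-magnitude cut-points per 15-second epoch for
#' waist- and ankle-worn sensors in people post stroke:
#'
#' | category      | waist VM/15 s | ankle VM/15 s |
#' |---------------|---------------|---------------|
#' | non-ambulation| <= 140        | <= 401        |
#' | 0.41--0.8 m/s | 141--572      | 402--1862     |
#' | 0.81--1.2 m/s | 573--990      | 1863--3265    |
#' | > 1.2 m/s     | >= 991        | >= 3266       |
#'
#' Cut-points for one epoch length do not transfer to another, which is
#' why only the recommended 15-second tables are built in.
#'
#' @param placement `"waist"` or `"ankle"`.
#' @return A [cutpoint_table()].
#' @examples
#' classify_epoch(759, published_cutpoints("waist"))  # med
#' @export
published_cutpoints <- function(placement = c("waist", "ankle")) {
  placement <- match.arg(placement)
  boundaries <- switch(placement,
                       waist = c(140L, 572L, 990L),
                       ankle = c(401L, 1862L, 3265L))
  cutpoint_table(boundaries, placement = placement, axis = "vm",
                 epoch_length_s = 15, filter_mode = "default")
}

#' Classify epoch counts into ambulation categories
#'
#' Maps each count into the unique cut-point interval containing it.
#' Counts must be non-negative integers; real-valued input is rejected
#' rather than rounded, to avoid silent drift at the boundaries.
#'
#' @param count_vm Vector of non-negative integer counts (on the axis the
#'   cut-point table was calibrated for).
#' @param cuts A [cutpoint_table()].
#' @return Ordered factor over [speed_categories()].
#' @export
classify_epoch <- function(count_vm, cuts) {
  if (!inherits(cuts, "cutpoint_table"))
    stop_speedcuts("`cuts` must be a cutpoint_table", "invalid_argument")
  if (length(count_vm) == 0L) return(as_speed_category(character(0)))
  if (!is_count_vector(count_vm))
    stop_speedcuts("counts must be non-negative integers",
                   "invalid_argument")
  b <- cuts$boundaries
  idx <- findInterval(count_vm, c(b + 0.5)) + 1L
  as_speed_category(speed_categories()[idx])
}

#' Add predicted categories to an epoch table
#'
#' @param table Epoch-table data frame whose placement, epoch length and
#'   filter mode match `cuts`.
#' @param cuts A [cutpoint_table()].
#' @return The table with an added `predicted_category` column; row count
#'   unchanged.
#' @export
classify_table <- function(table, cuts) {
  sub <- match_stratum(table, cuts)
  col <- if (cuts$axis == "vm") "count_vm" else "count_v"
  sub$predicted_category <- classify_epoch(sub[[col]], cuts)
  sub
}

#' Evaluate predicted against true categories
#'
#' @param table Epoch-table data frame with `category` and
#'   `predicted_category` columns (see [classify_table()]).
#' @return An object of class `classification_report`: a 4 x 4 confusion
#'   matrix (true categories in rows, predictions in columns), the
#'   per-category sensitivity/specificity as in [category_performance()],
#'   and the overall accuracy (trace over total).
#' @export
evaluate <- function(table) {
  if (!is.data.frame(table) || !"predicted_category" %in% names(table))
    stop_speedcuts("`table` must carry a predicted_category column",
                   "invalid_argument")
  if (nrow(table) == 0L)
    stop_speedcuts("no rows to evaluate", "empty_input")
  true <- as_speed_category(table$category)
  pred <- as_speed_category(table$predicted_category)
  cm <- base::table(true = true, predicted = pred)
  structure(list(confusion_matrix = unclass(cm),
                 per_category = per_category_stats(true, pred),
                 overall_accuracy = sum(diag(cm)) / sum(cm),
                 n = nrow(table)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d epochs, accuracy %.3f\n",
              x$n, x$overall_accuracy))
  print(x$confusion_matrix)
  print(x$per_category, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Render cut-point intervals as display strings
#'
#' @param cuts A [cutpoint_table()].
#' @return Character vector of four interval strings in category order,
#'   e.g. `"≤140"`, `"141–572"`, `"573–990"`,
#'   `"≥991"` for the published waist table.
#' @export
format_cutpoint_intervals <- function(cuts) {
  if (!inherits(cuts, "cutpoint_table"))
    stop_speedcuts("`cuts` must be a cutpoint_table", "invalid_argument")
  b <- cuts$boundaries
  c(paste0("≤", b[1]),
    paste0(b[1] + 1, "–", b[2]),
    paste0(b[2] + 1, "–", b[3]),
    paste0("≥", b[3] + 1))
}
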