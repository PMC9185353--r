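# ROC-based cut-point calibration: empirical ROC curves with trapezoidal
# AUC, optimal operating points by the closest-to-corner criterion, AUC
# grading, and assembly of the three ordered count boundaries that
# partition epochs into the four ambulation categories.

#' Empirical ROC curve
#'
#' Builds the ROC curve of a score against a binary label, assuming
#' higher scores indicate the positive class. Candidate thresholds are
#' the midpoints between consecutive distinct scores plus the two
#' infinite endpoints, so the curve contains one operating point per
#' distinct score and always includes `(sensitivity, 1 - specificity)`
#' endpoints `(0, 0)` and `(1, 1)`. The AUC is computed by the
#' trapezoidal rule and equals the Mann--Whitney pairwise concordance
#' (ties counted 1/2).
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (logical, 0/1, or a two-level factor with
#'   `positive` naming the positive level).
#' @param positive The positive level when `labels` is not already
#'   logical/0-1.
#' @return An object of class `roc_curve` with elements `thresholds`
#'   (descending), `sensitivity`, `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  if (!is.numeric(scores) || !all(is.finite(scores)))
    stop_speedcuts("scores must be finite numbers", "invalid_argument")
  if (length(scores) != length(labels))
    stop_speedcuts("scores and labels must have equal length",
                   "invalid_argument")
  lab <- if (is.logical(labels)) labels
         else if (is.numeric(labels) && all(labels %in% c(0, 1)))
           labels == 1
         else if (!is.null(positive)) as.character(labels) == positive
         else stop_speedcuts(
           "labels must be logical/0-1 or `positive` must be given",
           "invalid_argument")
  if (all(lab) || !any(lab))
    stop_speedcuts("both classes must be present", "degenerate_labels")
  d <- sort(unique(scores), decreasing = TRUE)
  thresholds <- c(Inf, if (length(d) > 1) (d[-1] + d[-length(d)]) / 2, -Inf)
  pos <- scores[lab]
  neg <- scores[!lab]
  Fp <- ecdf(pos)
  Fn <- ecdf(neg)
  sens <- 1 - Fp(thresholds)  # P(pos score > t)
  spec <- Fn(thresholds)      # P(neg score <= t)
  x <- 1 - spec
  auc <- sum(diff(x) * (head(sens, -1) + tail(sens, -1)) / 2)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, %d pos / %d neg, AUC %.3f\n",
              length(x$thresholds), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Optimal cut-point by the closest-to-corner criterion
#'
#' Selects the operating point nearest to the upper-left corner of the
#' ROC plot, i.e. minimizing `sqrt((1 - sens)^2 + (1 - spec)^2)`
#' (sensitivity = 1 and 1 - specificity = 0). Ties are broken in favour
#' of higher sensitivity (preferring detection of the positive side),
#' then the lower threshold.
#'
#' @param curve A [roc_curve()].
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_cutpoint <- function(curve) {
  if (!inherits(curve, "roc_curve"))
    stop_speedcuts("`curve` must be a roc_curve", "invalid_argument")
  if (length(curve$thresholds) < 3)
    stop_speedcuts("curve is degenerate (single operating point)",
                   "degenerate_curve")
  d2 <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
  best <- which(d2 <= min(d2) + 1e-12)
  if (length(best) > 1) {
    best <- best[curve$sensitivity[best] >=
                   max(curve$sensitivity[best]) - 1e-12]
    best <- best[which.min(curve$thresholds[best])]
  }
  list(threshold = curve$thresholds[best],
       sensitivity = curve$sensitivity[best],
       specificity = curve$specificity[best])
}

#' Grade an AUC value
#'
#' The conventional discrimination bands: AUC < 0.7 poor, 0.7--0.79 fair,
#' 0.8--0.89 good, at least 0.90 excellent, and exactly 1 a perfect test.
#'
#' @param auc Numeric vector of AUC values in `[0, 1]`.
#' @return Ordered factor with levels
#'   `poor < fair < good < excellent < perfect`.
#' @examples
#' grade_auc(c(0.6, 0.85, 1))
#' @export
grade_auc <- function(auc) {
  if (!is.numeric(auc) || any(!is.finite(auc)) || any(auc < 0 | auc > 1))
    stop_speedcuts("auc must lie within [0, 1]", "invalid_argument")
  lab <- ifelse(auc >= 1, "perfect",
         ifelse(auc >= 0.9, "excellent",
         ifelse(auc >= 0.8, "good",
         ifelse(auc >= 0.7, "fair", "poor"))))
  factor(lab, levels = c("poor", "fair", "good", "excellent", "perfect"),
         ordered = TRUE)
}

#' Cut-point table for one placement/axis/epoch stratum
#'
#' Three strictly increasing non-negative integer boundaries
#' `(T1, T2, T3)` partition the non-negative integers into four count
#' intervals: non-ambulation `<= T1`, slow `[T1 + 1, T2]`, medium
#' `[T2 + 1, T3]`, fast `>= T3 + 1`.
#'
#' @param boundaries Integer vector `c(T1, T2, T3)`, strictly increasing
#'   and non-negative.
#' @param placement,axis,epoch_length_s,filter_mode Stratum labels.
#' @param roc Optional list of the three boundary [roc_curve()]s.
#' @param optimal Optional list of the three selected operating points.
#' @return An object of class `cutpoint_table`.
#' @export
cutpoint_table <- function(boundaries, placement, axis = "vm",
                           epoch_length_s = 15, filter_mode = "default",
                           roc = NULL, optimal = NULL) {
  if (!is_count_vector(boundaries) || length(boundaries) != 3L)
    stop_speedcuts("boundaries must be three non-negative integers",
                   "invalid_argument")
  if (!(boundaries[1] < boundaries[2] && boundaries[2] < boundaries[3]))
    stop_speedcuts("boundaries must be strictly increasing",
                   "invalid_argument")
  if (!axis %in% c("vertical", "vm"))
    stop_speedcuts("axis must be 'vertical' or 'vm'", "invalid_argument")
  structure(list(boundaries = as.integer(boundaries),
                 placement = placement, axis = axis,
                 epoch_length_s = epoch_length_s,
                 filter_mode = filter_mode, roc = roc, optimal = optimal),
            class = "cutpoint_table")
}

#' @export
print.cutpoint_table <- function(x, ...) {
  iv <- format_cutpoint_intervals(x)
  cat(sprintf("<cutpoint_table> %s %s counts/%g s (%s filter)\n",
              x$placement, x$axis, x$epoch_length_s, x$filter_mode))
  for (i in seq_along(iv))
    cat(sprintf("  %-7s %s\n", speed_categories()[i], iv[i]))
  if (!is.null(x$roc))
    cat(sprintf("  boundary AUCs: %s\n",
                paste(sprintf("%.2f", boundary_aucs(x)), collapse = ", ")))
  invisible(x)
}

#' Boundary AUCs of a calibrated cut-point table
#'
#' @param cuts A [cutpoint_table()] produced by [build_cutpoint_table()].
#' @return Numeric vector of the three boundary AUCs.
#' @export
boundary_aucs <- function(cuts) {
  if (is.null(cuts$roc))
    stop_speedcuts("cut-point table carries no ROC curves",
                   "invalid_argument")
  vapply(cuts$roc, function(r) r$auc, numeric(1))
}

#' Calibrate cut-points from a labelled epoch table
#'
#' Runs three binary ROC analyses on the counts of one
#' placement/axis/epoch stratum. With the default cumulative
#' dichotomization the boundaries split the ordered categories as:
#' non-ambulation vs all walking; non-ambulation + slow vs medium + fast;
#' everything vs fast. (`scheme = "adjacent"` instead contrasts each pair
#' of neighbouring categories.) Each boundary's optimal real threshold
#' `t` -- the closest-to-corner point -- is floored to the integer
#' `T = floor(t)`, giving contiguous integer intervals `<= T` /
#' `>= T + 1`. If noise makes an upper boundary collide with a lower one,
#' the violating boundary is recomputed restricted to thresholds above
#' the lower boundary and the event is reported via [message()].
#'
#' @param table Epoch-table data frame (see [generate_cohort()]) holding
#'   all four categories for the requested stratum.
#' @param placement `"waist"` or `"ankle"`.
#' @param axis `"vertical"` or `"vm"`.
#' @param epoch_length_s 15 or 60.
#' @param filter_mode Filter mode to select (default `"default"`).
#' @param scheme `"cumulative"` (default) or `"adjacent"`.
#' @return A [cutpoint_table()] carrying the three boundary
#'   [roc_curve()]s and selected operating points.
#' @export
build_cutpoint_table <- function(table, placement, axis = "vm",
                                 epoch_length_s = 15,
                                 filter_mode = "default",
                                 scheme = c("cumulative", "adjacent")) {
  scheme <- match.arg(scheme)
  if (!axis %in% c("vertical", "vm"))
    stop_speedcuts("axis must be 'vertical' or 'vm'", "invalid_argument")
  col <- if (axis == "vm") "count_vm" else "count_v"
  sub <- table[table$placement == placement &
                 table$epoch_length_s == epoch_length_s &
                 table$filter_mode == filter_mode, , drop = FALSE]
  cat_num <- as.integer(as_speed_category(sub$category))
  if (length(unique(cat_num)) < 4L)
    stop_speedcuts(sprintf(
      "stratum %s/%s/%g s does not contain all four categories",
      placement, axis, epoch_length_s), "insufficient_classes")
  scores <- sub[[col]]
  rocs <- vector("list", 3)
  opts <- vector("list", 3)
  bounds <- integer(3)
  for (b in 1:3) {
    if (scheme == "cumulative") {
      sel <- rep(TRUE, length(scores))
      pos <- cat_num > b
    } else {
      sel <- cat_num %in% c(b, b + 1)
      pos <- cat_num[sel] == b + 1
    }
    rocs[[b]] <- roc_curve(scores[sel], pos)
    opts[[b]] <- optimal_cutpoint(rocs[[b]])
    bounds[b] <- floor_threshold(opts[[b]]$threshold, scores[sel])
  }
  # enforce strictly increasing boundaries
  for (b in 2:3) {
    if (bounds[b] <= bounds[b - 1]) {
      message(sprintf(
        "boundary %d (T = %d) collided with boundary %d (T = %d); %s",
        b, bounds[b], b - 1, bounds[b - 1],
        "recomputing restricted to higher thresholds"))
      cv <- rocs[[b]]
      ok <- which(is.finite(cv$thresholds) &
                    cv$thresholds > bounds[b - 1] + 1)
      if (length(ok) > 0) {
        d2 <- (1 - cv$sensitivity[ok])^2 + (1 - cv$specificity[ok])^2
        bounds[b] <- floor(cv$thresholds[ok[which.min(d2)]])
      }
      if (bounds[b] <= bounds[b - 1]) bounds[b] <- bounds[b - 1] + 1L
    }
  }
  cutpoint_table(bounds, placement = placement, axis = axis,
                 epoch_length_s = epoch_length_s,
                 filter_mode = filter_mode, roc = rocs, optimal = opts)
}

# Floor an optimal threshold to an integer boundary; infinite thresholds
# (degenerate optima at the curve endpoints) fall back to the observed
# score range.
floor_threshold <- function(t, scores) {
  if (!is.finite(t)) t <- if (t > 0) max(scores) else min(scores) - 1
  as.integer(floor(t))
}

per_category_stats <- function(true, pred) {
  lv <- speed_categories()
  true <- as_speed_category(true)
  pred <- as_speed_category(pred)
  out <- data.frame(category = as_speed_category(lv),
                    n = integer(4), sensitivity = numeric(4),
                    specificity = numeric(4))
  for (i in seq_along(lv)) {
    in_cat <- true == lv[i]
    out$n[i] <- sum(in_cat)
    out$sensitivity[i] <- if (any(in_cat)) mean(pred[in_cat] == lv[i])
                          else NA_real_
    out$specificity[i] <- if (any(!in_cat)) mean(pred[!in_cat] != lv[i])
                          else NA_real_
  }
  out
}

#' Per-category sensitivity and specificity of a cut-point table
#'
#' Classifies every epoch of the table into the cut-point intervals and
#' reports, per category, the sensitivity (fraction of the category's
#' epochs classified into its own interval) and specificity (fraction of
#' all other epochs classified outside that interval).
#'
#' @param table Labelled epoch-table data frame.
#' @param cuts A [cutpoint_table()] for the same placement and epoch
#'   length.
#' @return Data frame with columns `category`, `n`, `sensitivity`,
#'   `specificity`.
#' @export
category_performance <- function(table, cuts) {
  sub <- match_stratum(table, cuts)
  col <- if (cuts$axis == "vm") "count_vm" else "count_v"
  pred <- classify_epoch(sub[[col]], cuts)
  per_category_stats(sub$category, pred)
}

match_stratum <- function(table, cuts) {
  if (!inherits(cuts, "cutpoint_table"))
    stop_speedcuts("`cuts` must be a cutpoint_table", "invalid_argument")
  if (!is.data.frame(table))
    stop_speedcuts("`table` must be a data frame", "invalid_argument")
  if (nrow(table) == 0L) return(table)
  if (!all(table$placement == cuts$placement))
    stop_speedcuts("table placement does not match cut-point table",
                   "invalid_argument")
  if (!all(table$epoch_length_s == cuts$epoch_length_s))
    stop_speedcuts("table epoch length does not match cut-point table",
                   "invalid_argument")
  if (!all(table$filter_mode == cuts$filter_mode))
    stop_speedcuts("table filter mode does not match cut-point table",
                   "invalid_argument")
  table
}
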