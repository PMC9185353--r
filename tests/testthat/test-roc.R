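test_that("ROC curve has valid endpoints, monotone arms and MW AUC", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(20:150, 1)
    scores <- if (rep %% 2 == 0) rnorm(n) else sample(0:30, n, TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    rc <- roc_curve(scores, labels)
    # endpoints (sens, 1-spec) = (0,0) and (1,1)
    expect_equal(rc$sensitivity[1], 0)
    expect_equal(1 - rc$specificity[1], 0)
    expect_equal(rc$sensitivity[length(rc$sensitivity)], 1)
    expect_equal(rc$specificity[length(rc$specificity)], 0)
    # both arms move monotonically as the threshold drops
    expect_true(all(diff(rc$sensitivity) >= 0))
    expect_true(all(diff(1 - rc$specificity) >= 0))
    # trapezoidal AUC equals brute-force pairwise concordance
    expect_equal(rc$auc, mann_whitney_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent ROC implementation", {
  set.seed(55)
  scores <- c(rnorm(80, 1), rnorm(70))
  labels <- c(rep(1, 80), rep(0, 70))
  rc <- roc_curve(scores, labels)
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(rc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("degenerate label sets are rejected", {
  expect_error(roc_curve(1:5, rep(1, 5)), class = "degenerate_labels")
  expect_error(roc_curve(1:5, rep(0, 5)), class = "degenerate_labels")
  expect_error(roc_curve(1:4, c(0, 1, 1)), class = "invalid_argument")
})

test_that("perfect separation attains the corner", {
  rc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(rc$auc, 1)
  opt <- optimal_cutpoint(rc)
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)
  expect_gt(opt$threshold, 3)
  expect_lt(opt$threshold, 10)

  # worked example: U / (n1 n2) oracle on (1,2,3,4) / (0,0,1,1)
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc,
               mann_whitney_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)))
})

test_that("closest-to-corner selection minimizes the corner distance", {
  # hand-built three-point curve: distances sqrt(.17), sqrt(.08),
  # sqrt(.2525) -- the middle point wins
  curve <- structure(list(thresholds = c(30, 20, 10),
                          sensitivity = c(0.6, 0.8, 0.95),
                          specificity = c(0.9, 0.8, 0.5),
                          auc = NA_real_, n_pos = 10, n_neg = 10),
                     class = "roc_curve")
  opt <- optimal_cutpoint(curve)
  expect_equal(opt$sensitivity, 0.8)
  expect_equal(opt$specificity, 0.8)
  expect_equal(opt$threshold, 20)

  single <- structure(list(thresholds = c(Inf, -Inf),
                           sensitivity = c(0, 1), specificity = c(1, 0),
                           auc = 0.5, n_pos = 1, n_neg = 1),
                      class = "roc_curve")
  expect_error(optimal_cutpoint(single), class = "degenerate_curve")
})

test_that("under the null the selected point hovers near the diagonal", {
  set.seed(99)
  sens <- spec <- numeric(100)
  for (i in 1:100) {
    sc <- rnorm(600)
    lb <- rep(c(0, 1), each = 300)
    o <- optimal_cutpoint(roc_curve(sc, lb))
    sens[i] <- o$sensitivity
    spec[i] <- o$specificity
  }
  expect_true(all(sens >= 0.3 & sens <= 0.7))
  expect_true(all(spec >= 0.3 & spec <= 0.7))
})

test_that("cut-point recovery matches the Gaussian closed form", {
  # two unit-variance Gaussians centred at 0 and 2: by symmetry the
  # corner-distance optimum sits at their midpoint, threshold = 1
  set.seed(42)
  recovered <- vapply(1:10, function(i) {
    scores <- c(rnorm(10000, 0), rnorm(10000, 2))
    labels <- rep(c(0, 1), each = 10000)
    optimal_cutpoint(roc_curve(scores, labels))$threshold
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 1), 0.02)
})

test_that("AUC grading follows the conventional bands", {
  expect_equal(as.character(grade_auc(c(0.6, 0.69, 0.7, 0.79, 0.8,
                                        0.85, 0.89, 0.9, 0.99, 1))),
               c("poor", "poor", "fair", "fair", "good", "good", "good",
                 "excellent", "excellent", "perfect"))
  expect_error(grade_auc(1.1), class = "invalid_argument")
  expect_error(grade_auc(-0.1), class = "invalid_argument")
  # non-decreasing step function over a fine grid
  grid <- seq(0, 1, by = 0.005)
  expect_true(all(diff(as.integer(grade_auc(grid))) >= 0))
})

test_that("calibration on separable classes lands between the blocks", {
  tab <- separable_table(40)
  cuts <- build_cutpoint_table(tab, "waist")
  b <- cuts$boundaries
  expect_true(b[1] >= 49 && b[1] < 100)
  expect_true(b[2] >= 199 && b[2] < 300)
  expect_true(b[3] >= 399 && b[3] < 500)
  expect_equal(boundary_aucs(cuts), c(1, 1, 1))

  # round-trip: classification by the recovered cuts reproduces labels
  rep_ <- evaluate(classify_table(tab, cuts))
  expect_equal(rep_$overall_accuracy, 1.0)

  # adjacent-pair dichotomization also yields ordered boundaries here
  adj <- build_cutpoint_table(tab, "waist", scheme = "adjacent")
  expect_true(all(diff(adj$boundaries) > 0))

  expect_error(build_cutpoint_table(tab[tab$category != "med", ], "waist"),
               class = "insufficient_classes")
})

test_that("recovered boundaries are bracketed by adjacent class medians", {
  for (s in 1:3) {
    coh <- generate_cohort(sim_config(placements = "waist", seed = 40 + s))
    b <- build_cutpoint_table(coh, "waist")$boundaries
    expect_true(b[1] < 519 && 519 < b[2] && b[2] < 759 &&
                  759 < b[3] && b[3] < 1147)
  }
})

test_that("colliding boundaries are repaired and reported", {
  # medium counts placed *below* slow counts force boundary 2 to collide
  tab <- make_epoch_table(list(nonamb = rep(0:10, 3),
                               slow = rep(500:540, 2),
                               med = rep(100:140, 2),
                               fast = rep(700:740, 2)))
  expect_message(cuts <- build_cutpoint_table(tab, "waist"),
                 "collided")
  expect_true(all(diff(cuts$boundaries) > 0))
})

test_that("per-category performance matches a direct recount", {
  tab <- separable_table(25)
  cuts <- cutpoint_table(c(75, 250, 450), "waist")
  perf <- category_performance(tab, cuts)
  expect_true(all(perf$sensitivity == 1))
  expect_true(all(perf$specificity == 1))

  # every slow epoch pushed into the med interval: slow sensitivity 0
  shifted <- tab
  shifted$count_vm[shifted$category == "slow"] <- 300L
  perf2 <- category_performance(shifted, cuts)
  expect_equal(perf2$sensitivity[perf2$category == "slow"], 0)

  # random counts: agree with an explicit enumeration oracle
  set.seed(77)
  rnd <- make_epoch_table(list(nonamb = sample(0:600, 50, TRUE),
                               slow = sample(0:600, 50, TRUE),
                               med = sample(0:600, 50, TRUE),
                               fast = sample(0:600, 50, TRUE)))
  perf3 <- category_performance(rnd, cuts)
  pred <- classify_epoch(rnd$count_vm, cuts)
  for (cat in speed_categories()) {
    tp <- sum(rnd$category == cat & pred == cat)
    fn <- sum(rnd$category == cat & pred != cat)
    tn <- sum(rnd$category != cat & pred != cat)
    fp <- sum(rnd$category != cat & pred == cat)
    expect_equal(perf3$sensitivity[perf3$category == cat], tp / (tp + fn))
    expect_equal(perf3$specificity[perf3$category == cat], tn / (tn + fp))
  }
})
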