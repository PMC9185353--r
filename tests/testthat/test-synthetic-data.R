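test_that("sim_config enforces its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(placements = "wrist"), class = "invalid_argument")
  expect_error(sim_config(epoch_length_s = 30), class = "invalid_argument")
  expect_error(sim_config(sampling_rate_hz = 4), class = "invalid_argument")

  # medians must increase slow < med < fast
  cm <- default_class_medians()
  cm$median[cm$placement == "waist" & cm$axis == "vm" &
              cm$epoch_length_s == 15 & cm$category == "med"] <- 400
  expect_error(sim_config(class_medians = cm), class = "invalid_argument")

  # non-ambulation median must sit below the slow median
  cm2 <- default_class_medians()
  cm2$median[cm2$placement == "waist" & cm2$axis == "vm" &
               cm2$epoch_length_s == 15 & cm2$category == "nonamb"] <- 600
  expect_error(sim_config(class_medians = cm2), class = "invalid_argument")
})

test_that("gait signal generator is deterministic and speed-sensitive", {
  cfg <- sim_config()
  expect_error(simulate_gait_signal(0, 60, "waist", cfg),
               class = "invalid_argument")
  expect_error(simulate_gait_signal(3.5, 60, "waist", cfg),
               class = "invalid_argument")
  expect_error(simulate_gait_signal(1, 10, "waist", cfg),
               class = "invalid_argument")

  a <- simulate_gait_signal(1.0, 40, "waist", cfg)
  b <- simulate_gait_signal(1.0, 40, "waist", cfg)
  expect_identical(a$axes, b$axes)

  # dynamic (gravity-removed) RMS grows with speed
  rms_dyn <- function(sig) {
    x <- sig$axes$vertical - mean(sig$axes$vertical)
    sqrt(mean(x^2))
  }
  slow <- simulate_gait_signal(0.5, 60, "waist", cfg)
  fast <- simulate_gait_signal(1.4, 60, "waist", cfg)
  expect_gt(rms_dyn(fast), rms_dyn(slow))

  # ankle moves more than waist at the same speed
  ankle <- simulate_gait_signal(1.0, 60, "ankle", cfg)
  waist <- simulate_gait_signal(1.0, 60, "waist", cfg)
  expect_gt(rms_dyn(ankle), rms_dyn(waist))
})

test_that("non-ambulation signals yield near-zero counts", {
  cfg <- sim_config()
  expect_error(simulate_nonambulation_signal("jogging", 300, cfg),
               class = "invalid_argument")
  expect_error(simulate_nonambulation_signal("sitting", 10, cfg),
               class = "invalid_argument")

  sit <- simulate_nonambulation_signal("sitting", 300, cfg)
  ep <- aggregate_epochs(signal_to_counts(sit), 15)
  expect_equal(median(ep$count_vm), 0)

  # washing dishes stays at or below walking at 0.8 m/s in nearly all
  # paired epochs
  wd_counts <- wk_counts <- integer(0)
  for (r in 1:4) {
    wd <- simulate_nonambulation_signal("washing_dishes", 420, cfg,
                                        seed = 100 + r)
    wk <- simulate_gait_signal(0.8, 420, "waist", cfg, seed = 200 + r)
    wd_counts <- c(wd_counts,
                   aggregate_epochs(signal_to_counts(wd), 15)$count_vm)
    wk_counts <- c(wk_counts,
                   aggregate_epochs(signal_to_counts(wk,
                     placement = "waist"), 15)$count_vm)
  }
  expect_gte(mean(wd_counts[1:100] <= wk_counts[1:100]), 0.95)
})

test_that("direct count sampling hits the configured medians", {
  cfg <- sim_config()
  expect_error(sample_counts_direct("sprint", "waist", "vm", 10, cfg),
               class = "invalid_argument")

  slow <- sample_counts_direct("slow", "waist", "vm", 10000, cfg)
  expect_lt(abs(median(slow) - 519) / 519, 0.05)
  fast <- sample_counts_direct("fast", "ankle", "vm", 10000, cfg)
  expect_lt(abs(median(fast) - 4045) / 4045, 0.05)

  # non-ambulation at 15 s epochs: zero-inflated with median 0
  na15 <- sample_counts_direct("nonamb", "waist", "vm", 10000, cfg)
  expect_equal(median(na15), 0)
  expect_gt(max(na15), 0)

  # degenerate spread collapses every draw onto the median
  cfg0 <- sim_config(dispersion = 0)
  expect_true(all(sample_counts_direct("med", "waist", "vm", 500,
                                       cfg0) == 759L))

  # same stratum, same config: identical draws
  expect_identical(sample_counts_direct("slow", "ankle", "vm", 50, cfg),
                   sample_counts_direct("slow", "ankle", "vm", 50, cfg))
})

test_that("cohort generation applies trimming and the seed contract", {
  coh1 <- generate_cohort(sim_config(n_participants = 1,
                                     placements = "waist", seed = 5))
  walk <- coh1[coh1$task == "walk_self_selected", ]
  expect_equal(nrow(walk), 22L)  # (360 - 2 x 15) / 15
  expect_true(all(walk$category != "nonamb"))
  expect_true(all(coh1$category[coh1$task %in%
    c("sitting", "setting_table", "washing_dishes")] == "nonamb"))
  expect_true(all(is.na(coh1$speed_mps) == (coh1$category == "nonamb")))

  empty <- generate_cohort(sim_config(n_participants = 0))
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty), names(coh1))

  again <- generate_cohort(sim_config(n_participants = 1,
                                      placements = "waist", seed = 5))
  expect_identical(coh1, again)
  other <- generate_cohort(sim_config(n_participants = 1,
                                      placements = "waist", seed = 6))
  expect_false(identical(coh1$count_vm, other$count_vm))
  expect_identical(names(coh1), names(other))
})

test_that("count-level and signal-level cohorts share one schema", {
  cfg <- sim_config(n_participants = 1, placements = "waist", seed = 3)
  by_count <- generate_cohort(cfg, level = "count")
  by_signal <- generate_cohort(cfg, level = "signal")
  expect_identical(names(by_count), names(by_signal))
  expect_identical(lapply(by_count, class), lapply(by_signal, class))
  expect_equal(nrow(by_count), nrow(by_signal))  # same trimming rule
})

test_that("widening class separation raises downstream AUC", {
  widened <- default_class_medians()
  sel <- widened$placement == "waist" & widened$axis == "vm" &
    widened$epoch_length_s == 15
  widened$median[sel] <- c(0, 519, 1100, 2400)
  wins <- 0L
  for (s in 1:10) {
    narrow <- build_cutpoint_table(
      generate_cohort(sim_config(n_participants = 16,
                                 placements = "waist", seed = s)), "waist")
    wide <- build_cutpoint_table(
      generate_cohort(sim_config(n_participants = 16,
                                 placements = "waist",
                                 class_medians = widened, seed = s)),
      "waist")
    if (mean(boundary_aucs(wide)) > mean(boundary_aucs(narrow)))
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
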