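# Independent oracles and fixture builders used across test files.

# Pairwise Mann-Whitney concordance: P(pos > neg) + P(pos == neg) / 2,
# by brute-force enumeration of all positive-negative pairs.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# Build a labelled epoch table directly from count vectors per category.
make_epoch_table <- function(counts_by_category, placement = "waist",
                             epoch_length_s = 15,
                             filter_mode = "default") {
  rows <- lapply(names(counts_by_category), function(cat) {
    vm <- as.integer(counts_by_category[[cat]])
    v <- as.integer(floor(vm * 0.6))
    horiz <- as.integer(round(sqrt(pmax(as.numeric(vm)^2 -
                                          as.numeric(v)^2, 0) / 2)))
    data.frame(participant_id = "P001", placement = placement,
               filter_mode = filter_mode,
               task = if (cat == "nonamb") "sitting"
                      else "walk_self_selected",
               category = factor(cat, levels = speed_categories(),
                                 ordered = TRUE),
               speed_mps = if (cat == "nonamb") NA_real_ else 1,
               epoch_index = seq_along(vm),
               epoch_length_s = epoch_length_s,
               count_v = v, count_ap = horiz, count_ml = horiz,
               count_vm = vm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Four cleanly separated count blocks, one per category.
separable_table <- function(n_per_cat = 30, placement = "waist") {
  make_epoch_table(list(
    nonamb = rep(0:49, length.out = n_per_cat),
    slow = rep(100:199, length.out = n_per_cat),
    med = rep(300:399, length.out = n_per_cat),
    fast = rep(500:599, length.out = n_per_cat)
  ), placement = placement)
}

# A pure sinusoid accel_signal on the vertical axis.
sine_signal <- function(freq_hz, amp_g, duration_s = 60, fs = 30,
                        offset_g = 0) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  accel_signal(offset_g + amp_g * sin(2 * pi * freq_hz * t),
               numeric(length(t)), numeric(length(t)),
               sampling_rate_hz = fs)
}
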