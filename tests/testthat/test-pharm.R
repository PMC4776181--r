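make_protocol <- function() drug_protocol(drug_window = c(120, 180))

test_that("binning conserves spike counts and normalizes baseline to exactly 100", {
  cfg <- spike_sim_config(mean_rate = 5, epoch_duration = 240, seed = 3,
                          isi_model = "poisson_refractory")
  tr <- simulate_spike_train(cfg)
  tc <- bin_rates(tr, make_protocol())
  expect_equal(mean(tc$normalized_pct[tc$phase == "baseline"]), 100)
  covered <- tr$spike_times >= min(tc$bin_start_s) &
    tr$spike_times < max(tc$bin_end_s)
  expect_equal(sum(tc$rate_hz * 20), sum(covered))
  # re-normalizing an already-normalized series is the identity
  renorm <- 100 * tc$normalized_pct /
    mean(tc$normalized_pct[tc$phase == "baseline"])
  expect_equal(renorm, tc$normalized_pct)
})

test_that("percent change recovers injected drug effects", {
  cfg <- spike_sim_config(mean_rate = 5, epoch_duration = 240, seed = 17,
                          isi_model = "poisson_refractory")
  # no effect: ~0 in expectation
  ch0 <- vapply(1:40, function(i) {
    percent_change(bin_rates(simulate_drug_epoch(cfg, 0, c(120, 180), i),
                             make_protocol()))
  }, numeric(1))
  expect_lt(abs(mean(ch0)) / (sd(ch0) / sqrt(40)), 3)

  ch_neg <- vapply(1:40, function(i) {
    percent_change(bin_rates(simulate_drug_epoch(cfg, -0.4, c(120, 180), i),
                             make_protocol()))
  }, numeric(1))
  expect_lt(abs(mean(ch_neg) + 40), 2.5)

  ch_pos <- vapply(1:40, function(i) {
    percent_change(bin_rates(simulate_drug_epoch(cfg, 0.5, c(120, 180), i),
                             make_protocol()))
  }, numeric(1))
  expect_lt(abs(mean(ch_pos) - 50) / (sd(ch_pos) / sqrt(40)), 3.5)
})

test_that("silenced windows and zero baselines take the documented error paths", {
  # all spikes before the drug window: drug bins are exactly 0%
  tr <- spike_train(seq(60.1, 119.9, by = 0.2), 240)
  tc <- bin_rates(tr, make_protocol())
  expect_true(all(tc$normalized_pct[tc$phase == "drug"] == 0))

  # no spikes in the baseline: normalization undefined
  tr2 <- spike_train(seq(130, 170, by = 0.2), 240)
  expect_error(bin_rates(tr2, make_protocol()), class = "dopaphys_zero_baseline")

  expect_error(drug_protocol(drug_window = c(120, 170), bin_width = 20),
               class = "dopaphys_config_error")
  expect_error(drug_protocol(drug_window = c(120, 180),
                             baseline_window = c(100, 140)),
               class = "dopaphys_config_error")
})

test_that("condition contrast summarizes group x condition and flags differences", {
  base <- cohort_firing_table(simulate_spike_cohort(
    spike_sim_config(mean_rate = 1.7, epoch_duration = 120, n_units = 12,
                     seed = 71, isi_model = "pacemaker_gaussian",
                     group = "control", condition = "baseline"), "cb"))
  base2 <- cohort_firing_table(simulate_spike_cohort(
    spike_sim_config(mean_rate = 2.4, epoch_duration = 120, n_units = 12,
                     seed = 72, isi_model = "pacemaker_gaussian",
                     group = "eNRG1", condition = "baseline"), "eb"))
  ptx <- cohort_firing_table(simulate_spike_cohort(
    spike_sim_config(mean_rate = 1.9, epoch_duration = 120, n_units = 12,
                     seed = 73, isi_model = "pacemaker_gaussian",
                     group = "control", condition = "PTX"), "cp"))
  ptx2 <- cohort_firing_table(simulate_spike_cohort(
    spike_sim_config(mean_rate = 1.9, epoch_duration = 120, n_units = 12,
                     seed = 74, isi_model = "pacemaker_gaussian",
                     group = "eNRG1", condition = "PTX"), "ep"))
  tab <- dplyr::bind_rows(base, base2, ptx, ptx2)
  res <- condition_contrast(tab)
  expect_equal(nrow(res$summary), 4L)
  bl <- res$comparisons[grepl("baseline: control vs eNRG1", res$comparisons$measure), ]
  px <- res$comparisons[grepl("PTX: control vs eNRG1", res$comparisons$measure), ]
  # generators differ at baseline and are equalized under PTX
  expect_lt(bl$p_value, 0.05)
  expect_gt(px$p_value, 0.05)

  expect_error(condition_contrast(base, conditions = c("baseline", "wash")),
               class = "dopaphys_config_error")
})

test_that("superfusion response normalizes rate and CV to their own baselines", {
  # build a train whose drug window doubles the rate and doubles the ISI CV
  set.seed(99)
  base_isis <- abs(rnorm(460, 0.2, 0.01))
  drug_isis <- abs(rnorm(600, 0.1, 0.01))       # CV 5% -> 10%
  times <- cumsum(c(30, base_isis))
  times <- times[times < 120]
  t2 <- cumsum(c(120.05, drug_isis))
  t2 <- t2[t2 < 180]
  tr <- spike_train(sort(c(times, t2)), 240)
  proto <- drug_protocol(drug_window = c(120, 180), baseline_window = c(60, 120))
  res <- nmda_response(tr, proto)
  expect_lt(abs(res$frequency_percent - 200), 15)
  expect_lt(abs(res$cv_percent_of_baseline - 200), 40)

  silent <- spike_train(seq(60.1, 119.9, 0.2), 240)
  expect_error(nmda_response(silent, proto),
               class = "dopaphys_insufficient_data")
})
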