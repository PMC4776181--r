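test_that("hand-enumerated spike patterns give the expected bursts", {
  # ISIs 50,50,200,200,50 ms: burst of spikes 1-3, then a pair at the end
  b <- detect_bursts(c(0, 0.05, 0.10, 0.30, 0.50, 0.55))
  expect_equal(nrow(b), 2L)
  expect_equal(b$first_spike, c(1L, 5L))
  expect_equal(b$last_spike, c(3L, 6L))
  expect_equal(b$duration_s, c(0.10, 0.05))

  # no ISI below 80 ms: no onset, no bursts
  expect_equal(nrow(detect_bursts(seq(0, 1, by = 0.1))), 0L)

  # 80-160 ms band continues but cannot open: ISIs 50,120,50 -> one 4-spike burst
  b2 <- detect_bursts(cumsum(c(0, 0.05, 0.12, 0.05)))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$n_spikes, 4L)

  # boundary ties: exactly 80 ms does not open; exactly 160 ms continues
  expect_equal(nrow(detect_bursts(c(0, 0.08, 0.16))), 0L)
  b3 <- detect_bursts(c(0, 0.05, 0.21))
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$n_spikes, 3L)   # the exact-160 ISI extends the open burst

  expect_equal(nrow(detect_bursts(0.5)), 0L)       # <2 spikes: empty, no error
  expect_equal(nrow(detect_bursts(numeric(0))), 0L)
})

test_that("detector agrees with the brute-force rule-applier on random ISI sequences", {
  alphabet <- c(40, 100, 120, 200)
  set.seed(42)
  for (rep in 1:500) {
    len <- sample(1:7, 1)
    isis <- sample(alphabet, len, replace = TRUE)
    b <- detect_bursts(cumsum(c(0, isis / 1000)))
    got <- burst_table_to_labels(b, len + 1L)
    expect_identical(got, oracle_burst_label(isis),
                     info = paste(isis, collapse = ","))
  }
})

test_that("SWB boundary properties hold on simulated trains", {
  set.seed(7)
  for (rep in 1:25) {
    cfg <- spike_sim_config(mean_rate = runif(1, 2, 6),
                            in_burst_fraction = runif(1),
                            epoch_duration = 30, seed = 1000 + rep)
    tr <- simulate_spike_train(cfg)
    st <- burst_stats(tr)
    isis <- isi(tr)
    if (all(isis >= 80)) expect_equal(st$swb_percent, 0)
    if (st$swb_percent == 0) expect_true(all(isis >= 80))
    bs <- detect_bursts(tr)
    in_any <- sum(bs$n_spikes) == length(tr$spike_times)
    expect_equal(st$swb_percent == 100, in_any)
  }
})

test_that("detection is local and translation-invariant", {
  times <- c(0, 0.05, 0.10, 0.30, 0.50, 0.55)
  before <- detect_bursts(times)
  # appending a spike more than 160 ms after the last never changes bursts
  after <- detect_bursts(c(times, max(times) + 0.2))
  expect_equal(before$first_spike, after$first_spike[seq_len(nrow(before))])
  expect_equal(before$last_spike, after$last_spike[seq_len(nrow(before))])
  # uniform time translation
  shifted <- detect_bursts(times + 17.3)
  expect_equal(shifted$first_spike, before$first_spike)
  expect_equal(shifted$n_spikes, before$n_spikes)
  expect_equal(shifted$duration_s, before$duration_s)
})

test_that("detector SWB equals ground-truth label fraction on packet-built trains", {
  for (s in 1:10) {
    cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.5,
                            epoch_duration = 120, seed = 100 + s)
    tr <- simulate_spike_train(cfg)
    st <- burst_stats(tr)
    expect_equal(st$swb_percent, 100 * mean(ground_truth(tr)$in_burst))
  }
})

test_that("burst statistics follow their definitions", {
  tr <- spike_train(c(0, 0.05, 0.10, 0.30, 0.50, 0.55), 2,
                    spike_durations = rep(1.5, 6))
  st <- burst_stats(tr)
  expect_equal(st$swb_percent, 100 * 5 / 6)
  expect_equal(st$mean_rate_hz, 3)
  expect_equal(st$n_bursts, 2L)

  # tonic: no bursts, NA duration
  tonic <- spike_train(seq(0.1, 119.9, by = 0.25), 120)
  st2 <- burst_stats(tonic)
  expect_equal(st2$swb_percent, 0)
  expect_equal(st2$burst_frequency_hz, 0)
  expect_true(is.na(st2$mean_burst_duration_s))

  # a single burst in a 2-minute epoch: frequency 1/120
  one <- spike_train(cumsum(c(1, rep(0.05, 9))), 120)
  expect_equal(burst_stats(one)$burst_frequency_hz, 1 / 120)

  # burst set from a different train is refused
  other <- detect_bursts(spike_train(c(0.1, 0.15, 0.9), 2))
  expect_error(burst_stats(tr, other), class = "dopaphys_validation_error")
})

test_that("QC applies the in vivo unit rule and the in vitro spike rule", {
  ok <- spike_train(c(0.1, 0.2, 0.3), 2, unit_id = "broad",
                    spike_durations = c(1.5, 1.5, 1.5), setting = "in_vivo")
  narrow <- spike_train(c(0.1, 0.2, 0.3), 2, unit_id = "narrow",
                        spike_durations = c(0.9, 0.9, 0.9), setting = "in_vivo")
  vitro <- spike_train(c(0.1, 0.2, 0.3), 2, unit_id = "slice",
                       spike_durations = c(2.5, 1.0, 2.5), setting = "in_vitro")
  res <- qc_filter_units(list(ok, narrow, vitro))
  expect_named(res$accepted, c("broad", "slice"))
  expect_equal(res$rejected$unit_id, "narrow")
  expect_match(res$rejected$reason, "duration<1.1ms")
  expect_length(res$accepted$slice$spike_times, 2L)

  no_dur <- spike_train(c(0.1, 0.2), 2)
  expect_error(qc_filter_units(list(no_dur)), class = "dopaphys_validation_error")
})

test_that("cohort table carries one row per unit and group SWB tracks the regimes", {
  lo <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.31,
                         epoch_duration = 120, n_units = 8, seed = 51,
                         group = "control")
  hi <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.67,
                         epoch_duration = 120, n_units = 8, seed = 61,
                         group = "eNRG1")
  tab <- cohort_firing_table(c(simulate_spike_cohort(lo, "a"),
                               simulate_spike_cohort(hi, "b")))
  expect_equal(nrow(tab), 16L)
  means <- tapply(tab$swb_percent, tab$group, mean)
  expect_gt(means[["eNRG1"]], means[["control"]])

  expect_equal(nrow(cohort_firing_table(list())), 0L)
})
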