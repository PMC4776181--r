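test_that("simulations are seed-deterministic and seeds differ", {
  cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.5,
                          epoch_duration = 60, seed = 3)
  a <- simulate_spike_train(cfg)
  b <- simulate_spike_train(cfg)
  expect_identical(a$spike_times, b$spike_times)
  expect_identical(ground_truth(a), ground_truth(b))
  cfg2 <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.5,
                           epoch_duration = 60, seed = 4)
  expect_false(identical(simulate_spike_train(cfg2)$spike_times, a$spike_times))

  tcfg <- trace_sim_config(duration = 5, seed = 7)
  expect_identical(simulate_mipsc_trace(tcfg)$current,
                   simulate_mipsc_trace(tcfg)$current)
})

test_that("degenerate in-burst targets give pure-singleton and all-burst trains", {
  cfg0 <- spike_sim_config(mean_rate = 4, in_burst_fraction = 0,
                           epoch_duration = 60, seed = 1)
  tr0 <- simulate_spike_train(cfg0)
  expect_false(any(ground_truth(tr0)$in_burst))
  expect_equal(burst_stats(tr0)$swb_percent, 0)

  cfg1 <- spike_sim_config(mean_rate = 5, in_burst_fraction = 1,
                           burst_sizes = 5, epoch_duration = 60, seed = 2)
  tr1 <- simulate_spike_train(cfg1)
  gt1 <- ground_truth(tr1)
  expect_true(all(gt1$in_burst))
  expect_equal(burst_stats(tr1)$swb_percent, 100)
})

test_that("in-burst spike fraction hits its target across a 53-unit cohort", {
  cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.67,
                          epoch_duration = 120, n_units = 53, seed = 21)
  cohort <- simulate_spike_cohort(cfg)
  labels <- unlist(lapply(cohort, function(tr) ground_truth(tr)$in_burst))
  expect_lt(abs(mean(labels) - 0.67), 0.05)
})

test_that("realized mean rates match the configured rate for all ISI models", {
  for (model in c("two_state_burst", "pacemaker_gaussian", "poisson_refractory")) {
    cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.67,
                            epoch_duration = 120, n_units = 200, seed = 31,
                            isi_model = model)
    rates <- vapply(simulate_spike_cohort(cfg),
                    function(tr) length(tr$spike_times) / tr$epoch_duration,
                    numeric(1))
    se <- sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(rates) - 5) / se, 3)
  }
})

test_that("infeasible burst configurations are rejected", {
  cfg <- spike_sim_config(mean_rate = 12, in_burst_fraction = 0.3,
                          epoch_duration = 10, seed = 1)
  expect_error(simulate_spike_train(cfg), class = "dopaphys_config_error")
  expect_error(spike_sim_config(intra_burst_isi_ms = c(90, 10)),
               class = "dopaphys_config_error")
  expect_error(spike_sim_config(inter_event_isi_ms = c(150, 10)),
               class = "dopaphys_config_error")
})

test_that("mIPSC generator produces calibrated events and clean null traces", {
  # zero-rate: pure noise in, zero events out at the 8 pA threshold
  tr0 <- simulate_mipsc_trace(trace_sim_config(event_rate = 0, duration = 30,
                                               noise_sd = 1.5, seed = 5))
  expect_equal(nrow(detect_minis(tr0)), 0L)

  # noiseless isolated events deflect the trace by exactly the drawn amplitude
  cfg <- trace_sim_config(event_rate = 0.2, duration = 30, noise_sd = 0,
                          seed = 6)
  tr <- simulate_mipsc_trace(cfg)
  gt <- attr(tr, "truth")
  expect_gt(nrow(gt), 2)
  for (i in seq_len(nrow(gt))) {
    sel <- trace_times(tr) >= gt$onset_time_s[i] &
      trace_times(tr) <= gt$onset_time_s[i] + 0.03
    expect_lt(abs(max(cfg$baseline_pa - tr$current[sel]) - gt$amplitude_pa[i]),
              0.05)
  }

  # Poisson event count lies in the 99% interval around rate * duration
  gt2 <- attr(simulate_mipsc_trace(trace_sim_config(duration = 120,
                                                    event_rate = 2, seed = 8)),
              "truth")
  expect_gte(nrow(gt2), qpois(0.005, 240))
  expect_lte(nrow(gt2), qpois(0.995, 240))

  expect_error(trace_sim_config(duration = 1e6, event_rate = 10),
               class = "dopaphys_config_error")
  expect_error(trace_sim_config(tau_rise_ms = 7, tau_decay_ms = 5),
               class = "dopaphys_config_error")
})

test_that("drug-epoch modulation thins or superposes only inside the window", {
  cfg <- spike_sim_config(mean_rate = 5, epoch_duration = 240, seed = 13,
                          isi_model = "poisson_refractory")
  base <- simulate_spike_train(cfg)
  same <- simulate_drug_epoch(cfg, effect = 0, drug_window = c(120, 180))
  expect_identical(same$spike_times, base$spike_times)

  dimmed <- simulate_drug_epoch(cfg, effect = -1 + 1e-9, drug_window = c(120, 180))
  expect_lte(sum(dimmed$spike_times >= 120 & dimmed$spike_times < 180), 1L)
  # outside the window the base train is untouched
  expect_identical(dimmed$spike_times[dimmed$spike_times < 120],
                   base$spike_times[base$spike_times < 120])

  rates <- vapply(1:30, function(i) {
    tr <- simulate_drug_epoch(cfg, effect = -0.4, drug_window = c(120, 180),
                              unit_index = i)
    sum(tr$spike_times >= 120 & tr$spike_times < 180) / 60
  }, numeric(1))
  expect_lt(abs(mean(rates) - 3) / (sd(rates) / sqrt(30)), 3)

  boosted <- simulate_drug_epoch(cfg, effect = 0.5, drug_window = c(120, 180))
  expect_gt(sum(boosted$spike_times >= 120 & boosted$spike_times < 180),
            sum(base$spike_times >= 120 & base$spike_times < 180))

  expect_error(simulate_drug_epoch(cfg, effect = -0.4, drug_window = c(200, 300)),
               class = "dopaphys_config_error")
  expect_error(simulate_drug_epoch(cfg, effect = -1, drug_window = c(120, 180)),
               class = "dopaphys_config_error")
})

test_that("step-response generators carry analytic ground truth", {
  ahp <- simulate_step_response("ahp", list(amplitude_pa = 100, tau_ms = 50))
  expect_equal(attr(ahp, "truth")$charge_pa_ms, 5000)
  expect_equal(max(ahp$current) - (-20), 100, tolerance = 1e-6)

  gb <- simulate_step_response("gaba_puff", list(amplitude_pa = 800))
  expect_equal(min(gb$current), -20 - attr(gb, "truth")$peak_pa,
               tolerance = 1e-6)
  expect_lt(abs(attr(gb, "truth")$peak_pa - 800), 1)

  ih <- simulate_step_response("ih", list(i_h_pa = 425))
  expect_equal(attr(ih, "truth")$i_h_pa, 425)

  expect_error(simulate_step_response("nonsense"))
})
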