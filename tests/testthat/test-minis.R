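test_that("detector recovers simulated events with high hit rate and low bias", {
  cfg <- trace_sim_config(seed = 7)            # 120 s, 2 Hz, 30 +/- 5 pA
  trace <- simulate_mipsc_trace(cfg)
  gt <- attr(trace, "truth")
  ev <- detect_minis(trace)
  acc <- ev[!ev$is_double_peak, ]

  expect_lt(abs(nrow(ev) / 120 - nrow(gt) / 120) / (nrow(gt) / 120), 0.1)
  expect_lt(abs(mean(acc$amplitude_pa) - mean(gt$amplitude_pa)) /
              mean(gt$amplitude_pa), 0.1)
  hits <- vapply(gt$onset_time_s,
                 function(t) any(abs(ev$onset_time_s - t) <= 0.002), logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure noise produces essentially no detections", {
  tr <- simulate_mipsc_trace(trace_sim_config(event_rate = 0, duration = 60,
                                              noise_sd = 1.5, seed = 3))
  expect_equal(nrow(detect_minis(tr)), 0L)
  tr2 <- simulate_mipsc_trace(trace_sim_config(event_rate = 0, duration = 120,
                                               noise_sd = 2, seed = 4))
  expect_lt(nrow(detect_minis(tr2)) / 120, 0.05)
})

test_that("detection rejects unsuitable traces", {
  slow <- current_trace(rnorm(1000), 1000, protocol = "mipsc")
  expect_error(detect_minis(slow), class = "dopaphys_resolution_error")
  wrong <- current_trace(rnorm(1000), 5000, protocol = "ahp")
  expect_error(detect_minis(wrong), class = "dopaphys_protocol_error")
})

test_that("overlapping events 3 ms apart are flagged as double peaks", {
  fs <- 5000
  n <- fs * 2
  x <- rep(-20, n)
  ker <- 30 * dopaphys:::biexp_kernel(1.5, 7, 1 / fs)
  for (t0 in c(1.000, 1.003)) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0:(i0 + length(ker) - 1L)
    x[idx] <- x[idx] - ker
  }
  tr <- current_trace(x, fs, protocol = "mipsc")
  ev <- detect_minis(tr, detection_config(smooth_ms = 0))
  expect_gte(nrow(ev), 1L)
  expect_true(any(ev$is_double_peak))
  # and the flagged event is excluded from kinetics
  ek <- event_kinetics(ev, tr)
  expect_true(all(is.na(ek$decay_tau_ms[ek$is_double_peak])))
})

test_that("noiseless kinetics are recovered exactly", {
  fs <- 10000
  x <- rep(-20, fs * 2)
  ker <- 30 * dopaphys:::biexp_kernel(1.5, 7, 1 / fs)
  i0 <- fs
  x[i0:(i0 + length(ker) - 1L)] <- x[i0:(i0 + length(ker) - 1L)] - ker
  tr <- current_trace(x, fs, protocol = "mipsc")
  ev <- detect_minis(tr, detection_config(smooth_ms = 0))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$amplitude_pa - 30), 0.05)
  ek <- event_kinetics(ev, tr, detection_config(smooth_ms = 0))
  expect_lt(abs(ek$decay_tau_ms - 7) / 7, 0.01)
  expect_lt(abs(ek$rise_time_ms - oracle_biexp_rise(1.5, 7)), 0.05)
})

test_that("detection is invariant to time shift and holding-current offset", {
  cfg <- trace_sim_config(duration = 30, seed = 12)
  tr <- simulate_mipsc_trace(cfg)
  ev <- detect_minis(tr)
  shifted <- current_trace(tr$current - 55, tr$sampling_rate, protocol = "mipsc")
  ev2 <- detect_minis(shifted)
  expect_equal(ev2$onset_index, ev$onset_index)
  expect_equal(ev2$amplitude_pa, ev$amplitude_pa, tolerance = 1e-10)
  delayed <- current_trace(c(rep(tr$current[1], 5000), tr$current),
                           tr$sampling_rate, protocol = "mipsc")
  ev3 <- detect_minis(delayed)
  expect_equal(nrow(ev3), nrow(ev))
  expect_equal(ev3$peak_index - 5000L, ev$peak_index)
})

test_that("cell summary enforces the >50-event rule for kinetics", {
  short <- simulate_mipsc_trace(trace_sim_config(duration = 20, event_rate = 2,
                                                 seed = 5))
  ev <- detect_minis(short)
  cs <- cell_summary(ev, short)
  expect_lt(cs$n_clean_events, 51)
  expect_true(is.na(cs$decay_tau_ms))
  expect_false(is.na(cs$mean_amplitude_pa))
  expect_gt(cs$event_frequency_hz, 0)

  empty <- simulate_mipsc_trace(trace_sim_config(duration = 20, event_rate = 0,
                                                 noise_sd = 1, seed = 6))
  cs0 <- cell_summary(detect_minis(empty), empty)
  expect_equal(cs0$event_frequency_hz, 0)
  expect_true(is.na(cs0$mean_amplitude_pa))

  long <- simulate_mipsc_trace(trace_sim_config(duration = 60, event_rate = 2,
                                                seed = 7))
  evl <- detect_minis(long)
  csl <- cell_summary(evl, long)
  expect_gt(csl$n_clean_events, 50)
  expect_false(is.na(csl$decay_tau_ms))
  # averaged-waveform and per-event kinetics agree on homogeneous events
  csp <- cell_summary(evl, long, kinetics = "per_event")
  expect_lt(abs(csl$decay_tau_ms - csp$decay_tau_ms) / csp$decay_tau_ms, 0.25)
})

test_that("pooling draws exactly the requested events per cell, reproducibly", {
  set.seed(31)
  ev <- tibble::tibble(
    cell_id = rep(c("a", "b", "c", "small"), c(150, 150, 150, 40)),
    group = rep(c("g1", "g1", "g2", "g2"), c(150, 150, 150, 40)),
    amplitude_pa = rnorm(490, 30, 5),
    is_double_peak = FALSE)
  expect_message(pooled <- pool_for_cumulative(ev, 100, seed = 2), "small")
  expect_equal(nrow(pooled), 300L)
  expect_equal(as.integer(table(pooled$cell_id)), c(100L, 100L, 100L))
  pooled2 <- suppressMessages(pool_for_cumulative(ev, 100, seed = 2))
  expect_identical(pooled$amplitude_pa, pooled2$amplitude_pa)
})

test_that("pooled KS comparison detects a 5 pA amplitude shift across cohorts", {
  set.seed(8)
  mk <- function(gr, mu, n_cells) {
    tibble::tibble(
      cell_id = rep(sprintf("%s%02d", gr, 1:n_cells), each = 120),
      group = gr, amplitude_pa = rnorm(120 * n_cells, mu, 5),
      is_double_peak = FALSE)
  }
  ev <- dplyr::bind_rows(mk("ctl", 30, 15), mk("trt", 25, 15))
  pooled <- pool_for_cumulative(ev, 100, seed = 3)
  ks <- ks_comparison(pooled$amplitude_pa[pooled$group == "ctl"],
                      pooled$amplitude_pa[pooled$group == "trt"],
                      measure = "amplitude")
  expect_lt(ks$p_value, 0.01)
})
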