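test_that("spike-train CSV reader handles minimal files and attaches metadata", {
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeLines(c("unit_id,spike_time_s", "u1,0.1", "u1,0.2"), csv)
  jsonlite::write_json(list(u1 = list(epoch_duration_s = 2, group = "control",
                                      condition = "baseline", setting = "in_vivo")),
                       js, auto_unbox = TRUE)
  trains <- read_spike_trains(csv, js)
  expect_length(trains, 1L)
  expect_equal(length(trains$u1$spike_times), 2L)
  expect_equal(trains$u1$epoch_duration, 2)
  expect_equal(trains$u1$group, "control")
})

test_that("spike-train reader rejects malformed input with named units", {
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  writeLines(c("unit_id,spike_time_s", "u1,0.2", "u1,0.1"), csv)
  jsonlite::write_json(list(u1 = list(epoch_duration_s = 2)), js, auto_unbox = TRUE)
  expect_error(read_spike_trains(csv, js), class = "dopaphys_validation_error")
  expect_error(read_spike_trains(csv, js), "u1")

  writeLines(c("unit,t", "u1,0.1"), csv)
  expect_error(read_spike_trains(csv, js), class = "dopaphys_format_error")
  expect_error(read_spike_trains("no/such/file.csv", js),
               class = "dopaphys_format_error")
})

test_that("spike-train write/read round trip is the identity on a 50-unit cohort", {
  cfg <- spike_sim_config(mean_rate = 4, in_burst_fraction = 0.4, n_units = 50,
                          epoch_duration = 30, seed = 11)
  cohort <- simulate_spike_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spike_trains(cohort, csv)
  back <- read_spike_trains(csv)
  expect_equal(length(back), 50L)
  for (id in names(cohort)) {
    expect_equal(back[[id]]$spike_times, cohort[[id]]$spike_times)
    expect_equal(back[[id]]$spike_durations, cohort[[id]]$spike_durations)
    expect_equal(back[[id]]$epoch_duration, cohort[[id]]$epoch_duration)
    expect_equal(back[[id]]$group, cohort[[id]]$group)
    expect_equal(back[[id]]$setting, cohort[[id]]$setting)
  }
})

test_that("spike_train constructor enforces its invariants", {
  expect_error(spike_train(c(0.1, 0.1), 1), class = "dopaphys_validation_error")
  expect_error(spike_train(c(0.1, 2.5), 1), class = "dopaphys_validation_error")
  expect_error(spike_train(0.1, 1, spike_durations = c(1, 2)),
               class = "dopaphys_validation_error")
  expect_error(spike_train(0.1, 1, spike_durations = -1),
               class = "dopaphys_validation_error")
  expect_silent(spike_train(numeric(0), 10))
})

test_that("trace round trip is bit-exact and malformed headers error", {
  cfg <- trace_sim_config(duration = 2, seed = 5)
  tr <- simulate_mipsc_trace(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_current_trace(tr, path)
  back <- read_current_trace(path)
  expect_identical(back$current, tr$current)
  expect_equal(back$sampling_rate, tr$sampling_rate)
  expect_equal(back$protocol, "mipsc")

  writeLines(c("# protocol=mipsc", "current_pa", "1", "2"), path)
  expect_error(read_current_trace(path), class = "dopaphys_format_error")
  expect_error(current_trace(c(1, NaN), 1000),
               class = "dopaphys_validation_error")
})

test_that("trace duration follows n / sampling_rate", {
  tr <- current_trace(rnorm(1000), 10000)
  expect_equal(trace_duration(tr), 0.1)
})

test_that("summary tables round trip and reject heterogeneous records", {
  cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.5,
                          epoch_duration = 20, n_units = 3, seed = 2)
  tab <- cohort_firing_table(simulate_spike_cohort(cfg))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(tab, path)
  back <- read_summary_table(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$swb_percent, tab$swb_percent)
  expect_equal(names(back), names(tab))

  write_summary_table(tab[0, ], path)   # degenerate: header-only
  expect_equal(nrow(read_summary_table(path)), 0L)

  expect_error(write_summary_table(list(tab[1, ], tab[1, c(1, 3)]), path),
               class = "dopaphys_type_error")
})

test_that("ground-truth labels survive the spike serialization round trip", {
  cfg <- spike_sim_config(mean_rate = 5, in_burst_fraction = 0.6,
                          epoch_duration = 30, seed = 9)
  tr <- simulate_spike_train(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  truth_path <- withr::local_tempfile(fileext = ".json")
  write_spike_trains(tr, csv)
  jsonlite::write_json(ground_truth(tr), truth_path, digits = NA)
  back <- read_spike_trains(csv)[[1]]
  gt <- tibble::as_tibble(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  expect_equal(gt$spike_time_s, back$spike_times)
  expect_equal(gt$in_burst, ground_truth(tr)$in_burst)
})
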