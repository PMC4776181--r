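#' Detect bursts with the 80/160 ms (Grace-Bunney) criterion
#'
#' Scanning interspike intervals left to right, a burst opens at the first
#' ISI strictly below `onset_ms` (both spikes of the onset pair belong to the
#' burst), extends while each following ISI is at most `offset_ms`, and
#' terminates at the first ISI strictly above `offset_ms`. ISIs in the
#' continuation band `[onset_ms, offset_ms]` extend an open burst but never
#' open one. An ISI of exactly `onset_ms` does not open a burst; an ISI of
#' exactly `offset_ms` continues one. Minimum burst size is 2 spikes.
#'
#' @param train A [spike_train()] (or bare numeric vector of spike times in
#'   seconds).
#' @param onset_ms Burst-onset ISI bound in ms (default 80).
#' @param offset_ms Burst-termination ISI bound in ms (default 160).
#' @return A tibble of class `burst_set`, one row per burst:
#'   `first_spike`, `last_spike` (1-based indices into the spike times),
#'   `n_spikes`, `onset_time_s`, `duration_s`. Fewer than 2 spikes yield an
#'   empty burst set (not an error).
#' @export
detect_bursts <- function(train, onset_ms = 80, offset_ms = 160) {
  times <- if (inherits(train, "spike_train")) train$spike_times else as.numeric(train)
  n <- length(times)
  empty <- tibble(first_spike = integer(0), last_spike = integer(0),
                  n_spikes = integer(0), onset_time_s = numeric(0),
                  duration_s = numeric(0))
  class(empty) <- c("burst_set", class(empty))
  attr(empty, "n_spikes_total") <- n
  if (n < 2L) return(empty)
  isi_ms <- diff(times) * 1000
  m <- n - 1L
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i <= m) {
    if (isi_ms[i] < onset_ms) {
      j <- i + 1L
      while (j <= m && isi_ms[j] <= offset_ms) j <- j + 1L
      first <- c(first, i)
      last <- c(last, j)          # spike j is the last one inside the burst
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- tibble(first_spike = first, last_spike = last,
                n_spikes = last - first + 1L,
                onset_time_s = times[first],
                duration_s = times[last] - times[first])
  class(out) <- c("burst_set", class(out))
  attr(out, "n_spikes_total") <- n
  out
}

#' Firing-pattern statistics of one unit
#'
#' Computes the per-unit statistics tabulated for dopaminergic cohorts:
#' mean rate, percentage of spikes within bursts (SWB), burst frequency,
#' mean burst duration, and the ISI coefficient of variation from
#' [cv_of_isis()]. Burst frequency is reported in Hz (bursts per second).
#'
#' @param train A [spike_train()].
#' @param bursts Optional [detect_bursts()] result for this train; computed
#'   if missing. A burst set whose spike count does not match the train is a
#'   validation error.
#' @param cv_bin_width_ms Histogram bin width handed to [cv_of_isis()].
#' @return One-row tibble: `unit_id`, `group`, `condition`, `setting`,
#'   `n_spikes`, `n_bursts`, `mean_rate_hz`, `swb_percent`,
#'   `burst_frequency_hz`, `mean_burst_duration_s` (NA when no bursts),
#'   `cv_isi_percent`, `cv_fallback`.
#' @export
burst_stats <- function(train, bursts = NULL, cv_bin_width_ms = 10) {
  stopifnot(inherits(train, "spike_train"))
  bursts <- bursts %||% detect_bursts(train)
  n <- length(train$spike_times)
  if (!is.null(attr(bursts, "n_spikes_total")) &&
      attr(bursts, "n_spikes_total") != n) {
    abort(sprintf("unit '%s': burst set was computed from a different train.",
                  train$unit_id), class = "dopaphys_validation_error")
  }
  n_in_burst <- sum(bursts$n_spikes)
  cv <- tryCatch(cv_of_isis(train, bin_width_ms = cv_bin_width_ms),
                 dopaphys_insufficient_data = function(e) NULL)
  tibble(
    unit_id = train$unit_id, group = train$group, condition = train$condition,
    setting = train$setting,
    n_spikes = n, n_bursts = nrow(bursts),
    mean_rate_hz = n / train$epoch_duration,
    swb_percent = if (n > 0) 100 * n_in_burst / n else NA_real_,
    burst_frequency_hz = nrow(bursts) / train$epoch_duration,
    mean_burst_duration_s = if (nrow(bursts) > 0) mean(bursts$duration_s) else NA_real_,
    cv_isi_percent = if (is.null(cv)) NA_real_ else cv$cv_percent,
    cv_fallback = if (is.null(cv)) NA else cv$fallback_used)
}

#' Apply unit-inclusion criteria based on spike waveform duration
#'
#' In vivo, units are dopaminergic candidates only if their spikes are broad:
#' a unit is retained when its median spike duration (onset to negative
#' peak) is at least `in_vivo_min_ms` (default 1.1 ms). In vitro, individual
#' spikes shorter than `in_vitro_min_ms` (default 2 ms) are dropped from the
#' train before any statistic; the unit itself is kept. The in vivo rule is
#' summarized per unit by the median because the inclusion criterion is
#' stated per unit while durations are measured per spike.
#'
#' @param trains List of [spike_train()] objects, each with
#'   `spike_durations` present (missing durations are a validation error).
#' @param in_vivo_min_ms,in_vitro_min_ms Duration cutoffs in ms.
#' @return List with `accepted` (list of trains, in vitro ones already
#'   filtered spike-wise) and `rejected` (tibble `unit_id`, `reason`).
#' @export
qc_filter_units <- function(trains, in_vivo_min_ms = 1.1, in_vitro_min_ms = 2) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  accepted <- list()
  rejected <- tibble(unit_id = character(0), reason = character(0))
  for (tr in trains) {
    if (is.null(tr$spike_durations)) {
      abort(sprintf("unit '%s': spike_durations required for QC.", tr$unit_id),
            class = "dopaphys_validation_error")
    }
    if (tr$setting == "in_vivo") {
      if (length(tr$spike_times) == 0L ||
          median(tr$spike_durations) < in_vivo_min_ms) {
        rejected <- dplyr::bind_rows(
          rejected, tibble(unit_id = tr$unit_id,
                           reason = sprintf("duration<%.1fms", in_vivo_min_ms)))
      } else {
        accepted[[tr$unit_id]] <- tr
      }
    } else {
      keep <- tr$spike_durations >= in_vitro_min_ms
      filtered <- spike_train(tr$spike_times[keep], tr$epoch_duration,
                              unit_id = tr$unit_id,
                              spike_durations = tr$spike_durations[keep],
                              group = tr$group, condition = tr$condition,
                              setting = tr$setting)
      accepted[[tr$unit_id]] <- filtered
    }
  }
  list(accepted = accepted, rejected = rejected)
}

#' Per-unit firing statistics for a cohort
#'
#' One row of [burst_stats()] per QC-passed unit; this is the table the
#' group-level statistics consume.
#'
#' @param trains List of [spike_train()] objects (already QC-filtered).
#' @param cv_bin_width_ms Passed to [burst_stats()].
#' @return Tibble with one row per unit (zero-row with full schema for empty
#'   input).
#' @export
cohort_firing_table <- function(trains, cv_bin_width_ms = 10) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  if (length(trains) == 0L) {
    return(burst_stats(spike_train(c(0.1, 0.2), 1), cv_bin_width_ms = cv_bin_width_ms)[0, ])
  }
  purrr::map_dfr(trains, burst_stats, cv_bin_width_ms = cv_bin_width_ms)
}
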