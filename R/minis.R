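# Miniature synaptic event detection and kinetics.
#
# Detection scheme: the trace is lightly boxcar-smoothed, a trailing
# local-median baseline is subtracted, and inward deflections exceeding the
# amplitude threshold for a minimum dwell time become candidate events. The
# baseline is frozen at its pre-crossing value for all per-event
# measurements so the event itself cannot drag its own reference down.

#' Detection settings for miniature synaptic events
#'
#' @param threshold_pa Amplitude threshold in pA (default 8, the conventional
#'   mini-detection level).
#' @param baseline_ms Trailing local-median baseline window (default 50 ms).
#' @param min_interevent_ms Refractory gap between event onsets (default 5 ms).
#' @param peak_search_ms Window after the threshold crossing searched for the
#'   peak (default 10 ms).
#' @param smooth_ms Boxcar pre-smoothing width (default 0.6 ms). Smoothing is
#'   what keeps the false-positive rate negligible at threshold-to-noise
#'   ratios of ~4; its bias on a 1.5 ms rise-time event peak is ~0.1%.
#' @param min_above_ms Minimum dwell above threshold (default 0.4 ms).
#' @param onset_lookback_ms How far before the crossing the sub-10%-of-peak
#'   onset sample is searched (default 10 ms).
#' @param decay_limit_ms Longest span after the peak considered for the decay
#'   (default 100 ms).
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold_pa = 8, baseline_ms = 50,
                             min_interevent_ms = 5, peak_search_ms = 10,
                             smooth_ms = 0.6, min_above_ms = 0.4,
                             onset_lookback_ms = 10, decay_limit_ms = 100) {
  stopifnot_scalar_number(threshold_pa, "threshold_pa", min = 1e-9)
  stopifnot_scalar_number(baseline_ms, "baseline_ms", min = 1e-9)
  structure(list(threshold_pa = threshold_pa, baseline_ms = baseline_ms,
                 min_interevent_ms = min_interevent_ms,
                 peak_search_ms = peak_search_ms, smooth_ms = smooth_ms,
                 min_above_ms = min_above_ms,
                 onset_lookback_ms = onset_lookback_ms,
                 decay_limit_ms = decay_limit_ms),
            class = "detection_config")
}

# Local maxima of y with prominence >= prom; returns indices.
find_peaks <- function(y, prom) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left and right to the higher of the bounding minima
    left_min <- min(y[1:i])
    right_min <- min(y[i:n])
    keep[k] <- (y[i] - max(left_min, right_min)) >= prom
  }
  cand[keep]
}

#' Detect miniature synaptic events in a voltage-clamp trace
#'
#' Events are inward (negative) current deflections whose baseline-subtracted
#' magnitude exceeds `threshold_pa`. Amplitude is measured baseline-to-peak
#' with the baseline frozen at its value just before the threshold crossing;
#' the onset is the last sample below 10% of the peak before the crossing.
#' Events in which a second rise is registered before the current has decayed
#' to 50% of the peak — either a dip-and-rebound of at least the threshold,
#' or a second prominent hump in the rising-phase slope (merged events have
#' no dip) — are flagged `is_double_peak`; they still count as events, but
#' are excluded from amplitude pooling and kinetics averaging downstream.
#'
#' @param trace A [current_trace()] with protocol `"mipsc"`; sampling rates
#'   below 2 kHz are a resolution error (rise times unresolvable).
#' @param cfg A [detection_config()].
#' @return Tibble of class `mini_events`, one row per event: `onset_time_s`,
#'   `onset_index`, `peak_time_s`, `peak_index`, `amplitude_pa` (positive
#'   magnitude), `baseline_pa`, `is_double_peak`. Attributes carry the trace
#'   duration, cell/group and config.
#' @export
detect_minis <- function(trace, cfg = detection_config()) {
  stopifnot(inherits(trace, "current_trace"), inherits(cfg, "detection_config"))
  if (trace$protocol != "mipsc") {
    abort(sprintf("cell '%s': protocol is '%s', expected 'mipsc'.",
                  trace$cell_id, trace$protocol), class = "dopaphys_protocol_error")
  }
  fs <- trace$sampling_rate
  if (fs < 2000) {
    abort("sampling rate below 2 kHz: rise times unresolvable.",
          class = "dopaphys_resolution_error")
  }
  ms <- fs / 1000
  xs <- boxcar(trace$current, max(1L, round(cfg$smooth_ms * ms)))
  base <- trailing_median(xs, round(cfg$baseline_ms * ms))
  d <- base - xs                       # positive = inward deflection
  n <- length(d)

  above <- d >= cfg$threshold_pa
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_i <- which(r$values & r$lengths >= max(1L, round(cfg$min_above_ms * ms)))

  rows <- vector("list", length(runs_i))
  prev_onset <- -Inf
  refr <- cfg$min_interevent_ms / 1000
  for (k in seq_along(runs_i)) {
    i_start <- starts[runs_i[k]]
    if ((i_start - 1) / fs - prev_onset < refr) next
    b0 <- base[max(1L, i_start - 1L)]
    seg_end <- min(n, i_start + round(cfg$peak_search_ms * ms))
    seg <- b0 - xs[i_start:seg_end]
    peak_rel <- which.max(seg)
    peak_idx <- i_start + peak_rel - 1L
    amp <- seg[peak_rel]
    if (!is.finite(amp) || amp < cfg$threshold_pa) next
    # reject decay-tail flickers of the previous event: the candidate must
    # also rise by >= threshold above its own local pre-run level
    loc_lb <- max(1L, i_start - round(5 * ms))
    b_loc <- median(xs[loc_lb:max(loc_lb, i_start - 1L)])
    if (b_loc - xs[peak_idx] < cfg$threshold_pa) next

    lb <- max(1L, i_start - round(cfg$onset_lookback_ms * ms))
    pre <- b0 - xs[lb:i_start]
    below <- which(pre <= 0.1 * amp)
    onset_idx <- if (length(below) > 0) lb + below[length(below)] - 1L else lb

    # decay span for the double-peak check: peak -> 50% of peak
    dk_end <- min(n, peak_idx + round(cfg$decay_limit_ms * ms))
    dec <- b0 - xs[peak_idx:dk_end]
    i50 <- which(dec <= 0.5 * amp)[1]
    i50 <- if (is.na(i50)) length(dec) else i50
    dbl <- FALSE
    if (i50 > 2L) {
      span <- dec[1:i50]
      rebound <- max(span - cummin(span))
      if (rebound >= cfg$threshold_pa) dbl <- TRUE
    }
    if (!dbl) {
      # merged events: look for two prominent humps in the rising-phase slope
      # (segment starts 1 ms before onset so the first hump has a flat left
      # reference and full prominence)
      rise_from <- max(1L, onset_idx - round(1 * ms))
      rise_seg <- b0 - xs[rise_from:min(n, peak_idx + round(2 * ms))]
      sm <- boxcar(rise_seg, max(3L, round(2 * ms)))
      u <- diff(sm) * ms                # pA per ms
      if (length(u) > 4L) {
        pk <- find_peaks(u, prom = max(cfg$threshold_pa, 0.5 * max(u)))
        if (length(pk) >= 2L) dbl <- TRUE
      }
    }

    prev_onset <- (i_start - 1) / fs
    rows[[k]] <- tibble(
      onset_time_s = (onset_idx - 1) / fs, onset_index = onset_idx,
      peak_time_s = (peak_idx - 1) / fs, peak_index = peak_idx,
      amplitude_pa = amp, baseline_pa = b0, is_double_peak = dbl)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(onset_time_s = numeric(0), onset_index = integer(0),
                  peak_time_s = numeric(0), peak_index = integer(0),
                  amplitude_pa = numeric(0), baseline_pa = numeric(0),
                  is_double_peak = logical(0))
  }
  class(out) <- c("mini_events", class(out))
  attr(out, "duration_s") <- trace_duration(trace)
  attr(out, "cell_id") <- trace$cell_id
  attr(out, "group") <- trace$group
  attr(out, "config") <- cfg
  out
}

# Interpolated time (s) at which the deflection y (sampled at fs, first
# sample at time t0) crosses `level` going up, searching i in idx range.
cross_up_time <- function(y, level, fs, t0) {
  i <- which(y >= level)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t0)
  frac <- (level - y[i - 1L]) / (y[i] - y[i - 1L])
  t0 + (i - 2L + frac) / fs
}

# Single-exponential decay fit on the 50% -> 10% span of the decay limb.
# Fitting from the exact peak of a difference-of-exponentials event inflates
# tau (the residual rise component flattens the early decay), so the fit
# starts where the deflection has fallen to half the peak.
fit_decay_tau <- function(d_evt, peak_rel, amp, fs) {
  dec <- d_evt[peak_rel:length(d_evt)]
  i50 <- which(dec <= 0.5 * amp)[1]
  i10 <- which(dec <= 0.1 * amp)[1]
  if (is.na(i50)) return(NA_real_)
  if (is.na(i10)) i10 <- length(dec)
  if (i10 - i50 < 5L) return(NA_real_)
  yy <- dec[i50:i10]
  tt_ms <- (seq_along(yy) - 1) / fs * 1000
  t_half_ms <- (i50 - 1) / fs * 1000
  tau0 <- max(t_half_ms / log(2), 1 / fs * 1000)
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A0 * exp(-tt_ms / tau),
                      start = list(A0 = yy[1], tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 100,
                                                           ftol = 1e-8,
                                                           ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  tau <- coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) NA_real_ else tau
}

# 10-90% rise time (ms) with linear interpolation, on the rising limb.
rise_10_90 <- function(d_evt, peak_rel, amp, fs) {
  rise <- d_evt[1:peak_rel]
  t10 <- cross_up_time(rise, 0.1 * amp, fs, 0)
  t90 <- cross_up_time(rise, 0.9 * amp, fs, 0)
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  (t90 - t10) * 1000
}

#' Per-event kinetics: 10-90% rise time and single-exponential decay tau
#'
#' Rise time is the interpolated interval between the 10% and 90% crossings
#' of the peak on the rising limb. The decay time constant comes from a
#' least-squares single-exponential fit over the 50%-to-10%-of-peak span of
#' the decay limb (or up to the next event onset, whichever comes first),
#' initialized from the half-decay time. Double-peak events get NA kinetics.
#'
#' @param events A [detect_minis()] result.
#' @param trace The same [current_trace()].
#' @param cfg The [detection_config()] used for detection.
#' @return `events` with `rise_time_ms` and `decay_tau_ms` columns added.
#'   Events whose decay fit fails keep NA and are counted in the
#'   `n_fit_failed` attribute.
#' @export
event_kinetics <- function(events, trace, cfg = attr(events, "config")) {
  stopifnot(inherits(events, "mini_events"))
  cfg <- cfg %||% detection_config()
  fs <- trace$sampling_rate
  ms <- fs / 1000
  xs <- boxcar(trace$current, max(1L, round(cfg$smooth_ms * ms)))
  n <- length(xs)
  rise <- decay <- rep(NA_real_, nrow(events))
  failed <- 0L
  for (i in seq_len(nrow(events))) {
    if (events$is_double_peak[i]) next
    o <- events$onset_index[i]
    lim <- min(n, events$peak_index[i] + round(cfg$decay_limit_ms * ms))
    if (i < nrow(events)) lim <- min(lim, events$onset_index[i + 1L] - 1L)
    if (lim <= o + 2L) next
    d_evt <- events$baseline_pa[i] - xs[o:lim]
    peak_rel <- events$peak_index[i] - o + 1L
    amp <- events$amplitude_pa[i]
    rise[i] <- rise_10_90(d_evt, peak_rel, amp, fs)
    decay[i] <- fit_decay_tau(d_evt, peak_rel, amp, fs)
    if (is.na(decay[i])) failed <- failed + 1L
  }
  out <- dplyr::mutate(events, rise_time_ms = rise, decay_tau_ms = decay)
  class(out) <- class(events)
  for (a in c("duration_s", "cell_id", "group", "config")) {
    attr(out, a) <- attr(events, a)
  }
  attr(out, "n_fit_failed") <- failed
  out
}

#' Per-cell mini summary with averaged-waveform kinetics
#'
#' Event frequency counts every detected event (an overlapping double event
#' is still a synaptic event); mean amplitude and kinetics use only clean
#' (non-double-peak) events, mirroring the convention that events are
#' *selected* to reject double peaks before averaging. Kinetics are reported
#' only when more than `min_events_kinetics` clean events are available; by
#' default they are measured on the onset-aligned average waveform of the
#' clean events, `kinetics = "per_event"` averages per-event fits instead.
#'
#' @param events A [detect_minis()] result.
#' @param trace The matching [current_trace()].
#' @param cfg Detection config (defaults to the one stored in `events`).
#' @param kinetics `"averaged_waveform"` (default) or `"per_event"`.
#' @param min_events_kinetics Kinetics require strictly more accepted events
#'   than this (default 50).
#' @param avg_window_ms `c(pre, post)` window around the onset used for the
#'   average waveform (default `c(2, 50)`).
#' @return One-row tibble: `cell_id`, `group`, `n_events` (all detections),
#'   `n_clean_events`, `event_frequency_hz`, `mean_amplitude_pa`,
#'   `rise_time_ms`, `decay_tau_ms`.
#' @export
cell_summary <- function(events, trace, cfg = attr(events, "config"),
                         kinetics = c("averaged_waveform", "per_event"),
                         min_events_kinetics = 50,
                         avg_window_ms = c(2, 50)) {
  stopifnot(inherits(events, "mini_events"))
  kinetics <- match.arg(kinetics)
  cfg <- cfg %||% detection_config()
  acc <- events[!events$is_double_peak, , drop = FALSE]
  dur <- attr(events, "duration_s") %||% trace_duration(trace)
  out <- tibble(cell_id = attr(events, "cell_id") %||% trace$cell_id,
                group = attr(events, "group") %||% trace$group,
                n_events = nrow(events),
                n_clean_events = nrow(acc),
                event_frequency_hz = nrow(events) / dur,
                mean_amplitude_pa = if (nrow(acc) > 0) mean(acc$amplitude_pa) else NA_real_,
                rise_time_ms = NA_real_, decay_tau_ms = NA_real_)
  if (nrow(acc) <= min_events_kinetics) return(out)

  fs <- trace$sampling_rate
  ms <- fs / 1000
  if (kinetics == "per_event") {
    ev <- if ("decay_tau_ms" %in% names(events)) events else
      event_kinetics(events, trace, cfg)
    acc <- ev[!ev$is_double_peak, , drop = FALSE]
    out$rise_time_ms <- mean(acc$rise_time_ms, na.rm = TRUE)
    out$decay_tau_ms <- mean(acc$decay_tau_ms, na.rm = TRUE)
    return(out)
  }
  xs <- boxcar(trace$current, max(1L, round(cfg$smooth_ms * ms)))
  n <- length(xs)
  pre <- round(avg_window_ms[1] * ms); post <- round(avg_window_ms[2] * ms)
  # average only clean segments: no other event (of any kind) may start
  # inside the averaging window, or its tail would inflate the decay
  all_onsets <- events$onset_index
  segs <- purrr::pmap(list(acc$onset_index, acc$baseline_pa), function(o, b0) {
    if (o - pre < 1L || o + post > n) return(NULL)
    others <- all_onsets[all_onsets != o]
    if (any(others > o - pre & others < o + post)) return(NULL)
    b0 - xs[(o - pre):(o + post)]
  })
  segs <- segs[!purrr::map_lgl(segs, is.null)]
  if (length(segs) <= min_events_kinetics) return(out)
  avg <- Reduce(`+`, segs) / length(segs)
  peak_rel <- which.max(avg)
  amp <- avg[peak_rel]
  d0 <- avg - stats::median(avg[1:max(2L, pre)])   # re-reference to pre-onset
  amp <- max(d0)
  peak_rel <- which.max(d0)
  out$rise_time_ms <- rise_10_90(d0, peak_rel, amp, fs)
  out$decay_tau_ms <- fit_decay_tau(d0, peak_rel, amp, fs)
  out
}

#' Pool fixed-size amplitude subsamples across cells
#'
#' For cumulative-distribution comparisons: from every cell with at least
#' `events_per_cell` accepted events, draw exactly `events_per_cell`
#' amplitudes (seeded, without replacement) and concatenate. Cells with too
#' few events are excluded with a message.
#'
#' @param events Tibble of events from one or more cells: needs columns
#'   `cell_id`, `amplitude_pa`, `is_double_peak`, and optionally `group`.
#' @param events_per_cell Subsample size per cell (default 100).
#' @param seed Integer seed; cell `k` (in cell-id order) uses the derived
#'   stream `seed + k`.
#' @return Tibble `cell_id`, `group`, `amplitude_pa` with
#'   `events_per_cell` rows per retained cell.
#' @export
pool_for_cumulative <- function(events, events_per_cell = 100, seed = 1L) {
  if (!"group" %in% names(events)) events$group <- "all"
  acc <- events[!events$is_double_peak, , drop = FALSE]
  ids <- sort(unique(acc$cell_id))
  out <- list()
  for (k in seq_along(ids)) {
    amps <- acc$amplitude_pa[acc$cell_id == ids[k]]
    grp <- acc$group[acc$cell_id == ids[k]][1]
    if (length(amps) < events_per_cell) {
      inform(sprintf("cell '%s' excluded from pooling: %d < %d events.",
                     ids[k], length(amps), events_per_cell))
      next
    }
    sub <- with_seed(seed + k, sample(amps, events_per_cell))
    out[[length(out) + 1L]] <- tibble(cell_id = ids[k], group = grp,
                                      amplitude_pa = sub)
  }
  if (length(out) == 0L) {
    return(tibble(cell_id = character(0), group = character(0),
                  amplitude_pa = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Cumulative amplitude distributions by group
#'
#' @param pooled Output of [pool_for_cumulative()].
#' @return A ggplot object (empirical CDFs per group).
#' @export
plot_cumulative_amplitudes <- function(pooled) {
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$amplitude_pa,
                                       colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "mIPSC amplitude (pA)", y = "cumulative probability",
                  colour = "group") +
    ggplot2::theme_minimal()
}
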