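# Synthetic spike-train generation with known ground truth.
#
# Burst ground truth is defined by generator "packets", not by the 80/160 ms
# detector, so detector validation stays non-circular: packets are built with
# intra-packet ISIs below 80 ms and inter-event gaps above 160 ms, which makes
# them detectable by construction, but agreement is measured, never assumed.

#' Configuration for the spike-train simulator
#'
#' @param mean_rate Target mean firing rate in Hz.
#' @param in_burst_fraction Target expected fraction of spikes inside burst
#'   packets (`two_state_burst` model only), in `[0, 1]`.
#' @param intra_burst_isi_ms `c(mean, sd)` of intra-packet ISIs in ms;
#'   truncated to (refractory, 80) so packets satisfy the burst-onset
#'   criterion by construction. Mean must be < 80.
#' @param inter_event_isi_ms Optional `c(mean, sd)` of inter-event gaps in ms
#'   (mean must be > 160). When `NULL` (default) the mean is derived from
#'   `mean_rate` and the packet mix, and the sd is 20% of the mean.
#' @param burst_sizes Integer support of the packet-size distribution (all
#'   >= 2).
#' @param burst_size_probs Probabilities over `burst_sizes` (default uniform).
#' @param epoch_duration Epoch length in seconds.
#' @param n_units Number of units for [simulate_spike_cohort()].
#' @param seed Integer seed; fully determines the output. Unit `i` of a
#'   cohort uses the derived stream `seed + i`.
#' @param isi_model `"two_state_burst"`, `"pacemaker_gaussian"` or
#'   `"poisson_refractory"`.
#' @param pacemaker_isi_sd_ms ISI standard deviation for the pacemaker model;
#'   default 5% of the mean ISI.
#' @param unit_rate_sd Between-unit standard deviation of the mean rate (Hz,
#'   default 0): each simulated unit draws its own rate from a truncated
#'   normal around `mean_rate`, emulating cell-to-cell heterogeneity. Draws
#'   are clamped to the feasible range of the ISI model.
#' @param refractory_ms Absolute refractory floor for all ISIs (default 2 ms).
#' @param spike_duration_ms `c(mean, sd)` of simulated per-spike waveform
#'   durations (onset to negative peak), used by QC; default `c(1.5, 0.15)`.
#' @param group,condition,setting Metadata attached to generated trains.
#' @return A `spike_sim_config` list.
#' @export
spike_sim_config <- function(mean_rate = 5,
                             in_burst_fraction = 0.5,
                             intra_burst_isi_ms = c(40, 15),
                             inter_event_isi_ms = NULL,
                             burst_sizes = 2:8,
                             burst_size_probs = NULL,
                             epoch_duration = 120,
                             n_units = 1L,
                             seed = 1L,
                             isi_model = c("two_state_burst", "pacemaker_gaussian",
                                           "poisson_refractory"),
                             pacemaker_isi_sd_ms = NULL,
                             unit_rate_sd = 0,
                             refractory_ms = 2,
                             spike_duration_ms = c(1.5, 0.15),
                             group = "control", condition = "baseline",
                             setting = "in_vivo") {
  isi_model <- match.arg(isi_model)
  stopifnot_scalar_number(mean_rate, "mean_rate", min = 1e-6)
  stopifnot_scalar_number(epoch_duration, "epoch_duration", min = 1e-6)
  if (in_burst_fraction < 0 || in_burst_fraction > 1) {
    abort("in_burst_fraction must be in [0, 1].", class = "dopaphys_config_error")
  }
  if (intra_burst_isi_ms[1] >= 80) {
    abort("intra-burst ISI mean must be < 80 ms.", class = "dopaphys_config_error")
  }
  if (!is.null(inter_event_isi_ms) && inter_event_isi_ms[1] <= 160) {
    abort("inter-event ISI mean must be > 160 ms.", class = "dopaphys_config_error")
  }
  if (any(burst_sizes < 2)) {
    abort("burst_sizes must all be >= 2.", class = "dopaphys_config_error")
  }
  burst_size_probs <- burst_size_probs %||% rep(1 / length(burst_sizes), length(burst_sizes))
  structure(
    list(mean_rate = mean_rate, in_burst_fraction = in_burst_fraction,
         intra_burst_isi_ms = intra_burst_isi_ms,
         inter_event_isi_ms = inter_event_isi_ms,
         burst_sizes = as.integer(burst_sizes),
         burst_size_probs = burst_size_probs / sum(burst_size_probs),
         epoch_duration = epoch_duration, n_units = as.integer(n_units),
         seed = as.integer(seed), isi_model = isi_model,
         pacemaker_isi_sd_ms = pacemaker_isi_sd_ms,
         unit_rate_sd = unit_rate_sd,
         refractory_ms = refractory_ms,
         spike_duration_ms = spike_duration_ms,
         group = group, condition = condition, setting = setting),
    class = "spike_sim_config")
}

# Mean of a normal truncated to (a, b).
truncnorm_mean <- function(mu, s, a, b) {
  al <- (a - mu) / s; be <- (b - mu) / s
  z <- stats::pnorm(be) - stats::pnorm(al)
  mu + s * (stats::dnorm(al) - stats::dnorm(be)) / z
}

# Untruncated mean that yields truncated mean `target` for sd `s` on (a, b).
truncnorm_adjust <- function(target, s, a, b) {
  if (s <= 0) return(target)
  f <- function(mu) truncnorm_mean(mu, s, a, b) - target
  lo <- target - 6 * s; hi <- target + 6 * s
  if (f(lo) * f(hi) > 0) return(target)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Packet mixing probability giving expected in-packet spike fraction f for
# mean packet size B: solve f = pB / (pB + 1 - p).
packet_prob <- function(f, B) {
  if (f <= 0) return(0)
  if (f >= 1) return(1)
  f / (B * (1 - f) + f)
}

# Derived inter-event gap mean (s) hitting the requested mean rate.
derive_gap_mean <- function(cfg, rate = cfg$mean_rate) {
  B <- sum(cfg$burst_sizes * cfg$burst_size_probs)
  p <- packet_prob(cfg$in_burst_fraction, B)
  S <- p * B + (1 - p)                       # expected spikes per event
  intra <- cfg$intra_burst_isi_ms[1] / 1000
  g <- S / rate - p * (B - 1) * intra
  if (g <= 0.165) {
    abort(paste0("infeasible config: derived inter-event gap ",
                 sprintf("%.0f ms", g * 1000),
                 " must exceed 160 ms; lower mean_rate or in_burst_fraction."),
          class = "dopaphys_config_error")
  }
  g
}

#' Simulate one spike train with ground-truth burst labels
#'
#' Three ISI models are available. `two_state_burst` alternates burst packets
#' (sizes drawn from the configured distribution, intra-packet ISIs from a
#' truncated normal below 80 ms) with singleton spikes, separated by
#' inter-event gaps above 160 ms, mixed so the expected in-packet spike
#' fraction equals `in_burst_fraction`. `pacemaker_gaussian` draws ISIs from
#' a truncated normal (regular, pacemaker-like firing). `poisson_refractory`
#' draws exponential ISIs on top of an absolute refractory floor. Truncated
#' normals are mean-corrected so the realized mean matches the configured
#' value despite truncation.
#'
#' The returned train carries a `truth` attribute: a tibble with
#' `spike_time_s`, `in_burst`, `packet_id`. A packet cut to a single spike by
#' the epoch end is relabelled as not-in-burst (a lone spike is not a burst).
#'
#' @param cfg A [spike_sim_config()].
#' @param unit_index Which derived RNG stream to use (default 1).
#' @param unit_id Unit label; default `"u<unit_index>"`.
#' @return A [spike_train()] with attribute `truth`.
#' @export
simulate_spike_train <- function(cfg, unit_index = 1L, unit_id = NULL) {
  stopifnot(inherits(cfg, "spike_sim_config"))
  unit_id <- unit_id %||% sprintf("u%03d", unit_index)
  with_seed(cfg$seed + as.integer(unit_index), {
    rate <- unit_rate(cfg)
    res <- switch(cfg$isi_model,
      two_state_burst = sim_two_state(cfg, rate),
      pacemaker_gaussian = sim_pacemaker(cfg, rate),
      poisson_refractory = sim_poisson_refractory(cfg, rate))
    times <- res$times
    durs <- rnorm_trunc(length(times), cfg$spike_duration_ms[1],
                        cfg$spike_duration_ms[2], lower = 0.1)
    tr <- spike_train(times, cfg$epoch_duration, unit_id = unit_id,
                      spike_durations = durs, group = cfg$group,
                      condition = cfg$condition, setting = cfg$setting)
    attr(tr, "truth") <- tibble(spike_time_s = times,
                                in_burst = res$in_burst,
                                packet_id = res$packet_id)
    tr
  })
}

# Per-unit rate draw, clamped to the model's feasible range.
unit_rate <- function(cfg) {
  if (cfg$unit_rate_sd <= 0) return(cfg$mean_rate)
  upper <- Inf
  if (cfg$isi_model == "two_state_burst" &&
      is.null(cfg$inter_event_isi_ms)) {
    B <- sum(cfg$burst_sizes * cfg$burst_size_probs)
    p <- packet_prob(cfg$in_burst_fraction, B)
    S <- p * B + (1 - p)
    upper <- 0.97 * S / (0.170 + p * (B - 1) * cfg$intra_burst_isi_ms[1] / 1000)
  }
  rnorm_trunc(1, cfg$mean_rate, cfg$unit_rate_sd,
              lower = max(0.2, 0.1 * cfg$mean_rate), upper = upper)
}

sim_two_state <- function(cfg, rate = cfg$mean_rate) {
  refr_s <- cfg$refractory_ms / 1000
  B <- sum(cfg$burst_sizes * cfg$burst_size_probs)
  p <- packet_prob(cfg$in_burst_fraction, B)
  gm <- if (is.null(cfg$inter_event_isi_ms)) derive_gap_mean(cfg, rate)
        else cfg$inter_event_isi_ms[1] / 1000
  gs <- if (is.null(cfg$inter_event_isi_ms)) 0.2 * gm
        else cfg$inter_event_isi_ms[2] / 1000
  gm_adj <- truncnorm_adjust(gm, gs, 0.1605, Inf)
  im <- cfg$intra_burst_isi_ms[1] / 1000
  is_ <- cfg$intra_burst_isi_ms[2] / 1000
  im_adj <- truncnorm_adjust(im, is_, refr_s, 0.0795)

  # start the renewal process in (approximate) equilibrium: simulate from a
  # warm-up period before time zero and keep only spikes in [0, epoch);
  # without this, counting starts on a fresh gap and mean rates carry a
  # small O(1/epoch) deficit
  warm <- 5 * gm_adj + 0.5
  times <- numeric(0); in_burst <- logical(0); packet_id <- integer(0)
  t <- -warm; pk <- 0L
  repeat {
    t <- t + rnorm_trunc(1, gm_adj, gs, lower = 0.1605)
    if (t >= cfg$epoch_duration) break
    if (p > 0 && runif(1) < p) {
      pk <- pk + 1L
      size <- cfg$burst_sizes[sample.int(length(cfg$burst_sizes), 1L,
                                         prob = cfg$burst_size_probs)]
      pk_times <- t
      for (j in seq_len(size - 1L)) {
        t <- t + rnorm_trunc(1, im_adj, is_, lower = refr_s, upper = 0.0795)
        if (t >= cfg$epoch_duration) break
        pk_times <- c(pk_times, t)
      }
      if (length(pk_times) >= 2L) {
        times <- c(times, pk_times)
        in_burst <- c(in_burst, rep(TRUE, length(pk_times)))
        packet_id <- c(packet_id, rep(pk, length(pk_times)))
      } else {
        times <- c(times, pk_times)
        in_burst <- c(in_burst, FALSE)
        packet_id <- c(packet_id, NA_integer_)
      }
    } else {
      times <- c(times, t)
      in_burst <- c(in_burst, FALSE)
      packet_id <- c(packet_id, NA_integer_)
    }
  }
  keep <- times >= 0
  times <- times[keep]; in_burst <- in_burst[keep]; packet_id <- packet_id[keep]
  # packets cut to a single spike by the epoch start are no longer bursts
  if (length(times) > 0L && any(in_burst)) {
    counts <- table(packet_id[in_burst])
    lone <- as.integer(names(counts)[counts < 2L])
    cut <- !is.na(packet_id) & packet_id %in% lone
    in_burst[cut] <- FALSE
    packet_id[cut] <- NA_integer_
  }
  list(times = times, in_burst = in_burst, packet_id = packet_id)
}

sim_pacemaker <- function(cfg, rate = cfg$mean_rate) {
  refr_s <- cfg$refractory_ms / 1000
  mu <- 1 / rate
  s <- (cfg$pacemaker_isi_sd_ms %||% (0.05 * mu * 1000)) / 1000
  mu_adj <- truncnorm_adjust(mu, s, refr_s, Inf)
  n_max <- ceiling(cfg$epoch_duration * rate * 1.5) + 20L
  isis <- rnorm_trunc(n_max, mu_adj, s, lower = refr_s)
  # uniform phase on the first interval puts the process in steady state
  times <- cumsum(isis) - runif(1) * isis[1L]
  times <- times[times >= 0 & times < cfg$epoch_duration]
  list(times = times, in_burst = rep(FALSE, length(times)),
       packet_id = rep(NA_integer_, length(times)))
}

sim_poisson_refractory <- function(cfg, rate = cfg$mean_rate) {
  refr_s <- cfg$refractory_ms / 1000
  mean_isi <- 1 / rate
  if (mean_isi <= refr_s) {
    abort("mean_rate too high for the refractory floor.",
          class = "dopaphys_config_error")
  }
  n_max <- ceiling(cfg$epoch_duration * rate * 2) + 50L
  isis <- refr_s + rexp(n_max, rate = 1 / (mean_isi - refr_s))
  times <- cumsum(isis) - runif(1) * isis[1L]
  times <- times[times >= 0 & times < cfg$epoch_duration]
  list(times = times, in_burst = rep(FALSE, length(times)),
       packet_id = rep(NA_integer_, length(times)))
}

#' Simulate a cohort of spike trains
#'
#' Unit `i` uses the derived seed `cfg$seed + i`, so cohorts are reproducible
#' and units are independent.
#'
#' @param cfg A [spike_sim_config()] with `n_units` set.
#' @param id_prefix Prefix for unit ids.
#' @return Named list of [spike_train()] objects (each with its `truth`
#'   attribute).
#' @export
simulate_spike_cohort <- function(cfg, id_prefix = "u") {
  trains <- lapply(seq_len(cfg$n_units), function(i) {
    simulate_spike_train(cfg, unit_index = i,
                         unit_id = sprintf("%s%03d", id_prefix, i))
  })
  setNames(trains, purrr::map_chr(trains, "unit_id"))
}

#' Ground-truth burst labels of a simulated train
#'
#' @param train A train produced by [simulate_spike_train()].
#' @return Tibble `spike_time_s`, `in_burst`, `packet_id`.
#' @export
ground_truth <- function(train) {
  gt <- attr(train, "truth")
  if (is.null(gt)) {
    abort("train carries no ground-truth labels (not simulated?).",
          class = "dopaphys_validation_error")
  }
  gt
}

#' Apply a multiplicative drug effect to a simulated train
#'
#' Spike intensity inside `drug_window` is multiplied by `1 + effect`:
#' suppression (`effect < 0`) is realized by random thinning of in-window
#' spikes, facilitation (`effect > 0`) by superposing an independent Poisson
#' train at rate `effect * mean_rate` inside the window. Outside the window
#' the base ISI model is untouched.
#'
#' @param cfg A [spike_sim_config()] describing the base train.
#' @param effect Fractional rate change, `> -1` (e.g. `-0.4` for a 40%
#'   suppression).
#' @param drug_window `c(start_s, end_s)` within the epoch.
#' @param unit_index Derived RNG stream index (as in
#'   [simulate_spike_train()]).
#' @param unit_id Optional unit label.
#' @return A [spike_train()]; superposed spikes carry `in_burst = FALSE`
#'   ground-truth labels.
#' @export
simulate_drug_epoch <- function(cfg, effect, drug_window, unit_index = 1L,
                                unit_id = NULL) {
  if (effect <= -1) {
    abort("effect must be > -1.", class = "dopaphys_config_error")
  }
  if (drug_window[1] < 0 || drug_window[2] > cfg$epoch_duration ||
      drug_window[2] <= drug_window[1]) {
    abort("drug_window must lie within the epoch.", class = "dopaphys_config_error")
  }
  base <- simulate_spike_train(cfg, unit_index = unit_index, unit_id = unit_id)
  gt <- ground_truth(base)
  with_seed(cfg$seed + 500000L + as.integer(unit_index), {
    times <- base$spike_times
    in_win <- times >= drug_window[1] & times < drug_window[2]
    if (effect < 0) {
      drop <- in_win & (runif(length(times)) >= 1 + effect)
      keep <- !drop
      times <- times[keep]
      gt <- gt[keep, ]
      durs <- base$spike_durations[keep]
    } else if (effect > 0) {
      w <- diff(drug_window)
      n_add <- rpois(1, effect * cfg$mean_rate * w)
      add <- sort(runif(n_add, drug_window[1], drug_window[2]))
      add <- setdiff(add, times)
      all_t <- sort(c(times, add))
      gt <- tibble(spike_time_s = all_t,
                   in_burst = all_t %in% gt$spike_time_s[gt$in_burst],
                   packet_id = NA_integer_)
      durs <- rnorm_trunc(length(all_t), cfg$spike_duration_ms[1],
                          cfg$spike_duration_ms[2], lower = 0.1)
      times <- all_t
    } else {
      durs <- base$spike_durations
    }
    tr <- spike_train(times, cfg$epoch_duration, unit_id = base$unit_id,
                      spike_durations = durs, group = cfg$group,
                      condition = cfg$condition, setting = cfg$setting)
    attr(tr, "truth") <- gt
    attr(tr, "drug_window") <- drug_window
    attr(tr, "effect") <- effect
    tr
  })
}
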