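# Synthetic voltage-clamp traces with analytic ground truth.

#' Configuration for the mIPSC trace simulator
#'
#' Events arrive as a homogeneous Poisson process; each adds a
#' difference-of-exponentials waveform
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))`, peak-normalized so the drawn
#' amplitude is the event's true baseline-to-peak magnitude. Inward events
#' are negative deflections at the (negative) holding potential. Rise and
#' decay are independently parameterized, matching how mini kinetics are
#' reported.
#'
#' @param sampling_rate Hz (default 5000).
#' @param duration Trace length in s.
#' @param event_rate Poisson event rate in Hz.
#' @param amplitude_pa `c(mean, sd)` of event amplitudes in pA (positive
#'   magnitudes, truncated above 1 pA).
#' @param tau_rise_ms,tau_decay_ms Kinetic time constants in ms;
#'   `tau_decay_ms > tau_rise_ms > 0`.
#' @param noise_sd Additive Gaussian noise sd in pA.
#' @param baseline_pa Baseline holding current in pA.
#' @param holding_potential mV.
#' @param seed Integer seed; fully determines the trace.
#' @param cell_id,group Metadata.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(sampling_rate = 5000, duration = 120,
                             event_rate = 2, amplitude_pa = c(30, 5),
                             tau_rise_ms = 1.5, tau_decay_ms = 7,
                             noise_sd = 2, baseline_pa = -20,
                             holding_potential = -60, seed = 1L,
                             cell_id = "cell1", group = "control") {
  if (!(tau_decay_ms > tau_rise_ms && tau_rise_ms > 0)) {
    abort("need tau_decay_ms > tau_rise_ms > 0.", class = "dopaphys_config_error")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0.", class = "dopaphys_config_error")
  if (duration * event_rate > 1e6) {
    abort("more than 1e6 events requested.", class = "dopaphys_config_error")
  }
  structure(
    list(sampling_rate = sampling_rate, duration = duration,
         event_rate = event_rate, amplitude_pa = amplitude_pa,
         tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
         noise_sd = noise_sd, baseline_pa = baseline_pa,
         holding_potential = holding_potential, seed = as.integer(seed),
         cell_id = cell_id, group = group),
    class = "trace_sim_config")
}

# Peak-normalized difference-of-exponentials kernel sampled at `dt` seconds,
# truncated at 8 decay time constants.
biexp_kernel <- function(tau_rise_ms, tau_decay_ms, dt) {
  tr <- tau_rise_ms / 1000; td <- tau_decay_ms / 1000
  tp <- log(td / tr) * td * tr / (td - tr)
  peak <- exp(-tp / td) - exp(-tp / tr)
  tt <- seq(0, 8 * td, by = dt)
  (exp(-tt / td) - exp(-tt / tr)) / peak
}

#' Simulate an mIPSC trace with ground-truth events
#'
#' @param cfg A [trace_sim_config()].
#' @return A [current_trace()] (protocol `"mipsc"`) with attribute `truth`:
#'   a tibble of `onset_time_s`, `amplitude_pa` (positive magnitudes).
#' @export
simulate_mipsc_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sampling_rate
    n <- round(cfg$duration * fs)
    dt <- 1 / fs
    n_ev <- rpois(1, cfg$event_rate * cfg$duration)
    onset <- sort(runif(n_ev, 0, cfg$duration))
    amp <- rnorm_trunc(n_ev, cfg$amplitude_pa[1], cfg$amplitude_pa[2], lower = 1)
    x <- rep(cfg$baseline_pa, n)
    if (n_ev > 0) {
      ker <- biexp_kernel(cfg$tau_rise_ms, cfg$tau_decay_ms, dt)
      kl <- length(ker)
      for (i in seq_len(n_ev)) {
        i0 <- floor(onset[i] * fs) + 1L
        idx <- i0:min(n, i0 + kl - 1L)
        x[idx] <- x[idx] - amp[i] * ker[seq_along(idx)]
      }
    }
    if (cfg$noise_sd > 0) x <- x + rnorm(n, 0, cfg$noise_sd)
    tr <- current_trace(x, fs, cell_id = cfg$cell_id,
                        holding_potential = cfg$holding_potential,
                        group = cfg$group, protocol = "mipsc")
    attr(tr, "truth") <- tibble(onset_time_s = onset, amplitude_pa = amp)
    tr
  })
}

#' Simulate an evoked/intrinsic current protocol trace
#'
#' Deterministic protocol traces plus optional Gaussian noise, with analytic
#' ground truth attached:
#' \describe{
#'   \item{`gaba_puff`}{baseline, then an inward plateau of magnitude
#'     `amplitude_pa` reached with single-exponential onset `tau_on_ms` from
#'     `t_on_s` and released with `tau_off_ms` at `t_off_s`. Truth: analytic
#'     peak magnitude.}
#'   \item{`ahp`}{outward exponential tail `amplitude_pa * exp(-t/tau_ms)`
#'     starting at the pulse-end mark `t_on_s`. Truth: peak `A` and analytic
#'     charge `A * tau` (pA.ms).}
#'   \item{`ih`}{voltage step of `step_mv` at `t_on_s` for `step_dur_s`:
#'     instantaneous ohmic jump `i_inst_pa` plus a slowly developing sag
#'     `i_h_pa * (1 - exp(-t/tau_sag_ms))`. Truth: `i_h_pa`.}
#'   \item{`seal_test`}{ideal single-compartment response to a voltage step:
#'     `I(t) = dV/(Rs+Rm) + (dV/Rs - dV/(Rs+Rm)) * exp(-t/tau)` with
#'     `tau = Cm * Rs*Rm/(Rs+Rm)`. Truth: `rs_mohm`, `rm_mohm`, `cm_pf`.}
#' }
#'
#' @param protocol One of `"gaba_puff"`, `"ahp"`, `"ih"`, `"seal_test"`.
#' @param params Named list of protocol parameters (see Details above);
#'   common ones: `sampling_rate`, `duration`, `t_on_s`, `noise_sd`,
#'   `baseline_pa`, `seed`, `cell_id`, `group`.
#' @return A [current_trace()] with attribute `truth` (named list).
#' @export
simulate_step_response <- function(protocol = c("gaba_puff", "ahp", "ih", "seal_test"),
                                   params = list()) {
  protocol <- match.arg(protocol)
  p <- utils::modifyList(step_defaults(protocol), params)
  fs <- p$sampling_rate
  n <- round(p$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- rep(p$baseline_pa, n)
  marks <- NULL
  truth <- list()

  if (protocol == "gaba_puff") {
    on <- tt >= p$t_on_s & tt < p$t_off_s
    off <- tt >= p$t_off_s
    x[on] <- x[on] - p$amplitude_pa * (1 - exp(-(tt[on] - p$t_on_s) / (p$tau_on_ms / 1000)))
    reached <- p$amplitude_pa * (1 - exp(-(p$t_off_s - p$t_on_s) / (p$tau_on_ms / 1000)))
    x[off] <- x[off] - reached * exp(-(tt[off] - p$t_off_s) / (p$tau_off_ms / 1000))
    marks <- tibble(time_s = p$t_on_s, description = "puff_on")
    truth <- list(peak_pa = reached)
  } else if (protocol == "ahp") {
    tail <- tt >= p$t_on_s
    x[tail] <- x[tail] + p$amplitude_pa * exp(-(tt[tail] - p$t_on_s) / (p$tau_ms / 1000))
    marks <- tibble(time_s = p$t_on_s, description = "pulse_end")
    truth <- list(peak_pa = p$amplitude_pa,
                  charge_pa_ms = p$amplitude_pa * p$tau_ms)
  } else if (protocol == "ih") {
    t_off <- p$t_on_s + p$step_dur_s
    on <- tt >= p$t_on_s & tt < t_off
    rel <- tt[on] - p$t_on_s
    x[on] <- x[on] + p$i_inst_pa -
      p$i_h_pa * (1 - exp(-rel / (p$tau_sag_ms / 1000)))
    marks <- tibble(time_s = c(p$t_on_s, t_off),
                    description = c("step_on", "step_off"))
    truth <- list(i_h_pa = p$i_h_pa, step_mv = p$step_mv)
  } else { # seal_test
    rs <- p$rs_mohm; rm <- p$rm_mohm; cm <- p$cm_pf
    tau <- cm * 1e-12 * (rs * rm / (rs + rm)) * 1e6       # seconds
    i_ss <- p$step_mv / (rs + rm) * 1000                  # pA
    i_pk <- p$step_mv / rs * 1000
    on <- tt >= p$t_on_s
    rel <- tt[on] - p$t_on_s
    x[on] <- x[on] + i_ss + (i_pk - i_ss) * exp(-rel / tau)
    marks <- tibble(time_s = p$t_on_s, description = "step_on")
    truth <- list(rs_mohm = rs, rm_mohm = rm, cm_pf = cm, step_mv = p$step_mv,
                  tau_s = tau)
  }

  if (p$noise_sd > 0) {
    x <- with_seed(p$seed, x + rnorm(n, 0, p$noise_sd))
  }
  tr <- current_trace(x, fs, cell_id = p$cell_id,
                      holding_potential = p$holding_potential,
                      group = p$group,
                      protocol = if (protocol == "seal_test") "seal_test" else protocol,
                      stimulus_marks = marks)
  attr(tr, "truth") <- truth
  attr(tr, "step_mv") <- p$step_mv %||% NULL
  tr
}

step_defaults <- function(protocol) {
  base <- list(sampling_rate = 10000, noise_sd = 0, baseline_pa = -20,
               holding_potential = -55, seed = 1L, cell_id = "cell1",
               group = "control", step_mv = NULL)
  extra <- switch(protocol,
    gaba_puff = list(duration = 10, t_on_s = 2, t_off_s = 6,
                     amplitude_pa = 800, tau_on_ms = 300, tau_off_ms = 500),
    ahp = list(duration = 1.2, t_on_s = 0.2, amplitude_pa = 100, tau_ms = 50),
    ih = list(duration = 1.2, t_on_s = 0.2, step_dur_s = 0.8, step_mv = -70,
              i_inst_pa = -250, i_h_pa = 425, tau_sag_ms = 150),
    seal_test = list(duration = 0.1, t_on_s = 0.02, step_mv = -10,
                     rs_mohm = 15, rm_mohm = 366, cm_pf = 122,
                     sampling_rate = 50000))
  utils::modifyList(base, extra)
}
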