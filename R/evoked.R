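# Evoked and intrinsic current measurements from voltage-clamp traces.
# Inward currents are negative samples; reported amplitudes are positive
# magnitudes (sign convention noted in each return description).

first_mark <- function(trace, description = NULL) {
  mk <- trace$stimulus_marks
  if (is.null(mk) || nrow(mk) == 0L) {
    abort(sprintf("cell '%s': protocol requires a stimulus mark.", trace$cell_id),
          class = "dopaphys_protocol_error")
  }
  if (!is.null(description)) {
    mk <- mk[mk$description == description, , drop = FALSE]
    if (nrow(mk) == 0L) {
      abort(sprintf("cell '%s': no stimulus mark '%s'.", trace$cell_id, description),
            class = "dopaphys_protocol_error")
    }
  }
  mk$time_s[1]
}

#' Peak agonist-evoked inward current
#'
#' Baseline is the median current before the stimulus mark; the peak is the
#' maximum baseline-subtracted inward deflection after the mark, reported as
#' a positive magnitude in pA (inward-negative sign convention).
#'
#' @param trace A [current_trace()] with protocol `"gaba_puff"` and a
#'   stimulus mark.
#' @param baseline_s Seconds of pre-stimulus trace used for the baseline
#'   (default 1 s).
#' @param smooth_ms Boxcar smoothing applied before the peak read (default
#'   10 ms). Agonist-evoked currents develop over hundreds of ms, so this
#'   does not clip the peak but stops the maximum-of-noise bias that would
#'   otherwise inflate small responses.
#' @return One-row tibble of class `evoked_response`: `cell_id`, `group`,
#'   `protocol`, `peak_amplitude_pa`, `peak_time_s`, `charge_transfer_pa_ms`
#'   (NA for this protocol), `measurement_start_s`, `measurement_end_s`,
#'   `zero_response`.
#' @export
gaba_evoked_peak <- function(trace, baseline_s = 1, smooth_ms = 10) {
  stopifnot(inherits(trace, "current_trace"))
  if (trace$protocol != "gaba_puff") {
    abort(sprintf("cell '%s': protocol is '%s', expected 'gaba_puff'.",
                  trace$cell_id, trace$protocol), class = "dopaphys_protocol_error")
  }
  t_on <- first_mark(trace)
  tt <- trace_times(trace)
  xs <- boxcar(trace$current,
               max(1L, round(smooth_ms / 1000 * trace$sampling_rate)))
  pre <- xs[tt < t_on & tt >= t_on - baseline_s]
  post <- xs[tt >= t_on]
  if (length(post) == 0L) {
    abort(sprintf("cell '%s': no post-stimulus samples.", trace$cell_id),
          class = "dopaphys_protocol_error")
  }
  b0 <- median(pre)
  d <- b0 - post                        # positive = inward
  pk <- which.max(d)
  evoked_row(trace, peak = d[pk], peak_time = t_on + (pk - 1) / trace$sampling_rate,
             charge = NA_real_, win = c(t_on, max(tt)),
             zero = max(d) <= 2 * sd(pre - b0))
}

evoked_row <- function(trace, peak, peak_time, charge, win, zero = FALSE) {
  out <- tibble(cell_id = trace$cell_id, group = trace$group,
                protocol = trace$protocol, peak_amplitude_pa = peak,
                peak_time_s = peak_time, charge_transfer_pa_ms = charge,
                measurement_start_s = win[1], measurement_end_s = win[2],
                zero_response = zero)
  class(out) <- c("evoked_response", class(out))
  out
}

#' Percent of the evoked current remaining under blockade
#'
#' `100 * blocked peak / control peak`, for a control/co-application pair
#' from the same cell and protocol.
#'
#' @param control,blocked [gaba_evoked_peak()] rows.
#' @return Percent remaining (scalar). A non-positive control peak is an
#'   undefined-ratio error.
#' @export
percent_blockade <- function(control, blocked) {
  if (control$peak_amplitude_pa <= 0) {
    abort("control peak is not positive; blockade percentage undefined.",
          class = "dopaphys_validation_error")
  }
  100 * blocked$peak_amplitude_pa / control$peak_amplitude_pa
}

#' Afterhyperpolarization tail-current measures
#'
#' After the pulse-end mark, the outward tail is measured against the
#' pre-pulse median baseline: the peak amplitude (fast AHP component, pA,
#' outward-positive) and the trapezoidal charge transfer (slow component,
#' pA.ms) integrated from the pulse end until the current first returns to
#' baseline or the window ends. A tail never exceeding baseline + 2 sd is
#' returned as a flagged zero response rather than an error.
#'
#' @param trace A [current_trace()] with protocol `"ahp"` and a pulse-end
#'   stimulus mark.
#' @param baseline_s Pre-pulse baseline span (default 0.1 s).
#' @return One-row `evoked_response` tibble (see [gaba_evoked_peak()]).
#' @export
ahp_measures <- function(trace, baseline_s = 0.1) {
  stopifnot(inherits(trace, "current_trace"))
  if (trace$protocol != "ahp") {
    abort(sprintf("cell '%s': protocol is '%s', expected 'ahp'.",
                  trace$cell_id, trace$protocol), class = "dopaphys_protocol_error")
  }
  t0 <- first_mark(trace)
  tt <- trace_times(trace)
  pre <- trace$current[tt < t0 & tt >= t0 - baseline_s]
  b0 <- median(pre)
  sel <- tt >= t0
  tail_t <- tt[sel]; tail_i <- trace$current[sel] - b0   # positive = outward
  noise <- sd(pre - b0)
  # zero-response and return-to-baseline decisions use a 5 ms smoothed copy
  # so single noise excursions cannot mimic or truncate a tail
  tail_s <- boxcar(tail_i, max(1L, round(0.005 * trace$sampling_rate)))
  if (length(tail_i) == 0L || max(tail_s) <= 2 * noise) {
    return(evoked_row(trace, peak = 0, peak_time = t0, charge = 0,
                      win = c(t0, max(tt)), zero = TRUE))
  }
  pk <- which.max(tail_i)
  ret <- which(tail_s[-seq_len(pk)] <= 0)
  end <- if (length(ret) > 0) pk + ret[1] - 1L else length(tail_i)
  charge <- trapz(tail_t[1:end], tail_i[1:end]) * 1000   # pA.s -> pA.ms
  evoked_row(trace, peak = tail_i[pk], peak_time = tail_t[pk],
             charge = charge, win = c(t0, tail_t[end]))
}

#' Sag current and passive membrane properties from step protocols
#'
#' For an `"ih"` trace (hyperpolarizing step with `step_on`/`step_off`
#' marks), the hyperpolarization-activated sag current is estimated by
#' fitting `I(t) = I_inf + B * exp(-(t - t_on)/tau)` to the post-transient
#' portion of the step (from `settle_ms` after onset) and reading the full
#' sag amplitude `|B|` referenced to step onset; `method = "difference"`
#' instead returns steady state (last 50 ms of the step) minus the
#' instantaneous current at `settle_ms`, which under-reads whatever sag has
#' already activated by then.
#'
#' For a `"seal_test"` trace, the capacitive transient of a small step of
#' `step_mv` is fitted with a single exponential; standard single-compartment
#' estimates follow: `Rs = dV / I_peak` (peak extrapolated to step onset),
#' `Rm = dV / I_ss - Rs`, `Cm = tau * (Rs + Rm) / (Rs * Rm)`.
#'
#' @param trace A [current_trace()] with protocol `"ih"` or `"seal_test"`.
#' @param step_mv Voltage-step amplitude in mV; taken from the simulation
#'   truth attribute when present, otherwise required.
#' @param settle_ms Post-onset settle time before the sag fit / instantaneous
#'   read (default 20 ms).
#' @param method `"fit"` (default) or `"difference"` for the I_h estimate.
#' @return One-row tibble: `cell_id`, `group`, `protocol`, `i_h_pa`,
#'   `rs_mohm`, `rm_mohm`, `cm_pf` (passive fields NA for `"ih"`, `i_h_pa`
#'   NA for `"seal_test"`).
#' @export
ih_and_passive <- function(trace, step_mv = NULL, settle_ms = 20,
                           method = c("fit", "difference")) {
  stopifnot(inherits(trace, "current_trace"))
  method <- match.arg(method)
  if (!trace$protocol %in% c("ih", "seal_test")) {
    abort(sprintf("cell '%s': protocol is '%s', expected 'ih' or 'seal_test'.",
                  trace$cell_id, trace$protocol), class = "dopaphys_protocol_error")
  }
  step_mv <- step_mv %||% attr(trace, "step_mv") %||%
    (attr(trace, "truth") %||% list())$step_mv
  tt <- trace_times(trace)
  fs <- trace$sampling_rate
  out <- tibble(cell_id = trace$cell_id, group = trace$group,
                protocol = trace$protocol, i_h_pa = NA_real_,
                rs_mohm = NA_real_, rm_mohm = NA_real_, cm_pf = NA_real_)

  if (trace$protocol == "ih") {
    t_on <- first_mark(trace, "step_on")
    t_off <- first_mark(trace, "step_off")
    sel <- tt >= t_on + settle_ms / 1000 & tt < t_off
    ts <- tt[sel] - t_on; ys <- trace$current[sel]
    ss <- mean(trace$current[tt >= t_off - 0.05 & tt < t_off])
    inst <- mean(trace$current[tt >= t_on + settle_ms / 1000 &
                                 tt < t_on + (settle_ms + 10) / 1000])
    if (method == "difference") {
      out$i_h_pa <- abs(ss - inst)
      return(out)
    }
    tau0 <- 0.1
    fit <- tryCatch(
      minpack.lm::nlsLM(ys ~ I_inf + B * exp(-ts / tau),
                        start = list(I_inf = ss, B = inst - ss, tau = tau0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || coef(fit)[["tau"]] <= 0) {
      out$i_h_pa <- abs(ss - inst)     # documented fallback
    } else {
      out$i_h_pa <- abs(coef(fit)[["B"]])
    }
    return(out)
  }

  # seal_test
  if (is.null(step_mv)) {
    abort("seal_test analysis needs `step_mv`.", class = "dopaphys_protocol_error")
  }
  t_on <- first_mark(trace, "step_on")
  pre <- median(trace$current[tt < t_on])
  sel <- tt >= t_on
  ts <- tt[sel] - t_on; ys <- trace$current[sel] - pre
  i_ss0 <- mean(ys[ts >= max(ts) * 0.8])
  a0 <- ys[2] - i_ss0
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ I_ss + A * exp(-ts / tau),
                      start = list(I_ss = i_ss0, A = a0, tau = 0.002),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    abort(sprintf("cell '%s': capacitive-transient fit failed.", trace$cell_id),
          class = "dopaphys_fit_error")
  }
  cf <- coef(fit)
  i_peak <- cf[["I_ss"]] + cf[["A"]]        # extrapolated to step onset, pA
  i_ss <- cf[["I_ss"]]
  tau <- cf[["tau"]]                        # s
  rs <- step_mv / i_peak * 1000             # MOhm (mV / pA * 1000)
  rm <- step_mv / i_ss * 1000 - rs
  cm <- tau / (rs * rm / (rs + rm)) * 1e6   # pF (s / MOhm -> uF; *1e6 -> pF)
  out$rs_mohm <- abs(rs); out$rm_mohm <- abs(rm); out$cm_pf <- abs(cm)
  out
}
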