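# Independent oracles used across the suite. These are written directly from
# the rule statements, not from the package implementation, so agreement is
# a real check rather than an identity.

# Brute-force burst labelling by walking spikes with an open/closed state:
# a burst opens on two consecutive spikes closer than `onset` ms (both spikes
# belong to it) and closes on an interval greater than `offset` ms.
# Returns an integer burst id per spike (0 = not in a burst).
oracle_burst_label <- function(isi_ms, onset = 80, offset = 160) {
  n <- length(isi_ms) + 1L
  lab <- integer(n)
  k <- 0L
  open <- FALSE
  for (s in seq_along(isi_ms)) {
    if (!open) {
      if (isi_ms[s] < onset) {
        open <- TRUE
        k <- k + 1L
        lab[s] <- k
        lab[s + 1L] <- k
      }
    } else {
      if (isi_ms[s] > offset) {
        open <- FALSE
      } else {
        lab[s + 1L] <- k
      }
    }
  }
  lab
}

# Burst labels from a detect_bursts() table, same encoding as the oracle.
burst_table_to_labels <- function(bursts, n_spikes) {
  lab <- integer(n_spikes)
  for (b in seq_len(nrow(bursts))) {
    lab[bursts$first_spike[b]:bursts$last_spike[b]] <- b
  }
  lab
}

# Exact two-sided Mann-Whitney p for small samples by full enumeration of
# all group assignments: p = P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|).
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  vals <- c(x, y)
  u_of <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  centre <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
}

# Two-sample KS statistic as the maximum ECDF gap over all observed points.
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# Closed-form 10-90% rise time (ms) of a peak-normalized difference of
# exponentials, by root finding on the rising limb.
oracle_biexp_rise <- function(tau_rise_ms, tau_decay_ms) {
  tr <- tau_rise_ms; td <- tau_decay_ms
  tp <- log(td / tr) * td * tr / (td - tr)
  pk <- exp(-tp / td) - exp(-tp / tr)
  f <- function(t) (exp(-t / td) - exp(-t / tr)) / pk
  t10 <- stats::uniroot(function(t) f(t) - 0.1, c(1e-9, tp))$root
  t90 <- stats::uniroot(function(t) f(t) - 0.9, c(1e-9, tp))$root
  t90 - t10
}

# Build a spike_train directly from ISIs in ms.
train_from_isis <- function(isi_ms, pad_s = 1, ...) {
  times <- cumsum(c(0.5, isi_ms / 1000))
  spike_train(times, epoch_duration = max(times) + pad_s, ...)
}
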