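# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All simulators funnel their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "dopaphys_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Trailing (causal) running median over `k` samples: value at i is the
# median of samples (i-k+1)..i. Built on the centred stats::runmed.
trailing_median <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L || length(x) <= k) return(rep(median(x), length(x)))
  cen <- stats::runmed(x, k, endrule = "median")
  half <- (k - 1L) %/% 2L
  out <- c(rep(cen[half + 1L], half), cen[seq_len(length(x) - half)])
  out
}

# Centred boxcar smoothing with edge replication.
boxcar <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  n <- length(x)
  half_l <- (k - 1L) %/% 2L
  half_r <- k - 1L - half_l
  xp <- c(rep(x[1L], half_l), x, rep(x[n], half_r))
  cs <- cumsum(xp)
  (cs[(k):(n + k - 1L)] - c(0, cs[seq_len(n - 1L)])) / k
}

# Standard error of the mean; NA for n < 2.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

# Truncated normal draws by rejection (bounds far in the tail in all uses).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(mean, lower), upper)
  out
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)),
          class = "dopaphys_config_error")
  }
  invisible(x)
}
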