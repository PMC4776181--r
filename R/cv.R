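#' ISI coefficient of variation via Gaussian histogram fit
#'
#' The regularity index used for pacemaker-like firing: ISIs are histogrammed
#' at `bin_width_ms`, a Gaussian `A * exp(-(x - mu)^2 / (2 sigma^2))` is
#' least-squares fitted to the bin counts, and CV = 100 * sigma / mu
#' (percent). If the fit fails to converge, or returns a nonphysical result
#' (`mu <= 0`), the sample sd/mean of the raw ISIs is used instead and
#' `fallback_used` is set — the Gaussian model is only meaningful for
#' unimodal, pacemaker-like ISI distributions, and bursty (bimodal) trains
#' routinely take the fallback path.
#'
#' @param train A [spike_train()] or a bare numeric vector of ISIs in ms.
#' @param bin_width_ms Histogram bin width (default 10 ms).
#' @param min_isis Minimum number of ISIs required (default 10); fewer is an
#'   insufficient-data error.
#' @return An object of class `isi_cv_fit`: list with `cv_percent`, `mu_ms`,
#'   `sigma_ms`, `bin_width_ms`, `fit_ok`, `fallback_used`, `n_isis`.
#'   Degenerate zero-variance ISI sets give CV = 0 via the fallback.
#' @export
cv_of_isis <- function(train, bin_width_ms = 10, min_isis = 10) {
  isis <- if (inherits(train, "spike_train")) isi(train, "ms") else as.numeric(train)
  if (length(isis) < min_isis) {
    abort(sprintf("need at least %d ISIs, have %d.", min_isis, length(isis)),
          class = "dopaphys_insufficient_data")
  }
  m <- mean(isis); s <- sd(isis)
  fit_ok <- FALSE; fallback <- TRUE
  mu <- m; sigma <- s
  breaks <- seq(floor(min(isis) / bin_width_ms) * bin_width_ms - bin_width_ms,
                ceiling(max(isis) / bin_width_ms) * bin_width_ms + bin_width_ms,
                by = bin_width_ms)
  h <- graphics::hist(isis, breaks = breaks, plot = FALSE)
  centers <- h$mids; counts <- h$counts
  if (sum(counts > 0) >= 3 && s > 0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ A * exp(-(centers - mu)^2 / (2 * sigma^2)),
        start = list(A = max(counts), mu = m, sigma = s),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8,
                                             ptol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- coef(fit)
      if (is.finite(cf[["mu"]]) && cf[["mu"]] > 0 && is.finite(cf[["sigma"]])) {
        mu <- cf[["mu"]]; sigma <- abs(cf[["sigma"]])
        fit_ok <- TRUE; fallback <- FALSE
      }
    }
  }
  structure(
    list(cv_percent = 100 * sigma / mu, mu_ms = mu, sigma_ms = sigma,
         bin_width_ms = bin_width_ms, fit_ok = fit_ok,
         fallback_used = fallback, n_isis = length(isis)),
    class = "isi_cv_fit")
}

#' @export
print.isi_cv_fit <- function(x, ...) {
  cat(sprintf("<isi_cv_fit> CV = %.2f%% (mu = %.1f ms, sigma = %.1f ms, %s)\n",
              x$cv_percent, x$mu_ms, x$sigma_ms,
              if (x$fallback_used) "sample-statistic fallback" else "Gaussian fit"))
  invisible(x)
}

#' @export
tidy.isi_cv_fit <- function(x, ...) {
  tibble(term = c("mu_ms", "sigma_ms"), estimate = c(x$mu_ms, x$sigma_ms))
}

#' @export
glance.isi_cv_fit <- function(x, ...) {
  tibble(cv_percent = x$cv_percent, fit_ok = x$fit_ok,
         fallback_used = x$fallback_used, n_isis = x$n_isis,
         bin_width_ms = x$bin_width_ms)
}
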