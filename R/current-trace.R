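#' Construct a voltage-clamp current trace
#'
#' A uniformly sampled current recording in pA. Inward currents are negative
#' samples by convention; analysis functions report amplitudes as positive
#' magnitudes and state the sign convention in their docs.
#'
#' @param current Numeric vector of current samples in pA, all finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param cell_id Cell label.
#' @param holding_potential Holding potential in mV.
#' @param group Group label.
#' @param protocol One of `"mipsc"`, `"gaba_puff"`, `"ahp"`, `"ih"`,
#'   `"seal_test"`.
#' @param stimulus_marks Optional tibble with columns `time_s`, `description`.
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(current, sampling_rate, cell_id = "cell1",
                          holding_potential = -60, group = "control",
                          protocol = c("mipsc", "gaba_puff", "ahp", "ih", "seal_test"),
                          stimulus_marks = NULL) {
  protocol <- match.arg(protocol)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", min = 1e-9)
  current <- as.numeric(current)
  if (any(!is.finite(current))) {
    abort(sprintf("cell '%s': current contains non-finite samples.", cell_id),
          class = "dopaphys_validation_error")
  }
  if (!is.null(stimulus_marks)) {
    stimulus_marks <- as_tibble(stimulus_marks)
    if (!all(c("time_s", "description") %in% names(stimulus_marks))) {
      abort("stimulus_marks needs columns time_s, description.",
            class = "dopaphys_validation_error")
    }
  }
  structure(
    list(cell_id = as.character(cell_id),
         sampling_rate = sampling_rate,
         current = current,
         holding_potential = holding_potential,
         group = as.character(group),
         protocol = protocol,
         stimulus_marks = stimulus_marks),
    class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace '%s'> %s, %.3f s @ %g kHz, hold %g mV, group=%s\n",
              x$cell_id, x$protocol, trace_duration(x), x$sampling_rate / 1000,
              x$holding_potential, x$group))
  invisible(x)
}

#' Duration of a current trace in seconds
#' @param trace A [current_trace()].
#' @export
trace_duration <- function(trace) {
  length(trace$current) / trace$sampling_rate
}

#' Sample times of a current trace
#'
#' Sample `i` is taken at `(i - 1) / sampling_rate` seconds.
#' @param trace A [current_trace()].
#' @export
trace_times <- function(trace) {
  (seq_along(trace$current) - 1) / trace$sampling_rate
}

#' Read a current trace from annotated CSV
#'
#' Format: comment header lines `# sampling_rate_hz=...`,
#' `# holding_potential_mv=...`, `# protocol=...` (plus optional
#' `# cell_id=`, `# group=`, `# stim=<time_s>:<description>` lines), then a
#' single `current_pa` column.
#'
#' @param path File path.
#' @return A [current_trace()].
#' @export
read_current_trace <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path), class = "dopaphys_format_error")
  }
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", m[[1L]])
  }
  fs <- get_field("sampling_rate_hz")
  if (is.null(fs)) {
    abort("trace header is missing sampling_rate_hz.", class = "dopaphys_format_error")
  }
  hp <- get_field("holding_potential_mv")
  proto <- get_field("protocol")
  if (is.null(proto)) {
    abort("trace header is missing protocol.", class = "dopaphys_format_error")
  }
  stim_lines <- grep("^#\\s*stim=", hdr, value = TRUE)
  marks <- NULL
  if (length(stim_lines) > 0L) {
    parts <- strsplit(sub("^#\\s*stim=", "", stim_lines), ":", fixed = TRUE)
    marks <- tibble(time_s = as.numeric(purrr::map_chr(parts, 1)),
                    description = purrr::map_chr(parts, 2))
  }
  # base strtod parsing: bit-exact round trip of %.17g samples
  df <- utils::read.csv(path, comment.char = "#")
  if (!"current_pa" %in% names(df)) {
    abort("trace CSV must have a current_pa column.", class = "dopaphys_format_error")
  }
  current_trace(df$current_pa,
                sampling_rate = as.numeric(fs),
                cell_id = get_field("cell_id") %||% "cell1",
                holding_potential = as.numeric(hp %||% "-60"),
                group = get_field("group") %||% "control",
                protocol = proto,
                stimulus_marks = marks)
}

#' Write a current trace to annotated CSV
#'
#' Inverse of [read_current_trace()]; samples are written with full double
#' precision so the round trip is bit-exact.
#'
#' @param trace A [current_trace()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_current_trace <- function(trace, path) {
  hdr <- c(
    sprintf("# sampling_rate_hz=%s", format(trace$sampling_rate, digits = 17)),
    sprintf("# holding_potential_mv=%s", format(trace$holding_potential, digits = 17)),
    sprintf("# protocol=%s", trace$protocol),
    sprintf("# cell_id=%s", trace$cell_id),
    sprintf("# group=%s", trace$group))
  if (!is.null(trace$stimulus_marks) && nrow(trace$stimulus_marks) > 0L) {
    hdr <- c(hdr, sprintf("# stim=%s:%s",
                          format(trace$stimulus_marks$time_s, digits = 17),
                          trace$stimulus_marks$description))
  }
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  writeLines("current_pa", con)
  writeLines(sprintf("%.17g", trace$current), con)
  invisible(path)
}

#' Plot a current trace
#'
#' @param object A [current_trace()].
#' @param downsample Keep every n-th sample for display (default keeps about
#'   20k points).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.current_trace <- function(object, downsample = NULL, ...) {
  n <- length(object$current)
  step <- downsample %||% max(1L, n %/% 20000L)
  idx <- seq(1L, n, by = step)
  df <- tibble(time_s = (idx - 1) / object$sampling_rate,
               current_pa = object$current[idx])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$current_pa)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "current (pA)",
                  title = sprintf("%s (%s)", object$cell_id, object$protocol)) +
    ggplot2::theme_minimal()
  if (!is.null(object$stimulus_marks) && nrow(object$stimulus_marks) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$stimulus_marks$time_s,
                                 linetype = "dashed", colour = "red")
  }
  p
}
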