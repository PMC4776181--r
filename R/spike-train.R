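#' Construct a spike train
#'
#' A spike train is one unit's spike times over a recording epoch, together
#' with per-cell metadata. Times are seconds from epoch start; the epoch is
#' treated as half-open `[0, epoch_duration)` so that
#' `mean rate = n_spikes / epoch_duration` is unambiguous.
#'
#' @param spike_times Numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, epoch_duration]`.
#' @param epoch_duration Epoch length in seconds.
#' @param unit_id Unit label.
#' @param spike_durations Optional per-spike waveform durations in ms
#'   (onset to negative peak), same length as `spike_times`, all positive.
#' @param group Group label (e.g. `"control"`, `"eNRG1"`).
#' @param condition Condition label (e.g. `"baseline"`, `"PTX"`).
#' @param setting `"in_vivo"` or `"in_vitro"`; selects the unit-inclusion rule
#'   applied by [qc_filter_units()].
#' @return An object of class `spike_train`.
#' @seealso [detect_bursts()], [burst_stats()], [read_spike_trains()]
#' @export
spike_train <- function(spike_times, epoch_duration, unit_id = "unit1",
                        spike_durations = NULL, group = "control",
                        condition = "baseline",
                        setting = c("in_vivo", "in_vitro")) {
  setting <- match.arg(setting)
  stopifnot_scalar_number(epoch_duration, "epoch_duration", min = 0)
  spike_times <- as.numeric(spike_times)
  if (any(is.na(spike_times))) {
    abort(sprintf("unit '%s': spike_times contain NA.", unit_id),
          class = "dopaphys_validation_error")
  }
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0)) {
    abort(sprintf("unit '%s': spike_times must be strictly increasing.", unit_id),
          class = "dopaphys_validation_error")
  }
  if (length(spike_times) > 0L &&
      (min(spike_times) < 0 || max(spike_times) > epoch_duration)) {
    abort(sprintf("unit '%s': spike_times outside [0, epoch_duration].", unit_id),
          class = "dopaphys_validation_error")
  }
  if (!is.null(spike_durations)) {
    spike_durations <- as.numeric(spike_durations)
    if (length(spike_durations) != length(spike_times) ||
        any(is.na(spike_durations)) || any(spike_durations <= 0)) {
      abort(sprintf(
        "unit '%s': spike_durations must be positive and match spike_times in length.",
        unit_id), class = "dopaphys_validation_error")
    }
  }
  structure(
    list(unit_id = as.character(unit_id),
         spike_times = spike_times,
         epoch_duration = epoch_duration,
         spike_durations = spike_durations,
         group = as.character(group),
         condition = as.character(condition),
         setting = setting),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train '%s'> %d spikes / %.1f s (%.2f Hz), group=%s, condition=%s, %s\n",
              x$unit_id, length(x$spike_times), x$epoch_duration,
              length(x$spike_times) / x$epoch_duration, x$group, x$condition,
              x$setting))
  invisible(x)
}

#' Interspike intervals of a spike train
#'
#' @param train A [spike_train()].
#' @param units `"ms"` (default) or `"s"`.
#' @return Numeric vector of ISIs.
#' @export
isi <- function(train, units = c("ms", "s")) {
  units <- match.arg(units)
  d <- diff(train$spike_times)
  if (units == "ms") d * 1000 else d
}

#' Read spike trains from CSV plus a JSON metadata sidecar
#'
#' The CSV has columns `unit_id,spike_time_s[,spike_duration_ms]`; the JSON
#' sidecar is keyed by `unit_id` with fields `epoch_duration_s`, `group`,
#' `condition`, `setting`. Units appearing in the CSV but missing from the
#' sidecar are an error, as are non-increasing times within a unit.
#'
#' @param path Path to the spike CSV.
#' @param meta_path Path to the JSON sidecar; defaults to `path` with the
#'   extension replaced by `.json`.
#' @return Named list of [spike_train()] objects.
#' @export
read_spike_trains <- function(path, meta_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path), class = "dopaphys_format_error")
  }
  meta_path <- meta_path %||% paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(meta_path)) {
    abort(sprintf("metadata sidecar '%s' does not exist.", meta_path),
          class = "dopaphys_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("unit_id", "spike_time_s") %in% names(df))) {
    abort("spike CSV must have columns unit_id, spike_time_s.",
          class = "dopaphys_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ids <- unique(df$unit_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$unit_id == id, ]
    m <- meta[[as.character(id)]]
    if (is.null(m)) {
      abort(sprintf("unit '%s' has no metadata entry.", id),
            class = "dopaphys_format_error")
    }
    durs <- if ("spike_duration_ms" %in% names(rows)) rows$spike_duration_ms else NULL
    if (!is.null(durs) && all(is.na(durs))) durs <- NULL
    spike_train(rows$spike_time_s,
                epoch_duration = m$epoch_duration_s,
                unit_id = id,
                spike_durations = durs,
                group = m$group %||% "control",
                condition = m$condition %||% "baseline",
                setting = m$setting %||% "in_vivo")
  })
  setNames(out, ids)
}

#' Write spike trains to CSV plus a JSON metadata sidecar
#'
#' Inverse of [read_spike_trains()]; the round trip is lossless at double
#' precision.
#'
#' @param trains List of [spike_train()] objects.
#' @param path Output CSV path; the sidecar goes to the same path with a
#'   `.json` extension unless `meta_path` is given.
#' @param meta_path Optional sidecar path.
#' @return Invisibly, `path`.
#' @export
write_spike_trains <- function(trains, path, meta_path = NULL) {
  meta_path <- meta_path %||% paste0(tools::file_path_sans_ext(path), ".json")
  if (inherits(trains, "spike_train")) trains <- list(trains)
  df <- purrr::map_dfr(trains, function(tr) {
    tibble(unit_id = tr$unit_id,
           spike_time_s = tr$spike_times,
           spike_duration_ms = if (is.null(tr$spike_durations)) NA_real_ else tr$spike_durations)
  })
  readr::write_csv(df, path, progress = FALSE)
  meta <- lapply(trains, function(tr) {
    list(epoch_duration_s = tr$epoch_duration, group = tr$group,
         condition = tr$condition, setting = tr$setting)
  })
  names(meta) <- purrr::map_chr(trains, "unit_id")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Raster plot of one or more spike trains
#'
#' @param object A [spike_train()] or list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_train <- function(object, ...) {
  plot_raster(list(object))
}

#' @rdname autoplot.spike_train
#' @param trains List of spike trains.
#' @export
plot_raster <- function(trains, ...) {
  df <- purrr::map_dfr(trains, function(tr) {
    tibble(unit_id = tr$unit_id, group = tr$group, spike_time_s = tr$spike_times)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spike_time_s, y = .data$unit_id,
                                   colour = .data$group)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "group") +
    ggplot2::theme_minimal()
}
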