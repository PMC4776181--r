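#' Drug-application protocol
#'
#' Describes baseline and drug windows for a rate time course. By default
#' the baseline spans the 60 s immediately before application (the mean rate
#' in that minute is the 100% reference), and rates are binned at 20 s.
#'
#' @param drug_window `c(start_s, end_s)` of the application epoch.
#' @param baseline_window `c(start_s, end_s)`; default the 60 s immediately
#'   preceding `drug_window`.
#' @param bin_width Bin width in seconds (default 20); must divide both
#'   window lengths.
#' @param label Free-text protocol label (e.g. `"muscimol +2nA"`).
#' @return A `drug_protocol` list.
#' @export
drug_protocol <- function(drug_window, baseline_window = NULL, bin_width = 20,
                          label = "drug") {
  baseline_window <- baseline_window %||% c(drug_window[1] - 60, drug_window[1])
  if (baseline_window[2] > drug_window[1]) {
    abort("baseline_window must precede drug_window.", class = "dopaphys_config_error")
  }
  for (w in list(baseline_window, drug_window)) {
    len <- diff(w)
    if (len <= 0 || abs(len / bin_width - round(len / bin_width)) > 1e-9) {
      abort("bin_width must divide both window lengths.",
            class = "dopaphys_config_error")
    }
  }
  structure(list(baseline_window = baseline_window, drug_window = drug_window,
                 bin_width = bin_width, label = label),
            class = "drug_protocol")
}

#' Binned, baseline-normalized firing-rate time course
#'
#' Bins the whole epoch on a grid anchored at the baseline-window start,
#' computes the rate per bin (spike count / bin width), and normalizes each
#' bin to the mean baseline-window rate times 100, so the baseline bins
#' average exactly 100%.
#'
#' @param train A [spike_train()] whose epoch covers both protocol windows.
#' @param protocol A [drug_protocol()].
#' @return Tibble of class `rate_timecourse`: `bin_start_s`, `bin_end_s`,
#'   `rate_hz`, `normalized_pct`, `phase` (`"pre"`, `"baseline"`, `"drug"`,
#'   `"post"`). A unit with zero baseline rate is an undefined-normalization
#'   error (condition class `dopaphys_zero_baseline`).
#' @export
bin_rates <- function(train, protocol) {
  stopifnot(inherits(train, "spike_train"), inherits(protocol, "drug_protocol"))
  bw <- protocol$bin_width
  b0 <- protocol$baseline_window[1]
  if (b0 < 0 || protocol$drug_window[2] > train$epoch_duration) {
    abort(sprintf("unit '%s': epoch does not cover the protocol windows.",
                  train$unit_id), class = "dopaphys_config_error")
  }
  start <- b0 - bw * floor(b0 / bw)   # grid anchored at baseline start
  edges <- seq(start, train$epoch_duration + 1e-9, by = bw)
  edges <- edges[edges <= train$epoch_duration + 1e-9]
  if (length(edges) < 2L) {
    abort("epoch too short to bin.", class = "dopaphys_config_error")
  }
  lo <- edges[-length(edges)]; hi <- edges[-1]
  counts <- purrr::map2_dbl(lo, hi, function(a, b) {
    sum(train$spike_times >= a & train$spike_times < b)
  })
  rate <- counts / bw
  in_win <- function(w) lo >= w[1] - 1e-9 & hi <= w[2] + 1e-9
  phase <- dplyr::case_when(
    in_win(protocol$baseline_window) ~ "baseline",
    in_win(protocol$drug_window) ~ "drug",
    hi <= protocol$baseline_window[1] + 1e-9 ~ "pre",
    TRUE ~ "post")
  base_rate <- mean(rate[phase == "baseline"])
  if (!is.finite(base_rate) || base_rate <= 0) {
    abort(sprintf("unit '%s': zero baseline rate, normalization undefined.",
                  train$unit_id), class = "dopaphys_zero_baseline")
  }
  out <- tibble(bin_start_s = lo, bin_end_s = hi, rate_hz = rate,
                normalized_pct = 100 * rate / base_rate, phase = phase)
  class(out) <- c("rate_timecourse", class(out))
  attr(out, "protocol") <- protocol
  attr(out, "unit_id") <- train$unit_id
  attr(out, "group") <- train$group
  out
}

#' Mean percent change in rate during the drug window
#'
#' `mean(normalized drug-window bins) - 100`: negative for suppression,
#' positive for facilitation. Only bins strictly inside the drug window are
#' averaged (partial onset/offset bins outside the window are not).
#'
#' @param tc A [bin_rates()] time course.
#' @return Signed percent change (scalar).
#' @export
percent_change <- function(tc) {
  stopifnot(inherits(tc, "rate_timecourse"))
  mean(tc$normalized_pct[tc$phase == "drug"]) - 100
}

#' Plot a baseline-normalized rate time course
#'
#' @param object A [bin_rates()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_timecourse <- function(object, ...) {
  proto <- attr(object, "protocol")
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$bin_start_s + .data$bin_end_s) / 2,
                                       y = .data$normalized_pct)) +
    ggplot2::annotate("rect", xmin = proto$drug_window[1], xmax = proto$drug_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "firing rate (% of baseline)",
                  title = proto$label) +
    ggplot2::theme_minimal()
}

#' Cross-condition, cross-group contrast of a firing measure
#'
#' Summarizes a per-unit statistics table (e.g. [cohort_firing_table()]
#' output) by group and condition (mean, SEM, n) and runs Mann-Whitney
#' comparisons between groups within each condition and between conditions
#' within each group — the design in which a blocker can abolish a
#' between-group difference.
#'
#' @param table Per-unit tibble with `group`, `condition` and the measure
#'   column.
#' @param measure Column name to contrast (default `"mean_rate_hz"`).
#' @param conditions Character vector of condition labels expected in the
#'   table; unknown labels are a config error.
#' @return List with `summary` (group x condition tibble) and `comparisons`
#'   (tibble of Mann-Whitney results).
#' @export
condition_contrast <- function(table, measure = "mean_rate_hz",
                               conditions = c("baseline", "PTX")) {
  if (!all(conditions %in% unique(table$condition))) {
    abort(sprintf("condition label(s) %s not present in table.",
                  paste(setdiff(conditions, unique(table$condition)),
                        collapse = ", ")),
          class = "dopaphys_config_error")
  }
  tab <- table[table$condition %in% conditions, , drop = FALSE]
  summ <- tab |>
    group_by(.data$group, .data$condition) |>
    summarise(n = dplyr::n(),
              mean = mean(.data[[measure]], na.rm = TRUE),
              sem = sem(.data[[measure]]), .groups = "drop")
  comps <- list()
  groups <- sort(unique(tab$group))
  for (cond in conditions) {
    if (length(groups) == 2L) {
      a <- tab[[measure]][tab$group == groups[1] & tab$condition == cond]
      b <- tab[[measure]][tab$group == groups[2] & tab$condition == cond]
      if (length(a) >= 3 && length(b) >= 3) {
        comps[[length(comps) + 1L]] <-
          mann_whitney(a, b, measure = sprintf("%s [%s: %s vs %s]",
                                               measure, cond, groups[1], groups[2]))
      }
    }
  }
  for (g in groups) {
    if (length(conditions) == 2L) {
      a <- tab[[measure]][tab$group == g & tab$condition == conditions[1]]
      b <- tab[[measure]][tab$group == g & tab$condition == conditions[2]]
      if (length(a) >= 3 && length(b) >= 3) {
        comps[[length(comps) + 1L]] <-
          mann_whitney(a, b, measure = sprintf("%s [%s: %s vs %s]",
                                               measure, g, conditions[1], conditions[2]))
      }
    }
  }
  list(summary = summ,
       comparisons = if (length(comps)) dplyr::bind_rows(comps) else
         group_comparison_schema())
}

#' Normalized frequency and CV response to a superfused drug
#'
#' For agonist-superfusion designs: mean rate and ISI coefficient of
#' variation are each computed inside the baseline and drug (analysis)
#' windows and expressed as percent of their own baseline value. The
#' windowed CV is the sample sd/mean of the in-window ISIs (windows are too
#' short for a stable histogram fit).
#'
#' @param train A [spike_train()].
#' @param protocol A [drug_protocol()]; `drug_window` is the post-application
#'   analysis span.
#' @param min_isis Minimum ISIs required in each window (default 10).
#' @return One-row tibble: `unit_id`, `group`, `frequency_percent`,
#'   `cv_percent_of_baseline`.
#' @export
nmda_response <- function(train, protocol, min_isis = 10) {
  stopifnot(inherits(train, "spike_train"), inherits(protocol, "drug_protocol"))
  win_stats <- function(w) {
    t_in <- train$spike_times[train$spike_times >= w[1] & train$spike_times < w[2]]
    if (length(t_in) < min_isis + 1L) {
      abort(sprintf("unit '%s': fewer than %d ISIs in window [%g, %g].",
                    train$unit_id, min_isis, w[1], w[2]),
            class = "dopaphys_insufficient_data")
    }
    d <- diff(t_in)
    list(rate = length(t_in) / diff(w), cv = 100 * sd(d) / mean(d))
  }
  base <- win_stats(protocol$baseline_window)
  drug <- win_stats(protocol$drug_window)
  tibble(unit_id = train$unit_id, group = train$group,
         frequency_percent = 100 * drug$rate / base$rate,
         cv_percent_of_baseline = 100 * drug$cv / base$cv)
}
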