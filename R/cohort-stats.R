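# Group-level nonparametric statistics and publication-style summaries.
# Tests delegate to the standard stats implementations; the surrounding
# surface normalizes inputs, applies the sample-size policies and returns
# tidy one-row tibbles.

group_comparison_schema <- function() {
  tibble(measure = character(0), test = character(0), statistic = numeric(0),
         p_value = numeric(0), n1 = integer(0), n2 = integer(0),
         significant = logical(0))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact U distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with mid-rank tie
#' correction and continuity correction. The reported statistic is U for
#' the first sample. Significance at 0.05.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param measure Label carried into the result.
#' @param exact_max Combined-n switch point for the exact distribution
#'   (default 20).
#' @return One-row `group_comparison` tibble: `measure`, `test`,
#'   `statistic`, `p_value`, `n1`, `n2`, `significant`. Fully tied samples
#'   give p = 1 with a warning.
#' @export
mann_whitney <- function(x, y, measure = "", exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("each group needs n >= 3.", class = "dopaphys_insufficient_data")
  }
  if (length(unique(c(x, y))) == 1L) {
    warn("all observations tied; p = 1.")
    res <- list(statistic = c(W = length(x) * length(y) / 2), p.value = 1)
  } else {
    exact <- (length(x) + length(y)) <= exact_max && !any(duplicated(c(x, y)))
    res <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE))
  }
  row <- tibble(measure = measure, test = "mann_whitney",
                statistic = unname(res$statistic), p_value = res$p.value,
                n1 = length(x), n2 = length(y),
                significant = res$p.value < 0.05)
  class(row) <- c("group_comparison", class(row))
  row
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Intended for pooled per-cell amplitude samples
#' ([pool_for_cumulative()]). Asymptotic p-value.
#'
#' @param x,y Numeric samples, each n >= 10 (fewer is an insufficient-data
#'   error).
#' @param measure Label carried into the result.
#' @return One-row `group_comparison` tibble (statistic = D).
#' @export
ks_comparison <- function(x, y, measure = "") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 10 || length(y) < 10) {
    abort("each side needs n >= 10 for the KS comparison.",
          class = "dopaphys_insufficient_data")
  }
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  row <- tibble(measure = measure, test = "ks",
                statistic = unname(res$statistic), p_value = res$p.value,
                n1 = length(x), n2 = length(y),
                significant = res$p.value < 0.05)
  class(row) <- c("group_comparison", class(row))
  row
}

#' One-way ANOVA with distribution-free post-hoc comparisons
#'
#' One-way F test over k >= 3 labelled groups, followed (optionally) by
#' Holm-adjusted pairwise Mann-Whitney tests. The post-hoc family is a
#' configuration choice; Holm-adjusted rank tests keep the follow-up
#' consistent with the primary between-group test used elsewhere.
#'
#' @param data Data frame with the value and group columns.
#' @param value,group Column names (strings).
#' @param posthoc Run pairwise comparisons (default TRUE).
#' @return List of class `anova_posthoc`: `anova` (one-row tibble with
#'   `f_statistic`, `df1`, `df2`, `p_value`), `posthoc` (tibble of pairwise
#'   Holm-adjusted Mann-Whitney results, or NULL). Groups of constant equal
#'   values (zero variance everywhere) are a validation error.
#' @export
oneway_anova_posthoc <- function(data, value, group, posthoc = TRUE) {
  v <- data[[value]]; g <- factor(data[[group]])
  if (nlevels(g) < 3) {
    abort("need at least 3 groups.", class = "dopaphys_insufficient_data")
  }
  if (any(table(g) < 3)) {
    abort("each group needs n >= 3.", class = "dopaphys_insufficient_data")
  }
  if (sd(v) == 0) {
    abort("all values identical: F statistic undefined.",
          class = "dopaphys_validation_error")
  }
  fit <- aov(v ~ g)
  s <- summary(fit)[[1]]
  res <- list(
    anova = tibble(f_statistic = s[["F value"]][1],
                   df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                   p_value = s[["Pr(>F)"]][1]),
    posthoc = NULL)
  if (posthoc) {
    lv <- levels(g)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    rows <- purrr::map(pairs, function(pr) {
      mann_whitney(v[g == pr[1]], v[g == pr[2]],
                   measure = paste(pr, collapse = " vs "))
    })
    ph <- dplyr::bind_rows(rows)
    ph$p_adjusted <- p.adjust(ph$p_value, method = "holm")
    ph$significant <- ph$p_adjusted < 0.05
    res$posthoc <- ph
  }
  class(res) <- "anova_posthoc"
  res
}

#' @export
print.anova_posthoc <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.3g, p = %.4g\n",
              a$df1, a$df2, a$f_statistic, a$p_value))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc (Holm-adjusted pairwise Mann-Whitney):\n")
    print(as.data.frame(x$posthoc[, c("measure", "p_value", "p_adjusted",
                                      "significant")]))
  }
  invisible(x)
}

#' @export
tidy.anova_posthoc <- function(x, ...) {
  if (is.null(x$posthoc)) return(x$anova)
  x$posthoc
}

#' @export
glance.anova_posthoc <- function(x, ...) x$anova

#' @export
tidy.group_comparison <- function(x, ...) as_tibble(x)

#' Mean +/- SEM summary rows per measure and group
#'
#' @param table Per-cell tibble with a `group` column.
#' @param measures Character vector of measure column names; defaults to all
#'   numeric columns except counts/ids.
#' @return Tibble: `measure`, `group`, `n_cells`, `mean`, `sem`.
#' @export
summarise_by_group <- function(table, measures = NULL) {
  measures <- measures %||%
    setdiff(names(table)[purrr::map_lgl(table, is.numeric)],
            c("n_spikes", "n_bursts", "n_events", "n_clean_events"))
  out <- list()
  for (m in measures) {
    out[[m]] <- table |>
      group_by(.data$group) |>
      summarise(n_cells = dplyr::n(), mean = mean(.data[[m]], na.rm = TRUE),
                sem = sem(.data[[m]]), .groups = "drop") |>
      mutate(measure = m, .before = 1)
  }
  dplyr::bind_rows(out)
}

#' Build a structured results report from per-cell tables
#'
#' Takes a named list of per-cell tibbles (each with a `group` column and
#' numeric measure columns), emits mean +/- SEM summary rows per measure and
#' group, plus pairwise Mann-Whitney comparisons between the two groups for
#' every measure, and optionally writes `summary.csv`, `comparisons.csv` and
#' `report.json` to a directory.
#'
#' @param tables Named list of per-cell tibbles.
#' @param out_dir Optional output directory (created if needed).
#' @param required_measures Optional character vector; missing ones trigger
#'   an incomplete-report warning but the partial report is still returned.
#' @return List of class `results_report`: `summary`, `comparisons`.
#' @export
build_results_report <- function(tables, out_dir = NULL,
                                 required_measures = NULL) {
  summ <- list(); comps <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab) || nrow(tab) == 0L) next
    measures <- setdiff(names(tab)[purrr::map_lgl(tab, is.numeric)],
                        c("n_spikes", "n_bursts", "n_events", "n_clean_events"))
    s <- summarise_by_group(tab, measures)
    s$stage <- nm
    summ[[nm]] <- s
    groups <- sort(unique(tab$group))
    if (length(groups) == 2L) {
      for (m in measures) {
        a <- tab[[m]][tab$group == groups[1]]
        b <- tab[[m]][tab$group == groups[2]]
        if (sum(!is.na(a)) >= 3 && sum(!is.na(b)) >= 3) {
          cmp <- mann_whitney(a, b, measure = paste(nm, m, sep = "."))
          comps[[paste(nm, m, sep = ".")]] <- cmp
        }
      }
    }
  }
  summary_tbl <- if (length(summ)) dplyr::bind_rows(summ) else
    tibble(measure = character(0), group = character(0),
           n_cells = integer(0), mean = numeric(0), sem = numeric(0),
           stage = character(0))
  comp_tbl <- if (length(comps)) dplyr::bind_rows(comps) else
    group_comparison_schema()
  if (!is.null(required_measures)) {
    missing <- setdiff(required_measures, summary_tbl$measure)
    if (length(missing) > 0L) {
      warn(sprintf("incomplete report: missing measures %s.",
                   paste(missing, collapse = ", ")))
    }
  }
  report <- structure(list(summary = summary_tbl, comparisons = comp_tbl),
                      class = "results_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"), progress = FALSE)
    readr::write_csv(comp_tbl, file.path(out_dir, "comparisons.csv"), progress = FALSE)
    jsonlite::write_json(list(summary = summary_tbl, comparisons = comp_tbl),
                         file.path(out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.results_report <- function(x, ...) {
  cat(sprintf("<results_report> %d summary rows, %d comparisons\n",
              nrow(x$summary), nrow(x$comparisons)))
  invisible(x)
}
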