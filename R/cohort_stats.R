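#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test for paired baseline/follow-up measurements with the
#' drop-zeros convention: zero differences are removed, absolute differences
#' are ranked with average ranks on ties, and the statistic is
#' `W = min(W+, W-)`. For up to 25 effective pairs the two-sided p-value is
#' computed from the exact null distribution of the signed-rank sum
#' (tie-aware, by dynamic programming over the doubled ranks); beyond that a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param baseline,followup Paired numeric vectors of equal length, or give
#'   a two-column matrix/data frame as `baseline` and leave `followup`
#'   missing.
#' @return A `cvi_htest` with fields `method`, `statistic` (W), `p_value`,
#'   `n_effective` and `approx` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(baseline, followup = NULL) {
  if (is.null(followup)) {
    m <- as.matrix(baseline)
    if (ncol(m) != 2) abort("need paired values: two vectors or a 2-column table.")
    baseline <- m[, 1]; followup <- m[, 2]
  }
  if (length(baseline) != length(followup)) {
    abort("`baseline` and `followup` must have equal length.")
  }
  d <- baseline - followup
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1.")
    return(cvi_htest("wilcoxon_signed_rank", c(W = 0), 1, 0L, approx = "degenerate"))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  if (n <= 25) {
    p <- wilcoxon_exact_p(r, w)
    approx <- "exact"
  } else {
    ties <- table(abs(d))
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - n * (n + 1) / 4 + 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(z))
    approx <- "normal"
  }
  cvi_htest("wilcoxon_signed_rank", c(W = w), p, n, approx = approx)
}

# Exact two-sided p for the signed-rank statistic W = min(W+, W-) under the
# null of random signs, with tied (average) ranks. Works on doubled ranks so
# all masses sit on integers.
wilcoxon_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  s2 <- sum(r2)
  w2 <- as.integer(round(2 * w))
  if (2 * w2 >= s2) return(1)
  dist <- numeric(s2 + 1L)
  dist[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(s2 + 1L - ri)])
    dist <- (dist + shifted) / 2
  }
  min(1, 2 * sum(dist[seq_len(w2 + 1L)]))
}

#' Paired or Welch two-sample t-test
#'
#' Thin wrapper over [stats::t.test()]: paired t when `paired = TRUE`,
#' Welch's unequal-variance t otherwise, always two-sided. Degenerate input
#' (essentially constant data) yields a missing p-value with a warning
#' rather than an error.
#'
#' @param a,b Numeric samples (`paired = TRUE` requires equal length).
#' @param paired Logical.
#' @return A `cvi_htest` with the t statistic, p-value and effective n.
#' @export
t_tests <- function(a, b, paired = FALSE) {
  method <- if (paired) "paired_t" else "welch_t"
  n_eff <- if (paired) sum(stats::complete.cases(a, b)) else
    sum(!is.na(a)) + sum(!is.na(b))
  res <- tryCatch(stats::t.test(a, b, paired = paired), error = function(e) e)
  if (inherits(res, "error") || !is.finite(res$p.value)) {
    reason <- if (inherits(res, "error")) conditionMessage(res) else
      "essentially constant data"
    warn(sprintf("t-test undefined (%s); returning missing p.", reason))
    return(cvi_htest(method, c(t = NA_real_), NA_real_, n_eff))
  }
  cvi_htest(method, c(t = unname(res$statistic)), res$p.value, n_eff)
}

#' One-way analysis of variance with R-squared
#'
#' Delegates the fit to [stats::aov()] and reports the F statistic, its
#' p-value and the explained-variance ratio
#' `R^2 = SS_between / SS_total`. With all values identical the F statistic
#' is undefined and `R^2 = 0` is returned with a warning.
#'
#' @param groups Either a list of numeric samples, or a numeric vector with
#'   `labels` giving group membership.
#' @param labels Optional group labels when `groups` is one vector.
#' @return A `cvi_htest` with `r_squared` set.
#' @export
one_way_anova <- function(groups, labels = NULL) {
  if (is.list(groups) && is.null(labels)) {
    values <- unlist(groups, use.names = FALSE)
    labels <- rep(seq_along(groups), lengths(groups))
  } else {
    values <- groups
  }
  keep <- !is.na(values)
  values <- values[keep]; labels <- factor(labels[keep])
  if (nlevels(labels) < 2) abort("one-way ANOVA needs at least 2 groups.")
  if (length(values) <= nlevels(labels)) {
    abort("one-way ANOVA needs more observations than groups.")
  }
  if (max(values) == min(values)) {
    warn("all values identical; F undefined, R^2 = 0.")
    return(cvi_htest("one_way_anova", c(F = NA_real_), NA_real_,
                     length(values), r_squared = 0))
  }
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  ss_between <- tab["labels", "Sum Sq"]
  ss_total <- sum(tab[, "Sum Sq"])
  cvi_htest("one_way_anova", c(F = tab["labels", "F value"]),
            tab["labels", "Pr(>F)"], length(values),
            r_squared = ss_between / ss_total)
}

cvi_htest <- function(method, statistic, p_value, n_effective,
                      r_squared = NA_real_, approx = NA_character_) {
  structure(
    list(method = method, statistic = statistic, p_value = p_value,
         n_effective = n_effective, r_squared = r_squared, approx = approx),
    class = "cvi_htest"
  )
}

#' @export
print.cvi_htest <- function(x, ...) {
  cat(sprintf("<cvi_htest> %s: %s = %s, p = %s, n = %d%s%s\n",
              x$method, names(x$statistic)[1],
              format(unname(x$statistic[1]), digits = 4),
              format(x$p_value, digits = 4), x$n_effective,
              if (!is.na(x$r_squared)) sprintf(", R^2 = %.3f", x$r_squared) else "",
              if (!is.na(x$approx)) sprintf(" [%s]", x$approx) else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cvi_htest <- function(x, ...) {
  tibble(
    method = x$method,
    statistic = unname(x$statistic[1]),
    p.value = x$p_value,
    n = x$n_effective,
    r.squared = x$r_squared
  )
}

#' @export
glance.cvi_htest <- function(x, ...) tidy(x)

#' Read a long-format paired cohort table
#'
#' Expects a CSV with columns `eye_id, group, visit, metric, value`
#' (`visit` in `baseline`/`followup`); each `(eye_id, visit, metric)` may
#' appear at most once.
#'
#' @param path CSV path.
#' @return A validated tibble of class `paired_cohort`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_paired_cohort(df)
}

#' Validate a data frame as a paired cohort table
#'
#' @param df Data frame with columns `eye_id, group, visit, metric, value`.
#' @return The tibble with class `paired_cohort` prepended.
#' @export
as_paired_cohort <- function(df) {
  need <- c("eye_id", "group", "visit", "metric", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  dup <- df |>
    dplyr::count(.data$eye_id, .data$visit, .data$metric) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (eye_id, visit, metric) row(s), e.g. %s/%s/%s.",
                  dup$eye_id[1], dup$visit[1], dup$metric[1]))
  }
  class(df) <- c("paired_cohort", class(df))
  df
}

#' Long cohort table from wide per-eye metric rows
#'
#' Pivots `choroid_metrics`-style rows (one per eye-visit) into the long
#' `paired_cohort` layout used by the statistics battery.
#'
#' @param metrics Data frame with `eye_id`, `visit` and numeric metric
#'   columns.
#' @param group Group label (`"study"` or `"control"`), recycled or a
#'   column name already present in `metrics`.
#' @param metrics_cols Which columns to pivot; defaults to the standard
#'   metric columns present.
#' @return A `paired_cohort` tibble.
#' @export
cohort_table_from_metrics <- function(metrics, group = "study",
                                      metrics_cols = NULL) {
  metrics <- as_tibble(as.data.frame(metrics))
  if (is.null(metrics_cols)) {
    metrics_cols <- intersect(
      c("TCA_mm2", "LA_mm2", "SA_mm2", "CVI", "LA_SA", "SFCT_um", "CT_um"),
      names(metrics))
  }
  if (!"group" %in% names(metrics)) metrics$group <- group
  long <- tidyr::pivot_longer(
    metrics[, c("eye_id", "group", "visit", metrics_cols)],
    cols = dplyr::all_of(metrics_cols),
    names_to = "metric", values_to = "value")
  as_paired_cohort(long)
}

#' Read a per-eye cohort spreadsheet
#'
#' Imports an `.xlsx` deposit of per-eye metric values (requires the
#' readxl package) and maps the user-declared columns onto the long
#' `paired_cohort` layout. Spreadsheet layouts vary, so the mapping is
#' explicit: `value_cols` names the metric columns, `visit_col`/`group_col`
#' the design columns.
#'
#' @param path `.xlsx` path.
#' @param sheet Sheet name or index.
#' @param eye_col,group_col,visit_col Column names in the sheet.
#' @param value_cols Named character vector: `c(metric_name = sheet_column)`.
#' @return A `paired_cohort` tibble.
#' @export
read_cohort_xlsx <- function(path, sheet = 1, eye_col, group_col, visit_col,
                             value_cols) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("reading .xlsx requires the 'readxl' package.")
  }
  if (!file.exists(path)) abort(sprintf("spreadsheet not found: %s", path))
  raw <- readxl::read_excel(path, sheet = sheet)
  df <- tibble(
    eye_id = as.character(raw[[eye_col]]),
    group = as.character(raw[[group_col]]),
    visit = as.character(raw[[visit_col]])
  )
  long <- purrr::map_dfr(names(value_cols), function(m) {
    dplyr::mutate(df, metric = m, value = as.numeric(raw[[value_cols[[m]]]]))
  })
  as_paired_cohort(long)
}

#' Group summary of one metric
#'
#' Mean, sample sd (n-1 denominator), range and count of a metric for one
#' group at one visit -- the "mean +/- sd (range)" cells of a cohort table.
#'
#' @param table A `paired_cohort` (or compatible) data frame.
#' @param metric,group,visit Cell selectors.
#' @return A one-row tibble `(metric, group, visit, mean, sd, min, max, n)`.
#' @export
summarize_metric <- function(table, metric, group, visit) {
  rows <- dplyr::filter(table, .data$metric == !!metric,
                        .data$group == !!group, .data$visit == !!visit)
  if (nrow(rows) == 0) {
    abort(sprintf("no rows for metric '%s', group '%s', visit '%s'.",
                  metric, group, visit))
  }
  v <- rows$value
  tibble(metric = metric, group = group, visit = visit,
         mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
         min = min(v), max = max(v), n = length(v))
}

#' Paired cohort statistics battery
#'
#' For every metric in the table: a paired Wilcoxon signed-rank test of
#' baseline vs follow-up within each group; a Welch t-test and one-way
#' ANOVA (with R^2) between groups at each visit; and a Welch t-test
#' comparing the per-eye percent change between groups. P-values are
#' reported unadjusted.
#'
#' @param table A `paired_cohort` data frame.
#' @param metrics Metrics to test; defaults to all present.
#' @return A tidy tibble: `metric, comparison, group, method, statistic,
#'   p.value, r.squared, n`.
#' @export
cohort_tests <- function(table, metrics = unique(table$metric)) {
  groups <- unique(table$group)
  purrr::map_dfr(metrics, function(m) {
    sub <- dplyr::filter(table, .data$metric == !!m)
    wide <- tidyr::pivot_wider(sub, id_cols = c("eye_id", "group"),
                               names_from = "visit", values_from = "value")
    rows <- list()
    for (g in groups) {
      gw <- dplyr::filter(wide, .data$group == !!g)
      if (all(c("baseline", "followup") %in% names(gw)) &&
          sum(stats::complete.cases(gw$baseline, gw$followup)) >= 1) {
        ht <- wilcoxon_signed_rank(gw$baseline, gw$followup)
        rows <- c(rows, list(tidy_row(m, "baseline_vs_followup", g, ht)))
      }
    }
    if (length(groups) >= 2) {
      for (v in intersect(c("baseline", "followup"), names(wide))) {
        samples <- lapply(groups, function(g) wide[[v]][wide$group == g])
        if (all(lengths(samples) >= 2)) {
          ht_t <- t_tests(samples[[1]], samples[[2]])
          ht_a <- one_way_anova(samples)
          cmp <- paste0("between_groups_", v)
          rows <- c(rows, list(tidy_row(m, cmp, NA_character_, ht_t),
                               tidy_row(m, cmp, NA_character_, ht_a)))
        }
      }
      if (all(c("baseline", "followup") %in% names(wide))) {
        pc <- dplyr::mutate(wide, pct = percent_change(.data$baseline, .data$followup))
        samples <- lapply(groups, function(g) pc$pct[pc$group == g])
        if (all(lengths(samples) >= 2)) {
          ht <- t_tests(samples[[1]], samples[[2]])
          rows <- c(rows, list(tidy_row(m, "pct_change_between_groups",
                                        NA_character_, ht)))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

tidy_row <- function(metric, comparison, group, ht) {
  dplyr::bind_cols(tibble(metric = metric, comparison = comparison,
                          group = group), tidy(ht))
}
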