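#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard AS R94 implementation with explicit
#' domain checks (3 <= n <= 5000, non-degenerate sample).
#'
#' @param values numeric vector.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop_bad_arg("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(values))
  if (stats::sd(values) == 0) stop_bad_arg("sample is constant; test undefined")
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p_value = t$p.value)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided test of location shift.  With `mode = "auto"` the exact null
#' distribution is enumerated when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param mode `"auto"`, `"exact"` or `"normal-approx"`.
#' @param metric,label_a,label_b optional annotations carried through.
#' @return List of class `group_comparison`: `statistic` (rank-sum W of the
#'   first sample), `p_value`, `n_a`, `n_b`, `mode`, plus annotations.
#'   All-tied inputs give `p_value = 1` with a warning.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal-approx"),
                          metric = NA_character_, label_a = "A", label_b = "B") {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop_bad_arg("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(structure(list(statistic = sum(rank(c(x, y))[seq_along(x)]),
                          p_value = 1, n_a = length(x), n_b = length(y),
                          mode = "degenerate", metric = metric,
                          label_a = label_a, label_b = label_b),
                     class = "group_comparison"))
  }
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 20L) && !ties,
                  exact = TRUE,
                  `normal-approx` = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(list(statistic = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
                 p_value = wt$p.value, n_a = length(x), n_b = length(y),
                 mode = if (exact) "exact" else "normal-approx",
                 metric = metric, label_a = label_a, label_b = label_b),
            class = "group_comparison")
}

#' Tukey five-number box-plot summary
#'
#' Median and quartiles by linear interpolation (type-7 quantiles); whiskers
#' at the sample extremes; points beyond 1.5 IQR from the quartiles are
#' listed as outliers.
#'
#' @param values non-empty numeric vector.
#' @return List of class `boxplot_summary`: `min`, `q1`, `median`, `q3`,
#'   `max`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop_bad_arg("empty input")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  out <- values[values < qs[1] - 1.5 * iqr | values > qs[3] + 1.5 * iqr]
  structure(list(min = min(values), q1 = qs[1], median = qs[2], q3 = qs[3],
                 max = max(values), outliers = sort(out)),
            class = "boxplot_summary")
}

## default contrasts mirroring the study's figures
default_comparison_plan <- function() {
  cancer <- c("ILC", "IDC1", "IDC2", "IDC3")
  benign <- c("fib_a", "fib_m")
  idc <- c("IDC1", "IDC2", "IDC3")
  breast_metrics <- c("pct_blue", "pct_yellow", "pct_red", "yb_ratio")
  plan <- list()
  for (m in breast_metrics) {
    plan[[length(plan) + 1L]] <- list(metric = m, level = "breast",
                                      a = cancer, b = benign,
                                      label_a = "cancer", label_b = "benign")
    plan[[length(plan) + 1L]] <- list(metric = m, level = "breast",
                                      a = idc, b = "ILC",
                                      label_a = "IDC", label_b = "ILC")
    plan[[length(plan) + 1L]] <- list(metric = m, level = "breast",
                                      a = "fib_a", b = "fib_m",
                                      label_a = "fib_a", label_b = "fib_m")
  }
  for (ct in list(list(a = cancer, b = benign, la = "cancer", lb = "benign"),
                  list(a = idc, b = benign, la = "IDC", lb = "benign"),
                  list(a = "ILC", b = benign, la = "ILC", lb = "benign"),
                  list(a = idc, b = "ILC", la = "IDC", lb = "ILC")))
    plan[[length(plan) + 1L]] <- list(metric = "yb_factor", level = "patient",
                                      a = ct$a, b = ct$b,
                                      label_a = ct$la, label_b = ct$lb)
  plan
}

#' Group comparisons over a cohort
#'
#' Runs one two-sided rank-sum test per (metric, contrast).  Breast-level
#' metrics (`pct_blue`, `pct_yellow`, `pct_red`, `yb_ratio`) are taken from
#' the tumorous breast of each patient; the YB Factor contrasts are
#' patient-level.  p-values are reported unadjusted (a Benjamini-Hochberg
#' column is added for reference but plays no role in any decision).
#'
#' @param cohort a `data.frame` from [patient_table] (or
#'   [generate_cohort]), with one row per patient.
#' @param plan list of contrasts; each entry has `metric`, `level`
#'   (`"breast"` or `"patient"`), group label sets `a` and `b`, and display
#'   labels.  Defaults to the study's contrasts.
#' @param breast_side which breast feeds breast-level contrasts
#'   (`"tumor"`, the default convention, or `"both"`).
#' @return `data.frame`: metric, contrast, n_a, n_b, statistic,
#'   p_unadjusted, p_bh.  Contrasts with an empty group are skipped with a
#'   warning.
#' @export
compare_groups <- function(cohort, plan = default_comparison_plan(),
                           breast_side = c("tumor", "both")) {
  breast_side <- match.arg(breast_side)
  rows <- list()
  for (ct in plan) {
    ga <- cohort[cohort$group %in% ct$a, , drop = FALSE]
    gb <- cohort[cohort$group %in% ct$b, , drop = FALSE]
    pull <- function(g) {
      if (ct$level == "patient") return(g[[ct$metric]])
      if (breast_side == "tumor") return(g[[paste0("tumor_", ct$metric)]])
      c(g[[paste0("tumor_", ct$metric)]], g[[paste0("opposite_", ct$metric)]])
    }
    va <- pull(ga); vb <- pull(gb)
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (!length(va) || !length(vb)) {
      warning("empty group for contrast ", ct$label_a, " vs ", ct$label_b,
              " (", ct$metric, "); skipped")
      next
    }
    t <- rank_sum_test(va, vb, metric = ct$metric,
                       label_a = ct$label_a, label_b = ct$label_b)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = ct$metric, level = ct$level,
      contrast = paste(ct$label_a, "vs", ct$label_b),
      n_a = t$n_a, n_b = t$n_b, statistic = t$statistic,
      p_unadjusted = t$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_unadjusted, method = "BH")
  out
}
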