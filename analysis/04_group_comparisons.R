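#!/usr/bin/env Rscript
## Nonparametric group comparisons over the simulated cohort: rank-sum tests
## for the breast-level composition metrics and the patient-level YB Factor,
## plus box-plot summaries for the figure-style displays.

suppressMessages(library(mammowtmm))

path <- "results/cohort_metrics.csv"
if (!file.exists(path)) {
  cat("cohort table not found; run analysis/01_simulate_cohort.R first\n")
  quit(status = 1)
}
cohort <- read.csv(path)

cmp <- suppressWarnings(compare_groups(cohort))
dir.create("results", showWarnings = FALSE)
write.csv(cmp, "results/group_comparisons.csv", row.names = FALSE)

cat("key contrasts (two-sided Wilcoxon rank-sum, unadjusted p):\n")
show <- cmp[cmp$contrast %in% c("cancer vs benign", "IDC vs ILC",
                                "fib_a vs fib_m"), ]
print(show[, c("metric", "contrast", "n_a", "n_b", "p_unadjusted")],
      row.names = FALSE, digits = 3)

## five-number summaries of the YB Factor per group (box-plot ingredients)
groups <- split(cohort$yb_factor, cohort$group)
box <- do.call(rbind, lapply(names(groups), function(g) {
  b <- boxplot_summary(groups[[g]])
  data.frame(group = g, min = b$min, q1 = b$q1, median = b$median,
             q3 = b$q3, max = b$max, n_outliers = length(b$outliers))
}))
write.csv(box, "results/yb_factor_boxplots.csv", row.names = FALSE)
cat("wrote results/group_comparisons.csv and results/yb_factor_boxplots.csv\n")
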