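test_that("Shapiro-Wilk wrapper matches its contract", {
  set.seed(5)
  g <- rnorm(50); e <- rexp(50)
  expect_gt(shapiro_wilk(g)$p_value, 0.05)
  expect_lt(shapiro_wilk(e)$p_value, 0.05)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("rank-sum exact p equals brute-force enumeration", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  set.seed(14)
  for (i in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(rnorm(nx), 3); y <- round(rnorm(ny, 0.5), 3)
    if (any(duplicated(c(x, y)))) next
    t <- rank_sum_test(x, y)
    expect_equal(t$mode, "exact")
    expect_equal(t$p_value, oracle_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("rank-sum handles degenerate and tied inputs", {
  x <- c(1, 2, 3)
  expect_equal(suppressWarnings(rank_sum_test(x, x))$p_value, 1)
  expect_warning(rank_sum_test(c(2, 2), c(2, 2)), "tied")
})

test_that("rank-sum p is symmetric under label swap and modes agree", {
  set.seed(8)
  x <- rnorm(30); y <- rnorm(25, 0.3)
  expect_equal(rank_sum_test(x, y)$p_value, rank_sum_test(y, x)$p_value,
               tolerance = 1e-12)
  ## large-sample: exact (forced) and normal approximation agree closely
  x2 <- rnorm(10); y2 <- rnorm(10, 0.8)
  p_ex <- rank_sum_test(x2, y2, mode = "exact")$p_value
  p_ap <- rank_sum_test(x2, y2, mode = "normal-approx")$p_value
  expect_lt(abs(p_ex - p_ap), 0.01)
})

test_that("box-plot summary follows the type-7 quartile convention", {
  b <- boxplot_summary(1:9)
  expect_equal(b$median, 5); expect_equal(b$q1, 3); expect_equal(b$q3, 7)
  expect_length(b$outliers, 0)
  s <- boxplot_summary(42)
  expect_true(all(c(s$min, s$q1, s$median, s$q3, s$max) == 42))
  o <- boxplot_summary(c(1:10, 100))
  expect_equal(o$outliers, 100)
  expect_true(b$min <= b$q1 && b$q1 <= b$median && b$median <= b$q3 &&
                b$q3 <= b$max)
  expect_error(boxplot_summary(numeric()), "empty")
})

test_that("compare_groups composes rank_sum_test over the plan", {
  ## two hand-built patients per group: result must equal the direct test
  mk <- function(id, g, yb) {
    m <- compute_metrics(class_counts(10, round(10 * yb), 20))
    patient_record(id, g, "left", m, compute_metrics(class_counts(10, 10, 20)))
  }
  recs <- list(mk("a", "ILC", 1.2), mk("b", "ILC", 1.7),
               mk("c", "fib_a", 0.8), mk("d", "fib_a", 1.1))
  tab <- patient_table(recs)
  plan <- list(list(metric = "yb_factor", level = "patient",
                    a = "ILC", b = "fib_a", label_a = "ILC", label_b = "fib_a"))
  got <- compare_groups(tab, plan)
  want <- rank_sum_test(tab$yb_factor[tab$group == "ILC"],
                        tab$yb_factor[tab$group == "fib_a"])
  expect_equal(got$p_unadjusted, want$p_value)
  expect_equal(got$n_a, 2L); expect_equal(got$n_b, 2L)
  ## empty contrast is skipped with a warning
  plan2 <- c(plan, list(list(metric = "yb_factor", level = "patient",
                             a = "IDC2", b = "fib_a", label_a = "IDC",
                             label_b = "fib_a")))
  expect_warning(out2 <- compare_groups(tab, plan2), "empty group")
  expect_equal(nrow(out2), 1L)
})

test_that("default plan covers the study's contrasts", {
  tab <- generate_cohort(cohort_spec(seed = 3))
  cg <- compare_groups(tab)
  expect_true(all(c("cancer vs benign", "IDC vs ILC", "fib_a vs fib_m") %in%
                    cg$contrast))
  expect_true("yb_factor" %in% cg$metric)
  expect_true(all(cg$p_unadjusted >= 0 & cg$p_unadjusted <= 1))
  expect_true(all(cg$p_bh >= cg$p_unadjusted - 1e-12))
})
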