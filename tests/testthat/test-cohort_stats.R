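test_that("five concordant pairs give W = 0 and exact p = 2/2^5", {
  ht <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p_value, 0.0625)
  expect_identical(ht$n_effective, 5L)
  expect_identical(ht$approx, "exact")
})

test_that("identical pairs collapse to p = 1 with a warning", {
  expect_warning(ht <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(ht$p_value, 1)
  expect_identical(ht$n_effective, 0L)
})

test_that("exact signed-rank p matches full 2^n enumeration, ties included", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    base <- sample(-5:15, n, replace = TRUE)
    fol <- base - sample(-3:3, n, replace = TRUE)  # small integer diffs -> ties
    if (all(base == fol)) fol[1] <- fol[1] + 1
    ht <- wilcoxon_signed_rank(base, fol)
    expect_equal(ht$p_value, oracle_wilcoxon_p(base, fol),
                 info = sprintf("rep %d", rep))
  }
})

test_that("exact signed-rank p agrees with stats::wilcox.test when tie-free", {
  set.seed(72)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    # distinct magnitudes with random signs: tie-free for the exact reference
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    ht <- wilcoxon_signed_rank(d, rep(0, n))
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ht$p_value, ref$p.value)
  }
})

test_that("large samples switch to the corrected normal approximation", {
  set.seed(73)
  d <- rnorm(40, mean = 0.3)
  ht <- wilcoxon_signed_rank(d, rep(0, 40))
  expect_identical(ht$approx, "normal")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ht$p_value, ref$p.value, tolerance = 1e-9)
  # a monotone sign/order-preserving transform leaves the test unchanged
  ht2 <- wilcoxon_signed_rank(sign(d) * abs(d)^3, rep(0, 40))
  expect_equal(ht2$p_value, ht$p_value)
})

test_that("t tests cover identical, textbook and paired-identity cases", {
  a <- c(1, 2, 3, 4)
  ht <- t_tests(a, a)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p_value, 1)
  # closed-form Welch statistic
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7, 23.2, 17.5)
  ht2 <- t_tests(x, y)
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(unname(ht2$statistic), (mean(x) - mean(y)) / se, tolerance = 1e-12)
  # paired t equals the one-sample t on differences
  b <- a + c(0.5, -0.2, 0.9, 0.4)
  htp <- t_tests(a, b, paired = TRUE)
  ref <- stats::t.test(a - b)
  expect_equal(unname(htp$statistic), unname(ref$statistic))
  expect_equal(htp$p_value, ref$p.value)
  # essentially constant data: missing p with a warning
  expect_warning(htc <- t_tests(c(1, 1, 1), c(1, 1, 1), paired = TRUE),
                 "undefined")
  expect_true(is.na(htc$p_value))
})

test_that("one-way ANOVA reproduces the sum-of-squares decomposition", {
  set.seed(74)
  g <- list(rnorm(8, 10), rnorm(6, 12), rnorm(7, 9))
  ht <- one_way_anova(g)
  values <- unlist(g)
  labels <- rep(1:3, lengths(g))
  grand <- mean(values)
  ss_b <- sum(vapply(1:3, function(i) length(g[[i]]) * (mean(g[[i]]) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(1:3, function(i) sum((g[[i]] - mean(g[[i]]))^2), numeric(1)))
  ss_t <- sum((values - grand)^2)
  expect_equal(ss_b + ss_w, ss_t, tolerance = 1e-9)
  expect_equal(ht$r_squared, ss_b / ss_t, tolerance = 1e-12)
  ms_b <- ss_b / 2; ms_w <- ss_w / (length(values) - 3)
  expect_equal(unname(ht$statistic), ms_b / ms_w, tolerance = 1e-12)
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(75)
  a <- rnorm(9, 5); b <- rnorm(11, 6)
  ht <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(unname(ht$statistic), unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht$p_value, tt$p.value, tolerance = 1e-10)
  # equal group means: R^2 ~ 0
  ht0 <- one_way_anova(list(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(ht0$r_squared, 0, tolerance = 1e-12)
  expect_warning(htc <- one_way_anova(list(c(2, 2), c(2, 2, 2))), "identical")
  expect_equal(htc$r_squared, 0)
})

test_that("tidy and glance return one-row broom-style summaries", {
  ht <- one_way_anova(list(c(1, 2, 3), c(4, 5, 7)))
  td <- tidy(ht)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_named(td, c("method", "statistic", "p.value", "n", "r.squared"))
  expect_identical(glance(ht), td)
})

test_that("group summaries use the sample sd and report the range", {
  tab <- as_paired_cohort(data.frame(
    eye_id = c("e1", "e2", "e1"), group = "study",
    visit = c("baseline", "baseline", "followup"),
    metric = "CVI", value = c(64.2, 69.8, 60)
  ))
  s <- summarize_metric(tab, "CVI", "study", "baseline")
  expect_equal(s$min, 64.2)
  expect_equal(s$max, 69.8)
  expect_equal(s$sd, sd(c(64.2, 69.8)))
  s1 <- summarize_metric(tab, "CVI", "study", "followup")
  expect_true(is.na(s1$sd))
  expect_equal(s1$min, s1$max)
  expect_error(summarize_metric(tab, "CVI", "control", "baseline"), "no rows")
  # spreadsheet-style recomputation on a larger draw
  set.seed(76)
  v <- round(rnorm(19, 74.1, 4.7), 1)
  tab19 <- as_paired_cohort(data.frame(
    eye_id = sprintf("e%02d", 1:19), group = "study", visit = "baseline",
    metric = "CVI", value = v))
  s19 <- summarize_metric(tab19, "CVI", "study", "baseline")
  expect_equal(s19$mean, sum(v) / 19, tolerance = 1e-12)
  expect_equal(s19$sd, sqrt(sum((v - mean(v))^2) / 18), tolerance = 1e-12)
})

test_that("cohort tables validate duplicates and round-trip through CSV", {
  df <- data.frame(eye_id = c("e1", "e1"), group = "study",
                   visit = c("baseline", "baseline"),
                   metric = "CVI", value = c(0.7, 0.8))
  expect_error(as_paired_cohort(df), "duplicate")
  good <- data.frame(eye_id = rep(c("e1", "e2"), each = 2), group = "study",
                     visit = rep(c("baseline", "followup"), 2),
                     metric = "CVI", value = c(0.74, 0.69, 0.75, 0.71))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(good, path, row.names = FALSE)
  tab <- read_cohort_table(path)
  expect_s3_class(tab, "paired_cohort")
  expect_identical(nrow(tab), 4L)
  expect_error(read_cohort_xlsx(tempfile(fileext = ".xlsx"), 1, "a", "b", "c",
                                c(CVI = "d")), "not found")
})

test_that("the battery emits the expected comparisons per metric", {
  set.seed(77)
  n <- 10
  mk <- function(gr, mu_b, mu_f, sdv) {
    b <- rnorm(n, mu_b, sdv); f <- b - rnorm(n, mu_b - mu_f, sdv / 3)
    data.frame(eye_id = sprintf("%s%02d", gr, 1:n), group = gr,
               visit = rep(c("baseline", "followup"), each = n),
               metric = "CVI", value = c(b, f))
  }
  tab <- as_paired_cohort(rbind(mk("study", 0.74, 0.69, 0.03),
                                mk("control", 0.67, 0.668, 0.01)))
  out <- cohort_tests(tab)
  expect_setequal(
    unique(out$comparison),
    c("baseline_vs_followup", "between_groups_baseline",
      "between_groups_followup", "pct_change_between_groups"))
  expect_true(all(out$p.value >= 0 & out$p.value <= 1, na.rm = TRUE))
  wsr <- dplyr::filter(out, comparison == "baseline_vs_followup",
                       group == "study")
  expect_lt(wsr$p.value, 0.05)  # built-in effect should be detected
  anova_rows <- dplyr::filter(out, method == "one_way_anova")
  expect_true(all(!is.na(anova_rows$r.squared)))
})
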