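test_that("two identical samples give a null t of zero and p of one", {
  x <- c(12.1, 14.3, 11.8, 13.5, 12.9, 15.2)
  cmp <- compare_independent(x, x)
  expect_equal(cmp$statistic, 0, tolerance = 1e-9)
  expect_equal(cmp$p_value, 1, tolerance = 1e-9)
  expect_match(cmp$test_used, "Student")
})

test_that("the independent engine matches the pooled-variance t oracle", {
  a <- c(12.1, 14.3, 11.8, 13.5, 12.9, 15.2)
  b <- c(10.4, 11.9, 12.7, 9.8, 11.2)
  cmp <- compare_independent(a, b)
  orc <- oracle_pooled_t(a, b)
  expect_equal(cmp$statistic, orc$t, tolerance = 1e-9)
  expect_equal(cmp$p_value, orc$p, tolerance = 1e-9)
  td <- tidy(cmp)
  expect_equal(td$n, 11)
  expect_true(td$parametric)
})

test_that("clearly non-normal groups fall back to Mann-Whitney", {
  a <- c(rep(0.1, 8), 50, 80, 120)  # heavy right tail
  b <- c(rep(0.2, 7), 60, 90)
  cmp <- compare_independent(a, b)
  expect_match(cmp$test_used, "Mann")
  expect_false(cmp$parametric)
  expect_match(cmp$descriptives$summary[1], "\\(")  # median (Q1-Q3) style
})

test_that("degenerate independent data is refused", {
  expect_error(compare_independent(rep(3, 5), rep(3, 6)),
               class = "sleepfbn_degenerate_data")
  expect_error(compare_independent(1, c(2, 3)),
               class = "sleepfbn_insufficient_data")
})

test_that("the paired engine matches the closed-form paired t oracle", {
  before <- c(24.0, 31.2, 18.5, 27.9, 22.4, 30.1, 25.5, 21.0)
  after <- before + c(3.1, 1.2, 4.9, 0.4, 2.6, 3.8, 1.9, 2.2)
  cmp <- compare_paired(before, after)
  d <- after - before
  t_orc <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$statistic, t_orc, tolerance = 1e-9)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_orc), length(d) - 1),
               tolerance = 1e-9)
  expect_equal(cmp$mean_difference, mean(d))
})

test_that("constant or zero paired differences hit the degenerate path", {
  x <- c(1, 2, 3, 4, 5)
  expect_error(compare_paired(x, x + 2), class = "sleepfbn_degenerate_data")
  expect_error(compare_paired(x, x), class = "sleepfbn_degenerate_data")
  expect_error(compare_paired(1:3, 1:4), class = "sleepfbn_pairing")
})

test_that("chi-squared matches the sum((O-E)^2/E) oracle", {
  even <- matrix(c(5, 5, 5, 5), 2, 2)
  cmp <- compare_categorical(even)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)

  tab <- matrix(c(12, 3, 5, 10), 2, 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  cmp2 <- compare_categorical(tab)
  expect_equal(cmp2$statistic, x2, tolerance = 1e-9)
  expect_equal(cmp2$p_value, pchisq(x2, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("degenerate tables and the Fisher option behave as documented", {
  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               class = "sleepfbn_invalid_input")
  expect_error(compare_categorical(matrix(c(-1, 2, 3, 4), 2, 2)),
               class = "sleepfbn_invalid_input")
  sparse <- matrix(c(2, 8, 7, 3), 2, 2)
  auto <- compare_categorical(sparse, exact = "auto")
  expect_match(auto$test_used, "Fisher")
  expect_length(auto$notes, 1)
  pearson <- compare_categorical(sparse)
  expect_match(pearson$test_used, "Pearson")
  expect_match(pearson$notes, "expected cell")
})

test_that("a two-timepoint repeated-measures ANOVA reduces to the paired t", {
  tab <- withr::with_seed(31, tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:12), each = 2),
    timepoint = rep(c("baseline", "6M"), 12),
    value = rnorm(24, 50, 10)
  ))
  long <- compare_longitudinal(tab)
  wide <- tidyr::pivot_wider(tab, names_from = "timepoint",
                             values_from = "value")
  prd <- compare_paired(wide$baseline, wide$`6M`)
  expect_equal(long$statistic, prd$statistic^2, tolerance = 1e-6)
  expect_equal(long$p_value, prd$p_value, tolerance = 1e-6)
})

test_that("a planted within-subject trend is detected with high power", {
  k <- 5
  rej <- vapply(1:500, function(s) {
    withr::with_seed(s, {
      mu <- seq(0, 1.5, length.out = k)  # monotone, 1.5 within-subject SD
      y <- matrix(rnorm(14 * k), 14, k) +
        matrix(rep(rnorm(14, 0, 1), k), 14, k) +
        matrix(rep(mu, each = 14), 14, k)
      tab <- tibble::tibble(
        subject_id = rep(sprintf("S%02d", 1:14), k),
        timepoint = rep(paste0("T", 1:k), each = 14),
        value = as.vector(y)
      )
      compare_longitudinal(tab)$p_value < 0.05
    })
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("longitudinal preconditions are enforced", {
  tab <- tibble::tibble(subject_id = rep(c("A", "B"), each = 3),
                        timepoint = rep(c("t1", "t2", "t3"), 2),
                        value = rnorm(6))
  expect_error(compare_longitudinal(tab),
               class = "sleepfbn_insufficient_data")
})

test_that("larger planted shifts never raise the median p-value", {
  shifts <- c(0, 0.5, 1, 1.5)
  med_p <- vapply(shifts, function(delta) {
    p <- vapply(1:200, function(s) {
      withr::with_seed(s, {
        a <- rnorm(15) + delta
        b <- rnorm(10)
      })
      compare_independent(a, b)$p_value
    }, numeric(1))
    median(p)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("t and Mann-Whitney decisions agree for large normal samples", {
  agree <- vapply(1:500, function(s) {
    withr::with_seed(s, {
      a <- rnorm(100); b <- rnorm(100)
    })
    t_sig <- t.test(a, b, var.equal = TRUE)$p.value < 0.05
    w_sig <- wilcox.test(a, b)$p.value < 0.05
    t_sig == w_sig
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
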