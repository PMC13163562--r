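test_that("cohort summaries report mean, sample SD and range per variable", {
  exams <- make_exams(n = 2, sex = c("M", "F"), scan_dlp_mgycm = c(40, 60))
  s <- summarize_cohort(derive_exams(exams))
  row <- s[s$variable == "scan_dlp_mgycm", ]
  expect_equal(row$mean, 50)
  expect_equal(row$sd, 14.14214, tolerance = 1e-6)  # n - 1 denominator
  expect_equal(row$min, 40)
  expect_equal(row$max, 60)
  expect_equal(row$n, 2L)
})

test_that("a constant-valued cohort degenerates to sd 0 and min = mean = max", {
  s <- summarize_cohort(derive_exams(make_exams(n = 5)))
  expect_true(all(s$sd == 0))
  expect_true(all(s$min == s$mean & s$mean == s$max))
})

test_that("sex comparisons are attached only when both sexes are represented", {
  set.seed(42)
  exams <- make_exams(n = 12, sex = rep(c("M", "F"), each = 6),
                      scan_dlp_mgycm = runif(12, 30, 80))
  s <- summarize_cohort(derive_exams(exams))
  row <- s[s$variable == "scan_dlp_mgycm", ]
  expect_true(is.finite(row$p_sex))
  expect_true(row$test %in% c("t_test", "mann_whitney"))

  single <- summarize_cohort(derive_exams(make_exams(n = 5, sex = "M")))
  expect_true(all(is.na(single$p_sex)))
  expect_true(all(single$test == "unavailable"))
})

test_that("degenerate cohorts are rejected", {
  expect_error(summarize_cohort(tibble::tibble()),
               class = "ctdose_empty_input")
  expect_error(summarize_cohort(derive_exams(make_exams(n = 3))[0, ]),
               class = "ctdose_empty_input")
  expect_error(summarize_cohort(derive_exams(make_exams(n = 3))[1, ]),
               class = "ctdose_insufficient_data")
})

test_that("identical samples give p = 1 and small groups are rejected", {
  cmp <- compare_sexes(as.numeric(1:10), as.numeric(1:10))
  expect_equal(cmp$p_value, 1)
  expect_error(compare_sexes(1:2, 1:10),
               class = "ctdose_insufficient_data")
})

test_that("the normality gate picks the t-test for normal data and the rank test otherwise", {
  set.seed(7)
  x <- rnorm(30)
  y <- rnorm(30, 5)
  cmp <- compare_sexes(x, y)
  expect_equal(cmp$test, "t_test")
  expect_lt(cmp$p_value, 0.001)

  xe <- rexp(30)             # strongly skewed: Shapiro-Wilk rejects
  ye <- rexp(30) * 2
  expect_gt(min(shapiro.test(xe)$p.value < 0.05,
                shapiro.test(ye)$p.value < 0.05), 0)
  cmp2 <- compare_sexes(xe, ye)
  expect_equal(cmp2$test, "mann_whitney")

  # zero-spread group cannot be screened for normality -> rank test
  cmp3 <- compare_sexes(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_equal(cmp3$test, "mann_whitney")
})

test_that("gated p-values agree with a 10,000-draw permutation oracle", {
  set.seed(123)
  x <- rnorm(15, 0, 1)
  y <- rnorm(15, 0.8, 1)
  cmp <- compare_sexes(x, y)
  expect_equal(cmp$test, "t_test")
  p_perm <- perm_pvalue(x, y, B = 10000)
  expect_lt(abs(cmp$p_value - p_perm), 0.03)

  xe <- rexp(25)^2
  ye <- rexp(25)^2 * 3
  cmp2 <- compare_sexes(xe, ye)
  expect_equal(cmp2$test, "mann_whitney")
  rank_stat <- function(a, b) sum(rank(c(a, b))[seq_along(a)])
  p_perm2 <- perm_pvalue(xe, ye, B = 10000, stat = rank_stat)
  expect_lt(abs(cmp2$p_value - p_perm2), 0.03)
})

test_that("the below-reference share uses a strict boundary and sums to 100", {
  d <- deff_distribution(c(30, 32, 34), 32)
  expect_equal(d$pct_below, 100 / 3, tolerance = 1e-9)
  expect_equal(d$pct_below + d$pct_at_or_above, 100)

  expect_equal(deff_distribution(rep(20, 7), 32)$pct_below, 100)
  expect_error(deff_distribution(numeric(0)), class = "ctdose_empty_input")

  set.seed(9)
  for (i in 1:20) {
    dd <- deff_distribution(runif(sample(1:50, 1), 20, 40))
    expect_equal(dd$pct_below + dd$pct_at_or_above, 100)
  }
})
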