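test_that("efficiency gain is one minus the response ratio", {
  expect_equal(round(efficiency_gain(2084, 3600), 2), 0.42)
  expect_equal(efficiency_gain(3600, 3600), 0)
  expect_equal(efficiency_gain(1800, 3600), 0.5)
  expect_error(efficiency_gain(4000, 3600))
})

test_that("paired t matches the textbook formula and flags degeneracy", {
  set.seed(31)
  x <- rnorm(40); y <- rnorm(40)
  res <- paired_t(x, y)
  d <- x - y
  t_direct <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_direct, tolerance = 1e-10)
  expect_equal(res$df, 39L)
  expect_equal(res$p, 2 * pt(-abs(t_direct), 39), tolerance = 1e-12)
  # cross-check against the stock implementation
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # identical arms: t = 0 is degenerate here (zero-variance differences)
  same <- paired_t(x, x)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  # constant nonzero differences
  con <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(con$degenerate)
  expect_identical(con$t, Inf)
  # invariant to a common shift
  sh <- paired_t(x + 5, y + 5)
  expect_equal(sh$t, res$t, tolerance = 1e-10)
})

test_that("pearson_r behaves at the boundaries", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2 * x + 3), 1)
})

test_that("chi-square independence is the uncorrected Pearson statistic", {
  dep <- cbind(male = c(44, 28, 8, 11, 12), female = c(41, 22, 14, 7, 16))
  res <- chi_square_independence(dep)
  expect_equal(round(res$chi2, 1), 3.9)
  expect_equal(res$df, 4L)
  # brute-force sum((O - E)^2 / E) on random tables
  set.seed(17)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_independence(tab)$chi2, sum((tab - E)^2 / E),
                 tolerance = 1e-10)
  }
  # proportional rows carry no association
  expect_equal(chi_square_independence(rbind(c(10, 20), c(20, 40)))$chi2, 0,
               tolerance = 1e-10)
  # worked 2x2
  tab <- rbind(c(10, 20), c(30, 40))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_independence(tab)$chi2, sum((tab - E)^2 / E))
})

test_that("descriptives report moment coefficients", {
  d <- descriptives(c(1, 1, 4, 4))
  expect_equal(d$mean, 2.5)
  expect_equal(d$sd, sd(c(1, 1, 4, 4)))
  expect_equal(d$skewness, 0)
  con <- descriptives(rep(3, 10))
  expect_equal(con$sd, 0)
  expect_true(is.na(con$skewness) && is.na(con$kurtosis))
  set.seed(23)
  big <- rnorm(1e5, 0.71, 1.62)
  db <- descriptives(big)
  expect_lt(abs(db$mean - 0.71), 3 * 1.62 / sqrt(1e5))
  expect_lt(abs(db$sd - 1.62), 0.02)
  expect_lt(abs(db$skewness), 0.05)
  expect_lt(abs(db$kurtosis), 0.1)
})

test_that("the comparison report assembles the study statistics", {
  st <- run_study(study_config(n_persons = 30L, seed = 6L), ipq18)
  rep <- st$report
  expect_s3_class(rep, "comparison_report")
  expect_equal(rep$efficiency_gain,
               1 - st$totals$cat_responses / st$totals$nat_responses)
  expect_equal(rep$pearson_r,
               cor(st$persons$cat_theta, st$persons$nat_theta))
  expect_equal(rep$paired_t_length$df, 29L)
  # deterministic given the study
  rep2 <- comparison_report(st)
  expect_equal(rep, rep2)
})

test_that("demographics attach chi-square tables and group comparisons", {
  st <- run_study(study_config(n_persons = 40L, seed = 14L), ipq18)
  set.seed(15)
  demo <- data.frame(person = 1:40,
                     gender = sample(c("M", "F"), 40, replace = TRUE),
                     department = sample(c("IM", "Surg"), 40, replace = TRUE))
  rep <- comparison_report(st, demo)
  expect_named(rep$demographics, "department")
  cs <- rep$demographics$department$chi_square
  expect_equal(cs$df, 1L)
  av <- rep$demographics$department$anova
  ref <- oneway.test(st$persons$cat_theta ~ factor(demo$department),
                     var.equal = TRUE)
  expect_equal(av$F, unname(ref$statistic), tolerance = 1e-10)
  # no demographics: section omitted
  expect_null(comparison_report(st)$demographics)
})

test_that("a single-person study flags the paired tests as unavailable", {
  st <- run_study(study_config(n_persons = 1L, seed = 8L), ipq18)
  expect_null(st$report$paired_t_length)
  expect_true(is.na(st$report$pearson_r))
})

test_that("render_report writes a readable summary", {
  st <- run_study(study_config(n_persons = 10L, seed = 9L), ipq18)
  path <- withr::local_tempfile(fileext = ".txt")
  render_report(st, path = path)
  txt <- readLines(path)
  expect_true(any(grepl("efficiency gain", txt)))
  expect_true(any(grepl("paired t", txt)))
})
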