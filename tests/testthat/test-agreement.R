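test_that("identical non-constant columns give perfect agreement", {
  A <- c(3, 1, 4, 1, 5, 9, 2.6)
  r <- icc_2_1(cbind(A, A))
  expect_equal(r$estimate, 1)
  expect_true(r$meets_clinical)
  expect_true(r$meets_interchangeable)
  # fully constant table: degenerate, defined as 1
  rc <- icc_2_1(cbind(rep(2, 6), rep(2, 6)))
  expect_true(rc$degenerate)
  expect_equal(rc$estimate, 1)
})

test_that("ICC(2,1) matches the explicit sums-of-squares oracle", {
  set.seed(606)
  x <- cbind(rnorm(6), rnorm(6))
  x[, 2] <- x[, 1] + rnorm(6, 0, 3)
  expect_lt(abs(icc_2_1(x)$estimate - icc_oracle_sums(x)), 1e-10)
})

test_that("ICC(2,1) estimate and confidence bound match an independent implementation", {
  # cross-check against the two-way absolute-agreement single-rater ICC of
  # the pingouin library
  set.seed(77)
  A <- rnorm(15)
  B <- 0.9 * A + rnorm(15, 0.1, 0.5)
  r <- icc_2_1(cbind(A, B))
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(A = A, B = B), csv, row.names = FALSE)
  py <- paste(
    "import sys, pandas as pd, pingouin as pg",
    "df = pd.read_csv(sys.argv[1])",
    "long = df.reset_index().melt(id_vars='index', var_name='r', value_name='y')",
    "icc = pg.intraclass_corr(long, targets='index', raters='r', ratings='y')",
    "row = icc[icc['Type'] == 'ICC(A,1)'].iloc[0]",
    "print('%.12f,%.3f,%.3f' % (row['ICC'], row['CI95'][0], row['CI95'][1]))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py), shQuote(csv)), stdout = TRUE)
  vals <- as.numeric(strsplit(utils::tail(out, 1), ",")[[1]])
  expect_equal(r$estimate, vals[1], tolerance = 1e-9)
  expect_equal(r$lower_ci_95, vals[2], tolerance = 0.01)  # pingouin rounds its CI
  expect_equal(r$upper_ci_95, vals[3], tolerance = 0.01)
})

test_that("ICC(2,1) is invariant to common shifts and positive scalings", {
  set.seed(8)
  x <- cbind(rnorm(12, 70, 8), rnorm(12, 70, 8))
  base <- icc_2_1(x)$estimate
  expect_equal(icc_2_1(x + 17.3)$estimate, base, tolerance = 1e-12)
  expect_equal(icc_2_1(x * 4.2)$estimate, base, tolerance = 1e-12)
  expect_error(icc_2_1(x[1:4, ]), "at least 5")
})

test_that("Bland-Altman collapses correctly when the devices agree exactly", {
  tab <- data.frame(participant = rep(1:4, each = 2),
                    a = rnorm(8, 70, 5))
  tab$b <- tab$a
  r <- bland_altman_repeated(tab)
  expect_equal(r$bias, 0)
  expect_equal(r$sd_of_differences, 0)
  expect_equal(r$loa_upper - r$loa_lower, 0)
  expect_equal(r$outlier_fraction, 0)
})

test_that("repeated-measures SD matches a by-hand ANOVA decomposition", {
  # 3 participants x 2 blocks, hand-enumerable differences
  tab <- data.frame(participant = rep(c("p1", "p2", "p3"), each = 2),
                    a = c(70, 72, 65, 66, 80, 81))
  tab$b <- tab$a + c(0.5, 1.5, -1.0, 0.0, 2.0, 3.0)
  r <- bland_altman_repeated(tab)
  d <- tab$b - tab$a
  expect_equal(r$bias, mean(d), tolerance = 1e-12)
  expect_equal(r$sd_of_differences, ba_oracle_sd(d, tab$participant),
               tolerance = 1e-12)
  expect_equal(r$method, "repeated")
  expect_equal(r$loa_lower, r$bias - 1.96 * r$sd_of_differences)
  expect_equal(r$loa_upper, r$bias + 1.96 * r$sd_of_differences)
  # outside-LoA fraction is reproducible from the returned limits
  expect_equal(r$outlier_fraction, mean(d < r$loa_lower | d > r$loa_upper))
})

test_that("one observation per participant reduces to the classical estimator", {
  set.seed(5150)
  d <- rnorm(40, 0.2, 1.3)
  tab <- data.frame(participant = sprintf("s%02d", 1:40), a = 0, b = d)
  r <- bland_altman_repeated(tab)
  expect_equal(r$method, "classical")
  expect_equal(r$bias, mean(d))
  expect_equal(r$sd_of_differences, sd(d))
})

test_that("log-transform mode differences log-measurements and guards positivity", {
  tab <- data.frame(participant = rep(1:5, each = 2),
                    a = runif(10, 50, 90))
  tab$b <- tab$a * exp(rnorm(10, 0, 0.02))
  r <- bland_altman_repeated(tab, log_transform = TRUE)
  expect_true(r$log_transformed)
  expect_equal(r$bias, mean(log(tab$b) - log(tab$a)), tolerance = 1e-12)
  tab$a[1] <- -1
  expect_error(bland_altman_repeated(tab, log_transform = TRUE),
               "strictly positive")
})

test_that("the normality test separates Gaussian from heavy-tailed differences", {
  p_norm <- vapply(1:100, function(s) {
    set.seed(s); test_normality(rnorm(200))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_t2 <- vapply(1:100, function(s) {
    set.seed(s); test_normality(rt(200, df = 2))$p
  }, numeric(1))
  expect_gte(mean(p_t2 < 0.05), 0.90)
  expect_error(test_normality(c(1, 2)), "3 <= n")
  expect_error(test_normality(rep(1, 10)), "degenerate")
})

test_that("Q-Q data pairs ordered differences with normal quantiles", {
  set.seed(12)
  d <- rnorm(500, 0, 2.5)
  qq <- qq_data(d)
  expect_equal(length(qq$theoretical), 500)
  expect_true(!is.unsorted(qq$sample))
  slope <- unname(coef(lm(qq$sample ~ qq$theoretical))[2])
  expect_lt(abs(slope - sd(d)) / sd(d), 0.1)
  expect_equal(length(qq_data(c(3, 1, 2))$sample), 3)
  expect_error(qq_data(c(1, 2)), "at least 3")
})

test_that("criteria thresholds implement the 90% / 75% rules", {
  fake <- function(est, low) {
    structure(list(estimate = est, lower_ci_95 = low,
                   meets_clinical = est > 0.90,
                   meets_interchangeable = low > 0.75),
              class = "icc_result")
  }
  tab <- evaluate_criteria(list(hr = fake(0.999, 0.994),
                                lf_hf = fake(0.836, 0.656),
                                borderline = fake(0.91, 0.74)))
  expect_equal(tab$clinical_pass, c(TRUE, FALSE, TRUE))
  expect_equal(tab$interchangeable_pass, c(TRUE, FALSE, FALSE))
  expect_equal(tab$verdict[1], "good to excellent agreement")
  expect_equal(tab$verdict[2], "insufficient agreement")
  expect_equal(tab$verdict[3], "clinical only")
  expect_equal(tab$icc_pct, c(99.9, 83.6, 91.0))
  expect_equal(tab$lower_ci_pct, c(99.4, 65.6, 74.0))
})

test_that("paired tables drop unusable rows pairwise and count them", {
  f <- expand.grid(participant = c("p1", "p2", "p3", "p4", "p5"),
                   block = c("B1", "B2"), device = c("A", "B"),
                   stringsAsFactors = FALSE)
  f$condition <- "fixation"
  set.seed(2)
  f$hr <- rnorm(nrow(f), 70, 5)
  f$usable <- TRUE
  f$usable[f$participant == "p2" & f$block == "B1" & f$device == "A"] <- FALSE
  tab <- paired_feature_table(f, "hr", c("A", "B"))
  expect_equal(nrow(tab), 9)
  expect_equal(attr(tab, "n_dropped"), 1)
})
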