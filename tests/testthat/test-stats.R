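test_that("ICC is 1 for identical raters and matches an independent reference", {
  m <- cbind(c(3, 7, 1, 9, 5), c(3, 7, 1, 9, 5))
  res <- icc_agreement(m)
  expect_equal(res$icc_single, 1)
  expect_equal(res$icc_average, 1)

  # 5 x 2 fixture with expected values frozen from an independent
  # implementation of the two-way ANOVA ICC decomposition
  m <- cbind(c(10, 12, 8, 15, 11), c(11, 14, 9, 15, 13))
  ag <- icc_agreement(m, model = "agreement")
  expect_equal(ag$icc_single, 0.855072463768116, tolerance = 1e-9)
  expect_equal(ag$icc_average, 0.921875, tolerance = 1e-9)
  cs <- icc_agreement(m, model = "consistency")
  expect_equal(cs$icc_single, 0.944, tolerance = 1e-9)
  expect_equal(cs$icc_average, 0.9711934156378602, tolerance = 1e-9)

  expect_warning(icc_agreement(matrix(5, 4, 2)),
                 class = "perivasc_degenerate_warning")
  expect_error(icc_agreement(matrix(1:2, 1, 2)),
               class = "perivasc_input_error")
})

test_that("ICC recovers a planted reliability in simulation", {
  set.seed(301)
  n <- 200
  truth <- rnorm(n, 0, 2)          # between-subject SD 2
  ratings <- cbind(truth + rnorm(n), truth + rnorm(n)) # rater noise SD 1
  res <- icc_agreement(ratings)
  expect_equal(res$icc_single, 0.8, tolerance = 0.05) # 4 / (4 + 1)
})

test_that("two-group ANOVA F equals the pooled-variance t squared", {
  set.seed(302)
  d <- data.frame(y = c(rnorm(12, 0), rnorm(15, 0.7)),
                  group = rep(c("a", "b"), c(12, 15)))
  gc <- group_comparison(d, "y")
  tt <- t.test(y ~ group, data = d, var.equal = TRUE)
  expect_equal(gc$anova$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(gc$anova$p, tt$p.value, tolerance = 1e-10)
})

test_that("identical groups give a null ANOVA and Bonferroni never shrinks P", {
  d <- data.frame(y = rep(c(1, 2, 3), 3),
                  group = rep(c("a", "b", "c"), each = 3))
  gc <- group_comparison(d, "y")
  expect_equal(gc$anova$f, 0, tolerance = 1e-12)
  expect_equal(gc$anova$p, 1, tolerance = 1e-12)
  expect_true(all(gc$posthoc$p_bonferroni >= gc$posthoc$p_raw))
  expect_true(all(gc$posthoc$p_bonferroni <= 1))
  expect_equal(nrow(gc$posthoc), 3)

  set.seed(303)
  d2 <- data.frame(y = rnorm(60), group = sample(c("a", "b", "c"), 60, TRUE))
  gc2 <- group_comparison(d2, "y")
  expect_true(all(gc2$posthoc$p_bonferroni ==
                    pmin(1, gc2$posthoc$p_raw * 3)))
})

test_that("paired quadrant test handles identity, shift and noise", {
  x <- c(1.2, 1.3, 1.25, 1.4, 1.1)
  same <- paired_quadrant_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- paired_quadrant_test(x + 1, x)
  expect_equal(shift$mean_difference, 1)
  expect_lt(shift$p, 1e-6)
  set.seed(304)
  y <- x + 0.05 + rnorm(5, 0, 0.01)
  res <- paired_quadrant_test(y, x)
  expect_equal(res$p, t.test(y, x, paired = TRUE)$p.value)
  expect_error(paired_quadrant_test(1, numeric(0)),
               class = "perivasc_input_error")
})

test_that("univariate standardized beta equals the Pearson correlation", {
  set.seed(305)
  d <- data.frame(out = rnorm(40))
  d$x1 <- 0.5 * d$out + rnorm(40)
  d$x2 <- rnorm(40)
  d$sex <- sample(c("M", "F"), 40, TRUE)
  reg <- regression_suite(d, outcome = "out",
                          predictors = c("x1", "x2", "sex"))
  expect_equal(reg$univariate$standardized_beta[1], cor(d$out, d$x1),
               tolerance = 1e-10)
  expect_equal(reg$univariate$standardized_beta[2], cor(d$out, d$x2),
               tolerance = 1e-10)
  sx <- as.numeric(factor(d$sex)) - 1
  expect_equal(reg$univariate$standardized_beta[3], cor(d$out, sx),
               tolerance = 1e-10)
  # entry rule is exactly "univariate P < 0.2"
  expect_setequal(reg$entered,
                  reg$univariate$predictor[reg$univariate$p_value < 0.2])

  # outcome identical to predictor: beta exactly 1 (a perfect fit, so lm's
  # reliability warning is expected and harmless here)
  d$dup <- d$out
  reg2 <- suppressWarnings(
    regression_suite(d, outcome = "out", predictors = "dup"))
  expect_equal(reg2$univariate$standardized_beta, 1, tolerance = 1e-10)
})

test_that("null predictors have near-zero beta at large n", {
  set.seed(306)
  d <- data.frame(out = rnorm(2000), x = rnorm(2000))
  reg <- regression_suite(d, outcome = "out", predictors = "x")
  expect_lt(abs(reg$univariate$standardized_beta), 0.06)
})

test_that("collinear multivariate designs fail loudly, naming the offenders", {
  set.seed(307)
  d <- data.frame(out = rnorm(30))
  d$a <- 0.9 * d$out + rnorm(30, 0, 0.1)
  d$b <- d$a
  expect_error(regression_suite(d, outcome = "out", predictors = c("a", "b")),
               class = "perivasc_collinearity_error")
})

test_that("duration sub-analysis splits, compares and fits per stratum", {
  set.seed(308)
  n <- 60
  dur <- c(runif(35, 6, 35), runif(25, 37, 90))
  inj <- runif(n, 0, 4)
  refl <- 1.2 + ifelse(dur < 36, 0.04 * inj, 0) + rnorm(n, 0, 0.02)
  d <- data.frame(duration_months = dur, injections_per_year = inj,
                  corrected_reflectivity = refl)
  res <- duration_subanalysis(d)
  expect_equal(res$strata$n, c(35, 25))
  # link planted only in the early stratum
  expect_lt(res$regressions$p[1], 0.05)
  expect_gt(res$regressions$p[2], 0.05)
  expect_equal(res$regressions$standardized_beta[1],
               cor(inj[dur < 36], refl[dur < 36]), tolerance = 1e-10)

  expect_error(duration_subanalysis(d[d$duration_months < 36, ]),
               class = "perivasc_input_error")
  small <- d[c(1:20, which(dur >= 36)[1:2]), ]
  expect_warning(duration_subanalysis(small),
                 class = "perivasc_small_stratum_warning")
})

test_that("label-shuffled data reject at the nominal 5% rate", {
  set.seed(309)
  y <- rnorm(60)
  labels <- rep(c("a", "b", "c"), each = 20)
  hits <- 0L
  for (i in 1:1000) {
    d <- data.frame(y = y, group = sample(labels))
    if (group_comparison(d, "y")$anova$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 1000, 0.03)
  expect_lt(hits / 1000, 0.07)
})
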