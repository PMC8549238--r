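test_that("obesity classification applies the exact thresholds", {
  cov <- data.frame(
    subject_id = sprintf("s%d", 1:6),
    sex = c("man", "man", "woman", "woman", "man", "woman"),
    bmi = c(30.0, 29.99, 30.0, 25, 35, 28),
    waist = c(102.0, 102.1, 88.0, 88.1, 90, 100),
    whr = c(0.90, 0.91, 0.85, 0.86, 0.89, 0.80))
  o <- classify_obesity(cov)
  expect_equal(o$general, c(1, 0, 1, 0, 1, 0))       # BMI >= 30 inclusive
  expect_equal(o$central_wc, c(0, 1, 0, 1, 0, 1))    # strict > 102 / > 88
  expect_equal(o$central_whr, c(0, 1, 0, 1, 0, 0))   # strict > 0.90 / > 0.85
  bad <- cov; bad$sex[1] <- "unknown"
  expect_error(classify_obesity(bad), "sex")
})

test_that("crude tertile OR equals the 2x2 cross-product ratio", {
  # T3: 30 cases / 70 noncases, T1: 20 cases / 80 noncases
  outcome <- c(rep(1, 20), rep(0, 80), rep(1, 25), rep(0, 75),
               rep(1, 30), rep(0, 70))
  tert <- rep(c("T1", "T2", "T3"), each = 100)
  res <- fit_tertile_logistic(outcome, tert)
  or3 <- res$estimates$or[res$estimates$tertile == "T3"]
  expect_equal(or3, (30 * 80) / (70 * 20), tolerance = 1e-6)
  expect_equal(res$estimates$or[1], 1)       # reference
  expect_true(all(res$estimates$ci_low[-1] <= res$estimates$or[-1] &
                    res$estimates$or[-1] <= res$estimates$ci_high[-1]))
  # widening alpha narrows the CI monotonically
  res90 <- fit_tertile_logistic(outcome, tert, alpha = 0.10)
  expect_gt(res90$estimates$ci_low[3], res$estimates$ci_low[3])
  expect_lt(res90$estimates$ci_high[3], res$estimates$ci_high[3])
})

test_that("null crude ORs are near 1 at large n", {
  set.seed(15)
  n <- 100000
  tert <- rep(c("T1", "T2", "T3"), length.out = n)
  outcome <- rbinom(n, 1, 0.3)
  res <- fit_tertile_logistic(outcome, tert)
  expect_true(all(res$estimates$or[-1] > 0.95 & res$estimates$or[-1] < 1.05))
})

test_that("trend test is monotone-sensitive, deterministic, and guarded", {
  set.seed(23)
  n <- 10000
  tert <- rep(c("T1", "T2", "T3"), length.out = n)
  idx <- as.numeric(factor(tert))
  p_dbl <- 1 / (1 + exp(-(log(0.2) + log(2) * (idx - 1))))
  y <- rbinom(n, 1, p_dbl)
  p1 <- p_for_trend(y, tert)
  expect_lt(p1, 0.001)
  expect_identical(p1, p_for_trend(y, tert))
  expect_error(fit_tertile_logistic(rep(1, 9), rep(c("T1","T2","T3"), 3)),
               "both classes")
  expect_error(fit_tertile_logistic(rep(0:1, 5)[1:9], rep(c("T1","T2"), 5)[1:9]),
               "nonempty")
})

test_that("separation and exposure collinearity raise informative errors", {
  # perfectly separated outcome
  tert <- rep(c("T1", "T2", "T3"), each = 30)
  y <- as.integer(tert == "T3")
  expect_error(fit_tertile_logistic(y, tert), "separation")
})

test_that("aliased covariates are dropped, exposure estimates unchanged", {
  set.seed(31)
  n <- 600
  cov <- simulate_covariates(n, seed = 31)
  tert <- assign_tertiles(rnorm(n))
  y <- rbinom(n, 1, 0.3)
  # menopause 'not_applicable' duplicates sex == 'man': aliased, dropped
  expect_message(
    res <- fit_tertile_logistic(y, tert, cov, adjusted = TRUE),
    "aliased")
  expect_true(all(is.finite(res$estimates$or)))
})

test_that("tertile descriptives match hand-computed ANOVA and chi-square", {
  tert <- rep(c("T1", "T2", "T3"), each = 4)
  cov <- data.frame(
    age = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4),     # identical sets
    grp = c("x", "x", "y", "y", "x", "x", "y", "y", "x", "x", "y", "y"),
    mono = rep("only", 12),
    val = c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16))
  d <- tertile_descriptives(cov, tert)
  # identical value sets: F = 0, p = 1
  expect_equal(d$p_value[d$variable == "age"], 1, tolerance = 1e-12)
  # exact independence: chi-square p = 1
  expect_equal(unique(d$p_value[d$variable == "grp"]), 1, tolerance = 1e-12)
  # single-level categorical flagged, test skipped
  expect_equal(d$flag[d$variable == "mono"], "single_level")
  expect_true(is.na(d$p_value[d$variable == "mono"]))
  # 2x3 chi-square against the direct formula
  set.seed(40)
  g2 <- sample(c("u", "v"), 12, replace = TRUE)
  cov2 <- data.frame(g2 = g2)
  d2 <- tertile_descriptives(cov2, tert)
  tab <- table(g2, tert)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi <- sum((tab - expected)^2 / expected)
  p_hand <- pchisq(chi, df = (nrow(tab) - 1) * (ncol(tab) - 1),
                   lower.tail = FALSE)
  expect_equal(unique(d2$p_value), p_hand, tolerance = 1e-10)
})

test_that("sample-size formula reproduces the design calculations", {
  expect_equal(compute_sample_size(0.65, 0.04, 0.05), 546)
  expect_equal(compute_sample_size(0.5, 0.05, 0.05), 384)
  expect_equal(compute_sample_size(0, 0.04, 0.05), 0)
  # design effect multiplies before rounding
  expect_equal(compute_sample_size(0.65, 0.04, 0.05, design_effect = 1.5),
               round(0.65 * 0.35 * qnorm(0.975)^2 / 0.04^2 * 1.5))
  expect_error(compute_sample_size(0.5, 0), "positive")
  expect_error(compute_sample_size(1.5, 0.04), "p must be")
})

test_that("planted odds ratios are recovered by the adjusted model", {
  set.seed(55)
  n <- 20000
  cov <- simulate_covariates(n, seed = 55)
  scores <- data.frame(subject_id = cov$subject_id, net_score = rnorm(n))
  scores$net_tertile <- assign_tertiles(scores$net_score)
  om <- list(y = list(intercept = -1,
                      effects = list(net = c(T2 = log(1.2), T3 = log(2.0)))))
  y <- simulate_outcomes(scores, om, seed = 56)
  res <- suppressMessages(
    fit_tertile_logistic(y$y, scores$net_tertile, cov, adjusted = TRUE))
  or3 <- res$estimates$or[res$estimates$tertile == "T3"]
  expect_gt(or3, 2.0 * 0.9); expect_lt(or3, 2.0 * 1.1)
})
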