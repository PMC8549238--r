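test_that("sample correlation matches the Pearson formula", {
  set.seed(1)
  z <- data.frame(subject_id = 1:30,
                  a = rnorm(30), b = rnorm(30), c = rnorm(30))
  zs <- standardize_intakes(z)
  S <- sample_correlation(zs)
  # textbook formula, computed long-hand
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(S["a", "b"], pearson(z$a, z$b), tolerance = 1e-12)
  expect_equal(S["a", "c"], pearson(z$a, z$c), tolerance = 1e-12)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  # perfect and antithetic columns
  z2 <- data.frame(subject_id = 1:10, x = 1:10, same = 1:10, anti = 10:1)
  S2 <- sample_correlation(standardize_intakes(z2))
  expect_equal(S2["x", "same"], 1)
  expect_equal(S2["x", "anti"], -1)
})

test_that("unpenalized graphical lasso inverts the correlation matrix", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fit <- graphical_lasso(S, 0)
  expect_equal(fit$omega, matrix(c(4, -2, -2, 4) / 3, 2), tolerance = 1e-6)
  # Omega S = I within 1e-5 on random well-conditioned matrices
  for (seed in 1:5) {
    S5 <- random_correlation(5, seed)
    f <- graphical_lasso(S5, 0)
    expect_lt(max(abs(f$omega %*% S5 - diag(5))), 1e-5)
  }
})

test_that("full-shrinkage penalty yields an exactly diagonal precision", {
  S <- random_correlation(6, 99)
  lam <- max(abs(S[upper.tri(S)]))
  fit <- graphical_lasso(S, lam)
  om <- fit$omega
  expect_true(all(om[upper.tri(om)] == 0))
  expect_equal(diag(om), 1 / diag(S), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("penalized fit agrees with the frozen convex-optimizer oracle", {
  # 4x4 fixture at lambda = 0.1; oracle precision computed once with an
  # independent penalized-likelihood solver on the identical objective
  S <- matrix(c(1, .5, .2, 0,
                .5, 1, .3, .1,
                .2, .3, 1, .4,
                0, .1, .4, 1), 4)
  oracle <- matrix(c(
    1.1910678653, -0.4714643001, -0.0248178085, 0,
    -0.4714643001, 1.2282879327, -0.1985096336, 0,
    -0.0248178085, -0.1985096336, 1.14108491, -0.3296703659,
    0, 0, -0.3296703659, 1.0989011188), 4)
  fit <- graphical_lasso(S, 0.1, tol = 1e-8)
  expect_lt(max(abs(fit$omega - oracle)), 1e-4)
})

test_that("graphical lasso validates inputs and flags singular problems", {
  expect_error(graphical_lasso(matrix(c(1, 2, 3, 1), 2), 0.1), "symmetric")
  expect_error(graphical_lasso(diag(2), -0.1), "lambda")
  Ssing <- matrix(1, 3, 3)  # rank 1
  expect_error(graphical_lasso(Ssing, 0), "positive penalty")
})

test_that("support-constrained refit zeroes the masked entries only", {
  S <- random_correlation(5, 7)
  mask <- matrix(TRUE, 5, 5); mask[1, 5] <- mask[5, 1] <- FALSE
  fit <- graphical_lasso(S, 0, zero_mask = mask)
  expect_equal(fit$omega[1, 5], 0)
  # constrained MLE matches S on the free entries (standard stationarity)
  w <- solve(fit$omega)
  free <- mask & upper.tri(mask)
  expect_lt(max(abs(w[free] - S[free])), 1e-5)
})

test_that("precision-to-partial uses the closed form and flags edges", {
  om <- matrix(c(2, -1, -1, 2), 2)
  net <- precision_to_partial(om)
  expect_equal(net$rho[1, 2], 0.5)
  # diagonal precision: empty edge list
  net0 <- precision_to_partial(diag(3))
  expect_equal(nrow(net0$edges), 0)
  expect_true(all(net0$rho[upper.tri(net0$rho)] == 0))
  # covariance-inversion oracle on a 3x3 fixture
  om3 <- matrix(c(2, -0.6, 0.3,
                  -0.6, 1.5, -0.4,
                  0.3, -0.4, 1.8), 3)
  net3 <- precision_to_partial(om3)
  sig <- solve(om3)
  for (i in 1:2) for (j in (i + 1):3) {
    others <- setdiff(1:3, c(i, j))
    # partial correlation the long way: correlate residuals after
    # regressing out the remaining variable (population formula)
    s <- sig
    r_ij <- (s[i, j] - s[i, others] * s[others, j] / s[others, others]) /
      sqrt((s[i, i] - s[i, others]^2 / s[others, others]) *
             (s[j, j] - s[others, j]^2 / s[others, others]))
    expect_equal(net3$rho[i, j], r_ij, tolerance = 1e-10)
  }
  # strong flag threshold
  expect_equal(net3$edges$strong, abs(net3$edges$partial_correlation) >= 0.2)
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)), "positive")
})

test_that("round trip: planted precision -> partials recovers planted values", {
  st <- planted_structure(8, list(c(1, 2, 3)), 0.2)
  pp <- build_planted_precision(st)
  net <- precision_to_partial(pp)
  expect_equal(net$rho[1, 2], pp$achieved_partial[1, 2], tolerance = 1e-9)
  expect_equal(net$rho[2, 3], pp$achieved_partial[2, 3], tolerance = 1e-9)
})

test_that("EBIC penalty selection behaves on degenerate and null inputs", {
  st <- planted_structure(10, list(), numeric(0))
  pp <- build_planted_precision(st)
  tab <- simulate_intake_table(pp, 2000, "identity", seed = 31)
  std <- standardize_intakes(tab)
  # single-element grid is returned as-is
  sel1 <- select_penalty(std, lambda_grid = 0.2)
  expect_equal(sel1$lambda, 0.2)
  # independence data: few false edges
  false_edges <- vapply(1:20, function(s) {
    tt <- simulate_intake_table(pp, 2000, "identity", seed = 100 + s)
    sel <- select_penalty(standardize_intakes(tt))
    om <- sel$refit$omega
    sum(abs(om[upper.tri(om)]) > 1e-10)
  }, numeric(1))
  expect_gte(sum(false_edges <= 2), 18)
})

test_that("edge count is non-increasing with the penalty (monitored)", {
  st <- planted_structure(12, list(1:4, 5:8), c(0.2, 0.15))
  pp <- build_planted_precision(st)
  std <- standardize_intakes(simulate_intake_table(pp, 400, "identity",
                                                   seed = 17))
  S <- sample_correlation(std)
  grid <- exp(seq(log(0.5), log(0.02), length.out = 8))
  ks <- vapply(grid, function(l) {
    om <- graphical_lasso(S, l)$omega
    sum(abs(om[upper.tri(om)]) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))  # descending lambda => growing support
})
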