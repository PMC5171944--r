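# independent oracle: MA slope from the leading eigenvector of the
# covariance matrix
eigen_ma_slope <- function(x, y) {
  v <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE)$vectors[, 1]
  v[2] / v[1]
}

test_that("major-axis regression recovers a perfect line", {
  x <- c(1, 2, 3, 4, 5)
  fit <- ma_regression(x, 2 * x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(diff(fit$slope_ci95), 0)
})

test_that("major-axis slope equals the eigenvector oracle", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 0, runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, 0, runif(1, 0.2, 2))
    if (abs(cov(x, y)) < 1e-8) next
    fit <- ma_regression(x, y)
    expect_equal(fit$slope, eigen_ma_slope(x, y), tolerance = 1e-10)
  }
})

test_that("major-axis slope is reciprocal under axis swap and bracketed
           by the two OLS slopes", {
  set.seed(21)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, 0, 0.5)
  f1 <- ma_regression(x, y); f2 <- ma_regression(y, x)
  expect_equal(f1$slope * f2$slope, 1, tolerance = 1e-10)
  b_ols <- cov(x, y) / var(x)
  b_rev <- cov(x, y) / var(y)   # reciprocal OLS slope of x on y
  expect_gt(f1$slope, min(b_ols, 1 / b_rev))
  expect_lt(f1$slope, max(b_ols, 1 / b_rev))
})

test_that("major axis is invariant to translation and common scaling", {
  set.seed(5)
  x <- rnorm(20); y <- 1.4 * x + rnorm(20, 0, 0.6)
  f <- ma_regression(x, y)
  f_shift <- ma_regression(x + 100, y - 50)
  expect_equal(f_shift$slope, f$slope, tolerance = 1e-12)
  f_scale <- ma_regression(3 * x, 3 * y)
  expect_equal(f_scale$slope, f$slope, tolerance = 1e-12)
  expect_equal(f_scale$slope_ci95, f$slope_ci95, tolerance = 1e-12)
})

test_that("major-axis confidence interval covers the true slope ~95%", {
  set.seed(99)
  slope_true <- 1
  th <- atan(slope_true)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sig <- R %*% diag(c(4, 0.5)) %*% t(R)
  cB <- chol(Sig)
  hits <- 0; reps <- 500
  for (r in seq_len(reps)) {
    Z <- matrix(rnorm(60), 30, 2) %*% cB
    ci <- ma_regression(Z[, 1], Z[, 2])$slope_ci95
    hits <- hits + (ci[1] <= slope_true && slope_true <= ci[2])
  }
  expect_gt(hits / reps, 0.90)
  expect_lt(hits / reps, 0.985)
})

test_that("degenerate scatters are refused with clear errors", {
  expect_error(ma_regression(1:2, 2:3), "at least 3")
  set.seed(1)
  x <- rnorm(10)
  # constant x: the axis is vertical and no finite slope exists
  expect_error(ma_regression(x * 0 + 5, x), "vertical|undefined|degenerate",
               ignore.case = TRUE)
  # constant y: the axis is horizontal, slope 0
  expect_equal(ma_regression(x, x * 0 + 5)$slope, 0)
})

test_that("paired comparison gates between t and signed-rank", {
  a <- c(1, 2, 3, 4, 5)
  same <- paired_compare(a, a)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$test_used, "degenerate")

  set.seed(42)
  b <- rnorm(30)
  shifted <- paired_compare(b + 1, b - rnorm(30))  # ~1 sd shift
  expect_identical(shifted$test_used, "paired_t")
  expect_lt(shifted$p_value, 0.05)

  # strongly skewed differences fail the normality gate
  set.seed(8)
  d <- rexp(40)^2
  skewed <- paired_compare(d, rep(0, 40))
  expect_identical(skewed$test_used, "wilcoxon_signed_rank")
})

test_that("paired comparison holds its nominal type-I error", {
  set.seed(2024)
  reps <- 2000
  rej <- 0
  for (r in seq_len(reps)) {
    d <- rnorm(20)
    rej <- rej + (paired_compare(d, rep(0, 20))$p_value < 0.05)
  }
  expect_gt(rej / reps, 0.035)
  expect_lt(rej / reps, 0.065)
})

test_that("group comparison separates distinct groups, not identical ones", {
  g <- c(1, 2, 3, 4)
  same <- group_compare(g, g)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  set.seed(31)
  res <- group_compare(rnorm(10), rnorm(10, 3))
  expect_lt(res$p_value, 0.01)
  expect_identical(res$test_used, "welch_t")
  # constant group triggers the exact permutation fallback
  perm <- group_compare(c(5, 5), c(1, 2, 9))
  expect_identical(perm$test_used, "permutation")
  expect_true(perm$p_value > 0 && perm$p_value <= 1)
})

test_that("weighted screen equals the normal-equations oracle", {
  set.seed(13)
  n <- 24
  x <- rnorm(n); y <- 0.7 * x + rnorm(n, 0, 0.8)
  w <- runif(n, 0.5, 4)
  fit <- weighted_screen(y, x, w)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  expect_equal(unname(fit$coefficients), as.vector(beta),
               tolerance = 1e-10)
  # unit weights reduce to ordinary least squares
  fit1 <- weighted_screen(y, x, rep(1, n))
  beta1 <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit1$coefficients), as.vector(beta1),
               tolerance = 1e-10)
})

test_that("weighted screen handles exact fits, factors and bad inputs", {
  x <- 1:10
  fit <- weighted_screen(2 + 3 * x, x, runif(10, 0.5, 2))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)

  set.seed(77)
  g <- rep(c("u", "v", "w"), each = 8)
  y <- rnorm(24) + (g == "w") * 3
  ffit <- weighted_screen(y, g, rep(1, 24))
  expect_true(is.na(ffit$slope))   # no single slope for 3 levels
  expect_lt(ffit$p_value, 0.01)

  expect_error(weighted_screen(y, rep("u", 24), rep(1, 24)), "constant")
  expect_error(weighted_screen(y, g, rep(-1, 24)), "weights")
})

test_that("heteroskedasticity switches inference to White (HC0)", {
  set.seed(12)
  n <- 120
  x <- runif(n, 0, 10)
  y <- 1 + 0.5 * x + rnorm(n, 0, 0.2 + 1.2 * x)  # variance grows with x
  fit <- weighted_screen(y, x, rep(1, n))
  expect_true(fit$heteroskedastic)
  expect_identical(fit$inference_method, "white_robust")
  expect_equal(fit$r_squared, cor(y, fitted(lm(y ~ x)))^2,
               tolerance = 1e-9)

  set.seed(12)
  y2 <- 1 + 0.5 * x + rnorm(n, 0, 1)
  fit2 <- weighted_screen(y2, x, rep(1, n))
  expect_false(fit2$heteroskedastic)
  expect_identical(fit2$inference_method, "standard")
})

test_that("two-way ANOVA matches hand-computed balanced sums of squares", {
  # balanced 2x2 with r = 4: type II equals the textbook decomposition
  set.seed(9)
  A <- rep(rep(c("a1", "a2"), each = 4), 2)
  B <- rep(c("b1", "b2"), each = 8)
  y <- 5 + (A == "a2") * 2 + (B == "b2") * -1 +
    (A == "a2" & B == "b2") * 0.5 + rnorm(16, 0, 0.7)

  cm <- mean(y)
  ssa <- 8 * sum((tapply(y, A, mean) - cm)^2)
  ssb <- 8 * sum((tapply(y, B, mean) - cm)^2)
  cell <- tapply(y, interaction(A, B), mean)
  sscells <- 4 * sum((cell - cm)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((y - ave(y, A, B))^2)
  f <- c(ssa, ssb, ssab) / (sse / 12)
  p_hand <- pf(f, 1, 12, lower.tail = FALSE)

  got <- two_way_anova(y, A, B)
  expect_equal(c(got$p_a, got$p_b, got$p_interaction), p_hand,
               tolerance = 1e-9)
})

test_that("two-way ANOVA isolates the active factor and flags degeneracy", {
  A <- rep(c("x", "y"), each = 6)
  B <- rep(c("p", "q"), 6)
  set.seed(4)
  y <- (A == "y") * 10 + rnorm(12, 0, 0.1)
  got <- two_way_anova(y, A, B)
  expect_lt(got$p_a, 1e-6)
  expect_gt(got$p_b, 0.05)
  expect_gt(got$p_interaction, 0.05)

  flat <- two_way_anova(rep(3, 12), A, B)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$p_a))
})

test_that("leave-one-out sensitivity finds a planted influential point", {
  set.seed(6)
  n <- 15
  x <- c(rnorm(n - 1), 10)               # one high-leverage point
  y <- c(rnorm(n - 1), 12)               # creating spurious significance
  full <- weighted_screen(y, x)
  sens <- outlier_sensitivity(y, x)
  expect_lt(full$p_value, 0.10)
  expect_gt(sens$p_loo[n], 0.10)
  expect_true(sens$crosses_10[n])

  # stable design: no point moves p across thresholds
  set.seed(16)
  x2 <- rnorm(30); y2 <- 2 * x2 + rnorm(30, 0, 0.3)
  sens2 <- outlier_sensitivity(y2, x2)
  expect_false(any(sens2$crosses_05))
})

test_that("significance marks follow the reporting tiers", {
  expect_identical(signif_marks(c(0.005, 0.03, 0.08, 0.5, NA)),
                   c("**", "*", "+", "", ""))
})
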