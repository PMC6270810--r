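test_that("single-descriptor PLS equals univariate least squares", {
  set.seed(51)
  x <- rnorm(20); y <- 2.5 * x + rnorm(20, sd = 0.3)
  m <- fit_pls(matrix(x, ncol = 1), y, 1)
  ols <- coef(lm(y ~ x))
  expect_equal(m$coefficients, unname(ols[2]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(predict(m, matrix(x, ncol = 1)), unname(fitted(lm(y ~ x))),
               tolerance = 1e-10)
})

test_that("full-rank PLS predictions equal ordinary least squares", {
  set.seed(52)
  for (rep in 1:50) {
    n <- sample(8:16, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    m <- fit_pls(X, y, p)
    ols_fit <- lm.fit(cbind(1, X), y)$fitted.values
    rel <- max(abs(predict(m, X) - ols_fit)) /
      max(abs(ols_fit - mean(y)), 1e-8)
    expect_lt(rel, 1e-6)
  }
})

test_that("duplicating the descriptor column leaves predictions unchanged", {
  set.seed(53)
  x <- rnorm(15)
  y <- 1.3 * x + rnorm(15, sd = 0.1)
  m1 <- fit_pls(matrix(x, ncol = 1), y, 1)
  m2 <- fit_pls(cbind(x, x), y, 1)
  expect_equal(predict(m2, cbind(x, x)), predict(m1, matrix(x, ncol = 1)),
               tolerance = 1e-8)
  # the shared signal splits evenly across the two identical columns
  expect_equal(m2$coefficients[1], m2$coefficients[2], tolerance = 1e-10)
  expect_equal(sum(m2$coefficients), m1$coefficients, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("latent-path and coefficient-path predictions coincide", {
  set.seed(54)
  X <- matrix(rnorm(18 * 10), 18)
  y <- rnorm(18)
  m <- fit_pls(X, y, 4)
  # rebuild predictions through scores: T C + y_mean
  Xc <- sweep(X, 2, m$x_mean)
  t_pred <- m$y_mean + drop(m$scores %*% m$C)
  expect_equal(predict(m, X), t_pred, tolerance = 1e-8)
})

test_that("rank and sample-size limits raise informative errors", {
  X <- matrix(rnorm(10 * 2), 10)
  expect_error(fit_pls(X, rep(1, 10), 1), "zero variance")
  expect_error(fit_pls(X, rnorm(10), 5), "supports only")
  expect_error(fit_pls(X, rnorm(10), 9), "n_components \\+ 2")
  expect_error(loo_cv(X, rnorm(10), 9), "N - 1")
})

test_that("leave-one-out CV equals the brute-force refit oracle", {
  set.seed(55)
  X <- matrix(rnorm(12 * 20), 12)
  y <- rnorm(12)
  cv <- loo_cv(X, y, 3)
  pred <- vapply(1:12, function(i)
    predict(fit_pls(X[-i, , drop = FALSE], y[-i], 3),
            X[i, , drop = FALSE]), numeric(1))
  press_oracle <- sum((y - pred)^2)
  expect_equal(cv$press_cv, press_oracle, tolerance = 1e-8)
  expect_equal(cv$q2, 1 - press_oracle / sum((y - mean(y))^2),
               tolerance = 1e-8)
  expect_equal(cv$sep, sqrt(press_oracle / (12 - 3 - 1)), tolerance = 1e-8)
})

test_that("a noiseless linear response cross-validates almost perfectly", {
  set.seed(56)
  X <- matrix(rnorm(40 * 6), 40)
  y <- drop(X %*% rnorm(6))
  cv <- loo_cv(X, y, 6)
  expect_gte(cv$q2, 0.999)
})

test_that("permuted activities destroy cross-validated performance", {
  set.seed(57)
  n <- 50
  X <- matrix(rnorm(n * 10), n)
  y <- drop(X %*% rnorm(10)) + rnorm(n, sd = 0.5)
  low <- 0L
  for (t in 1:100) {
    q2 <- loo_cv(X, sample(y), 2)$q2
    if (q2 <= 0.3) low <- low + 1L
  }
  expect_gte(low, 95L)
})

test_that("the component scan applies selection rules, incl. the published one", {
  # the published CB1 cross-validation scan: q2 peaks at N = 2
  published <- data.frame(
    N = 1:15,
    sep = c(0.268, 0.263, 0.273, 0.277, 0.284, 0.297, 0.305, 0.311, 0.318,
            0.322, 0.329, 0.335, 0.341, 0.348, 0.355),
    q2 = c(0.704, 0.722, 0.709, 0.709, 0.703, 0.685, 0.677, 0.674, 0.671,
           0.673, 0.672, 0.673, 0.672, 0.672, 0.672))
  expect_identical(select_components(published, rule = "max_q2"), 2L)
  # plateau rule on a monotone curve returns the plateau start
  plateau <- data.frame(N = 1:6, q2 = c(0.2, 0.5, 0.69, 0.695, 0.7, 0.7))
  expect_identical(select_components(plateau, rule = "first_plateau",
                                     tol = 0.02), 3L)
  # explicit override wins regardless of the scan
  expect_identical(select_components(published, rule = "fixed", n_fixed = 10),
                   10L)
  expect_error(select_components(published, rule = "fixed"), "n_fixed")
})

test_that("scan_components agrees with loo_cv at each component count", {
  set.seed(58)
  X <- matrix(rnorm(16 * 8), 16)
  y <- drop(X %*% rnorm(8)) + rnorm(16, sd = 0.4)
  scan <- scan_components(X, y, n_max = 4)
  for (N in 1:4) {
    cv <- loo_cv(X, y, N)
    expect_equal(scan$q2[scan$N == N], cv$q2, tolerance = 1e-10)
    expect_equal(scan$sep[scan$N == N], cv$sep, tolerance = 1e-10)
  }
})

test_that("final statistics match their defining formulas", {
  set.seed(59)
  X <- matrix(rnorm(15 * 8), 15)
  y <- drop(X %*% rnorm(8)) + rnorm(15, sd = 0.3)
  N <- 3
  m <- fit_pls(X, y, N)
  fs <- final_stats(m, X, y)
  pred <- predict(m, X)
  rss <- sum((y - pred)^2); tss <- sum((y - mean(y))^2)
  expect_equal(fs$r2, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(fs$see, sqrt(rss / (15 - N - 1)), tolerance = 1e-12)
  expect_equal(fs$f_stat, (fs$r2 / N) / ((1 - fs$r2) / (15 - N - 1)),
               tolerance = 1e-12)
  # a perfect linear response fits perfectly at full rank
  y_exact <- drop(X %*% rnorm(8))
  m_ex <- fit_pls(X, y_exact, 8)
  fs_ex <- final_stats(m_ex, X, y_exact)
  expect_equal(fs_ex$r2, 1, tolerance = 1e-8)
  expect_lt(fs_ex$see, 1e-4)
})

test_that("field contributions are |coefficient| x stdev block sums", {
  set.seed(60)
  X <- matrix(rnorm(20 * 6), 20)
  colnames(X) <- paste0(rep(c("s", "e"), each = 3), 1:3)
  attr(X, "block") <- rep(c("steric", "electrostatic"), each = 3)
  attr(X, "point") <- rep(1:3, 2)
  y <- drop(X %*% rnorm(6)) + rnorm(20, sd = 0.2)
  m <- fit_pls(X, y, 3)
  contrib <- field_contributions(m)
  expect_equal(sum(contrib), 100, tolerance = 1e-9)
  raw <- abs(m$coefficients) * apply(X, 2, sd)
  expect_equal(unname(contrib[["steric"]]),
               100 * sum(raw[1:3]) / sum(raw), tolerance = 1e-9)
  # duplicated blocks split contributions evenly
  X2 <- cbind(X[, 1:3], X[, 1:3])
  attr(X2, "block") <- rep(c("steric", "electrostatic"), each = 3)
  attr(X2, "point") <- rep(1:3, 2)
  m2 <- fit_pls(X2, y, 2)
  c2 <- field_contributions(m2)
  expect_equal(unname(c2[["steric"]]), 50, tolerance = 1e-6)
  # a model fitted without block labels refuses
  m3 <- fit_pls(matrix(rnorm(20 * 2), 20), y, 1)
  expect_error(field_contributions(m3), "block-labelled")
})
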