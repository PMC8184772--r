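test_that("the objective evaluator matches hand arithmetic", {
  X <- matrix(c(1, -1), 2, 1)
  Y <- c(1, -1)
  expect_equal(en_objective(X, Y, 0, 0, 0), sum(Y^2))
  expect_equal(en_objective(X, Y, 1, 0, 0), 0)
  expect_equal(en_objective(X, Y, 1, 2, 3), 0 + 2 * 1 + 3 * 1)
  # literal (unsquared) ridge evaluation for reporting
  expect_equal(en_objective(X, Y, 2, 0, 3, ridge = "literal"),
               sum((Y - 2 * X)^2) + 3 * 2)
  expect_error(en_objective(X, c(1, 2, 3), 1, 0, 0), "shapes")
})

test_that("full shrinkage and OLS limits hold", {
  set.seed(81)
  X <- matrix(rnorm(40), 10, 4)
  Y <- rnorm(10)
  lmax <- lambda1_max(X, Y)
  expect_equal(fit_en(X, Y, lmax * 1.0001, 0)$n_nonzero, 0)
  expect_gt(fit_en(X, Y, lmax * 0.9, 0)$n_nonzero, 0)

  # single standardized predictor, no penalty -> OLS slope
  x <- rnorm(10)
  y <- 2 * x + rnorm(10, sd = 0.1)
  f <- fit_en(matrix(x, 10, 1), y, 0, 0)
  xs <- (x - mean(x)) / sd(x)
  expect_equal(f$beta[1], sum(xs * (y - mean(y))) / sum(xs^2),
               tolerance = 1e-7)
  expect_true(f$converged)
  expect_lt(f$kkt_max, 1e-6)
})

test_that("coordinate descent attains brute-force grid minima on p = 2", {
  set.seed(82)
  for (rep in 1:4) {
    X <- matrix(rnorm(16), 8, 2)
    Y <- rnorm(8)
    l1 <- runif(1, 0.1, 2); l2 <- runif(1, 0.1, 2)
    f <- fit_en(X, Y, l1, l2)
    # oracle: exhaustive grid over standardized-scale coefficients
    Xs <- scale(X)
    Yc <- Y - mean(Y)
    g <- seq(-3, 3, by = 0.005)
    grid <- as.matrix(expand.grid(b1 = g, b2 = g))
    obj <- colSums((Yc - tcrossprod(Xs, grid))^2) +
      l1 * rowSums(abs(grid)) + l2 * rowSums(grid^2)
    expect_lte(f$objective, min(obj) + 1e-6)
  }
})

test_that("the objective never increases across solver sweeps", {
  # re-run with successively larger sweep caps; objective non-increasing
  set.seed(83)
  X <- matrix(rnorm(12 * 30), 12)
  Y <- rep(c(-1, 1), 6)
  objs <- vapply(c(1, 2, 5, 20, 200), function(ms) {
    suppressWarnings(fit_en(X, Y, 0.5, 0.5, max_sweeps = ms))$objective
  }, 0)
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("solutions agree with an independent elastic-net implementation", {
  skip_if_not_installed("glmnet")
  set.seed(84)
  n <- 20; p <- 6
  X <- matrix(rnorm(n * p), n)
  # pre-standardize (mean 0, unit n-1 variance) so both solvers penalize
  # the same coefficients; glmnet then runs without its own scaling
  X <- scale(X)
  Y <- drop(X[, 1:2] %*% c(2, -1)) + rnorm(n, sd = 0.5)
  alpha <- 0.5; lam <- 0.3
  # map glmnet's objective onto |Y-Xb|^2 + l1|b|_1 + l2|b|_2^2; glmnet
  # standardizes the response internally, which leaves its L1 term at
  # 2*n*lam*alpha but shrinks its ridge term by 1/sd_n(y)
  sdy <- sqrt(mean((Y - mean(Y))^2))
  l1 <- 2 * n * lam * alpha
  l2 <- n * lam * (1 - alpha) / sdy
  f <- fit_en(X, Y, l1, l2)
  g <- glmnet::glmnet(X, Y, alpha = alpha, lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  bg <- as.numeric(g$beta)
  expect_equal(f$beta_raw, bg, tolerance = 1e-4)
})

test_that("lambda selection brackets the CV optimum", {
  set.seed(85)
  n_d <- 6
  donors <- rep(sprintf("D%d", 1:n_d), each = 2)
  Y <- rep(c(-1, 1), n_d)
  X <- matrix(rnorm(2 * n_d * 40, sd = 0.3), 2 * n_d)
  X[, 1:5] <- X[, 1:5] + outer(Y, rep(1, 5))   # separable signal
  cv <- cv_lambda_path(X, Y, donors, n_lambda = 25, decades = 2)
  expect_gte(cv$lambda_1se, cv$lambda_min)
  expect_lte(cv$cv_mean[cv$i_1se],
             cv$cv_mean[cv$i_min] + cv$cv_sd[cv$i_min] + 1e-12)
  expect_equal(cv$cv_mean[cv$i_min], 0)   # perfectly separable
  # degenerate-input contracts
  expect_error(cv_lambda_path(X, rep(2, 2 * n_d), donors), "coded")
  expect_error(cv_lambda_path(X, rep(1, 2 * n_d), donors),
               "lacks one of the two gravity conditions")
  expect_error(cv_lambda_path(X[1:4, ], Y[1:4], donors[1:4]), "3 donors")
})

test_that("label shuffling within donors drives CV error to chance", {
  set.seed(86)
  n_d <- 6
  donors <- rep(sprintf("D%d", 1:n_d), each = 2)
  X <- matrix(rnorm(2 * n_d * 30), 2 * n_d)
  errs <- replicate(15, {
    Y <- unlist(lapply(seq_len(n_d), function(i) sample(c(-1, 1))))
    cv <- cv_lambda_path(X, Y, donors, n_lambda = 12, decades = 2)
    # error at a pre-chosen mid-grid penalty: the min over the path is
    # optimistically biased by selection and is not the null level
    cv$cv_mean[6]
  })
  expect_gt(mean(errs), 0.35)
  expect_lt(mean(errs), 0.65)
})

test_that("model significance feeds paired scores into the exact test", {
  set.seed(87)
  n_d <- 8
  donors <- rep(sprintf("D%d", 1:n_d), each = 2)
  Y <- rep(c(-1, 1), n_d)
  X <- matrix(rnorm(2 * n_d * 20, sd = 0.2), 2 * n_d)
  X[, 1:4] <- X[, 1:4] + outer(Y, rep(1.5, 4))
  cv <- cv_lambda_path(X, Y, donors, n_lambda = 20, decades = 2)
  ms <- model_significance(cv)
  expect_equal(nrow(ms$scores), n_d)
  # all 8 donors separate -> exact enumeration floor 2/256
  expect_equal(ms$test$p_two_sided, 0.0078125)
  expect_true(all(ms$scores$diff > 0))
})

test_that("component report ranks and orients model features", {
  set.seed(88)
  X <- matrix(rnorm(16 * 5), 16)
  colnames(X) <- paste("S", c("a", "b", "c", "d", "e"), "response",
                       sep = "|")
  Y <- rep(c(-1, 1), 8)
  X[, 1] <- X[, 1] + Y; X[, 2] <- X[, 2] - Y
  f <- fit_en(X, Y, 0.5, 0.5)
  rep_ <- component_report(f)
  expect_true(all(rep_$abs_beta > 0))
  expect_equal(rep_$direction[rep_$feature == colnames(X)[1]],
               "increased-in-uG")
  expect_equal(rep_$direction[rep_$feature == colnames(X)[2]],
               "decreased-in-uG")
  # an all-zero model gives an empty table
  f0 <- fit_en(X, Y, lambda1_max(X, Y) * 1.01, 0)
  expect_equal(nrow(component_report(f0)), 0)
})
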