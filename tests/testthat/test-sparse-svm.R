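test_that("elastic-net penalty evaluates the textbook cases", {
  expect_identical(elastic_net_penalty(c(0, 0, 0), 0.3), 0)
  expect_identical(elastic_net_penalty(c(1, -1), 1), 2)
  expect_identical(elastic_net_penalty(c(1, -1), 0), 1)
  expect_equal(elastic_net_penalty(c(2, -3), 0.4),
               0.5 * 0.6 * 13 + 0.4 * 5)
  expect_error(elastic_net_penalty(c(1, 2), 1.5), "alpha")
})

test_that("lambda >= lambda_max shrinks every coefficient to exactly zero", {
  d <- toy_shift_data(n = 60, p = 8, shift = 3, seed = 4)
  lmax <- svm_lambda_max(d$X, d$y, alpha = 1)
  for (lam in c(lmax, 2 * lmax)) {
    fit <- svm_enet(d$X, d$y, lambda = lam, alpha = 1)
    expect_identical(fit$support_count, 0L)
    expect_true(all(fit$beta == 0))
  }
  # just below lambda_max something enters
  fit <- svm_enet(d$X, d$y, lambda = 0.8 * lmax, alpha = 1)
  expect_gt(fit$support_count, 0L)
})

test_that("support is non-increasing in lambda at alpha = 1", {
  d <- toy_shift_data(n = 80, p = 15, shift = 2, seed = 9)
  lmax <- svm_lambda_max(d$X, d$y, alpha = 1)
  lams <- exp(seq(log(lmax), log(0.01 * lmax), length.out = 12))
  supp <- vapply(lams, function(l) {
    svm_enet(d$X, d$y, lambda = l, alpha = 1)$support_count
  }, integer(1))
  # along decreasing lambda the support grows; allow one numerical blip
  expect_lte(sum(diff(supp) < 0), 1L)
})

test_that("separable one-dimensional data is fit perfectly at small lambda", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  fit <- svm_enet(X, y, lambda = 1e-3, alpha = 1, standardize = FALSE)
  expect_identical(as.numeric(predict(fit, X)), y)
})

test_that("decision scores and predictions follow the linear rule", {
  d <- toy_shift_data(n = 30, p = 2, seed = 2)
  model <- svm_enet(d$X, d$y, lambda = 1, alpha = 1)
  model$beta <- c(1, 2); model$beta0 <- -1
  expect_identical(decision_scores(model, matrix(c(3, 4), 1)), 10)
  model$beta <- c(0, 0); model$beta0 <- 0.7
  expect_identical(decision_scores(model, d$X), rep(0.7, nrow(d$X)))
  expect_true(all(predict(model, d$X) == 1))
  # a score of exactly zero goes to the majority class
  model$beta0 <- 0
  expect_true(all(predict(model, d$X) == -1))
  expect_error(decision_scores(model, d$X[, 1, drop = FALSE]), "columns")
})

test_that("training-score split always feeds the HD estimator", {
  d <- toy_shift_data(n = 50, p = 5, shift = 2, ratio = 4, seed = 6)
  fit <- svm_enet(d$X, d$y, lambda = 0.5, alpha = 0.5)
  t <- decision_scores(fit, d$X)
  expect_true(is.finite(hellinger_from_scores(t[d$y == -1], t[d$y == 1])))
})

test_that("objective agrees with a 50,000-step subgradient oracle", {
  set.seed(21)
  for (i in 1:10) {
    X <- matrix(rnorm(18), 6, 3)
    y <- sample(rep(c(-1, 1), 3))
    lambda <- runif(1, 0.5, 2)
    alpha <- sample(c(0.3, 0.7, 1), 1)
    # CD on one fixed smoothing width can sit O(n * gamma) above the exact
    # hinge optimum; evaluate the exact objective at two widths and keep
    # the better fit
    mine <- min(vapply(c(1e-4, 1e-5), function(g) {
      fit <- suppressWarnings(
        svm_enet(X, y, lambda = lambda, alpha = alpha, gamma = g,
                 tol = 1e-12, maxit = 200000L, standardize = FALSE))
      svm_objective(X, y, fit$beta, fit$beta0, lambda, alpha)
    }, numeric(1)))
    oracle <- subgrad_svm_oracle(X, y, lambda, alpha)$objective
    expect_equal(mine, oracle, tolerance = 1e-4)
  }
})

test_that("ridge-penalized fit matches the quadratic-programming oracle", {
  skip_if_not_installed("quadprog")
  set.seed(31)
  for (i in 1:10) {
    X <- matrix(rnorm(24), 8, 3)
    y <- sample(rep(c(-1, 1), 4))
    C <- runif(1, 0.5, 3)
    qp <- qp_svm_oracle(X, y, C)
    # primal 0.5||b||^2 + C sum hinge == C * (sum hinge + (1/C) * 0.5||b||^2),
    # i.e. the package objective at lambda = 1/C, alpha = 0, times C
    mine <- C * min(vapply(c(1e-4, 1e-5), function(g) {
      fit <- suppressWarnings(
        svm_enet(X, y, lambda = 1 / C, alpha = 0, gamma = g,
                 tol = 1e-12, maxit = 200000L, standardize = FALSE))
      svm_objective(X, y, fit$beta, fit$beta0, 1 / C, 0)
    }, numeric(1)))
    expect_equal(mine, qp$objective, tolerance = 1e-4)
  }
})

test_that("row permutation does not change the fit", {
  d <- toy_shift_data(n = 40, p = 6, shift = 2, seed = 13)
  fit1 <- svm_enet(d$X, d$y, lambda = 0.8, alpha = 0.7)
  perm <- sample(nrow(d$X))
  fit2 <- svm_enet(d$X[perm, ], d$y[perm], lambda = 0.8, alpha = 0.7)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-5)
  expect_equal(fit1$beta0, fit2$beta0, tolerance = 1e-5)
})

test_that("invalid inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(svm_enet(X, rep(1, 10), lambda = 1), "both classes")
  expect_error(svm_enet(X, rep(c(0, 1), 5), lambda = 1), "-1")
  X[1, 1] <- NA
  expect_error(svm_enet(X, rep(c(-1, 1), 5), lambda = 1), "finite")
  expect_error(svm_enet(matrix(rnorm(20), 10, 2), rep(c(-1, 1), 5),
                        lambda = -1), "lambda")
})
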