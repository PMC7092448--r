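test_that("HD tuning finds the informative feature", {
  set.seed(14)
  n <- 120
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(rnorm(n) + 2 * (y == 1) * 2, rnorm(n))  # 4-sigma shift vs noise
  tw <- tune_by_hd(X, y, grid = ssshd_grid(alphas = c(0.5, 1), nlambda = 8),
                   seed = 1)
  expect_true(tw$model$beta[1] != 0)
  expect_gt(tw$value, 1)
  # the winner really is the sweep's 1-SE choice: nothing sparser within
  # one SE of the best scores higher
  sw <- tw$sweep
  ib <- which.max(sw$hd)
  eligible <- sw$hd >= sw$hd[ib] - sw$hd_se[ib] & sw$nzero > 0
  expect_identical(min(sw$nzero[eligible]),
                   sw$nzero[sw$lambda == tw$lambda & sw$alpha == tw$alpha])
})

test_that("grid handling is deterministic", {
  d <- toy_shift_data(n = 80, p = 6, shift = 3, seed = 22)
  g1 <- ssshd_grid(alphas = 1, lambdas = c(2, 1, 0.5))
  g2 <- ssshd_grid(alphas = 1, lambdas = c(2, 1, 0.5, 2, 1, 0.5))
  t1 <- tune_by_hd(d$X, d$y, grid = g1, seed = 3)
  t2 <- tune_by_hd(d$X, d$y, grid = g2, seed = 3)
  expect_identical(t1$lambda, t2$lambda)
  expect_identical(t1$alpha, t2$alpha)
  # an all-zero sweep is reported as such
  lmax <- svm_lambda_max(d$X, d$y, alpha = 1)
  expect_error(tune_by_hd(d$X, d$y, seed = 1,
                          grid = ssshd_grid(alphas = 1, lambdas = 3 * lmax)),
               "no informative fit")
})

test_that("stability selection satisfies the counting identity", {
  d <- toy_shift_data(n = 80, p = 10, shift = 4, seed = 17)
  grid <- ssshd_grid(alphas = 1, nlambda = 6)
  res <- stability_select(d$X, d$y, grid = grid, K = 5, fraction = 0.6,
                          seed = 42, cv_folds = 2)
  expect_equal(sum(res$frequencies * res$runs),
               sum(lengths(res$per_run_supports)))
  expect_true(all(res$frequencies >= 0 & res$frequencies <= 1))
  expect_true(all(vapply(res$frequencies * res$runs, function(v) {
    abs(v - round(v)) < 1e-9
  }, logical(1))))
  # K = 1 gives only 0/1 frequencies
  res1 <- stability_select(d$X, d$y, grid = grid, K = 1, fraction = 0.6,
                           seed = 1, cv_folds = 2)
  expect_true(all(res1$frequencies %in% c(0, 1)))
})

test_that("stability selection is reproducible and ratio-preserving", {
  d <- toy_shift_data(n = 60, p = 8, shift = 4, ratio = 2, seed = 30)
  grid <- ssshd_grid(alphas = 1, nlambda = 5)
  r1 <- stability_select(d$X, d$y, grid = grid, K = 4, seed = 9,
                         cv_folds = 2)
  r2 <- stability_select(d$X, d$y, grid = grid, K = 4, seed = 9,
                         cv_folds = 2)
  expect_identical(r1$frequencies, r2$frequencies)
  expect_identical(r1$chosen_params, r2$chosen_params)
  expect_error(stability_select(d$X, d$y, grid = grid, K = 2,
                                fraction = 0.05, seed = 1),
               "minority subsample")
})

test_that("a strong feature dominates the stability ranking", {
  for (seed in c(101, 202, 303)) {
    d <- toy_shift_data(n = 200, p = 20, shift = 4, seed = seed)
    res <- stability_select(d$X, d$y,
                            grid = ssshd_grid(alphas = 1, nlambda = 6),
                            K = 30, fraction = 0.5, seed = seed,
                            cv_folds = 2)
    expect_gte(res$frequencies[1], 0.9)
    expect_identical(rank_features(res)[1], 1L)
  }
})

test_that("ranking and top-q selection are stable and nested", {
  res <- structure(
    list(frequencies = c(0.2, 0.9, 0.9, 0.1), runs = 10L,
         per_run_supports = list(), chosen_params = list(),
         ranking = order(-c(0.2, 0.9, 0.9, 0.1), 1:4), fraction = 0.5,
         feature_names = paste0("V", 1:4)),
    class = "ssshd"
  )
  expect_identical(rank_features(res)[1:2], c(2L, 3L))
  expect_identical(select_top_q(res, 1), 2L)
  expect_identical(sort(select_top_q(res, 4)), 1:4)
  for (q in 1:3) {
    expect_true(all(select_top_q(res, q) %in% select_top_q(res, q + 1)))
  }
  expect_error(select_top_q(res, 0), "between")
  expect_error(select_top_q(res, 5), "between")
  # all-equal frequencies rank in index order
  res$frequencies <- rep(0.5, 4)
  res$ranking <- order(-res$frequencies, 1:4)
  expect_identical(rank_features(res), 1:4)
})

test_that("rankings export as TSV", {
  d <- toy_shift_data(n = 60, p = 5, shift = 4, seed = 2)
  res <- stability_select(d$X, d$y,
                          grid = ssshd_grid(alphas = 1, nlambda = 5),
                          K = 3, seed = 4, cv_folds = 2)
  path <- tempfile(fileext = ".tsv")
  write_ranking(res, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("feature_id", "inclusion_frequency", "rank"))
  expect_identical(back$rank, seq_len(5L))
  expect_true(all(diff(back$inclusion_frequency) <= 0))
})
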