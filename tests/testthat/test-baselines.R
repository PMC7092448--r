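test_that("Fisher score matches hand arithmetic and conventions", {
  X <- cbind(f1 = c(0, 2, 4, 6), f2 = c(1, 1, 1, 1), f3 = c(0, 0, 2, 2))
  y <- c(-1, -1, 1, 1)
  fs <- fisher_score(X, y)
  expect_equal(fs$values[[1]], abs(5 - 1) / (2 + 2))   # {0,2} vs {4,6}
  expect_identical(fs$values[[2]], 0)                  # identical classes
  expect_identical(fs$values[[3]], Inf)                # zero-variance shift
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(fisher_score(X[perm, ], y[perm])$values, fs$values)
  expect_error(fisher_score(X[c(1, 3, 4), ], y[c(1, 3, 4)]), "at least 2")
})

test_that("Relief weights match a brute-force enumeration", {
  # deterministic full pass (m = n)
  X <- matrix(c(-1, -1.1, 1, 1.1), 4, 1)
  y <- c(-1, -1, 1, 1)
  w <- relief_weights(X, y, m = 4)
  # brute force: visit every point, nearest hit/miss by enumeration
  brute <- 0
  for (i in 1:4) {
    d2 <- (X[i, 1] - X[, 1])^2; d2[i] <- Inf
    hit <- which(d2 == min(d2[y == y[i]]) & y == y[i])[1]
    miss <- which(d2 == min(d2[y != y[i]]) & y != y[i])[1]
    brute <- brute - (X[i, 1] - X[hit, 1])^2 + (X[i, 1] - X[miss, 1])^2
  }
  expect_equal(w$values, brute)
  expect_gt(w$values, 0)   # misses are farther than hits
  # duplicating every sample keeps the weight sign (brute force again)
  X2 <- rbind(X, X); y2 <- c(y, y)
  w2 <- relief_weights(X2, y2)
  expect_gt(w2$values, 0)
  # constant feature gets exactly zero weight
  Xc <- cbind(X, 5)
  expect_identical(relief_weights(Xc, y)$values[2], 0)
  expect_error(relief_weights(X[1:3, , drop = FALSE], c(-1, -1, 1)),
               "at least 2")
})

test_that("Relief is seed-reproducible and finds a strong feature", {
  d <- toy_shift_data(n = 100, p = 20, shift = 4, seed = 5)
  w1 <- relief_weights(d$X, d$y, m = 50, seed = 99)
  w2 <- relief_weights(d$X, d$y, m = 50, seed = 99)
  expect_identical(w1$values, w2$values)
  top_hits <- vapply(1:50, function(s) {
    which.max(relief_weights(d$X, d$y, m = 50, seed = s)$values) == 1L
  }, logical(1))
  expect_gte(mean(top_hits), 0.95)
})

test_that("ROC and PRC filters score columns like the metrics module", {
  d <- toy_shift_data(n = 60, p = 5, shift = 6, ratio = 2, seed = 12)
  roc_f <- aucroc_filter(d$X, d$y)
  prc_f <- aucprc_filter(d$X, d$y)
  expect_equal(roc_f$values[1], 1)             # near-perfect separator
  expect_equal(prc_f$values[1], 1, tolerance = 1e-9)
  for (j in 1:5) {
    a <- auc_roc_lower_trapezoid(d$X[, j], d$y)
    expect_equal(roc_f$values[j], max(a, 1 - a))
    expect_equal(prc_f$values[j],
                 max(auc_prc(d$X[, j], d$y), auc_prc(-d$X[, j], d$y)))
  }
  # pure-noise columns sit near 1/2 before orientation correction
  expect_lt(max(abs(vapply(2:5, function(j) {
    auc_roc_lower_trapezoid(d$X[, j], d$y)
  }, numeric(1)) - 0.5)), 0.2)
})

test_that("all tuning criteria nail linearly separable toy data", {
  d <- toy_shift_data(n = 60, p = 4, shift = 6, seed = 3)
  grid <- ssshd_grid(alphas = c(0.5, 1), nlambda = 6)
  for (tuner in list(tune_by_hd, tune_by_acc, tune_by_roc)) {
    tw <- tuner(d$X, d$y, grid = grid, seed = 1)
    expect_equal(mean(predict(tw$model, d$X) == d$y), 1)
  }
  # a single-point grid is returned as-is
  one <- ssshd_grid(alphas = 0.5, lambdas = 0.7)
  tw <- tune_by_acc(d$X, d$y, grid = one, seed = 1)
  expect_identical(tw$lambda, 0.7)
  expect_identical(tw$alpha, 0.5)
})

test_that("accuracy tuning admits far more null features than HD under skew", {
  # scaled-down 15:1 under-determined scenario; the high within-block
  # correlation is what forces accuracy deep into the path before it
  # recovers from the boundary shift, so the contrast is structural
  s <- scenario(p = 400, rho = 0.92, n0 = 450, n1 = 30)
  out <- run_table1(s, criteria = c("acc", "hd"), reps = 20, seed = 77)
  ic_acc <- out$IC[out$criterion == "acc"]
  ic_hd <- out$IC[out$criterion == "hd"]
  expect_gt(ic_acc, 5 * ic_hd)
  expect_gt(out$FDR[out$criterion == "acc"],
            out$FDR[out$criterion == "hd"])
})

test_that("feature scores export as ranked TSV", {
  fs <- fisher_score(toy_shift_data(seed = 8)$X, toy_shift_data(seed = 8)$y)
  path <- tempfile(fileext = ".tsv")
  write_scores(fs, path)
  back <- read.delim(path)
  expect_identical(names(back), c("feature_id", "score", "rank"))
  expect_identical(back$rank, seq_len(nrow(back)))
})
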