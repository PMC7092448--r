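# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of the closed form, pair
# counting instead of the trapezoid, subgradient descent / quadratic
# programming instead of coordinate descent.

# Squared Hellinger distance between N(mu1, v1) and N(mu0, v0) by direct
# numerical integration of the defining integral.
hd_sq_quadrature <- function(mu0, v0, mu1, v1) {
  f <- function(x) {
    (sqrt(stats::dnorm(x, mu1, sqrt(v1))) -
       sqrt(stats::dnorm(x, mu0, sqrt(v0))))^2
  }
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Pair-counting (Mann-Whitney) AUC with ties counted one half.
auc_pair_counting <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == -1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Subgradient descent on the exact hinge + elastic-net objective with a
# diminishing a / t^0.9 schedule, tracking the best iterate. The 50k-step
# budget is split across three step scales (restarting from the incumbent)
# so that a poorly scaled instance cannot stall the oracle.
subgrad_svm_oracle <- function(X, y, lambda, alpha, steps = 50000L) {
  p <- ncol(X)
  beta <- numeric(p); b0 <- 0
  best <- svm_objective(X, y, beta, b0, lambda, alpha)
  best_beta <- beta; best_b0 <- b0
  base <- 1 / max(sqrt(rowSums(X^2)))
  scales <- c(3, 1, 0.3)
  chunk <- floor(steps / length(scales))
  for (a_step in base * scales) {
    beta <- best_beta; b0 <- best_b0
    for (t in seq_len(chunk)) {
      m <- y * (drop(X %*% beta) + b0)
      act <- m < 1
      g_beta <- -colSums((y * act) * X) +
        lambda * ((1 - alpha) * beta + alpha * sign(beta))
      g_b0 <- -sum(y[act])
      step <- a_step / t^0.9
      beta <- beta - step * g_beta
      b0 <- b0 - step * g_b0
      obj <- svm_objective(X, y, beta, b0, lambda, alpha)
      if (obj < best) {
        best <- obj; best_beta <- beta; best_b0 <- b0
      }
    }
  }
  list(objective = best, beta = best_beta, beta0 = best_b0)
}

# Soft-margin SVM primal (ridge penalty) solved as a quadratic program in
# (beta, beta0, xi): minimize 0.5 ||beta||^2 + C sum xi subject to
# y_i (x_i' beta + beta0) >= 1 - xi_i and xi >= 0. Tiny ridge on the
# unpenalized coordinates keeps the QP strictly convex.
qp_svm_oracle <- function(X, y, C) {
  n <- nrow(X); p <- ncol(X)
  nv <- p + 1L + n
  D <- diag(c(rep(1, p), 1e-8, rep(1e-8, n)))
  dvec <- c(rep(0, p + 1L), rep(-C, n))   # +C sum(xi) in the objective
  A1 <- cbind(y * X, y, diag(n))        # margin constraints
  A2 <- cbind(matrix(0, n, p + 1L), diag(n))  # xi >= 0
  A <- t(rbind(A1, A2))
  b <- c(rep(1, n), rep(0, n))
  sol <- quadprog::solve.QP(D, dvec, A, b)
  beta <- sol$solution[seq_len(p)]
  b0 <- sol$solution[p + 1L]
  list(beta = beta, beta0 = b0,
       objective = 0.5 * sum(beta^2) +
         C * sum(pmax(0, 1 - y * (drop(X %*% beta) + b0))))
}

# Small linearly-structured binary dataset: one informative feature with
# the requested class-mean shift, the rest pure noise.
toy_shift_data <- function(n = 100L, p = 10L, shift = 4, ratio = 1,
                           seed = 1L) {
  set.seed(seed)
  n1 <- round(n / (1 + ratio))
  n0 <- n - n1
  y <- rep(c(-1, 1), c(n0, n1))
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1L] <- X[y == 1, 1L] + shift
  ord <- sample.int(n)
  list(X = X[ord, , drop = FALSE], y = y[ord])
}
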