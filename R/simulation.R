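# Blocked-covariance Gaussian generator and the benchmarking harness that
# compares the ACC / ROC / HD tuning criteria by how well they recover the
# key features.

#' Simulation scenario
#'
#' Two multivariate-normal classes share a blocked AR(1)-style correlation
#' matrix: entries \eqn{\rho^{|i-j|}} within the key-feature block (the
#' first `n_key` features) and within the null block, zero between blocks,
#' unit diagonal. Class means differ by `delta` on the key features and by
#' zero on the null features. The benchmark settings are p in \{100, 2000\},
#' rho in \{0, 0.4, 0.92\}, n0 + n1 = 960 at majority:minority ratios 1:1,
#' 3:1, 9:1, 15:1, with `n_key = 10` and `delta = 2`.
#'
#' @param p Total number of features (>= n_key).
#' @param rho Within-block correlation parameter in \[0, 1).
#' @param n0,n1 Majority and minority class sizes.
#' @param n_key Number of key (informative) features.
#' @param delta Mean shift on the key features.
#' @return An object of class `ssshd_scenario`.
#' @export
scenario <- function(p, rho, n0, n1, n_key = 10L, delta = 2) {
  p <- as.integer(p); n_key <- as.integer(n_key)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (n_key > p) stop("n_key cannot exceed p", call. = FALSE)
  if (n0 < 1L || n1 < 1L) stop("class sizes must be positive", call. = FALSE)
  structure(list(p = p, rho = rho, n0 = as.integer(n0),
                 n1 = as.integer(n1), n_key = n_key, delta = delta),
            class = "ssshd_scenario")
}

#' Blocked covariance matrix of a scenario
#'
#' @param s An [scenario()] object.
#' @return The p x p covariance matrix: \eqn{\rho^{|i-j|}} within the key
#'   and null blocks, zero between blocks, symmetric positive definite.
#' @export
build_covariance <- function(s) {
  stopifnot(inherits(s, "ssshd_scenario"))
  Sigma <- matrix(0, s$p, s$p)
  blocks <- list(seq_len(s$n_key),
                 if (s$p > s$n_key) (s$n_key + 1L):s$p else integer(0))
  for (b in blocks) {
    if (length(b) == 0L) next
    Sigma[b, b] <- s$rho^abs(outer(seq_along(b), seq_along(b), "-"))
  }
  Sigma
}

# AR(1) blocks have the classic recursion X_1 = Z_1,
# X_i = rho X_{i-1} + sqrt(1 - rho^2) Z_i, which reproduces the
# rho^{|i-j|} covariance without a p x p Cholesky factor.
.ar1_block <- function(n, m, rho) {
  Z <- matrix(stats::rnorm(n * m), n, m)
  if (rho == 0 || m == 1L) return(Z)
  s <- sqrt(1 - rho^2)
  for (j in 2:m) Z[, j] <- rho * Z[, j - 1L] + s * Z[, j]
  Z
}

#' Generate a scenario dataset
#'
#' Draws `n0` majority rows from \eqn{N_p(0, \Sigma)} (label -1) and `n1`
#' minority rows from \eqn{N_p(\mu_1, \Sigma)} (label +1) where
#' \eqn{\mu_1} equals `delta` on the key features and 0 elsewhere; rows are
#' then shuffled. Uses the AR(1) recursion per block, which is an exact
#' sampler for the blocked covariance of [build_covariance()].
#'
#' @param s An [scenario()] object.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list with `X` (n x p), `y` (labels in \{-1, +1\}) and the
#'   scenario `s`.
#' @export
generate_data <- function(s, seed = NULL) {
  stopifnot(inherits(s, "ssshd_scenario"))
  .with_seed(seed, {
    n <- s$n0 + s$n1
    X <- cbind(.ar1_block(n, s$n_key, s$rho),
               if (s$p > s$n_key) .ar1_block(n, s$p - s$n_key, s$rho))
    y <- rep(c(-1, 1), c(s$n0, s$n1))
    X[y == 1, seq_len(s$n_key)] <- X[y == 1, seq_len(s$n_key)] + s$delta
    ord <- sample.int(n)
    list(X = X[ord, , drop = FALSE], y = y[ord], scenario = s)
  })
}

#' Score a selected feature set against the scenario truth
#'
#' @param selected Integer set of selected feature indices.
#' @param s An [scenario()] object.
#' @return A list with `C` (correctly selected key features), `IC`
#'   (selected null features) and `FDR = IC / (C + IC)` with the 0/0 case
#'   defined as 0.
#' @export
evaluate_selection <- function(selected, s) {
  stopifnot(inherits(s, "ssshd_scenario"))
  selected <- as.integer(selected)
  if (length(selected) > 0 &&
      (any(selected < 1L) || any(selected > s$p))) {
    stop("selected indices must lie in 1..p", call. = FALSE)
  }
  C <- sum(selected <= s$n_key)
  IC <- length(selected) - C
  list(C = C, IC = IC, FDR = if (C + IC == 0L) 0 else IC / (C + IC))
}

#' Compare tuning criteria on replicated scenario data
#'
#' For each replication: generate a dataset, sweep one shared
#' (lambda, alpha) grid of sparse-SVM fits, and let each criterion (ACC,
#' ROC, HD) pick its winner from the identical fits -- no stability
#' subsampling is involved, so the comparison isolates the tuning
#' criterion. The support of each winner is scored with
#' [evaluate_selection()], and per-criterion means of C, IC and FDR over
#' replications are reported.
#'
#' The default grid is deliberately compact -- two mixing values, a
#' LASSO-like arm (`alpha = 1`) whose path stays sparse and a ridge-like
#' arm (`alpha = 0.05`) whose path extends deep into the dense regime, by
#' 8 lambdas -- so that replicated runs at p = 2000 stay within a desktop
#' compute budget while the path still spans the full range from the
#' empty model to fits with hundreds of active features; pass a larger
#' [ssshd_grid()] for a finer sweep. Solver effort per fit is likewise
#' capped (`tol = 1e-4`, `maxit = 150`): selection outcomes are driven by
#' which coefficients are nonzero, which stabilizes long before full
#' convergence of the dense path tail.
#'
#' @param s An [scenario()] object.
#' @param criteria Subset of `c("acc", "roc", "hd")`.
#' @param reps Number of replications.
#' @param seed Master seed; per-replication seeds are spawned from it so
#'   each cell is reproducible.
#' @param grid An [ssshd_grid()]; defaults to
#'   `ssshd_grid(alphas = c(0.05, 1), nlambda = 8)`.
#' @param cv_folds Stratified folds for the criterion evaluation, as in
#'   [tune_by_hd()].
#' @inheritParams svm_enet
#' @return A data.frame with one row per criterion: `criterion`, `C`,
#'   `IC`, `FDR`, `reps`.
#' @export
run_table1 <- function(s, criteria = c("acc", "roc", "hd"), reps = 50L,
                       seed = NULL, grid = NULL, cv_folds = 3L,
                       gamma = 0.25, tol = 1e-4, maxit = 150L) {
  stopifnot(inherits(s, "ssshd_scenario"))
  criteria <- match.arg(criteria, c("acc", "roc", "hd"),
                        several.ok = TRUE)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be at least 1", call. = FALSE)
  if (is.null(grid)) {
    grid <- ssshd_grid(alphas = c(0.05, 1), nlambda = 8L)
  }
  crit_col <- c(acc = "acc", roc = "auc", hd = "hd")
  rep_seeds <- .with_seed(seed, sample.int(.Machine$integer.max, reps))
  acc <- matrix(0, length(criteria), 3L,
                dimnames = list(criteria, c("C", "IC", "FDR")))
  for (r in seq_len(reps)) {
    dat <- generate_data(s, seed = rep_seeds[r])
    sw <- .svm_grid_sweep(dat$X, dat$y, grid, gamma = gamma, tol = tol,
                          maxit = maxit, cv_folds = cv_folds,
                          seed = rep_seeds[r])
    for (cr in criteria) {
      i <- .sweep_best(sw, crit_col[[cr]])
      sel <- sw$coefs[[i]]$support
      ev <- evaluate_selection(sel, s)
      acc[cr, ] <- acc[cr, ] + c(ev$C, ev$IC, ev$FDR)
    }
  }
  acc <- acc / reps
  data.frame(criterion = criteria, C = acc[, "C"], IC = acc[, "IC"],
             FDR = acc[, "FDR"], reps = reps, row.names = NULL)
}
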