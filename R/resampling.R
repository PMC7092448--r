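# SMOTE oversampling and stratified data-splitting protocols.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' SMOTE: synthetic minority oversampling
#'
#' Adds synthetic minority examples by interpolating between existing
#' minority instances: each synthetic point is \eqn{x + u (x_{nn} - x)}
#' with \eqn{u \sim U(0,1)} and \eqn{x_{nn}} drawn uniformly from the `k`
#' nearest minority neighbours of `x` (Euclidean distance on the raw
#' feature scale, minority class only). Enough synthetics are generated to
#' bring the majority:minority ratio down to `target_ratio` (default 1,
#' i.e. approximately balanced). Original rows are never modified or
#' removed; synthetic rows are appended with label +1.
#'
#' @param X Feature matrix.
#' @param y Labels in \{-1, +1\} with the minority coded +1.
#' @param k Number of nearest minority neighbours (must be < minority
#'   count).
#' @param target_ratio Desired majority:minority ratio after oversampling.
#' @param seed Integer seed; the augmentation is reproducible given it.
#' @return A list with the augmented `X`, `y` and a logical `synthetic`
#'   flag per row.
#' @export
smote <- function(X, y, k = 5L, target_ratio = 1, seed = NULL) {
  d <- .check_xy(X, y)
  k <- as.integer(k)
  idx1 <- which(d$y == 1)
  n1 <- length(idx1); n0 <- sum(d$y == -1)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (n1 <= k) {
    stop("minority count (", n1, ") must exceed k (", k, ")",
         call. = FALSE)
  }
  if (target_ratio <= 0) stop("target_ratio must be positive", call. = FALSE)
  need <- max(0L, as.integer(round(n0 / target_ratio)) - n1)
  if (need == 0L) {
    return(list(X = d$X, y = d$y, synthetic = rep(FALSE, nrow(d$X))))
  }
  X1 <- d$X[idx1, , drop = FALSE]
  D2 <- as.matrix(stats::dist(X1))^2
  diag(D2) <- Inf
  # k nearest minority neighbours per minority point (rows); built via
  # matrix() so that k = 1 keeps its dimensions
  nn <- t(matrix(apply(D2, 1L, function(r) order(r)[seq_len(k)]),
                 nrow = k))
  .with_seed(seed, {
    # spread the synthetic quota over minority points; when `need` is not
    # a multiple of the minority size, the remainder goes to a seeded
    # random choice of points
    quota <- rep(need %/% n1, n1)
    extra <- need %% n1
    if (extra > 0L) {
      lucky <- sample.int(n1, extra)
      quota[lucky] <- quota[lucky] + 1L
    }
    syn <- matrix(NA_real_, need, ncol(d$X))
    row <- 0L
    for (i in seq_len(n1)) {
      if (quota[i] == 0L) next
      picks <- nn[i, sample.int(k, quota[i], replace = TRUE)]
      u <- stats::runif(quota[i])
      for (s in seq_len(quota[i])) {
        row <- row + 1L
        syn[row, ] <- X1[i, ] + u[s] * (X1[picks[s], ] - X1[i, ])
      }
    }
    colnames(syn) <- colnames(d$X)
    list(X = rbind(d$X, syn), y = c(d$y, rep(1, need)),
         synthetic = c(rep(FALSE, nrow(d$X)), rep(TRUE, need)))
  })
}

#' Stratified k-fold plan
#'
#' Assigns every sample to one of `n_folds` folds so that each fold's
#' class ratio matches the full data within rounding: each class is
#' shuffled (seeded) and dealt round-robin across folds.
#'
#' @param y Labels in \{-1, +1\}.
#' @param n_folds Number of folds; no class may be smaller than this.
#' @param seed Integer seed for the within-class shuffle.
#' @return A list with `assignments` (fold index per sample) and
#'   `n_folds`.
#' @export
stratified_kfold <- function(y, n_folds = 5L, seed = NULL) {
  y <- .check_labels(y)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2", call. = FALSE)
  if (min(sum(y == 1), sum(y == -1)) < n_folds) {
    stop("each class must have at least n_folds members", call. = FALSE)
  }
  .with_seed(seed, {
    fold <- integer(length(y))
    for (cl in c(-1, 1)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    list(assignments = fold, n_folds = n_folds)
  })
}

#' Leave-one-out split sequence
#'
#' @param n Number of samples, at least 2.
#' @return A list of `n` elements, each `list(train =, test =)` with a
#'   singleton test set.
#' @export
loocv_indices <- function(n) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  lapply(seq_len(n), function(i) list(train = setdiff(seq_len(n), i),
                                      test = i))
}

#' Stratified subsample indices
#'
#' Draws the same fraction of each class without replacement, preserving
#' the class-imbalance ratio of the full data within rounding.
#'
#' @param y Labels in \{-1, +1\}.
#' @param fraction Per-class fraction in (0, 1\].
#' @param seed Integer seed.
#' @return Sorted integer vector of retained sample indices.
#' @export
stratified_subsample <- function(y, fraction, seed = NULL) {
  y <- .check_labels(y)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  sizes <- floor(fraction * c(sum(y == -1), sum(y == 1)))
  if (any(sizes < 1L)) {
    stop("fraction too small: a class draw would be empty", call. = FALSE)
  }
  .with_seed(seed, {
    i0 <- sample(which(y == -1), sizes[1L])
    i1 <- sample(which(y == 1), sizes[2L])
    sort(c(i0, i1))
  })
}
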