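# The sssHD algorithm: Hellinger-distance-maximizing tuning of the sparse
# SVM over a (lambda, alpha) grid, repeated over stratified subsamples and
# aggregated into inclusion frequencies.

#' Tuning grid for the sparse SVM
#'
#' Describes the (lambda, alpha) grid swept by the tuning criteria. Lambda
#' sequences are materialized per alpha at sweep time: `nlambda` log-spaced
#' values from the data-derived `svm_lambda_max` down to
#' `lambda_min_ratio * lambda_max`, following the path convention of
#' penalized-regression software. An explicit `lambdas` vector (decreasing)
#' overrides this and is shared across alphas.
#'
#' @param alphas Elastic-net mixing values, each in (0, 1\].
#' @param nlambda Number of lambda values per alpha.
#' @param lambda_min_ratio Ratio of the smallest to the largest lambda.
#' @param lambdas Optional explicit decreasing lambda sequence.
#' @return An object of class `ssshd_grid`.
#' @export
ssshd_grid <- function(alphas = seq(0.1, 1, by = 0.1), nlambda = 30L,
                       lambda_min_ratio = 0.01, lambdas = NULL) {
  alphas <- as.numeric(alphas)
  if (length(alphas) == 0L || any(alphas <= 0 | alphas > 1)) {
    stop("alphas must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(lambdas)) {
    lambdas <- as.numeric(lambdas)
    if (length(lambdas) == 0L || any(lambdas <= 0)) {
      stop("lambdas must be positive", call. = FALSE)
    }
    if (is.unsorted(rev(lambdas), strictly = FALSE)) {
      lambdas <- sort(lambdas, decreasing = TRUE)
    }
  }
  structure(list(alphas = alphas, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, lambdas = lambdas),
            class = "ssshd_grid")
}

.grid_lambdas <- function(grid, X, y, alpha, gamma) {
  if (!is.null(grid$lambdas)) return(grid$lambdas)
  lmax <- svm_lambda_max(X, y, alpha = alpha, gamma = gamma,
                         standardize = FALSE)   # X already standardized
  exp(seq(log(lmax), log(lmax * grid$lambda_min_ratio),
          length.out = grid$nlambda))
}

# Criteria (HD / ACC / lower-trapezoid AUCROC) for one path's score
# matrix, one value per lambda. Grid points whose fit is empty get the
# uninformative values HD = 0, AUC = 1/2.
.path_criteria <- function(scores, y, nzero) {
  neg <- y == -1
  vapply(seq_len(ncol(scores)), function(l) {
    t <- scores[, l]
    empty <- nzero[l] == 0L
    c(hd = if (empty) 0 else hellinger_from_scores(t[neg], t[!neg]),
      acc = mean(ifelse(t > 0, 1, -1) == y),
      auc = if (empty) 0.5 else auc_roc_lower_trapezoid(t, y))
  }, c(hd = 0, acc = 0, auc = 0))
}

# Sweep the whole grid once on (X, y): per grid point, fit the full data
# (that fit's support is the selection outcome) and score the three tuning
# criteria on out-of-fold decision scores from a stratified cv_folds-fold
# cross-validation, averaging the per-fold criterion values (the usual
# cross-validation convention). cv_folds = 0 scores the criteria on the
# in-sample decision scores instead. The sweep is shared by tune_by_hd /
# tune_by_acc / tune_by_roc and by the simulation harness so that the
# criteria compare identical fits.
.svm_grid_sweep <- function(X, y, grid, gamma = 0.25, tol = 1e-5,
                            maxit = 10000L, cv_folds = 3L, seed = NULL) {
  stopifnot(inherits(grid, "ssshd_grid"))
  d <- .check_xy(X, y)
  std <- .standardize(d$X)
  cv_folds <- as.integer(cv_folds)
  plan <- if (cv_folds >= 2L) {
    stratified_kfold(d$y, n_folds = cv_folds, seed = seed)
  }
  rows <- list()
  coefs <- list()
  k <- 0L
  for (a in grid$alphas) {
    lams <- .grid_lambdas(grid, std$Xs, d$y, a, gamma)
    path <- .cd_svm_path(std$Xs, d$y, lams, a, gamma, tol,
                         as.integer(maxit))
    nzero_full <- colSums(path$beta != 0)
    if (is.null(plan)) {
      scores <- sweep(std$Xs %*% path$beta, 2L, path$beta0, "+")
      crit <- .path_criteria(scores, d$y, nzero_full)
      se <- crit * 0
    } else {
      per_fold <- vector("list", cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- plan$assignments != f
        pf <- .cd_svm_path(std$Xs[tr, , drop = FALSE], d$y[tr], lams, a,
                           gamma, tol, as.integer(maxit))
        so <- sweep(std$Xs[!tr, , drop = FALSE] %*% pf$beta, 2L,
                    pf$beta0, "+")
        per_fold[[f]] <- .path_criteria(so, d$y[!tr],
                                        colSums(pf$beta != 0))
      }
      crit <- Reduce(`+`, per_fold) / cv_folds
      se <- sqrt(Reduce(`+`, lapply(per_fold, function(m) (m - crit)^2)) /
                   (cv_folds - 1L) / cv_folds)
    }
    for (l in seq_along(lams)) {
      k <- k + 1L
      bs <- path$beta[, l]
      supp <- which(bs != 0)
      rows[[k]] <- data.frame(alpha = a, lambda = lams[l],
                              nzero = length(supp), hd = crit["hd", l],
                              acc = crit["acc", l], auc = crit["auc", l],
                              hd_se = se["hd", l], acc_se = se["acc", l],
                              auc_se = se["auc", l],
                              converged = path$converged[l])
      coefs[[k]] <- list(support = supp, beta_std = bs[supp],
                         beta0_std = path$beta0[l])
    }
  }
  list(stats = do.call(rbind, rows), coefs = coefs, std = std,
       p = ncol(d$X), gamma = gamma, cv_folds = cv_folds)
}

# Deterministic winner under a criterion column by the one-standard-error
# rule: among grid points whose criterion lies within one fold-SE of the
# best value, take the most parsimonious fit (fewest nonzero coefficients,
# then largest lambda, then largest alpha). With cv_folds = 0 the SE is 0
# and the rule reduces to strict maximization with parsimony tie-breaks.
# For the HD criterion, beta = 0 points (constant scores, HD 0) are never
# eligible while an informative fit exists.
.sweep_best <- function(sweep, criterion) {
  st <- sweep$stats
  if (all(st$nzero == 0L)) {
    stop("no informative fit: every grid point produced beta = 0",
         call. = FALSE)
  }
  v <- st[[criterion]]
  se <- st[[paste0(criterion, "_se")]]
  ib <- which.max(v)
  cand <- which(v >= v[ib] - se[ib])
  if (criterion == "hd") cand <- cand[st$nzero[cand] > 0L]
  cand[order(st$nzero[cand], -st$lambda[cand], -st$alpha[cand])][1L]
}

# Rebuild an svm_enet object (original feature scale) for grid point i.
.sweep_model <- function(sweep, i) {
  cf <- sweep$coefs[[i]]
  st <- sweep$stats[i, ]
  beta <- numeric(sweep$p)
  beta[cf$support] <- cf$beta_std / sweep$std$scale[cf$support]
  beta0 <- cf$beta0_std -
    sum(cf$beta_std * sweep$std$center[cf$support] /
          sweep$std$scale[cf$support])
  structure(
    list(beta = beta, beta0 = beta0, lambda = st$lambda, alpha = st$alpha,
         gamma = sweep$gamma, support_count = length(cf$support),
         converged = st$converged, iters = NA_integer_, p = sweep$p),
    class = "svm_enet"
  )
}

.tune_by <- function(X, y, grid, criterion, cv_folds, seed, gamma, tol,
                     maxit) {
  sweep <- .svm_grid_sweep(X, y, grid, gamma = gamma, tol = tol,
                           maxit = maxit, cv_folds = cv_folds, seed = seed)
  i <- .sweep_best(sweep, criterion)
  st <- sweep$stats[i, ]
  list(lambda = st$lambda, alpha = st$alpha,
       model = .sweep_model(sweep, i), value = st[[criterion]],
       criterion = criterion, sweep = sweep$stats)
}

#' Tune the sparse SVM by maximizing the Hellinger distance
#'
#' Fits the elastic-net SVM at every grid point on the full data (the
#' selected model), and scores each grid point by the Hellinger distance
#' between the class-split decision-score distributions evaluated on
#' held-out data: a stratified `cv_folds`-fold cross-validation computes
#' out-of-fold scores and the per-fold HD values are averaged, the usual
#' cross-validation convention. Out-of-fold evaluation is essential --
#' measured on the training scores themselves the HD grows with every
#' coefficient that enters the model, informative or not, and maximizing
#' it degenerates into picking the densest fit. On held-out scores noise
#' coefficients inflate the within-class score variances without moving
#' the class means apart, so the criterion peaks at economical fits.
#'
#' The winner is chosen by the one-standard-error rule familiar from
#' cross-validated regularization paths: among grid points whose criterion
#' lies within one fold-SE of the best value, the most parsimonious fit
#' wins (fewest nonzero coefficients, then largest lambda, then largest
#' alpha). Near its maximum the held-out HD is flat -- fits that separate
#' the classes equally well are statistically indistinguishable -- and the
#' 1-SE rule converts that plateau into a stable preference for the most
#' economical separating model. Grid points whose fit has `beta = 0`
#' produce constant scores and receive HD 0, so they can never beat an
#' informative fit.
#'
#' @inheritParams svm_enet
#' @param grid An [ssshd_grid()].
#' @param cv_folds Number of stratified folds for criterion evaluation;
#'   `0` scores the criterion on the in-sample decision scores instead
#'   (not recommended, see above).
#' @param seed Integer seed for the fold assignment; the tuning is
#'   deterministic given it.
#' @return A list with `lambda`, `alpha`, `model` (an `svm_enet` on the
#'   original feature scale), `value` (the achieved criterion), and `sweep`
#'   (the per-grid-point statistics).
#' @export
tune_by_hd <- function(X, y, grid = ssshd_grid(), cv_folds = 3L,
                       seed = NULL, gamma = 0.25, tol = 1e-5,
                       maxit = 10000L) {
  .tune_by(X, y, grid, "hd", cv_folds, seed, gamma, tol, maxit)
}

#' Stability selection with HD-tuned sparse SVM fits
#'
#' Repeats the HD-maximizing tuning of [tune_by_hd()] on `K` stratified
#' subsamples (the same fraction drawn from each class, preserving the
#' class-imbalance ratio), records which coefficients are nonzero in each
#' run, and aggregates into per-feature inclusion frequencies
#' \eqn{f_j = K^{-1}\sum_k 1\{\hat\beta_j^{(k)} \neq 0\}}. Features are
#' ranked by decreasing frequency (index order breaks ties).
#'
#' @inheritParams tune_by_hd
#' @param K Number of subsampling runs.
#' @param fraction Per-class subsampling fraction in (0, 1); both classes
#'   use the same fraction so every subsample keeps the original imbalance
#'   ratio.
#' @param seed Integer seed; the whole procedure is reproducible given the
#'   seed.
#' @return An object of class `ssshd`: list with `frequencies`, `runs`,
#'   `per_run_supports`, `chosen_params`, `ranking`, `fraction`.
#' @examples
#' \donttest{
#' set.seed(1)
#' X <- matrix(rnorm(100 * 10), 100, 10)
#' X[, 1] <- X[, 1] + 2 * (seq_len(100) <= 30)
#' y <- rep(c(1, -1), c(30, 70))
#' res <- stability_select(X, y, grid = ssshd_grid(alphas = 1, nlambda = 8),
#'                         K = 10, seed = 7)
#' rank_features(res)[1]
#' }
#' @export
stability_select <- function(X, y, grid = ssshd_grid(), K = 100L,
                             fraction = 0.5, seed = NULL, cv_folds = 3L,
                             gamma = 0.25, tol = 1e-5, maxit = 10000L) {
  d <- .check_xy(X, y)
  K <- as.integer(K)
  if (K < 1L) stop("K must be at least 1", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  n1 <- sum(d$y == 1)
  need <- max(2L, as.integer(cv_folds))
  if (floor(fraction * n1) < need) {
    stop("minority subsample would have fewer than ", need, " members; ",
         "use fraction >= ", signif(need / n1, 3), call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  run_seeds <- sample.int(.Machine$integer.max, K)
  p <- ncol(d$X)
  counts <- integer(p)
  supports <- vector("list", K)
  params <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- stratified_subsample(d$y, fraction, seed = run_seeds[k])
    tk <- tune_by_hd(d$X[idx, , drop = FALSE], d$y[idx], grid = grid,
                     cv_folds = cv_folds, seed = run_seeds[k],
                     gamma = gamma, tol = tol, maxit = maxit)
    supp <- which(tk$model$beta != 0)
    counts[supp] <- counts[supp] + 1L
    supports[[k]] <- supp
    params[[k]] <- c(lambda = tk$lambda, alpha = tk$alpha)
  }
  f <- counts / K
  structure(
    list(frequencies = f, runs = K, per_run_supports = supports,
         chosen_params = params, ranking = order(-f, seq_len(p)),
         fraction = fraction,
         feature_names = colnames(d$X) %||% paste0("V", seq_len(p))),
    class = "ssshd"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank features by inclusion frequency
#'
#' Stable sort by decreasing inclusion frequency; equal frequencies keep
#' their index order, so the ranking is deterministic.
#'
#' @param res An `ssshd` object from [stability_select()].
#' @return Integer vector: feature indices from most to least stable.
#' @export
rank_features <- function(res) {
  stopifnot(inherits(res, "ssshd"))
  res$ranking
}

#' Select the top q features
#'
#' @param res An `ssshd` object.
#' @param q Number of features to keep, between 1 and p.
#' @return Integer vector of the q top-ranked feature indices.
#' @export
select_top_q <- function(res, q) {
  stopifnot(inherits(res, "ssshd"))
  p <- length(res$frequencies)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 1 || q > p) {
    stop("q must be between 1 and ", p, call. = FALSE)
  }
  res$ranking[seq_len(as.integer(q))]
}

#' Export an inclusion-frequency ranking as TSV
#'
#' Writes columns `feature_id`, `inclusion_frequency`, `rank`.
#'
#' @param res An `ssshd` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ranking <- function(res, path) {
  stopifnot(inherits(res, "ssshd"))
  p <- length(res$frequencies)
  rk <- integer(p)
  rk[res$ranking] <- seq_len(p)
  df <- data.frame(feature_id = res$feature_names,
                   inclusion_frequency = res$frequencies, rank = rk)
  df <- df[res$ranking, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.ssshd <- function(x, ...) {
  cat("sssHD stability selection:", x$runs, "runs, per-class fraction",
      x$fraction, "\n")
  top <- utils::head(x$ranking, 5L)
  cat("  top features:",
      paste0(x$feature_names[top], " (f=",
             format(x$frequencies[top], digits = 2), ")",
             collapse = ", "), "\n")
  invisible(x)
}
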