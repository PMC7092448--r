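# Imbalance-aware evaluation: confusion rates, G-mean, F-measure, ROC and
# precision-recall curves, and the lower-trapezoid area rules.

.check_labels <- function(y) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) {
    stop("labels must be -1 (majority/negative) or +1 (minority/positive)",
         call. = FALSE)
  }
  y
}

#' Confusion counts
#'
#' Counts true/false positives and negatives, with the minority class
#' (+1) as positive and the majority (-1) as negative.
#'
#' @param y_true,y_pred Label vectors in \{-1, +1\} of equal length.
#' @return A list with integer fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- .check_labels(y_true)
  y_pred <- .check_labels(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  list(tp = sum(y_true == 1 & y_pred == 1),
       tn = sum(y_true == -1 & y_pred == -1),
       fp = sum(y_true == -1 & y_pred == 1),
       fn = sum(y_true == 1 & y_pred == -1))
}

.rate <- function(num, den) if (den == 0) 0 else num / den

#' Imbalance-aware rates from confusion counts
#'
#' TPR (recall), TNR, FPR, precision, G-mean (geometric mean of TPR and
#' TNR) and F-measure (harmonic mean of precision and recall). Ratios with
#' a zero denominator return 0, which keeps every metric defined for
#' degenerate classifiers such as the all-negative one.
#'
#' @param cc Confusion counts from [confusion()], or any list with fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @return A list with `tpr`, `tnr`, `fpr`, `precision`, `g_mean`,
#'   `f_measure`.
#' @export
rates <- function(cc) {
  tpr <- .rate(cc$tp, cc$tp + cc$fn)
  tnr <- .rate(cc$tn, cc$tn + cc$fp)
  fpr <- .rate(cc$fp, cc$fp + cc$tn)
  prec <- .rate(cc$tp, cc$tp + cc$fp)
  f <- if (prec + tpr == 0) 0 else 2 * prec * tpr / (prec + tpr)
  list(tpr = tpr, tnr = tnr, fpr = fpr, precision = prec,
       g_mean = sqrt(tpr * tnr), f_measure = f)
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold under the strict
#' "predict positive when score > c" rule, traversed from c = +Inf (the
#' (0,0) corner) down to c = -Inf (the (1,1) corner). Larger scores are
#' associated with the positive class.
#'
#' @param scores Continuous classifier outputs.
#' @param y Labels in \{-1, +1\}, both classes present.
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold (FPR non-decreasing).
#' @export
roc_points <- function(scores, y) {
  y <- .check_labels(y)
  if (length(scores) != length(y)) {
    stop("scores and y must have equal length", call. = FALSE)
  }
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- y[ord] == 1
  grp <- cumsum(!duplicated(s))          # distinct-score groups, descending
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  thr <- unique(s)
  # predicting "> thr[k]" captures groups 1..k-1, i.e. counts up to the end
  # of the previous group
  tpk <- c(0, tp[last][-sum(last)])
  fpk <- c(0, fp[last][-sum(last)])
  data.frame(threshold = c(Inf, thr, -Inf),
             fpr = c(0, fpk / n0, 1),
             tpr = c(0, tpk / n1, 1))
}

# Area under a curve given per-distinct-x departure (max) and arrival (min)
# values of the monotone traversal: trapezoids between the value when the
# curve leaves x_k and the value when it first reaches x_{k+1}. Vertical
# segments contribute nothing; diagonal jumps from tied scores are averaged.
.trapz_grouped <- function(x, v_depart, v_arrive) {
  K <- length(x)
  if (K < 2L) return(0)
  sum(0.5 * (v_depart[-K] + v_arrive[-1L]) * diff(x))
}

#' Area under the ROC curve, lower trapezoidal rule
#'
#' Groups the ROC points of [roc_points()] by distinct FPR value; within a
#' group the TPR rises vertically, contributing no area. Between distinct
#' FPR values the trapezoid connects the highest TPR at the current FPR to
#' the lowest TPR at the next FPR, so score ties shared between classes
#' (diagonal jumps) are credited half, never more. For tie-free scores the
#' result equals the pair-counting (Mann-Whitney) area exactly.
#'
#' @inheritParams roc_points
#' @return A number in \[0, 1\]; 1/2 when all scores are equal.
#' @export
auc_roc_lower_trapezoid <- function(scores, y) {
  pts <- roc_points(scores, y)
  r <- rle(pts$fpr)
  iend <- cumsum(r$lengths)
  istart <- c(1L, utils::head(iend, -1L) + 1L)
  # TPR is non-decreasing along the traversal, so within an FPR group the
  # arrival (min) is the first point and the departure (max) the last
  .trapz_grouped(r$values, pts$tpr[iend], pts$tpr[istart])
}

#' Precision-recall curve points
#'
#' One (recall, precision) point per distinct score threshold under the
#' "> c" rule, plus the (recall = 1) endpoint where everything is predicted
#' positive (precision = prevalence) and a (recall = 0) anchor that carries
#' the precision of the first non-empty prediction set, the standard
#' horizontal extension.
#'
#' @inheritParams roc_points
#' @return A data.frame with columns `threshold`, `recall`, `precision`,
#'   ordered by decreasing threshold (recall non-decreasing).
#' @export
pr_points <- function(scores, y) {
  y <- .check_labels(y)
  if (length(scores) != length(y)) {
    stop("scores and y must have equal length", call. = FALSE)
  }
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- y[ord] == 1
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(grp, fromLast = TRUE)
  thr <- unique(s)
  tpk <- c(tp[last][-sum(last)], tp[length(tp)])
  fpk <- c(fp[last][-sum(last)], fp[length(fp)])
  thr <- c(thr[-1L], -Inf)               # "> c" with c between groups
  keep <- (tpk + fpk) > 0
  thr <- thr[keep]; tpk <- tpk[keep]; fpk <- fpk[keep]
  rec <- tpk / n1
  prec <- tpk / (tpk + fpk)
  data.frame(threshold = c(Inf, thr),
             recall = c(0, rec),
             precision = c(prec[1L], prec))
}

#' Area under the precision-recall curve
#'
#' The same grouped trapezoid convention as
#' [auc_roc_lower_trapezoid()], applied over distinct recall values: along
#' the traversal precision falls within a recall group, so the trapezoid
#' connects the lowest precision at the current recall to the highest at
#' the next. No nonlinear PR interpolation is attempted.
#'
#' @inheritParams roc_points
#' @return A number in \[0, 1\]; equals the prevalence n1/n when all
#'   scores are equal.
#' @export
auc_prc <- function(scores, y) {
  pts <- pr_points(scores, y)
  r <- rle(pts$recall)
  iend <- cumsum(r$lengths)
  istart <- c(1L, utils::head(iend, -1L) + 1L)
  # precision falls within a recall group, so the departure (min) is the
  # last point of the group and the arrival (max) the first
  .trapz_grouped(r$values, pts$precision[iend], pts$precision[istart])
}

#' Export a curve as TSV
#'
#' Writes the data.frame from [roc_points()] or [pr_points()] unchanged.
#'
#' @param curve A curve data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
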