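#' Standard error of the mean
#'
#' \eqn{\mathrm{SEM} = \sqrt{\sum_i (x_i - \bar x)^2 / (N(N-1))}}, the
#' uncertainty of a cross-validation mean over \eqn{N} iterations.
#'
#' @param values numeric vector.
#' @return The SEM; `NA` (with a warning) for fewer than 2 values, never a
#'   silent 0.
#' @export
sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) {
    warning("SEM undefined for fewer than 2 values")
    return(NA_real_)
  }
  sqrt(sum((values - mean(values))^2) / (n * (n - 1)))
}

.sem_quiet <- function(values) {
  n <- length(values)
  if (n < 2L) return(NA_real_)
  sqrt(sum((values - mean(values))^2) / (n * (n - 1)))
}

#' Confusion-matrix rates at a threshold
#'
#' Calls `score >= threshold` positive and reports TPR = TP/(FN+TP),
#' FPR = FP/(TN+FP) and ACC = (TP+TN)/(TP+FP+TN+FN).  A rate whose
#' denominator is empty (no positives for TPR, no negatives for FPR) is
#' returned as `NA`, never coerced to 0.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels of the same length.
#' @param threshold decision threshold.
#' @return A list with `tpr`, `fpr`, `acc` and the counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_rates <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), length(threshold) == 1L)
  .check_binary_response(labels)
  call_pos <- scores >= threshold
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1)
  tn <- sum(!call_pos & labels == 0)
  npos <- tp + fn
  nneg <- fp + tn
  list(tpr = if (npos > 0) tp / npos else NA_real_,
       fpr = if (nneg > 0) fp / nneg else NA_real_,
       acc = (tp + tn) / length(scores),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Threshold grid over a score range
#'
#' Partitions the empirical score range into equal steps of at most `step`
#' after min-max rescaling to \[0, 1\], giving the ascending threshold grid
#' used for mean ROC curves.
#'
#' @param scores pooled numeric scores.
#' @param step maximum threshold step on the rescaled scale (default 0.05).
#' @return Ascending numeric thresholds spanning the score range.
#' @export
roc_thresholds <- function(scores, step = 0.05) {
  stopifnot(step > 0, step <= 1)
  rng <- range(scores)
  if (diff(rng) == 0) return(rng[1])
  rng[1] + diff(rng) * seq(0, 1, by = step)
}

#' Per-threshold positive-call fractions of one fold
#'
#' The fraction of a held-out patient's voxels called positive at each
#' threshold.  Under leave-one-patient-out a fold has a single label, so
#' this fraction is the fold's TPR contribution when the patient is mutated
#' and its FPR contribution when wild-type.
#'
#' @param scores the fold's voxel scores (non-empty).
#' @param thresholds ascending threshold grid.
#' @return Numeric vector of fractions, non-increasing in threshold.
#' @export
fold_curve <- function(scores, thresholds) {
  if (!length(scores)) stop("empty score vector")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  vapply(thresholds, function(t) mean(scores >= t), 0)
}

#' Trapezoidal area under an ROC polyline
#'
#' \eqn{\mathrm{AUC} \approx \frac12 \sum_i (\mathrm{FPR}_{i+1} -
#' \mathrm{FPR}_i)(\mathrm{TPR}_i + \mathrm{TPR}_{i+1})} over points sorted
#' by FPR.  Over the full set of empirical thresholds of pooled two-class
#' scores this equals the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \frac12 P(s^+ = s^-)} exactly.
#'
#' @param fpr,tpr coordinates in \[0, 1\], sorted by ascending FPR, with the
#'   anchor points (0, 0) and (1, 1) present.
#' @return The AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(fpr, tpr) {
  n <- length(fpr)
  stopifnot(length(tpr) == n, n >= 2)
  if (anyNA(fpr) || anyNA(tpr)) stop("NA rates in ROC input")
  if (any(fpr < 0 | fpr > 1 | tpr < 0 | tpr > 1))
    stop("rates must lie in [0, 1]")
  if (is.unsorted(fpr)) stop("points must be sorted by ascending FPR")
  if (fpr[1] != 0 || tpr[1] != 0 || fpr[n] != 1 || tpr[n] != 1)
    stop("ROC polyline must contain the anchor points (0,0) and (1,1)")
  sum(diff(fpr) * (tpr[-n] + tpr[-1])) / 2
}

#' Pooled-score empirical AUC
#'
#' Trapezoidal AUC over all empirical thresholds of the pooled scores
#' (every distinct score value), equivalent to the Mann-Whitney statistic
#' including the half-weight tie term.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return The AUC.
#' @export
pooled_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  .check_binary_response(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("pooled AUC needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  n <- length(s)
  ends <- c(s[-n] != s[-1], TRUE)  # last position of each distinct score
  tpr <- c(0, cumsum(y)[ends] / npos)
  fpr <- c(0, cumsum(1 - y)[ends] / nneg)
  auc_trapezoid(fpr, tpr)
}

#' Mean ROC curve over leave-one-patient-out folds
#'
#' Each fold holds one patient's scores and a single label; mutated folds
#' contribute per-threshold TPR curves and wild-type folds FPR curves (see
#' [fold_curve()]).  Curves are averaged per threshold within each class,
#' with a per-threshold SEM over the contributing folds, and the AUC is the
#' trapezoidal area of the (mean FPR, mean TPR) polyline augmented with the
#' (0,0) and (1,1) anchors.  A per-fold AUC is reconstructed by pairing
#' each fold's own curve with the opposite class's mean curve.
#'
#' @param folds list of folds, each a list with `scores` (numeric voxel
#'   scores), `label` (0/1) and optionally `fold_id`.
#' @param thresholds ascending threshold grid; default
#'   `roc_thresholds(all pooled scores, step)`.
#' @param step threshold step for the default grid.
#' @param gene optional gene name, used in messages and stored.
#' @return An object of class `"roc_curve"` with `thresholds`, `mean_tpr`,
#'   `mean_fpr`, `sem_tpr`, `sem_fpr`, `auc`, `fold_aucs` (named per fold),
#'   `n_pos`, `n_neg`.
#' @export
mean_roc <- function(folds, thresholds = NULL, step = 0.05, gene = NULL) {
  if (!length(folds)) stop("no folds supplied")
  labels <- vapply(folds, function(f) as.numeric(f$label), 0)
  .check_binary_response(labels)
  ids <- vapply(seq_along(folds), function(i) {
    id <- folds[[i]]$fold_id
    if (is.null(id)) sprintf("fold%d", i) else as.character(id)
  }, "")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop(sprintf(paste0("imbalanced target%s: need at least one mutated and ",
                        "one wild-type fold (%d positive, %d negative)"),
         if (is.null(gene)) "" else paste0(" for gene ", gene),
         n_pos, n_neg))
  if (is.null(thresholds))
    thresholds <- roc_thresholds(unlist(lapply(folds, `[[`, "scores")), step)
  curves <- t(vapply(folds, function(f) fold_curve(f$scores, thresholds),
                     numeric(length(thresholds))))
  pos <- labels == 1
  mean_tpr <- colMeans(curves[pos, , drop = FALSE])
  mean_fpr <- colMeans(curves[!pos, , drop = FALSE])
  sem_tpr <- apply(curves[pos, , drop = FALSE], 2, .sem_quiet)
  sem_fpr <- apply(curves[!pos, , drop = FALSE], 2, .sem_quiet)

  path <- function(f, t) auc_trapezoid(c(0, rev(f), 1), c(0, rev(t), 1))
  auc <- path(mean_fpr, mean_tpr)
  fold_aucs <- vapply(seq_along(folds), function(i) {
    if (pos[i]) path(mean_fpr, curves[i, ]) else path(curves[i, ], mean_tpr)
  }, 0)
  names(fold_aucs) <- ids

  structure(list(thresholds = thresholds, mean_tpr = mean_tpr,
                 mean_fpr = mean_fpr, sem_tpr = sem_tpr, sem_fpr = sem_fpr,
                 auc = auc, fold_aucs = fold_aucs, fold_labels = labels,
                 n_pos = n_pos, n_neg = n_neg, gene = gene),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Mean ROC%s over %d folds (%d mutated, %d wild-type)\n",
              if (is.null(x$gene)) "" else paste0(" [", x$gene, "]"),
              length(x$fold_labels), x$n_pos, x$n_neg))
  cat(sprintf("  %d thresholds; mean-curve AUC = %.3f; per-fold AUC = %.3f +/- %.3f (SEM)\n",
              length(x$thresholds), x$auc, mean(x$fold_aucs),
              .sem_quiet(x$fold_aucs)))
  invisible(x)
}

#' Plot a mean ROC curve with its SEM band
#'
#' @param x a [mean_roc()] result.
#' @param band draw the per-threshold TPR SEM band (default `TRUE`).
#' @param col curve color.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_curve <- function(x, band = TRUE, col = "navy", ...) {
  fpr <- c(0, rev(x$mean_fpr), 1)
  tpr <- c(0, rev(x$mean_tpr), 1)
  plot(fpr, tpr, type = "l", col = col, lwd = 2,
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  if (band && any(!is.na(x$sem_tpr))) {
    up <- pmin(rev(x$mean_tpr + ifelse(is.na(x$sem_tpr), 0, x$sem_tpr)), 1)
    lo <- pmax(rev(x$mean_tpr - ifelse(is.na(x$sem_tpr), 0, x$sem_tpr)), 0)
    polygon(c(rev(x$mean_fpr), rev(rev(x$mean_fpr))),
            c(up, rev(lo)), border = NA, col = adjustcolor(col, 0.2))
    lines(fpr, tpr, col = col, lwd = 2)
  }
  abline(0, 1, lty = 3, col = "grey50")
  legend("bottomright", bty = "n",
         legend = sprintf("%sAUC = %.3f",
                          if (is.null(x$gene)) "" else paste0(x$gene, ": "),
                          x$auc))
  invisible(x)
}

#' Pooled accuracy at a target false positive rate
#'
#' Selects the threshold of a mean ROC curve whose mean FPR is nearest to
#' `target_fpr` (ties to the lower threshold) and reports the pooled
#' accuracy over all fold voxels at that threshold.
#'
#' @param roc a [mean_roc()] result.
#' @param folds the fold list used to build `roc`.
#' @param target_fpr operating point (default 0.2).
#' @return A list with `acc`, `threshold` and `fpr` (the mean FPR actually
#'   attained).  `acc` is `NA` with a warning when the curve does not span
#'   `target_fpr`.
#' @export
acc_at_fpr <- function(roc, folds, target_fpr = 0.2) {
  stopifnot(inherits(roc, "roc_curve"))
  if (target_fpr < min(roc$mean_fpr) || target_fpr > max(roc$mean_fpr)) {
    warning(sprintf("mean ROC does not span FPR %.2f; ACC undefined",
                    target_fpr))
    return(list(acc = NA_real_, threshold = NA_real_, fpr = NA_real_))
  }
  idx <- which.min(abs(roc$mean_fpr - target_fpr))  # first hit = lower threshold
  thr <- roc$thresholds[idx]
  scores <- unlist(lapply(folds, `[[`, "scores"))
  labels <- unlist(lapply(seq_along(folds), function(i)
    rep(as.numeric(folds[[i]]$label), length(folds[[i]]$scores))))
  list(acc = mean((scores >= thr) == labels), threshold = thr,
       fpr = roc$mean_fpr[idx])
}

#' One-way ANOVA on AUC scores across contrast combinations
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test with \eqn{k-1} and \eqn{N-k} degrees of freedom) comparing AUC
#' distributions between groups, as used to compare contrast combinations.
#'
#' @param groups a named list of numeric AUC vectors, one per group; at
#'   least 2 groups with at least 2 finite values each.
#' @return An object of class `"htest"` with the F statistic, degrees of
#'   freedom and p-value.
#' @examples
#' auc_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))$statistic  # F = 13.5
#' @export
auc_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  sizes <- vapply(groups, function(g) sum(is.finite(g)), 0L)
  if (any(sizes < 2L))
    stop("degenerate groups: every group needs at least 2 finite values")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups))))
  df <- df[is.finite(df$value), ]
  stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
}
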