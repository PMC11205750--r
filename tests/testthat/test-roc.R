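test_that("sem matches its definition and flags undefined inputs", {
  expect_equal(sem(c(1, 1, 1)), 0)
  expect_equal(sem(c(0, 1)), 0.5)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(sample(3:30, 1))
    expect_equal(sem(x), sd(x) / sqrt(length(x)), tolerance = 1e-12)
  }
  expect_warning(v <- sem(3), "fewer than 2")
  expect_true(is.na(v))
})

test_that("confusion rates follow their defining formulas", {
  r <- confusion_rates(c(.9, .8, .3, .1), c(1, 1, 0, 0), 0.5)
  expect_equal(r$tpr, 1)
  expect_equal(r$fpr, 0)
  expect_equal(r$acc, 1)

  r0 <- confusion_rates(c(.9, .8, .3, .1), c(1, 1, 0, 0), 0)
  expect_equal(r0$tpr, 1)
  expect_equal(r0$fpr, 1)
  expect_equal(r0$acc, 0.5)

  # empty denominators stay NA, never silently 0
  r1 <- confusion_rates(c(.2, .8), c(1, 1), 0.5)
  expect_true(is.na(r1$fpr))
  expect_equal(r1$tpr, 0.5)

  # brute-force counting oracle across all empirical thresholds
  set.seed(31)
  scores <- round(runif(200), 2)
  labels <- rbinom(200, 1, 0.4)
  for (t in sort(unique(scores))) {
    got <- confusion_rates(scores, labels, t)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_along(scores)) {
      pos <- scores[i] >= t
      if (pos && labels[i] == 1) tp <- tp + 1
      if (pos && labels[i] == 0) fp <- fp + 1
      if (!pos && labels[i] == 0) tn <- tn + 1
      if (!pos && labels[i] == 1) fn <- fn + 1
    }
    expect_equal(got$tpr, tp / (tp + fn))
    expect_equal(got$fpr, fp / (fp + tn))
    expect_equal(got$acc, (tp + tn) / 200)
  }
})

test_that("fold curves are positive-call fractions at each threshold", {
  th <- seq(0, 1, by = 0.1)
  expect_equal(fold_curve(c(2, 3, 4), th), rep(1, length(th)))
  # all scores below the minimum threshold: FPR contribution identically 0
  expect_equal(fold_curve(c(-2, -1), th), rep(0, length(th)))
  set.seed(5)
  sc <- runif(50)
  expect_equal(fold_curve(sc, th),
               vapply(th, function(t) sum(sc >= t) / 50, 0))
  expect_error(fold_curve(numeric(0), th), "empty")
  expect_error(fold_curve(sc, rev(th)), "ascending")
})

test_that("trapezoidal AUC handles anchors, rejects bad input, and equals Mann-Whitney on pooled scores", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 1)), 0.5)
  expect_equal(auc_trapezoid(c(0, 0, 1), c(0, 1, 1)), 1)
  expect_error(auc_trapezoid(c(0.1, 1), c(0, 1)), "anchor")
  expect_error(auc_trapezoid(c(0, 0.6, 0.4, 1), c(0, 0.5, 0.6, 1)),
               "ascending")
  expect_error(auc_trapezoid(c(0, 2), c(0, 1)), "0, 1")

  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    scores <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE) / 5
    expect_equal(pooled_auc(scores, labels), mw_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("mean ROC averages fold curves by class with per-threshold SEM", {
  th <- seq(-2, 2, by = 0.25)
  folds <- list(
    list(fold_id = "P1", scores = seq(0.5, 1.5, length.out = 100), label = 1),
    list(fold_id = "P2", scores = seq(0.6, 1.8, length.out = 100), label = 1),
    list(fold_id = "P3", scores = seq(-1.5, -0.5, length.out = 100), label = 0),
    list(fold_id = "P4", scores = seq(-1.8, -0.6, length.out = 100), label = 0))
  roc <- mean_roc(folds, thresholds = th)
  expect_equal(roc$auc, 1)
  expect_equal(unname(roc$fold_aucs), rep(1, 4))

  # hand-computed means and SEM at every threshold
  c1 <- fold_curve(folds[[1]]$scores, th)
  c2 <- fold_curve(folds[[2]]$scores, th)
  expect_equal(roc$mean_tpr, (c1 + c2) / 2)
  expect_equal(roc$sem_tpr,
               vapply(seq_along(th), function(i)
                 sd(c(c1[i], c2[i])) / sqrt(2), 0))

  # identical folds -> SEM exactly 0
  same <- list(list(scores = c(1, 2, 3), label = 1),
               list(scores = c(1, 2, 3), label = 1),
               list(scores = c(-1, 0), label = 0),
               list(scores = c(-1, 0), label = 0))
  roc2 <- mean_roc(same)
  expect_true(all(roc2$sem_tpr == 0))
  expect_true(all(roc2$sem_fpr == 0))

  # monotone non-increasing mean curves
  expect_true(all(diff(roc$mean_tpr) <= 0))
  expect_true(all(diff(roc$mean_fpr) <= 0))

  # single-class folds are an explicit imbalance error
  expect_error(mean_roc(list(list(scores = 1:3, label = 1),
                             list(scores = 1:3, label = 1)),
                        gene = "PTEN"),
               "imbalanced target.*PTEN")
})

test_that("ROC construction is invariant under strictly increasing score transforms", {
  set.seed(43)
  folds <- lapply(1:6, function(i)
    list(fold_id = i, scores = rnorm(80, mean = i %% 2),
         label = i %% 2))
  r1 <- mean_roc(folds, step = 0.1)
  warped <- lapply(folds, function(f) {
    f$scores <- exp(f$scores / 2)
    f
  })
  # same grid positions after min-max rescaling need not hold exactly for a
  # nonlinear warp, so compare the rank-based pooled AUC instead
  sc <- unlist(lapply(folds, `[[`, "scores"))
  lb <- unlist(lapply(folds, function(f) rep(f$label, length(f$scores))))
  expect_equal(pooled_auc(exp(sc / 2), lb), pooled_auc(sc, lb),
               tolerance = 1e-12)
  # affine transforms preserve the rescaled threshold grid, hence the curve
  shifted <- lapply(folds, function(f) {
    f$scores <- 5 * f$scores - 2
    f
  })
  r3 <- mean_roc(shifted, step = 0.1)
  expect_equal(r3$mean_tpr, r1$mean_tpr, tolerance = 1e-12)
  expect_equal(r3$auc, r1$auc, tolerance = 1e-12)
})

test_that("accuracy at the target FPR picks the nearest threshold and pools voxels", {
  th <- c(0, 1, 2, 3)
  folds <- list(list(scores = c(2.5, 2.5, 2.5, 0.5), label = 1),
                list(scores = c(2.6, 2.4, 0.1, 0.2), label = 1),
                list(scores = c(0.5, 0.5, 2.5, 0.5), label = 0),
                list(scores = c(0.4, 0.6, 2.4, 0.9), label = 0))
  roc <- mean_roc(folds, thresholds = th)
  got <- acc_at_fpr(roc, folds, target_fpr = 0.2)
  # manual nearest-FPR inspection over the 4-point curve
  manual_idx <- which.min(abs(roc$mean_fpr - 0.2))
  expect_equal(got$threshold, th[manual_idx])
  sc <- unlist(lapply(folds, `[[`, "scores"))
  lb <- rep(c(1, 1, 0, 0), each = 4)
  expect_equal(got$acc, mean((sc >= got$threshold) == lb))

  # a perfect classifier with a wide class gap: the threshold nearest
  # FPR 0.2 falls in the gap, so pooled accuracy is 1
  perfect <- list(list(scores = c(5.0, 5.1), label = 1),
                  list(scores = c(5.2, 5.3), label = 1),
                  list(scores = c(-5.0, -5.1), label = 0),
                  list(scores = c(-5.2, -5.3), label = 0))
  rp <- mean_roc(perfect)
  expect_equal(acc_at_fpr(rp, perfect, 0.2)$acc, 1)
})

test_that("one-way ANOVA matches hand computation and a brute-force oracle", {
  ident <- auc_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(unname(ident$statistic), 0)
  expect_equal(ident$p.value, 1)

  ht <- auc_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(unname(ht$statistic), 13.5)

  set.seed(47)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1),
                                                   mean = j / 2))
    names(groups) <- paste0("g", seq_len(k))
    got <- auc_anova(groups)
    want <- brute_anova(groups)
    expect_equal(unname(got$statistic), want$F, tolerance = 1e-9)
    expect_equal(got$p.value, want$p, tolerance = 1e-9)
  }

  expect_error(auc_anova(list(a = 1:3)), "2 groups")
  expect_error(auc_anova(list(a = 1:3, b = 2)), "degenerate")
})
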