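#' Enumerate contrast combinations
#'
#' All non-empty subsets of the available contrasts, ordered by cardinality
#' (single, double, ...) and, within a cardinality, lexicographically by
#' the canonical contrast order of the input.  Five contrasts give the 31
#' combinations in groups of 5, 10, 10, 5 and 1.
#'
#' @param contrasts ordered character vector of distinct contrast names
#'   (1 to 8).
#' @return A named list of character vectors (names join the members with
#'   `"+"`), with an integer attribute `"cardinality"` giving each subset's
#'   size.
#' @examples
#' length(contrast_combinations(mri_contrasts()))  # 31
#' @export
contrast_combinations <- function(contrasts) {
  k <- length(contrasts)
  if (k < 1L || k > 8L) stop("need between 1 and 8 contrasts")
  if (anyDuplicated(contrasts)) stop("duplicate contrast names")
  out <- list()
  card <- integer(0)
  for (m in seq_len(k)) {
    sets <- combn(contrasts, m, simplify = FALSE)
    out <- c(out, sets)
    card <- c(card, rep.int(m, length(sets)))
  }
  names(out) <- vapply(out, paste, "", collapse = "+")
  attr(out, "cardinality") <- card
  out
}

#' Leave-one-patient-out sweep over genes and contrast combinations
#'
#' Runs the full study grid: for every retained gene, every contrast
#' combination and every patient fold, fits a boosted-stump GAM on the
#' remaining patients' voxel feature matrix, scores the held-out patient's
#' voxels, and evaluates a mean ROC with SEM bands, trapezoidal AUC, pooled
#' AUC, and pooled accuracy at the target FPR operating point.  Genes with
#' fewer than `min_class` mutated or wild-type patients are skipped with a
#' warning (recorded, not failed).  Fold scores are centered by subtracting
#' each fold's fitted intercept, which removes the class-prior shift the
#' intercept inherits from the held-out label under leave-one-patient-out
#' (see the methods vignette); `center = FALSE` keeps raw predictions.
#'
#' Every fit is audited for train/test leakage (the held-out patient must
#' not appear in the training rows) and for a non-increasing training
#' deviance trace.
#'
#' @param cohort an `"mri_cohort"` (or any object with the same layout).
#' @param genes genes to analyse (default: all in the cohort).
#' @param contrasts contrasts available (default: all in the cohort).
#' @param combinations list of contrast subsets (default:
#'   [contrast_combinations()] of `contrasts`).
#' @param n_rounds,learning_rate,feature_policy passed to [gam_boost_fit()].
#' @param threshold_step maximum ROC threshold step on the rescaled score
#'   range.
#' @param normalize,reference_contrast passed to [build_feature_matrix()].
#' @param min_class minimum mutated and wild-type patients per retained
#'   gene.
#' @param center subtract each fold's intercept from its scores.
#' @param target_fpr operating point for the pooled accuracy.
#' @return An object of class `"lopo_sweep"`; see `summary()` and `plot()`
#'   methods.  Components include `results` (one row per gene x
#'   combination), `fold_aucs` (long table of per-fold AUCs), `rocs`
#'   (nested list of `"roc_curve"` objects), `skipped`, `n_fits`,
#'   `leakage_violations` and `deviance_monotone`.
#' @export
lopo_sweep <- function(cohort, genes = NULL, contrasts = NULL,
                       combinations = NULL, n_rounds = 300,
                       learning_rate = 0.1,
                       feature_policy = c("cyclic", "best"),
                       threshold_step = 0.05,
                       normalize = c("per-contrast", "reference"),
                       reference_contrast = "T1W-CE",
                       min_class = 2, center = TRUE, target_fpr = 0.2) {
  feature_policy <- match.arg(feature_policy)
  normalize <- match.arg(normalize)
  patients <- if (inherits(cohort, "mri_cohort")) cohort$patients else cohort
  if (length(patients) < 3L) stop("need at least 3 patients")
  if (is.null(contrasts)) contrasts <- names(patients[[1]]$volumes)
  if (is.null(genes)) genes <- names(patients[[1]]$genotype)
  if (is.null(combinations)) combinations <- contrast_combinations(contrasts)

  pids <- vapply(patients, `[[`, "", "patient_id")
  geno <- vapply(patients, function(p) as.numeric(p$genotype[genes]),
                 numeric(length(genes)))
  geno <- matrix(geno, nrow = length(genes),
                 dimnames = list(genes, pids))

  # normalized per-voxel features, computed once for all combinations
  fm <- build_feature_matrix(patients, contrasts, genes[1],
                             normalize = normalize,
                             reference_contrast = reference_contrast)
  X <- as.matrix(fm[, contrasts, drop = FALSE])
  pid_row <- fm$patient_id

  n_pos <- rowSums(geno == 1)
  n_neg <- rowSums(geno == 0)
  keep <- n_pos >= min_class & n_neg >= min_class
  skipped <- data.frame(gene = genes[!keep], n_pos = n_pos[!keep],
                        n_neg = n_neg[!keep],
                        reason = rep("imbalanced target", sum(!keep)),
                        row.names = NULL)
  if (nrow(skipped))
    warning("skipping imbalanced gene(s): ",
            paste(skipped$gene, collapse = ", "))
  run_genes <- genes[keep]

  results <- list()
  fold_rows <- list()
  rocs <- list()
  n_fits <- 0L
  leakage <- 0L
  dev_ok <- TRUE

  for (gene in run_genes) {
    y_vox <- geno[gene, pid_row]
    rocs[[gene]] <- list()
    for (ci in seq_along(combinations)) {
      comb <- combinations[[ci]]
      comb_name <- names(combinations)[ci]
      folds <- vector("list", length(pids))
      for (fi in seq_along(pids)) {
        test_id <- pids[fi]
        train <- pid_row != test_id
        if (test_id %in% pid_row[train]) leakage <- leakage + 1L
        fit <- gam_boost_fit(X[train, comb, drop = FALSE], y_vox[train],
                             n_rounds = n_rounds,
                             learning_rate = learning_rate,
                             feature_policy = feature_policy)
        n_fits <- n_fits + 1L
        tr <- fit$deviance_trace
        if (any(diff(c(fit$null_deviance, tr)) >
                1e-8 * max(1, fit$null_deviance)))
          dev_ok <- FALSE
        sc <- predict(fit, X[!train, comb, drop = FALSE])
        if (center) sc <- sc - fit$intercept
        folds[[fi]] <- list(fold_id = test_id, scores = sc,
                            label = geno[gene, test_id])
      }
      roc <- mean_roc(folds, step = threshold_step, gene = gene)
      acc <- acc_at_fpr(roc, folds, target_fpr = target_fpr)
      pooled <- pooled_auc(unlist(lapply(folds, `[[`, "scores")),
                           unlist(lapply(seq_along(folds), function(i)
                             rep(folds[[i]]$label,
                                 length(folds[[i]]$scores)))))
      rocs[[gene]][[comb_name]] <- roc
      results[[length(results) + 1L]] <- data.frame(
        gene = gene, combination = comb_name,
        n_contrasts = length(comb),
        auc_mean_curve = roc$auc,
        auc_fold_mean = mean(roc$fold_aucs),
        auc_fold_sem = .sem_quiet(roc$fold_aucs),
        auc_pooled = pooled,
        acc_at_target_fpr = acc$acc,
        acc_threshold = acc$threshold,
        n_folds = length(folds))
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        gene = gene, combination = comb_name,
        n_contrasts = length(comb),
        fold = names(roc$fold_aucs), auc = unname(roc$fold_aucs))
    }
  }

  structure(list(
    results = if (length(results)) do.call(rbind, results) else NULL,
    fold_aucs = if (length(fold_rows)) do.call(rbind, fold_rows) else NULL,
    rocs = rocs,
    skipped = skipped,
    genes = run_genes,
    contrasts = contrasts,
    combinations = combinations,
    n_fits = n_fits,
    leakage_violations = leakage,
    deviance_monotone = dev_ok,
    target_fpr = target_fpr,
    settings = list(n_rounds = n_rounds, learning_rate = learning_rate,
                    feature_policy = feature_policy,
                    threshold_step = threshold_step, normalize = normalize,
                    min_class = min_class, center = center)
  ), class = "lopo_sweep")
}

#' @export
print.lopo_sweep <- function(x, ...) {
  cat(sprintf("LOPO sweep: %d genes x %d combinations x %d folds = %d fits\n",
              length(x$genes), length(x$combinations),
              if (!is.null(x$results)) x$results$n_folds[1] else 0L,
              x$n_fits))
  cat(sprintf("  leakage violations: %d; deviance monotone: %s\n",
              x$leakage_violations, x$deviance_monotone))
  if (nrow(x$skipped))
    cat("  skipped:", paste(x$skipped$gene, collapse = ", "), "\n")
  if (!is.null(x$results)) {
    agg <- tapply(x$results$auc_fold_mean, x$results$gene, mean)
    cat("  mean AUC per gene (over combinations):\n")
    print(round(agg, 3))
  }
  invisible(x)
}

#' Summarize a LOPO sweep
#'
#' Aggregates the sweep into the study's report tables: per (gene,
#' cardinality group) the combination with the highest mean per-fold AUC,
#' per-gene one-way ANOVA comparing per-fold AUCs across combinations, and
#' gene-level means.
#'
#' @param object a [lopo_sweep()] result.
#' @param ... unused.
#' @return A `"summary.lopo_sweep"` list with `best_per_group`, `anova`
#'   (gene, F, df1, df2, p), `per_gene` and the full `results` table.
#' @export
summary.lopo_sweep <- function(object, ...) {
  res <- object$results
  if (is.null(res)) stop("empty sweep: no genes were analysed")
  best <- do.call(rbind, lapply(split(res, res[c("gene", "n_contrasts")]),
    function(d) d[which.max(d$auc_fold_mean), ]))
  best <- best[order(best$gene, best$n_contrasts), ]
  rownames(best) <- NULL

  anova_tab <- do.call(rbind, lapply(object$genes, function(g) {
    fa <- object$fold_aucs[object$fold_aucs$gene == g, ]
    ht <- auc_anova(split(fa$auc, fa$combination))
    data.frame(gene = g, F = unname(ht$statistic),
               df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
               p = ht$p.value)
  }))

  per_gene <- do.call(rbind, lapply(split(res, res$gene), function(d)
    data.frame(gene = d$gene[1],
               mean_auc = mean(d$auc_fold_mean),
               mean_auc_pooled = mean(d$auc_pooled),
               mean_acc = mean(d$acc_at_target_fpr, na.rm = TRUE),
               best_combination = d$combination[which.max(d$auc_fold_mean)],
               best_auc = max(d$auc_fold_mean))))
  rownames(per_gene) <- NULL

  structure(list(best_per_group = best, anova = anova_tab,
                 per_gene = per_gene, results = res,
                 n_fits = object$n_fits, skipped = object$skipped),
            class = "summary.lopo_sweep")
}

#' @export
print.summary.lopo_sweep <- function(x, ...) {
  cat("LOPO sweep summary\n\nPer-gene overview:\n")
  print(x$per_gene, row.names = FALSE, digits = 3)
  cat("\nBest combination per cardinality group:\n")
  print(x$best_per_group[c("gene", "n_contrasts", "combination",
                           "auc_fold_mean", "auc_fold_sem")],
        row.names = FALSE, digits = 3)
  cat("\nOne-way ANOVA of per-fold AUC across combinations:\n")
  print(x$anova, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot best-per-group AUC bars for one gene
#'
#' Bar chart of the highest-mean-AUC combination in each cardinality group
#' with SEM error bars.
#'
#' @param x a [lopo_sweep()] result.
#' @param gene gene to plot (default: first analysed gene).
#' @param ... passed to [barplot()].
#' @return `x`, invisibly.
#' @export
plot.lopo_sweep <- function(x, gene = NULL, ...) {
  if (is.null(gene)) gene <- x$genes[1]
  s <- summary(x)
  b <- s$best_per_group[s$best_per_group$gene == gene, ]
  if (!nrow(b)) stop("gene not present in sweep: ", gene)
  mids <- barplot(b$auc_fold_mean, names.arg = b$combination,
                  ylim = c(0, 1.05), las = 2, cex.names = 0.7,
                  ylab = "Mean AUC", main = gene, ...)
  segments(mids, b$auc_fold_mean - b$auc_fold_sem,
           mids, b$auc_fold_mean + b$auc_fold_sem)
  abline(h = 0.5, lty = 3, col = "grey50")
  invisible(x)
}

#' Write sweep result tables to CSV
#'
#' Writes `results.csv`, `fold_aucs.csv`, `best_per_group.csv`,
#' `anova.csv` and `skipped.csv` into a directory.
#'
#' @param sweep a [lopo_sweep()] result.
#' @param directory output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_results <- function(sweep, directory) {
  stopifnot(inherits(sweep, "lopo_sweep"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  s <- summary(sweep)
  paths <- c(results = file.path(directory, "results.csv"),
             fold_aucs = file.path(directory, "fold_aucs.csv"),
             best_per_group = file.path(directory, "best_per_group.csv"),
             anova = file.path(directory, "anova.csv"),
             skipped = file.path(directory, "skipped.csv"))
  write.csv(s$results, paths["results"], row.names = FALSE)
  write.csv(sweep$fold_aucs, paths["fold_aucs"], row.names = FALSE)
  write.csv(s$best_per_group, paths["best_per_group"], row.names = FALSE)
  write.csv(s$anova, paths["anova"], row.names = FALSE)
  write.csv(sweep$skipped, paths["skipped"], row.names = FALSE)
  invisible(paths)
}
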