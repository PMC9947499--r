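#' Fit a two-class linear discriminant model
#'
#' Gaussian equal-covariance LDA: class means, pooled within-class
#' covariance with optional shrinkage toward the scaled identity
#' (`(1 - lambda) S + lambda * mean(diag(S)) * I`), and log-priors estimated
#' from training class frequencies unless supplied. With two-dimensional
#' avalanche features and small folds the pooled covariance can be
#' near-singular, hence the shrinkage default of 0.1.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y class labels (coercible to a 2-level factor); levels are kept in
#'   sorted order, which fixes the prediction tie-break.
#' @param shrinkage shrinkage weight lambda in [0, 1].
#' @param priors optional named prior probabilities (must sum to 1).
#' @return object of class `lda_model`.
#' @export
lda_fit <- function(x, y, shrinkage = 0.1, priors = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2)
    stop("lda_fit is a two-class model; got ", nlevels(y), " level(s)", call. = FALSE)
  y <- factor(y, levels = sort(levels(y)))
  if (any(table(y) < 2))
    stop("each class needs at least 2 samples", call. = FALSE)
  stop_if_not_scalar_number(shrinkage, "shrinkage", min = 0, max = 1)
  p <- ncol(x)
  means <- matrix(NA_real_, 2, p, dimnames = list(levels(y), colnames(x)))
  for (l in levels(y)) means[l, ] <- colMeans(x[y == l, , drop = FALSE])
  pooled <- matrix(0, p, p)
  for (l in levels(y)) {
    xi <- x[y == l, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(xi, 2, colMeans(xi)))
  }
  pooled <- pooled / (nrow(x) - 2)
  cov <- (1 - shrinkage) * pooled + shrinkage * mean(diag(pooled)) * diag(p)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch))
    stop("pooled covariance is singular; increase `shrinkage`", call. = FALSE)
  if (is.null(priors)) {
    priors <- as.numeric(table(y)) / length(y)
    names(priors) <- levels(y)
  } else {
    if (!isTRUE(all.equal(sum(priors), 1)))
      stop("priors must sum to 1", call. = FALSE)
    priors <- priors[levels(y)]
  }
  structure(list(class_means = means, pooled_covariance = cov,
                 shrinkage = shrinkage, log_priors = log(priors),
                 class_labels = levels(y), cov_chol = ch,
                 feature_names = colnames(x)),
            class = "lda_model")
}

#' Predict with a linear discriminant model
#'
#' Assigns the class maximising the linear discriminant
#' `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`; exact score ties go to
#' the lexicographically first class label.
#'
#' @param model an [lda_fit()] model.
#' @param x feature matrix (samples x features) matching the model dimension.
#' @return list with `class` (factor), `scores` (samples x 2 discriminant
#'   matrix) and `posterior` (samples x 2).
#' @export
lda_predict <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  x <- as.matrix(x)
  p <- ncol(model$class_means)
  if (ncol(x) != p)
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 p, ncol(x)), call. = FALSE)
  inv <- chol2inv(model$cov_chol)
  scores <- vapply(seq_len(2), function(k) {
    mu <- model$class_means[k, ]
    drop(x %*% (inv %*% mu)) - drop(mu %*% inv %*% mu) / 2 + model$log_priors[k]
  }, numeric(nrow(x)))
  if (nrow(x) == 1) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- model$class_labels
  # which.max takes the first maximum: lexicographic tie-break (labels sorted)
  cls <- factor(model$class_labels[apply(scores, 1, which.max)],
                levels = model$class_labels)
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  list(class = cls, scores = scores, posterior = post)
}

#' Confusion counts and the four reported metrics
#'
#' Sensitivity = TP/P, specificity = TN/N, PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). A zero denominator yields `NA` with a warning - an
#' undefined ratio is surfaced, never silently imputed.
#'
#' @param y_true,y_pred binary label vectors over the same two classes.
#' @param positive_class the label counted as positive.
#' @return list with `counts` (named TP/FP/TN/FN), `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @export
confusion_metrics <- function(y_true, y_pred, positive_class) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  labs <- unique(c(y_true, y_pred))
  if (!positive_class %in% labs)
    stop("positive class ", positive_class, " not among the labels", call. = FALSE)
  if (length(labs) > 2)
    stop("labels are not binary: ", paste(labs, collapse = ", "), call. = FALSE)
  pos <- y_true == positive_class
  pred_pos <- y_pred == positive_class
  counts <- c(TP = sum(pos & pred_pos), FP = sum(!pos & pred_pos),
              TN = sum(!pos & !pred_pos), FN = sum(pos & !pred_pos))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    unname(num / den)
  }
  list(counts = counts,
       sensitivity = ratio(counts["TP"], counts["TP"] + counts["FN"], "sensitivity"),
       specificity = ratio(counts["TN"], counts["TN"] + counts["FP"], "specificity"),
       ppv = ratio(counts["TP"], counts["TP"] + counts["FP"], "PPV"),
       npv = ratio(counts["TN"], counts["TN"] + counts["FN"], "NPV"))
}

#' Stratified train/test split
#'
#' Splits sample indices into train and test sets while maintaining every
#' stratum's proportion (per-stratum test share within one sample of
#' `test_fraction`).
#'
#' @param strata stratum label per sample (e.g. the cohort).
#' @param test_fraction fraction held out, in (0, 1) (default 0.3).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (a partition of
#'   `seq_along(strata)`).
#' @export
stratified_split <- function(strata, test_fraction = 0.3, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  strata <- as.character(strata)
  if (any(table(strata) < 2))
    stop("every stratum needs at least 2 members", call. = FALSE)
  with_seed(seed, {
    test <- integer(0)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      n_test <- max(1L, min(length(idx) - 1L, round(length(idx) * test_fraction)))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(strata), test), test = test)
  })
}

# stratified fold assignment
kfold_indices <- function(y, n_folds, seed = NULL) {
  y <- as.character(y)
  if (n_folds > min(table(y)))
    stop("`n_folds` exceeds the smallest class size", call. = FALSE)
  with_seed(seed, {
    fold <- integer(length(y))
    for (l in unique(y)) {
      idx <- sample(which(y == l))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Stratified k-fold cross-validation of the LDA classifier
#'
#' Partitions the training data into stratified folds of near-equal size;
#' every sample is validated exactly once. Reports mean and SD of
#' sensitivity, specificity and PPV over folds (the cross-validation table's
#' columns) plus the raw per-fold confusion counts.
#'
#' @param x feature matrix, `y` binary labels (training data).
#' @param y class labels.
#' @param positive_class label counted as positive.
#' @param n_folds number of folds (default 6, i.e. fold size about 17% of
#'   the training data).
#' @param shrinkage LDA shrinkage weight.
#' @param seed integer seed for the fold assignment.
#' @return object of class `cv_report`: `per_fold` data frame, `mean`/`sd`
#'   named vectors over `sensitivity`, `specificity`, `ppv`, `fold_size`,
#'   `n_folds`, `seed`.
#' @export
kfold_cv <- function(x, y, positive_class, n_folds = 6, shrinkage = 0.1,
                     seed = NULL) {
  x <- as.matrix(x); y <- factor(y)
  fold <- kfold_indices(y, n_folds, seed)
  rows <- lapply(seq_len(n_folds), function(f) {
    tr <- fold != f; te <- fold == f
    model <- lda_fit(x[tr, , drop = FALSE], y[tr], shrinkage)
    pred <- lda_predict(model, x[te, , drop = FALSE])$class
    m <- suppressWarnings(confusion_metrics(y[te], pred, positive_class))
    data.frame(fold = f, n = sum(te), TP = m$counts["TP"], FP = m$counts["FP"],
               TN = m$counts["TN"], FN = m$counts["FN"],
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, row.names = NULL)
  })
  per_fold <- do.call(rbind, rows)
  metrics <- c("sensitivity", "specificity", "ppv")
  structure(list(per_fold = per_fold,
                 mean = vapply(metrics, function(m) mean(per_fold[[m]], na.rm = TRUE),
                               numeric(1)),
                 sd = vapply(metrics, function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                             numeric(1)),
                 fold_size = mean(per_fold$n), n_folds = n_folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds (mean size %.1f)\n", x$n_folds, x$fold_size))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.4f (sd %.4f)\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' The five cohort-comparison tasks
#'
#' Binary tasks over the three sub-cohorts: pooled tasks A&B vs C and
#' B&C vs A, and the three pairwise tasks. The positive class is the pooled
#' post-infection group for A&B vs C, sub-cohort A for B&C vs A, and the
#' first-named cohort for pairwise tasks.
#'
#' @return named list of tasks, each with `name`, `mapping` (cohort ->
#'   task label) and `positive`.
#' @export
comparison_tasks <- function() {
  list(
    `A&B vs C` = list(name = "A&B vs C",
                      mapping = c(A = "AB", B = "AB", C = "C"), positive = "AB"),
    `B&C vs A` = list(name = "B&C vs A",
                      mapping = c(A = "A", B = "BC", C = "BC"), positive = "A"),
    `A vs B` = list(name = "A vs B", mapping = c(A = "A", B = "B"), positive = "A"),
    `A vs C` = list(name = "A vs C", mapping = c(A = "A", C = "C"), positive = "A"),
    `B vs C` = list(name = "B vs C", mapping = c(B = "B", C = "C"), positive = "B"))
}

#' Run the five cohort-comparison classifications
#'
#' For each task: subjects of excluded cohorts are dropped, cohorts are
#' mapped to the task's binary labels, the data are split 70/30 stratified
#' by cohort, the classifier is cross-validated on the training set
#' (k-fold), refit on the full training set and evaluated on the held-out
#' test set.
#'
#' @param features data frame with columns `alpha`, `sigma`, `cohort` (and
#'   optionally `subject_id`), e.g. from [simulate_cohort_features()] or
#'   stacked [compute_features()] rows.
#' @param tasks list of tasks (default [comparison_tasks()]).
#' @param test_fraction held-out fraction (default 0.3).
#' @param n_folds cross-validation folds (default 6).
#' @param shrinkage LDA shrinkage weight.
#' @param seed master seed (split and folds derive per-task seeds from it).
#' @return object of class `comparison_report`: `cv` (one row per task:
#'   sensitivity/specificity/ppv mean and sd, fold size), `test` (one row
#'   per task: sensitivity, specificity, ppv, npv), `counts` (per-task test
#'   confusion counts), `reports` (per-task `cv_report`s).
#' @export
run_comparisons <- function(features, tasks = comparison_tasks(),
                            test_fraction = 0.3, n_folds = 6, shrinkage = 0.1,
                            seed = 1) {
  stopifnot(all(c("alpha", "sigma", "cohort") %in% names(features)))
  cv_rows <- list(); test_rows <- list(); counts <- list(); reports <- list()
  for (task in tasks) {
    keep <- features$cohort %in% names(task$mapping)
    if (!all(names(task$mapping) %in% features$cohort))
      stop("missing cohort for task ", task$name, call. = FALSE)
    f <- features[keep, , drop = FALSE]
    ylab <- unname(task$mapping[f$cohort])
    x <- as.matrix(f[, c("alpha", "sigma")])
    split <- stratified_split(f$cohort, test_fraction,
                              seed = derive_seed(seed, paste0("split-", task$name)))
    cv <- kfold_cv(x[split$train, , drop = FALSE], ylab[split$train],
                   positive_class = task$positive, n_folds = n_folds,
                   shrinkage = shrinkage,
                   seed = derive_seed(seed, paste0("folds-", task$name)))
    model <- lda_fit(x[split$train, , drop = FALSE], ylab[split$train], shrinkage)
    pred <- lda_predict(model, x[split$test, , drop = FALSE])$class
    tm <- suppressWarnings(confusion_metrics(ylab[split$test], pred, task$positive))
    cv_rows[[task$name]] <- data.frame(
      task = task$name,
      sensitivity = cv$mean["sensitivity"], sensitivity_sd = cv$sd["sensitivity"],
      specificity = cv$mean["specificity"], specificity_sd = cv$sd["specificity"],
      ppv = cv$mean["ppv"], ppv_sd = cv$sd["ppv"],
      fold_size = cv$fold_size, row.names = NULL)
    test_rows[[task$name]] <- data.frame(
      task = task$name, sensitivity = tm$sensitivity,
      specificity = tm$specificity, ppv = tm$ppv, npv = tm$npv,
      n_test = length(split$test), row.names = NULL)
    counts[[task$name]] <- tm$counts
    reports[[task$name]] <- cv
  }
  structure(list(cv = do.call(rbind, c(cv_rows, make.row.names = FALSE)),
                 test = do.call(rbind, c(test_rows, make.row.names = FALSE)),
                 counts = counts, reports = reports, seed = seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\nCross-validation (train):\n")
  print(x$cv, digits = 3)
  cat("Held-out test set:\n")
  print(x$test, digits = 3)
  invisible(x)
}
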