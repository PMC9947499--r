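test_that("the 1-D decision boundary sits at the class-mean midpoint", {
  x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  model <- lda_fit(x, y, shrinkage = 0)
  pred <- lda_predict(model, matrix(c(0.99, 1.01, 1.0), ncol = 1))
  expect_identical(as.character(pred$class), c("a", "b", "a"))  # tie -> first label
})

test_that("well-separated clusters are classified perfectly", {
  set.seed(2)
  x <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
             matrix(rnorm(100, 10, 0.1), ncol = 2))
  y <- rep(c("near", "far"), each = 50)
  model <- lda_fit(x, y)
  expect_identical(as.character(lda_predict(model, x)$class), y)
})

test_that("identical class distributions classify at chance", {
  set.seed(3)
  x_tr <- matrix(rnorm(800), ncol = 2); y_tr <- rep(c("a", "b"), each = 200)
  x_te <- matrix(rnorm(800), ncol = 2); y_te <- rep(c("a", "b"), each = 200)
  model <- lda_fit(x_tr, y_tr)
  acc <- mean(lda_predict(model, x_te)$class == y_te)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("the discriminant matches the closed-form Bayes rate on Gaussians", {
  set.seed(4)
  n <- 10000
  x <- rbind(matrix(rnorm(n), ncol = 2),
             sweep(matrix(rnorm(n), ncol = 2), 2, c(2, 0), `+`))
  y <- rep(c("a", "b"), each = n / 2)
  model <- lda_fit(x, y, shrinkage = 0)
  err <- mean(lda_predict(model, x)$class != y)
  bayes <- pnorm(-1)  # mean separation 2, unit covariance
  expect_lt(abs(err - bayes), 0.02)
})

test_that("the hand-rolled LDA agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  x <- rbind(matrix(rnorm(120, 0, 1), ncol = 2),
             sweep(matrix(rnorm(80, 0, 1), ncol = 2), 2, c(1.5, -1), `+`))
  y <- c(rep("a", 60), rep("b", 40))
  mine <- lda_predict(lda_fit(x, y, shrinkage = 0), x)$class
  ref <- predict(MASS::lda(x, grouping = y), x)$class
  expect_identical(as.character(mine), as.character(ref))
})

test_that("shifting priors moves the boundary away from the favoured class", {
  x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  even <- lda_fit(x, y, shrinkage = 0, priors = c(a = 0.5, b = 0.5))
  skew <- lda_fit(x, y, shrinkage = 0, priors = c(a = 0.9, b = 0.1))
  probe <- matrix(1.2, ncol = 1)  # just past the even-prior boundary
  expect_identical(as.character(lda_predict(even, probe)$class), "b")
  expect_identical(as.character(lda_predict(skew, probe)$class), "a")
  expect_error(lda_predict(even, matrix(1, ncol = 3)), "dimension mismatch")
  expect_error(lda_fit(x[1:4, , drop = FALSE], c("a", "a", "a", "b")), "2 samples")
})

test_that("confusion metrics follow the printed formulas", {
  y_true <- c(rep("pos", 4), rep("neg", 4))
  y_pred <- c("pos", "pos", "pos", "neg", "pos", "pos", "neg", "neg")
  m <- confusion_metrics(y_true, y_pred, "pos")  # TP=3 FN=1 FP=2 TN=2
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 2 / 3)
  perfect <- confusion_metrics(y_true, y_true, "pos")
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]) == 1))
  # metric identities where defined
  fnr <- m$counts["FN"] / (m$counts["TP"] + m$counts["FN"])
  fpr <- m$counts["FP"] / (m$counts["TN"] + m$counts["FP"])
  expect_equal(m$sensitivity + unname(fnr), 1)
  expect_equal(m$specificity + unname(fpr), 1)
  w <- capture_warnings(res <- confusion_metrics(rep("neg", 4), rep("neg", 4), "neg"))
  expect_true(any(grepl("specificity undefined", w)))
  expect_true(is.na(res$specificity))
  expect_true(is.na(res$npv))
  expect_error(confusion_metrics(c("a", "b", "c"), c("a", "b", "c"), "a"),
               "not binary")
})

test_that("stratified splitting preserves cohort proportions", {
  strata <- rep(c("A", "B", "C"), each = 40)
  sp <- stratified_split(strata, 0.3, seed = 6)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(strata))
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_equal(as.integer(table(strata[sp$test])), c(12L, 12L, 12L))
  expect_identical(stratified_split(strata, 0.3, seed = 6), sp)
  expect_error(stratified_split(strata, 1.2), "test_fraction")
  expect_error(stratified_split(c("A", "B", "B"), 0.3, seed = 1), "2 members")
})

test_that("k-fold CV partitions the training data and scores separability", {
  set.seed(7)
  x <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 5, 0.1), ncol = 2))
  y <- rep(c("pos", "neg"), each = 30)
  cv <- kfold_cv(x, y, positive_class = "pos", n_folds = 6, seed = 8)
  expect_identical(sum(cv$per_fold$n), 60L)
  expect_equal(unname(cv$mean), c(1, 1, 1))
  expect_equal(unname(cv$sd), c(0, 0, 0))
  expect_error(kfold_cv(x, y, "pos", n_folds = 40), "smallest class")
})

test_that("null features cross-validate inside the binomial chance band", {
  specs <- list(A = cohort_spec("A", 40), B = cohort_spec("B", 40))
  feats <- simulate_cohort_features(specs, n_cascades = 400, seed = 9)
  cv <- kfold_cv(as.matrix(feats[, c("alpha", "sigma")]), feats$cohort,
                 positive_class = "A", n_folds = 6, seed = 10)
  expect_lt(abs(cv$mean["sensitivity"] - 0.5), 0.2)
})

test_that("the five comparison tasks report both table shapes", {
  feats <- simulate_cohort_features(default_cohort_specs(n_subjects = 20),
                                    n_cascades = 600, seed = 11)
  rep5 <- run_comparisons(feats, n_folds = 4, seed = 12)
  expect_identical(nrow(rep5$cv), 5L)
  expect_identical(nrow(rep5$test), 5L)
  expect_setequal(rep5$cv$task, names(comparison_tasks()))
  expect_true(all(rep5$test$sensitivity >= 0 & rep5$test$sensitivity <= 1,
                  na.rm = TRUE))
  # determinism of the full report
  rep5b <- run_comparisons(feats, n_folds = 4, seed = 12)
  expect_identical(rep5$cv, rep5b$cv)
  expect_identical(rep5$test, rep5b$test)
  expect_error(run_comparisons(feats[feats$cohort != "C", ]), "missing cohort")
})

test_that("label shuffling never lifts test accuracy above chance", {
  # leakage check: train-label permutations must not transfer signal
  specs <- default_cohort_specs(n_subjects = 30)[c("A", "C")]
  feats <- simulate_cohort_features(specs, n_cascades = 600, seed = 13)
  x <- as.matrix(feats[, c("alpha", "sigma")])
  y <- feats$cohort
  sp <- stratified_split(y, 0.3, seed = 14)
  accs <- vapply(1:20, function(i) {
    y_sh <- y
    y_sh[sp$train] <- with_seed_test(1000 + i, sample(y[sp$train]))
    model <- lda_fit(x[sp$train, ], y_sh[sp$train])
    mean(lda_predict(model, x[sp$test, ])$class == y[sp$test])
  }, numeric(1))
  # the 20 permutations share one test set, so their accuracies are
  # correlated; a leak would push the mean towards the true separability (~1)
  expect_lt(mean(accs), 0.65)
})
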