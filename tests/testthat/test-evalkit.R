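test_that("MCC reproduces its defining cases", {
  expect_equal(round(mcc(tp = 6, fp = 0, fn = 2, tn = 14), 2), 0.81)
  expect_identical(mcc(tp = 5, fp = 0, fn = 0, tn = 5), 1)
  expect_identical(mcc(tp = 0, fp = 5, fn = 5, tn = 0), -1)
  # chance convention when a denominator factor vanishes
  expect_identical(mcc(tp = 0, fp = 0, fn = 3, tn = 7), 0)
  expect_identical(mcc(tp = 4, fp = 6, fn = 0, tn = 0), 0)
})

test_that("MCC is bounded and symmetric under class swap", {
  set.seed(21)
  for (i in 1:25) {
    cm <- as.list(sample(0:9, 4, replace = TRUE))
    names(cm) <- c("tp", "fp", "fn", "tn")
    if (sum(unlist(cm)) == 0) next
    m1 <- do.call(mcc, cm)
    expect_gte(m1, -1); expect_lte(m1, 1)
    m2 <- mcc(tp = cm$tn, fp = cm$fn, fn = cm$fp, tn = cm$tp)
    expect_equal(m1, m2)
  }
})

test_that("threshold selection maximizes MCC over the candidate midpoints", {
  res <- select_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(res$threshold, 0.5)
  expect_equal(res$mcc_at_threshold, 1)
  expect_error(select_threshold(c(0.3, 0.6), c(0, 0)), "both classes")
  # reported MCC always equals the MCC recomputed from the induced matrix
  set.seed(77)
  for (i in 1:20) {
    s <- runif(20); y <- c(0, 1, rbinom(18, 1, 0.4))
    got <- select_threshold(s, y)
    expect_equal(got$mcc_at_threshold, mcc(confusion_at(s, y, got$threshold)))
    oracle <- oracle_best_threshold(s, y)
    expect_equal(got$threshold, oracle$threshold)
    expect_equal(got$mcc_at_threshold, oracle$mcc)
  }
})

test_that("AUC equals the Mann-Whitney statistic, ties counted half", {
  set.seed(31)
  for (i in 1:10) {
    s <- round(runif(30), 1)           # coarse scores force ties
    y <- c(0, 1, rbinom(28, 1, 0.5))
    rep <- evaluate_predictions(s, y, 0.5, n_boot = 10, seed = 1)
    expect_equal(rep$estimate[rep$metric == "auc"], oracle_auc_mw(s, y))
  }
  # cross-check against an independent ROC package
  skip_if_not_installed("pROC")
  set.seed(5)
  s <- runif(40); y <- c(0, 1, rbinom(38, 1, 0.35))
  rep <- evaluate_predictions(s, y, 0.5, n_boot = 10, seed = 1)
  roc <- suppressMessages(pROC::roc(y, s, levels = c(0, 1),
                                    direction = "<"))
  expect_equal(rep$estimate[rep$metric == "auc"],
               as.numeric(pROC::auc(roc)))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  s <- runif(25); y <- c(0, 1, rbinom(23, 1, 0.5))
  a1 <- evaluate_predictions(s, y, 0.5, n_boot = 10, seed = 1)
  a2 <- evaluate_predictions(plogis(5 * s - 2), y, 0.5, n_boot = 10, seed = 1)
  expect_equal(a1$estimate[a1$metric == "auc"],
               a2$estimate[a2$metric == "auc"])
})

test_that("point metrics reproduce the worked confusion matrix", {
  # 22 cases inducing TP=6, FP=0, FN=2, TN=14 at threshold 0.5
  scores <- c(rep(0.9, 6), rep(0.1, 2), rep(0.2, 14))
  labels <- c(rep(1, 8), rep(0, 14))
  rep <- evaluate_predictions(scores, labels, 0.5, n_boot = 50, seed = 9)
  est <- setNames(rep$estimate, rep$metric)
  expect_equal(round(est[["accuracy"]], 2), 0.91)
  expect_equal(round(est[["f1"]], 2), 0.86)
  expect_equal(round(est[["precision"]], 2), 1.00)
  expect_equal(est[["sensitivity"]], 0.75)
  expect_equal(est[["specificity"]], 1.00)
  # perfectly separable data at the separating threshold
  perfect <- evaluate_predictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5,
                                  n_boot = 20, seed = 2)
  expect_true(all(perfect$estimate == 1))
})

test_that("bootstrap intervals bracket the estimate and are reproducible", {
  set.seed(3)
  s <- runif(40); y <- c(0, 1, rbinom(38, 1, 0.4))
  r1 <- evaluate_predictions(s, y, 0.5, n_boot = 200, seed = 42)
  r2 <- evaluate_predictions(s, y, 0.5, n_boot = 200, seed = 42)
  expect_identical(r1, r2)
  ok <- !is.na(r1$estimate)
  expect_true(all(r1$lower[ok] <= r1$estimate[ok] + 1e-12))
  expect_true(all(r1$estimate[ok] <= r1$upper[ok] + 1e-12))
  r3 <- evaluate_predictions(s, y, 0.5, n_boot = 200, seed = 43)
  expect_false(identical(r1$lower, r3$lower))
})

test_that("undefined metrics are reported as NA with a warning", {
  s <- c(0.2, 0.3, 0.4, 0.6); y <- c(0, 0, 1, 1)
  expect_warning(rep <- evaluate_predictions(s, y, 1, n_boot = 10, seed = 1),
                 "undefined")
  expect_true(is.na(rep$estimate[rep$metric == "precision"]))
  expect_error(evaluate_predictions(s, c(1, 1, 1, 1), 0.5), "both classes")
})
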