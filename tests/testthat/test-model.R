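# Small synthetic tensors keep these tests fast; the full-scale experiment
# lives in the acceptance suite.

tiny_dataset <- function(n = 24, seed = 2) {
  set.seed(seed)
  X <- array(0, dim = c(224, 224, n))
  labels <- rep(c("acceptable", "unacceptable"), length.out = n)
  for (i in seq_len(n)) {
    if (labels[i] == "acceptable") X[30:90, 30:90, i] <- 255
    else X[130:190, 130:190, i] <- 255
    X[, , i] <- pmin(255, X[, , i] + matrix(runif(224^2) * 40, 224))
  }
  list(X = X, labels = labels)
}

test_that("an untrained classifier keeps the output contracts", {
  clf <- build_classifier(seed = 4)
  x <- matrix(runif(224^2) * 255, 224)
  expect_warning(r <- predict_risk(clf, x), "untrained")
  expect_gte(r, 0); expect_lte(r, 1)
  # deterministic forward passes
  expect_identical(suppressWarnings(predict_risk(clf, x)),
                   suppressWarnings(predict_risk(clf, x)))
  # two-class head: probabilities sum to one
  fwd <- spiroqc:::nn_forward(clf$params, clf$geom,
                              array(x, dim = c(224, 224, 1)))
  expect_identical(nrow(fwd$logits), 2L)
  expect_equal(colSums(fwd$probs), 1)
  expect_equal(unname(fwd$probs[2, 1]), suppressWarnings(predict_risk(clf, x)))
  # batched risks equal one-by-one risks (a 3-slice array would be read as
  # one RGB input, so the batch has 4 slices)
  x2 <- matrix(runif(224^2) * 255, 224)
  batch <- array(c(x, x2, x, x2), dim = c(224, 224, 4))
  rb <- suppressWarnings(predict_risk(clf, batch))
  expect_equal(rb[1], suppressWarnings(predict_risk(clf, x)))
  expect_equal(rb[2], suppressWarnings(predict_risk(clf, x2)))
  expect_identical(rb[1], rb[3])
  expect_error(predict_risk(clf, matrix(0, 100, 100)), "shape")
  expect_error(build_classifier(pretrained = TRUE), "not bundled")
})

test_that("early stopping returns the best evaluation under its patience rule", {
  # validation error increases monotonically after evaluation 3
  errs <- c(0.5, 0.4, 0.3, 0.35, 0.4)
  st4 <- spiroqc:::early_stop_status(errs[1:4], patience = 2)
  expect_false(st4$stop)
  st5 <- spiroqc:::early_stop_status(errs, patience = 2)
  expect_true(st5$stop)          # stops at evaluation 5
  expect_identical(st5$best, 3L) # returns parameters from evaluation 3
})

test_that("training learns a separable tiny problem and keeps the best epoch", {
  td <- tiny_dataset()
  sp <- split_dataset(td$labels, split_spec(seed = 1))
  fit <- train_classifier(build_classifier(seed = 4), td$X, td$labels,
                          tc = train_config(max_epochs = 8, mini_batch = 8,
                                            learning_rate = 3e-3),
                          ac = augment_config(enabled = FALSE),
                          train_idx = sp$train, val_idx = sp$validation,
                          seed = 11)
  expect_true(fit$trained)
  h <- fit$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  # returned parameters reproduce the best recorded validation loss
  vfwd <- spiroqc:::nn_forward(fit$params, fit$geom,
                               td$X[, , sp$validation])
  yval <- match(td$labels[sp$validation], fit$classes)
  expect_equal(spiroqc:::nn_loss(vfwd$probs, yval), min(h$val_loss))
  expect_identical(fit$best_epoch, which.min(h$val_loss))
})

test_that("training is reproducible and zero-width augmentation is identity", {
  td <- tiny_dataset(n = 12)
  sp <- split_dataset(td$labels, split_spec(seed = 2))
  tc <- train_config(max_epochs = 3, mini_batch = 6, learning_rate = 1e-3)
  f1 <- train_classifier(build_classifier(seed = 4), td$X, td$labels, tc,
                         augment_config(enabled = FALSE),
                         sp$train, sp$validation, seed = 7)
  f2 <- train_classifier(build_classifier(seed = 4), td$X, td$labels, tc,
                         augment_config(enabled = FALSE),
                         sp$train, sp$validation, seed = 7)
  expect_identical(f1$params, f2$params)
  zero <- augment_config(rotation_deg = c(0, 0), translate_x_px = c(0, 0),
                         translate_y_px = c(0, 0), scale_x = c(1, 1),
                         scale_y = c(1, 1))
  f3 <- train_classifier(build_classifier(seed = 4), td$X, td$labels, tc,
                         zero, sp$train, sp$validation, seed = 7)
  expect_identical(f1$params, f3$params)
  expect_identical(f1$history, f3$history)
})

test_that("degenerate training inputs are rejected", {
  td <- tiny_dataset(n = 8)
  sp <- list(train = 1:6, validation = 7:8)
  one_class <- rep("acceptable", 8)
  expect_error(train_classifier(build_classifier(), td$X, one_class,
                                train_config(), augment_config(),
                                sp$train, sp$validation),
               "single class")
  expect_error(train_classifier(build_classifier(), td$X, td$labels,
                                train_config(), augment_config(),
                                sp$train, integer(0)),
               "validation")
})

test_that("splits are disjoint, exhaustive and stratified", {
  labels <- rep(c("acceptable", "unacceptable"), c(145, 79))
  sp <- split_dataset(labels, split_spec(seed = 10))
  all_idx <- sort(c(sp$train, sp$validation, sp$test))
  expect_identical(all_idx, seq_along(labels))
  expect_identical(length(intersect(sp$train, sp$test)), 0L)
  expect_identical(length(intersect(sp$train, sp$validation)), 0L)
  expect_identical(length(unique(labels[sp$test])), 2L)
  expect_lt(abs(length(sp$test) / length(labels) - 0.1), 0.01)
})

test_that("checkpoints round-trip through save and load", {
  clf <- build_classifier(seed = 9)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_classifier(clf, f)
  back <- load_classifier(f)
  expect_identical(back$params, clf$params)
  expect_identical(back$classes, clf$classes)
})
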