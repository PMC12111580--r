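tiny_mlp_model <- function(size = 16L, classes = 2L, seed = 1L) {
  # one conv + pooled linear head: enough capacity for the separable toys
  set.seed(seed)
  m <- swimrep:::new_module("toynet")
  m$children$conv <- mod_conv2d(3L, 8L, 3L, stride = 2L, pad = 1L)
  m$children$head <- mod_linear(8L, classes)
  m
}

sr_forward.sr_toynet <- function(m, x, ...) {
  h <- ag_relu(sr_forward(m$children$conv, ag_tensor(vl(x))))
  sr_forward(m$children$head, ag_mean_hw(h))
}
registerS3method("sr_forward", "sr_toynet", sr_forward.sr_toynet,
                 envir = asNamespace("swimrep"))

test_that("supervised training drives a separable problem to high accuracy and obeys its contracts", {
  dat <- make_separable_images(40, size = 16, seed = 2)
  model <- tiny_mlp_model()
  before <- swimrep:::sr_state_dict(model)
  fit0 <- train_supervised(model, dat$x, dat$y, train_config(epochs = 0))
  expect_identical(swimrep:::sr_state_dict(model), before)
  fit <- train_supervised(model, dat$x, dat$y,
                          train_config(lr = 5e-3, epochs = 20, batch_size = 16,
                                       seed = 3))
  ev <- evaluate(model, dat$x, dat$y)
  expect_gte(ev$accuracy, 0.99)
  expect_equal(nrow(fit$history), 20)
  expect_lt(fit$history$loss[20], fit$history$loss[1])
})

test_that("the step schedule scales the learning rate at the stated milestones", {
  cfg <- train_config(lr = 1e-4, epochs = 6, milestones = c(2, 4), gamma = 0.1)
  lrs <- vapply(1:6, function(e) swimrep:::lr_at_epoch(cfg, e), numeric(1))
  expect_equal(lrs, c(1e-4, 1e-4, 1e-5, 1e-5, 1e-6, 1e-6))
  expect_error(train_config(lr = -1), "lr > 0")
  expect_error(train_config(gamma = 0), "gamma")
})

test_that("evaluation reproduces hand-computed metrics and is deterministic", {
  # identity case
  cm_perfect <- diag(c(5L, 3L, 2L))
  mp <- metrics_from_confusion(cm_perfect)
  expect_equal(mp$accuracy, 1)
  expect_equal(unname(mp$f1), rep(1, 3))
  # contingency toy: TP=8, FN=2, FP=1, TN=9
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE)
  m <- metrics_from_confusion(cm)
  expect_equal(unname(m$precision[1]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(m$recall[1]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m$f1[1]), 2 * (8 / 9 * 0.8) / (8 / 9 + 0.8), tolerance = 1e-12)
  expect_equal(m$accuracy, 17 / 20)
  # metric identities on random confusion matrices
  set.seed(60)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    cmr <- matrix(stats::rpois(k * k, 5), k, k)
    mr <- metrics_from_confusion(cmr)
    expect_equal(mr$accuracy, sum(diag(cmr)) / sum(cmr))
    # micro-F1 equals accuracy for single-label classification
    micro_p <- sum(diag(cmr)) / sum(colSums(cmr))
    expect_equal(micro_p, mr$accuracy)
  }
  # absent class flagged as NaN recall
  cm0 <- matrix(c(5L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 4L), 3, 3, byrow = TRUE)
  m0 <- metrics_from_confusion(cm0)
  expect_true(is.nan(m0$recall[2]))
  expect_equal(m0$absent_classes, 2L)
})

test_that("random scores give chance-level AUC and evaluate is repeatable", {
  set.seed(61)
  dat <- make_separable_images(30, size = 16, seed = 5)
  model <- tiny_mlp_model(seed = 9)
  e1 <- evaluate(model, dat$x, dat$y)
  e2 <- evaluate(model, dat$x, dat$y)
  expect_identical(e1$confusion, e2$confusion)
  expect_identical(e1$auc, e2$auc)
  # chance-level AUC for labels independent of the scores
  n <- 1000
  scores <- cbind(stats::runif(n), stats::runif(n))
  y <- sample(1:2, n, replace = TRUE)
  r <- pROC::roc(as.integer(y == 1), scores[, 1], quiet = TRUE, direction = "<")
  expect_lt(abs(as.numeric(pROC::auc(r)) - 0.5), 0.1)
})

test_that("pseudo-labeling partitions by strict confidence threshold", {
  # direct check of the acceptance rule on a model with known outputs
  dat <- make_separable_images(10, size = 16, seed = 6)
  model <- tiny_mlp_model(seed = 2)
  train_supervised(model, dat$x, dat$y,
                   train_config(lr = 5e-3, epochs = 25, batch_size = 16, seed = 1))
  probs <- predict_proba(model, dat$x)
  conf <- apply(probs, 1, max)
  for (tau in c(0.5, 0.9, 0.95)) {
    pool <- pseudo_label_round(model, dat$x, tau)
    expect_equal(nrow(pool$accepted), sum(conf > tau))
    expect_true(all(pool$accepted$confidence > tau))
    expect_equal(sort(c(pool$accepted$index, pool$residual)),
                 seq_len(dim(dat$x)[4]))
  }
  # strict inequality: tau = 1 accepts nothing
  expect_equal(nrow(pseudo_label_round(model, dat$x, 1.0)$accepted), 0)
  # empty unlabeled set is a valid empty pool
  empty <- pseudo_label_round(model, array(0, c(3, 16, 16, 0)), 0.95)
  expect_equal(nrow(empty$accepted), 0)
  expect_length(empty$residual, 0)
})

test_that("the SSL loop grows its training set at a permissive threshold and logs rounds", {
  dat <- make_separable_images(30, size = 16, seed = 7)
  n <- dim(dat$x)[4]
  sp <- split_dataset(n, "ssl", seed = 3, stratify_labels = dat$y)
  labeled <- list(x = dat$x[, , , sp$labeled, drop = FALSE], y = dat$y[sp$labeled])
  unlabeled <- list(x = dat$x[, , , sp$unlabeled, drop = FALSE])
  validation <- list(x = dat$x[, , , sp$validation, drop = FALSE],
                     y = dat$y[sp$validation])
  model <- tiny_mlp_model(seed = 4)
  res <- ssl_train(model, labeled, unlabeled, validation,
                   train_config(lr = 5e-3, epochs = 15, batch_size = 16, seed = 2),
                   tau = 0.5, max_rounds = 2)
  expect_true(all(c("round", "accepted", "train_size", "val_accuracy") %in%
                  names(res$history)))
  expect_gte(nrow(res$history), 2)
  expect_gt(res$history$train_size[2], res$history$train_size[1])
  expect_gte(res$best_accuracy, res$history$val_accuracy[1])
})

test_that("training aborts with a diagnostic when the loss turns non-finite", {
  dat <- make_separable_images(10, size = 16, seed = 8)
  model <- tiny_mlp_model(seed = 3)
  model$children$conv$params$w$v[1] <- NaN
  expect_error(
    train_supervised(model, dat$x, dat$y,
                     train_config(lr = 1e-3, epochs = 2, batch_size = 8, seed = 1)),
    "diverged")
})
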