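# Supervised training (Adam + cross-entropy with optional step decay),
# evaluation metrics, and the pseudo-label semi-supervised protocol: train on
# the labeled half, pseudo-label the unlabeled pool at a 0.95 confidence
# threshold, merge accepted items, retrain, and stop once validation accuracy
# no longer improves, returning the best-validation checkpoint.

#' Adam optimizer
#' @param params named list of parameter nodes (from [sr_parameters()]).
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @return an optimizer object.
#' @export
opt_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  o <- new.env(parent = emptyenv())
  o$params <- params
  o$lr <- lr; o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps
  o$m <- lapply(params, function(p) array(0, dim1(p$v)))
  o$vv <- lapply(params, function(p) array(0, dim1(p$v)))
  o$t <- 0L
  class(o) <- "sr_adam"
  o
}

#' @rdname opt_adam
#' @param o the optimizer.
#' @export
opt_step <- function(o) {
  o$t <- o$t + 1L
  bc1 <- 1 - o$beta1^o$t
  bc2 <- 1 - o$beta2^o$t
  for (i in seq_along(o$params)) {
    p <- o$params[[i]]
    if (is.null(p$g)) next
    o$m[[i]] <- o$beta1 * o$m[[i]] + (1 - o$beta1) * p$g
    o$vv[[i]] <- o$beta2 * o$vv[[i]] + (1 - o$beta2) * p$g^2
    p$v <- p$v - o$lr * (o$m[[i]] / bc1) / (sqrt(o$vv[[i]] / bc2) + o$eps)
  }
  invisible(o)
}

#' @rdname opt_adam
#' @export
opt_zero_grad <- function(o) {
  for (p in o$params) p$g <- NULL
  invisible(o)
}

#' Training configuration
#'
#' @param lr learning rate (cross-entropy objective; Adam optimizer).
#' @param epochs full passes over the training data.
#' @param batch_size minibatch size.
#' @param milestones optional epoch indices at which the learning rate is
#'   scaled by `gamma` (step schedule).
#' @param gamma step-schedule scaling factor in (0, 1].
#' @param seed RNG seed controlling shuffling (and any fresh initialization).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 10L, batch_size = 32L,
                         milestones = NULL, gamma = 0.1, seed = 42L) {
  stopifnot(lr > 0, gamma > 0, gamma <= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 milestones = milestones, gamma = gamma,
                 seed = as.integer(seed)),
            class = "train_config")
}

lr_at_epoch <- function(cfg, epoch) {
  if (is.null(cfg$milestones)) return(cfg$lr)
  cfg$lr * cfg$gamma^sum(epoch > cfg$milestones)
}

#' Train a model with cross-entropy
#'
#' Minimizes mean cross-entropy with Adam at the configured learning rate and
#' optional step decay; records per-epoch mean loss, learning rate and (when
#' validation data is given) validation accuracy. Fully seeded; zero epochs
#' leave the model untouched.
#' @param model a module.
#' @param x input array `(3, H, W, N)`.
#' @param y integer labels (1-based).
#' @param cfg a [train_config()].
#' @param val optional list(x, y) evaluated after each epoch.
#' @return list with `model` and a data-frame `history`.
#' @export
train_supervised <- function(model, x, y, cfg = train_config(), val = NULL) {
  n <- dim(x)[4]
  stopifnot(n >= 1, length(y) == n)
  params <- sr_parameters(model)
  opt <- opt_adam(params, lr = cfg$lr)
  history <- data.frame()
  if (cfg$epochs == 0) return(list(model = model, history = history))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    sr_set_training(model, TRUE)
    opt$lr <- lr_at_epoch(cfg, epoch)
    perm <- sample(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      with_tape({
        logits <- sr_forward(model, ag_tensor(xb))
        loss <- ag_cross_entropy(logits, yb)
        if (!is.finite(vl(loss))) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (lr = ", opt$lr, "); lower the learning rate")
        }
        opt_zero_grad(opt)
        ag_backward(loss)
      })
      opt_step(opt)
      losses <- c(losses, vl(loss))
    }
    val_acc <- NA_real_
    if (!is.null(val)) {
      val_acc <- evaluate(model, val$x, val$y)$accuracy
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = opt$lr,
                                         loss = mean(losses),
                                         val_accuracy = val_acc))
  }
  list(model = model, history = history)
}

#' Class-probability predictions
#' @param model a module.
#' @param x input array `(3, H, W, N)`.
#' @param batch_size forward batch size.
#' @return `(N, K)` matrix of softmax probabilities.
#' @export
predict_proba <- function(model, x, batch_size = 64L) {
  sr_set_training(model, FALSE)
  n <- dim(x)[4]
  out <- NULL
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    logits <- vl(sr_forward(model, ag_tensor(x[, , , idx, drop = FALSE])))
    p <- vl(ag_softmax1(ag_tensor(logits)))
    out <- rbind(out, t(matrix(p, nrow = dim(logits)[1])))
  }
  out
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predictions. Precision is the positive
#' predicted value TP/(TP+FP); recall TP/(TP+FN); F1 their harmonic mean.
#' Classes absent from the data yield NaN recall (flagged).
#' @param cm square confusion matrix.
#' @return list of accuracy, per-class vectors and macro averages.
#' @export
metrics_from_confusion <- function(cm) {
  total <- sum(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, NaN)
  recall <- ifelse(support > 0, tp / support, NaN)
  f1 <- ifelse(is.finite(precision) & is.finite(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NaN)
  list(accuracy = sum(tp) / total,
       precision = precision, recall = recall, f1 = f1,
       macro_precision = mean(precision, na.rm = TRUE),
       macro_recall = mean(recall, na.rm = TRUE),
       macro_f1 = mean(f1, na.rm = TRUE),
       absent_classes = which(support == 0),
       confusion = cm)
}

#' Evaluate a model on labeled data
#'
#' Deterministic (eval-mode) metrics: accuracy, per-class precision (positive
#' predicted value), recall and F1, the confusion matrix, and one-vs-rest
#' ROC/AUC per class from the softmax scores.
#' @param model a module.
#' @param x input array `(3, H, W, N)`.
#' @param y integer true labels (1-based).
#' @param class_names optional class names for the report.
#' @return a `metrics_report` list.
#' @export
evaluate <- function(model, x, y, class_names = NULL) {
  stopifnot(dim(x)[4] >= 1)
  probs <- predict_proba(model, x)
  k <- ncol(probs)
  if (is.null(class_names)) class_names <- as.character(seq_len(k))
  pred <- max.col(probs, ties.method = "first")
  cm <- matrix(0L, k, k, dimnames = list(true = class_names, pred = class_names))
  for (i in seq_along(y)) cm[y[i], pred[i]] <- cm[y[i], pred[i]] + 1L
  rep <- metrics_from_confusion(cm)
  auc <- rep(NA_real_, k)
  roc <- vector("list", k)
  for (c in seq_len(k)) {
    truth <- as.integer(y == c)
    if (length(unique(truth)) == 2) {
      r <- pROC::roc(truth, probs[, c], quiet = TRUE, direction = "<")
      auc[c] <- as.numeric(pROC::auc(r))
      roc[[c]] <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
    }
  }
  names(auc) <- class_names
  rep$auc <- auc
  rep$roc <- roc
  rep$n <- length(y)
  class(rep) <- "metrics_report"
  rep
}

# ---- pseudo-labeling -------------------------------------------------------

#' One pseudo-labeling round
#'
#' Scores the unlabeled items; items whose maximum softmax probability
#' strictly exceeds the confidence threshold enter the accepted pool with
#' their argmax label, the rest stay residual.
#' @param model a trained model.
#' @param x_unlabeled input array `(3, H, W, N)` (N may be 0).
#' @param tau confidence threshold.
#' @return a `pseudo_label_pool`: `accepted` (data frame of `index`, `label`,
#'   `confidence`), `residual` (indices), `tau`.
#' @export
pseudo_label_round <- function(model, x_unlabeled, tau = 0.95) {
  n <- if (length(dim(x_unlabeled)) == 4) dim(x_unlabeled)[4] else 0L
  if (n == 0) {
    return(structure(list(accepted = data.frame(index = integer(0),
                                                label = integer(0),
                                                confidence = numeric(0)),
                          residual = integer(0), tau = tau),
                     class = "pseudo_label_pool"))
  }
  probs <- predict_proba(model, x_unlabeled)
  conf <- apply(probs, 1, max)
  lab <- max.col(probs, ties.method = "first")
  acc <- which(conf > tau)
  structure(list(accepted = data.frame(index = acc, label = lab[acc],
                                       confidence = conf[acc]),
                 residual = setdiff(seq_len(n), acc), tau = tau),
            class = "pseudo_label_pool")
}

#' Pseudo-label semi-supervised training
#'
#' Step 1 trains on the labeled set. Each following round pseudo-labels the
#' residual unlabeled pool at threshold `tau`, merges the accepted items
#' (hard labels, unit weight) with all previously accepted ones and the
#' labeled set, continues training, and evaluates on validation. The loop
#' stops when validation accuracy fails to improve over the previous round or
#' a round accepts nothing new; the best-validation checkpoint is restored
#' into the returned model.
#' @param model a module.
#' @param labeled,validation lists with `x` and `y`.
#' @param unlabeled list with `x` (labels, if present, are ignored).
#' @param cfg a [train_config()] used for the initial fit and each round.
#' @param tau confidence threshold.
#' @param max_rounds safety cap on pseudo-label rounds.
#' @return list with `model`, `history` (per-round accepted counts and
#'   validation accuracy) and `best_round`.
#' @export
ssl_train <- function(model, labeled, unlabeled, validation,
                      cfg = train_config(), tau = 0.95, max_rounds = 5L) {
  fit <- train_supervised(model, labeled$x, labeled$y, cfg,
                          val = validation)
  acc0 <- evaluate(model, validation$x, validation$y)$accuracy
  history <- data.frame(round = 0L, accepted = 0L, train_size = length(labeled$y),
                        val_accuracy = acc0)
  best <- list(acc = acc0, state = sr_state_dict(model), round = 0L)
  pool_idx <- seq_len(if (length(dim(unlabeled$x)) == 4) dim(unlabeled$x)[4] else 0L)
  pseudo_x <- NULL; pseudo_y <- integer(0)
  prev_acc <- acc0
  for (round in seq_len(max_rounds)) {
    if (!length(pool_idx)) break
    pool <- pseudo_label_round(model, unlabeled$x[, , , pool_idx, drop = FALSE], tau)
    if (!nrow(pool$accepted)) {
      message("ssl_train: round ", round, " accepted no items; stopping")
      break
    }
    taken <- pool_idx[pool$accepted$index]
    pool_idx <- pool_idx[pool$residual]
    add_x <- unlabeled$x[, , , taken, drop = FALSE]
    pseudo_x <- if (is.null(pseudo_x)) add_x else {
      comb <- array(0, c(dim(add_x)[1:3], dim(pseudo_x)[4] + dim(add_x)[4]))
      comb[, , , seq_len(dim(pseudo_x)[4])] <- pseudo_x
      comb[, , , dim(pseudo_x)[4] + seq_len(dim(add_x)[4])] <- add_x
      comb
    }
    pseudo_y <- c(pseudo_y, pool$accepted$label)
    tx <- array(0, c(dim(labeled$x)[1:3], length(labeled$y) + length(pseudo_y)))
    tx[, , , seq_along(labeled$y)] <- labeled$x
    tx[, , , length(labeled$y) + seq_along(pseudo_y)] <- pseudo_x
    ty <- c(labeled$y, pseudo_y)
    rcfg <- cfg
    rcfg$seed <- cfg$seed + round
    train_supervised(model, tx, ty, rcfg)
    acc <- evaluate(model, validation$x, validation$y)$accuracy
    history <- rbind(history, data.frame(round = round,
                                         accepted = nrow(pool$accepted),
                                         train_size = length(ty),
                                         val_accuracy = acc))
    if (acc > best$acc) best <- list(acc = acc, state = sr_state_dict(model),
                                     round = round)
    if (acc <= prev_acc) break   # patience of one full round
    prev_acc <- acc
  }
  sr_load_state_dict(model, best$state)
  list(model = model, history = history, best_round = best$round,
       best_accuracy = best$acc)
}
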