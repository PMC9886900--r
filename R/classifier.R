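#' Construct a linear cancer-type classifier object
#'
#' The model evaluated under encryption is linear: scores `z = W x + b` with
#' `W` a `K x f` weight matrix.  Because the softmax is monotone, the
#' predicted class is `argmax_k z_k`, so inference never needs the
#' non-linearity -- the property that makes encrypted evaluation cheap.
#'
#' @param weights `K x f` numeric matrix.
#' @param bias length-`K` numeric vector.
#' @param lambda_l1 L1 penalty used in training.
#' @param class_names,feature_names names for rows/columns of `weights`.
#' @param folds,seed training metadata.
#' @param cv optional cross-validation table kept for inspection.
#' @return An object of class `"helr_model"`.
#' @export
helr_model <- function(weights, bias, lambda_l1, class_names, feature_names,
                       folds = NA_integer_, seed = NA_integer_, cv = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(class_names) ||
      ncol(weights) != length(feature_names))
    stop("weight matrix shape does not match class/feature names")
  if (length(bias) != length(class_names))
    stop("bias length does not match the number of classes")
  if (!is.finite(lambda_l1) || lambda_l1 < 0)
    stop("lambda_l1 must be a nonnegative number")
  dimnames(weights) <- list(class_names, feature_names)
  structure(list(weights = weights, bias = as.numeric(bias),
                 lambda_l1 = as.numeric(lambda_l1),
                 class_names = as.character(class_names),
                 feature_names = as.character(feature_names),
                 folds = folds, seed = seed, cv = cv),
            class = "helr_model")
}

#' @export
print.helr_model <- function(x, ...) {
  cat(sprintf("L1-penalized linear classifier: %d classes x %d features, lambda = %.4g\n",
              nrow(x$weights), ncol(x$weights), x$lambda_l1))
  nz <- sum(colSums(x$weights != 0) > 0)
  cat(sprintf("  features with nonzero weight: %d (%.1f%%)\n",
              nz, 100 * nz / ncol(x$weights)))
  if (!is.null(x$cv))
    cat(sprintf("  CV accuracy at chosen lambda: %.3f\n",
                max(x$cv$mean_accuracy)))
  invisible(x)
}

#' @export
coef.helr_model <- function(object, ...) {
  cbind(`(bias)` = object$bias, object$weights)
}

#' @export
summary.helr_model <- function(object, ...) {
  nzw <- colSums(object$weights != 0)
  out <- list(
    n_classes = nrow(object$weights),
    n_features = ncol(object$weights),
    lambda_l1 = object$lambda_l1,
    nonzero_features = sum(nzw > 0),
    max_abs_weight = max(abs(object$weights)),
    cv = object$cv)
  class(out) <- "summary.helr_model"
  out
}

#' @export
print.summary.helr_model <- function(x, ...) {
  cat(sprintf("%d-class linear model over %d features (lambda = %.4g)\n",
              x$n_classes, x$n_features, x$lambda_l1))
  cat(sprintf("  nonzero features: %d; max |weight| = %.4g\n",
              x$nonzero_features, x$max_abs_weight))
  if (!is.null(x$cv)) { cat("  cross-validation path:\n"); print(x$cv) }
  invisible(x)
}

#' Predict classes or linear scores
#'
#' @param object a `"helr_model"`.
#' @param newdata feature matrix with columns matching the model (by name
#'   when both are named).
#' @param type `"class"` for 0-based class ids (argmax of `z`, ties to the
#'   lowest id) or `"score"` for the linear score matrix.
#' @param ... unused.
#' @export
predict.helr_model <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$weights))
    stop(sprintf("feature dimension mismatch: model has %d, data has %d",
                 ncol(object$weights), ncol(X)))
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names))
    stop("feature names/order of the data do not match the model")
  z <- X %*% t(object$weights) + matrix(object$bias, nrow(X),
                                        length(object$bias), byrow = TRUE)
  if (type == "score") return(z)
  max.col(z, ties.method = "first") - 1L
}

#' @rdname predict.helr_model
#' @param model a `"helr_model"`.
#' @param X feature matrix.
#' @return 0-based predicted class ids.
#' @export
predict_argmax <- function(model, X) predict(model, X, type = "class")

#' Rescale a model so all weights fit the fixed-point contract
#'
#' Divides `W` and `b` by a common positive constant so that every weight
#' has magnitude strictly below 1, as the quantizer requires.  Scaling all
#' scores by the same positive factor leaves the argmax unchanged, so
#' predictions are unaffected.
#'
#' @param model a `"helr_model"`.
#' @param margin keep `max |w|` at most this value after scaling.
#' @return The rescaled model (with attribute `"scale"`).
#' @export
normalize_model_weights <- function(model, margin = 0.999) {
  mx <- max(abs(model$weights))
  s <- if (mx >= margin) mx / margin else 1
  out <- model
  out$weights <- model$weights / s
  out$bias <- model$bias / s
  attr(out, "scale") <- s
  out
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds so that every class is spread as
#' evenly as possible: within each class, shuffled samples are dealt to
#' folds round-robin, keeping per-fold class counts within one of each
#' other.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per sample.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as_class_ids(y)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the multiclass L1-penalized logistic-regression model
#'
#' Minimizes the multinomial logistic loss plus a Lasso penalty
#' `lambda * sum(|beta|)`, which drives the weights of uninformative
#' features to exactly zero -- the principal guard against overfitting when
#' features far outnumber samples.  The penalty strength is chosen by
#' stratified k-fold cross-validated accuracy over `lambda_grid` (ties go to
#' the stronger penalty); the final model is refit on all data at the chosen
#' value.  Deterministic given `seed`.
#'
#' @param X feature matrix (samples x features), the selected features.
#' @param y class labels, 0-based ids or factor; at least two classes.
#' @param lambda_grid candidate penalties (default `10^-3 .. 10^2`,
#'   11 log-spaced points).
#' @param k_folds folds for cross-validation.
#' @param seed RNG seed for fold assignment.
#' @param class_names optional class names (defaults to `class0..`).
#' @return A `"helr_model"` with the cross-validation table in `$cv` and the
#'   held-out evaluation of the chosen penalty in `$cv_report` (an
#'   [evaluate_model()] report over pooled out-of-fold predictions).
#' @export
train_multiclass_lr <- function(X, y, lambda_grid = 10^seq(-3, 2, length.out = 11),
                                k_folds = 5L, seed = 1L, class_names = NULL) {
  X <- as.matrix(X)
  y <- as_class_ids(y)
  K <- length(unique(y))
  if (K < 2) stop("training labels contain a single class")
  if (max(y) != K - 1 || min(y) != 0)
    stop("labels must use every class id in 0..K-1")
  if (is.null(class_names)) class_names <- sprintf("class%d", 0:(K - 1))
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  fold <- stratified_folds(y, k_folds, seed)
  acc <- matrix(NA_real_, k_folds, length(lambda_grid))
  oof_score <- matrix(NA_real_, nrow(X), K)
  oof_best <- rep(NA_integer_, nrow(X))
  for (fd in seq_len(k_folds)) {
    tr <- fold != fd
    fit <- glmnet_multinomial(X[tr, , drop = FALSE], y[tr], lambda_grid)
    for (li in seq_along(lambda_grid)) {
      co <- lr_coefs(fit, lambda_grid[li], K, ncol(X))
      z <- X[!tr, , drop = FALSE] %*% t(co$W) +
        matrix(co$b, sum(!tr), K, byrow = TRUE)
      pred <- max.col(z, ties.method = "first") - 1L
      acc[fd, li] <- mean(pred == y[!tr])
    }
  }
  mean_acc <- colMeans(acc)
  best_li <- which(mean_acc == max(mean_acc))[1]    # grid is descending: ties
  best_lambda <- lambda_grid[best_li]               # go to the larger penalty
  # pooled out-of-fold predictions at the chosen penalty, for honest metrics
  for (fd in seq_len(k_folds)) {
    tr <- fold != fd
    fit <- glmnet_multinomial(X[tr, , drop = FALSE], y[tr], lambda_grid)
    co <- lr_coefs(fit, best_lambda, K, ncol(X))
    z <- X[!tr, , drop = FALSE] %*% t(co$W) + matrix(co$b, sum(!tr), K, byrow = TRUE)
    oof_score[!tr, ] <- z
    oof_best[!tr] <- max.col(z, ties.method = "first") - 1L
  }
  fit <- glmnet_multinomial(X, y, lambda_grid)
  co <- lr_coefs(fit, best_lambda, K, ncol(X))
  cv <- data.frame(lambda = lambda_grid, mean_accuracy = mean_acc)
  model <- helr_model(co$W, co$b, best_lambda, class_names,
                      feature_names = colnames(X) %||% sprintf("f%06d", seq_len(ncol(X))),
                      folds = k_folds, seed = seed, cv = cv)
  model$fold_accuracy <- acc[, best_li]
  model$cv_report <- eval_report(y, oof_best, oof_score)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

glmnet_multinomial <- function(X, y, lambda_grid) {
  fam <- if (length(unique(y)) == 2) "binomial" else "multinomial"
  glmnet::glmnet(X, factor(y), family = fam, alpha = 1,
                 lambda = lambda_grid, standardize = FALSE,
                 maxit = 2e5)
}

# dense K x f weights + K biases at penalty lam from a glmnet fit
lr_coefs <- function(fit, lam, K, f) {
  co <- glmnet::coef.glmnet(fit, s = lam, exact = FALSE)
  if (is.list(co)) {
    W <- t(vapply(co, function(m) as.numeric(m)[-1], numeric(f)))
    b <- vapply(co, function(m) as.numeric(m)[1], 0)
  } else {
    # binomial: single contrast for the positive class
    beta <- as.numeric(co)
    W <- rbind(0, beta[-1])
    b <- c(0, beta[1])
  }
  list(W = W, b = b)
}

#' One-vs-rest binary models, one per cancer type
#'
#' Retrains the classifier per class with labels 1 (the class of interest)
#' versus 0 (every other class), over the same feature matrix.  These serve
#' as per-disease detectors complementing the multiclass model.
#'
#' @inheritParams train_multiclass_lr
#' @return A named list of binary `"helr_model"` objects (class names
#'   `c("other", <class>)`).
#' @export
train_binary_models <- function(X, y, lambda_grid = 10^seq(-3, 2, length.out = 11),
                                k_folds = 5L, seed = 1L, class_names = NULL) {
  y <- as_class_ids(y)
  K <- length(unique(y))
  if (K < 2) stop("need at least two classes")
  if (is.null(class_names)) class_names <- sprintf("class%d", 0:(K - 1))
  out <- lapply(0:(K - 1), function(k) {
    yb <- as.integer(y == k)
    if (length(unique(yb)) < 2)
      stop(sprintf("class %d is absent from the labels", k))
    train_multiclass_lr(X, yb, lambda_grid, k_folds, seed,
                        class_names = c("other", class_names[k + 1]))
  })
  names(out) <- class_names
  out
}

#' Cross-validated accuracy as a function of the number of selected features
#'
#' Starting from the top `step` features by the given score and increasing
#' by `step`, retrains the model at each feature count with the same folds
#' and seed, so rows are comparable.  The selected sets are nested by
#' construction ([select_top_features()] prefixes).
#'
#' @param X full feature matrix.
#' @param y labels.
#' @param scores a `"feature_scores"` object (default: chi-square on `X, y`).
#' @param step feature-count increment.
#' @param max_f largest feature count (capped at `ncol(X)`).
#' @inheritParams train_multiclass_lr
#' @return Data frame with `n_features` and `cv_accuracy`.
#' @export
feature_count_sweep <- function(X, y, scores = NULL, step = 1000L,
                                max_f = ncol(X),
                                lambda_grid = 10^seq(-3, 2, length.out = 5),
                                k_folds = 5L, seed = 1L) {
  if (max_f > ncol(X)) stop("max_f exceeds the number of features")
  if (is.null(scores)) scores <- chi_square_scores(X, y)
  grid <- unique(c(seq(step, max_f, by = step), max_f))
  rows <- lapply(grid, function(nf) {
    sel <- select_top_features(scores, nf)
    m <- train_multiclass_lr(X[, sel, drop = FALSE], y, lambda_grid,
                             k_folds, seed)
    data.frame(n_features = nf, cv_accuracy = max(m$cv$mean_accuracy))
  })
  do.call(rbind, rows)
}

# ------------------------------------------------------------- evaluation

# Mann-Whitney AUC with average ranks for ties
rank_auc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

eval_report <- function(y, pred, score) {
  K <- ncol(score)
  classes <- 0:(K - 1)
  cm <- table(factor(y, levels = classes), factor(pred, levels = classes))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class_auc <- vapply(classes, function(k) rank_auc(score[, k + 1], y == k), 0)
  # micro-average AUC over pooled one-vs-rest (sample, class) pairs
  pooled_scores <- as.numeric(score)
  pooled_labels <- as.numeric(outer(y, classes, "==")) > 0
  structure(list(
    accuracy = mean(pred == y),
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    per_class_auc = setNames(per_class_auc, paste0("class", classes)),
    mauc = rank_auc(pooled_scores, pooled_labels),
    confusion = cm), class = "helr_eval")
}

#' Evaluate a model on labeled data
#'
#' Reports accuracy, macro precision/recall/F1, the one-vs-rest ROC AUC of
#' each class, and the micro-average AUC (MAUC) over all pooled
#' (sample, class) score pairs -- the robust summary for unbalanced
#' cohorts.  ROC ranking uses the linear scores `z`, which order samples
#' identically to softmax probabilities.
#'
#' @param model a `"helr_model"`.
#' @param X_test,y_test held-out features and labels.
#' @return An object of class `"helr_eval"`.
#' @export
evaluate_model <- function(model, X_test, y_test) {
  y <- as_class_ids(y_test)
  z <- predict(model, X_test, type = "score")
  pred <- max.col(z, ties.method = "first") - 1L
  eval_report(y, pred, z)
}

#' @export
print.helr_eval <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.3f R %.3f F1 %.3f | MAUC %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$mauc))
  cat("per-class AUC:",
      paste(sprintf("%s=%.3f", names(x$per_class_auc), x$per_class_auc),
            collapse = ", "), "\n")
  invisible(x)
}
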