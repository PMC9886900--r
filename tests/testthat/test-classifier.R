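make_separable <- function(n = 40, seed = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(f1 = y * 3 + runif(n), f2 = (1 - y) * 3 + runif(n))
  list(X = X, y = y)
}

test_that("a linearly separable toy problem is fit perfectly", {
  d <- make_separable()
  m <- train_multiclass_lr(d$X, d$y, k_folds = 4, seed = 1)
  expect_equal(mean(predict_argmax(m, d$X) == d$y), 1)
})

test_that("an overwhelming L1 penalty zeroes all weights and predicts the majority class", {
  set.seed(8)
  y <- c(rep(0L, 32), rep(1L, 16))
  X <- matrix(rnorm(48 * 5), 48, 5, dimnames = list(NULL, paste0("f", 1:5)))
  m <- train_multiclass_lr(X, y, lambda_grid = c(1e6), k_folds = 4, seed = 1)
  expect_true(all(m$weights == 0))
  expect_true(all(predict_argmax(m, X) == 0L))   # majority class via intercepts
})

test_that("argmax prediction follows z = Wx + b with deterministic tie-breaking", {
  # bias-only model: W = 0, b = (0.1, 0.9) predicts class 1 for any input
  m <- helr_model(matrix(0, 2, 3), bias = c(0.1, 0.9), lambda_l1 = 0,
                  class_names = c("c0", "c1"), feature_names = paste0("f", 1:3))
  set.seed(3)
  X <- matrix(runif(15), 5, 3, dimnames = list(NULL, paste0("f", 1:3)))
  expect_true(all(predict_argmax(m, X) == 1L))
  # exact tie in z goes to the lowest class id
  tie <- helr_model(matrix(0, 3, 2), bias = c(0.5, 0.5, 0.2), lambda_l1 = 0,
                    class_names = paste0("c", 0:2), feature_names = c("a", "b"))
  expect_equal(predict_argmax(tie, matrix(0, 1, 2,
                                          dimnames = list(NULL, c("a", "b")))), 0L)
  # dimension mismatch is rejected
  expect_error(predict(m, matrix(0, 1, 5)), "mismatch")
})

test_that("argmax is invariant to strictly increasing transforms of the scores", {
  set.seed(12)
  m <- helr_model(matrix(rnorm(12), 3, 4), rnorm(3), 0.1,
                  paste0("c", 0:2), paste0("f", 1:4))
  X <- matrix(runif(40, 0, 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  z <- predict(m, X, type = "score")
  base <- max.col(z, ties.method = "first")
  for (tf in list(function(v) 2 * v + 7, function(v) exp(v),
                  function(v) exp(v) / rowSums(exp(v)))) {  # incl. softmax
    expect_equal(max.col(tf(z), ties.method = "first"), base)
  }
})

test_that("the count of exactly-zero weights shrinks as the penalty relaxes", {
  coh <- reference_cohort()
  fm <- build_feature_matrix(coh, 500)
  sel <- select_top_features(chi_square_scores(fm, coh$labels), 60)
  X <- fm[, sel]
  lams <- 10^seq(1, -3, length.out = 6)      # decreasing penalty
  fit <- glmnet::glmnet(X, factor(coh$labels), family = "multinomial",
                        alpha = 1, lambda = lams, standardize = FALSE)
  nz <- vapply(lams, function(l) {
    co <- glmnet::coef.glmnet(fit, s = l)
    sum(vapply(co, function(m) sum(as.numeric(m)[-1] == 0), 0))
  }, 0)
  expect_true(all(diff(nz) <= 0))
})

test_that("stratified folds keep per-fold class proportions within one sample", {
  coh <- reference_cohort()
  y <- unname(coh$labels)
  fold <- stratified_folds(y, 5, seed = 1)
  tab <- table(fold, y)
  for (k in seq_len(ncol(tab)))
    expect_lte(diff(range(tab[, k])), 1)
  # deterministic given seed
  expect_identical(fold, stratified_folds(y, 5, seed = 1))
})

test_that("held-out accuracy on the synthetic cohort beats the majority baseline", {
  coh <- reference_cohort()
  fm <- build_feature_matrix(coh, 500)
  sel <- select_top_features(chi_square_scores(fm, coh$labels), 90)
  X <- fm[, sel]
  fold <- stratified_folds(coh$labels, 5, seed = 1)
  tr <- fold != 1
  m <- train_multiclass_lr(X[tr, ], coh$labels[tr], k_folds = 3, seed = 1,
                           class_names = coh$class_names)
  acc <- mean(predict_argmax(m, X[!tr, ]) == coh$labels[!tr])
  baseline <- max(table(coh$labels[!tr])) / sum(!tr)   # counting oracle
  expect_gt(acc, baseline)
})

test_that("one-vs-rest binary models are relabeled correctly and recall matches positive rate", {
  coh <- reference_cohort()
  fm <- build_feature_matrix(coh, 500)
  sel <- select_top_features(chi_square_scores(fm, coh$labels), 60)
  X <- fm[, sel]
  y <- unname(coh$labels)
  bms <- train_binary_models(X, y, lambda_grid = 10^seq(-3, 1, length.out = 5),
                             k_folds = 3, seed = 1,
                             class_names = coh$class_names)
  expect_length(bms, 3)
  expect_named(bms, coh$class_names)
  for (k in 0:2) {
    ev <- evaluate_model(bms[[k + 1]], X, as.integer(y == k))
    # applied to a pure-class-k set, the positive rate is the model's recall
    pure <- X[y == k, , drop = FALSE]
    pos_rate <- mean(predict_argmax(bms[[k + 1]], pure) == 1L)
    recall_k <- sum(predict_argmax(bms[[k + 1]], X) == 1L & y == k) / sum(y == k)
    expect_equal(pos_rate, recall_k)
  }
  expect_error(train_binary_models(X, rep(0L, nrow(X))), "at least two classes")
})

test_that("evaluation metrics match hand computation and known endpoints", {
  # hand-built 4-sample score table: AUC equals the rank-sum oracle
  score <- c(0.9, 0.4, 0.6, 0.1)
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(helr:::rank_auc(score, pos), oracle_auc(score, pos))
  expect_equal(helr:::rank_auc(score, pos), 1)      # separable ordering
  score2 <- c(0.9, 0.6, 0.4, 0.1)
  pos2 <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(helr:::rank_auc(score2, pos2), oracle_auc(score2, pos2))
  expect_equal(helr:::rank_auc(score2, pos2), 0.75)

  # perfect scores give MAUC 1; label-independent scores give ~0.5
  set.seed(6)
  y <- rep(0:2, each = 40)
  perfect <- diag(3)[y + 1, ] + matrix(runif(360, 0, 0.1), 120, 3)
  rep1 <- helr:::eval_report(y, max.col(perfect, "first") - 1L, perfect)
  expect_equal(rep1$mauc, 1)
  expect_equal(rep1$accuracy, 1)
  rand <- matrix(runif(360), 120, 3)
  rep2 <- helr:::eval_report(y, max.col(rand, "first") - 1L, rand)
  expect_lt(abs(rep2$mauc - 0.5), 0.06)
})

test_that("the feature-count sweep reuses folds and reflects nested selections", {
  coh <- reference_cohort()
  fm <- build_feature_matrix(coh, 500)
  sc <- chi_square_scores(fm, coh$labels)
  # step = f gives a single row
  one <- feature_count_sweep(fm, coh$labels, scores = sc, step = ncol(fm),
                             max_f = ncol(fm),
                             lambda_grid = c(0.01), k_folds = 3, seed = 1)
  expect_equal(nrow(one), 1L)
  # accuracy with all planted features available >= accuracy with two features
  acc1 <- feature_count_sweep(fm, coh$labels, scores = sc, step = 2, max_f = 2,
                              lambda_grid = c(0.01), k_folds = 3, seed = 1)
  accP <- feature_count_sweep(fm, coh$labels, scores = sc, step = 60, max_f = 60,
                              lambda_grid = c(0.01), k_folds = 3, seed = 1)
  expect_gte(accP$cv_accuracy[1], acc1$cv_accuracy[1])
  expect_error(feature_count_sweep(fm, coh$labels, max_f = ncol(fm) + 1),
               "exceeds")
})

test_that("training rejects degenerate label sets", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_multiclass_lr(X, rep(0L, 10)), "single class")
})

test_that("weight normalization preserves predictions while meeting the quantizer contract", {
  set.seed(14)
  m <- helr_model(matrix(rnorm(8, sd = 3), 2, 4), rnorm(2), 0.1,
                  c("a", "b"), paste0("f", 1:4))
  nm <- normalize_model_weights(m)
  expect_lt(max(abs(nm$weights)), 1)
  X <- matrix(runif(40, 0, 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(predict_argmax(nm, X), predict_argmax(m, X))
})
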