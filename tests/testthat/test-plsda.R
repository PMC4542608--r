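# Mann-Whitney pair-counting AUC, the independent ROC oracle
pair_count_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(pairs)
}

test_that("NIPALS weights align with the cross-covariance SVD and separate toy clouds", {
  set.seed(2)
  X <- rbind(matrix(stats::rnorm(20, 0), 5, 4),
             matrix(stats::rnorm(20, 6), 5, 4))
  lab <- rep(c("a", "b"), each = 5)
  m <- plsda_fit(X, lab, 1)
  pr <- plsda_predict(m, X)
  expect_equal(as.character(pr$class), lab)

  Xc <- scale(X, scale = FALSE)
  Y <- cbind(as.numeric(lab == "a"), as.numeric(lab == "b"))
  Yc <- scale(Y, scale = FALSE)
  u1 <- svd(crossprod(Xc, Yc))$u[, 1]
  cosine <- abs(sum(m$x_weights[, 1] * u1))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("predictions match the mixOmics reference implementation", {
  set.seed(42)
  X <- matrix(stats::rnorm(60), 6, 10,
              dimnames = list(NULL, paste0("V", 1:10)))
  lab <- factor(rep(c("a", "b"), each = 3))
  m <- plsda_fit(X, lab, 2)
  pr <- plsda_predict(m, X)
  ref <- mixOmics::plsda(X, lab, ncomp = 2, scale = FALSE)
  ref_pred <- predict(ref, X)$predict[, , 2]
  expect_equal(unname(pr$scores), unname(ref_pred), tolerance = 1e-6)

  # successive score vectors are mutually orthogonal
  gram <- crossprod(m$scores)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
})

test_that("prediction obeys the centering identity and row equivariance", {
  set.seed(7)
  X <- matrix(stats::rnorm(80), 8, 10)
  lab <- rep(c("a", "b"), 4)
  m <- plsda_fit(X, lab, 2)

  Xmean <- matrix(m$x_mean, 3, 10, byrow = TRUE)
  pr <- plsda_predict(m, Xmean)
  for (i in 1:3) expect_equal(unname(pr$scores[i, ]), unname(m$y_mean))

  perm <- sample(nrow(X))
  expect_equal(plsda_predict(m, X[perm, ])$scores,
               plsda_predict(m, X)$scores[perm, ])
  expect_error(plsda_predict(m, X[, 1:5]), "channel mismatch")
})

test_that("degenerate fits are rejected", {
  X <- matrix(stats::rnorm(40), 4, 10)
  expect_error(plsda_fit(X, rep("a", 4), 1), "two classes")
  expect_error(plsda_fit(X, c("a", "a", "b", "b"), 5), "rank")
})

test_that("resampled evaluation is deterministic and never leaks sites", {
  x <- default_screened()
  plan <- resampling_plan(n_iterations = 3, rng_seed = 99)
  e1 <- balanced_resample_evaluate(x$d, x$a, plan, n_latent = 3)
  e2 <- balanced_resample_evaluate(x$d, x$a, plan, n_latent = 3)
  expect_identical(e1$per_iteration, e2$per_iteration)
  expect_identical(e1$class_rates, e2$class_rates)
  expect_true(e1$split_disjoint)
  # confusion rows sum to the per-class test counts
  for (cm in e1$per_iteration) expect_true(all(rowSums(cm) > 0))
})

test_that("the random-label negative control collapses to chance", {
  x <- default_screened()
  plan <- resampling_plan(n_iterations = 100, rng_seed = 17)
  nc3 <- negative_control(x$d, x$a, plan, n_latent = 3)
  expect_lt(abs(nc3$overall_rate - 1 / 3), 0.05)

  two <- x$a[x$a$assigned_class != "nonmineralized_myringosclerosis", ]
  nc2 <- negative_control(x$d, two,
                          resampling_plan(n_iterations = 100, rng_seed = 18),
                          n_latent = 3)
  expect_lt(abs(nc2$overall_rate - 1 / 2), 0.05)
})

test_that("forcing the identity permutation reproduces the plain evaluation", {
  x <- default_screened()
  plan <- resampling_plan(n_iterations = 5, rng_seed = 41)
  plain <- balanced_resample_evaluate(x$d, x$a, plan, n_latent = 3)
  forced <- balanced_resample_evaluate(x$d, x$a, plan, n_latent = 3,
                                       .permute_labels = identity)
  expect_identical(plain$per_iteration, forced$per_iteration)
})

test_that("ROC points and AUC agree with the pair-count oracle and pROC", {
  # perfectly separating scores
  perfect <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(perfect$auc, 1)

  # hand example: pair counting gives 3 of 4 concordant pairs
  hand <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(hand$auc, 0.75)
  expect_identical(pair_count_auc(c(0.1, 0.4, 0.35, 0.8),
                                  c(FALSE, FALSE, TRUE, TRUE)), 0.75)

  # label-independent scores sit near 0.5; cross-check against pROC
  set.seed(12)
  sc <- stats::rnorm(2000)
  tr <- rep(c(TRUE, FALSE), 1000)
  r <- roc_curve(sc, tr)
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_equal(r$auc, as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                             levels = c(FALSE, TRUE),
                                             direction = "<"))),
               tolerance = 1e-10)
  expect_equal(r$auc, pair_count_auc(sc, tr), tolerance = 1e-10)
  # monotone curve with fixed endpoints
  expect_false(is.unsorted(r$points$fpr))
  expect_false(is.unsorted(r$points$tpr))
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(r$points[nrow(r$points), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)

  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("binary diagnostic metrics follow their definitions", {
  m <- binary_metrics(matrix(c(9, 1, 1, 9), 2, 2, byrow = TRUE))
  expect_equal(unlist(m[c("ppv", "npv", "sensitivity", "specificity",
                          "accuracy")]),
               c(ppv = 0.9, npv = 0.9, sensitivity = 0.9, specificity = 0.9,
                 accuracy = 0.9))

  perfect <- binary_metrics(matrix(c(7, 0, 0, 13), 2, 2, byrow = TRUE))
  expect_true(all(unlist(perfect[1:5]) == 1))

  m2 <- binary_metrics(matrix(c(95, 5, 1, 99), 2, 2, byrow = TRUE))
  expect_equal(m2$ppv, 95 / 96)
  expect_equal(m2$sensitivity, 0.95)
  expect_equal(m2$accuracy, 194 / 200)

  # zero denominators are undefined, not zero
  degenerate <- binary_metrics(matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE))
  expect_true(is.na(degenerate$sensitivity))
  expect_true(is.na(degenerate$ppv) || degenerate$ppv >= 0)
})

test_that("cross-validated latent-variable choice returns a sane count", {
  set.seed(33)
  X <- rbind(matrix(stats::rnorm(100, 0), 10, 10),
             matrix(stats::rnorm(100, 3), 10, 10))
  lab <- rep(c("a", "b"), each = 10)
  k <- choose_n_latent(X, lab, max_latent = 5, folds = 5, seed = 1)
  expect_gte(k, 1L)
  expect_lte(k, 5L)
})
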