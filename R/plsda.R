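#' Fit a PLS-DA model by the NIPALS recursion
#'
#' Partial least squares discriminant analysis: the class labels are one-hot
#' encoded into a response matrix Y, X and Y are column-centered, and latent
#' variables are extracted one at a time by the NIPALS PLS2 recursion —
#' iterate `w = E'u / |E'u|`, `t = E w`, `q = F't / t't`, `u = F q / q'q`
#' to convergence, then deflate `E <- E - t p'` with `p = E't / t't` and
#' `F <- F - t q'`. The regression coefficients
#' `B = W (P'W)^{-1} Q'` map centered spectra to centered class responses.
#'
#' @param X Numeric matrix, spectra in rows.
#' @param labels Class label per row; at least two classes must be present.
#' @param n_latent Number of latent variables, >= 1 and at most
#'   min(n - 1, p).
#' @param tol Convergence tolerance on the change of `w` (default 1e-10).
#' @param max_iter Maximum NIPALS iterations per component (default 500).
#' @return A `plsda_model`: centering vectors `x_mean`, `y_mean`; matrices
#'   `x_weights` (W), `x_loadings` (P), `y_loadings` (Q), `scores` (T);
#'   `coefficients` (channels x classes); `n_latent`; `class_order`.
#' @export
plsda_fit <- function(X, labels, n_latent, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  if (length(labels) != nrow(X)) stop("one label per row of X required")
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (n_latent < 1L || n_latent > kmax) {
    stop(sprintf("n_latent must be in 1..%d (rank bound)", kmax))
  }
  cls <- levels(labels)
  Y <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  Y[cbind(seq_len(n), as.integer(labels))] <- 1

  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  E <- sweep(X, 2L, x_mean)
  F_ <- sweep(Y, 2L, y_mean)

  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Q <- matrix(0, length(cls), n_latent)
  Tm <- matrix(0, n, n_latent)

  for (a in seq_len(n_latent)) {
    u <- F_[, which.max(colSums(F_^2))]
    w_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) {
        stop(sprintf("X residual exhausted at component %d; n_latent exceeds the effective rank", a))
      }
      w <- w / nw
      t_ <- E %*% w
      tt <- sum(t_^2)
      if (tt < .Machine$double.eps) {
        stop(sprintf("degenerate score vector at component %d; n_latent exceeds the effective rank", a))
      }
      q <- crossprod(F_, t_) / tt
      u <- F_ %*% q / sum(q^2)
      if (!is.null(w_old) && sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    p_ <- crossprod(E, t_) / tt
    E <- E - t_ %*% t(p_)
    F_ <- F_ - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tm[, a] <- t_
  }

  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  colnames(B) <- cls
  structure(
    list(x_mean = x_mean, y_mean = y_mean, x_weights = W, x_loadings = P,
         y_loadings = Q, scores = Tm, coefficients = B,
         n_latent = n_latent, class_order = cls),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d latent variables, classes: %s\n",
              x$n_latent, paste(x$class_order, collapse = ", ")))
  invisible(x)
}

#' Predict classes from a fitted PLS-DA model
#'
#' Continuous responses are `(X - x_mean) B + y_mean`, one column per class;
#' the hard label is the argmax, ties broken by `class_order`.
#'
#' @param m A `plsda_model`.
#' @param X Matrix of spectra (rows); channel count must match the training
#'   data.
#' @return List with `class` (factor with the model's class order) and
#'   `scores` (continuous response matrix).
#' @export
plsda_predict <- function(m, X) {
  stopifnot(inherits(m, "plsda_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_mean)) {
    stop(sprintf("channel mismatch: model has %d channels, X has %d",
                 length(m$x_mean), ncol(X)))
  }
  Yhat <- sweep(X, 2L, m$x_mean) %*% m$coefficients
  Yhat <- sweep(Yhat, 2L, m$y_mean, `+`)
  hard <- m$class_order[max.col(Yhat, ties.method = "first")]
  list(class = factor(hard, levels = m$class_order), scores = Yhat)
}

#' Choose the number of latent variables by cross-validation
#'
#' Stratified k-fold cross-validated overall accuracy over `1..max_latent`
#' latent variables; the smallest count within floor of the best mean
#' accuracy wins (parsimony on ties).
#'
#' @param X Spectra matrix.
#' @param labels Class labels.
#' @param max_latent Largest candidate (default 10, capped at the rank
#'   bound).
#' @param folds Number of folds (default 5).
#' @param seed Optional seed for the fold assignment.
#' @return Integer: chosen number of latent variables.
#' @export
choose_n_latent <- function(X, labels, max_latent = 10L, folds = 5L,
                            seed = NULL) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  kmax <- min(max_latent, n - ceiling(n / folds) - 1L, ncol(X))
  if (kmax < 1L) stop("too few spectra for cross-validation")
  fold <- integer(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  acc <- matrix(NA_real_, folds, kmax)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (nlevels(droplevels(labels[tr])) < 2L || sum(!tr) == 0L) next
    m_full <- try(plsda_fit(X[tr, , drop = FALSE], labels[tr], kmax),
                  silent = TRUE)
    if (inherits(m_full, "try-error")) next
    for (a in seq_len(kmax)) {
      m_a <- m_full
      keep <- seq_len(a)
      m_a$x_weights <- m_full$x_weights[, keep, drop = FALSE]
      m_a$x_loadings <- m_full$x_loadings[, keep, drop = FALSE]
      m_a$y_loadings <- m_full$y_loadings[, keep, drop = FALSE]
      m_a$coefficients <- m_a$x_weights %*%
        solve(crossprod(m_a$x_loadings, m_a$x_weights)) %*% t(m_a$y_loadings)
      colnames(m_a$coefficients) <- m_full$class_order
      m_a$n_latent <- a
      pr <- plsda_predict(m_a, X[!tr, , drop = FALSE])
      acc[f, a] <- mean(pr$class == labels[!tr])
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  best <- max(mean_acc)
  as.integer(which(mean_acc >= best - 1e-12)[1L])
}

#' Describe the balanced resampling scheme
#'
#' @param n_iterations Number of resampling iterations (default 100).
#' @param train_fraction Fraction of each class's sites used for training
#'   (default 0.6).
#' @param balance Downsample every class to the smallest class's site count
#'   each iteration (default TRUE).
#' @param rng_seed Optional integer seed; equal seeds give identical
#'   reports.
#' @return A `resampling_plan`.
#' @export
resampling_plan <- function(n_iterations = 100L, train_fraction = 0.6,
                            balance = TRUE, rng_seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(
    list(n_iterations = as.integer(n_iterations),
         train_fraction = train_fraction, balance = balance,
         split_unit = "site", rng_seed = rng_seed),
    class = "resampling_plan"
  )
}

#' Class-balanced resampled PLS-DA evaluation with leave-sites-out splitting
#'
#' Per iteration: (i) optionally downsample each class at site granularity to
#' the smallest class's site count; (ii) split each class's sites
#' `train_fraction` / rest into train and test, so no site ever contributes
#' to both; (iii) fit PLS-DA on the training spectra and predict the test
#' spectra; (iv) accumulate the confusion matrix. Reported rates are per
#' iteration, then averaged. For two-class tasks the positive-class
#' continuous scores of all test predictions are pooled across iterations
#' for the ROC curve, and the diagnostic metrics are computed from the summed
#' confusion matrix.
#'
#' @param d A `spectral_dataset`.
#' @param assignments Data frame with `site_id` and `assigned_class`
#'   (e.g. from [screen_dataset()]); only the listed sites participate.
#' @param plan A [resampling_plan()].
#' @param n_latent Latent variables per fit (see [choose_n_latent()]).
#' @param positive_class For binary tasks, the class treated as positive;
#'   default `"mineralized_myringosclerosis"` when present, else the first
#'   class.
#' @param .permute_labels Internal hook used by [negative_control()]: when
#'   TRUE the class labels are permuted uniformly over sites each iteration
#'   (preserving class sizes); when a function, it is applied to the label
#'   vector instead (identity reproduces the unpermuted evaluation exactly).
#' @return An `evaluation_report`: `confusion` (summed), `per_iteration`
#'   (list of confusion matrices), `class_rates` (mean per-class correct
#'   rates), `overall_rate` (mean over iterations), and for binary tasks
#'   `binary` ([binary_metrics()] of the summed confusion), `roc`
#'   ([roc_curve()] points) and `auc`.
#' @export
balanced_resample_evaluate <- function(d, assignments, plan, n_latent,
                                       positive_class = NULL,
                                       .permute_labels = FALSE) {
  stopifnot(inherits(d, "spectral_dataset"),
            inherits(plan, "resampling_plan"))
  keep <- match(assignments$site_id, d$meta$site_id)
  if (anyNA(keep)) stop("assignments refer to unknown site_ids")
  X <- d$intensities[keep, , drop = FALSE]
  site <- assignments$site_id
  cls0 <- factor(assignments$assigned_class)
  classes <- levels(cls0)
  n_cls <- length(classes)
  if (n_cls < 2L) stop("need at least two classes to evaluate")
  sizes <- table(cls0)
  if (any(sizes < 2L)) {
    stop("class(es) with fewer than 2 sites: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (is.null(positive_class)) {
    positive_class <- if ("mineralized_myringosclerosis" %in% classes) {
      "mineralized_myringosclerosis"
    } else classes[1L]
  }
  if (!is.null(plan$rng_seed)) set.seed(plan$rng_seed)

  conf_sum <- matrix(0L, n_cls, n_cls, dimnames = list(truth = classes,
                                                       predicted = classes))
  per_iter <- vector("list", plan$n_iterations)
  iter_class_rates <- matrix(NA_real_, plan$n_iterations, n_cls,
                             dimnames = list(NULL, classes))
  iter_overall <- numeric(plan$n_iterations)
  roc_scores <- numeric(0)
  roc_truth <- logical(0)
  split_audit <- logical(plan$n_iterations)

  for (it in seq_len(plan$n_iterations)) {
    cls <- cls0
    if (isTRUE(.permute_labels)) {
      cls <- cls0[sample.int(length(cls0))]
    } else if (is.function(.permute_labels)) {
      cls <- .permute_labels(cls0)
    }

    active <- seq_along(site)
    if (plan$balance) {
      m <- min(table(cls))
      active <- unlist(lapply(classes, function(cl) {
        i <- which(cls == cl)
        if (length(i) > m) sample(i, m) else i
      }), use.names = FALSE)
    }
    train <- integer(0); test <- integer(0)
    for (cl in classes) {
      i <- active[cls[active] == cl]
      n_i <- length(i)
      n_tr <- max(1L, min(n_i - 1L, round(plan$train_fraction * n_i)))
      tr <- sample(i, n_tr)
      train <- c(train, tr)
      test <- c(test, setdiff(i, tr))
    }
    split_audit[it] <- length(intersect(site[train], site[test])) == 0L

    fit <- plsda_fit(X[train, , drop = FALSE], cls[train], n_latent)
    pr <- plsda_predict(fit, X[test, , drop = FALSE])
    truth <- factor(cls[test], levels = classes)
    pred <- factor(as.character(pr$class), levels = classes)
    cm <- table(truth = truth, predicted = pred)
    per_iter[[it]] <- cm
    conf_sum <- conf_sum + cm
    rs <- rowSums(cm)
    iter_class_rates[it, ] <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
    iter_overall[it] <- sum(diag(cm)) / sum(cm)
    if (n_cls == 2L) {
      roc_scores <- c(roc_scores, pr$scores[, positive_class])
      roc_truth <- c(roc_truth, truth == positive_class)
    }
  }

  rep_ <- list(
    classes = classes,
    confusion = conf_sum,
    per_iteration = per_iter,
    class_rates = colMeans(iter_class_rates, na.rm = TRUE),
    overall_rate = mean(iter_overall),
    iteration_overall_rates = iter_overall,
    split_disjoint = all(split_audit),
    n_latent = n_latent,
    plan = plan
  )
  if (n_cls == 2L) {
    pos <- positive_class
    neg <- setdiff(classes, pos)
    m2 <- matrix(c(conf_sum[pos, pos], conf_sum[pos, neg],
                   conf_sum[neg, pos], conf_sum[neg, neg]),
                 2L, 2L, byrow = TRUE,
                 dimnames = list(truth = c(pos, neg),
                                 predicted = c(pos, neg)))
    rep_$positive_class <- pos
    rep_$binary <- binary_metrics(m2)
    roc <- roc_curve(roc_scores, roc_truth)
    rep_$roc <- roc$points
    rep_$auc <- roc$auc
  }
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d iterations, %d latent variables\n",
              x$plan$n_iterations, x$n_latent))
  cat("mean per-class correct rates:\n")
  print(round(100 * x$class_rates, 1))
  cat(sprintf("mean overall correct rate: %.1f%%\n", 100 * x$overall_rate))
  if (!is.null(x$binary)) {
    b <- x$binary
    cat(sprintf("binary (positive = %s): PPV %.2f%% NPV %.2f%% SE %.2f%% SP %.2f%% OA %.2f%%, AUC %.3f\n",
                x$positive_class, 100 * b$ppv, 100 * b$npv,
                100 * b$sensitivity, 100 * b$specificity,
                100 * b$accuracy, x$auc))
  }
  invisible(x)
}

#' Random-label negative control
#'
#' Re-runs the full balanced resampled evaluation with class labels permuted
#' uniformly at random over sites each iteration (class sizes preserved).
#' Any genuine spectral signal is destroyed, so the mean overall correct rate
#' should collapse to chance, 1/n_classes; a higher value indicates leakage
#' in the evaluation design.
#'
#' @inheritParams balanced_resample_evaluate
#' @return An `evaluation_report` (see [balanced_resample_evaluate()]).
#' @export
negative_control <- function(d, assignments, plan, n_latent,
                             positive_class = NULL) {
  balanced_resample_evaluate(d, assignments, plan, n_latent,
                             positive_class = positive_class,
                             .permute_labels = TRUE)
}

#' Receiver operating characteristic curve and AUC
#'
#' Sweeps the decision threshold over all unique scores (equal scores grouped
#' at one threshold), computing (1 - specificity, sensitivity) at each, with
#' endpoints (0, 0) and (1, 1); the area under the curve is the trapezoid
#' rule, equal to the Mann-Whitney pair-counting statistic.
#'
#' @param scores Continuous positive-class scores.
#' @param truth Logical (or two-level) vector: TRUE/positive class per score.
#' @return List with `points` (data.frame `fpr`, `tpr`, ordered) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  if (is.factor(truth) || is.character(truth)) {
    lv <- unique(as.character(truth))
    if (length(lv) > 2L) stop("truth must be binary")
    truth <- as.character(truth) == lv[which.max(lv == as.character(truth))]
  }
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("scores/truth length mismatch")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present in truth")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t_ <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t_); fp <- cumsum(!t_)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / n_pos, 1)
  fpr <- c(0, fp[last] / n_neg, 1)
  keep <- !duplicated(cbind(fpr, tpr))
  pts <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Diagnostic metrics from a 2x2 confusion matrix
#'
#' Rows are truth, columns predictions, positive class first:
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/total. A zero denominator
#' yields `NA` (undefined), never 0.
#'
#' @param confusion 2x2 numeric matrix of nonnegative counts, rows = truth
#'   (positive first), columns = predicted (positive first).
#' @return List with `ppv`, `npv`, `sensitivity`, `specificity`, `accuracy`
#'   as fractions, plus the `confusion` matrix.
#' @export
binary_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(2L, 2L))) stop("confusion must be 2x2")
  if (any(confusion < 0)) stop("counts must be nonnegative")
  tp <- confusion[1L, 1L]; fn <- confusion[1L, 2L]
  fp <- confusion[2L, 1L]; tn <- confusion[2L, 2L]
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(ppv = safe(tp, tp + fp),
       npv = safe(tn, tn + fn),
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       accuracy = safe(tp + tn, tp + fn + fp + tn),
       confusion = confusion)
}
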