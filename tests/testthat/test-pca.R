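sign_convention <- function(v) {
  apply(v, 2, function(col) if (col[which.max(abs(col))] < 0) -col else col)
}

test_that("pca_fit matches a brute-force covariance eigensolve", {
  set.seed(3)
  X <- matrix(stats::rnorm(20), 5, 4)
  fit <- pca_fit(X, 4)

  Xc <- scale(X, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  expect_equal(unname(fit$loadings), unname(sign_convention(ev$vectors)),
               tolerance = 1e-8)
  expect_equal(unname(fit$explained_variance_fraction),
               ev$values / sum(ev$values), tolerance = 1e-8)
  expect_equal(unname(fit$scores),
               unname(Xc %*% sign_convention(ev$vectors)), tolerance = 1e-8)
})

test_that("rank-1 data concentrate variance in the first component", {
  base <- stats::rnorm(30)
  X <- outer(c(1, 2, 3, 5, 8), base)
  fit <- pca_fit(X, 2)
  expect_gte(fit$explained_variance_fraction[1], 0.999)
})

test_that("a full decomposition reconstructs the data", {
  set.seed(9)
  X <- matrix(stats::rnorm(48), 8, 6)
  k <- min(nrow(X) - 1, ncol(X))
  fit <- pca_fit(X, k)
  rec <- fit$scores %*% t(fit$loadings) +
    matrix(fit$mean_spectrum, nrow(X), ncol(X), byrow = TRUE)
  expect_lt(max(abs(rec - X)) / max(abs(X)), 1e-6)
})

test_that("fits are orthonormal with nonincreasing variance fractions", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(stats::rnorm(15 * 8), 15, 8)
    fit <- pca_fit(X, 6)
    gram <- crossprod(fit$loadings)
    expect_lt(max(abs(gram - diag(6))), 1e-8)
    expect_false(is.unsorted(rev(fit$explained_variance_fraction)))
    expect_lte(sum(fit$explained_variance_fraction), 1 + 1e-12)
  }
  expect_error(pca_fit(matrix(stats::rnorm(12), 3, 4), 3), "n_components")
})

test_that("scores are invariant to spectrum order and equivariant to channel permutation", {
  set.seed(21)
  X <- matrix(stats::rnorm(12 * 9), 12, 9)
  fit <- pca_fit(X, 4)

  perm_rows <- sample(nrow(X))
  fit_r <- pca_fit(X[perm_rows, ], 4)
  expect_equal(unname(fit_r$scores), unname(fit$scores[perm_rows, ]),
               tolerance = 1e-8)

  perm_cols <- sample(ncol(X))
  fit_c <- pca_fit(X[, perm_cols], 4)
  expect_equal(unname(fit_c$loadings), unname(fit$loadings[perm_cols, ]),
               tolerance = 1e-8)
})

test_that("per-class PCA recovers the phenotype marker bands", {
  x <- default_screened()
  models <- per_class_pca(x$d, x$a, n_components = 7)

  min_model <- models$mineralized_myringosclerosis
  expect_true(loading_has_band(min_model, 960))
  expect_true(loading_has_band(min_model, 1044))

  cho_model <- models$cholesteatoma
  expect_true(loading_has_band(cho_model, 1005))
  expect_true(loading_has_band(cho_model, 1447))
  expect_true(loading_has_band(cho_model, 1654))

  # bands absent from the generating tables are not reported
  expect_false(loading_has_band(cho_model, 1044))
  expect_false(loading_has_band(min_model, 1005))
})

test_that("per-class PCA is deterministic and validates class sizes", {
  d1 <- generate_dataset(small_config(seed = 13))
  d2 <- generate_dataset(small_config(seed = 13))
  a1 <- data.frame(site_id = d1$meta$site_id,
                   assigned_class = d1$meta$true_label)
  m1 <- per_class_pca(d1, a1, n_components = 3)
  m2 <- per_class_pca(d2, a1, n_components = 3)
  expect_identical(m1, m2)
  expect_error(per_class_pca(d1, a1, n_components = 6),
               "cholesteatoma")
})
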