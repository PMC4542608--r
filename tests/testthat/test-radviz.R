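test_that("symmetry, single-anchor mass and the hand-computed case embed correctly", {
  # equal standardized weights on symmetric anchors cancel to the origin
  scores <- cbind(c(0, 1, 0.3), c(0, 1, 0.3), c(0, 1, 0.3), c(0, 1, 0.3))
  emb <- radviz_embed(scores)
  expect_true(all(sqrt(rowSums(emb$points[2:3, ]^2)) < 1e-12))

  # all mass on one anchor lands exactly on it
  scores <- rbind(c(1, 0, 0), c(0, 1, 1), c(0, 0, 0))
  emb <- radviz_embed(scores)
  expect_equal(unname(emb$points[1, ]), unname(emb$anchors[1, ]),
               tolerance = 1e-12)

  # K = 3, anchors at 90/210/330 degrees, u = (0.5, 0.5, 0):
  # p = (a1 + a2) / 2 = ((0,1) + (-sqrt(3)/2, -1/2)) / 2
  scores <- rbind(c(0, 0, 0), c(1, 1, 1), c(0.5, 0.5, 0))
  emb <- radviz_embed(scores)
  expect_equal(unname(emb$points[3, ]), c(-sqrt(3) / 4, 0.25),
               tolerance = 1e-12)
})

test_that("all embedded points lie inside the unit disk", {
  for (seed in 1:5) {
    set.seed(seed)
    scores <- matrix(stats::rnorm(40 * 6), 40, 6)
    emb <- radviz_embed(scores)
    expect_true(all(sqrt(rowSums(emb$points^2)) <= 1 + 1e-12))
    expect_true(all(emb$normalized_scores >= 0 & emb$normalized_scores <= 1))
  }
})

test_that("rotating the anchors rotates every point identically", {
  set.seed(8)
  scores <- matrix(stats::runif(30 * 5), 30, 5)
  theta <- 0.73
  emb0 <- radviz_embed(scores)
  emb1 <- radviz_embed(scores, rotation = theta)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(unname(emb1$points), unname(emb0$points %*% t(rot)),
               tolerance = 1e-10)
})

test_that("degenerate inputs follow the documented conventions", {
  # all-zero standardized row maps to the origin
  scores <- rbind(c(0, 0), c(1, 1), c(0.4, 0.6))
  emb <- radviz_embed(scores)
  expect_equal(unname(emb$points[1, ]), c(0, 0))

  # zero-range dimension warns and contributes nothing
  expect_warning(emb2 <- radviz_embed(cbind(c(1, 1, 1), c(0, 1, 2))),
                 "zero range")
  expect_true(all(emb2$normalized_scores[, 1] == 0))

  expect_error(radviz_embed(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("anchor PCs are selected by between-class separation", {
  set.seed(5)
  n <- 30
  cls <- rep(c("a", "b", "c"), each = n / 3)
  scores <- cbind(
    PC1 = stats::rnorm(n, 0, 1),
    PC2 = stats::rnorm(n, ifelse(cls == "a", -5, ifelse(cls == "b", 0, 5)), 0.3),
    PC3 = stats::rnorm(n, 0, 1)
  )
  model <- structure(list(scores = scores), class = "pca_model")
  expect_equal(select_anchor_pcs(model, cls, 1), 2L)
  expect_equal(select_anchor_pcs(model, cls, 3), 1:3)
  expect_error(select_anchor_pcs(model, cls, 4), "k_select")

  # identical class distributions on every PC: ties resolved by PC index
  tied <- structure(list(scores = cbind(PC1 = rep(1:3, 10),
                                        PC2 = rep(1:3, 10),
                                        PC3 = rep(1:3, 10))),
                    class = "pca_model")
  expect_equal(select_anchor_pcs(tied, rep(c("a", "b"), 15), 2), c(1L, 2L))
})

test_that("the mineralized class forms a separable cluster in the disk", {
  x <- default_screened()
  pooled <- pca_fit(x$d, 7)
  sel <- select_anchor_pcs(pooled, x$a$assigned_class, 7)
  emb <- radviz_embed(pooled$scores[, sel, drop = FALSE])
  cls <- x$a$assigned_class
  centroids <- vapply(split(seq_along(cls), cls), function(i) {
    colMeans(emb$points[i, , drop = FALSE])
  }, numeric(2))
  cd <- as.matrix(stats::dist(t(centroids)))
  min_centroid_sep <- min(cd[upper.tri(cd)])
  within_min <- mean(stats::dist(
    emb$points[cls == "mineralized_myringosclerosis", , drop = FALSE]))
  expect_gt(min_centroid_sep, within_min)
})
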