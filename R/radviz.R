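#' RadViz embedding of score vectors onto the unit disk
#'
#' Radial visualization places the K score dimensions as anchors equally
#' spaced on the unit circle (anchor j at angle `2*pi*(j-1)/K + pi/2`, so the
#' first anchor points up) and each sample at the weighted mean of the anchor
#' positions, weighted by its min-max standardized scores:
#' `p = sum_j u_j a_j / sum_j u_j` with `u_j` in [0, 1]. Every point lies in
#' the convex hull of the anchors, hence inside the unit disk. A sample with
#' all standardized scores zero has an undefined weighted mean (0/0) and is
#' mapped to the origin by convention; a dimension with zero range is mapped
#' to constant 0 with a warning.
#'
#' @param scores Numeric matrix, samples x K (K >= 2), e.g. PC scores.
#' @param anchor_labels Labels of the K anchors; default the column names.
#' @param rotation Constant angle (radians) added to every anchor; rotating
#'   the anchors rotates all embedded points identically.
#' @return A `radviz_embedding`: `anchor_labels`, `anchor_angles` (radians),
#'   `anchors` (K x 2 unit vectors), `points` (samples x 2),
#'   `normalized_scores` (samples x K, in [0, 1]).
#' @export
radviz_embed <- function(scores, anchor_labels = colnames(scores),
                         rotation = 0) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (k < 2L) stop("RadViz needs at least 2 dimensions")
  if (is.null(anchor_labels)) anchor_labels <- paste0("dim", seq_len(k))

  u <- scores
  for (j in seq_len(k)) {
    rng <- range(scores[, j])
    if (rng[1] < rng[2]) {
      u[, j] <- (scores[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      warning(sprintf("dimension '%s' has zero range; mapped to constant 0",
                      anchor_labels[j]))
      u[, j] <- 0
    }
  }

  angles <- 2 * pi * (seq_len(k) - 1L) / k + pi / 2 + rotation
  anchors <- cbind(x = cos(angles), y = sin(angles))
  w <- rowSums(u)
  pts <- matrix(0, nrow = nrow(u), ncol = 2L,
                dimnames = list(rownames(scores), c("x", "y")))
  nz <- w > 0
  if (any(nz)) {
    pts[nz, ] <- (u[nz, , drop = FALSE] %*% anchors) / w[nz]
  }
  structure(
    list(anchor_labels = anchor_labels, anchor_angles = angles,
         anchors = anchors, points = pts, normalized_scores = u),
    class = "radviz_embedding"
  )
}

#' @export
print.radviz_embedding <- function(x, ...) {
  cat(sprintf("<radviz_embedding> %d points on %d anchors (%s)\n",
              nrow(x$points), length(x$anchor_labels),
              paste(x$anchor_labels, collapse = ", ")))
  invisible(x)
}

#' Select the principal components that best separate the classes
#'
#' Ranks each PC of a pooled model by the one-way variance ratio of its
#' scores (between-class sum of squares / (g - 1)) divided by
#' (within-class sum of squares / (n - g)) and returns the indices of the
#' `k_select` highest-ranked PCs, in ascending PC order. Exact ties are
#' broken in favour of the lower PC index.
#'
#' @param model A `pca_model` fitted on the pooled dataset.
#' @param classes Class label per spectrum (same order as the model scores).
#' @param k_select Number of PCs to select.
#' @return Integer vector of PC indices, ascending.
#' @export
select_anchor_pcs <- function(model, classes, k_select) {
  stopifnot(inherits(model, "pca_model"))
  scores <- model$scores
  if (length(classes) != nrow(scores)) {
    stop("classes must have one label per spectrum")
  }
  if (k_select < 1L || k_select > ncol(scores)) {
    stop(sprintf("k_select must be in 1..%d", ncol(scores)))
  }
  classes <- factor(classes)
  g <- nlevels(classes)
  n <- nrow(scores)
  fstat <- vapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]
    mu <- mean(s)
    mu_g <- tapply(s, classes, mean)
    n_g <- tabulate(classes)
    ssb <- sum(n_g * (mu_g - mu)^2)
    ssw <- sum((s - mu_g[as.integer(classes)])^2)
    if (ssw <= 0) return(Inf)
    (ssb / (g - 1)) / (ssw / (n - g))
  }, numeric(1))
  ranked <- order(-fstat, seq_along(fstat))
  sort(ranked[seq_len(k_select)])
}

#' Plot a RadViz embedding
#'
#' Base-graphics disk plot with anchors labelled on the circle.
#'
#' @param x A `radviz_embedding`.
#' @param classes Optional class label per point, used for colours.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.radviz_embedding <- function(x, classes = NULL, ...) {
  th <- seq(0, 2 * pi, length.out = 361L)
  graphics::plot(cos(th), sin(th), type = "l", asp = 1, xlab = "", ylab = "",
                 axes = FALSE, ...)
  col <- if (is.null(classes)) 1L else as.integer(factor(classes)) + 1L
  graphics::points(x$points, col = col, pch = 16, cex = 0.7)
  graphics::text(1.1 * x$anchors, labels = x$anchor_labels, cex = 0.8)
  if (!is.null(classes)) {
    cl <- levels(factor(classes))
    graphics::legend("bottomleft", legend = cl, col = seq_along(cl) + 1L,
                     pch = 16, bty = "n", cex = 0.7)
  }
  invisible(x)
}
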