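#' Principal component analysis of a spectral dataset
#'
#' Centered (not variance-scaled) PCA via [stats::prcomp()]. The broad
#' autofluorescence background is deliberately left in the data, so the
#' leading components are typically background-dominated and the sharper
#' Raman marker bands surface in later loadings; marker searches should scan
#' all retained loadings, not only PC1. Loading sign indeterminacy is
#' resolved by forcing each loading's largest-magnitude element positive.
#'
#' @param x A `spectral_dataset` or a numeric matrix with spectra in rows.
#' @param n_components Number of components K to retain, >= 1 and <=
#'   min(n_spectra - 1, n_channels).
#' @return A `pca_model`: `mean_spectrum`, `loadings` (channels x K,
#'   orthonormal), `scores` (spectra x K), `explained_variance_fraction`
#'   (length K, nonincreasing), `wavenumber` when known.
#' @export
pca_fit <- function(x, n_components) {
  wn <- NULL
  ids <- NULL
  if (inherits(x, "spectral_dataset")) {
    wn <- x$wavenumber
    ids <- x$meta$site_id
    x <- x$intensities
  }
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  kmax <- min(n - 1L, p)
  if (n_components < 1L || n_components > kmax) {
    stop(sprintf("n_components must be in 1..%d (= min(n_spectra - 1, n_channels))",
                 kmax))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # largest-magnitude element of each loading made positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(pc$sdev^2)
  frac <- (pc$sdev^2 / total_var)[seq_len(k)]
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(k))
  if (!is.null(ids)) rownames(scores) <- ids
  structure(
    list(mean_spectrum = pc$center, loadings = load, scores = scores,
         explained_variance_fraction = frac, n_components = k,
         wavenumber = wn),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d channels\n",
              x$n_components, nrow(x$loadings)))
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = " "),
      "\n")
  invisible(x)
}

#' Fit one PCA per assigned class
#'
#' Mirrors inspecting per-phenotype loadings for marker bands: the
#' mineralized class should show 960/1044 cm^-1 structure among its first
#' loadings and cholesteatoma the 1005/1447/1654 cm^-1 protein bands.
#'
#' @param d A `spectral_dataset`.
#' @param assignments Output of [screen_dataset()] (or any data.frame with
#'   `site_id` and `assigned_class`).
#' @param n_components Components per class (default 7).
#' @return Named list of [pca_fit()] models, one per class.
#' @export
per_class_pca <- function(d, assignments, n_components = 7L) {
  stopifnot(inherits(d, "spectral_dataset"))
  cls <- assignments$assigned_class[match(d$meta$site_id,
                                          assignments$site_id)]
  if (anyNA(cls)) stop("assignments missing for some site_ids")
  out <- list()
  for (cl in sort(unique(cls))) {
    idx <- which(cls == cl)
    if (length(idx) <= n_components) {
      stop(sprintf("class '%s' has %d spectra; need more than n_components = %d",
                   cl, length(idx), n_components))
    }
    out[[cl]] <- pca_fit(dataset_subset(d, idx), n_components)
  }
  out
}

#' Check whether a marker band appears in a model's loadings
#'
#' TRUE when some loading among the model's components has a local maximum
#' of |loading| within `tol` of `center` whose magnitude reaches
#' `min_magnitude` times that loading's peak magnitude. The magnitude floor
#' keeps the check meaningful: noise-dominated loadings carry local maxima
#' everywhere, but rarely near their own peak magnitude, so marker bands
#' absent from the data are not reported (verified against phenotypes
#' generated without the queried band).
#'
#' @param model A `pca_model` fitted on a dataset (so `wavenumber` is known).
#' @param center Wavenumber (cm^-1) of the expected marker band.
#' @param tol Matching tolerance (cm^-1), default 4.
#' @param min_magnitude Fraction of the loading's peak |loading| a local
#'   maximum must reach to count (default 0.8).
#' @return Logical.
#' @export
loading_has_band <- function(model, center, tol = 4, min_magnitude = 0.8) {
  stopifnot(inherits(model, "pca_model"), !is.null(model$wavenumber))
  wn <- model$wavenumber
  for (j in seq_len(model$n_components)) {
    a <- abs(model$loadings[, j])
    n <- length(a)
    i <- 2:(n - 1)
    lm <- i[a[i] >= a[i - 1] & a[i] >= a[i + 1] & a[i] >= min_magnitude * max(a)]
    if (any(abs(wn[lm] - center) <= tol)) return(TRUE)
  }
  FALSE
}
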