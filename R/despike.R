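#' Remove cosmic-ray spikes with a Hampel filter
#'
#' Cosmic rays hit the CCD as narrow (1-2 channel) positive transients far
#' above the local signal. Each channel is compared with the median of a
#' sliding window; a channel whose robust z-score
#' `|x - median| / (1.4826 * MAD)` against that window exceeds `threshold`
#' is replaced by the window median. All flags are computed on the original
#' intensities before any replacement. This is the only intensity-altering
#' preprocessing in the pipeline: the autofluorescence background is
#' deliberately left untouched and no baseline correction, smoothing or
#' normalization is performed anywhere.
#'
#' Windows are truncated at the spectrum edges so every channel is screened.
#' A window whose MAD is exactly zero (locally constant signal) flags any
#' channel deviating from the median, which is the desired behaviour for a
#' spike on a flat region.
#'
#' @param s A [raman_spectrum()].
#' @param window Odd window length in channels, >= 3 (default 21; wide
#'   enough that the windowed MAD is stable and spike-free noisy spectra are
#'   essentially never altered).
#' @param threshold Robust z-score above which a channel is declared a spike
#'   (default 8).
#' @param max_fraction Data-quality guard: if more than this fraction of
#'   channels would be replaced (default 0.02) the spectrum is presumed
#'   corrupt and an error is raised rather than silently rewriting it.
#' @return List with `spectrum` (the despiked [raman_spectrum()]) and
#'   `spikes` (integer indices of replaced channels, possibly empty).
#' @export
despike <- function(s, window = 21L, threshold = 8, max_fraction = 0.02) {
  stopifnot(inherits(s, "raman_spectrum"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3")
  }
  n <- length(s$intensity)
  if (window > n) stop("window longer than spectrum")
  if (threshold <= 0) stop("threshold must be positive")

  x <- s$intensity
  k <- (window - 1L) %/% 2L
  spikes <- integer(0)
  repl <- numeric(0)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    w <- x[lo:hi]
    med <- stats::median(w)
    sig <- 1.4826 * stats::median(abs(w - med))
    dev <- abs(x[i] - med)
    z <- if (sig > .Machine$double.eps) dev / sig else
      ifelse(dev > .Machine$double.eps, Inf, 0)
    if (z > threshold) {
      spikes <- c(spikes, i)
      repl <- c(repl, med)
    }
  }
  if (length(spikes) > max_fraction * n) {
    stop(sprintf(
      "despike would alter %d of %d channels (> %.1f%%); spectrum fails the data-quality cap",
      length(spikes), n, 100 * max_fraction))
  }
  out <- s
  out$intensity[spikes] <- repl
  list(spectrum = out, spikes = spikes)
}

#' Despike every spectrum of a dataset
#'
#' @param d A `spectral_dataset`.
#' @inheritParams despike
#' @return The dataset with despiked intensities; attribute `"spikes"` holds
#'   the per-spectrum list of replaced channel indices.
#' @export
despike_dataset <- function(d, window = 21L, threshold = 8,
                            max_fraction = 0.02) {
  stopifnot(inherits(d, "spectral_dataset"))
  spikes <- vector("list", nrow(d$intensities))
  names(spikes) <- d$meta$site_id
  for (i in seq_len(nrow(d$intensities))) {
    r <- despike(dataset_spectrum(d, i), window = window,
                 threshold = threshold, max_fraction = max_fraction)
    d$intensities[i, ] <- r$spectrum$intensity
    spikes[[i]] <- r$spikes
  }
  attr(d, "spikes") <- spikes
  d
}
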