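#' Detect a peak inside a wavenumber band
#'
#' Searches the window `[band_center - band_width/2, band_center +
#' band_width/2]` for the strongest interior local maximum and measures its
#' prominence against a straight chord drawn across the band, so the slowly
#' varying autofluorescence background cancels to first order. To keep the
#' nominal threshold meaningful on shot-noise-limited spectra, the chord
#' endpoints are each averaged over the three outermost band channels and the
#' residual is smoothed with a three-channel running mean before the maximum
#' is taken; the prominence is then compared with a robust channel-noise
#' estimate (1.4826 * MAD of first differences / sqrt(2)) from a signal-free
#' flanking window, scaled by sqrt(2/3) to the variance of the averaged
#' statistic. The peak is called only if prominence / noise exceeds
#' `snr_threshold`. Both prominence and noise scale linearly with the
#' intensity, so the decision is invariant to multiplying the spectrum by a
#' positive constant.
#'
#' Ties between equal maxima are broken in favour of the channel closer to
#' `band_center`.
#'
#' @param s A [raman_spectrum()].
#' @param band_center Band center (cm^-1), default 960 (phosphate nu1).
#' @param band_width Full band width (cm^-1), default 20.
#' @param snr_threshold Minimum prominence-to-noise ratio (default 5).
#' @param noise_window Wavenumber range used for the noise estimate
#'   (default c(1700, 1800); the long flank above the amide-I region stabilizes the estimate, and the first-difference estimator is insensitive to the smooth residual amide-I tail).
#' @return A `peak_call` list (`center`, `height_above_local_baseline`,
#'   `prominence`, `snr`, `in_band = TRUE`) or `NULL` when no peak passes.
#' @export
find_band_peak <- function(s, band_center = 960, band_width = 20,
                           snr_threshold = 5, noise_window = c(1700, 1800)) {
  stopifnot(inherits(s, "raman_spectrum"))
  lo <- band_center - band_width / 2
  hi <- band_center + band_width / 2
  wn <- s$wavenumber
  if (lo < min(wn) || hi > max(wn)) {
    stop(sprintf("band [%.1f, %.1f] not fully inside the axis", lo, hi))
  }
  idx <- which(wn >= lo & wn <= hi)
  if (length(idx) < 5L) stop("band spans fewer than 5 channels")
  y <- s$intensity[idx]
  x <- wn[idx]
  n <- length(y)

  # chord across the band, endpoints averaged over the 3 outermost channels
  m <- min(3L, n %/% 2L)
  y_lo <- mean(y[seq_len(m)]); y_hi <- mean(y[seq(n - m + 1L, n)])
  x_lo <- mean(x[seq_len(m)]); x_hi <- mean(x[seq(n - m + 1L, n)])
  chord <- y_lo + (y_hi - y_lo) * (x - x_lo) / (x_hi - x_lo)
  resid <- y - chord
  # 3-channel running mean stabilizes the max statistic against shot noise
  sm <- as.numeric(stats::filter(resid, rep(1 / 3, 3L), sides = 2L))
  sm[is.na(sm)] <- resid[is.na(sm)]

  interior <- seq(2L, n - 1L)
  cand <- interior[sm[interior] >= sm[interior - 1L] &
                     sm[interior] >= sm[interior + 1L]]
  if (length(cand) == 0L) return(NULL)
  best_prom <- max(sm[cand])
  ties <- cand[sm[cand] >= best_prom - .Machine$double.eps * abs(best_prom)]
  best <- ties[which.min(abs(x[ties] - band_center))]

  noise <- noise_sd(s, noise_window) * sqrt(2 / 3)
  prominence <- sm[best]
  snr <- if (noise > 0) prominence / noise else Inf
  if (prominence <= 0 || snr <= snr_threshold) return(NULL)
  structure(
    list(center = x[best],
         height_above_local_baseline = prominence,
         prominence = prominence, snr = snr, in_band = TRUE),
    class = "peak_call"
  )
}

# Robust channel-noise estimate from a flanking signal-free window: the
# sd of successive differences divided by sqrt(2), robustified via MAD.
# Scales linearly with the spectrum, keeping band decisions scale-free.
noise_sd <- function(s, noise_window) {
  idx <- which(s$wavenumber >= noise_window[1] &
                 s$wavenumber <= noise_window[2])
  if (length(idx) < 5L) {
    stop("noise window covers fewer than 5 channels")
  }
  d <- diff(s$intensity[idx])
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

#' Partition a dataset into the three analysis classes
#'
#' Spectra with the gross label `"cholesteatoma"` pass through unchanged;
#' every `"myringosclerosis"` spectrum is assigned
#' `"mineralized_myringosclerosis"` when [find_band_peak()] calls a phosphate
#' nu1 peak in the 20 cm^-1 band at 960 cm^-1, and
#' `"nonmineralized_myringosclerosis"` otherwise.
#'
#' @param d A `spectral_dataset` with gross labels present for all spectra.
#' @inheritParams find_band_peak
#' @return A `data.frame` with one row per spectrum: `site_id`,
#'   `gross_label`, `assigned_class`, `peak_center`, `snr`.
#' @export
screen_dataset <- function(d, band_center = 960, band_width = 20,
                           snr_threshold = 5, noise_window = c(1700, 1800)) {
  stopifnot(inherits(d, "spectral_dataset"))
  gl <- d$meta$gross_label
  if (any(is.na(gl) | !nzchar(gl) | gl == "NA")) {
    stop("unlabeled spectrum: every spectrum needs a gross_label")
  }
  known <- c("cholesteatoma", "myringosclerosis")
  if (!all(gl %in% known)) {
    stop("unknown gross label(s): ",
         paste(setdiff(unique(gl), known), collapse = ", "))
  }
  n <- nrow(d$intensities)
  assigned <- character(n)
  center <- rep(NA_real_, n)
  snr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (gl[i] == "cholesteatoma") {
      assigned[i] <- "cholesteatoma"
    } else {
      pk <- find_band_peak(dataset_spectrum(d, i), band_center = band_center,
                           band_width = band_width,
                           snr_threshold = snr_threshold,
                           noise_window = noise_window)
      if (!is.null(pk)) {
        assigned[i] <- "mineralized_myringosclerosis"
        center[i] <- pk$center
        snr[i] <- pk$snr
      } else {
        assigned[i] <- "nonmineralized_myringosclerosis"
      }
    }
  }
  data.frame(site_id = d$meta$site_id, gross_label = gl,
             assigned_class = assigned, peak_center = center, snr = snr,
             stringsAsFactors = FALSE)
}
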