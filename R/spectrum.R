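#' Construct a single-site Raman spectrum
#'
#' A `raman_spectrum` is one site's measurement: a strictly ascending
#' wavenumber axis (cm^-1), an intensity vector in detector counts of the
#' same length, and site metadata. All downstream stages consume spectra
#' through [assemble_dataset()].
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1), strictly
#'   ascending.
#' @param intensity Numeric vector of intensities (counts), same length as
#'   `wavenumber`; must be finite.
#' @param site_id,specimen_id Character identifiers for the measured site and
#'   the specimen it belongs to.
#' @param gross_label Optional gross (otoscopic) pathology label, one of
#'   `"cholesteatoma"` or `"myringosclerosis"`, or `NA`.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, site_id = NA_character_,
                           specimen_id = NA_character_,
                           gross_label = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have the same length")
  }
  if (length(wavenumber) < 2L) stop("a spectrum needs at least two channels")
  if (any(!is.finite(wavenumber))) stop("non-finite wavenumber values")
  bad <- which(!is.finite(intensity))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite intensity at channel(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber axis must be strictly ascending")
  }
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         site_id = as.character(site_id),
         specimen_id = as.character(specimen_id),
         gross_label = as.character(gross_label)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> site %s (%s), %d channels, %.0f-%.0f cm^-1\n",
              x$site_id, x$gross_label, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Assemble spectra into a dataset on a common axis
#'
#' Collects spectra measured at individual sites into a `spectral_dataset`:
#' an n_spectra x n_channels intensity matrix on one shared wavenumber axis
#' plus a metadata table. Spectra whose axes differ from the first spectrum's
#' axis by less than half the channel spacing are linearly interpolated onto
#' that axis (and the dataset is flagged as interpolated); larger differences
#' are an error, since silently regridding disparate measurements would mix
#' incompatible acquisitions.
#'
#' @param spectra List of [raman_spectrum()] objects. If `manifest` is given
#'   the list names must be the file names the manifest refers to.
#' @param manifest Optional `data.frame` with columns `file`, `specimen_id`,
#'   `site_id`, `gross_label` and optionally `true_label`; joined to the
#'   spectra by file name and overriding per-spectrum metadata.
#' @return A `spectral_dataset`: list with `wavenumber` (common axis),
#'   `intensities` (matrix, spectra in rows), `meta` (data.frame with
#'   `site_id`, `specimen_id`, `gross_label`, and `true_label` when known)
#'   and `interpolated` (logical flag).
#' @export
assemble_dataset <- function(spectra, manifest = NULL) {
  if (length(spectra) == 0L) stop("no spectra supplied")
  stopifnot(all(vapply(spectra, inherits, logical(1), "raman_spectrum")))

  if (!is.null(manifest)) {
    req <- c("file", "specimen_id", "site_id", "gross_label")
    if (!all(req %in% names(manifest))) {
      stop("manifest must have columns: ", paste(req, collapse = ", "))
    }
    files <- names(spectra)
    if (is.null(files)) stop("spectra must be named by file to join a manifest")
    idx <- match(files, manifest$file)
    if (anyNA(idx)) {
      stop("missing manifest row for file(s): ",
           paste(files[is.na(idx)], collapse = ", "))
    }
    for (i in seq_along(spectra)) {
      spectra[[i]]$site_id <- as.character(manifest$site_id[idx[i]])
      spectra[[i]]$specimen_id <- as.character(manifest$specimen_id[idx[i]])
      spectra[[i]]$gross_label <- as.character(manifest$gross_label[idx[i]])
    }
    true_label <- if ("true_label" %in% names(manifest)) {
      as.character(manifest$true_label[idx])
    } else NULL
  } else {
    true_label <- NULL
  }

  axis <- spectra[[1L]]$wavenumber
  step <- stats::median(diff(axis))
  interpolated <- FALSE
  n <- length(spectra)
  mat <- matrix(NA_real_, nrow = n, ncol = length(axis))
  for (i in seq_len(n)) {
    s <- spectra[[i]]
    if (length(s$wavenumber) == length(axis) &&
        identical(s$wavenumber, axis)) {
      mat[i, ] <- s$intensity
    } else {
      dev <- if (length(s$wavenumber) == length(axis)) {
        max(abs(s$wavenumber - axis))
      } else Inf
      if (dev < step / 2) {
        mat[i, ] <- stats::approx(s$wavenumber, s$intensity, xout = axis,
                                  rule = 2)$y
        interpolated <- TRUE
      } else {
        stop(sprintf(
          "axis of spectrum %d ('%s') deviates from the common axis by more than half a step",
          i, s$site_id))
      }
    }
  }

  site_id <- vapply(spectra, `[[`, character(1), "site_id")
  if (anyDuplicated(site_id)) {
    stop("duplicate site_id: ",
         paste(unique(site_id[duplicated(site_id)]), collapse = ", "))
  }
  meta <- data.frame(
    site_id = site_id,
    specimen_id = vapply(spectra, `[[`, character(1), "specimen_id"),
    gross_label = vapply(spectra, `[[`, character(1), "gross_label"),
    stringsAsFactors = FALSE
  )
  if (!is.null(true_label)) meta$true_label <- true_label
  rownames(mat) <- site_id

  structure(
    list(wavenumber = axis, intensities = mat, meta = meta,
         interpolated = interpolated),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d channels, %.0f-%.0f cm^-1\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$wavenumber), max(x$wavenumber)))
  if ("true_label" %in% names(x$meta)) {
    print(table(x$meta$true_label))
  } else {
    print(table(x$meta$gross_label))
  }
  invisible(x)
}

#' Extract one spectrum from a dataset
#'
#' @param d A `spectral_dataset`.
#' @param i Row index or site_id.
#' @return A [raman_spectrum()].
#' @export
dataset_spectrum <- function(d, i) {
  stopifnot(inherits(d, "spectral_dataset"))
  if (is.character(i)) i <- match(i, d$meta$site_id)
  raman_spectrum(d$wavenumber, d$intensities[i, ],
                 site_id = d$meta$site_id[i],
                 specimen_id = d$meta$specimen_id[i],
                 gross_label = d$meta$gross_label[i])
}

#' Subset a spectral dataset by row
#'
#' @param d A `spectral_dataset`.
#' @param idx Integer or logical row index, or character site_ids.
#' @return A `spectral_dataset` with the selected spectra.
#' @export
dataset_subset <- function(d, idx) {
  stopifnot(inherits(d, "spectral_dataset"))
  if (is.character(idx)) idx <- match(idx, d$meta$site_id)
  out <- d
  out$intensities <- d$intensities[idx, , drop = FALSE]
  out$meta <- d$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}
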