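#' Read a single spectrum from disk
#'
#' Reads a two-column (wavenumber cm^-1, intensity counts) CSV or TSV file,
#' or a simple JCAMP-DX file (`##XYPOINTS=(XY..XY)` or AFFN
#' `##XYDATA=(X++(Y..Y))` forms). A descending stored axis is reversed to the
#' ascending in-memory convention and the fact recorded in the `"reversed"`
#' attribute. The wavenumber axis is treated as already calibrated; no
#' intensity correction of any kind is applied here.
#'
#' @param path File path.
#' @param dialect One of `"csv"`, `"tsv"`, `"jcampdx"`; default guessed from
#'   the file extension (`.csv`, `.tsv`/`.txt`, `.jdx`/`.dx`).
#' @param site_id,specimen_id,gross_label Optional metadata (usually supplied
#'   later via the manifest in [assemble_dataset()]).
#' @return A [raman_spectrum()]; attribute `"reversed"` is `TRUE` if the file
#'   stored the axis descending.
#' @export
read_spectrum <- function(path, dialect = NULL, site_id = NA_character_,
                          specimen_id = NA_character_,
                          gross_label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dialect)) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv",
      jdx = "jcampdx", dx = "jcampdx",
      stop("cannot guess dialect from extension '", ext,
           "'; pass dialect explicitly"))
  }
  dialect <- match.arg(dialect, c("csv", "tsv", "jcampdx"))

  if (dialect == "jcampdx") {
    xy <- read_jcampdx(path)
  } else {
    sep <- if (dialect == "csv") "," else "\t"
    first <- readLines(path, n = 1L)
    has_header <- !grepl("^[-+0-9.eE\\s]+[,\t][-+0-9.eE\\s]+$", first)
    df <- utils::read.table(path, sep = sep, header = has_header,
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("expected two columns in ", path)
    x <- suppressWarnings(as.numeric(df[[1L]]))
    y <- suppressWarnings(as.numeric(df[[2L]]))
    bad <- which((is.na(x) & !is.nan(x)) | (is.na(y) & !is.nan(y)))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value in %s at data line %d", path, bad[1L]))
    }
    xy <- list(x = x, y = y)
  }

  x <- xy$x; y <- xy$y
  dx <- diff(x)
  reversed <- FALSE
  if (all(dx < 0)) {
    x <- rev(x); y <- rev(y); reversed <- TRUE
  } else if (!all(dx > 0)) {
    stop("wavenumber axis in ", path, " is not monotonic")
  }
  bad <- which(!is.finite(y))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite intensity in %s at channel %d", path, bad[1L]))
  }
  s <- raman_spectrum(x, y, site_id = site_id, specimen_id = specimen_id,
                      gross_label = gross_label)
  attr(s, "reversed") <- reversed
  s
}

# Minimal JCAMP-DX reader: XYPOINTS pair tables and AFFN (plain-number)
# X++(Y..Y) tables. XFACTOR/YFACTOR honoured; compressed (SQZ/DIF/DUP)
# encodings are out of scope.
read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(name, default = NA_real_) {
    pat <- paste0("^##", name, "=\\s*(.*)$")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) return(default)
    as.numeric(sub(pat, "\\1", hit[1L], ignore.case = TRUE))
  }
  xfac <- get_field("XFACTOR", 1)
  yfac <- get_field("YFACTOR", 1)

  start <- grep("^##(XYPOINTS|XYDATA)=", lines, ignore.case = TRUE)
  if (length(start) == 0L) stop("no XYPOINTS or XYDATA block in ", path)
  start <- start[1L]
  is_pairs <- grepl("^##XYPOINTS", lines[start], ignore.case = TRUE)
  end <- grep("^##", lines[seq(start + 1L, length(lines))])[1L]
  end <- if (is.na(end)) length(lines) else start + end - 1L
  body <- lines[seq(start + 1L, end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("empty data block in ", path)

  if (is_pairs) {
    toks <- unlist(strsplit(paste(body, collapse = " "), "[,;[:space:]]+"))
    toks <- toks[nzchar(toks)]
    v <- as.numeric(toks)
    if (anyNA(v) || length(v) %% 2L != 0L) {
      stop("malformed XYPOINTS block in ", path)
    }
    x <- v[seq(1L, length(v), 2L)] * xfac
    y <- v[seq(2L, length(v), 2L)] * yfac
  } else {
    rows <- lapply(body, function(ln) {
      toks <- unlist(strsplit(trimws(ln), "[,[:space:]]+"))
      v <- as.numeric(toks[nzchar(toks)])
      if (anyNA(v) || length(v) < 2L) stop("malformed XYDATA line in ", path)
      v
    })
    x0 <- vapply(rows, `[`, numeric(1), 1L)
    ny <- vapply(rows, length, integer(1)) - 1L
    deltax <- get_field("DELTAX")
    if (is.na(deltax)) {
      if (length(rows) > 1L) {
        deltax <- (x0[2L] - x0[1L]) / ny[1L]
      } else {
        lastx <- get_field("LASTX")
        deltax <- (lastx / xfac - x0[1L]) / (ny[1L] - 1L)
      }
    } else {
      deltax <- deltax / xfac
    }
    x <- unlist(mapply(function(a, k) a + deltax * (seq_len(k) - 1L),
                       x0, ny, SIMPLIFY = FALSE)) * xfac
    y <- unlist(lapply(rows, `[`, -1L)) * yfac
  }
  list(x = x, y = y)
}

#' Write a dataset as two-column CSV files plus a manifest
#'
#' One `wavenumber_cm-1,intensity` CSV per spectrum, a tab-separated manifest
#' (`file`, `specimen_id`, `site_id`, `gross_label`, `true_label`) and, when
#' the dataset carries a generating configuration, that configuration as
#' YAML.
#'
#' @param d A `spectral_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "spectral_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(d$meta$site_id, ".csv")
  for (i in seq_len(nrow(d$intensities))) {
    df <- data.frame(check.names = FALSE,
                     `wavenumber_cm-1` = d$wavenumber,
                     intensity = d$intensities[i, ])
    utils::write.csv(df, file.path(dir, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  man <- cbind(data.frame(file = files, stringsAsFactors = FALSE), d$meta)
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cfg <- attr(d, "config")
  if (!is.null(cfg)) {
    yaml::write_yaml(config_as_list(cfg), file.path(dir, "config.yaml"))
  }
  invisible(man_path)
}

#' Read a dataset written by [write_dataset()] (or any manifest + files)
#'
#' @param manifest Path to a manifest TSV, or a directory containing
#'   `manifest.tsv`.
#' @param dialect Spectrum file dialect passed to [read_spectrum()].
#' @return A `spectral_dataset`.
#' @export
read_dataset <- function(manifest, dialect = NULL) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.tsv")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  spectra <- lapply(man$file, function(f) {
    read_spectrum(file.path(dir, f), dialect = dialect)
  })
  names(spectra) <- man$file
  assemble_dataset(spectra, manifest = man)
}
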