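#' Specify a single Raman band
#'
#' @param center Band center (cm^-1).
#' @param amplitude Relative intensity, >= 0 (dimensionless; converted to
#'   counts via the phenotype's `band_scale`).
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @param shape `"lorentzian"` (default; sharp mineral/protein modes) or
#'   `"gaussian"` (broad amide-I envelope).
#' @param role Optional substitution role for apatite bands: `"nu1_main"`
#'   (960 cm^-1, broadens with substitution), `"nu3"` (1044 cm^-1, grows with
#'   substitution) or `"nu1_shoulder"` (948 cm^-1, resolved only in the
#'   pure-apatite limit).
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, amplitude, fwhm,
                      shape = c("lorentzian", "gaussian"), role = NA_character_) {
  shape <- match.arg(shape)
  if (!is.na(role)) {
    role <- match.arg(role, c("nu1_main", "nu3", "nu1_shoulder"))
  }
  if (amplitude < 0) stop("band amplitude must be >= 0")
  if (fwhm <= 0) stop("band fwhm must be > 0")
  structure(list(center = center, amplitude = amplitude, fwhm = fwhm,
                 shape = shape, role = role), class = "band_spec")
}

#' Define a tissue phenotype's spectral forward model
#'
#' A phenotype is a set of Raman bands on top of a broad autofluorescence
#' background. The background is a low-order polynomial in the normalized
#' wavenumber, scaled to counts by `baseline_scale`; it must be nonnegative
#' over any axis it is rendered on. For the mineralized phenotype the scalar
#' `substitution_degree` d in [0, 1] models carbonate/silicate substitution of
#' the apatite lattice: the 960 cm^-1 nu1 band broadens as
#' `fwhm * (1 + kappa * d)`, the 1044 cm^-1 nu3 amplitude scales as
#' `amplitude * d`, and the 948 cm^-1 nu1 shoulder as `amplitude * (1 - d)`,
#' so d = 0 is the sharp pure-apatite limit with a resolved 948 shoulder and
#' no nu3 intensity.
#'
#' @param label One of `"cholesteatoma"`, `"mineralized_myringosclerosis"`,
#'   `"nonmineralized_myringosclerosis"`.
#' @param bands List of [band_spec()] objects.
#' @param substitution_degree Substitution degree d in [0, 1]; ignored for
#'   bands without a substitution role.
#' @param substitution_kappa Broadening rate of the nu1 band per unit d
#'   (default 1.5).
#' @param baseline_coefficients Polynomial coefficients (ascending powers of
#'   the axis normalized to [0, 1]) of the autofluorescence background.
#' @param baseline_scale Background amplitude in counts.
#' @param band_scale Counts per unit relative band amplitude.
#' @return A `phenotype_model`.
#' @export
phenotype_model <- function(label, bands, substitution_degree = NA_real_,
                            substitution_kappa = 1.5,
                            baseline_coefficients = c(1.0, 1.2, -1.4, 0.4),
                            baseline_scale = 400, band_scale = 300) {
  label <- match.arg(label, c("cholesteatoma", "mineralized_myringosclerosis",
                              "nonmineralized_myringosclerosis"))
  stopifnot(all(vapply(bands, inherits, logical(1), "band_spec")))
  if (!is.na(substitution_degree) &&
      (substitution_degree < 0 || substitution_degree > 1)) {
    stop("substitution_degree must be in [0, 1]")
  }
  if (baseline_scale < 0) stop("baseline_scale must be >= 0")
  structure(
    list(label = label, bands = bands,
         substitution_degree = substitution_degree,
         substitution_kappa = substitution_kappa,
         baseline_coefficients = baseline_coefficients,
         baseline_scale = baseline_scale, band_scale = band_scale),
    class = "phenotype_model"
  )
}

#' Default phenotype models
#'
#' Loads the versioned band table shipped with the package
#' (`extdata/phenotype_bands.yaml`) describing the three phenotypes:
#' cholesteatoma (keratin/collagen protein bands at 956, 1005, 1032, 1128,
#' 1447, 1654 and ~1680 cm^-1), mineralized myringosclerosis (apatite
#' phosphate bands at 948/960/1044 plus 748 cm^-1 and weak connective-tissue
#' bands) and non-mineralized myringosclerosis (weak protein bands with faint
#' 960/1048 mineral traces).
#'
#' @param path Alternative band-table YAML; default the shipped one.
#' @return Named list of [phenotype_model()] objects.
#' @export
default_phenotype_models <- function(path = system.file(
    "extdata", "phenotype_bands.yaml", package = "otoraman")) {
  tab <- yaml::read_yaml(path)
  out <- lapply(names(tab$phenotypes), function(lbl) {
    ph <- tab$phenotypes[[lbl]]
    bands <- lapply(ph$bands, function(b) {
      band_spec(b$center, b$amplitude, b$fwhm,
                shape = if (is.null(b$shape)) "lorentzian" else b$shape,
                role = if (is.null(b$role)) NA_character_ else b$role)
    })
    phenotype_model(
      label = lbl, bands = bands,
      substitution_degree = if (is.null(ph$substitution_degree)) NA_real_
                            else ph$substitution_degree,
      substitution_kappa = tab$substitution_kappa,
      baseline_coefficients = unlist(tab$baseline_coefficients),
      baseline_scale = ph$baseline_scale,
      band_scale = tab$band_scale)
  })
  names(out) <- names(tab$phenotypes)
  out
}

# Evaluate one band profile on the axis, after applying the substitution
# mapping of the mineral phase.
band_profile <- function(b, axis, substitution_degree, kappa) {
  amp <- b$amplitude
  fwhm <- b$fwhm
  d <- substitution_degree
  if (!is.na(b$role) && !is.na(d)) {
    if (b$role == "nu1_main") fwhm <- fwhm * (1 + kappa * d)
    if (b$role == "nu3") amp <- amp * d
    if (b$role == "nu1_shoulder") amp <- amp * (1 - d)
  }
  half <- fwhm / 2
  if (b$shape == "lorentzian") {
    amp / (1 + ((axis - b$center) / half)^2)
  } else {
    amp * exp(-log(2) * ((axis - b$center) / half)^2)
  }
}

#' Render a noise-free phenotype spectrum
#'
#' Sum of the phenotype's band profiles over its autofluorescence background,
#' evaluated on `axis`. Deterministic; noise and specimen variation are added
#' by [generate_dataset()].
#'
#' @param model A [phenotype_model()].
#' @param axis Strictly ascending wavenumber grid (cm^-1).
#' @return A [raman_spectrum()] with `site_id` `"clean"`.
#' @export
render_clean_spectrum <- function(model, axis) {
  stopifnot(inherits(model, "phenotype_model"))
  if (any(diff(axis) <= 0)) stop("axis must be strictly ascending")
  lo <- min(axis); hi <- max(axis)
  for (b in model$bands) {
    if (b$center < lo || b$center > hi) {
      stop(sprintf("band at %.1f cm^-1 lies outside the axis [%.1f, %.1f]",
                   b$center, lo, hi))
    }
  }
  t <- (axis - lo) / (hi - lo)
  baseline <- model$baseline_scale *
    drop(outer(t, seq_along(model$baseline_coefficients) - 1L, `^`) %*%
           model$baseline_coefficients)
  if (any(baseline < 0)) {
    stop("autofluorescence baseline is negative over the axis")
  }
  y <- baseline
  for (b in model$bands) {
    y <- y + model$band_scale *
      band_profile(b, axis, model$substitution_degree, model$substitution_kappa)
  }
  raman_spectrum(axis, y, site_id = "clean",
                 gross_label = gross_label_of(model$label))
}

gross_label_of <- function(true_label) {
  ifelse(true_label == "cholesteatoma", "cholesteatoma", "myringosclerosis")
}

#' Configure the synthetic-data generator
#'
#' The generator draws, per phenotype, `n_specimens_per_class` specimens with
#' a log-normal specimen-level amplitude multiplier (standard deviation
#' `specimen_effect_sd` on the log scale, drawn once per specimen) and
#' `n_sites_per_specimen` measured sites per specimen. Within a specimen the
#' only site-to-site variation is measurement noise, so between-specimen
#' variation dominates within-specimen variation, as replicate measurements
#' on tissue sites show. Shot noise is Poisson on the total counts per
#' channel; cosmic-ray spikes are planted per spectrum with a Poisson count,
#' a width of 1-2 channels and a uniform amplitude.
#'
#' @param axis_start,axis_end,axis_step Wavenumber grid (cm^-1); default
#'   600-1800 at 2 cm^-1, the fingerprint region covering all modelled bands.
#' @param phenotypes Named list of [phenotype_model()]s; default
#'   [default_phenotype_models()].
#' @param n_specimens_per_class,n_sites_per_specimen Sampling design
#'   (defaults 4 and 10).
#' @param specimen_effect_sd Log-scale sd of the specimen amplitude
#'   multiplier (default 0.25).
#' @param shot_noise Apply Poisson noise to total counts (default TRUE).
#' @param spike_rate Expected cosmic-ray spikes per spectrum (default 1).
#' @param spike_amplitude_range Spike amplitude range in counts
#'   (default 500-3000).
#' @param rng_seed Integer seed; equal seeds give bit-identical datasets.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(axis_start = 600, axis_end = 1800,
                              axis_step = 2,
                              phenotypes = default_phenotype_models(),
                              n_specimens_per_class = 4L,
                              n_sites_per_specimen = 10L,
                              specimen_effect_sd = 0.25,
                              shot_noise = TRUE,
                              spike_rate = 1,
                              spike_amplitude_range = c(500, 3000),
                              rng_seed = 1L) {
  if (axis_start >= axis_end) stop("axis_start must be < axis_end")
  if (axis_step <= 0) stop("axis_step must be > 0")
  if (n_specimens_per_class < 1L || n_sites_per_specimen < 1L) {
    stop("specimen and site counts must be >= 1")
  }
  if (spike_rate < 0) stop("spike_rate must be >= 0")
  if (specimen_effect_sd < 0) stop("specimen_effect_sd must be >= 0")
  stopifnot(length(spike_amplitude_range) == 2L,
            spike_amplitude_range[1] <= spike_amplitude_range[2])
  structure(
    list(axis_start = axis_start, axis_end = axis_end, axis_step = axis_step,
         phenotypes = phenotypes,
         n_specimens_per_class = as.integer(n_specimens_per_class),
         n_sites_per_specimen = as.integer(n_sites_per_specimen),
         specimen_effect_sd = specimen_effect_sd,
         shot_noise = shot_noise, spike_rate = spike_rate,
         spike_amplitude_range = spike_amplitude_range,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

# Serializable view of a config (phenotypes reduced to their band tables),
# echoed into run reports and written next to generated datasets.
config_as_list <- function(cfg) {
  ph <- lapply(cfg$phenotypes, function(m) {
    list(label = m$label,
         substitution_degree = m$substitution_degree,
         substitution_kappa = m$substitution_kappa,
         baseline_scale = m$baseline_scale,
         band_scale = m$band_scale,
         baseline_coefficients = m$baseline_coefficients,
         bands = lapply(m$bands, function(b) {
           list(center = b$center, amplitude = b$amplitude, fwhm = b$fwhm,
                shape = b$shape, role = b$role)
         }))
  })
  out <- unclass(cfg)
  out$phenotypes <- ph
  out
}

#' Generate a labelled synthetic spectral dataset
#'
#' Renders each phenotype's clean spectrum, applies the specimen amplitude
#' multiplier, Poisson shot noise and cosmic-ray spikes, and assembles
#' everything into a `spectral_dataset` whose metadata carry the ground-truth
#' phenotype (`true_label`), the gross label presented to the screen, and the
#' specimen multiplier. Spike ground truth is stored in the `"spikes_truth"`
#' attribute, the generating configuration in `"config"`.
#'
#' @param config A [simulation_config()].
#' @return A `spectral_dataset`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  axis <- seq(config$axis_start, config$axis_end, by = config$axis_step)
  n_ch <- length(axis)

  spectra <- list()
  meta <- list()
  spikes_truth <- list()
  short <- c(cholesteatoma = "cho", mineralized_myringosclerosis = "min",
             nonmineralized_myringosclerosis = "nmi")

  for (lbl in names(config$phenotypes)) {
    model <- config$phenotypes[[lbl]]
    clean <- render_clean_spectrum(model, axis)$intensity
    tag <- if (lbl %in% names(short)) short[[lbl]] else substr(lbl, 1, 3)
    for (sp in seq_len(config$n_specimens_per_class)) {
      mult <- exp(stats::rnorm(1L, 0, config$specimen_effect_sd))
      specimen_id <- sprintf("%s_s%02d", tag, sp)
      for (site in seq_len(config$n_sites_per_specimen)) {
        y <- clean * mult
        if (config$shot_noise) y <- stats::rpois(n_ch, y)
        spike_ch <- integer(0)
        n_spikes <- stats::rpois(1L, config$spike_rate)
        meta_n_spikes <- n_spikes
        if (n_spikes > 0L) {
          for (j in seq_len(n_spikes)) {
            width <- sample(1:2, 1L)
            pos <- sample.int(n_ch - width + 1L, 1L)
            amp <- round(stats::runif(1L, config$spike_amplitude_range[1],
                                      config$spike_amplitude_range[2]))
            idx <- pos:(pos + width - 1L)
            y[idx] <- y[idx] + amp
            spike_ch <- union(spike_ch, idx)
          }
        }
        site_id <- sprintf("%s_t%02d", specimen_id, site)
        spectra[[site_id]] <- raman_spectrum(
          axis, y, site_id = site_id, specimen_id = specimen_id,
          gross_label = gross_label_of(lbl))
        meta[[site_id]] <- data.frame(
          site_id = site_id, true_label = lbl,
          specimen_multiplier = mult, n_spikes = meta_n_spikes,
          stringsAsFactors = FALSE)
        spikes_truth[[site_id]] <- sort(spike_ch)
      }
    }
  }

  d <- assemble_dataset(spectra)
  extra <- do.call(rbind, meta)
  stopifnot(identical(extra$site_id, d$meta$site_id))
  d$meta$true_label <- extra$true_label
  d$meta$specimen_multiplier <- extra$specimen_multiplier
  d$meta$n_spikes <- extra$n_spikes
  attr(d, "spikes_truth") <- spikes_truth
  attr(d, "config") <- config
  d
}
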