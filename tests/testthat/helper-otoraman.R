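# Shared fixtures, built in code. The default-conditions dataset is
# generated once and cached for the session, since several files exercise
# the same despiked + screened data.
.test_cache <- new.env(parent = emptyenv())

default_screened <- function() {
  if (is.null(.test_cache$d)) {
    d <- despike_dataset(generate_dataset(simulation_config()))
    .test_cache$d <- d
    .test_cache$a <- screen_dataset(d)
  }
  list(d = .test_cache$d, a = .test_cache$a)
}

flat_spectrum <- function(n = 100, level = 1000, start = 600, step = 2,
                          site_id = "s1") {
  raman_spectrum(seq(start, by = step, length.out = n), rep(level, n),
                 site_id = site_id, gross_label = "myringosclerosis")
}

lorentzian <- function(axis, center, amplitude, fwhm) {
  amplitude / (1 + ((axis - center) / (fwhm / 2))^2)
}

# small 3-class generator configuration for fast structural tests
small_config <- function(seed = 1L, ...) {
  simulation_config(n_specimens_per_class = 2L, n_sites_per_specimen = 3L,
                    rng_seed = seed, ...)
}
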