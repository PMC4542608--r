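local_maxima_at <- function(s, lo, hi) {
  y <- s$intensity
  i <- 2:(length(y) - 1L)
  lm <- i[y[i] >= y[i - 1L] & y[i] >= y[i + 1L]]
  wn <- s$wavenumber[lm]
  wn[wn >= lo & wn <= hi]
}

test_that("substitution mapping shapes the rendered mineral spectrum", {
  axis <- seq(600, 1800, 2)
  m <- default_phenotype_models()$mineralized_myringosclerosis

  m$substitution_degree <- 0.8
  s <- render_clean_spectrum(m, axis)
  expect_true(any(abs(local_maxima_at(s, 940, 980) - 960) <= 2))
  expect_true(any(abs(local_maxima_at(s, 1020, 1070) - 1044) <= 2))

  # pure-apatite limit: no nu3 intensity, resolved 948 shoulder, sharp 960
  m$substitution_degree <- 0
  s0 <- render_clean_spectrum(m, axis)
  expect_length(local_maxima_at(s0, 1034, 1054), 0L)
  expect_true(any(abs(local_maxima_at(s0, 944, 952) - 948) <= 2))
  # rendered 960 width equals the configured pure-apatite fwhm: isolate the
  # nu1 band and measure its width at half maximum on a fine grid
  iso <- m
  iso$bands <- Filter(function(b) identical(b$role, "nu1_main"), m$bands)
  iso$baseline_scale <- 0
  fine <- seq(900, 1020, 0.1)
  y <- render_clean_spectrum(iso, fine)$intensity
  half <- max(y) / 2
  width <- diff(range(fine[y >= half]))
  expect_equal(width, 8, tolerance = 0.05)
})

test_that("1044/960 height ratio is nondecreasing in substitution degree", {
  axis <- seq(600, 1800, 2)
  m <- default_phenotype_models()$mineralized_myringosclerosis
  base <- m
  base$bands <- list()
  bg <- render_clean_spectrum(base, axis)$intensity
  ratio <- vapply(seq(0, 1, length.out = 5), function(d) {
    m$substitution_degree <- d
    y <- render_clean_spectrum(m, axis)$intensity - bg
    y[match(1044, axis)] / y[match(960, axis)]
  }, numeric(1))
  expect_false(is.unsorted(ratio))
})

test_that("degenerate renderings behave as documented", {
  axis <- seq(600, 1800, 2)
  empty <- phenotype_model("cholesteatoma", list(), baseline_scale = 0)
  expect_equal(render_clean_spectrum(empty, axis)$intensity,
               rep(0, length(axis)))

  off_axis <- phenotype_model("cholesteatoma",
                              list(band_spec(500, 1, 10)))
  expect_error(render_clean_spectrum(off_axis, axis), "500")

  neg_base <- phenotype_model("cholesteatoma", list(),
                              baseline_coefficients = c(-1, 0, 0, 0))
  expect_error(render_clean_spectrum(neg_base, axis), "negative")
})

test_that("equal seeds give bit-identical datasets, different seeds differ", {
  d1 <- generate_dataset(small_config(seed = 7))
  d2 <- generate_dataset(small_config(seed = 7))
  d3 <- generate_dataset(small_config(seed = 8))
  expect_identical(d1$intensities, d2$intensities)
  expect_identical(attr(d1, "spikes_truth"), attr(d2, "spikes_truth"))
  expect_false(identical(d1$intensities, d3$intensities))
})

test_that("noiseless limit reproduces the clean spectrum times the specimen multiplier", {
  cfg <- small_config(seed = 3, shot_noise = FALSE, spike_rate = 0)
  d <- generate_dataset(cfg)
  axis <- d$wavenumber
  clean <- lapply(cfg$phenotypes, function(m) {
    render_clean_spectrum(m, axis)$intensity
  })
  for (i in seq_len(nrow(d$intensities))) {
    expected <- clean[[d$meta$true_label[i]]] * d$meta$specimen_multiplier[i]
    expect_equal(d$intensities[i, ], expected, tolerance = 0,
                 ignore_attr = TRUE)
  }
})

test_that("planted cosmic-ray spikes follow the configured Poisson rate", {
  cfg <- simulation_config(n_specimens_per_class = 4L,
                           n_sites_per_specimen = 9L,
                           spike_rate = 2, rng_seed = 5)
  d <- generate_dataset(cfg)
  expect_gte(nrow(d$intensities), 100L)
  m <- mean(d$meta$n_spikes)
  expect_gte(m, 1.5)
  expect_lte(m, 2.5)
})

test_that("intensities are nonnegative, and integers under shot noise", {
  d <- generate_dataset(small_config(seed = 2))
  expect_true(all(d$intensities >= 0))
  expect_true(all(d$intensities == round(d$intensities)))
  d0 <- generate_dataset(small_config(seed = 2, shot_noise = FALSE,
                                      spike_rate = 0))
  expect_true(all(d0$intensities >= 0))
})

test_that("within-class distances are smaller than between-class distances", {
  x <- default_screened()
  d <- x$d
  cho <- d$intensities[d$meta$true_label == "cholesteatoma", ]
  min_ <- d$intensities[d$meta$true_label == "mineralized_myringosclerosis", ]
  within <- mean(c(as.numeric(stats::dist(cho)), as.numeric(stats::dist(min_))))
  between <- mean(as.matrix(stats::dist(rbind(cho, min_)))[
    seq_len(nrow(cho)), nrow(cho) + seq_len(nrow(min_))])
  expect_lt(within, between)
})
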