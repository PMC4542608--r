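#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: `generator` (a
#' [simulation_config()] or a list of its arguments) for synthetic data, or
#' `files` (list with `manifest` path) for measured spectra. Stage parameter
#' blocks default to the package defaults. All stage seeds are derived
#' deterministically from `rng_seed`, so any stage can be replayed in
#' isolation and a rerun with the same configuration is bit-identical.
#'
#' @param generator Optional [simulation_config()] or argument list.
#' @param files Optional list with `manifest` (path to a manifest TSV).
#' @param despike List: `window`, `threshold` (see [despike()]).
#' @param screen List: `band_center`, `band_width`, `snr_threshold`
#'   (see [screen_dataset()]).
#' @param pca List: `n_components` (see [pca_fit()]).
#' @param radviz List: `k_select` (see [select_anchor_pcs()]).
#' @param plsda List: `n_iterations`, `train_fraction`, `n_latent` (NULL to
#'   choose by cross-validation on the screened data).
#' @param rng_seed Mandatory integer seed for the whole run.
#' @return A `run_config`.
#' @export
run_config <- function(generator = NULL, files = NULL,
                       despike = list(window = 21L, threshold = 8),
                       screen = list(band_center = 960, band_width = 20,
                                     snr_threshold = 5),
                       pca = list(n_components = 7L),
                       radviz = list(k_select = 7L),
                       plsda = list(n_iterations = 100L,
                                    train_fraction = 0.6, n_latent = NULL),
                       rng_seed = NULL) {
  if (is.null(rng_seed)) stop("rng_seed is mandatory")
  if (is.null(generator) == is.null(files)) {
    stop("exactly one input source (generator or files) must be set")
  }
  if (!is.null(generator) && !inherits(generator, "simulation_config")) {
    generator <- do.call(simulation_config, generator)
  }
  defaults <- formals(run_config)
  fill <- function(x, nm) utils::modifyList(eval(defaults[[nm]]), x)
  structure(
    list(generator = generator, files = files,
         despike = fill(despike, "despike"), screen = fill(screen, "screen"),
         pca = fill(pca, "pca"), radviz = fill(radviz, "radviz"),
         plsda = fill(plsda, "plsda"), rng_seed = as.integer(rng_seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# Deterministic stage seed derived from the global seed and the stage name,
# kept inside the 32-bit integer range.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Run the full decision pipeline
#'
#' Orchestrates generate/ingest -> despike -> mineral screen -> pooled and
#' per-class PCA -> RadViz embedding -> three-class balanced resampled
#' PLS-DA -> random-label negative control -> binary mineralized-vs-
#' cholesteatoma discrimination with ROC, and collects everything into a
#' machine-readable summary. With `output_dir` set, stage outputs are written
#' as TSV/JSON files; a rerun with the same configuration produces a
#' byte-identical `summary.json`.
#'
#' @param cfg A [run_config()] (or path to its YAML).
#' @param output_dir Optional output directory.
#' @return Invisibly, a list with the dataset, assignments, PCA models,
#'   embedding, the three evaluation reports and the `summary` list.
#' @export
run_pipeline <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  d <- stage("input", {
    if (!is.null(cfg$generator)) {
      gen <- cfg$generator
      gen$rng_seed <- stage_seed(cfg$rng_seed, "generate")
      generate_dataset(gen)
    } else {
      read_dataset(cfg$files$manifest)
    }
  })

  d <- stage("despike", despike_dataset(
    d, window = cfg$despike$window, threshold = cfg$despike$threshold))
  n_spiked <- sum(lengths(attr(d, "spikes")) > 0)

  assignments <- stage("screen", screen_dataset(
    d, band_center = cfg$screen$band_center,
    band_width = cfg$screen$band_width,
    snr_threshold = cfg$screen$snr_threshold))
  class_counts <- table(assignments$assigned_class)

  pooled <- stage("pca", pca_fit(d, cfg$pca$n_components))
  per_class <- stage("pca_per_class", per_class_pca(
    d, assignments, n_components = min(cfg$pca$n_components,
                                       min(class_counts) - 1L)))

  emb <- stage("radviz", {
    k_sel <- min(cfg$radviz$k_select, pooled$n_components)
    sel <- select_anchor_pcs(pooled, assignments$assigned_class, k_sel)
    radviz_embed(pooled$scores[, sel, drop = FALSE])
  })

  n_latent <- cfg$plsda$n_latent
  if (is.null(n_latent)) {
    n_latent <- stage("choose_n_latent", choose_n_latent(
      d$intensities, assignments$assigned_class,
      seed = stage_seed(cfg$rng_seed, "choose_n_latent")))
  }
  plan3 <- resampling_plan(n_iterations = cfg$plsda$n_iterations,
                           train_fraction = cfg$plsda$train_fraction,
                           rng_seed = stage_seed(cfg$rng_seed, "classify"))
  eval3 <- stage("classify", balanced_resample_evaluate(
    d, assignments, plan3, n_latent))

  plan_nc <- plan3
  plan_nc$rng_seed <- stage_seed(cfg$rng_seed, "negative_control")
  eval_nc <- stage("negative_control", negative_control(
    d, assignments, plan_nc, n_latent))

  bin_cls <- c("mineralized_myringosclerosis", "cholesteatoma")
  eval_bin <- NULL
  if (all(bin_cls %in% assignments$assigned_class)) {
    a2 <- assignments[assignments$assigned_class %in% bin_cls, , drop = FALSE]
    plan_bin <- plan3
    plan_bin$rng_seed <- stage_seed(cfg$rng_seed, "binary")
    eval_bin <- stage("binary", balanced_resample_evaluate(
      d, a2, plan_bin, n_latent,
      positive_class = "mineralized_myringosclerosis"))
  }

  summary <- list(
    rng_seed = cfg$rng_seed,
    n_spectra = nrow(d$intensities),
    n_channels = ncol(d$intensities),
    n_spectra_with_spikes_removed = n_spiked,
    class_counts = as.list(class_counts),
    n_latent = n_latent,
    three_class = list(
      class_rates_percent = as.list(round(100 * eval3$class_rates, 2)),
      overall_rate_percent = round(100 * eval3$overall_rate, 2)),
    negative_control_overall_rate_percent =
      round(100 * eval_nc$overall_rate, 2))
  if (!is.null(eval_bin)) {
    b <- eval_bin$binary
    summary$binary_mineralized_vs_cholesteatoma <- list(
      ppv_percent = round(100 * b$ppv, 2),
      npv_percent = round(100 * b$npv, 2),
      sensitivity_percent = round(100 * b$sensitivity, 2),
      specificity_percent = round(100 * b$specificity, 2),
      accuracy_percent = round(100 * b$accuracy, 2),
      auc = round(eval_bin$auc, 4))
  }
  if (!is.null(cfg$generator)) {
    summary$screen_agreement_percent <- round(
      100 * mean(assignments$assigned_class == d$meta$true_label), 2)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(assignments,
                       file.path(output_dir, "assignments.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(wavenumber = pooled$wavenumber, pooled$loadings),
      file.path(output_dir, "pca_loadings.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(site_id = rownames(pooled$scores), pooled$scores),
      file.path(output_dir, "pca_scores.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(site_id = assignments$site_id, emb$points,
                 assigned_class = assignments$assigned_class),
      file.path(output_dir, "radviz.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(eval_bin)) {
      utils::write.table(eval_bin$roc, file.path(output_dir, "roc.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    echo <- cfg
    if (!is.null(echo$generator)) {
      echo$generator <- config_as_list(echo$generator)
    }
    yaml::write_yaml(unclass(echo), file.path(output_dir, "config.yaml"))
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(dataset = d, assignments = assignments, pooled_pca = pooled,
                 per_class_pca = per_class, radviz = emb,
                 three_class = eval3, negative_control = eval_nc,
                 binary = eval_bin, summary = summary))
}
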