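# end-to-end experiment orchestration: data -> train (per size) -> analysis,
# with strict config validation, content-fingerprinted idempotent re-runs,
# and a JSON manifest

config_schema <- list(
  data = c("source", "L", "temperature", "n_samples", "burn_in", "thin",
           "method", "height", "width", "correlation_length", "pixel_count",
           "n_patches", "heldout_fraction", "seed"),
  model = c("hidden_sizes", "schedule", "epochs_per_stage", "minibatch",
            "seed"),
  analysis = c("n_bins", "mode", "n_samples_energy", "gibbs_n_keep",
               "gibbs_n_chains", "gibbs_thin", "gibbs_burn_in", "betas",
               "truncation_floor", "criticality_tol", "seed"),
  output = c("dir")
)

#' Validate an experiment configuration
#'
#' Checks section and key names against the schema (unknown keys are
#' rejected, protecting against config drift), and requires an explicit seed
#' in every stochastic section, so a config fully determines all outputs.
#'
#' @param config Nested list with sections `data`, `model`, `analysis`,
#'   `output` (see [run_experiment()]).
#' @return The config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  unknown_sections <- setdiff(names(config), names(config_schema))
  if (length(unknown_sections)) {
    abort(sprintf("Unknown config section(s): %s",
                  paste(unknown_sections, collapse = ", ")))
  }
  for (sec in c("data", "model", "analysis", "output")) {
    if (is.null(config[[sec]])) abort(sprintf("Missing config section `%s`.", sec))
    unknown <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(unknown)) {
      abort(sprintf("Unknown key(s) in `%s`: %s", sec,
                    paste(unknown, collapse = ", ")))
    }
  }
  for (sec in c("data", "model", "analysis")) {
    if (is.null(config[[sec]]$seed)) {
      abort(sprintf("Missing seed: `%s$seed` must be set explicitly.", sec))
    }
  }
  if (is.null(config$output$dir)) abort("`output$dir` must be set.")
  defaults <- list(
    data = list(source = "ising", L = 10L, temperature = 2.5,
                n_samples = 20000L, burn_in = 1000L, thin = 100L,
                method = "swendsen-wang", pixel_count = 13L,
                n_patches = 20000L, heldout_fraction = 0.2,
                height = 32L, width = 32L, correlation_length = 4),
    model = list(hidden_sizes = c(10L, 60L),
                 schedule = c(0.2, 0.1, 0.05, 0.01, 5e-3, 1e-3),
                 epochs_per_stage = 2L, minibatch = 32L),
    analysis = list(n_bins = 14L, mode = "sample", n_samples_energy = 2000L,
                    gibbs_n_keep = 20000L, gibbs_n_chains = 500L,
                    gibbs_thin = 10L, gibbs_burn_in = 500L, betas = NULL,
                    truncation_floor = 1e-5, criticality_tol = 0.2)
  )
  for (sec in names(defaults)) {
    miss <- setdiff(names(defaults[[sec]]), names(config[[sec]]))
    config[[sec]][miss] <- defaults[[sec]][miss]
  }
  invisible(config)
}

#' @rdname run_experiment
#' @param path Path to a YAML experiment configuration with the same
#'   sections as [validate_config()].
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configs requires the `yaml` package.")
  }
  validate_config(yaml::read_yaml(path))
}

stage_current <- function(manifest, name, hash, files) {
  !is.null(manifest$stages[[name]]) &&
    identical(manifest$stages[[name]]$hash, hash) &&
    all(file.exists(files))
}

#' Run a full encoding-analysis experiment
#'
#' Executes the pipeline stages: (1) synthesize stimuli (Ising patches or
#' binary textures) and split train/held-out; (2) train one RBM per hidden
#' size with CD1; (3) per model, draw Gibbs samples and compute fit quality
#' (held-out KL, sparsity, mean absolute correlation), the energy-entropy
#' profile, the hidden-codeword rank-frequency fit and, when `analysis$betas`
#' is given, the FIM spectrum sweep. Writes every intermediate artifact as
#' CSV/JSON under `output$dir` plus a manifest (config hash, per-stage wall
#' time, package version). Re-runs with an unchanged config skip completed
#' stages by content fingerprint.
#'
#' @param config Nested configuration list; see [validate_config()].
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config) {
  config <- validate_config(config)
  dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$output$dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list(stages = list())
  }
  manifest$package_version <- as.character(packageVersion("boltzcode"))
  manifest$config_hash <- rlang::hash(config)

  paths <- list(
    train = file.path(config$output$dir, "data_train.txt"),
    heldout = file.path(config$output$dir, "data_heldout.txt"),
    fit = file.path(config$output$dir, "fit_quality.csv"),
    slopes = file.path(config$output$dir, "slope_vs_size.csv")
  )
  model_path <- function(n) file.path(config$output$dir,
                                      sprintf("model_%03d.json", n))
  profile_path <- function(n) file.path(config$output$dir,
                                        sprintf("profile_%03d.csv", n))
  rankfreq_path <- function(n) file.path(config$output$dir,
                                         sprintf("rank_frequency_%03d.csv", n))
  sweep_path <- function(n) file.path(config$output$dir,
                                      sprintf("fim_sweep_%03d.csv", n))

  # ---- stage: data -------------------------------------------------------
  data_hash <- rlang::hash(config$data)
  if (!stage_current(manifest, "data", data_hash,
                     c(paths$train, paths$heldout))) {
    t0 <- proc.time()[["elapsed"]]
    d <- config$data
    source_obj <- if (d$source == "ising") {
      sample_ising(d$L, d$temperature, d$n_samples, d$burn_in, d$thin,
                   seed = d$seed, method = d$method)
    } else if (d$source == "textures") {
      generate_binary_textures(d$n_samples, d$height, d$width,
                               d$correlation_length, seed = d$seed)
    } else {
      abort(sprintf("Unknown data source `%s`.", d$source))
    }
    patches <- extract_patches(source_obj, patch_spec_for_pixels(d$pixel_count),
                               d$n_patches, seed = d$seed + 1L)
    split <- split_dataset(patches, d$heldout_fraction, seed = d$seed + 2L)
    write_pattern_dataset(split$train, paths$train)
    write_pattern_dataset(split$heldout, paths$heldout)
    manifest$stages$data <- list(hash = data_hash,
                                 files = c(paths$train, paths$heldout),
                                 seconds = proc.time()[["elapsed"]] - t0)
  }
  train <- read_pattern_dataset(paths$train)
  heldout <- read_pattern_dataset(paths$heldout)

  # ---- stage: train (per hidden size) ------------------------------------
  m <- config$model
  sizes <- as.integer(m$hidden_sizes)
  train_hash <- rlang::hash(list(config$data, config$model))
  if (!stage_current(manifest, "train", train_hash, model_path(sizes))) {
    t0 <- proc.time()[["elapsed"]]
    for (k in seq_along(sizes)) {
      fit <- train_cd1(train, sizes[[k]], schedule = m$schedule,
                       epochs_per_stage = m$epochs_per_stage,
                       minibatch = m$minibatch, seed = m$seed + k)
      write_rbm(fit, model_path(sizes[[k]]))
    }
    manifest$stages$train <- list(hash = train_hash,
                                  files = model_path(sizes),
                                  seconds = proc.time()[["elapsed"]] - t0)
  }

  # ---- stage: analysis ---------------------------------------------------
  a <- config$analysis
  an_files <- c(paths$fit, paths$slopes, profile_path(sizes),
                rankfreq_path(sizes),
                if (!is.null(a$betas)) sweep_path(sizes))
  an_hash <- rlang::hash(config[c("data", "model", "analysis")])
  if (!stage_current(manifest, "analysis", an_hash, an_files)) {
    t0 <- proc.time()[["elapsed"]]
    fit_rows <- list(); profiles <- list()
    for (k in seq_along(sizes)) {
      n <- sizes[[k]]
      model <- read_rbm(model_path(n))
      states <- gibbs_sample(model, n_keep = a$gibbs_n_keep,
                             n_chains = a$gibbs_n_chains, thin = a$gibbs_thin,
                             burn_in = a$gibbs_burn_in, seed = a$seed + k)
      kl <- model_data_kl(pattern_dataset(states$v), heldout)
      stats <- activity_stats(states)
      fit_rows[[k]] <- dplyr::mutate(stats, kl_bits = kl, n_hidden = n)
      prof <- energy_entropy_profile(model, train, n_bins = a$n_bins,
                                     mode = a$mode,
                                     n_samples = a$n_samples_energy,
                                     seed = a$seed + 100L + k)
      profiles[[k]] <- prof
      write.csv(prof$bins, profile_path(n), row.names = FALSE)
      rf <- rank_frequency(pattern_dataset(states$h))
      write.csv(dplyr::mutate(tidy.rank_frequency(rf),
                              slope = attr(rf, "slope")),
                rankfreq_path(n), row.names = FALSE)
      if (!is.null(a$betas)) {
        sw <- spectrum_sweep(model, a$betas, n_samples = a$gibbs_n_keep,
                             n_chains = a$gibbs_n_chains, thin = a$gibbs_thin,
                             burn_in = a$gibbs_burn_in,
                             truncation_floor = a$truncation_floor,
                             seed = a$seed + 200L + k)
        write.csv(sw$summary, sweep_path(n), row.names = FALSE)
      }
    }
    write.csv(dplyr::bind_rows(fit_rows), paths$fit, row.names = FALSE)
    slopes <- slope_vs_model_size(profiles,
                                  criticality_tol = a$criticality_tol)
    slopes_out <- dplyr::mutate(
      slopes,
      onset_suppression = attr(slopes, "onset_suppression"),
      onset_criticality = attr(slopes, "onset_criticality"))
    write.csv(slopes_out, paths$slopes, row.names = FALSE)
    manifest$stages$analysis <- list(hash = an_hash, files = an_files,
                                     seconds = proc.time()[["elapsed"]] - t0)
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
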