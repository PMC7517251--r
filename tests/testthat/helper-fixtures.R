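# Heavyweight fixtures shared across acceptance tests, built once per run.
# The flagship fixture follows the scaled-down study protocol: 20,000
# Swendsen-Wang samples of a 10x10 lattice at T = 2.5 (1,000 sweeps burn-in,
# thin 100), 20,000 13-pixel circular patches, and a 60-hidden-unit RBM
# trained by CD1 with the staged schedule at 2 epochs per stage, minibatch 32.

fixture_cache <- new.env(parent = emptyenv())

ising_patch_model_60 <- function() {
  if (is.null(fixture_cache$t2)) {
    lattice <- sample_ising(10, 2.5, 20000, burn_in = 1000, thin = 100,
                            seed = 101)
    patches <- extract_patches(lattice, patch_spec_for_pixels(13), 20000,
                               seed = 102)
    model <- train_cd1(patches, 60, epochs_per_stage = 2, minibatch = 32,
                       seed = 103)
    fixture_cache$t2 <- list(patches = patches, model = model)
  }
  fixture_cache$t2
}

# model-size family on Ising patches at one temperature (full CD1 schedule,
# reduced ensemble); returns per-size fit statistics and profiles
train_size_family <- function(temperature, sizes = c(5, 10, 20, 35, 60),
                              seed = 200) {
  key <- paste0("family_", temperature)
  if (is.null(fixture_cache[[key]])) {
    lattice <- sample_ising(10, temperature, 20000, burn_in = 1000,
                            thin = 100, seed = seed)
    patches <- extract_patches(lattice, patch_spec_for_pixels(13), 20000,
                               seed = seed + 1)
    sp <- split_dataset(patches, 0.2, seed = seed + 2)
    rows <- list()
    profiles <- list()
    for (k in seq_along(sizes)) {
      fit <- train_cd1(sp$train, sizes[[k]], epochs_per_stage = 8,
                       minibatch = 4, seed = seed + 10 + k)
      states <- gibbs_sample(fit, n_keep = 20000, n_chains = 500, thin = 10,
                             burn_in = 500, seed = seed + 20 + k)
      kl <- model_data_kl(pattern_dataset(states$v), sp$heldout)
      stats <- activity_stats(states)
      profiles[[k]] <- energy_entropy_profile(
        fit, sp$train, n_bins = 10, mode = "sample", n_samples = 2000,
        seed = seed + 30 + k)
      rows[[k]] <- dplyr::mutate(stats, kl_bits = kl,
                                 rf_slope = attr(
                                   rank_frequency(pattern_dataset(states$h)),
                                   "slope"))
    }
    fixture_cache[[key]] <- list(
      stats = dplyr::bind_rows(rows),
      profiles = profiles,
      slopes = slope_vs_model_size(profiles, criticality_tol = 0.2)
    )
  }
  fixture_cache[[key]]
}

# count of upward steps exceeding a noise allowance in a trend sequence
n_trend_inversions <- function(x, tol = 0) sum(diff(x) > tol)
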